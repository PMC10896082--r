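test_that("CDS translation follows the standard code with N and frame handling", {
  expect_equal(translate_cds("ATG")$sequence, "M")
  expect_equal(translate_cds("ATGTAA")$sequence, "M*")
  expect_equal(translate_cds("GATGAA")$sequence, "DE")   # the catalytic dyad
  expect_equal(translate_cds("GATGAA", frame = 2)$sequence, "M")
  expect_equal(translate_cds("ATGNNAAAAT")$sequence, "MXK")  # partial codon dropped
  expect_error(translate_cds(""), "empty")
  expect_error(translate_cds("ATGU"), "outside")
})

test_that("GH13 filter on the curated gut-enriched table gives the 14 functional sucrases", {
  tab <- gh13_table()
  expect_equal(nrow(tab), 23L)
  pass <- gh13_filter(tab)
  expect_equal(nrow(pass), 14L)
  expect_true(all(c("ENSSSA1UGG000718", "ENSSSA1UGG009974") %in% pass$gene_id))
  # the previously proposed RNAi target lacking signal peptide and dyad
  expect_false("ENSSSA1UGG000756" %in% pass$gene_id)
  # E/R dyad and residue-less rows are out even with a signal peptide
  expect_false("ENSSSA1UGG007699" %in% pass$gene_id)
  expect_false("ENSSSA1UGG001314" %in% pass$gene_id)
  expect_true(all(pass$signal_peptide))
  expect_equal(pass$fold, sort(pass$fold, decreasing = TRUE))
  # D-score threshold 0.45 separates every signal +/- annotation
  expect_true(min(tab$d_score[tab$signal_peptide]) >= 0.474)
  expect_true(max(tab$d_score[!tab$signal_peptide]) <= 0.428)
  expect_equal(nrow(gh13_filter(tab[0, ])), 0L)
})

test_that("NPA scanning agrees with a naive substring oracle", {
  expect_equal(scan_npa("MKLVW")$positions, integer(0))
  expect_false(scan_npa("MKLVW")$hg_cys)
  expect_equal(scan_npa("NPANPA")$positions, c(1L, 4L))
  s <- paste0(strrep("G", 90), "NPA", "X", "C", strrep("G", 114),
              "NPA", strrep("G", 40))
  got <- scan_npa(s)
  expect_equal(got$positions, c(91L, 210L))
  expect_true(got$hg_cys)   # C two residues after the end of box one
  set.seed(3)
  alph <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  for (i in 1:1000) {
    s <- paste(sample(c(alph, "N", "P", "A"), sample(5:60, 1), replace = TRUE),
               collapse = "")
    expect_identical(scan_npa(s)$positions, npa_oracle(s))
  }
})

test_that("water-specific classification is exact on annotated profiles and monotone", {
  profs <- aqp_profiles_from_table()
  ws <- vapply(profs, classify_water_specific, logical(1))
  names(ws) <- vapply(profs, function(p) p$gene_id, character(1))
  expect_true(ws[["ENSSSA1UGG010352"]])     # F/H/A/R with both NPA boxes
  expect_false(ws[["ENSSSA1UGG011828"]])    # F/I/S/R tetrad
  expect_false(ws[["ENSSSA1UGG001892"]])    # no motifs recorded
  # removing any single required feature flips a true profile to false
  base <- list(npa_b = 91, npa_e = 210, arR = c("F", "H", "A", "R"))
  expect_true(classify_water_specific(
    aquaporin_profile("x", base$npa_b, base$npa_e, base$arR)))
  expect_false(classify_water_specific(
    aquaporin_profile("x", NA, base$npa_e, base$arR)))
  expect_false(classify_water_specific(
    aquaporin_profile("x", base$npa_b, NA, base$arR)))
  for (k in 1:4) {
    arR <- base$arR
    arR[k] <- "G"
    expect_false(classify_water_specific(
      aquaporin_profile("x", base$npa_b, base$npa_e, arR)))
  }
  # profile construction verifies residues against a sequence
  seqv <- paste0(strrep("G", 70), "F", strrep("G", 200))
  expect_error(aquaporin_profile("x", 91, 210, c("F", "H", "A", "R"),
                                 arR_pos = c(71, 89, 207, 213),
                                 sequence = seqv), "do not match")
})

test_that("osmoregulation target selection joins filters with enrichment", {
  aqt <- aquaporin_table()
  enr <- data.frame(gene_id = aqt$gene_id, fold = aqt$fold)
  enr <- enr[!is.na(enr$fold), ]
  # at a 32-fold cut the water channel is the unique aquaporin target
  sel <- suppressWarnings(select_osmoregulation_targets(
    enr, gh13_filter(gh13_table()), aqp_profiles_from_table(), fold_min = 32))
  expect_equal(sel$gene_id[sel$class == "aquaporin"], "ENSSSA1UGG010352")
  expect_equal(sel$fold[sel$class == "aquaporin"], 32.7)
  # empty sucrase input -> no sucrase targets
  sel2 <- select_osmoregulation_targets(enr, gh13_filter(gh13_table())[0, ],
                                        aqp_profiles_from_table()[6],
                                        fold_min = 2)
  expect_equal(nrow(sel2), 0L)
  # genes missing from the enrichment table are dropped with a warning
  expect_warning(
    select_osmoregulation_targets(enr[0, ], gh13_filter(gh13_table()),
                                  list(), fold_min = 2),
    "dropped")
})

test_that("synthetic protein cohorts are recovered exactly and reproducibly", {
  syn <- synth_proteins(n = 20, planted_aqp = 1, planted_gh13 = 3, seed = 5)
  expect_identical(sort(gh13_filter(syn$gh13)$gene_id), sort(syn$truth$gh13))
  profs <- aqp_profiles_from_table(syn$aqp)
  ws <- vapply(profs, classify_water_specific, logical(1))
  ids <- vapply(profs, function(p) p$gene_id, character(1))
  expect_identical(sort(ids[ws]), sort(syn$truth$aqp))
  # planted sequence truly carries the motifs at the declared positions
  s <- syn$proteins[[syn$truth$aqp[1]]]
  got <- scan_npa(s)
  expect_equal(got$positions, c(91L, 210L))
  expect_true(got$hg_cys)
  expect_equal(substr(s, 71, 71), "F")
  expect_equal(substr(s, 207, 207), "A")
  # selection returns exactly the planted genes
  sel <- select_osmoregulation_targets(syn$enrichment, gh13_filter(syn$gh13),
                                       profs, fold_min = 2)
  expect_setequal(sel$gene_id, c(syn$truth$gh13, syn$truth$aqp))
  # determinism and the zero-planted case
  syn2 <- synth_proteins(n = 20, planted_aqp = 1, planted_gh13 = 3, seed = 5)
  expect_identical(syn$proteins, syn2$proteins)
  syn0 <- synth_proteins(n = 6, planted_aqp = 0, planted_gh13 = 0, seed = 2)
  expect_equal(length(syn0$truth$aqp) + length(syn0$truth$gh13), 0L)
  if (nrow(syn0$gh13) > 0) expect_equal(nrow(gh13_filter(syn0$gh13)), 0L)
  d <- withr::local_tempdir()
  write_fasta(syn$proteins, file.path(d, "p.fasta"))
  back <- Biostrings::readAAStringSet(file.path(d, "p.fasta"))
  expect_equal(as.character(back), syn$proteins)
})
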