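test_that("terminal reactions map amino acids to their final synthesis step", {
  toy <- get_toy()
  ann <- terminal_reactions(toy$model)
  row_of <- function(aa) ann[ann$amino_acid == aa, ]
  expect_equal(row_of("lys-L")$reaction_id, "SSA1_Bt_LYSA")
  expect_equal(row_of("lys-L")$compartment, "c")
  expect_equal(row_of("arg-L")$genes, "argH")
  # the three branched-chain amino acids share the one transaminase
  bc <- ann[ann$amino_acid %in% c("val-L", "leu-L", "ile-L"), ]
  expect_setequal(unique(bc$genes), "BCAT")
  # symbiont-terminal pathways are reported with compartment p
  expect_equal(row_of("thr-L")$compartment, "p")
  expect_equal(row_of("trp-L")$genes, "trpB")
  # transports never count as the terminal step
  expect_false(any(grepl("^TP_", ann$reaction_id)))
  # a model with no amino-acid biomass has nothing to report
  expect_equal(nrow(terminal_reactions(chain_model())), 0L)
  expect_error(terminal_reactions(toy$model, amino_acids = "nope-L"), "absent")
})

test_that("single-gene reactions exclude isozyme-mediated steps", {
  toy <- get_toy()
  sg <- single_gene_reactions(toy$model)
  expect_true(all(c("SSA1_Bt_ARGH", "SSA1_Bt_LYSA", "SSA1_Bt_BCAT_VAL") %in% sg))
  expect_false("SSA1_Bt_PHETA1" %in% sg)     # aspC OR AAT2
  expect_false("TP_chor" %in% sg)            # spontaneous transport
  m <- parallel_model()
  expect_setequal(single_gene_reactions(m), c("P1", "P2"))
})

test_that("symbiosis target selection reproduces the toy truth under both policies", {
  toy <- get_toy()
  gd <- get_toy_gene_scan()
  ann <- terminal_reactions(toy$model)
  sg <- single_gene_reactions(toy$model)
  hgt <- hgt_table()
  hgt <- hgt[!is.na(hgt$gene_symbol) & !duplicated(hgt$gene_symbol), ]
  folds <- stats::setNames(hgt$fold, hgt$gene_symbol)
  sel <- select_symbiosis_targets(gd, ann, sg, policy = "advisory",
                                  hgt_genes = toy$truth$hgt_genes,
                                  model = toy$model, hgt_enrichment = folds)
  expect_setequal(sel$gene_id[sel$selected], toy$truth$symbiosis_targets)
  # flags trace back to the deletion scan without re-derivation drift
  ess <- stats::setNames(gd$essential, gd$entity_id)
  expect_true(all(sel$essential == ess[sel$gene_id]))
  # dapB enters through the upstream-essential-HGT rule, not terminality
  expect_equal(sel$rule[sel$gene_id == "dapB"], "upstream_essential_hgt")
  expect_false(sel$terminal_reaction[sel$gene_id == "dapB"])
  # symbiont-compartment terminals are reported but not host-targetable
  expect_true(all(c("thrC", "metE", "trpB") %in% sel$gene_id))
  expect_false(any(sel$host_targetable[sel$gene_id %in% c("thrC", "metE", "trpB")]))
  # strict policy demotes aspC (its terminal step has an isozyme) ...
  strict <- select_symbiosis_targets(gd, ann, sg, policy = "strict",
                                     hgt_genes = toy$truth$hgt_genes,
                                     model = toy$model, hgt_enrichment = folds)
  expect_false(strict$selected[strict$gene_id == "aspC"])
  # ... and relaxing the policy never removes a target (monotonicity)
  expect_true(all(strict$gene_id[strict$selected] %in%
                  sel$gene_id[sel$selected]))
  # no essential genes -> empty report
  gd0 <- gd
  gd0$essential <- FALSE
  sel0 <- select_symbiosis_targets(gd0, ann, sg)
  expect_equal(nrow(sel0), 0L)
})

test_that("losing the symbiont prephenate route makes the host mutase essential", {
  toy <- get_toy()
  # pseudogenization scenario: pheA drops out of the symbiont genome
  pruned <- delete_gene(toy$model, "pheA")
  gd <- single_gene_deletion(pruned, genes = c("CM", "aspC", "argH"))
  expect_true(gd$essential[gd$entity_id == "CM"])
})

test_that("origin annotation joins the HGT table and rejects duplicates", {
  targets <- data.frame(gene_id = c("argH", "BCAT", "lysA"),
                        stringsAsFactors = FALSE)
  hgt <- hgt_table()
  dedup <- hgt[!is.na(hgt$gene_symbol) & !duplicated(hgt$gene_symbol), ]
  out <- annotate_origin(targets, dedup, key = "gene_symbol")
  expect_equal(out$origin, c("HGT", "intrinsic", "HGT"))
  expect_equal(out$source_organism[1], "Erwinia")
  expect_true(is.na(out$source_organism[2]))
  # empty table -> all intrinsic
  out0 <- annotate_origin(targets, dedup[0, ], key = "gene_symbol")
  expect_true(all(out0$origin == "intrinsic"))
  # the table as printed carries a duplicated gene entry -> error
  expect_error(annotate_origin(targets, hgt_table(), key = "gene_id"),
               "duplicate")
})

test_that("the combined report compiles, orders and round-trips", {
  toy <- get_toy()
  gd <- get_toy_gene_scan()
  ann <- terminal_reactions(toy$model)
  sg <- single_gene_reactions(toy$model)
  hgt <- hgt_table()
  hgt <- hgt[!is.na(hgt$gene_symbol) & !duplicated(hgt$gene_symbol), ]
  sel <- select_symbiosis_targets(gd, ann, sg, policy = "advisory",
                                  hgt_genes = toy$truth$hgt_genes,
                                  model = toy$model,
                                  hgt_enrichment = stats::setNames(
                                    hgt$fold, hgt$gene_symbol))
  sel <- annotate_origin(sel[sel$selected, ], hgt, key = "gene_symbol")
  syn <- synth_proteins(12, 1, 2, seed = 8)
  osmo <- select_osmoregulation_targets(syn$enrichment,
                                        gh13_filter(syn$gh13),
                                        aqp_profiles_from_table(syn$aqp),
                                        fold_min = 2)
  rep <- compile_report(osmo, sel)
  # 3 osmoregulation + 6 symbiosis candidates
  expect_equal(sum(rep$category == "osmoregulation"), 3L)
  expect_equal(sum(rep$category == "symbiosis"), 6L)
  expect_equal(rep$origin[rep$gene_id == "argH"], "HGT")
  expect_equal(rep$source_organism[rep$gene_id == "dapB"], "Rickettsia")
  expect_equal(rep, rep[order(rep$category, rep$gene_id), ],
               ignore_attr = TRUE)
  d <- withr::local_tempdir()
  write_target_report(rep, file.path(d, "r.tsv"))
  back <- utils::read.delim(file.path(d, "r.tsv"), stringsAsFactors = FALSE)
  expect_equal(back$gene_id, rep$gene_id)
  expect_equal(back$criteria_met, rep$criteria_met)
  write_target_report(rep, file.path(d, "r.json"))
  jback <- jsonlite::read_json(file.path(d, "r.json"), simplifyVector = TRUE)
  expect_equal(jback$gene_id, rep$gene_id)
  # id collision across categories is an error
  osmo2 <- osmo
  osmo2$gene_id[1] <- "argH"
  expect_error(compile_report(osmo2, sel), "both categories")
  # empty inputs give an empty report with the full header
  e <- compile_report(osmo[0, ], sel[0, ])
  expect_equal(nrow(e), 0L)
  expect_true(all(c("gene_id", "category", "criteria_met") %in% names(e)))
})
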