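#' Translate a coding sequence to protein
#'
#' Standard genetic code, reading from the given frame; the trailing
#' partial codon is dropped, stop codons are rendered `*`, and codons
#' containing `N` translate to `X`.
#'
#' @param sequence nucleotide string over `A, C, G, T, N` (case
#'   insensitive).
#' @param frame reading frame, 1, 2 or 3.
#' @param gene_id optional identifier carried into the result.
#' @return a `protein_record`: list with `gene_id`, `sequence`
#'   (amino-acid string, 1-based positions) and `source = "translated"`.
#' @examples
#' translate_cds("ATGGATGAATAA")$sequence  # "MDE*"
#' @export
translate_cds <- function(sequence, frame = 1L, gene_id = NA_character_) {
  if (is.na(sequence) || nchar(sequence) == 0L) stop("empty nucleotide sequence")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A, C, G, T, N}")
  }
  stopifnot(frame %in% 1:3)
  s <- substr(sequence, frame, nchar(sequence))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) stop("no complete codon in frame ", frame)
  s <- substr(s, 1L, 3L * n_codon)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "X"))
  protein_record(gene_id, aa, source = "translated")
}

#' @rdname translate_cds
#' @param aa_sequence amino-acid string (20 standard residues, `X`,
#'   `*`).
#' @param source provenance tag, `"translated"` or `"provided"`.
#' @export
protein_record <- function(gene_id, aa_sequence, source = "provided") {
  aa_sequence <- toupper(aa_sequence)
  if (nchar(aa_sequence) < 1L) stop("protein sequence must be non-empty")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", aa_sequence)) {
    stop("protein sequence contains non-standard residues")
  }
  structure(list(gene_id = gene_id, sequence = aa_sequence, source = source),
            class = "protein_record")
}

#' Filter GH13 sucrase candidates on signal peptide and catalytic dyad
#'
#' A glycoside hydrolase family 13 alpha-glucosidase is retained as a
#' functional secreted sucrase only when it has a predicted signal
#' peptide and the intact catalytic dyad: aspartate nucleophile and
#' glutamate proton donor. Passing records are sorted by fold
#' enrichment, descending.
#'
#' @param records data.frame with columns `gene_id`, `fold`,
#'   `signal_peptide` (logical), `d_score`, `nucleophile_res`,
#'   `proton_donor_res` (residue letters or `NA`); extra columns are
#'   carried through.
#' @param d_threshold SignalP discrimination-score threshold used to
#'   sanity-check the annotation: rows marked signal-positive should
#'   have `d_score >= d_threshold`.
#' @return the passing subset of `records`, sorted by `fold`.
#' @export
gh13_filter <- function(records, d_threshold = 0.45) {
  if (nrow(records) == 0L) return(records)
  req <- c("gene_id", "fold", "signal_peptide", "nucleophile_res",
           "proton_donor_res")
  stopifnot(all(req %in% names(records)))
  if ("d_score" %in% names(records)) {
    bad <- records$signal_peptide & !is.na(records$d_score) &
      records$d_score < d_threshold
    if (any(bad)) {
      warning("signal-positive record(s) below the D-score threshold: ",
              paste(records$gene_id[bad], collapse = ", "))
    }
  }
  keep <- records$signal_peptide &
    !is.na(records$nucleophile_res) & records$nucleophile_res == "D" &
    !is.na(records$proton_donor_res) & records$proton_donor_res == "E"
  out <- records[keep, , drop = FALSE]
  out[order(-out$fold), , drop = FALSE]
}

#' Scan a protein for NPA boxes and the mercury-sensitive cysteine
#'
#' Finds every exact `NPA` trimer (1-based start positions) and reports
#' whether a cysteine sits two residues after the end of the first NPA
#' box, i.e. at `start + 4` (the mercury-sensitivity mark of DRIP-type
#' water channels).
#'
#' @param protein a `protein_record` or plain amino-acid string.
#' @return list with `positions` (integer vector, possibly empty) and
#'   `hg_cys` (logical).
#' @examples
#' scan_npa("XXNPAXCX")  # positions 3, hg_cys TRUE (C at 3 + 4)
#' @export
scan_npa <- function(protein) {
  s <- if (inherits(protein, "protein_record")) protein$sequence else toupper(protein)
  hits <- gregexpr("NPA", s, fixed = TRUE)[[1]]
  pos <- if (hits[1] == -1L) integer(0) else as.integer(hits)
  hg <- length(pos) > 0L && substr(s, pos[1] + 4L, pos[1] + 4L) == "C"
  list(positions = pos, hg_cys = hg)
}

#' Aquaporin motif profile
#'
#' Per-gene record of the aquaporin selectivity features: start
#' positions of the loop-B and loop-E NPA boxes, the aromatic/arginine
#' (ar/R) constriction tetrad at helix 2, helix 5, LE1 and LE2, and the
#' mercury-sensitive cysteine flag. Positions are 1-based.
#'
#' @param gene_id identifier.
#' @param npa_b,npa_e 1-based starts of the two NPA boxes, or `NA`.
#' @param arR character vector of the four tetrad residues in order
#'   (helix2, helix5, LE1, LE2), or `NULL` when unannotated.
#' @param arR_pos optional integer vector of the tetrad positions.
#' @param hg_cys logical, cysteine two residues after the first NPA box.
#' @param sequence optional amino-acid sequence; when given together
#'   with `arR_pos`, the tetrad residues are verified against it.
#' @return an `aquaporin_profile` object.
#' @export
aquaporin_profile <- function(gene_id, npa_b = NA_integer_, npa_e = NA_integer_,
                              arR = NULL, arR_pos = NULL, hg_cys = FALSE,
                              sequence = NULL) {
  if (!is.na(npa_b) && !is.na(npa_e) && npa_b >= npa_e) {
    stop("loop-B NPA box must precede the loop-E box")
  }
  if (!is.null(arR)) {
    arR <- toupper(as.character(arR))
    if (length(arR) != 4L || any(nchar(arR) != 1L)) {
      stop("arR tetrad must be four single residues")
    }
    names(arR) <- c("helix2", "helix5", "LE1", "LE2")
    if (!is.null(sequence) && !is.null(arR_pos)) {
      seen <- vapply(arR_pos, function(p) substr(sequence, p, p), character(1))
      if (!all(seen == unname(arR))) {
        stop("tetrad residues do not match the sequence at the given ",
             "positions for ", gene_id)
      }
    }
  }
  structure(list(gene_id = gene_id, npa_b = npa_b, npa_e = npa_e,
                 arR = arR, arR_pos = arR_pos, hg_cys = isTRUE(hg_cys)),
            class = "aquaporin_profile")
}

#' Classify an aquaporin as a water-specific (DRIP-type) channel
#'
#' TRUE if and only if both NPA boxes are present and the ar/R tetrad is
#' exactly phenylalanine / histidine / alanine / arginine in order. An
#' absent tetrad classifies as not water-specific (no error).
#'
#' @param profile an [aquaporin_profile()].
#' @return logical.
#' @export
classify_water_specific <- function(profile) {
  stopifnot(inherits(profile, "aquaporin_profile"))
  if (is.na(profile$npa_b) || is.na(profile$npa_e)) return(FALSE)
  if (is.null(profile$arR)) return(FALSE)
  all(unname(profile$arR) == c("F", "H", "A", "R"))
}

#' Select osmoregulation gene targets
#'
#' Combines the enrichment screen with the protein filters: sucrase
#' targets are GH13-passing genes at or above `fold_min` enrichment;
#' aquaporin targets are water-specific profiles at or above
#' `fold_min`. Genes present in a filter output but absent from the
#' enrichment table are dropped with a warning.
#'
#' @param enrichment data.frame with at least `gene_id` and `fold`
#'   (e.g. from [enrichment_test()]).
#' @param gh13_pass data.frame from [gh13_filter()].
#' @param aqp_profiles list of [aquaporin_profile()] objects.
#' @param fold_min minimum fold enrichment (default 2).
#' @return data.frame with columns `gene_id`, `class` (`"sucrase"` or
#'   `"aquaporin"`), `fold` and `criteria_met`; sucrases ranked by fold.
#' @export
select_osmoregulation_targets <- function(enrichment, gh13_pass, aqp_profiles,
                                          fold_min = 2) {
  lookup <- stats::setNames(enrichment$fold, enrichment$gene_id)
  pick <- function(ids, class, criteria) {
    fold <- lookup[ids]
    missing <- ids[is.na(fold)]
    if (length(missing) > 0L) {
      warning("gene(s) missing from the enrichment table dropped: ",
              paste(missing, collapse = ", "))
    }
    keep <- !is.na(fold) & fold >= fold_min
    n <- sum(keep)
    data.frame(gene_id = ids[keep], class = rep(class, n),
               fold = unname(fold[keep]),
               criteria_met = rep(paste0(criteria, ";enriched>=", fold_min), n),
               stringsAsFactors = FALSE)
  }
  suc <- pick(gh13_pass$gene_id, "sucrase", "gh13_pass")
  wsp <- vapply(aqp_profiles, classify_water_specific, logical(1))
  aqp_ids <- vapply(aqp_profiles, function(p) p$gene_id, character(1))[wsp]
  aqp <- pick(aqp_ids, "aquaporin", "water_specific")
  out <- rbind(suc[order(-suc$fold), , drop = FALSE],
               aqp[order(-aqp$fold), , drop = FALSE])
  rownames(out) <- NULL
  out
}
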