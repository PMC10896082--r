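#' Bundled annotation tables for the cassava whitefly screen
#'
#' Accessors for the curated per-gene annotation tables shipped with the
#' package: gut-enriched GH13 alpha-glucosidase candidates (signal
#' peptide D-score, cleavage site and catalytic dyad residues),
#' aquaporin motif profiles (NPA boxes and ar/R tetrad), and
#' horizontally transferred genes of bacterial origin with enriched
#' bacteriocyte expression. These mirror published annotation of the
#' SSA1-SG1 whitefly transcriptome and are the default inputs of the
#' osmoregulation screen.
#'
#' @return `gh13_table()`: data.frame with one row per GH13 candidate,
#'   columns `gene_id`, `meam1_gene`, `log_cpm`, `fold`,
#'   `signal_peptide` (logical), `d_score`, `cleavage_site`,
#'   `nucleophile_res`/`_pos`, `proton_donor_res`/`_pos`.
#' @export
gh13_table <- function() {
  tab <- utils::read.delim(
    system.file("extdata", "gh13_gut_enriched.tsv", package = "holotarget"),
    stringsAsFactors = FALSE,
    colClasses = c(nucleophile_res = "character",
                   proton_donor_res = "character"))
  tab$signal_peptide <- tab$signal_peptide == "+"
  tab
}

#' @rdname gh13_table
#' @return `aquaporin_table()`: data.frame of aquaporin motif
#'   annotation; `NA` marks features not recorded for a gene. `log_cpm`
#'   and `fold` are present only for the gut-enriched genes.
#' @export
aquaporin_table <- function() {
  utils::read.delim(
    system.file("extdata", "aquaporin_profiles.tsv", package = "holotarget"),
    stringsAsFactors = FALSE,
    colClasses = c(h2_res = "character", h5_res = "character",
                   le1_res = "character", le2_res = "character"))
}

#' @rdname gh13_table
#' @param table an aquaporin annotation table as returned by
#'   [aquaporin_table()].
#' @return `aqp_profiles_from_table()`: list of [aquaporin_profile()]
#'   objects, one per table row.
#' @export
aqp_profiles_from_table <- function(table = aquaporin_table()) {
  lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    arR <- c(r$h2_res, r$h5_res, r$le1_res, r$le2_res)
    aquaporin_profile(
      gene_id = r$gene_id,
      npa_b = r$npa_b, npa_e = r$npa_e,
      arR = if (all(!is.na(arR))) arR else NULL,
      arR_pos = if (all(!is.na(arR))) c(r$h2_pos, r$h5_pos, r$le1_pos, r$le2_pos)
    )
  })
}

#' @rdname gh13_table
#' @return `hgt_table()`: data.frame of horizontally transferred genes
#'   as printed (one gene appears twice under two orthologue
#'   assignments; deduplicate by `gene_id` before passing it to
#'   [annotate_origin()]).
#' @export
hgt_table <- function() {
  utils::read.delim(
    system.file("extdata", "hgt_genes.tsv", package = "holotarget"),
    stringsAsFactors = FALSE)
}
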