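#' Simulate tissue RNA-seq count matrices with planted enrichment
#'
#' Gamma-Poisson (negative binomial) counts for a two-group tissue
#' design (target tissue vs whole body), with per-sample library-size
#' jitter (log-normal, sigma = 0.2) and a set of planted
#' tissue-enriched genes at known fold changes. Background genes draw
#' their baseline mean from a log-normal distribution around
#' `baseline_mean`; planted genes sit exactly at `baseline_mean` so
#' their true fold is interpretable.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per tissue group (>= 2).
#' @param baseline_mean expected count of a planted gene in the
#'   baseline tissue at the average library size.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param planted named numeric vector: gene index (or name
#'   `gene<index>`) to true fold enrichment in the target tissue; all
#'   folds must be positive.
#' @param tissues length-2 character vector, target then baseline.
#' @param seed integer seed; the same seed reproduces the matrix
#'   bit-identically.
#' @return list with `counts` (a [count_matrix()]) and `truth`
#'   (planted folds, baseline means, library factors).
#' @export
simulate_counts <- function(n_genes = 2000, n_per_group = 3,
                            baseline_mean = 100, dispersion = 0.1,
                            planted = numeric(0),
                            tissues = c("gut", "whole_body"), seed = 1) {
  stopifnot(n_per_group >= 2, dispersion > 0, length(tissues) == 2)
  if (length(planted) > 0 && any(planted <= 0)) {
    stop("planted folds must be positive")
  }
  genes <- paste0("gene", seq_len(n_genes))
  pl <- stats::setNames(rep(1, n_genes), genes)
  if (length(planted) > 0) {
    nm <- names(planted)
    if (is.null(nm)) nm <- paste0("gene", seq_along(planted))
    pl[nm] <- planted
  }
  withr::with_seed(seed, {
    base_mu <- stats::rlnorm(n_genes, log(baseline_mean), 1)
    base_mu[pl != 1] <- baseline_mean
    n_s <- 2L * n_per_group
    lib <- stats::rlnorm(n_s, 0, 0.2)
    grp <- rep(tissues, each = n_per_group)
    mu <- outer(base_mu, lib) * ifelse(grp[col(matrix(0, n_genes, n_s))] ==
                                         tissues[1], pl, 1)
    counts <- matrix(stats::rnbinom(n_genes * n_s, mu = mu,
                                    size = 1 / dispersion),
                     n_genes, n_s)
  })
  dimnames(counts) <- list(genes, paste0(rep(c("t", "b"), each = n_per_group),
                                         seq_len(n_per_group)))
  tissue <- stats::setNames(grp, colnames(counts))
  list(counts = count_matrix(counts, tissue),
       truth = list(planted = pl[pl != 1], baseline_mean = base_mu,
                    dispersion = dispersion, lib_factors = lib))
}

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  s <- paste(sample(.aa20, len, replace = TRUE), collapse = "")
  # scrub accidental NPA boxes so planted motifs are the only ones
  while (grepl("NPA", s, fixed = TRUE)) {
    s <- sub("NPA", "NGA", s, fixed = TRUE)
  }
  s
}

splice <- function(s, pos, insert) {
  paste0(substr(s, 1, pos - 1), insert,
         substr(s, pos + nchar(insert), nchar(s)))
}

#' Synthesise protein sets with planted osmoregulation motifs
#'
#' Generates `n` random protein sequences plus annotation tables in
#' which `planted_aqp` sequences carry the full water-specific
#' aquaporin signature (NPA boxes at positions 91 and 210, F/H/A/R
#' ar/R tetrad, mercury-sensitive cysteine two residues after the
#' first box) and `planted_gh13` records carry a signal peptide
#' (D-score >= 0.45) with the intact D/E catalytic dyad. Every decoy
#' violates exactly one rule (missing NPA box, broken tetrad, absent
#' signal peptide, E/R dyad, or missing catalytic residues), so a
#' correct screen recovers exactly the planted identifiers.
#'
#' @param n total number of genes (>= planted counts).
#' @param planted_aqp,planted_gh13 numbers of true aquaporins/GH13
#'   sucrases to plant.
#' @param seed integer seed.
#' @return list with `proteins` (named character vector of sequences),
#'   `gh13` (annotation data.frame in [gh13_table()] layout), `aqp`
#'   (in [aquaporin_table()] layout), `enrichment` (gene folds), and
#'   `truth` (the planted ids).
#' @export
synth_proteins <- function(n = 20, planted_aqp = 1, planted_gh13 = 3,
                           seed = 1) {
  stopifnot(planted_aqp + planted_gh13 <= n)
  withr::with_seed(seed, {
    ids <- sprintf("SYNT%05d", seq_len(n))
    n_decoy <- n - planted_aqp - planted_gh13
    role <- sample(c(rep("aqp", planted_aqp), rep("gh13", planted_gh13),
                     rep("decoy", n_decoy)))
    seqs <- vapply(rep(260, n), random_protein, character(1))
    aqp_rows <- list()
    gh13_rows <- list()
    truth_aqp <- character(0)
    truth_gh13 <- character(0)
    fold <- round(stats::runif(n, 4, 45), 2)
    log_cpm <- round(stats::runif(n, 2, 12), 2)
    scrub_npa <- function(s, keep) {
      # single-character splices can create chance NPA boxes; break them
      repeat {
        extra <- setdiff(scan_npa(s)$positions, keep)
        if (length(extra) == 0L) return(s)
        substr(s, extra[1] + 1L, extra[1] + 1L) <- "G"
      }
    }
    plant_aqp <- function(s, tetrad) {
      s <- splice(s, 91, "NPA")
      s <- splice(s, 95, "C")
      s <- splice(s, 210, "NPA")
      for (k in seq_along(tetrad$pos)) s <- splice(s, tetrad$pos[k], tetrad$res[k])
      scrub_npa(s, c(91, 210))
    }
    tet_true <- list(res = c("F", "H", "A", "R"), pos = c(71, 89, 207, 213))
    decoy_kind <- 0L
    for (i in seq_len(n)) {
      if (role[i] == "aqp") {
        seqs[i] <- plant_aqp(seqs[i], tet_true)
        truth_aqp <- c(truth_aqp, ids[i])
        aqp_rows[[length(aqp_rows) + 1L]] <- data.frame(
          gene_id = ids[i], h2_res = "F", h2_pos = 71, h5_res = "H",
          h5_pos = 89, le1_res = "A", le1_pos = 207, le2_res = "R",
          le2_pos = 213, npa_b = 91, npa_e = 210, stringsAsFactors = FALSE)
      } else if (role[i] == "gh13") {
        truth_gh13 <- c(truth_gh13, ids[i])
        np <- sample(180:260, 1)
        gh13_rows[[length(gh13_rows) + 1L]] <- data.frame(
          gene_id = ids[i], log_cpm = log_cpm[i], fold = fold[i],
          signal_peptide = TRUE, d_score = round(stats::runif(1, 0.5, 0.9), 3),
          nucleophile_res = "D", nucleophile_pos = np,
          proton_donor_res = "E", proton_donor_pos = np + sample(50:80, 1),
          stringsAsFactors = FALSE)
      } else {
        decoy_kind <- decoy_kind %% 5L + 1L
        if (decoy_kind == 1L) {          # aquaporin with a single NPA box
          seqs[i] <- scrub_npa(splice(splice(seqs[i], 91, "NPA"), 95, "C"), 91)
          aqp_rows[[length(aqp_rows) + 1L]] <- data.frame(
            gene_id = ids[i], h2_res = "F", h2_pos = 71, h5_res = "H",
            h5_pos = 89, le1_res = "A", le1_pos = 207, le2_res = "R",
            le2_pos = 213, npa_b = 91, npa_e = NA, stringsAsFactors = FALSE)
        } else if (decoy_kind == 2L) {   # broken ar/R tetrad (F/I/S/R)
          tet <- list(res = c("F", "I", "S", "R"), pos = tet_true$pos)
          seqs[i] <- plant_aqp(seqs[i], tet)
          aqp_rows[[length(aqp_rows) + 1L]] <- data.frame(
            gene_id = ids[i], h2_res = "F", h2_pos = 71, h5_res = "I",
            h5_pos = 89, le1_res = "S", le1_pos = 207, le2_res = "R",
            le2_pos = 213, npa_b = 91, npa_e = 210, stringsAsFactors = FALSE)
        } else if (decoy_kind == 3L) {   # GH13 without signal peptide
          gh13_rows[[length(gh13_rows) + 1L]] <- data.frame(
            gene_id = ids[i], log_cpm = log_cpm[i], fold = fold[i],
            signal_peptide = FALSE, d_score = round(stats::runif(1, 0.1, 0.4), 3),
            nucleophile_res = "D", nucleophile_pos = 227,
            proton_donor_res = "E", proton_donor_pos = 295,
            stringsAsFactors = FALSE)
        } else if (decoy_kind == 4L) {   # E/R dyad instead of D/E
          gh13_rows[[length(gh13_rows) + 1L]] <- data.frame(
            gene_id = ids[i], log_cpm = log_cpm[i], fold = fold[i],
            signal_peptide = TRUE, d_score = round(stats::runif(1, 0.5, 0.9), 3),
            nucleophile_res = "E", nucleophile_pos = 229,
            proton_donor_res = "R", proton_donor_pos = 287,
            stringsAsFactors = FALSE)
        } else {                         # GH13 with no catalytic residues
          gh13_rows[[length(gh13_rows) + 1L]] <- data.frame(
            gene_id = ids[i], log_cpm = log_cpm[i], fold = fold[i],
            signal_peptide = TRUE, d_score = round(stats::runif(1, 0.5, 0.9), 3),
            nucleophile_res = NA_character_, nucleophile_pos = NA_integer_,
            proton_donor_res = NA_character_, proton_donor_pos = NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  names(seqs) <- ids
  list(proteins = seqs,
       gh13 = if (length(gh13_rows)) do.call(rbind, gh13_rows) else
         data.frame(),
       aqp = if (length(aqp_rows)) do.call(rbind, aqp_rows) else data.frame(),
       enrichment = data.frame(gene_id = ids, fold = fold, log_cpm = log_cpm,
                               stringsAsFactors = FALSE),
       truth = list(aqp = truth_aqp, gh13 = truth_gh13))
}

#' Write protein sequences as FASTA
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param path output file.
#' @export
write_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(proteins)
}

#' Random viable metabolic models for property testing
#'
#' Builds a network around a guaranteed producing spine (nutrient
#' uptake, a linear conversion chain, a biomass sink) and pads it with
#' random conversion reactions; the spine guarantees a positive
#' optimal growth whatever the extras do. All bounds are finite, so
#' the model is also safe for vertex-enumeration oracles.
#'
#' @param n_metabolites chain length (>= 2).
#' @param n_reactions total reactions; must be at least
#'   `n_metabolites + 1` (the spine size).
#' @param seed integer seed; same seed, same model.
#' @return a [metabolic_model()] with objective `"BIOMASS"`.
#' @export
random_viable_model <- function(n_metabolites = 4, n_reactions = 8, seed = 1) {
  if (n_reactions < n_metabolites + 1) {
    stop("need n_reactions >= n_metabolites + 1 for a viable spine")
  }
  mets <- paste0("M", seq_len(n_metabolites), "[c]")
  withr::with_seed(seed, {
    rxns <- list(reaction("EX_M1", stats::setNames(-1, mets[1]),
                          lb = -10, ub = 0, kind = "exchange"))
    for (i in seq_len(n_metabolites - 1L)) {
      rxns[[length(rxns) + 1L]] <- reaction(
        paste0("CONV", i), stats::setNames(c(-1, 1), mets[i + 0:1]),
        lb = 0, ub = 1000, gpr = paste0("g_conv", i))
    }
    rxns[[length(rxns) + 1L]] <- reaction(
      "BIOMASS", stats::setNames(-1, mets[n_metabolites]),
      lb = 0, ub = 1000, kind = "biomass")
    n_extra <- n_reactions - length(rxns)
    for (k in seq_len(n_extra)) {
      pair <- sample(n_metabolites, 2)
      rev <- stats::runif(1) < 0.5
      rxns[[length(rxns) + 1L]] <- reaction(
        paste0("RND", k), stats::setNames(c(-1, 1), mets[pair]),
        lb = if (rev) -10 else 0, ub = 10, gpr = paste0("g_rnd", k))
    }
    metabolic_model(paste0("random_", seed), mets, rxns,
                    objective = "BIOMASS")
  })
}
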