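#' TMM normalisation factors
#'
#' Per-sample trimmed-mean-of-M-values normalisation factors, computed
#' by edgeR's TMM implementation (trim 30% on log-ratios M, 5% on
#' average intensities A; reference column = the sample whose
#' upper-quartile is closest to the mean upper-quartile). Genes with a
#' zero count in either member of a pair drop out of that pair's M/A
#' statistics. Factors are scaled to have geometric mean one.
#'
#' @param counts a [count_matrix()] or plain counts matrix.
#' @param ref_sample sample id to use as TMM reference, or `"auto"`.
#' @return named numeric vector of positive factors, one per sample.
#' @export
tmm_factors <- function(counts, ref_sample = "auto") {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (ncol(m) < 2L) stop("TMM needs at least two samples")
  zero <- colSums(m) == 0
  if (any(zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  ref <- NULL
  if (!identical(ref_sample, "auto")) {
    ref <- match(ref_sample, colnames(m))
    if (is.na(ref)) stop("unknown reference sample: ", ref_sample)
  }
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref,
                              logratioTrim = 0.3, sumTrim = 0.05)
  stats::setNames(as.numeric(f), colnames(m))
}

#' Counts per million under effective library sizes
#'
#' `cpm[g, s] = counts[g, s] / (library_size[s] * factor[s]) * 1e6`.
#'
#' @param counts a [count_matrix()] or counts matrix.
#' @param factors per-sample normalisation factors (default: all one).
#' @return numeric matrix of CPM values, same dimensions as the counts.
#' @export
compute_cpm <- function(counts, factors = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (is.null(factors)) factors <- rep(1, ncol(m))
  if (any(factors <= 0)) stop("normalisation factors must be positive")
  eff <- colSums(m) * factors
  if (any(eff == 0)) {
    stop("zero effective library size for sample(s): ",
         paste(colnames(m)[eff == 0], collapse = ", "))
  }
  sweep(m, 2L, eff, "/") * 1e6
}

#' Configuration for the tissue-enrichment test
#'
#' @param min_cpm,min_samples pre-test gene filter: keep genes with
#'   CPM > `min_cpm` in at least `min_samples` samples.
#' @param dispersion `"common"` for a single negative-binomial
#'   dispersion shared across genes (the default), or a fixed numeric
#'   dispersion.
#' @return a list of class `enrichment_config`.
#' @export
enrichment_config <- function(min_cpm = 1, min_samples = 2L,
                              dispersion = "common") {
  stopifnot(min_cpm >= 0, min_samples >= 1)
  structure(list(min_cpm = min_cpm, min_samples = as.integer(min_samples),
                 dispersion = dispersion),
            class = "enrichment_config")
}

#' Tissue-enrichment screen (negative-binomial likelihood-ratio test)
#'
#' Tests each gene for differential abundance between a target tissue
#' (gut or bacteriocyte) and a baseline (whole body), via TMM-normalised
#' negative-binomial generalised linear models with a likelihood-ratio
#' test on the tissue coefficient (edgeR). Positive `log_fc` means
#' enriched in the target tissue.
#'
#' @param counts a [count_matrix()].
#' @param target_tissue,baseline tissue labels present in `counts`.
#' @param config an [enrichment_config()].
#' @return data.frame with one row per retained gene: `gene_id`,
#'   `log_cpm` (average log2 CPM), `log_fc`, `fold` (`2^log_fc`),
#'   `p_value` and `q_value` (Benjamini-Hochberg).
#' @export
enrichment_test <- function(counts, target_tissue, baseline = "whole_body",
                            config = enrichment_config()) {
  stopifnot(inherits(counts, "count_matrix"))
  tis <- counts$tissue
  for (lab in c(target_tissue, baseline)) {
    if (!lab %in% tis) stop("tissue label not present in matrix: ", lab)
  }
  keep_s <- tis %in% c(target_tissue, baseline)
  m <- counts$counts[, keep_s, drop = FALSE]
  grp <- factor(tis[keep_s], levels = c(baseline, target_tissue))
  if (any(table(grp) < 2L)) stop("need at least 2 samples per tissue")
  keep_g <- rowSums(compute_cpm(m) > config$min_cpm) >= config$min_samples
  m <- m[keep_g, , drop = FALSE]
  if (nrow(m) == 0L) stop("no genes pass the expression filter")
  y <- edgeR::DGEList(counts = m, group = grp)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  design <- stats::model.matrix(~grp)
  if (identical(config$dispersion, "common")) {
    y <- edgeR::estimateGLMCommonDisp(y, design)
  } else {
    y$common.dispersion <- as.numeric(config$dispersion)
  }
  fit <- edgeR::glmFit(y, design)
  lrt <- edgeR::glmLRT(fit, coef = 2L)
  tab <- lrt$table
  data.frame(
    gene_id = rownames(tab),
    log_cpm = tab$logCPM,
    log_fc = tab$logFC,
    fold = 2^tab$logFC,
    p_value = tab$PValue,
    q_value = bh_adjust(tab$PValue),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min over {j : p_j >= p_i} of (m * p_j / rank_j)`, clipped at
#' one; monotone in `p`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Relative expression by the delta-delta-Cq method
#'
#' qPCR fold difference of a target gene in a tissue relative to a
#' calibrator tissue, normalised against one or more reference genes
#' (e.g. RPL13 and beta-tubulin):
#' `dCq = Cq_target - mean(Cq_references)`, with the reference mean
#' taken on the Cq scale (the geometric mean of the linear quantities);
#' `fold = 2^-(dCq_tissue - dCq_calibrator)`.
#'
#' @param qpcr data.frame with columns `gene_id`, `sample_id`, `tissue`,
#'   `cq`, `is_reference` (logical).
#' @param gene_id target gene.
#' @param target_tissue,calibrator_tissue tissue labels; the calibrator
#'   is typically the whole body.
#' @return list with `fold`, `ddcq`, and the per-tissue `dcq` values.
#' @export
ddcq_relative_expression <- function(qpcr, gene_id, target_tissue,
                                     calibrator_tissue = "whole_body") {
  stopifnot(all(c("gene_id", "tissue", "cq", "is_reference") %in% names(qpcr)))
  if (any(qpcr$cq <= 0)) stop("Cq values must be positive")
  dcq <- function(tissue) {
    sub <- qpcr[qpcr$tissue == tissue, , drop = FALSE]
    tgt <- sub$cq[sub$gene_id == gene_id & !sub$is_reference]
    refs <- sub[sub$is_reference, , drop = FALSE]
    if (length(tgt) == 0L) stop("no target measurements for ", gene_id,
                                " in tissue ", tissue)
    if (nrow(refs) == 0L) stop("no reference-gene measurements in tissue ",
                               tissue)
    ref_means <- tapply(refs$cq, refs$gene_id, mean)
    mean(tgt) - mean(ref_means)
  }
  d_t <- dcq(target_tissue)
  d_c <- dcq(calibrator_tissue)
  ddcq <- d_t - d_c
  list(fold = 2^(-ddcq), ddcq = ddcq,
       dcq = stats::setNames(c(d_t, d_c), c(target_tissue, calibrator_tissue)))
}

#' Write an enrichment table to TSV
#'
#' Columns: `gene_id`, `logCPM`, `logFC`, `fold`, `p`, `q`.
#'
#' @param records data.frame from [enrichment_test()].
#' @param path output file.
#' @export
write_enrichment <- function(records, path) {
  out <- data.frame(gene_id = records$gene_id, logCPM = records$log_cpm,
                    logFC = records$log_fc, fold = records$fold,
                    p = records$p_value, q = records$q_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(records)
}
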