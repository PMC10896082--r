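#' Gene-by-sample count matrix with tissue labels
#'
#' Container for gene-level read counts from dissected tissues (gut,
#' bacteriocyte) and whole-body libraries. Counts must be non-negative
#' integers; every sample carries a tissue label.
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns; dimnames are used as gene and sample identifiers.
#' @param tissue named character vector mapping each sample id to a
#'   tissue label (e.g. `"gut"`, `"bacteriocyte"`, `"whole_body"`).
#'
#' @return an object of class `count_matrix` with elements `counts`
#'   (integer matrix) and `tissue` (named character vector).
#' @examples
#' m <- matrix(rpois(12, 50), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' cm <- count_matrix(m, c(s1 = "gut", s2 = "gut", s3 = "whole_body"))
#' @export
count_matrix <- function(counts, tissue) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and complete")
  }
  if (max(abs(counts - round(counts))) > 1e-8) {
    stop("counts must be integral")
  }
  storage.mode(counts) <- "double"
  tissue <- tissue[colnames(counts)]
  if (any(is.na(tissue))) {
    stop("every sample needs a tissue label; missing: ",
         paste(setdiff(colnames(counts), names(tissue)), collapse = ", "))
  }
  structure(list(counts = counts, tissue = tissue), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  print(table(x$tissue))
  invisible(x)
}

#' Read a count matrix and sample sheet from TSV files
#'
#' @param counts_path TSV with gene ids in the first column and one
#'   column per sample.
#' @param samples_path TSV with columns `sample_id` and `tissue`.
#' @return a [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  ss <- utils::read.delim(samples_path)
  count_matrix(m, stats::setNames(as.character(ss$tissue), ss$sample_id))
}

#' Write a count matrix (and its sample sheet) to TSV
#'
#' @param x a [count_matrix()].
#' @param counts_path,samples_path output file paths.
#' @export
write_counts <- function(x, counts_path, samples_path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(x$tissue), tissue = unname(x$tissue)),
    samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
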