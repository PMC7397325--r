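#' Pathway activation z-score for one pathway in one sample
#'
#' Computes the single-sample pathway activation score
#' \deqn{Z_{tS} = \frac{\bar{X}_{tS} - \bar{X}_t}{\sigma_t / \sqrt{|S|}}}
#' where \eqn{\bar{X}_{tS}} is the mean expression of the pathway's genes in
#' sample \eqn{t}, \eqn{\bar{X}_t} and \eqn{\sigma_t} are the mean and
#' standard deviation of all genes in the sample, and \eqn{|S|} counts the
#' pathway genes present in the matrix (absent genes are dropped).
#'
#' @param matrix Expression matrix (genes x samples).
#' @param gene_set Character vector of gene IDs.
#' @param sample Sample ID (column name).
#' @param sd_divisor `"n-1"` (sample SD, default) or `"n"` (population SD).
#' @return The activation z-score, a single number.
#' @export
score_pathway <- function(matrix, gene_set, sample, sd_divisor = c("n-1", "n")) {
  check_expression_matrix(matrix)
  sd_divisor <- match.arg(sd_divisor)
  if (nrow(matrix) < 2) stop("score_pathway requires >= 2 genes in the matrix")
  if (!sample %in% colnames(matrix)) stop("sample not found: ", sample)
  present <- intersect(gene_set, rownames(matrix))
  if (!length(present)) stop("missing-gene error: no genes of the set are in the matrix")
  x <- matrix[, sample]
  sigma <- stats::sd(x)
  if (sd_divisor == "n") sigma <- sigma * sqrt((length(x) - 1) / length(x))
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate-sample error: sample ", sample, " has zero expression SD")
  }
  (mean(x[present]) - mean(x)) / (sigma / sqrt(length(present)))
}

#' Pathway activation z-scores for a collection of gene sets
#'
#' Applies [score_pathway()] to every (gene set, sample) pair, producing the
#' pathways x samples score matrix that feeds consensus NMF subgrouping. The
#' per-set count of genes absent from the matrix is reported with a message.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param gene_sets Named list of character vectors of gene IDs.
#' @param sd_divisor Passed to [score_pathway()].
#' @return Numeric matrix, pathways (sets) x samples.
#' @export
score_pathways <- function(matrix, gene_sets, sd_divisor = c("n-1", "n")) {
  check_expression_matrix(matrix)
  sd_divisor <- match.arg(sd_divisor)
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  if (nrow(matrix) < 2) stop("score_pathways requires >= 2 genes in the matrix")
  n <- nrow(matrix)
  col_mean <- colMeans(matrix)
  col_sd <- sqrt((colSums(matrix^2) - n * col_mean^2) / (n - 1))
  if (sd_divisor == "n") col_sd <- col_sd * sqrt((n - 1) / n)
  degen <- which(col_sd == 0 | !is.finite(col_sd))
  if (length(degen)) {
    stop("degenerate-sample error: zero expression SD in sample ",
         colnames(matrix)[degen[1]])
  }
  z <- matrix(NA_real_, nrow = length(gene_sets), ncol = ncol(matrix),
              dimnames = list(names(gene_sets), colnames(matrix)))
  for (i in seq_along(gene_sets)) {
    present <- intersect(gene_sets[[i]], rownames(matrix))
    absent <- length(gene_sets[[i]]) - length(present)
    if (absent > 0) {
      message("score_pathways: set '", names(gene_sets)[i], "': ",
              absent, " gene(s) absent from the matrix")
    }
    if (!length(present)) {
      stop("missing-gene error: set '", names(gene_sets)[i],
           "' has no genes in the matrix")
    }
    set_mean <- colMeans(matrix[present, , drop = FALSE])
    z[i, ] <- (set_mean - col_mean) / (col_sd / sqrt(length(present)))
  }
  z
}
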