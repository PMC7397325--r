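#' Read a gene expression matrix from TSV
#'
#' Reads a tab-separated file whose header row holds sample IDs and whose
#' first column holds gene IDs, returning a numeric matrix (genes x samples)
#' with `rownames` = gene IDs and `colnames` = sample IDs.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (file.size(path) == 0) stop("parse error: empty expression file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("parse error: expression file must have a gene-ID column and >= 1 sample column")
  }
  gene_ids <- as.character(df[[1]])
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("format error: duplicate gene IDs: ", paste(dup_g, collapse = ", "))
  }
  sample_ids <- colnames(df)[-1]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("format error: duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))) &
                   !is.na(as.matrix(df[, -1, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("parse error: non-numeric cell at row ", bad[1, 1],
           ", column ", colnames(df)[-1][bad[1, 2]])
    }
    storage.mode(vals) <- "double"
  }
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)
    stop("parse error: non-finite value at row ", bad[1, 1],
         " (gene ", gene_ids[bad[1, 1]], "), column ", sample_ids[bad[1, 2]])
  }
  rownames(vals) <- gene_ids
  colnames(vals) <- sample_ids
  vals
}

#' Write a gene expression matrix to TSV
#'
#' Inverse of [read_expression()]: values are written with 10 significant
#' digits so a round trip reproduces the matrix to that precision.
#'
#' @param matrix Numeric matrix with gene-ID rownames and sample-ID colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(matrix, path) {
  check_expression_matrix(matrix)
  df <- data.frame(gene_id = rownames(matrix),
                   signif(matrix, 10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_expression_matrix <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix needs gene-ID rownames and sample-ID colnames")
  }
  if (anyDuplicated(rownames(matrix))) stop("format error: duplicate gene IDs")
  if (anyDuplicated(colnames(matrix))) stop("format error: duplicate sample IDs")
  if (any(!is.finite(matrix))) stop("expression matrix contains non-finite values")
  invisible(TRUE)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' gene IDs. Duplicate genes within a line are removed with a warning.
#'
#' @param path Path to GMT file.
#' @return Named list of character vectors of gene IDs.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("format error: empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("format error: GMT line ", i, " has fewer than 3 fields")
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", fields[1], "' (line ", i,
              ") contains duplicate genes; deduplicated")
      genes <- unique(genes)
    }
    if (!length(genes)) stop("format error: GMT line ", i, " has an empty gene set")
    sets[[fields[1]]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors of gene IDs.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Collapse duplicate probes to one row per gene
#'
#' When several probes map to the same gene, the probe with the highest mean
#' expression across samples is kept (ties broken by input order) and the row
#' is renamed to the gene ID. Probes without a mapping are dropped.
#'
#' @param matrix Expression matrix with probe-ID rownames.
#' @param probe_to_gene Named character vector: names are probe IDs, values
#'   are gene IDs.
#' @return Expression matrix with one row per gene.
#' @export
collapse_duplicates <- function(matrix, probe_to_gene) {
  check_expression_matrix(matrix)
  if (length(probe_to_gene) == 0) stop("empty probe-to-gene mapping")
  if (is.null(names(probe_to_gene))) stop("probe_to_gene must be named by probe ID")
  probes <- intersect(rownames(matrix), names(probe_to_gene))
  if (!length(probes)) stop("no probes in the matrix are covered by the mapping")
  genes <- probe_to_gene[probes]
  means <- rowMeans(matrix[probes, , drop = FALSE])
  keep <- vapply(split(seq_along(probes), genes), function(idx) {
    idx[which.max(means[idx])]  # which.max keeps the earliest on ties
  }, integer(1))
  out <- matrix[probes[keep], , drop = FALSE]
  rownames(out) <- names(keep)
  out[order(rownames(out)), , drop = FALSE]
}

#' Median-center each gene across samples
#'
#' Subtracts from every gene row its median across samples, the first half of
#' the median-center-quantile (MCQ) cohort-assembly normalization.
#'
#' @param matrix Expression matrix.
#' @return Matrix with per-gene median 0.
#' @export
median_center <- function(matrix) {
  check_expression_matrix(matrix)
  if (ncol(matrix) < 1) stop("median_center requires >= 1 sample")
  meds <- apply(matrix, 1, stats::median)
  matrix - meds
}

#' Quantile-normalize samples
#'
#' Forces every sample column onto the common reference distribution (the
#' across-sample mean of order statistics), preserving within-column ranks;
#' ties receive the mean of their tied reference quantiles.
#'
#' @param matrix Expression matrix with >= 2 samples.
#' @return Quantile-normalized matrix.
#' @export
quantile_normalize <- function(matrix) {
  check_expression_matrix(matrix)
  if (ncol(matrix) < 2) stop("quantile_normalize requires >= 2 samples")
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Merge cohorts on their common genes
#'
#' Rows are restricted to the intersection of gene IDs across all inputs and
#' columns concatenated. The number of genes dropped from each input is
#' reported with a message.
#'
#' @param matrices List of >= 2 expression matrices with globally unique
#'   sample IDs.
#' @return Merged expression matrix.
#' @export
merge_cohorts <- function(matrices) {
  stopifnot(is.list(matrices))
  if (length(matrices) < 2) stop("merge_cohorts requires >= 2 matrices")
  lapply(matrices, check_expression_matrix)
  all_samples <- unlist(lapply(matrices, colnames))
  dup <- unique(all_samples[duplicated(all_samples)])
  if (length(dup)) stop("merge error: duplicate sample IDs across cohorts: ",
                        paste(dup, collapse = ", "))
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(common)) stop("merge error: empty gene intersection")
  for (i in seq_along(matrices)) {
    dropped <- nrow(matrices[[i]]) - length(common)
    message("merge_cohorts: input ", i, ": dropped ", dropped, " gene(s)")
  }
  do.call(cbind, lapply(matrices, function(m) m[common, , drop = FALSE]))
}

#' Read / write a clinical table
#'
#' The clinical TSV has columns `sample_id`, `time` (months to biochemical
#' recurrence or censoring), `event` (0/1), `gleason` (6-10 or NA) and
#' optionally `cohort`.
#'
#' @param path Path to the TSV file.
#' @return `read_clinical`: a data.frame. `write_clinical`: invisibly, `path`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "time", "event")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) stop("clinical table missing column(s): ",
                            paste(missing, collapse = ", "))
  if (any(df$time < 0)) stop("clinical table: negative time")
  if (!all(df$event %in% c(0, 1))) stop("clinical table: event must be 0/1")
  df
}

#' @rdname read_clinical
#' @param clinical Clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gamma (admixture proportion) matrix
#'
#' Samples x latent-signatures matrix of admixture proportions; each row sums
#' to 1. The TSV holds sample IDs in the first column and signature names in
#' the header.
#'
#' @param path Path to the TSV file.
#' @return `read_gamma`: numeric matrix (samples x signatures).
#' @export
read_gamma <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- as.character(df[[1]])
  if (any(g < -1e-9) || any(g > 1 + 1e-9)) stop("gamma entries must lie in [0,1]")
  if (any(abs(rowSums(g) - 1) > 1e-6)) stop("gamma rows must sum to 1")
  g
}

#' @rdname read_gamma
#' @param gamma Gamma matrix (samples x signatures) with dimnames.
#' @export
write_gamma <- function(gamma, path) {
  df <- data.frame(sample_id = rownames(gamma), signif(gamma, 10),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
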