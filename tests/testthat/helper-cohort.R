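# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Default synthetic cohort (seed 1), cached across test files.
default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(sim_config(seed = 1))
  }
  .fixture_env$cohort
}

# Pathway z-score matrix of the default cohort.
default_zscores <- function() {
  if (is.null(.fixture_env$z)) {
    coh <- default_cohort()
    .fixture_env$z <- suppressMessages(
      score_pathways(coh$expression, coh$truth$pathway_sets))
  }
  .fixture_env$z
}

# Small labelled expression matrix for io/scoring unit tests.
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# Exhaustive hypergeometric upper-tail oracle: enumerate every n-subset of a
# universe of size N, with set a = the first m elements, and count subsets
# sharing >= k elements with a.
enum_hyper_upper <- function(k, m, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= m)
  mean(hits >= k)
}
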