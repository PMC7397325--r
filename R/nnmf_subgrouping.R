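#' Split a signed score matrix into nonnegative parts
#'
#' NMF needs nonnegative input but pathway activation z-scores are signed.
#' Each row `r` is split into `max(r, 0)` and `max(-r, 0)`, doubling the row
#' count while preserving all sign information; the original row is exactly
#' the difference of its positive- and negative-part rows.
#'
#' @param z Numeric matrix (e.g. pathways x samples) with finite entries.
#' @return Nonnegative matrix with `2 * nrow(z)` rows; row names carry
#'   `_pos` / `_neg` suffixes.
#' @export
nonneg_transform <- function(z) {
  stopifnot(is.matrix(z), is.numeric(z))
  if (any(!is.finite(z))) stop("nonneg_transform: non-finite entries")
  pos <- pmax(z, 0)
  neg <- pmax(-z, 0)
  rn <- rownames(z)
  if (is.null(rn)) rn <- paste0("row", seq_len(nrow(z)))
  out <- rbind(pos, neg)
  rownames(out) <- c(paste0(rn, "_pos"), paste0(rn, "_neg"))
  out
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius loss \eqn{\|X - WH\|_F^2} with Lee-Seung
#' multiplicative updates from a random nonnegative initialization. The
#' objective trace is nonincreasing; iteration stops at `max_iter` or when
#' the relative objective change falls below `tol`.
#'
#' @param X Nonnegative numeric matrix (features x samples).
#' @param rank Factorization rank, `2 <= rank < min(dim(X))` (rank 1 is
#'   allowed for degenerate test cases).
#' @param seed Integer seed for the initialization.
#' @param max_iter Maximum iterations (default 2000).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @return List of class `nmf_fit`: `W` (features x rank), `H`
#'   (rank x samples), `objective_trace`, `iterations`, `seed`.
#' @export
nmf <- function(X, rank, seed = 1L, max_iter = 2000, tol = 1e-6) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (any(X < 0)) stop("nmf: input must be nonnegative")
  if (rank < 1 || rank >= min(dim(X))) {
    stop("nmf: rank out of range [1, min(dim) - 1]")
  }
  set.seed(as.integer(seed))
  n <- nrow(X); m <- ncol(X)
  W <- matrix(stats::runif(n * rank), n, rank)
  H <- matrix(stats::runif(rank * m), rank, m)
  eps <- .Machine$double.eps
  obj <- numeric(max_iter + 1)
  obj[1] <- sum((X - W %*% H)^2)
  it <- 0
  for (i in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H) / (W %*% tcrossprod(H) + eps))
    obj[i + 1] <- sum((X - W %*% H)^2)
    it <- i
    if (obj[i] - obj[i + 1] < tol * max(obj[i], eps)) break
  }
  structure(list(W = W, H = H, objective_trace = obj[seq_len(it + 1)],
                 iterations = it, seed = as.integer(seed)),
            class = "nmf_fit")
}

#' Assign samples to subgroups from an NMF fit
#'
#' Sample `t` is assigned to the subgroup `k` maximizing `H[k, t]`; ties
#' break toward the smallest index.
#'
#' @param fit An `nmf_fit` from [nmf()].
#' @return Integer vector of subgroup labels (named by sample if `H` has
#'   column names).
#' @export
assign_subgroups <- function(fit) {
  stopifnot(inherits(fit, "nmf_fit"))
  H <- fit$H
  if (any(colSums(H) == 0)) {
    stop("unassignable error: all-zero H column(s)")
  }
  labels <- apply(H, 2, which.max)
  if (!is.null(colnames(H))) names(labels) <- colnames(H)
  labels
}

#' Consensus matrix and cophenetic coefficient for one rank
#'
#' Runs [nmf()] `n_runs` times from different random initializations, assigns
#' samples to their argmax `H` row in each run, and records the fraction of
#' runs in which each sample pair co-clusters. The cophenetic coefficient is
#' the Pearson correlation between the consensus distances `1 - consensus`
#' and the cophenetic distances of their average-linkage hierarchical
#' clustering; values near 1 indicate a stable clustering at this rank.
#'
#' @param X Nonnegative matrix (features x samples).
#' @param rank Factorization rank.
#' @param n_runs Number of random restarts (default 30, must be >= 2).
#' @param seed Integer; run `i` uses `seed + i - 1`.
#' @param max_iter,tol Passed to [nmf()].
#' @return List of class `consensus_result`: `rank`, `consensus`
#'   (samples x samples, unit diagonal), `cophenetic`.
#' @export
consensus_nmf <- function(X, rank, n_runs = 30, seed = 1L,
                          max_iter = 2000, tol = 1e-6) {
  if (n_runs < 2) stop("consensus_nmf: n_runs must be >= 2")
  m <- ncol(X)
  co <- matrix(0, m, m)
  for (i in seq_len(n_runs)) {
    fit <- nmf(X, rank, seed = seed + i - 1L, max_iter = max_iter, tol = tol)
    lab <- assign_subgroups(fit)
    Z <- outer(lab, lab, "==")
    co <- co + Z
  }
  consensus <- co / n_runs
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(X), colnames(X))
  structure(list(rank = rank, consensus = consensus,
                 cophenetic = cophenetic_coefficient(consensus)),
            class = "consensus_result")
}

#' Cophenetic coefficient of a consensus matrix
#'
#' @param consensus Symmetric samples x samples matrix with entries in
#'   \[0,1\] and unit diagonal.
#' @return Correlation between `1 - consensus` distances and the cophenetic
#'   distances of their average-linkage dendrogram; 1 when either set of
#'   distances is constant (perfectly stable clustering).
#' @export
cophenetic_coefficient <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(d) == 0 || stats::sd(cd) == 0) return(1)
  stats::cor(as.vector(d), as.vector(cd))
}

#' Select the NMF rank by the cophenetic coefficient
#'
#' Computes [consensus_nmf()] for each candidate rank and returns the rank
#' with the highest cophenetic coefficient (ties break toward the smallest
#' rank), the standard consensus-clustering rule for choosing the number of
#' molecular subgroups.
#'
#' @param X Nonnegative matrix (features x samples).
#' @param ranks Candidate ranks (default 2:6).
#' @param n_runs Restarts per rank (default 30).
#' @param seed Integer seed; each rank uses an offset block of seeds.
#' @param max_iter,tol Passed to [nmf()].
#' @return List: `rank` (chosen), `table` (data.frame rank x cophenetic),
#'   `consensus` (list of `consensus_result`, one per rank).
#' @export
select_rank <- function(X, ranks = 2:6, n_runs = 30, seed = 1L,
                        max_iter = 2000, tol = 1e-6) {
  ranks <- sort(unique(as.integer(ranks)))
  results <- lapply(seq_along(ranks), function(i) {
    consensus_nmf(X, ranks[i], n_runs = n_runs,
                  seed = seed + (i - 1L) * 1000L, max_iter = max_iter, tol = tol)
  })
  coph <- vapply(results, `[[`, numeric(1), "cophenetic")
  names(results) <- paste0("rank", ranks)
  list(rank = ranks[which.max(coph)],
       table = data.frame(rank = ranks, cophenetic = coph),
       consensus = results)
}

#' Train a balanced random-forest subgroup classifier
#'
#' Trains a random forest (default 5001 trees) in which each tree's bootstrap
#' is down-sampled per class to the size of the smallest class, so subgroup
#' frequency imbalance does not bias the vote. Used both for the
#' pathway-z-score NMF subgroup classifier and, with gene-expression features
#' and two-class labels, for the HES6-style signature classifier.
#'
#' @param features Numeric matrix, features x samples.
#' @param labels Vector of class labels, one per sample (>= 2 classes, each
#'   with >= 2 samples).
#' @param n_trees Number of trees (default 5001).
#' @param seed Integer seed.
#' @return List of class `subgroup_classifier`: `model` (randomForest),
#'   `oob_accuracy`, `auc` (per-class one-vs-rest, from OOB votes), `levels`,
#'   `seed`.
#' @export
train_subgroup_classifier <- function(features, labels, n_trees = 5001, seed = 1L) {
  stopifnot(is.matrix(features))
  y <- factor(labels)
  if (nlevels(y) < 2) stop("training error: need >= 2 classes")
  tab <- table(y)
  if (any(tab < 2)) stop("training error: every class needs >= 2 samples")
  if (ncol(features) != length(y)) stop("features/labels length mismatch")
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = t(features), y = y, ntree = n_trees,
    strata = y, sampsize = rep(min(tab), nlevels(y)))
  oob_pred <- rf$predicted
  auc <- vapply(levels(y), function(cl) {
    auc_rank(rf$votes[, cl], y == cl)
  }, numeric(1))
  structure(list(model = rf, oob_accuracy = mean(oob_pred == y),
                 auc = auc, levels = levels(y), seed = as.integer(seed)),
            class = "subgroup_classifier")
}

# Rank-based (Mann-Whitney) AUC of score against a binary truth.
auc_rank <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Apply a trained subgroup classifier
#'
#' @param classifier A `subgroup_classifier` from [train_subgroup_classifier()].
#' @param features Numeric matrix, features x samples, same feature rows as
#'   at training.
#' @return List: `labels` (majority-vote class per sample), `votes`
#'   (samples x classes vote fractions).
#' @export
apply_classifier <- function(classifier, features) {
  stopifnot(inherits(classifier, "subgroup_classifier"))
  votes <- stats::predict(classifier$model, t(features), type = "vote")
  labels <- factor(classifier$levels[max.col(votes, ties.method = "first")],
                   levels = classifier$levels)
  names(labels) <- colnames(features)
  list(labels = labels, votes = votes)
}
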