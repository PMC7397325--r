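#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of observing at least the given overlap between two
#' gene sets drawn from a common universe: with sets of sizes `m` and `n`
#' (after restriction to the universe of size `N`) sharing `k` genes,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, m, n)`. The log10 p-value is
#' also computed by log-space summation so overlaps far beyond double
#' underflow (p < 1e-300) remain comparable.
#'
#' @param a,b Character vectors of gene IDs.
#' @param universe Character vector of gene IDs defining the universe; `a`
#'   and `b` are intersected with it before testing.
#' @param a_name,b_name Optional set names for the result.
#' @return List of class `overlap_result`: `set_a_name`, `set_b_name`, `k`,
#'   `m`, `n`, `N`, `p`, `log10_p`.
#' @export
hypergeom_overlap <- function(a, b, universe,
                              a_name = "set_a", b_name = "set_b") {
  universe <- unique(universe)
  if (!length(universe)) stop("degenerate-input error: empty universe")
  a <- intersect(unique(a), universe)
  b <- intersect(unique(b), universe)
  if (!length(a) || !length(b)) {
    stop("degenerate-input error: empty set after universe restriction")
  }
  k <- length(intersect(a, b))
  m <- length(a); n <- length(b); N <- length(universe)
  if (k == 0) {
    p <- 1; log10_p <- 0
  } else {
    # P(X >= k) summed in log space over the support [k, min(m, n)]
    j <- k:min(m, n)
    lt <- stats::dhyper(j, m, N - m, n, log = TRUE)
    mx <- max(lt)
    logp <- mx + log(sum(exp(lt - mx)))
    p <- exp(logp)
    log10_p <- logp / log(10)
  }
  structure(list(set_a_name = a_name, set_b_name = b_name,
                 k = k, m = m, n = n, N = N, p = p, log10_p = log10_p),
            class = "overlap_result")
}

#' Pairwise hypergeometric overlaps for a signature catalogue
#'
#' Tests every pair of gene sets against a common universe; self-pairs are
#' reported with `k = m`.
#'
#' @param sets Named list of >= 2 character vectors of gene IDs.
#' @param universe Character vector of gene IDs.
#' @return List: `p`, `log10_p`, `k` (symmetric matrices) and `results`
#'   (long-format data.frame over unordered pairs including self-pairs).
#' @export
pairwise_overlap_matrix <- function(sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (length(sets) < 2) stop("pairwise_overlap_matrix requires >= 2 sets")
  nm <- names(sets)
  L <- length(sets)
  pm <- matrix(NA_real_, L, L, dimnames = list(nm, nm))
  lm <- pm
  km <- matrix(NA_integer_, L, L, dimnames = list(nm, nm))
  rows <- list()
  for (i in seq_len(L)) {
    for (j in i:L) {
      r <- hypergeom_overlap(sets[[i]], sets[[j]], universe,
                             a_name = nm[i], b_name = nm[j])
      pm[i, j] <- pm[j, i] <- r$p
      lm[i, j] <- lm[j, i] <- r$log10_p
      km[i, j] <- km[j, i] <- r$k
      rows[[length(rows) + 1]] <- data.frame(
        set_a = nm[i], set_b = nm[j], k = r$k, m = r$m, n = r$n, N = r$N,
        p = r$p, log10_p = r$log10_p, stringsAsFactors = FALSE)
    }
  }
  list(p = pm, log10_p = lm, k = km, results = do.call(rbind, rows))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; a thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("bh_adjust: p-values must lie in [0,1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Newton solve of trigamma(x) = y, vectorized; mirrors the standard
# moment-matching machinery for the scaled-F variance model.
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Moderated-t differential expression, one subgroup vs rest
#'
#' For each subgroup, compares its samples against all others with a
#' moderated t-test: per-gene pooled variances are shrunk toward an
#' empirical-Bayes prior (`s0^2` with `d0` prior degrees of freedom estimated
#' by method of moments on the log variances, floored at 1), the moderated
#' statistic is `t = (mean1 - mean2) / (s_tilde * sqrt(1/n1 + 1/n2))` on
#' `d0 + n1 + n2 - 2` degrees of freedom, and two-sided p-values are BH
#' adjusted within each contrast. Genes are called significant when the
#' adjusted p-value is below `fdr_threshold` AND the absolute linear fold
#' change exceeds `fc_threshold` (expression is assumed log2 scale, so the
#' filter is `|delta log2| > log2(fc_threshold)`).
#'
#' @param matrix Expression matrix (genes x samples, log2 scale).
#' @param labels Subgroup label per sample (each subgroup needs >= 3 samples).
#' @param fdr_threshold Adjusted-p cutoff (default 0.001).
#' @param fc_threshold Linear fold-change cutoff (default 1.4).
#' @param prior_df Optional override for the prior degrees of freedom `d0`;
#'   `0` disables shrinkage, recovering the ordinary pooled t-test.
#' @return List of class `de_result`: `tables` (per-subgroup data.frames with
#'   gene, log2fc, t, df, p, adj_p, significant), `significant` (per-subgroup
#'   gene ID vectors), `d0`, `s0_sq`.
#' @export
moderated_t_de <- function(matrix, labels, fdr_threshold = 0.001,
                           fc_threshold = 1.4, prior_df = NULL) {
  check_expression_matrix(matrix)
  labels <- as.vector(labels)
  stopifnot(length(labels) == ncol(matrix))
  groups <- sort(unique(labels))
  tab <- table(labels)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    stop("DE error: subgroup(s) with < 3 samples: ", paste(small, collapse = ", "))
  }
  tables <- list(); sig <- list()
  for (g in groups) {
    in1 <- labels == g
    n1 <- sum(in1); n2 <- sum(!in1)
    m1 <- rowMeans(matrix[, in1, drop = FALSE])
    m2 <- rowMeans(matrix[, !in1, drop = FALSE])
    v1 <- apply(matrix[, in1, drop = FALSE], 1, stats::var)
    v2 <- apply(matrix[, !in1, drop = FALSE], 1, stats::var)
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    s2 <- pmax(s2, 1e-12)
    if (is.null(prior_df)) {
      # method of moments on log variances: Var(log s^2) = trigamma(d/2) + trigamma(d0/2)
      z <- log(s2)
      excess <- stats::var(z) - trigamma(d / 2)
      if (is.finite(excess) && excess > 0) {
        d0 <- max(2 * trigamma_inverse(excess), 1)
      } else {
        d0 <- max(10 * d, 1)  # no excess dispersion: near-complete shrinkage
      }
      s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                     digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- prior_df
      s0_sq <- if (d0 > 0) exp(mean(log(s2))) else 0
    }
    s_tilde_sq <- if (d0 > 0) (d0 * s0_sq + d * s2) / (d0 + d) else s2
    tstat <- (m1 - m2) / sqrt(s_tilde_sq * (1 / n1 + 1 / n2))
    df <- d0 + d
    p <- 2 * stats::pt(-abs(tstat), df = df)
    adj <- bh_adjust(p)
    lfc <- m1 - m2
    significant <- adj < fdr_threshold & abs(lfc) > log2(fc_threshold)
    tables[[as.character(g)]] <- data.frame(
      gene = rownames(matrix), log2fc = lfc, t = tstat, df = df,
      p = p, adj_p = adj, significant = significant,
      row.names = NULL, stringsAsFactors = FALSE)
    sig[[as.character(g)]] <- rownames(matrix)[significant]
  }
  structure(list(tables = tables, significant = sig,
                 fdr_threshold = fdr_threshold, fc_threshold = fc_threshold),
            class = "de_result")
}

#' Sample-level GSEA against a continuous ranking
#'
#' Tests whether a set of samples (e.g. an NMF subgroup) concentrates at the
#' top of a continuous per-sample ranking (e.g. DESNT gamma) using the
#' weighted Kolmogorov-Smirnov running-sum statistic: items are ordered by
#' decreasing score, hits increment the running sum proportionally to
#' `|score|^exponent` (normalized), misses decrement it by `1/(N - n)`, and
#' the enrichment score ES is the running sum's maximum signed deviation.
#' Significance is the permutation fraction of random equal-size member sets
#' with `|ES_perm| >= |ES|`, with a +1 pseudo-count.
#'
#' @param scores Named numeric vector of per-item scores.
#' @param members Character vector of member item names; non-empty strict
#'   subset of `names(scores)`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation draw.
#' @param exponent Hit-weight exponent (default 1 = weighted KS; 0 = classic
#'   unweighted KS).
#' @return List of class `gsea_result`: `es`, `p`, `n_perm`, `running`
#'   (running sum in rank order), `order` (item names in rank order).
#' @export
gsea_enrichment <- function(scores, members, n_perm = 10000, seed = 1L,
                            exponent = 1) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  members <- unique(members)
  if (!length(members)) stop("gsea error: empty member set")
  if (!all(members %in% names(scores))) {
    stop("gsea error: members absent from the ranking")
  }
  N <- length(scores)
  n <- length(members)
  if (n >= N) stop("gsea error: member set must be a strict subset")
  ord <- order(scores, decreasing = TRUE)
  s_ord <- scores[ord]
  hit <- names(s_ord) %in% members

  es_stat <- function(hit_idx_logical) {
    w <- abs(s_ord)^exponent
    hw <- w * hit_idx_logical
    denom <- sum(hw)
    if (denom == 0) hw_norm <- hit_idx_logical / sum(hit_idx_logical)
    else hw_norm <- hw / denom
    run <- cumsum(hw_norm - (!hit_idx_logical) / (N - n))
    unname(run[which.max(abs(run))])
  }
  es <- es_stat(hit)
  set.seed(as.integer(seed))
  perm_es <- vapply(seq_len(n_perm), function(i) {
    ph <- logical(N)
    ph[sample.int(N, n)] <- TRUE
    es_stat(ph)
  }, numeric(1))
  p <- (1 + sum(abs(perm_es) >= abs(es))) / (n_perm + 1)
  w <- abs(s_ord)^exponent
  hw <- w * hit
  hw_norm <- if (sum(hw) == 0) hit / n else hw / sum(hw)
  structure(list(es = es, p = p, n_perm = n_perm,
                 running = unname(cumsum(hw_norm - (!hit) / (N - n))),
                 order = names(s_ord)),
            class = "gsea_result")
}
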