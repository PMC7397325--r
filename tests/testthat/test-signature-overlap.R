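test_that("hypergeometric overlap matches hand values and enumeration", {
  u <- paste0("g", 1:10)
  # disjoint sets: upper tail at zero is exactly 1
  r0 <- hypergeom_overlap(u[1:3], u[4:6], u)
  expect_identical(r0$k, 0L + 0L)
  expect_equal(r0$p, 1)

  # N=10, m=n=5, k=5: only one of C(10,5) draws achieves full overlap
  r5 <- hypergeom_overlap(u[1:5], u[1:5], u)
  expect_equal(r5$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(r5$k, 5L)
})

test_that("hypergeometric p equals exhaustive enumeration on all small instances", {
  set.seed(15)
  for (i in 1:40) {
    N <- sample(5:15, 1)
    m <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    u <- paste0("g", 1:N)
    b <- paste0("g", sample(N, n))
    r <- hypergeom_overlap(u[1:m], b, u)
    expect_equal(r$p, enum_hyper_upper(r$k, m, n, N), tolerance = 1e-12)
  }
})

test_that("log-space tail survives far below double underflow", {
  N <- 20000; m <- 500; n <- 500; k <- 450
  u <- paste0("g", 1:N)
  r <- hypergeom_overlap(u[1:m], u[c(1:k, (m + 1):(m + n - k))], u)
  expect_identical(r$k, as.integer(k))
  expect_lt(r$log10_p, -300)
  expect_true(is.finite(r$log10_p))
})

test_that("pairwise overlap matrix is symmetric with sensible extremes", {
  u <- paste0("g", 1:100)
  sets <- list(A = u[1:10], B = u[11:20], C = u[21:30])
  pw <- pairwise_overlap_matrix(sets, u)
  expect_true(all(pw$p[upper.tri(pw$p)] == 1))
  expect_equal(pw$p, t(pw$p))
  expect_equal(diag(pw$k), c(10L, 10L, 10L), ignore_attr = TRUE)

  dup <- list(A = u[1:10], A2 = u[1:10])
  pwd <- pairwise_overlap_matrix(dup, u)
  # duplicated set attains the minimal achievable p for its sizes
  expect_equal(pwd$p["A", "A2"],
               hypergeom_overlap(u[1:10], u[1:10], u)$p)
  expect_equal(pwd$k["A", "A2"], 10L)
})

test_that("converging synthetic signature pairs overlap more significantly than nulls", {
  coh <- default_cohort()
  sets <- generate_signature_collection(coh$truth, sim_config(), 0.6, seed = 8)
  u <- rownames(coh$expression)
  pw <- pairwise_overlap_matrix(sets, u)
  converging <- vapply(1:3, function(k) {
    pw$log10_p[sprintf("SIG_SG%d_1", k), sprintf("SIG_SG%d_2", k)]
  }, numeric(1))
  nm <- names(sets)
  off <- pw$log10_p[nm, nm]
  pool <- sub("_[0-9]$", "", nm)
  same_pool <- outer(pool, pool, "==")
  null_pairs <- off[upper.tri(off) & !same_pool]
  expect_lt(max(converging), min(null_pairs))
})

test_that("BH adjustment matches hand step-up calculations", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.005, 0.011, 0.02, 0.04, 0.13)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0,1\\]")
})

test_that("moderated t with zero prior df reduces to the ordinary pooled t-test", {
  set.seed(33)
  m <- toy_matrix(matrix(rnorm(50 * 12), 50, 12))
  lab <- rep(c(1, 2), each = 6)
  de <- moderated_t_de(m, lab, prior_df = 0)
  tt <- apply(m, 1, function(x) {
    stats::t.test(x[lab == 1], x[lab == 2], var.equal = TRUE)$statistic
  })
  expect_equal(de$tables[["1"]]$t, unname(tt), tolerance = 1e-10)
})

test_that("null data yields essentially no significant genes at FDR 0.001", {
  total <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    m <- toy_matrix(matrix(rnorm(1000 * 30), 1000, 30))
    lab <- rep(c(1, 2), each = 15)
    de <- moderated_t_de(m, lab)
    total <- total + length(de$significant[["1"]])
  }
  expect_lte(total, 2)
})

test_that("a strongly spiked gene is detected and the fold-change filter holds", {
  set.seed(77)
  m <- toy_matrix(matrix(rnorm(200 * 100, sd = 0.5), 200, 100))
  lab <- rep(c(1, 2), each = 50)
  m["g1", lab == 1] <- m["g1", lab == 1] + 1.5   # true log2 FC 1.5
  de <- moderated_t_de(m, lab)
  expect_true("g1" %in% de$significant[["1"]])

  # tiny p but fold change below 1.4 on the linear scale: excluded
  m["g2", lab == 1] <- m["g2", lab == 1] + log2(1.3)
  de2 <- moderated_t_de(m, lab)
  tab <- de2$tables[["1"]]
  g2 <- tab[tab$gene == "g2", ]
  expect_lt(g2$adj_p, 0.001)
  expect_false(g2$significant)

  expect_error(moderated_t_de(m, c(rep(1, 2), rep(2, 98))), "< 3 samples")
})

test_that("moderated t ranks agree with the limma empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(55)
  m <- toy_matrix(matrix(rnorm(300 * 20), 300, 20))
  lab <- rep(c(1, 2), each = 10)
  m[1:30, lab == 1] <- m[1:30, lab == 1] + rep(runif(30, 0.5, 2), 10)
  de <- moderated_t_de(m, lab)
  design <- cbind(1, lab == 1)
  lfit <- limma::eBayes(limma::lmFit(m, design))
  expect_gt(cor(de$tables[["1"]]$t, lfit$t[, 2], method = "spearman"), 0.99)
})

test_that("GSEA enrichment score matches the hand running-sum evaluation", {
  scores <- setNames(10:1, paste0("s", 1:10))
  # members are the top three ranks: the running sum climbs to exactly 1
  # before the first miss, so ES = 1
  res <- gsea_enrichment(scores, c("s1", "s2", "s3"), n_perm = 200, seed = 1)
  expect_equal(res$es, 1, tolerance = 1e-12)
  expect_lt(res$p, 0.05)

  # hand value for interleaved members {s1, s4}: weights 10,7 of total 17,
  # misses decrement by 1/8
  res2 <- gsea_enrichment(scores, c("s1", "s4"), n_perm = 200, seed = 1)
  run <- c(10 / 17, 10 / 17 - 1 / 8, 10 / 17 - 2 / 8, 10 / 17 - 2 / 8 + 7 / 17)
  expect_equal(res2$es, max(abs(run)) * sign(run[which.max(abs(run))]),
               tolerance = 1e-12)
  expect_equal(res2$running[1:4], run, tolerance = 1e-12)
})

test_that("random member sets give null p-values and errors are raised", {
  set.seed(2)
  scores <- setNames(rnorm(60), paste0("s", 1:60))
  ps <- vapply(1:11, function(i) {
    set.seed(i)
    members <- sample(names(scores), 10)
    gsea_enrichment(scores, members, n_perm = 400, seed = i)$p
  }, numeric(1))
  expect_gt(median(ps), 0.1)

  expect_error(gsea_enrichment(scores, character(0)), "empty")
  expect_error(gsea_enrichment(scores, names(scores)), "strict subset")
})

test_that("with exponent 0 the GSEA p is invariant to monotone score rescaling", {
  set.seed(4)
  scores <- setNames(sort(rnorm(40), decreasing = TRUE), paste0("s", 1:40))
  members <- paste0("s", c(1, 3, 5, 8, 13))
  a <- gsea_enrichment(scores, members, n_perm = 500, seed = 9, exponent = 0)
  b <- gsea_enrichment(exp(scores) * 4, members, n_perm = 500, seed = 9,
                       exponent = 0)
  expect_equal(a$es, b$es, tolerance = 1e-12)
  expect_equal(a$p, b$p)
})
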