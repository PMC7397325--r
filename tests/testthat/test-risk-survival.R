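test_that("CCP score matches direct arithmetic and is affine invariant", {
  m <- toy_matrix(matrix(c(1, 2, 3, 4), 4, 1))
  s <- prolaris_score(m, c("g3", "g4"))
  expect_equal(unname(s), mean(c(0.5, 1.5) / sqrt(5 / 3)), tolerance = 1e-12)
  expect_equal(unname(s), 0.7746, tolerance = 1e-4)

  # genes at the sample mean score zero
  expect_equal(unname(prolaris_score(m, c("g1", "g4"))), 0)

  # affine transform of the sample leaves the score unchanged
  s2 <- prolaris_score(m * 2.5 + 7, c("g3", "g4"))
  expect_equal(s2, s, tolerance = 1e-12)

  expect_error(prolaris_score(toy_matrix(matrix(c(2, 2), 2, 1)), "g1"),
               "degenerate-sample")
  expect_error(prolaris_score(m, "nope"), "CCP")
})

test_that("top-quartile flagging is exact for all cohort sizes", {
  set.seed(1)
  s200 <- setNames(rnorm(200), sprintf("s%03d", 1:200))
  expect_identical(sum(prolaris_flag(s200)), 50L)
  # flagged samples are exactly the 50 highest scores
  expect_setequal(names(which(prolaris_flag(s200))),
                  names(sort(s200, decreasing = TRUE))[1:50])

  s4 <- setNames(c(1, 4, 2, 3), paste0("s", 1:4))
  f4 <- prolaris_flag(s4)
  expect_identical(sum(f4), 1L)
  expect_true(f4[["s2"]])

  for (N in c(5, 7, 50, 101, 333)) {
    sc <- setNames(rnorm(N), sprintf("x%04d", 1:N))
    expect_identical(sum(prolaris_flag(sc)), as.integer(ceiling(0.25 * N)))
  }

  # all-equal scores: first ceiling(N/4) by sample-ID order, with a message
  eq <- setNames(rep(1, 8), paste0("s", 1:8))
  expect_message(fe <- prolaris_flag(eq), "ties")
  expect_identical(names(which(fe)), c("s1", "s2"))

  expect_error(prolaris_flag(setNames(1:3, letters[1:3])), ">= 4")
})

test_that("DESNT assignment requires a strictly maximal gamma", {
  g <- rbind(c(0.6, 0.3, 0.1),
             c(0.5, 0.5, 0.0),
             c(1 / 3, 1 / 3, 1 / 3))
  dimnames(g) <- list(paste0("s", 1:3), c("DESNT", "A", "B"))
  expect_identical(unname(assign_desnt(g)), c(TRUE, FALSE, FALSE))
  expect_error(assign_desnt(g[, c("A", "B")]), "DESNT")
})

test_that("flag intersections conserve counts and match a hand tally", {
  fl <- data.frame(sample_id = paste0("s", 1:6),
                   desnt = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                   nmf1 = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
                   prolaris = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
                   hes6 = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  clin <- data.frame(sample_id = paste0("s", 1:6),
                     time = 1:6, event = c(1, 0, 1, 0, 1, 1))
  tab <- combine_flags(fl, clin)
  expect_equal(nrow(tab), 16)
  expect_equal(sum(tab$n), 6)
  expect_equal(sum(tab$events), 4)
  cell <- tab[tab$desnt & tab$nmf1 & tab$prolaris & tab$hes6, ]
  expect_equal(cell$n, 1)       # s5
  expect_equal(cell$events, 1)
  none <- tab[!tab$desnt & !tab$nmf1 & !tab$prolaris & !tab$hes6, ]
  expect_equal(none$n, 2)       # s3, s4
  expect_equal(none$events, 1)

  all_false <- data.frame(desnt = rep(FALSE, 5), nmf1 = FALSE,
                          prolaris = FALSE, hes6 = FALSE,
                          row.names = paste0("s", 1:5))
  tf <- combine_flags(all_false)
  expect_equal(tf$n[!tf$desnt & !tf$nmf1 & !tf$prolaris & !tf$hes6], 5)
  expect_equal(sum(tf$n), 5)
})

test_that("Kaplan-Meier estimates match hand product-limit calculations", {
  # times (1, 2+, 3) with events at 1 and 3: S(1) = 2/3, S(3) = 0
  km <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$surv, c(2 / 3, 0), tolerance = 1e-12)

  # no events: flat curve, quantile undefined
  km0 <- km_fit(c(1, 2, 3), c(0, 0, 0))
  expect_length(km0$time, 0)
  expect_true(is.na(time_to_event_quantile(km0, 0.25)))

  # n distinct event times without censoring: steps (n-k)/n
  kmn <- km_fit(1:5, rep(1, 5))
  expect_equal(kmn$surv, (4:0) / 5, tolerance = 1e-12)
  expect_true(all(diff(kmn$surv) <= 0))
  expect_true(all(kmn$surv >= 0 & kmn$surv <= 1))

  expect_error(km_fit(numeric(0), numeric(0)), "empty")
})

test_that("time-to-quantile reads the curve correctly", {
  km <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(time_to_event_quantile(km, 0.25), 1)  # S(1)=2/3 <= 0.75
  expect_equal(time_to_event_quantile(km, 0), 1)     # first event time

  # curve never below 0.75: undefined
  km_hi <- km_fit(c(1, 2, 3, 4, 5), c(1, 0, 0, 0, 0))
  expect_true(is.na(time_to_event_quantile(km_hi, 0.25)))
})

test_that("log-rank test is zero on duplicated groups and label-invariant", {
  t1 <- c(2, 4, 6, 8); e1 <- c(1, 1, 0, 1)
  lr <- logrank_test(c(t1, t1), c(e1, e1), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  set.seed(8)
  tm <- rexp(30); ev <- rbinom(30, 1, 0.7); gr <- rep(1:2, 15)
  a <- logrank_test(tm, ev, gr)
  b <- logrank_test(tm, ev, c("x", "y")[gr])
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)

  expect_error(logrank_test(t1, rep(0, 4), rep(1:2, 2)), "no events")
  expect_error(logrank_test(t1, e1, rep(1, 4)), ">= 2")
})

test_that("log-rank p agrees with the exhaustive permutation distribution", {
  # 8 samples, two groups of 4: enumerate all C(8,4) = 70 label assignments
  tm <- c(1.1, 2.3, 3.2, 4.8, 5.5, 6.1, 7.9, 9.4)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 1)
  gr <- c(1, 1, 1, 1, 2, 2, 2, 2)
  obs <- logrank_test(tm, ev, gr)
  combos <- combn(8, 4)
  stats <- apply(combos, 2, function(idx) {
    g <- rep(2, 8); g[idx] <- 1
    logrank_test(tm, ev, g)$statistic
  })
  p_perm <- mean(stats >= obs$statistic - 1e-9)
  expect_lt(abs(obs$p - p_perm), 0.1)
})

test_that("Cox regression recovers null and nonnull effects", {
  set.seed(3)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, rate = 0.05 * exp(0.7 * x))
  cc <- rexp(n, rate = 0.05)
  clin <- data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc))
  noise <- rnorm(n)
  fit <- cox_ph(clin, data.frame(x = x, noise = noise))
  bx <- fit[fit$term == "x", ]
  expect_lt(abs(bx$beta - 0.7), 3 * bx$se)
  bn <- fit[fit$term == "noise", ]
  expect_lt(abs(bn$beta), 3 * bn$se)
  expect_true(all(fit$lower < fit$hr & fit$hr < fit$upper))

  expect_error(cox_ph(clin, data.frame(k = rep(1, n))), "constant")
})

test_that("Cox score test at beta = 0 equals the log-rank statistic", {
  set.seed(12)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, rate = 0.1 * exp(0.5 * x))  # continuous: no ties
  ev <- rbinom(n, 1, 0.8)
  ev[1] <- 1
  clin <- data.frame(time = tm, event = ev)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = cbind(clin, x = x))
  lr <- logrank_test(tm, ev, x)
  expect_equal(unname(summary(fit)$sctest["test"]), lr$statistic,
               tolerance = 1e-8)
})

test_that("Cox Wald intervals attain near-nominal coverage", {
  covered <- 0
  for (s in 1:200) {
    set.seed(2000 + s)
    n <- 500
    x <- rbinom(n, 1, 0.5)
    tt <- rexp(n, rate = 0.03 * exp(0.7 * x))
    cc <- rexp(n, rate = 0.03)
    clin <- data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc))
    fit <- cox_ph(clin, data.frame(x = x))
    covered <- covered + (fit$lower <= exp(0.7) && exp(0.7) <= fit$upper)
  }
  expect_gte(covered / 200, 0.92)
  expect_lte(covered / 200, 0.98)
})

test_that("stratification conserves samples and degrades gracefully", {
  coh <- default_cohort()
  tr <- coh$truth
  sc <- prolaris_score(coh$expression, tr$de_genes[[1]][1:31])
  fl <- data.frame(sample_id = coh$clinical$sample_id,
                   desnt = unname(assign_desnt(tr$gamma_true)),
                   nmf1 = unname(tr$subgroup == 1),
                   prolaris = unname(prolaris_flag(sc)))
  st <- stratify_interaction(fl, coh$clinical, components = c("nmf1", "prolaris"))
  expect_equal(sum(st$strata_n), nrow(fl))
  expect_equal(nrow(st$pairwise), choose(4, 2))
  expect_true(all(st$pairwise$adj_p >= st$pairwise$p, na.rm = TRUE))
  expect_true(!is.null(st$cox))
  expect_equal(st$cox$term, c("n_flags", "gleason"))
  # more positive flags must raise the hazard on this generative model
  expect_gt(st$cox$beta[st$cox$term == "n_flags"], 0)

  # all flags false: single stratum, comparisons skipped with a notice
  fl0 <- data.frame(sample_id = coh$clinical$sample_id,
                    desnt = FALSE, nmf1 = FALSE, prolaris = FALSE)
  expect_message(st0 <- stratify_interaction(fl0, coh$clinical,
                                             components = "nmf1"),
                 "skipped")
  expect_null(st0$pairwise)
  expect_equal(unname(st0$strata_n["neither"]), nrow(fl0))
})
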