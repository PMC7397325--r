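#' Cell-cycle-progression (Prolaris-style) score
#'
#' For each sample, the mean of the within-sample z-score normalised
#' expression of the cell-cycle-progression (CCP) genes present in the
#' matrix: `score(t) = mean over CCP genes g of (x[g,t] - mean_t) / sd_t`,
#' with the mean and SD taken over all genes of the sample.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param ccp_genes Character vector of CCP gene IDs (at least one present).
#' @return Named numeric vector of per-sample scores.
#' @export
prolaris_score <- function(matrix, ccp_genes) {
  check_expression_matrix(matrix)
  if (nrow(matrix) < 2) stop("prolaris_score requires >= 2 genes")
  present <- intersect(ccp_genes, rownames(matrix))
  if (!length(present)) stop("no CCP genes present in the matrix")
  mu <- colMeans(matrix)
  n <- nrow(matrix)
  sdv <- sqrt((colSums(matrix^2) - n * mu^2) / (n - 1))
  if (any(sdv == 0 | !is.finite(sdv))) {
    stop("degenerate-sample error: zero expression SD")
  }
  z <- sweep(sweep(matrix[present, , drop = FALSE], 2, mu, "-"), 2, sdv, "/")
  colMeans(z)
}

#' Flag the top quartile of a risk score as high-risk
#'
#' Flags exactly the `ceiling((1 - quantile) * N)` highest-scoring samples
#' (default: the top 25%). Ties at the boundary are resolved by score then by
#' sample-ID order, and the tie-break is reported with a message.
#'
#' @param scores Named numeric vector of per-sample scores (N >= 4).
#' @param quantile Lower-quantile cutoff (default 0.75, i.e. the top 25%).
#' @return Named logical vector, `TRUE` for high-risk samples.
#' @export
prolaris_flag <- function(scores, quantile = 0.75) {
  stopifnot(is.numeric(scores))
  if (is.null(names(scores))) names(scores) <- sprintf("S%04d", seq_along(scores))
  N <- length(scores)
  if (N < 4) stop("prolaris_flag requires >= 4 samples")
  k <- ceiling((1 - quantile) * N)
  ord <- order(-scores, names(scores))
  cutoff_score <- scores[ord][k]
  if (sum(scores == cutoff_score) > 1) {
    message("prolaris_flag: ties at the boundary score ",
            signif(cutoff_score, 6), " resolved by sample-ID order")
  }
  flags <- stats::setNames(logical(N), names(scores))
  flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Assign DESNT status from a gamma matrix
#'
#' A sample is a "DESNT cancer" when the DESNT signature's gamma (its
#' admixture proportion) is strictly greater than every other signature's
#' gamma for that sample; ties mean not DESNT.
#'
#' @param gamma Samples x signatures matrix with one column named as
#'   `desnt_column`.
#' @param desnt_column Name of the DESNT column (default `"DESNT"`).
#' @return Named logical vector of DESNT flags.
#' @export
assign_desnt <- function(gamma, desnt_column = "DESNT") {
  stopifnot(is.matrix(gamma))
  if (!desnt_column %in% colnames(gamma)) {
    stop("missing DESNT column: ", desnt_column)
  }
  others <- gamma[, setdiff(colnames(gamma), desnt_column), drop = FALSE]
  flags <- gamma[, desnt_column] > apply(others, 1, max)
  stats::setNames(as.logical(flags), rownames(gamma))
}

#' Tabulate the intersections of the four high-risk flags
#'
#' Counts samples in each of the 16 combinations of the DESNT, NMF1, Prolaris
#' and HES6 high-risk flags; when a clinical table is supplied, the number of
#' PSA failures (events) per cell is added.
#'
#' @param flags Data.frame with logical columns `desnt`, `nmf1`, `prolaris`,
#'   `hes6` and rownames or a `sample_id` column identifying samples.
#' @param clinical Optional clinical data.frame (`sample_id`, `time`, `event`).
#' @return Data.frame of 16 rows: flag combination, `n`, and `events` when
#'   clinical data is given.
#' @export
combine_flags <- function(flags, clinical = NULL) {
  needed <- c("desnt", "nmf1", "prolaris", "hes6")
  missing <- setdiff(needed, colnames(flags))
  if (length(missing)) stop("flags missing column(s): ", paste(missing, collapse = ", "))
  if (any(is.na(flags[, needed]))) stop("flags must be defined for every sample")
  grid <- expand.grid(desnt = c(FALSE, TRUE), nmf1 = c(FALSE, TRUE),
                      prolaris = c(FALSE, TRUE), hes6 = c(FALSE, TRUE))
  key <- function(df) paste(df$desnt, df$nmf1, df$prolaris, df$hes6)
  fk <- key(flags)
  grid$n <- as.integer(table(factor(fk, levels = key(grid))))
  if (!is.null(clinical)) {
    sid <- if ("sample_id" %in% colnames(flags)) flags$sample_id else rownames(flags)
    ev <- clinical$event[match(sid, clinical$sample_id)]
    grid$events <- vapply(key(grid), function(kk) sum(ev[fk == kk]), numeric(1))
  }
  stopifnot(sum(grid$n) == nrow(flags))
  grid
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate via `survival::survfit`, returned as the step
#' function over event times (censored samples leave the risk set after
#' their censoring time, conventionally).
#'
#' @param times Nonnegative follow-up times (months).
#' @param events Event indicators (1 = biochemical recurrence, 0 = censored).
#' @return List of class `km_curve`: `time` (event times, ascending), `surv`,
#'   `n_risk`, `n_event`, `n` (cohort size).
#' @export
km_fit <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (!length(times)) stop("km_fit: empty input")
  if (any(times < 0)) stop("km_fit: negative times")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- sf$n.event > 0
  structure(list(time = sf$time[keep], surv = sf$surv[keep],
                 n_risk = sf$n.risk[keep], n_event = sf$n.event[keep],
                 n = length(times)),
            class = "km_curve")
}

#' Time until a given fraction of events
#'
#' The smallest event time at which the Kaplan-Meier survival estimate drops
#' to or below `1 - q` (e.g. `q = 0.25`: time to 25% events). `NA` when the
#' curve never reaches that level.
#'
#' @param curve A `km_curve` from [km_fit()].
#' @param q Event fraction (default 0.25).
#' @return Time in months, or `NA_real_` when undefined.
#' @export
time_to_event_quantile <- function(curve, q = 0.25) {
  stopifnot(inherits(curve, "km_curve"))
  if (q == 0) {
    return(if (length(curve$time)) curve$time[1] else NA_real_)
  }
  idx <- which(curve$surv <= 1 - q + 1e-12)
  if (!length(idx)) return(NA_real_)
  curve$time[idx[1]]
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected chi-square over pooled event times via
#' `survival::survdiff`, with `length(groups) - 1` degrees of freedom.
#'
#' @param times Follow-up times.
#' @param events Event indicators (0/1).
#' @param groups Group label per sample (>= 2 non-empty groups).
#' @return List: `statistic`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("logrank_test requires >= 2 non-empty groups")
  if (sum(events) == 0) stop("undefined-test error: no events")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie correction via `survival::coxph`;
#' Wald 95% confidence intervals `exp(beta +/- 1.96 SE)`.
#'
#' @param clinical Clinical data.frame with `time` and `event` columns.
#' @param covariates Data.frame of per-sample covariates (rows aligned with
#'   `clinical`); each must take >= 2 distinct values.
#' @return Data.frame: term, beta, se, hr, lower, upper, p.
#' @export
cox_ph <- function(clinical, covariates) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == nrow(clinical))
  if (sum(clinical$event) < 1) stop("cox_ph requires >= 1 event")
  const <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) < 2, logical(1))
  if (any(const)) {
    stop("constant covariate(s): ", paste(names(covariates)[const], collapse = ", "))
  }
  dat <- cbind(clinical[, c("time", "event")], covariates)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(colnames(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron",
                         control = survival::coxph.control(iter.max = 100))
  if (any(is.na(stats::coef(fit)))) {
    stop("cox_ph did not converge: NA coefficient(s); iterations = ", fit$iter)
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  data.frame(term = names(beta), beta = unname(beta), se = unname(se),
             hr = exp(unname(beta)),
             lower = exp(unname(beta) - 1.96 * unname(se)),
             upper = exp(unname(beta) + 1.96 * unname(se)),
             p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stratify by DESNT and SIG-HES6 status and compare outcomes
#'
#' Assigns each sample to one of four strata — `neither`, `desnt_only`
#' (DESNT-flagged but no SIG-HES6 component), `sighes6_only` (at least one of
#' the SIG-HES6 component flags but not DESNT), `both` — then runs pairwise
#' log-rank tests (BH-adjusted across the pairs actually compared), reports
#' the time-to-25%-events per stratum, the 0-4 risk-flag-count groups, and a
#' Cox model of the number of positive flags with Gleason as covariate when
#' available.
#'
#' @param flags Data.frame of logical flags (`desnt`, `nmf1`, `prolaris`,
#'   `hes6`) with a `sample_id` column or rownames.
#' @param clinical Clinical data.frame (`sample_id`, `time`, `event`,
#'   optionally `gleason`).
#' @param components SIG-HES6 component flags to use (default all of
#'   `nmf1`, `prolaris`, `hes6`; any subset present in `flags`).
#' @return List: `strata` (per-sample factor), `strata_n`, `tt25` (per
#'   stratum), `pairwise` (log-rank results with BH-adjusted p), `risk_count`
#'   (per-sample 0-4 count), `risk_count_logrank`, `cox` (or NULL).
#' @export
stratify_interaction <- function(flags, clinical,
                                 components = c("nmf1", "prolaris", "hes6")) {
  components <- intersect(components, colnames(flags))
  if (!length(components)) stop("no SIG-HES6 component flags available")
  if (!"desnt" %in% colnames(flags)) stop("flags must contain a 'desnt' column")
  sid <- if ("sample_id" %in% colnames(flags)) flags$sample_id else rownames(flags)
  idx <- match(sid, clinical$sample_id)
  if (any(is.na(idx))) stop("flags contain samples absent from the clinical table")
  clin <- clinical[idx, ]
  sighes6 <- Reduce(`|`, lapply(components, function(cc) flags[[cc]]))
  strata <- factor(ifelse(flags$desnt & sighes6, "both",
                          ifelse(flags$desnt, "desnt_only",
                                 ifelse(sighes6, "sighes6_only", "neither"))),
                   levels = c("neither", "desnt_only", "sighes6_only", "both"))
  strata_n <- table(strata)
  present <- names(strata_n)[strata_n > 0]

  tt25 <- vapply(levels(strata), function(s) {
    in_s <- strata == s
    if (!sum(in_s)) return(NA_real_)
    time_to_event_quantile(km_fit(clin$time[in_s], clin$event[in_s]), 0.25)
  }, numeric(1))

  pairwise <- NULL
  if (length(present) >= 2) {
    combos <- utils::combn(present, 2)
    rows <- lapply(seq_len(ncol(combos)), function(i) {
      a <- combos[1, i]; b <- combos[2, i]
      sel <- strata %in% c(a, b)
      lr <- tryCatch(logrank_test(clin$time[sel], clin$event[sel],
                                  droplevels(strata[sel])),
                     error = function(e) list(statistic = NA_real_, p = NA_real_))
      data.frame(stratum_a = a, stratum_b = b,
                 statistic = lr$statistic, p = lr$p, stringsAsFactors = FALSE)
    })
    pairwise <- do.call(rbind, rows)
    ok <- !is.na(pairwise$p)
    pairwise$adj_p <- NA_real_
    if (any(ok)) pairwise$adj_p[ok] <- bh_adjust(pairwise$p[ok])
  } else {
    message("stratify_interaction: fewer than 2 non-empty strata; comparisons skipped")
  }

  all_flags <- c("desnt", "nmf1", "prolaris", "hes6")
  have <- intersect(all_flags, colnames(flags))
  risk_count <- Reduce(`+`, lapply(have, function(cc) as.integer(flags[[cc]])))
  rc_logrank <- NULL
  if (length(unique(risk_count)) >= 2 && sum(clin$event) > 0) {
    rc_logrank <- logrank_test(clin$time, clin$event, risk_count)
  }

  cox <- NULL
  if ("gleason" %in% colnames(clin) && length(unique(risk_count)) >= 2 &&
      length(unique(clin$gleason)) >= 2) {
    cox <- cox_ph(clin, data.frame(n_flags = risk_count, gleason = clin$gleason))
  }
  list(strata = stats::setNames(strata, sid), strata_n = strata_n, tt25 = tt25,
       pairwise = pairwise, risk_count = stats::setNames(risk_count, sid),
       risk_count_logrank = rc_logrank, cox = cox)
}
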