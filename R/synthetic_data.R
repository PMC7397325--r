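#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the parameters of the generative model used for
#' testing: three (by default) latent pathway-activation subgroups, Dirichlet
#' admixture proportions (gamma) over latent expression signatures with one
#' DESNT-like signature, subgroup-linked differentially expressed genes, and
#' exponential time-to-recurrence with log-linear covariate effects and
#' independent censoring.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_samples Number of samples (default 300).
#' @param n_pathways Number of control pathways (default 14).
#' @param genes_per_pathway Genes per pathway; pathways are disjoint (default 40).
#' @param n_subgroups Number of latent subgroups (default 3).
#' @param activation_shift Mean expression offset, in within-sample SD units,
#'   added to a subgroup's active pathway genes (default 1.0).
#' @param n_latent_signatures Number of latent gamma signatures; the first is
#'   the DESNT-like one (default 4).
#' @param gamma_concentration Dirichlet concentration for gamma (default 0.5).
#' @param n_de_genes_per_subgroup DE genes per subgroup, disjoint from pathway
#'   genes and from other subgroups' DE genes (default 100).
#' @param de_log2fc Log2 fold change applied to a subgroup's DE genes (default 1.0).
#' @param baseline_hazard Baseline recurrence hazard per month (default 0.01).
#' @param subgroup_log_hazard Log-hazard offset per subgroup (default
#'   `c(1.2, 0, 0.3)`); length must equal `n_subgroups`.
#' @param desnt_gamma_log_hazard Log-hazard multiplier on the DESNT-like gamma
#'   (default 1.5).
#' @param censoring_rate Target censoring proportion in (0,1) (default 0.5).
#' @param noise_sd Gaussian noise SD (default 1.0).
#' @param desnt_tilt Multiplier applied to the DESNT-like gamma concentration
#'   for subgroup-1 samples (default 1 = gamma independent of subgroup; set
#'   above 1 to emulate cohorts where the poor-prognosis subgroup is enriched
#'   for high DESNT gamma).
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_samples = 300, n_pathways = 14,
                       genes_per_pathway = 40, n_subgroups = 3,
                       activation_shift = 1.0, n_latent_signatures = 4,
                       gamma_concentration = 0.5,
                       n_de_genes_per_subgroup = 100, de_log2fc = 1.0,
                       baseline_hazard = 0.01,
                       subgroup_log_hazard = c(1.2, 0, 0.3),
                       desnt_gamma_log_hazard = 1.5,
                       censoring_rate = 0.5, noise_sd = 1.0, desnt_tilt = 1,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, n_samples = n_samples, n_pathways = n_pathways,
              genes_per_pathway = genes_per_pathway, n_subgroups = n_subgroups,
              activation_shift = activation_shift,
              n_latent_signatures = n_latent_signatures,
              gamma_concentration = gamma_concentration,
              n_de_genes_per_subgroup = n_de_genes_per_subgroup,
              de_log2fc = de_log2fc, baseline_hazard = baseline_hazard,
              subgroup_log_hazard = subgroup_log_hazard,
              desnt_gamma_log_hazard = desnt_gamma_log_hazard,
              censoring_rate = censoring_rate, noise_sd = noise_sd,
              desnt_tilt = desnt_tilt, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos_int <- c("n_genes", "n_samples", "n_pathways", "genes_per_pathway",
               "n_subgroups", "n_latent_signatures", "n_de_genes_per_subgroup")
  for (f in pos_int) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stop("configuration error: ", f, " must be a positive integer")
    }
  }
  pos_real <- c("gamma_concentration", "baseline_hazard", "noise_sd")
  for (f in pos_real) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("configuration error: ", f, " must be a positive real")
    }
  }
  if (!is.numeric(cfg$censoring_rate) || cfg$censoring_rate <= 0 ||
      cfg$censoring_rate >= 1) {
    stop("configuration error: censoring_rate must lie in (0,1)")
  }
  if (!is.numeric(cfg$desnt_tilt) || !is.finite(cfg$desnt_tilt) ||
      cfg$desnt_tilt <= 0) {
    stop("configuration error: desnt_tilt must be a positive real")
  }
  if (length(cfg$subgroup_log_hazard) != cfg$n_subgroups) {
    stop("configuration error: subgroup_log_hazard must have length n_subgroups")
  }
  n_structured <- cfg$n_pathways * cfg$genes_per_pathway +
    cfg$n_subgroups * cfg$n_de_genes_per_subgroup +
    cfg$n_latent_signatures * 50
  if (cfg$n_pathways * cfg$genes_per_pathway > cfg$n_genes) {
    stop("configuration error: genes_per_pathway x n_pathways exceeds n_genes")
  }
  if (n_structured > cfg$n_genes) {
    stop("configuration error: n_genes too small for pathway + DE + latent gene blocks")
  }
  if (cfg$n_samples < cfg$n_subgroups) {
    stop("configuration error: n_samples must be >= n_subgroups")
  }
  invisible(cfg)
}

# Dirichlet draws via normalized gamma variates.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Generate a synthetic cohort
#'
#' Draws an expression matrix, clinical table and ground-truth labels under
#' the generative model described in the package vignette: baseline Gaussian
#' noise, plus an `activation_shift` on the active pathway genes of each
#' sample's subgroup, plus `de_log2fc` on the subgroup's DE genes, plus
#' gamma-weighted latent-signature effects (the DESNT-like signature
#' down-regulates its gene block). Recurrence times are exponential with
#' log-hazard `log(baseline_hazard) + subgroup_log_hazard[g] +
#' desnt_gamma_log_hazard * gamma_DESNT`; censoring is an independent
#' exponential tuned to hit `censoring_rate` approximately. By default gamma
#' is independent of subgroup; `desnt_tilt > 1` enriches subgroup 1 for high
#' DESNT gamma.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `expression` (genes x samples matrix),
#'   `clinical` (data.frame: sample_id, time, event, gleason, cohort) and
#'   `truth` (list: subgroup, gamma_true, de_genes, pathway_sets,
#'   pathway_subgroup, latent_blocks).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes; ns <- config$n_samples
  gene_ids <- sprintf("G%06d", seq_len(ng))
  sample_ids <- sprintf("S%04d", seq_len(ns))

  # disjoint gene blocks: pathways, then per-subgroup DE genes, then latent
  np <- config$n_pathways; gpp <- config$genes_per_pathway
  pathway_sets <- lapply(seq_len(np), function(i) {
    gene_ids[((i - 1) * gpp + 1):(i * gpp)]
  })
  names(pathway_sets) <- sprintf("PW%02d", seq_len(np))
  pathway_subgroup <- rep(seq_len(config$n_subgroups), length.out = np)

  off <- np * gpp
  nde <- config$n_de_genes_per_subgroup
  de_genes <- lapply(seq_len(config$n_subgroups), function(k) {
    gene_ids[(off + (k - 1) * nde + 1):(off + k * nde)]
  })
  names(de_genes) <- paste0("subgroup", seq_len(config$n_subgroups))

  off2 <- off + config$n_subgroups * nde
  nl <- config$n_latent_signatures
  latent_blocks <- lapply(seq_len(nl), function(s) {
    gene_ids[(off2 + (s - 1) * 50 + 1):(off2 + s * 50)]
  })
  names(latent_blocks) <- c("DESNT", if (nl > 1) sprintf("LS%d", 2:nl))

  # balanced random subgroup assignment (every subgroup non-empty for ns >= k)
  subgroup <- sample(rep(seq_len(config$n_subgroups), length.out = ns))

  # gamma: Dirichlet; optional DESNT concentration tilt for subgroup 1
  alpha <- rep(config$gamma_concentration, nl)
  gamma_true <- matrix(NA_real_, ns, nl,
                       dimnames = list(sample_ids, names(latent_blocks)))
  in1 <- subgroup == 1
  alpha1 <- alpha; alpha1[1] <- alpha[1] * config$desnt_tilt
  if (any(in1)) gamma_true[in1, ] <- rdirichlet(sum(in1), alpha1)
  if (any(!in1)) gamma_true[!in1, ] <- rdirichlet(sum(!in1), alpha)

  X <- matrix(stats::rnorm(ng * ns, sd = config$noise_sd), ng, ns,
              dimnames = list(gene_ids, sample_ids))
  for (k in seq_len(config$n_subgroups)) {
    active <- unlist(pathway_sets[pathway_subgroup == k], use.names = FALSE)
    cols <- subgroup == k
    if (length(active) && any(cols)) {
      X[active, cols] <- X[active, cols] + config$activation_shift
    }
    X[de_genes[[k]], cols] <- X[de_genes[[k]], cols] + config$de_log2fc
  }
  latent_effect <- ifelse(seq_len(nl) == 1, -1.0, 1.0)
  for (s in seq_len(nl)) {
    X[latent_blocks[[s]], ] <- X[latent_blocks[[s]], ] +
      rep(latent_effect[s] * gamma_true[, s], each = 50)
  }

  # exponential recurrence with log-linear effects; independent censoring
  lambda <- config$baseline_hazard *
    exp(config$subgroup_log_hazard[subgroup] +
          config$desnt_gamma_log_hazard * gamma_true[, 1])
  t_event <- stats::rexp(ns, rate = lambda)
  cens_rate <- config$censoring_rate / (1 - config$censoring_rate) * mean(lambda)
  t_cens <- stats::rexp(ns, rate = cens_rate)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  # Gleason shifted upward in the highest-hazard subgroup
  hi <- which.max(config$subgroup_log_hazard)
  gleason <- integer(ns)
  p_hi <- c(0.10, 0.20, 0.30, 0.25, 0.15)
  p_lo <- c(0.35, 0.30, 0.20, 0.10, 0.05)
  for (i in seq_len(ns)) {
    gleason[i] <- sample(6:10, 1, prob = if (subgroup[i] == hi) p_hi else p_lo)
  }

  clinical <- data.frame(sample_id = sample_ids, time = time, event = event,
                         gleason = gleason, cohort = "SIM1",
                         stringsAsFactors = FALSE)
  names(subgroup) <- sample_ids
  list(expression = X,
       clinical = clinical,
       truth = list(subgroup = subgroup, gamma_true = gamma_true,
                    de_genes = de_genes, pathway_sets = pathway_sets,
                    pathway_subgroup = pathway_subgroup,
                    latent_blocks = latent_blocks))
}

#' Generate a synthetic prognostic-signature collection
#'
#' Builds named gene sets that emulate a catalogue of published prognostic
#' signatures: for each subgroup, two signatures (sizes 31 and 49) draw a
#' fraction `overlap_fraction` of their genes from that subgroup's DE pool
#' and the remainder from unstructured background genes, so "converging"
#' pairs (same pool) and "non-converging" pairs exist by construction. Two
#' pure-background signatures are appended as nulls.
#'
#' @param truth `truth` element of [generate_cohort()] output.
#' @param config The [sim_config()] used to generate the cohort.
#' @param overlap_fraction Fraction of each signature drawn from its
#'   subgroup's DE pool, in \[0,1\].
#' @param seed Integer seed.
#' @return Named list of character vectors of gene IDs.
#' @export
generate_signature_collection <- function(truth, config, overlap_fraction, seed) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0,1]")
  }
  if (!length(truth$de_genes) || !all(lengths(truth$de_genes) > 0)) {
    stop("generation error: empty de_genes pool")
  }
  set.seed(as.integer(seed))
  gene_ids <- sprintf("G%06d", seq_len(config$n_genes))
  structured <- c(unlist(truth$pathway_sets, use.names = FALSE),
                  unlist(truth$de_genes, use.names = FALSE),
                  unlist(truth$latent_blocks, use.names = FALSE))
  background <- setdiff(gene_ids, structured)
  sizes <- c(31, 49)
  sets <- list()
  for (k in seq_along(truth$de_genes)) {
    pool <- truth$de_genes[[k]]
    for (j in seq_along(sizes)) {
      n_de <- round(overlap_fraction * sizes[j])
      n_de <- min(n_de, length(pool))
      genes <- c(sample(pool, n_de),
                 sample(background, sizes[j] - n_de))
      sets[[sprintf("SIG_SG%d_%d", k, j)]] <- sort(genes)
    }
  }
  for (j in seq_along(sizes)) {
    sets[[sprintf("SIG_NULL_%d", j)]] <- sort(sample(background, sizes[j]))
  }
  sets
}
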