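# sigconverge

Prognostic gene-expression signatures for prostate cancer rarely share genes,
even when they predict the same endpoint. When signatures derived by entirely
different routes *do* overlap far beyond chance, the shared genes plausibly sit
on the processes that actually drive progression — and combining such
convergent signature families should stratify patients better than any one
signature alone. `sigconverge` implements the full analysis chain needed to
test that idea on expression cohorts with linked biochemical-recurrence
outcomes, for computational biologists working with bulk transcriptomes:

1. **Cohort assembly** — duplicate-probe collapse (highest mean expression
   wins), per-gene median centering, quantile normalization, gene-intersection
   cohort merging; TSV and GMT readers/writers.
2. **Pathway activation scoring** — the single-sample z-score
   `Z_tS = (X̄_tS − X̄_t) / (σ_t / √|S|)` for a gene set *S* in sample *t*,
   where `X̄_t` and `σ_t` are the mean and SD over all genes of the sample.
3. **Consensus-NMF subgrouping** — signed z-scores are split into
   positive/negative parts, factorized by multiplicative-update Frobenius NMF
   over ranks 2–6 with 30 random restarts per rank, and the rank is selected
   by the cophenetic coefficient of the consensus (co-clustering) matrix;
   samples are assigned by the argmax of H, and a 5001-tree class-balanced
   random forest classifies new cohorts from their 14 pathway z-scores.
4. **Signature convergence** — upper-tail hypergeometric overlap tests between
   signatures (log-space, safe below p = 1e-300), one-vs-rest moderated-t
   differential expression (empirical-Bayes variance shrinkage; FDR < 0.001
   and fold change > 1.4), Benjamini–Hochberg adjustment, and weighted-KS
   GSEA of a sample class against a continuous ranking (10,000 permutations).
5. **Composite risk stratification** — four high-risk rules (DESNT: strictly
   maximal admixture proportion γ; NMF1 subgroup; Prolaris-style top-quartile
   CCP score; HES6-style classifier), their 16-cell intersection table, and
   outcome comparison by Kaplan–Meier curves, time-to-25%-events, BH-adjusted
   pairwise log-rank tests, and Gleason-adjusted Cox regression.
6. **Synthetic cohorts** — a generator with three latent pathway-activation
   subgroups, Dirichlet γ admixture with a DESNT-like component,
   subgroup-linked DE genes, and exponential recurrence with independent
   censoring, so every stage is testable end-to-end without external data.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a simulated
300-sample cohort (run them in order; outputs land in `results/`, full
matrices in `scratch/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_pathway_scores.R
Rscript analysis/03_nnmf_subgroups.R
Rscript analysis/04_signature_overlap.R
Rscript analysis/05_risk_stratification.R
```

Step 3 prints the rank-selection table and recovery diagnostics:

```
Cophenetic coefficients by rank:
 rank cophenetic
    2  0.9278237
    3  1.0000000
    4  0.9990005
    5  0.9955617
    6  0.9897019
Selected rank: 3 (generative truth: 3)
Adjusted Rand index vs simulated truth: 1.000
Random-forest subgroup classifier: OOB accuracy 100.0%, per-class AUC 1.000/1.000/1.000
```

The cophenetic coefficient peaks at rank 3 — consensus clustering is perfectly
stable there — matching the three subgroups built into the simulation, and the
NMF assignment reproduces the generative labels exactly (the synthetic
separation is deliberately clean; real cohorts are messier). Step 5 prints the
stratification that motivates the package:

```
Time to 25% events by stratum (months):
      stratum   n tt25_months
      neither 156      20.870
   desnt_only  44      14.370
 sighes6_only  71       3.354
         both  29       3.425
Cox (Gleason-adjusted): HR per additional positive biomarker = 1.57 (95% CI 1.39-1.78, p = 7.7e-13)
```

Patients flagged by both signature families reach 25% recurrences in months
rather than years, and each additional positive biomarker raises the hazard
independently of Gleason score — the qualitative pattern the convergence
hypothesis predicts (under this simulation's additive hazards the `both` and
`sighes6_only` strata sit close together; see the vignette on this point).

## File formats

- **expression TSV** — header row of sample IDs, first column gene IDs.
- **GMT** — one gene set per line: name, description, tab-separated gene IDs.
- **clinical TSV** — `sample_id`, `time` (months), `event` (0/1), `gleason`,
  `cohort`.
- **gamma TSV** — first column sample IDs, one column per latent signature
  (one named `DESNT`); rows sum to 1.

`inst/extdata/` ships small synthetic stand-in gene sets (14 control pathways,
a 31-gene CCP set, a 222-gene HES6-signature set) keyed to the simulator's
gene IDs; real pathway and signature definitions must be supplied as GMT.
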