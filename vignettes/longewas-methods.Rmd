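---
title: "Methods: longitudinal EWAS with technical and cell-composition adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal EWAS with technical and cell-composition adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longewas)
```

## Scope and model

`longewas` implements an epigenome-wide association (EWAS) workflow for DNA
methylation array data measured longitudinally in a patient/control design:
baseline case-control comparison, prediction of treatment response from
baseline methylation, and within-patient methylation change along treatment,
plus a robust smoking EWAS and the standard QC, filtering and diagnostic
machinery around them. Because no raw data ships with the package, a fully
synthetic EPIC-like generator with known ground truth stands in for real
cohorts; every analysis stage is validated against that truth.

Methylation at probe $j$ in sample $i$ is summarized by the beta value
$\beta_{ij} \in [0,1]$. Linear modelling operates on M-values,
$$M_{ij} = \log_2 \frac{\beta_{ij}}{1-\beta_{ij}},$$
computed after clipping beta into $[\epsilon, 1-\epsilon]$ with
$\epsilon = 0.001$ so the transform stays finite (`beta_to_m()`). The log2
logit is the field convention; the clipping offset only affects probes at
the measurement boundary and is configurable.

## Technical and cell-composition adjustment

Technical variation is summarized by the first $k = 10$ principal
components of the control-probe matrix (`control_pcs()`), column-centered
but not variance-scaled so the intensity-scale structure of the control
probes is preserved. The PC sign convention (largest-magnitude loading
positive) makes scores reproducible.

White-blood-cell composition is estimated per sample by reference-based
deconvolution at 100 signature CpGs (`estimate_cell_fractions()`): with
reference matrix $R$ (CpGs $\times$ 6 leukocyte types: CD8 T, CD4 T, NK,
B, monocytes, granulocytes) and observed signature betas $y$,
$$\hat\omega = \arg\min_{\omega \ge 0,\ \sum\omega \le 1} \lVert y - R\omega \rVert^2,$$
solved exactly as a quadratic program (`quadprog::solve.QP`), not by
clipped unconstrained least squares. The inequality sum constraint leaves
room for an unexplained remainder; the per-sample residual norm is
reported. A rank-deficient reference is rejected with its condition
number.

The first analysis step regresses each probe's M-values on an intercept,
the 10 control PCs and the 6 cell fractions (`residualize()`; exact QR
least squares, collinear covariates are reported by name). Missing betas
(capped by QC) are mean-imputed per probe before PCA and residualization.

## Association designs

* **Case-control** (`welch_case_control()`): Welch's unequal-variance
  t-test on the adjusted M-values, Welch–Satterthwaite df, two-sided p.
  The effect column pairs the test with the raw-beta group difference
  $\Delta\beta$ (patients minus controls) and
  $100\cdot\Delta\beta/\bar\beta_{\text{control}}$, mirroring how such
  tables are conventionally reported. Significant hits are refit post hoc
  with group and comorbid depression as binary predictors
  (`posthoc_depression_adjust()`) and classified as remaining
  significant, suggestive, or dropped.
* **Binary response prediction** (`predict_response_logistic()`):
  maximum-likelihood logistic regression of responder status on baseline
  M-value plus all covariates (control PCs, cell fractions, age, sex,
  smoking, depression, baseline anxiety score) in a single model; Wald z
  and two-sided normal p. Per-probe separation (unstable focal
  coefficient or non-convergence) is flagged and excluded from threshold
  classification — never silently shrunk.
* **Continuous response** (`response_continuous()`): OLS of percent
  anxiety-score improvement on baseline M-value plus the same covariates
  minus the baseline score, via the Frisch–Waugh decomposition (exactly
  the joint-model slope and t).
* **Longitudinal change** (`longitudinal_delta_test()`): within-patient
  differences of adjusted M-values between two timepoints, one-sample
  t-test per probe, separately in responders and non-responders.
* **Smoking** (`smoking_ewas_robust()`): Huber M-estimation
  ($k = 1.345$, 95% Gaussian efficiency) of beta on smoking status plus
  sex, age, cell fractions and control PCs.
* **Overlap** (`overlap_test()`): intersection count with the upper-tail
  hypergeometric probability, computed stably by `phyper()`.

Treatment response is a $\ge 50\%$ decrease of the anxiety score from
baseline (`label_response()`), boundary included; patients missing either
score are labelled missing, controls are excluded.

### Reference distributions and two design choices that matter

All p-values are two-sided. Welch, OLS and paired designs use their exact
t references. The logistic Wald statistic uses the normal reference, the
field standard. The robust design refers $z$ to $t_{n-p}$ and uses the
conventional asymptotic M-estimation covariance with Huber's
finite-sample correction (as in `MASS::summary.rlm`): in calibration
experiments at $n \approx 100$ with 19 covariates, sandwich-type
covariances were too variable (anti-conservative uncorrected, markedly
conservative with HC1 scaling), while the model-based form is
near-nominal on the generator's homoscedastic data.

For the longitudinal design, the technical adjustment is fit in **one
pooled regression over the arrays of both timepoints** rather than per
timepoint. Residualizing each timepoint separately forces each probe's
residuals to sum to zero within the tested samples, so the per-probe
intercept absorbs part of any stratum's mean change and the paired t-test
becomes conservative by construction (null genomic inflation
$\lambda \approx 0.5$–$0.8$ in small strata). In the pooled fit the
within-patient difference contrast is orthogonal to the intercept and
calibration is nominal. This also reflects how array-level technical
adjustment is done in practice: one model over the whole experiment.

## QC and probe filtering

Samples are excluded at baseline (and thereafter) if any of the following
fires (`sample_qc()`, thresholds in `qc_thresholds()`):

* call rate below 0.95 — fraction of non-missing genomic probes passing
  detection (boundary retained: exclusion is strict `<`);
* completely missing signal in at least 5% of probes;
* predicted sex differs from reported sex. The predictor uses chrY
  detection fraction ($\ge 0.5 \Rightarrow$ male) and, when no chrY
  probes exist, the fraction of chrX betas in the intermediate band
  (0.25, 0.75); with no sex-chromosome probes at all the status is
  explicitly "uncallable", never a silent guess;
* a control-probe class mean beyond 4 robust SDs
  (median $\pm\, k \cdot 1.4826 \cdot$ MAD). Class means are computed on
  the logit scale, where control intensities are additive and
  homoscedastic, and each sample is centered on the leave-one-out median
  of its processing batch (scaled for batch size): plate-level shifts are
  ordinary technical variation removed later by the control PCs and must
  not read as per-sample artifacts. With roughly $6 \times n$
  sample-class trials per cohort, a 4-SD rule still admits a small
  false-positive rate (about 0.3 exclusions per 200-sample run); the
  cutoff is configurable.

Probe filtering (`filter_probes()`) removes probes with a SNP within 5 bp
at MAF $\ge 0.01$ (both conditions required), cross-reactive probes,
control probes, and sex-chromosome probes. A probe hit by both the SNP
and cross-reactive rules counts once, tallied under SNP (documented
precedence). Sex-chromosome removal is a deliberate addition: chrX/chrY
probes are bimodal by sex, so any sex imbalance makes unstratified tests
anti-conservative there, and the arithmetic of evaluated-probe counts on
this array class indicates the practice is standard. The family-wise
threshold is $\alpha / n_{\text{evaluated}}$ (`bonferroni_threshold()`);
with 780,145 evaluated probes and $\alpha = 0.05$ this is
$6.409\times 10^{-8}$. Tiers: significant iff $p \le$ threshold
(boundary included), suggestive iff threshold $< p < 10^{-5}$ (strict
upper boundary).

## Diagnostics

`genomic_inflation()` computes
$\lambda = \mathrm{median}\{\chi^2_1(p)\} / \mathrm{median}(\chi^2_1)$
with the reference median evaluated from the inverse CDF at run time
(no transcribed constant). `qq_data()` pairs sorted p-values with
$(\mathrm{rank}-0.5)/n$ expectations on the $-\log_{10}$ scale.
`annotate_and_write()` attaches nearest-gene labels (a manifest lookup —
annotation provenance is the array manifest, not a distance computation),
orders by (p, probe id) with flagged rows last, and emits a BED-like
Manhattan file (`chrom, pos-1, pos, -log10 p, tier`; 0-based half-open).

## The synthetic generator

`generate_cohort()` emulates, with known truth:

* per-probe beta distributions (bimodal mixture of low/mid/high Beta
  components) with logit-normal noise (SD 0.15 on the natural-logit
  scale, ~0.02–0.04 on the beta scale at typical probes) — the logit
  noise keeps $[0,1]$ support and makes M-values exactly Gaussian;
* cell mixtures: Dirichlet weights (granulocyte-dominated, whole-blood
  like) times the reference profiles at the 100 signature CpGs;
* batch: one latent axis per processing batch (default one batch per
  chip of 8 arrays, as on this array class) with an additive logit-scale
  shift, signed probe-specific loadings on every control probe and on a
  random 20% of genomic probes — so control-probe PCs can genuinely
  remove it;
* sex signal: chrX intermediate in females and near 0/1 in males, chrY
  detected only in males;
* anxiety-score trajectories: baseline truncated normal (mean 24.5,
  SD 5.3, floor 19 — the inclusion threshold), follow-up
  $= \text{baseline} \times (1 - \text{improvement})$ with improvement
  from a two-component mixture placed strictly on either side of the 50%
  boundary, so the realized responder fraction is binomial around the
  target; response at the second follow-up is correlated with the first
  while matching a higher marginal;
* follow-up attrition in two channels (clinical dropout and missing
  methylation assay), reproducing the shrinking analysis panels of a
  longitudinal study;
* spiked effects per `effect_spec()`: case-control mean-beta shifts,
  baseline-methylation log-odds slopes on response (by the retrospective
  Gaussian construction, which realizes the logistic slope exactly), and
  responder-only per-timepoint drift;
* planted QC violators: call rate exactly 0.94, 6% missing signal, a
  swapped sex label, and a +6 logit shift of one control class.

What it does **not** emulate — hence what passing tests do not show about
real data: probe-type chemistry differences and intensity-dependent bias,
spatial chip artifacts, genotype-driven trimodal probes, correlated
neighbouring CpGs (probes are independent given batch), age/sex effects
on autosomal methylation, and real cell-type biology beyond the linear
mixing model.

## Numerical choices and degenerate inputs

Clipping offset 0.001; cell-fraction constraints enforced to $10^{-9}$;
residual-covariate orthogonality holds to $10^{-8}$ per probe; ties in
result ordering break by probe id; zero-variance probes, perfect
separation, non-convergence and zero-variance outcomes are flagged rows
(p absent) rather than numbers; a zero baseline anxiety score labels the
patient missing with a warning; serialization keeps 15 significant
digits and round-trips losslessly. Stage seeds derive from the run seed
by a fixed counter (`seed + stage index`), so `run_pipeline()` is
bit-reproducible for a given configuration.

## Problem sizes and known limitations

The shipped tests and the acceptance script exercise cohorts of 100–600
samples and 200–6,000 array probes (about 5,300 evaluated probes in the
calibration fixtures); the full 780,145-probe scale is supported but not
required by any shipped check.

Two limitations are worth stating plainly. First, the binary-response
logistic design inherits the small-sample anti-conservatism of
maximum-likelihood Wald tests: with ~20 covariates and fewer than ~100
labelled patients its null rejection rate runs near 0.08–0.10 at
$\alpha = 0.05$ (inflation vanishes as $p/n$ falls; at several hundred
patients it is nominal). The per-probe implementation is exact — it
matches `stats::glm` to ten decimals and is nominal without covariates —
so this is a property of the design at small $n$, and hits near the
threshold should be read accordingly. Second, at ~200 samples the
cohort-level chance alignment between the group contrast and the shared
adjustment covariates moves all probes' statistics together, so the
realized genomic inflation factor of a single null cohort disperses by
roughly $\pm 0.04$ around 1 — more than probe-sampling noise alone would
suggest; $\lambda$ from one small cohort should be judged with that
dispersion in mind.
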