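---
title: "Methods: SRB change scores, connectome metrics, and endocrine predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SRB change scores, connectome metrics, and endocrine predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cognet)
```

## The problem

Prospective studies of cognition after cancer treatment face a recurring
design: a patient group and a healthy control group are each tested twice,
months apart, on a battery of neuropsychological measures, and the question
is which individuals changed *more than retesting alone would produce*.
Observed retest change mixes true change with practice effects, regression
to the mean, and measurement noise, so raw difference scores are
uninterpretable at the individual level. `cognet` implements the full
analysis chain for this design — individual change detection, group
comparison of change rates, structural brain-network change, and
hormonal/genetic predictors of change — for a two-group cohort such as
orchiectomy-only testicular cancer patients versus matched controls.

## Standardized regression-based (SRB) change

For each measure, the control group's follow-up score is regressed on its
baseline score, premorbid IQ estimate, and age:

$$\hat{y}_{t2} = b_0 + b_1 y_{t1} + b_2 \,\mathrm{IQ} + b_3\,\mathrm{age}.$$

The intercept absorbs the average practice effect, the baseline slope
absorbs regression to the mean, and the covariates absorb demographic
trend. Every participant — patient or control — is then scored as

$$z = \frac{y_{t2} - \hat{y}_{t2}}{\mathrm{SEE}},$$

where SEE is the control fit's standard error of estimate with the usual
OLS denominator $n - 4$ (four fitted parameters). Under the control
generative model, $z$ is approximately standard normal, so $|z| \ge 1.64$
marks the extreme 5% at either tail; `classify_change()` treats the
boundary as change (inclusive bounds). Timed measures and error counts are
sign-flipped first (`harmonize_direction()`) so that positive harmonized
$z$ always means improvement; the global composite (GCS-z) is the plain
mean of the harmonized per-measure $z$ values, classified by the same
rule. Equal weights and no domain pre-averaging keep the composite's
definition transparent; because averaging shrinks variance, composite
change is much rarer than per-measure change, and tests assert exactly
that.

Design notes:

* No shrinkage is applied to the control regression even though the
  reference group is small (21 controls, 3 predictors): the SRB z is
  defined by the OLS fit, and regularizing it would change the meaning of
  the SEE denominator.
* A noiseless control fit (SEE = 0) is rejected as degenerate rather than
  producing infinite z-scores, and rank-deficient designs (e.g., constant
  age) are errors.
* The metastatic-exclusion sensitivity analysis reruns only the rate and
  odds-ratio stage on the filtered patients; SRB models depend only on
  controls and are not refitted.

## Rate comparison: exact tests and corrected odds ratios

Per measure and event type (declined/improved), the 2×2 table of patients
versus controls is compared with a two-sided Fisher exact test, defined by
the point-probability convention: with margins fixed, sum the
hypergeometric probabilities of every table whose point probability does
not exceed the observed one (relative tolerance `1e-7` absorbs
floating-point ties). The odds ratio is event odds in patients over
controls; when any cell is zero, the Haldane correction adds 0.5 to *all
four* cells before both the odds ratio and its Woolf logit interval

$$\exp\!\left(\ln \mathrm{OR} \pm z_{(1+\gamma)/2}
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right)$$

are formed from the corrected cells. The all-cells variant (rather than
correcting only zero cells) is the one that reproduces the package's
worked-example tables exactly. Group differences in continuous change
scores use Welch t-tests plus a bias-corrected and accelerated (BCa)
bootstrap interval for the mean difference (10,000 resamples by default;
jackknife acceleration; degenerate jackknife distributions fall back to the
percentile interval with a warning). The group-by-time question for a
continuous variable is answered two ways — a change-score regression of
$\Delta$ on baseline, group, and group×baseline with standardized
coefficients, and a two-way mixed ANOVA (group × time with subject as the
error stratum) — because both conventions are common and they answer
subtly different questions.

## Connectome metrics

The network stage starts from weighted, symmetric, zero-diagonal 90-node
connectivity matrices; how the weights were produced (streamline counts,
densities, ...) is deliberately out of scope and they are treated as
supplied. Each matrix is normalized by its mean off-diagonal strength
(zeros included), making all downstream analysis invariant to global weight
rescaling, and then binarized at each density $d$ in a grid by keeping the
$k = \mathrm{round}(d\,n(n-1)/2)$ strongest edges. Ties at the cutoff are
broken by node-index order so thresholding is reproducible; if fewer
nonzero weights exist than requested, all are kept and the achieved density
recorded. Binary rather than weighted metrics are used after thresholding —
the density-grid framing presupposes a fixed edge count, and binary metrics
are the convention in that lineage.

Per density the package computes mean local clustering $C$ (degree-<2 nodes
contribute 0), characteristic path length $L$ over reachable ordered pairs
(disconnected pairs are excluded and counted rather than imputed — at
densities of 0.06–0.12 fragmentation is rare but possible), global and
local efficiency, degree normalized by mean degree, and pair-normalized
betweenness. Small-worldness is

$$\mathrm{SW} = \frac{C/C_\mathrm{rand}}{L/L_\mathrm{rand}},$$

with $C_\mathrm{rand}, L_\mathrm{rand}$ the means over 20 degree-preserving
null graphs per density, generated by double-edge-swap rewiring
(`igraph::rewire`, $10|E|$ rewiring trials per null; self-loops and
multi-edges rejected, so the degree sequence is preserved exactly). Twenty
nulls is standard practice; the ensemble-mean stability is exercised in the
tests. Each metric is summarized as the trapezoidal integral over the
density grid ×100 (AUC), removing the arbitrary single-threshold choice.
Group×time effects on AUCs use the mixed ANOVA per metric; node-level
p-values are Benjamini–Hochberg adjusted across the 90 nodes, and change
values (t2 − t1) are summarized per group for surviving nodes.

"Normalized node degree" is a convention choice — degree divided by mean
network degree — since several normalizations circulate; it is stated
prominently because absolute node-degree AUC values are not comparable
across normalization conventions.

Internally, clustering, path lengths, and efficiencies are computed from
dense adjacency matrices with matrix-power BFS: at 90 nodes the per-call
overhead of repeated graph-library calls dominates the arithmetic, and the
dense route is checked against brute-force BFS oracles (and igraph) on
hundreds of random graphs in the test suite.

## Calculated free testosterone

Orchiectomy reduces testosterone production, and SHBG — the main serum
carrier — can rise over the same period, so total testosterone alone
misstates androgen exposure. Free testosterone is calculated from the
mass-action equilibria of testosterone binding to SHBG and albumin: with
$N = 1 + k_\mathrm{alb}[\mathrm{Alb}]$ folding albumin's weak, high-capacity
binding into a linear factor, FT is the positive root of

$$k_\mathrm{SHBG} N\,\mathrm{FT}^2 +
\left(N + k_\mathrm{SHBG}(\mathrm{SHBG} - \mathrm{TT})\right)\mathrm{FT}
- \mathrm{TT} = 0.$$

Constants default to the canonical published values
($k_\mathrm{SHBG} = 1.0\times10^9$ L/mol,
$k_\mathrm{alb} = 3.6\times10^4$ L/mol) and, because cohort albumin is
often not assayed, albumin defaults to 43 g/L; all are configurable. The
closed-form root is verified against an independent fixed-point solver to
`1e-6` nmol/L across a grid of inputs, and the free fraction lands in the
physiological 1–4% band at cohort-typical inputs (e.g., TT 15.87 nmol/L,
SHBG 38.18 nmol/L gives 0.30 nmol/L).

Predictor models are deliberately simple and mirror an exploratory screen:
within-group simple regressions of change outcomes on each predictor
(hormone baselines and change scores, symptom change scores, network change
values, CAG repeat length), with a pooled group×predictor interaction test
when a within-group slope reaches significance; a multiple regression of
cognitive change on testosterone adjusting for SHBG and CAG repeat length
(with a condition-number collinearity flag); and within-patient regressions
on binary risk-genotype carrier flags. The continuous harmonized z is the
primary outcome form (a binary declined/stable/improved outcome loses
information at these sample sizes). Multiple-testing correction across the
predictor screen is intentionally off by default — the screen is
exploratory and correction would hide the pattern of near-misses — but BH
adjustment is available to users via `p.adjust` on the returned tables.

## The synthetic cohort generator

Every stage is testable without patient data because the generator emulates
the data structure the analysis assumes:

* **Cognition.** 15 measures across 7 domains with realistic raw-score
  scales; control follow-up scores drawn from the linear model above with a
  practice effect (5% of the baseline mean, in the direction of better
  performance), baseline slope 0.85, modest IQ/age slopes, residual SD at
  45% of the baseline SD (test–retest r ≈ 0.85–0.9). Patients share the
  model; Bernoulli subgroups on selected measures receive shifts of 2.5
  residual SDs: decline subgroups on processing-speed and visuospatial
  measures (fractions 0.10–0.25) and improvement subgroups on recall
  measures (0.10–0.35), reproducing the qualitative published pattern —
  patient excess decline on speed/visuospatial tests, excess improvement on
  recall — without targeting exact real-data counts, which are facts about
  the original sample.
* **Hormones.** Group-specific baseline and change-score distributions
  (normal, truncated at a small positive floor) with defaults set to
  cohort-typical values for newly orchiectomized men versus controls —
  notably the patient SHBG rise (+9.11 vs +0.45 nmol/L) and neutrophil fall
  (−0.81 vs +0.06 ×10⁹/L).
* **Genotypes.** Bernoulli carrier flags (APOE ε4 0.30, COMT Val 0.70,
  BDNF Val/Val 0.65) and integer CAG repeat lengths (mean 22, SD 3).
* **Connectomes.** Per subject, a Watts–Strogatz ring lattice (90 nodes,
  neighborhood 6, rewiring 0.1) with lognormal edge weights (sdlog 0.5);
  follow-up applies multiplicative lognormal jitter (sdlog 0.1), and in
  controls the designated thalamic nodes (indices 77/78 in the standard
  90-region order) receive a −4/+4 edge change at follow-up, emulating a
  localized bilateral degree change detectable after FDR. Lognormal noise
  keeps weights positive; removed edges are the node's strongest, added
  edges get 90th-percentile weights so the change survives density
  thresholding.

What the generator does **not** emulate: measurement floors/ceilings and
integer raw scores, item-level response processes, covariate imbalance
between groups, distance-dependent connection topology and hemispheric
symmetry of real connectomes, and any dependence between cognitive change
and hormone or network change (unless designed into a test). Passing tests
therefore demonstrate that the machinery is correct and calibrated under
the assumed model, not that the model describes any particular cohort.

## Numerical and testing choices

* Default group sizes are 38 patients and 21 controls, the cohort sizes the
  package's worked examples are built around. Calibration and recovery
  tests use larger sizes chosen for statistical resolution: 10,000 scored
  subjects against a 5,000-control fit for the 5%-tail check (binomial SE
  ≈ 0.2 points), and 500 patients against 300 controls for subgroup
  recovery, where the enlarged control panel keeps control-fit noise from
  confounding the rate being recovered. With the study's own 21 controls,
  individual fitted coefficients are noisy (the tests assert recovery
  within reported standard errors, and ~92% of SEE draws land within 30% of
  truth — the chi-square dispersion at 17 df, not an implementation
  defect).
* The mixture expectation used in recovery tests is
  $f\,\Phi(\delta - t) + (1-f)\,\Phi(-t)$ for a subgroup fraction $f$
  shifted by $\delta$ residual SDs at threshold $t$: a designed decline of
  2.5 SDs does not push every subgroup member past 1.64.
* The published worked-example tables include a handful of internally
  inconsistent printed cells (odds ratios or bounds that cannot be obtained
  from their own printed counts under any single correction convention);
  these are flagged `consistent = FALSE` in `worked_example_tables()` and
  excluded from exact assertions. Confidence-interval bounds are asserted
  to printed precision plus a small allowance for the source's intermediate
  rounding.
* All simulation is seed-driven (base R Mersenne-Twister); connectome
  null-model sub-seeds are derived deterministically per subject-timepoint
  so that parallel or partial reruns reproduce.
* Graph-metric problem sizes in tests (200 random graphs of ≤ 30 nodes for
  oracle equivalence; the full default cohort for the small-world check)
  were chosen so brute-force enumeration stays exact and the suite stays
  fast.

## Known limitations

* Path-length and efficiency conventions for disconnected pairs differ
  across the literature (exclude, impute $n$, harmonic mean); this package
  excludes and counts. At densities below ~0.05 on 90 nodes this choice
  matters; within the default 0.06–0.12 grid it rarely does.
* The SRB approach assumes the control regression transfers to patients up
  to the modeled covariates; unmodeled group differences (e.g., premorbid
  IQ gaps) shift patient z-scores by construction.
* Absolute node-degree AUC values depend on the degree-normalization
  convention and on the raw connectivity weights; only within-convention
  contrasts (group × time) are meaningful.
* The exploratory predictor screen is uncorrected by design and its
  results should be treated as hypothesis-generating.
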