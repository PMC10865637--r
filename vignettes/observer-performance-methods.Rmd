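---
title: "Methods: observer performance and agreement analysis for CTG interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: observer performance and agreement analysis for CTG interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgobs)
```

## The setting

A multi-reader CTG study presents each of many obstetric professionals
(residents, midwives, obstetrician-gynecologists) with a series of
intrapartum cases and asks for a binary outcome prediction: fetal
hypoxia or normal outcome. The truth is the umbilical cord blood pH at
delivery, dichotomised at a threshold $\tau$ (default 7.15, moderate
hypoxia). `ctgobs` covers the four statistical components such a study
needs — case assignment, accuracy, agreement/reliability, and sample
size — plus a generator of synthetic cohorts with the same statistical
structure.

This vignette documents the models, the conventions chosen where the
design was genuinely open, and the limits of what the simulation-based
tests demonstrate.

## Outcome and strata conventions

* **Threshold rule.** `derive_outcome()` labels a case hypoxic when
  pH $< \tau$, *strictly*: a pH of exactly 7.15 is normal. Cord pH is
  validated against the physiologically plausible range [6.50, 7.60].
  When an input file carries a stored outcome column it is checked
  against the recomputed label rather than trusted.
* **Experience bands.** Years since diploma map to the four bands
  0–2, 2–4, 4–8, >8 with left-closed, right-open intervals, so each
  boundary value belongs to exactly one band (2 years → band 2–4).
* **Professions.** Three categories; student midwives are stored as
  midwives with a `student_midwife` provenance flag rather than as a
  fourth category, since cohorts of this kind rarely contain enough of
  them to analyse separately.

## Case assignment

Cases are grouped once into fixed batches of 10 (5 hypoxic + 5 normal),
identical for all readers; each reader walks the batches in order but
sees a private within-batch permutation, and may stop at any point.
Two consequences matter for analysis:

* any prefix of length $10k$ of a reader's sequence contains exactly
  $5k$ hypoxic cases, so early stoppers still see a balanced mix;
* readers who annotate few cases overlap heavily (they all start in
  batch 1), which is what makes the consensus-based agreement analysis
  well populated.

Batch composition is drawn by shuffling the hypoxic and normal pools
separately and filling batches 5+5; batch order is fixed, only the
within-batch order is per-reader. All permutations come from streams
keyed by `(seed, participant_id, batch)` (a 32-bit FNV-1a hash of the
key seeds a local RNG), so any reader's sequence is reproducible in
isolation and adding a reader never perturbs another's data.

## Accuracy metrics

Success rate, sensitivity and specificity pool annotations (they are
not averages of per-reader rates): the denominator of sensitivity is
the number of annotations of truly hypoxic cases, which matches the
precision implied by study-level confidence intervals. Degenerate
strata (no hypoxic, or no normal, annotations) report the affected
metric as undefined (`NA`) rather than zero.

All intervals are Wilson score intervals — the score-test inversion —
which remain sensible at extreme proportions and small denominators
where the Wald interval collapses. `wilson_interval()` accepts either a
count or a point estimate (useful when recomputing bounds from printed
tables whose numerators are not shown).

Group comparisons use a screening heuristic, not a test: two strata are
flagged as different on a metric when their confidence intervals do
*not* overlap (`flag_group_differences()`). Non-overlap of 95%
intervals is conservative relative to a formal two-sample test; the
flag is labelled as a heuristic in the output for that reason.

The pH difficulty profile (`success_by_ph_bin()`) bins annotations by
case pH into ranges delimited by eight thresholds (defaults 6.90, 6.98,
7.05, 7.13, 7.20, 7.28, 7.35, 7.43, chosen to spread a realistic case
mix roughly evenly); bins are right-open, so every annotation falls in
exactly one bin.

### Sample size

`sample_size_sens_spec()` implements the Buderer-type formula
$n_{se} = z^2\,Se(1-Se)/(d^2\,p)$, $n_{sp} = z^2\,Sp(1-Sp)/(d^2(1-p))$
with $d$ the CI half-width and $p$ the prevalence, returning the larger
requirement **rounded to the nearest integer**. With anticipated
Se = 0.45, Sp = 0.67, $d$ = 0.14, $p$ = 0.5 the formula gives 97.02;
the ceiling convention would report 98. Rounding to nearest is used
here because the canonical worked result for these inputs is 97; users
wanting the conservative convention can apply `ceiling()` to the
`components` attribute.

## Agreement and reliability

The unit of agreement is the **profession consensus**: for each case
annotated by at least one member of a profession, the majority label.
An exact tie is not a consensus; by default tied cases are excluded
from that profession's vector (`tie_policy = "exclude"`), with
`"hypoxia"`/`"normal"` available as forced-resolution alternatives for
sensitivity analyses.

For each profession pair, PA and Cohen's kappa are computed on the
cases both consensus vectors cover. PA gets a Wilson interval; kappa
gets the classic large-sample interval with
$SE = \sqrt{p_o(1-p_o)}/\big((1-p_e)\sqrt{N}\big)$, clipped to
$[-1, 1]$. Verbal categories follow the Altman scale for PA and the
Landis–Koch scale for kappa; both scales change class above 0.20, 0.40,
0.60 and 0.80, with the upper end of each printed range inclusive.
Values are rounded to 2 decimals before classification so quantities
falling in the unprinted gaps between ranges (e.g. 0.805) classify
deterministically. Agreement for a pair is additionally flagged
non-significant when the lower PA bound falls below 0.50 — i.e. when
the data cannot exclude coin-flip-level concordance.

Overall PA and kappa are weighted means of the pairwise values with
weights equal to the pairwise overlap counts, so pairs sharing more
cases contribute more. For their confidence intervals no closed form is
natural (the pairwise values share cases and readers), so the package
uses a **case-level bootstrap**: resample case ids with replacement,
recompute every pairwise value and the weighted mean on each resample
(2000 by default), and take percentile bounds. The bootstrap stream is
keyed by the seed, so results are exactly reproducible. Bootstrap
intervals for the overall values are wider than a naive Wilson interval
at the same nominal $n$ would be — they propagate the between-pair
variability as well as the binomial noise.

Not implemented, deliberately: multi-rater (Fleiss) kappa, weighted
kappa (labels are binary) and intra-observer repeatability — the
consensus-pairwise procedure above is the analysis this package exists
to provide.

## The synthetic cohort generator

The generator's defaults describe the study conditions the analysis is
designed for; they are fixed, not fitted.

* **Cases.** 100 cases, exactly 50 per side of $\tau$: pH is drawn from
  a normal(7.20, 0.12) truncated to [6.85, 7.47] — a realistic
  intrapartum cord-pH range with most mass on the normal side — sampled
  separately below and above $\tau$ to force the balanced split, then
  rounded to 2 decimals (the resolution of blood-gas reports; rounding
  is clamped so it never crosses the threshold).
* **Cohort.** 120 readers: 39 residents, 23 midwives (2 flagged as
  student midwives), 58 obstetrician-gynecologists; 84% university
  hospital; experience bands drawn from a 0.30/0.20/0.20/0.30 mixture
  (a labor-ward team skews toward the very junior and the very senior).
* **Participation.** Heavy-tailed: with probability 0.10 a reader
  completes all 100 cases, otherwise the count is log-normal
  (median 9, sdlog 1.1) truncated to [1, 99]. A single log-normal
  cannot simultaneously produce a median near 11, quartiles near 5 and
  36, and a visible group of completers; the point-mass + log-normal
  mixture can, which is why participation is modelled as a mixture.
* **Response model.** Reader $r$ calls hypoxia on case $c$ with
  probability $\sigma(a_r + b_r(\tau - \mathrm{pH}_c))$: $a_r$ is a
  bias toward over- or under-calling hypoxia
  (normal, mean 0, sd 0.4) and $b_r > 0$ a discrimination in log-odds
  per pH unit (log-normal, median 8, sdlog 0.5). This is the minimal
  model producing both near-chance accuracy adjacent to the threshold
  and high accuracy at the pH extremes — the U-shaped difficulty
  profile real readers show. At median discrimination, a case 0.15 pH
  units from the threshold is called correctly about 77% of the time.
* **Determinism.** Every draw (case pH, reader parameters,
  participation, each prediction) comes from a stream keyed by the seed
  and the entity ids, so identical configurations give byte-identical
  study tables and any subset of readers can be regenerated alone.

`recover_rater_parameters()` closes the loop: per-reader empirical
Se/Sp with Wilson intervals, and a maximum-likelihood logistic fit of
$(a, b)$ for readers with at least 30 annotations (below that the fit
is too unstable to be meaningful and is reported as `NA`).

### What the generator does and does not emulate

It reproduces the *statistical* structure — balanced design, cohort
composition, heavy-tailed participation, pH-dependent difficulty,
reader heterogeneity. It does not model: the CTG signals themselves or
any signal-quality effect (missing samples, maternal-heart-rate
contamination); learning over the session from the feedback readers
receive after each case (raters are stationary); correlation between
profession or experience and skill (latent parameters are drawn
independently of strata, so simulated strata differ only by sampling
noise); or selection effects in who volunteers. Consequently, passing
tests demonstrate the pipeline's correctness and calibration on data
with known structure — not that real readers behave like the model.

## Numerical and testing choices

* Quartiles in the participation descriptives use Tukey hinges
  (median-of-halves, as `fivenum()`), the convention matching published
  descriptive tables of this kind; linear interpolation
  (`quantile(type = 7)`) is available via `quartile_method`.
* Report CSVs round percentages to integers (half away from zero, the
  display convention of clinical tables) and metrics to 2 decimals;
  JSON mirrors keep full precision.
* The Wilson implementation is validated against a brute-force
  score-test inversion (root-finding) and `prop.test(correct = FALSE)`;
  kappa against hand-tallied 2×2 tables and an independent library
  computation; coverage of the Wilson interval is checked by simulation
  (10^4 draws at $n = 30$, $p = 0.5$) and, in the recovery experiment,
  against an exact Poisson-binomial oracle.
* The parameter-recovery experiment uses 200 readers × 100 annotations
  at known $(a = 0, b = 8)$ — large enough for stable coverage and
  error estimates, small enough to run routinely. The discrimination
  MLE shows the usual $O(1/n)$ upward bias at 100 observations per
  reader; its mean absolute error is checked against the asymptotic
  Fisher-information value rather than asserting exact mean
  unbiasedness.
* The end-to-end pipeline is tested for byte-identical reruns: the run
  manifest records row counts and md5 hashes of every output.

## Known limitations

* The kappa CI is the large-sample approximation; for very small
  overlaps it can be visibly too narrow. The bootstrap used for the
  overall values would be the natural upgrade for pairwise CIs too.
* The CI-overlap difference flag is a heuristic with non-nominal error
  rates; formal inference on stratum differences should use a proper
  two-proportion comparison.
* Consensus-level agreement overstates individual-level agreement:
  majority voting removes within-profession disagreement before PA and
  kappa are computed. This mirrors the procedure it implements; the
  caveat belongs in any report built on these numbers.
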