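---
title: "Methods: censored residue statistics and consumption risk screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored residue statistics and consumption risk screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishrisk)
```

## The problem

Anadromous fish returning to spawn carry persistent organic chemicals (PCBs,
PBDEs, dioxins/furans) and PFAS accumulated at sea into rivers where they are
harvested for food. `fishrisk` implements the complete quantitative chain for
evaluating that exposure from composite-sample tissue chemistry: (1) summing
congener panels into chemical-class totals when part of the panel is below
detection limits, (2) design-based summaries and comparisons that respect the
composite/technical-replicate structure of the laboratory data, (3) rank-based
multivariate comparisons that remain valid under censoring, and (4) the human
and wildlife risk arithmetic (TEQ, hazard quotients, cancer risk, whole-fish
wildlife screening).

The measurement unit is a *composite*: a homogenate of several fish of one
species, analyzed as three technical replicates. One measurement row is one
analyte (congener) in one replicate: a value in ng/g wet weight if detected,
or a detection limit with a censoring flag if not.

## Class totals under left-censoring

A replicate's class total (e.g. "total PCBs") treats the congener panel as a
left-censored sample. The default estimator is the Kaplan–Meier mean via the
standard flipping construction: with `M` the maximum over detected values and
detection limits, each concentration `x` maps to `y = M - x`, so a nondetect
(`x < DL`) becomes a right-censored `y > M - DL`. The product-limit survival
curve is fitted to the flipped sample (using the `survival` package for the
fit itself), its restricted mean is taken over the observed range, and the
result is flipped back; the total is `n_analytes` times this mean. The
restricted-mean (Efron) convention truncates the curve at the largest flipped
observation, which pins the smallest censored concentration at its detection
limit — the known, mild positive bias of this estimator. Ties between a
detected value and an equal detection limit rank the detected value higher,
the standard product-limit convention, making the estimator deterministic.

Two structural facts anchor the implementation and its tests: with no
censoring the KM total equals the simple sum exactly (recorded as method
`SIMPLE_SUM`), and the KM total can never exceed the total obtained by
substituting each nondetect at its full detection limit.

The product-limit mean degrades when censoring is heavy. A panel falls back
to the half-detection-limit substitution (method `HALF_DL`) when its censored
fraction exceeds `fallback_threshold` (default 0.8, following common guidance
that KM means are unreliable at very high censoring; the threshold is a
user-visible argument) or when fewer than two values are detected. Fully
censored panels always use `HALF_DL`, giving half the sum of detection
limits. No maximum-likelihood or regression-on-order-statistics estimator is
offered: the KM/half-DL pair is deliberately the entire estimator family.

An open representational choice: a class total could also be assembled by
summing per-analyte KM means across replicates. We instead compute one KM
mean per replicate panel and scale by the panel size, because the reporting
unit of the source tables is the replicate-level total ("3
replicates/composite averaged"), and per-panel estimation keeps the
fallback decision local to the replicate that triggered it.

## Design-based inference over composites

Technical replicates of one composite are not independent samples of the
river; the composite is the sampling unit. Group means therefore use
equal-weight design-based estimation with the composite as the cluster:
the variance of the mean is estimated by Taylor linearization over cluster
score totals (the with-replacement one-stage approximation), which for a
balanced design reduces to the classical variance of cluster means. The
survey machinery is implemented directly in `R/survey.R` and verified in the
tests against the two-cluster closed form (`SE = |m1 - m2| / 2`).

Degrees of freedom follow standard design-based practice: `n_composites - 1`
for confidence intervals, `n_A + n_B - 2` for the two-group t-test. With 5
composites per group and 3 replicates each, the simulated type-I error of
the t-test at `alpha = 0.05` sits near 0.055–0.06 (the acceptance suite
requires `[0.03, 0.08]` over 2000 null simulations), the small liberality
expected of linearization variances at few clusters. A single composite is
an error, not a degenerate interval.

## U-scores, ANOSIM and rank tests

Multivariate comparisons across species and years must not substitute
values for nondetects. The u-score of an observation within an analyte
column is the sum of its determinate pairwise comparisons: detected vs
detected compares numerically; a detected value beats a nondetect only when
it is at or above that nondetect's detection limit (otherwise the pair is
indeterminate and scores 0); two nondetects always overlap as intervals
`[0, DL)` and score 0. Columns sum to zero by antisymmetry and scores are
bounded by `n - 1`; any statistic computed on u-scores depends on the data
only through determinate orderings, so it is invariant to monotone
transformation of the concentrations.

ANOSIM then runs on Euclidean distances between u-score rows, permuting row
group labels; the implementation delegates the permutation test itself to
`vegan::anosim` (the standard tool, with `p = (1 + hits)/(n_permutations +
1)`), seeded explicitly so the permutation stream — and hence the p-value —
is exactly reproducible. The analysis unit defaults to the replicate; a
`unit = "composite"` option averages replicates first (a composite is
censored only when all its replicates are). Whether to run ANOSIM on
u-scores or on their column ranks is immaterial for the statistic's rank
character; both are available via `on_ranks`. Under complete group
separation `R = 1`; note the attainable minimum p is slightly above
`1/(n_permutations + 1)` because relabelings that reproduce the same
partition (e.g. swapping two group labels wholesale) tie the observed
maximum.

Kruskal–Wallis comparisons of single analytes are computed on u-scores (tie
corrected, via `stats::kruskal.test`), reducing to the ordinary test when
nothing is censored; a fully indeterminate column returns `H = 0, p = 1`
rather than an error. Wilcoxon rank-sum tests use the exact distribution for
groups of at most 10 without ties and the tie-corrected normal approximation
otherwise. Biplot coordinates are the SVD of the column-centered u-score
matrix (first two components, with explained-variance fractions); rendering
is left to the user.

## Toxicity registry and risk arithmetic

All reference constants live in one registry with fixed canonical units:
concentrations ng/g ww, noncancer doses and RfDs ng/kg-BW/day, cancer doses
mg/kg-day, wildlife values ng/g whole-fish ww. The WHO 2005 mammalian TEF
table (17 dioxins/furans, 12 coplanar PCBs) is bundled; RfDs are
Aroclor 1016 = 70 and Aroclor 1254 = 20 ng/kg/day (the lower value belongs
to 1254, consistent with the published hazard quotients), BDE-99 = 100,
2,3,7,8-TCDD = 0.0007 ng/kg/day, PFOS = 0.1 ng/kg/day (the draft 1e-7
mg/kg-day value), PFHxA = 500 and PFBA = 1000 ng/kg/day. Overrides come from
a flat `key = value unit` file whose unit tags are mandatory and checked per
key family — an RfD supplied without a unit, or in an unexpected unit, is an
error, which is the mechanism that makes mixed-unit arithmetic impossible.

The exposure dose is `concentration x ingestion rate x exposure factor /
body weight` with defaults 40 g/day, EF 1, 80 kg. Hazard quotients divide
the dose by the RfD; HQ < 1 indicates minimal noncancer concern. TEQ is the
TEF-weighted sum over dioxin-like congeners, with nondetects contributing
zero by default (`nd_policy = "ZERO"`; `"HALF_DL"` is the option — ZERO is
chosen as the conservative-toward-null default since the censoring treatment
of the source TEQs is unstated, and the ZERO result is always a lower
bound of the HALF_DL result). Cancer risk converts the TEQ concentration to
mg/kg, forms the lifetime-average daily dose `TEQ x IR/BW`, scales by the
exposure-duration fraction 30/78, and multiplies by the oral slope factor
1.3e5 (mg/kg-day)^-1; the 30/78 factor is applied multiplicatively, the only
reading consistent with published rows such as TEQ 2.92e-5 mg/kg -> dose
1.46e-8 mg/kg-day -> risk 7.3e-4.

Wildlife screening converts fillet concentrations to whole-fish equivalents
(PCB and dioxin/furan x1.83, PBDE x1.5, PFOS x2.13 — the only PFAS with a
published factor; other PFAS return an explicit "no conversion factor"
result, never a silent zero) and compares them strictly (`>`) to wildlife
values: mink 72 ng/g for total PCBs, American kestrel 8.7 ng/g for total
PBDEs, the Canadian PFOS values 4.6 (mammals) and 8.2 (birds) ng/g, and for
dioxins a generic 2,3,7,8-TCDD value derived as the mean of the water
standard 3.1e-9 µg/L times BCF 15,000 and times BAF 25,000, i.e. 6.2e-5
ng/g. (A differently-stated value of 6.5e-5 ng/kg circulates for the same
quantity; only 6.2e-5 ng/g is reproducible from the stated derivation, so
that is what `derive_dioxin_wv()` returns.) Roe samples are excluded from
whole-fish conversion via the `sample_type` metadata column, not by matching
species names. The dioxin screening column uses the dioxin/furan class total
times 1.83 screened against the TCDD value — a screening-level
simplification (congener-specific bioconcentration differs), which is why
that column should be read as a flag, not a concentration estimate.

The cancer table pools both collection years per species (size classes of a
species are pooled together); chemicals never detected in a group produce
blank (NA) dose and HQ cells rather than zeros.

## What the synthetic generator emulates

No raw congener-level dataset is publicly deposited, so the package carries
a seeded generator whose bundled profile is the testing ground for every
stage. Concentrations are lognormal: a composite-level draw per analyte
(log-sd 0.3) times a mean-one lognormal technical-replicate multiplier
(CV 0.15). Both variance components are assumptions — the true
between/within split is not published — and are stated here as such.
Censoring is purely deterministic: a drawn value below the analyte's
detection limit is emitted as a nondetect; there is no separate missingness
process.

The bundled profile reproduces, in expectation, the published species x year
class totals (e.g. Striped Bass 2018 total PCBs ~100 ng/g; Sea Lamprey PFOS
5.84 ng/g in 2018) with the published composite counts, fish-per-composite,
moisture and lipid values. Within a class, congener abundances follow a
fixed log-spread profile (2 decades for PCBs and PBDEs, 2.5 for
dioxins/furans) with the coplanar PCBs at the low-abundance tail — which is
what makes PCB-126 a tiny mass fraction but the dominant TEQ contributor, as
in real fish. PFAS detection limits are the published ones (PFOS 0.03 ng/g
etc.); species x analyte cells reported below detection are generated far
below their limits so they censor almost surely. Congener-class detection
limits are not published, so class-wide values (PCB 0.010, PBDE 0.012,
dioxin/furan 0.0018 ng/g) were calibrated once against the congener profiles
so that realized detection fractions land in the published ranges (PCBs
97–100%, PBDEs 62–89%, dioxins/furans 27–67%); the dioxin/furan range is the
binding constraint. Pooled rates land mid-range; individual species-year
groups can stray slightly outside the PBDE range because the species totals
span a wider scale than a single class detection limit can track — the
published ranges are treated as pooled targets.

What the generator does *not* emulate: PFAS were measured on a reduced
composite set in reality (the generator emits the full panel for every
composite); fish length/size covariates (the two smelt size classes are
separate labels only); spatial structure; inter-congener correlation beyond
the shared composite factor; and any distributional misspecification of real
tissue data. Passing tests therefore demonstrate the pipeline's correctness
and calibration under a realistic lognormal-censored regime, not the
distributional fidelity of any real dataset.

## Numerical and design choices

- Problem sizes in the test suite: 1000-panel property sweeps for the
  estimator bounds, 2000 null simulations for the t-test calibration, 500
  for ANOSIM (199 permutations each), 500 seeds for CI coverage, and 200
  seeds for generator-truth recovery on one species-year group; these sizes
  give Monte-Carlo error comfortably inside the asserted bands.
- Comparisons against published table cells use 1.5% relative tolerance,
  the chained-rounding allowance needed when a printed 3-significant-figure
  input feeds a printed output computed from unrounded intermediates
  (e.g. 14.3 x 1.83 = 26.17 vs a printed 26.1).
- Hazard quotients are reported to 2 significant figures in narrative
  output; full precision is retained internally.
- The KM fallback threshold (0.8) is strict (`>`): a panel at exactly 80%
  censoring still uses the product-limit estimator.
- `survey_t_test` on two groups with identical totals returns `t = 0, p =
  1` even when the variance estimate is zero.
- Seeds: every stochastic routine takes or records an explicit seed;
  `generate_dataset` derives everything from the single seed in its config.

## Limitations

The KM total inherits the Efron restricted-mean bias at the smallest
censored observation; at the dioxin/furan censoring levels this shows up as
a small upward bias (a few percent of the class total) that the recovery
tests bound at 10%. The linearization variance is mildly liberal below ~5
clusters. The wildlife screen is a screening-level comparison, not a dietary
exposure model for the receptors. PFAS cancer risk is out of scope by
design, as is any cooking-loss or mixture-interaction adjustment.
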