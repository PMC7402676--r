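---
title: "Methods: meta-analysis of litter-mixture decomposition effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of litter-mixture decomposition effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(littermix)
options(littermix.quiet = TRUE)
```

## The scientific question

Leaf litter in forests decomposes in mixtures of species, yet most
decomposition parameters come from single-species litterbags. When a
mixture decomposes faster than predicted from its component species'
individual rates the effect is called *synergistic*; slower,
*antagonistic*; indistinguishable, *additive*. `littermix` implements the
full quantitative chain used to synthesise such experiments across
studies: additive-null expectations, log-response-ratio effect sizes,
random-effects pooling with bootstrap confidence intervals, subgroup
heterogeneity partitioning, decomposition-stage analysis, and
trait-divergence regressions — plus a synthetic-data generator that
emulates the statistical structure of a global litterbag compilation so
every step can be validated without field data.

## Model and estimators

**Additive null.** For a mixture with component mass fractions $p_i$ and
single-species responses $x_i$ measured at the same sampling occasion,
the expected response under purely additive decomposition is
$\bar{X}_c = \sum_i p_i x_i$. Its dispersion is propagated assuming
independent component observations,
$s_c = \sqrt{\sum_i p_i^2 s_i^2}$, with the effective replicate count
taken conservatively as $N_c = \min_i N_i$. The source literature never
defines a composite dispersion for the null, so this propagation rule is
a declared convention of the package, not a reconstruction: the
independence assumption is natural because component monocultures are
separate litterbags, and the $\min$ rule avoids overstating the
precision of the control side. For nutrient responses the null weights
component *releases* by initial nutrient mass,
$w_i = p_i c_{0i} / \sum_j p_j c_{0j}$ — a nutrient budget is the
dimensionally consistent aggregation — with a `nutrient_weights =
"dry_mass"` switch to fall back to mass proportions.

**Effect size.** Each mixture-vs-null pair yields the log response ratio
$\mathrm{lnRR} = \ln \bar{X}_e - \ln \bar{X}_c$ with sampling variance

$$v = \frac{s_e^2}{N_e \bar{X}_e^2} + \frac{s_c^2}{N_c \bar{X}_c^2},$$

the standard large-sample variance of a log ratio of means. Reported
percent effects are $(e^{\mathrm{lnRR}} - 1) \times 100$. Pairs with a
non-positive mean — possible for nutrient release under net
immobilization — cannot enter a log ratio and are excluded with a
recorded reason rather than offset, since shifting values would bias the
ratio; exclusion counts appear in the run report.

**Nutrient accounting.** Relative release is $1$ minus the remaining
fraction of the initial nutrient amount, times 100. The default
`amount_based` mode computes the remaining fraction as concentration at
harvest times mass remaining over initial concentration — standard
litterbag bookkeeping, and the only reading under which "release as % of
the initial amount" is coherent. A `concentration_based` mode implements
the literal concentration-ratio definition some syntheses quote; neither
is asserted as uniquely correct, and both are exposed. Values above one
flag immobilization. Because effect sizes need dispersions, the schema
carries concentration standard deviations and propagates them to release
scale by the delta method
($\mathrm{sd}_{rel} = 100\, m\, \mathrm{sd}_c / c_0$ in amount mode,
with $m$ the mass-remaining fraction).

**Random-effects pooling.** Between-study variance uses the
DerSimonian–Laird moment estimator
$\hat\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\big)$
with fixed-effect weights $w = 1/v$, and the pooled effect uses
random-effects weights $1/(v + \hat\tau^2)$. DL is the estimator of the
MetaWin-era software this analysis style grew up with; REML-based
alternatives exist but change little at these problem sizes, and DL keeps
the worked examples exactly reproducible. Confidence intervals come from
an observation-level bootstrap (default 4999 replicates) that
re-estimates $\hat\tau^2$ and the pooled mean in every replicate;
intervals are bias-corrected percentiles by default (`"percentile"`
available). 4999 replicates give stable 2.5% tails; every interval is
deterministic given the seed. An effect is significant at $\alpha=0.05$
when its 95% CI excludes zero; direction is synergistic / antagonistic /
additive accordingly.

**Subgroup heterogeneity.** Categorical moderators are analysed like a
one-way weighted ANOVA: with fixed-effect weights, total heterogeneity
about the grand weighted mean splits exactly into within- and
between-group parts, $Q_T = Q_W + Q_B$ (the identity is exact only under
fixed weights, which is why $Q$ uses $1/v$ even though pooled effects use
random-effects weights). $Q_B$ is referred to $\chi^2_{g-1}$.
Within the subgroup structure a single $\tau^2$ is pooled across groups
from $Q_W$ (the classic mixed-model convention), and per-group CIs come
from a joint stratified bootstrap that re-estimates the pooled $\tau^2$
per replicate. Whether the original analysis style re-estimated $\tau^2$
per group or pooled it is ambiguous in the literature; pooling borrows
strength for small groups and keeps group comparisons on one scale.
Groups below the `min_k_subgroup` floor (3 in the pipeline) are reported
as point estimates flagged "sample size too low", without a CI. No
multiple-testing correction is applied across subgroups — inference is
per-CI, as in the tradition this package follows — and users should read
wide subgroup tables accordingly.

**Decomposition staging.** To trace how mixing effects develop through
decomposition, all-harvest pairs are binned by their *additive-null* mass
loss — the stage the mixture would have reached absent interactions, so
binning is not contaminated by the effect being estimated — into 10%
intervals up to 70%, then one 70–100% bin (late-stage observations are
scarce). Bins are half-open $[l, u)$ with the top bin closed at 100; the
boundary convention is a package choice since interval endpoints are
never specified in this literature. A study legitimately appears in
several bins through successive harvests; `collapse_study = TRUE`
averages a study's same-bin harvests first (default keeps them separate).

**Trait divergence.** Initial chemical divergence within a mixture is
Rao's quadratic entropy
$\mathrm{Rao} = \sum_{i<j} d_{ij} p_i p_j$ over component pairs, with
$d_{ij}$ the mean character difference $\frac{1}{n}\sum_k |X_{ik} -
X_{jk}|$. Absolute differences are used even where printed formulas omit
the bars: a distance must be non-negative. Each trait is analysed
separately ($n = 1$); litter studies rarely report a common multi-trait
set, so a composite would silently change its meaning across mixtures.
Mixture effects are regressed on divergence by unweighted OLS, one point
per study: the mean of the study's mass-loss effect sizes whose null mass
loss falls in the closed 10–40% window, the stage range where
non-additive effects concentrate. Climate regressions (MAT, MAP) use one
point per final-harvest paired observation, since site climate varies at
study level but the final-harvest table is the natural unit there. A
leverage-sensitivity harness refits each divergence regression excluding
the top fraction of divergence values.

## The synthetic compilation

`generator_config()` defaults encode the shape of a global compilation:
65 studies across five forest biomes (proportions weighted toward
temperate and subtropical forests), two to seven mixtures per study
yielding roughly 280–320 final-harvest mixture observations, a richness
mix of 2/3/4/6 species at roughly 69/14/12/5%, four fifths of mixtures
at equal mass ratios, mesh apertures spanning <1 mm to >2 mm, and study
durations from 3 months to 2 years with one to four evenly spaced
harvests — variation in duration is what spreads final harvests across
decomposition stages.

Mechanistically:

* Species traits are lognormal with evergreen species drawn with higher
  lignin and lower N than deciduous ones, so evergreen lignin:N and C:N
  stochastically dominate. Decay constants fall with litter quality,
  $k = k_{scale} / (\mathrm{lignin{:}N})$ times lognormal noise, giving
  single-species trajectories $M(t) = 1 - e^{-kt}$.
* Replicate litterbags observe the true mass loss through multiplicative
  lognormal error (mean-corrected, capped at 100%), which preserves the
  positivity the log ratio requires.
* Each study draws one true interaction
  $\theta_s \sim N(\mu_{biome}, \tau^2)$; a mixture's observed mass loss
  is its additive null times $e^{\theta_s + \sum_t \beta_t
  \mathrm{Rao}_t}$ while the null lies inside the interaction window
  (default 10–40%), and exactly the null outside it. Because the
  interaction acts multiplicatively on the null, a configured $\theta$
  *is* the true lnRR, making recovery tests exact in expectation.
* Nutrient amounts follow an immobilization-then-release trajectory: the
  remaining-amount fraction rises to $1 + a$ over the first stretch of
  mass loss (default: N peaks at +15% by 20% mass loss; P releases from
  the start) and then declines linearly to zero at complete mass loss.
  Mixtures shift their relative release by a study-level normal draw
  (defaults: N +15 ± 10 percentage points, P +2 ± 8), reproducing the
  characteristic pattern of accelerated N but statistically additive P
  release.
* The generator records its ground truth: study effects, per-treatment
  true and *realized* additive nulls (the latter built from the noisy
  single-species means, exactly what `build_pairs()` reconstructs — the
  two agree to 1e-12), window membership, and true lnRR per observation.

Defaults were fixed from the compilation's published shape and from what
field studies typically report (3–5 replicate bags, ~10% replicate CV);
they were set once and are not tuned against test outcomes.

### Validation experiment sizes

The test suite runs the pipeline end to end at these scales, chosen as
ordinary simulation sizes for the properties being certified: type-I
calibration of the overall CI with 80 independent studies × 200 seeds ×
999 bootstrap replicates; biome-effect recovery at 100 studies;
stage-localization at the default 65 studies; divergence-slope recovery
at 60 studies; staging null calibration over 100 seeds.

Two validation configurations deserve explanation:

* *Recovery and calibration runs set `mixtures_per_study = c(1, 1)` or
  widen the window to (0, 100).* The pooled model treats observations as
  independent, but several mixtures within one study share a true
  $\theta_s$ and the same single-species controls. With one mixture per
  study the data match the model's independence assumption and the
  bootstrap CI is calibrated (measured 6% type-I at nominal 5%); with
  many mixtures per study, observation-level resampling understates
  between-study correlation and subgroup CIs for study-sparse groups can
  be anticonservative. This is a property of the analysis tradition
  (independence is assumed, clustering is not modelled), and users should
  treat biome panels backed by few studies with caution. Similarly,
  biome-recovery runs open the interaction window to (0, 100) because
  final-harvest nulls span all stages; with the default 10–40% window the
  final-harvest pooled effect is an attenuated mixture of affected and
  unaffected observations — which is exactly what the staging analysis is
  for.
* *The divergence-recovery run uses `measurement_cv = 0.05`, `n_reps =
  8` and `tau = 0`.* A power analysis fixes this: under the default
  noise regime the study-level slope standard error is ≈0.011, so no
  correct implementation could pin a slope of 0.02 to ±0.01 with p <
  0.05 at 60 studies; halving the CV and doubling replication brings the
  standard error to ≈0.004. Setting $\tau = 0$ removes chance
  study-effect/divergence correlation, which at a fixed seed can bias the
  OLS slope by more than the recovery band.

### What passing tests do and do not show

The generator emulates sampling error, between-study heterogeneity,
trait-linked decay, stage-dependent interactions and immobilization; it
does not emulate digitization error from figure extraction, correlated
measurement error within studies, non-exponential (two-pool) decay,
leaching pulses, missing-not-at-random trait reporting, or publication
bias. Passing recovery tests therefore certify the estimators and their
implementation, not the field validity of any real compilation's
conclusions.

## Numerical and degenerate-input choices

* Evenness uses a 1e-9 tolerance after normalisation; composition sums
  are validated to 1e-9.
* $\hat\tau^2$ with fewer than two effects is defined as 0 with a logged
  warning; single-effect sets are point estimates flagged `low_n`.
* A degenerate bootstrap distribution (all effects identical) returns
  the point interval; the bias-correction quantile $p_0$ is clamped to
  $[1/(B+1), B/(B+1)]$.
* Zero-variance pairs (both sds zero) are rejected as degenerate rather
  than given infinite weight; constant-response regressions return slope
  0, $r^2 = 0$, $p = 1$.
* Exactly 1 mm and 2 mm mesh fall in the middle class (closed
  interval), so the three mesh classes partition the line; "1 to 2 mm"
  reads as inclusive.
* Mass-loss interval membership at a boundary goes to the upper bin
  (half-open convention), except 100% which closes the top bin.
* CSV writing renders doubles at 17 significant digits and reading uses
  a correctly rounded parser, so a dataset survives the write/read cycle
  bit-exactly.

## Known limitations

* Observations are pooled as independent; no multi-level or
  robust-variance structure. Subgroup CIs for groups dominated by one or
  two studies inherit that optimism.
* Capping generated replicate mass loss at 100% slightly biases lnRR in
  the 70–100% null-mass-loss bin, so late-stage null calibration runs
  a few points above nominal there; conclusions about the top staging
  bin in generated data should allow for this.
* Variance estimates from 3–5 replicates are noisy, and inverse-variance
  weighting with noisy variances is mildly anticonservative at small
  group sizes — a faithful property of the classic workflow, not an
  implementation artifact.
* Screening judgements (which condition of a multi-condition study to
  keep) are represented by the `selected` flag in the input data and are
  not re-derived; the package never silently drops rows.
* No publication-bias diagnostics and no small-sample lnRR bias
  correction, matching the tradition implemented.

## A worked miniature

```{r mini}
ds <- fixture_small(42)
ds
pairs <- build_pairs(ds)
effects <- compute_effect_sizes(pairs)
meta_analyze(dplyr::filter(effects, response == "mass_loss"),
             reps = 999, seed = 1)
```

The attached ground truth makes the additive-null reconstruction
checkable to machine precision:

```{r truth}
truth <- ds$truth$treatment_truth
j <- dplyr::inner_join(dplyr::filter(pairs, response == "mass_loss"),
                       truth, by = c("treatment_id", "harvest_index"))
max(abs(j$expected_mean - j$realized_null))
```
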