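---
title: "From RCC lanes to contrasts: the ncountr methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RCC lanes to contrasts: the ncountr methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncountr)
library(dplyr)
```

# The problem

Digital molecular barcoding (the nCounter platform) counts individual
mRNA molecules for a small targeted panel, one cartridge lane per RNA
sample. `ncountr` implements the full desk side of such an experiment
for a longitudinal two-group design: lane quality control, background
removal, two-stage normalization, per-gene repeated-measures modelling,
and the post-hoc power arithmetic used to plan follow-up studies. The
packaged panel is a 15-gene bovine leukocyte set — five pro-inflammatory
cytokines, one anti-inflammatory cytokine, six neuroactive
ligand-receptor genes, and the GAPDH/GUSB/YWHAZ reference trio — read
against two groups of 8 calves sampled at 0, 4 and 24 h around a noxious
stimulus (48 lanes in total).

# Lane quality control

Four checks are applied per lane, mirroring the platform's default
settings:

* **Imaging**: percentage of requested fields of view successfully
  scanned; lanes strictly below 75% fail. The bound itself passes
  because the rule is stated as "below 75 fails".
* **Binding density**: recorded reporter-spot density must lie in
  [0.1, 2.25] spots/µm²; both bounds inclusive. The density is read
  from the lane attributes, not recomputed from counts — the instrument
  reports it and no public formula reproduces it exactly.
* **Positive-control linearity**: squared Pearson correlation between
  log2(count + 1) and log2 concentration over the six-probe spike-in
  ladder (128 down to 0.125 fM in 4-fold steps); r² strictly below 0.95
  fails. The +1 offset keeps zero counts finite and is negligible at
  ladder count levels.
* **Limit of detection**: the 0.5 fM POS_E probe must strictly exceed
  mean + 2·SD of the negative controls, with the sample (n−1) SD.

Where the platform documentation states thresholds but not
inclusivity, the conventions above are this package's documented
choices. QC only flags lanes; dropping flagged lanes is an explicit
normalization option (`drop_qc_failures`), because retaining or
excluding a marginal lane is an analysis decision, not a file-format
fact.

# Normalization

Three steps, in a fixed order enforced by the `ncountr_expr` stage
machine:

1. **Background minimisation.** Per lane, the cutoff
   max(negatives) + 2·SD(negatives) is subtracted from every gene probe
   (reference genes included), clamping at zero. The max-based rule is
   the default; `mean_plus_2sd` is available because the two rules are
   often conflated in practice. Spike-in controls are never
   background-subtracted: they are synthetic targets with no endogenous
   background.
2. **Positive-control normalization.** Per-lane factor =
   (arithmetic mean over lanes of the per-lane geometric mean of raw
   positive counts) / (this lane's geometric mean).
3. **Reference-gene normalization.** The same construction on the three
   reference genes, computed after steps 1–2 so the factors see
   background-corrected, positive-normalized values.

Two exact identities follow and are property-tested. First, after step
3 the geometric mean of the reference genes is identical across lanes.
Second, multiplying every count in one lane by c > 0 is absorbed by the
factors up to a single run-wide constant: the normalization *target*
(the across-lane mean of geometric means) shifts by O(1/n lanes), so
each entry of the normalized matrix changes by one common factor and
relative expression is exactly invariant. Absolute invariance of a
single lane is impossible under any data-derived target; tests
therefore assert that the entrywise ratio between the scaled and
unscaled runs is constant to 1e-9.

Lanes with a zero positive-control count, or a nonpositive reference
value after background subtraction, are hard errors rather than
silently imputed — both indicate an unusable lane.

# Per-gene repeated-measures model

The design lists time with three levels *and* uses the 0 h value as a
covariate; both cannot hold in one model, since 0 h would then be
response and regressor at once. `ncountr` resolves this with two
companion fits:

* **Default (covariate) model** — responses at 4 and 24 h; fixed
  effects group, time, group×time plus each animal's 0 h value as a
  baseline covariate; within-animal correlation AR1 by measurement
  order. This model supplies the between-group contrasts at each time
  (`contrast_between_groups()`), with least-squares means evaluated at
  the grand-mean baseline.
* **Three-timepoint model** — all of 0/4/24 h as repeated responses,
  no covariate, fitted per group; supplies the within-group
  vs-baseline contrasts (`contrast_vs_baseline()`). With two time
  points and a freely estimated correlation this reproduces the
  matched-pairs t test exactly, which the tests verify against
  `t.test(paired = TRUE)` at 1e-8.

Estimation is REML: for a candidate correlation ρ the fixed effects
are profiled out by generalized least squares (the AR1 structure admits
a closed-form whitening), σ² is profiled as RSS/(n−p), and ρ is
maximized by Brent search on (−0.98, 0.98) followed by a
finite-difference Newton polish (step sizes 1e-4 then 1e-6) — Brent
alone stalls near sqrt(machine eps), which leaves visible error in
contrast standard errors. The tests confirm the optimum by perturbing
ρ by ±0.05 and by cross-checking against `nlme::gls(corAR1)`.

Choices worth stating:

* AR1 correlation is indexed by measurement order, not elapsed hours,
  despite the unequal 0/4/24 spacing — matching the convention of the
  mixed-model software this analysis style comes from. With at most
  three measures per animal, a separate random intercept on top of AR1
  is weakly identified, so the animal effect is carried entirely by
  the correlation structure; `compound_symmetry` stands in for a pure
  random-intercept model and `independence` gives ordinary least
  squares.
* Degrees of freedom use a between–within split: between-animal df =
  animals − between-effect parameters; within df = observations −
  animals − within-effect parameters. Group-at-time slices involve the
  interaction and take the within df. Satterthwaite/Kenward–Roger are
  deliberately out of scope; the simulation suite shows the resulting
  between-group test holds its nominal 0.05 level within [0.03, 0.07].
* The response is modeled on the normalized-count scale by default
  (residual normality is checked, not assumed); `log2p1` is a flag.
  Shapiro–Wilk and Anderson–Darling statistics are advisory and never
  gate a fit.
* No multiplicity adjustment by default; a Benjamini–Hochberg column
  is optional, since the original analysis style reports unadjusted
  p ≤ 0.05.
* Unbalanced data (e.g. one dropped QC-failing 24 h lane) are handled
  by the GLS machinery directly; nothing is imputed.

# Power and sample size

`power_two_sample()` and `power_paired()` compute exact noncentral-t
power — noncentrality d·sqrt(n₁n₂/(n₁+n₂)) with df n₁+n₂−2 for two
independent means, dz·sqrt(n) with df n−1 for matched pairs, where
dz = mean difference / sqrt(sd₁² + sd₂² − 2·r·sd₁·sd₂) and r defaults
to 0.5, the conventional assumption for repeated readings. Tests are
two-sided by default. `solve_effect_size()` inverts the power function
by bisection (the route used to recover an effect size from a reported
realised power), and `solve_n()` searches the smallest per-group n
reaching a target power. Monte-Carlo t-test oracles at 2×10⁵
replicates agree with the closed forms within 0.005.

# The synthetic-data generator

`simulate_runset()` writes complete RCC lane sets with known ground
truth. Defaults are the study conditions: 8 animals per group, times
0/4/24 h, 48 lanes, the packaged 27-probe codeset, 555 of 555 fields
of view. Endogenous and reference counts are negative binomial (size
20) around baseline means of 500 and 2000 respectively; each animal
carries a latent Gaussian log2 trajectory with AR1 correlation 0.5
between consecutive times (the same value the paired power analysis
assumes) and marginal SD 0.25; per-lane scale factors are log-normal
with log-SD 0.1; positives are Poisson at 250 counts/fM; negatives
Poisson with mean 5. The recorded binding density is total counts /
(100 × FOV), tuned so clean lanes land inside [0.1, 2.25]. Each lane
draws from its own RNG stream derived from the seed, so lane subsets
regenerate independently and byte-identically.

Because the latent animal effect is Gaussian on the log2 scale while
the default model is linear in counts, simulated data are
intentionally only approximately well-specified — like real data. For
clean parameter-recovery and error-rate studies,
`simulate_gene_values()` generates per-gene values that match the GLS
model exactly (Gaussian, linear scale, AR1 by order). Passing tests on
these generators demonstrate internal correctness of the estimators
and the pipeline's invariances; they cannot certify behaviour under
RNA degradation, hybridisation artifacts, or cartridge batch effects,
none of which are simulated.

`inject_qc_failure()` perturbs one lane so that exactly one chosen QC
check fails (e.g. counted FOV lowered to 74% of requested, or the top
and bottom rungs of the positive ladder swapped), mirroring the
one-failing-lane-in-48 pattern such experiments typically show.

# Problem sizes and numerical settings

The simulation suites use sizes chosen to keep Monte-Carlo error well
inside the asserted bands while remaining desk-scale: 500 replicates
per cell for the 3×3 (ρ ∈ {0, 0.3, 0.6} × effect ∈ {0, 1, 2} residual
SDs) recovery grid with type-I error pooled over the 1500 null fits;
2×10⁵ replicates for the power oracles; 20 replicates of 50 animals
per group for correlation recovery; 8–12 replicates for full-pipeline
sign-recovery and noise-reduction checks. Bisection tolerances are
1e-8 (effect size) and 40 halvings (QC threshold recovery); exact
identities are asserted at 1e-8–1e-10; the normalization invariances
at 1e-9. Numeric CSV output is fixed at 9 significant digits so
repeated runs are byte-identical.

# Known limitations

* The between–within df approximation is simple; small-sample
  inference for heavily unbalanced designs would be better served by
  Satterthwaite df.
* The AR1-by-order convention ignores the unequal 0/4/24 h spacing; a
  continuous-time AR1 would decay with elapsed hours.
* Reference genes are background-subtracted before factor computation;
  platforms differ on this and the alternative is not exposed as an
  option beyond the background-rule switch.
* The power module covers the two t-test designs only — no ANOVA/F
  power, and no a priori power for the mixed model itself, which the
  simple t-test calculation deliberately approximates.
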