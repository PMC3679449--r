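---
title: "Models and methods behind centrorep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind centrorep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`centrorep` analyses the coupling between centromere-proximal
replication-origin firing and pericentromeric chromatin in budding yeast:
sort-seq replication-timing profiles, the inference of which origins fire
late in a kinetochore-impaired mutant, and the geometry of pericentromeric
ChIP enrichment. This vignette is the package's own account of the models,
the defaults, and the choices made where the design was genuinely open.

## The replication-kinetics model

Each origin `i` is a point `x_i` with a mean firing time `t_i` (minutes
into S phase). Once fired, two forks leave the origin at constant velocity
`v` and terminate where they meet a converging fork or a chromosome end.
Under these assumptions the first-replication time of locus `x` is the min
rule

    T(x) = min_i ( t_i + |x − x_i| / v ).

Assumptions worth making explicit:

* **Constant fork velocity**, identical everywhere. Real forks stall and
  vary; none of that is modelled.
* **Chromosome ends absorb forks** — no telomere-specific behaviour.
* **Deterministic mode** treats `t_i` as exact. **Stochastic mode** draws
  each cell's firing time from `Normal(t_mean, t_sigma)` truncated at zero
  and skips origins failing a per-cell competence Bernoulli trial, then
  averages `T(x)` over `n_cells` cells (default 500). The truncated normal
  is this package's choice of firing-time family; it is isolated behind
  the origin parameters, so another family could be substituted without
  touching the rest of the model. Deterministic mode is the default used
  by the tests and the demo.

The sorted S-phase pool is modelled as cells uniformly distributed across
S-phase progression (the sorting gate spans S phase, and uniformity is the
simplest assumption not contradicted by anything we model), which gives
the linear conversion to relative copy number

    r(x) = 2 − T(x) / S_dur,  clipped to [1, 2].

An independent check is provided by `lattice_fork_oracle()`: an explicit
time-stepped simulation on a site lattice (default `dt` = 0.2 min,
`dx` = 500 bp) in which origins seed fork pairs when their time passes and
forks claim one site per `dx` of accumulated travel. It shares no code
with the min rule and agrees with it within one discretization step
(`dt + dx/v`); the property-based tests run it against the analytic map on
hundreds of random origin configurations.

## What the synthetic generator emulates — and what it does not

`make_genome()` builds `n_chrom` chromosomes (default 4 × 400 kb for fast
runs; 16 × 500 kb approximates the real genome's scale) with mid-chromosome
point centromeres. Origins sit on a regular grid (default spacing 40 kb)
whose phase is staggered across chromosomes — chromosome `c` of `n` has arm
origins at `cen ± ((2c−1)/(2n) + k)·spacing` — plus one origin 1 kb from
each centromere. The stagger matters: with identical phases, every
chromosome would offer origins at the same centromere distances and a
delayed-origin cutoff between two consecutive distances would be
unidentifiable. A real genome presents origins at many distances; the
stagger reproduces that property with a deterministic construction.

Mean firing times rise linearly with centromere distance from `t_early`
(10 min) at the pericentromeric origin to `t_late` (35 min) at the
chromosome end, so centromeric regions replicate early — the qualitative
feature the analyses depend on. No per-origin firing-time measurements are
modelled.

Sequencing is Poisson at bin level: `G2 ~ Poisson(depth)` and
`S ~ Poisson(depth · r(x)/1.5)` (1.5 being the midpoint of the copy-number
scale, so sample totals are comparable), with an optional multiplicative
per-bin bias vector as a mappability surrogate (default 1). ChIP tracks
are a flat background of 1 plus triangular bumps of half-width 1 kb at
binding sites, `input ~ Poisson(depth)`, `IP ~ Poisson(depth · e(x))`; in
mutant mode each bump's amplitude is multiplied by
`1 − ρ·exp(−d/λ_c)` with `d` the site's centromere distance.

Not emulated: read-level effects (alignment, GC bias, mappability
structure), sort impurity, copy-number variants, replication checkpoints,
or origin interference. Passing tests therefore demonstrate correctness of
the analysis chain under Poisson noise and the stated kinetics — not
robustness to artefacts real sequencing adds.

## Sort-seq pipeline choices

* **Ratio.** Both samples are scaled to equal totals before the per-bin
  S/G2 ratio, so the ratio is sequencing-depth-free. Bins with fewer than
  `min_count = 10` raw G2 reads are marked missing (`NA`), and every later
  stage propagates missingness rather than imputing.
* **Normalization to [1, 2].** The display convention anchors the 1st
  percentile of the ratio track at 1.0 and the 99th at 2.0, then clips.
  The anchors are estimated on a moving-average-denoised copy of the track
  (window 15 kb) while the map is applied to the raw values: anchoring on
  raw per-bin quantiles would let counting noise widen the anchor range,
  shrinking the profile's amplitude as depth drops — the displayed scale
  must estimate the signal range, not the noise range. A mean-anchored
  alternative (genome mean → 1.5) is available via `anchor = "mean"`.
* **Smoothing.** Centered moving average, default window 15 kb, computed
  within chromosomes only; missing bins are excluded from neighbours'
  windows and stay missing. A moving average was chosen over spline or
  loess smoothing because it is deterministic, parameter-transparent, and
  trivially NA-aware.
* **Peaks.** Strict local maxima with a prominence threshold (default
  0.02 copy-number units). On noise-free model profiles every called peak
  lies within one bin of an origin.

## Inferring the delayed-origin cutoff

`fit_delay_cutoff()` searches a grid of cutoffs `D` (default 0–50 kb in
2.5-kb steps) and delays `δ` (0–30 min in 2.5-min steps). For each
candidate, wild-type origins within `D` of a centromere are delayed by
`δ`, pushed through the deterministic kinetics model, and compared to the
observed mutant profile by sum of squared deviations over bins within
100 kb of a centromere. Numerical choices:

* **Scale matching.** The observed profile lives on the normalized
  display scale, so each model profile is normalized with the same
  convention (and smoothed with the same window, when given) before
  scoring. Sort-seq is a relative measurement; comparing a normalized
  observation to an unnormalized model would score the display convention,
  not the kinetics.
* **Scoring window.** Arm bins carry no information about a
  pericentromeric delay and only dilute the objective; 100 kb retains the
  full alleviation geometry around every centromere. Configurable.
* **Tie-breaks.** Grid cells are visited in increasing `D`, then `δ`, and
  only strict improvements are accepted — ties resolve to the smallest
  `D`, then the smallest `δ`. A mutant identical to wild type therefore
  returns `D = 0`. Note that all `D` between two consecutive origin
  distances flag the same origin set and score identically, so the
  reported cutoff is the smallest grid value consistent with the flagged
  set.
* **One genome-wide cutoff.** Chromosome-to-chromosome variation in the
  observed delay is explained by origin geometry (an undelayed origin just
  outside the cutoff alleviates the delay on its side), not by
  chromosome-specific cutoffs, so a single `(D, δ)` shared by all
  chromosomes is the parsimonious model. Per-chromosome fitting can be
  had by calling the function on single-chromosome inputs.

Per-origin delays (`origin_delays()`) are reported both in copy-number
units (the profile difference at the origin's bin) and in minutes
(multiplying by `S_dur`, with the factor recorded), since the display
normalization stretches the copy-number scale and the minute conversion is
only as good as that stretch. The delay-versus-distance curve is fitted
with `a·exp(−d/λ) + c` — three parameters encoding the observed shape
(largest at the centromere, vanishing on the arms); initialization
`a = max(y)`, `λ = 10` kb, `c = 0`, Levenberg–Marquardt, with a
Nelder–Mead fallback for singular Jacobians and an immediate exact return
for constant responses.

## ChIP geometry and the calibrated mutant reduction

The enrichment apex ratio between strains at a peak of amplitude `A` and
centromere distance `d` is

    ratio(d) = (1 + A) / (1 + A·(1 − ρ·e^(−d/λ_c))),

which is not itself of the form `a·e^(−d/λ) + c`; fitting the exponential
family to `ratio − 1` therefore recovers `λ_c` with a small systematic
underestimate that grows with `A` and `ρ`. The generator defaults were
fixed once by an a-priori identifiability analysis: `A = 2` (3-fold peaks
over background, typical of cohesin ChIP), `ρ = 0.3`, and
`λ_c = 20/ln 2 ≈ 28.9` kb, calibrated so apex enrichment is reduced by
exactly 10% at 20 kb from a centromere — i.e. the reduction is
"pericentromere-wide" on a 20-kb scale. At these values the regression's
intrinsic bias is about −15%, within the package's stated ±20% recovery
tolerance; substantially stronger reductions (`ρ ≥ 0.5`) would push the
family mismatch past that tolerance, which is worth knowing before fitting
this family to real data.

Peak calling uses the simplest auditable scheme — a height threshold
(default 1.5 × track median) plus a minimum apex separation (2 kb, higher
peak wins, ties leftmost) — rather than a named algorithm, so every call
is reproducible by inspection.

## Count statistics

Cohesion (two-dot) fractions and chromosome-loss rates are proportions of
small counts, so all intervals are Wilson score intervals and all
comparisons are two-sided Fisher exact tests (the tests verify them
against a from-scratch hypergeometric enumeration). The loss-rate
estimator is half-sectored colonies over total — loss at the first
division; full fluctuation analysis is out of scope. "Synergy" between
two perturbations is declared on the additive scale of excess rates: the
double perturbation's excess over control must exceed the sum of the two
single excesses.

## Problem sizes and determinism

The test suite and demo run on the 4 × 400 kb genome at 1-kb bins and
depth 300, sizes at which every stage (including the 21 × 13 cutoff grid,
each cell a full genome kinetics evaluation) completes in seconds while
leaving the delay and enrichment geometries fully resolvable. Every
stochastic step takes an explicit seed, and identical configurations
produce byte-identical outputs, which the demo tests assert.

## Known limitations

* The min-rule model has no checkpoint feedback, no limiting-factor
  recycling, and no multi-loading of helicases; it is the minimal model
  within which a firing-time delay propagates by passive replication.
* The minute-scale delay estimates inherit the display normalization's
  stretch; treat them as relative magnitudes unless the profile's true
  dynamic range is known.
* The exponential-decay regression family is a descriptive curve, not the
  generator's closed form; its decay-length estimates carry the bias
  quantified above.
* qPCR fold-enrichment SDs are computed over whatever replicate rows are
  supplied; the package does not distinguish technical from biological
  replication.
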