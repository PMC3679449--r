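# centrorep

Tools for analysing how replication-origin firing near centromeres shapes
genome-wide replication-timing profiles and pericentromeric cohesin
enrichment in budding yeast.

In yeast, centromeric regions replicate early in S phase, and kinetochore
components help recruit the firing machinery to centromere-proximal
origins. When that recruitment is impaired, origins within a short distance
of centromeres initiate late, replication of the pericentromere is delayed,
and cohesin enrichment around centromeres drops. `centrorep` implements the
quantitative side of that analysis for sorted-cell sequencing (sort-seq)
and ChIP data, together with a seeded synthetic-data generator so the whole
chain is testable without external sequencing data.

## What it computes

**Replication kinetics.** With origins at positions `x_i` firing at times
`t_i` and forks moving at velocity `v`, the time at which locus `x`
replicates is the min rule

```
T(x) = min_i ( t_i + |x − x_i| / v )
```

A population of cells sampled uniformly across an S phase of duration `S`
then shows relative copy number `r(x) = 2 − T(x)/S`, clipped to `[1, 2]` —
the scale on which sort-seq profiles are drawn (2.0 earliest, 1.0 latest).
A stochastic mode (truncated-normal firing times, per-origin competence)
and an independent brute-force lattice fork simulation are included.

**Sort-seq pipeline.** `compute_ratio()` (depth-normalized S/G2-M
per-bin ratio with coverage filtering), `normalize_profile()` (robust
rescale onto `[1.0, 2.0]`), `smooth_profile()` (per-chromosome moving
average), `differential_profile()` and `profile_peaks()` (peaks of the
timing profile coincide with origins).

**Timing inference.** `origin_delays()` evaluates the wild-type minus
mutant profile difference at each origin; `delay_distance_regression()`
fits `delay = a·exp(−d/λ) + c` against centromere distance `d`; and
`fit_delay_cutoff()` grid-searches the cutoff distance `D` and delay `δ`
such that delaying initiation of all origins within `D` kb of centromeres
by `δ` minutes recapitulates an observed mutant profile.

**ChIP and count statistics.** Fold enrichment anchored at a control locus
(`fold_enrichment()`), IP/input enrichment tracks, threshold-and-separation
peak calling, peak-height ratio regression against centromere distance, and
exact count statistics for cohesion (two-dot) assays and half-sectored
colony chromosome-loss assays (Wilson intervals, Fisher exact tests, an
additive-excess synergy test).

## Worked example

```r
library(centrorep)

out <- tempfile()
report <- run_demo(outdir = out, quiet = TRUE)   # default config, seed 7

report$delay_fit
#> $cutoff_D_hat
#> [1] 15
#> $delta_hat
#> [1] 10
#> $n_flagged
#> [1] 8

report$profile_range
#> [1] 1.021154 1.974473

report$chip$ratio_fit$lambda
#> [1] 27.18759
```

The demo builds a 4 × 400 kb genome (44 origins, one within 1 kb of each
centromere, early pericentromeric firing), simulates a mutant in which
origins within 17.5 kb of centromeres fire 10 minutes late, sequences both
strains at depth 300 with Poisson noise, reconstructs their profiles, and
fits the cutoff back: `cutoff_D_hat = 15` kb recovers the hidden truth to
within one origin spacing (the nearest origin ring inside the true 17.5-kb
cutoff sits at 15 kb, so 15 is the smallest cutoff consistent with the
data), and the fitted per-origin delay is exactly the simulated 10 min.
The ChIP peak-ratio regression recovers a decay length of 27.2 kb against
a generating value of 28.9 kb. All outputs (bedGraph tracks, BED peak and
origin annotations, TSV delay tables, JSON fits) are written under
`outdir`; rerunning with the same config is byte-identical.

A thin command-line wrapper with `demo`, `simulate`, `profile`, `diff` and
`fitdelay` subcommands is at `inst/scripts/centrorep.R`.

## Documentation

The methods vignette (`vignettes/centrorep-methods.Rmd`) describes the
model and its assumptions, what the synthetic generator does and does not
emulate, every tunable default with its rationale, and known limitations.
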