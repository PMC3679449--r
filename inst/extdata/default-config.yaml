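# centrorep default run configuration.
# Values flagged "free choice" have no published counterpart and were fixed
# once at realistic magnitudes; see the methods vignette for rationale.

seed: 7

genome:
  n_chrom: 4            # 4 x 400 kb for desk-scale runs; 16 x 500 kb for a
  chrom_length: 400000  # full-genome-sized demonstration
  origin_spacing: 40000
  t_early: 10           # minutes; earliest (pericentromeric) origins
  t_late: 35            # minutes; latest arm origins

kinetics:
  v: 1.5                # fork velocity, kb/min (free choice, yeast-typical)
  S_dur: 40             # S-phase duration, minutes (free choice)
  mode: deterministic
  n_cells: 500          # stochastic mode only

mutant:
  cutoff_D: 17.5        # kb; origins closer to a centromere are delayed
  delay_delta: 10       # minutes added to their mean firing time

sortseq:
  depth: 300            # mean G2 reads per bin (free choice)
  bin_width: 1000       # bp (free choice)
  min_count: 10         # G2 reads below this mark a bin missing
  smooth_window: 15     # kb moving average (free choice)
  anchor: quantile      # or "mean"

chip:
  site_spacing: 8000    # bp between synthetic binding sites
  amplitude: 2          # apex fold excess over background
  rho: 0.3              # fractional amplitude reduction at the centromere
  lambda_c: 28.853900817779268  # kb = 20/ln 2: 10% reduction at 20 kb
  depth: 300
  min_input: 10
  min_separation: 2     # kb between called peak apexes

fit:
  D_grid: [0, 2.5, 5, 7.5, 10, 12.5, 15, 17.5, 20, 22.5, 25, 27.5, 30,
           32.5, 35, 37.5, 40, 42.5, 45, 47.5, 50]
  delta_grid: [0, 2.5, 5, 7.5, 10, 12.5, 15, 17.5, 20, 22.5, 25, 27.5, 30]
  window: 100           # kb around centromeres scored by the cutoff fit
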