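#' Simulate sort-seq S and G2-M read counts from a copy-number profile
#'
#' Emulates sorted-fraction sequencing at bin level: the G2-M sample sees
#' every locus at equal (fully replicated) copy number, while the S-phase
#' sample sees locus `x` in proportion to its relative copy number `r(x)`.
#' Counts are independent Poisson draws,
#' `G2 ~ Poisson(depth * b(x))` and
#' `S ~ Poisson(depth * r(x)/1.5 * b(x))`,
#' where 1.5 is the midpoint of the \[1, 2\] scale (so both samples have
#' comparable totals for a typical genome) and `b(x)` is an optional
#' multiplicative per-bin bias (mappability surrogate), 1 by default.
#'
#' @param profile a `copy_number_profile` with all values in \[1, 2\].
#' @param depth mean reads per bin in the G2 sample (> 0).
#' @param seed optional integer seed; identical seeds give identical counts.
#' @param bias optional per-bin multiplicative bias vector (> 0).
#' @return `list(S = read_counts, G2 = read_counts)` on the profile's grid.
#' @export
simulate_sortseq_counts <- function(profile, depth = 300, seed = NULL,
                                    bias = NULL) {
  r <- profile$value
  if (depth <= 0) stop_param("depth must be > 0")
  if (anyNA(r) || any(r < 1 | r > 2)) {
    stop_param("profile values must lie in [1, 2]")
  }
  n <- length(r)
  b <- if (is.null(bias)) rep(1, n) else rep_len(bias, n)
  if (any(b <= 0)) stop_param("bias must be positive")
  if (!is.null(seed)) set.seed(seed)
  S <- rpois(n, depth * r / 1.5 * b)
  G2 <- rpois(n, depth * b)
  list(S = track_like(profile, as.numeric(S), "S", "read_counts"),
       G2 = track_like(profile, as.numeric(G2), "G2", "read_counts"))
}

#' Expected ChIP enrichment field
#'
#' The noise-free IP/input enrichment underlying [simulate_chip_counts()]:
#' `e(x) = 1 + sum_p A_p * max(0, 1 - |x - p| / halfwidth)` — a flat
#' background of 1 plus a triangular bump of half-width 1 kb at each binding
#' site. In mutant mode each bump's amplitude is multiplied by
#' `1 - rho * exp(-d_p / lambda_c)` with `d_p` the site's centromere
#' distance (kb), so the reduction is strongest at centromeres and decays
#' along the arms with length scale `lambda_c`.
#'
#' @param layout a [genome_layout()].
#' @param peaks data frame with columns `chrom`, `pos` (bp) and optionally
#'   `amplitude`; sites of protein binding.
#' @param amplitude fold excess over background at the apex, recycled when
#'   `peaks$amplitude` is absent.
#' @param mutant `NULL` for wild type, else `list(rho =, lambda_c =)` with
#'   `0 <= rho <= 1` (fractional amplitude reduction at the centromere) and
#'   `lambda_c > 0` (decay length, kb). The default reduction used by
#'   [run_demo()] is `rho = 0.3` with `lambda_c = 20/log(2)` kb, calibrated
#'   so apex enrichment is reduced by 10% at 20 kb from a centromere.
#' @param bin_width grid bin size (bp).
#' @param halfwidth kernel half-width in bp.
#' @return an `enrichment_track` of expected IP/input values.
#' @export
chip_expected_enrichment <- function(layout, peaks, amplitude = 2,
                                     mutant = NULL, bin_width = 1000,
                                     halfwidth = 1000) {
  len <- layout$length[match(peaks$chrom, layout$chrom)]
  if (anyNA(len) || any(peaks$pos < 0 | peaks$pos >= len)) {
    stop_param("peak positions must lie within layout chromosomes")
  }
  amp <- if ("amplitude" %in% names(peaks)) peaks$amplitude
         else rep_len(amplitude, nrow(peaks))
  if (!is.null(mutant)) {
    rho <- mutant$rho; lc <- mutant$lambda_c
    if (rho < 0 || rho > 1 || lc <= 0) {
      stop_param("mutant reduction needs 0 <= rho <= 1 and lambda_c > 0")
    }
    d <- centromere_distance(layout, peaks$chrom, peaks$pos)
    amp <- amp * (1 - rho * exp(-d / lc))
  }
  tr <- bin_track(layout, bin_width, 1, subclass = "enrichment_track")
  x <- track_centers(tr)
  for (i in seq_len(nrow(peaks))) {
    on <- tr$chrom == peaks$chrom[i]
    k <- pmax(0, 1 - abs(x[on] - peaks$pos[i]) / halfwidth)
    tr$value[on] <- tr$value[on] + amp[i] * k
  }
  tr
}

#' Simulate ChIP-seq IP and input read counts
#'
#' Poissonizes the expected enrichment field of
#' [chip_expected_enrichment()]:
#' `input ~ Poisson(depth)` and `IP ~ Poisson(depth * e(x))` per bin.
#'
#' @inheritParams chip_expected_enrichment
#' @param depth mean input reads per bin (> 0).
#' @param seed optional integer seed.
#' @return `list(ip = read_counts, input = read_counts, expected =
#'   enrichment_track)`.
#' @export
simulate_chip_counts <- function(layout, peaks, amplitude = 2, mutant = NULL,
                                 depth = 300, seed = NULL, bin_width = 1000,
                                 halfwidth = 1000) {
  if (depth <= 0) stop_param("depth must be > 0")
  e <- chip_expected_enrichment(layout, peaks, amplitude, mutant,
                                bin_width, halfwidth)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(e)
  ip <- rpois(n, depth * e$value)
  input <- rpois(n, depth)
  list(ip = track_like(e, as.numeric(ip), "IP", "read_counts"),
       input = track_like(e, as.numeric(input), "input", "read_counts"),
       expected = e)
}

#' Regularly spaced ChIP binding sites for synthetic genomes
#'
#' Convenience layout of binding sites every `spacing` bp along each
#' chromosome (offset by `spacing/2`), giving peaks at a range of centromere
#' distances for ratio-versus-distance analyses.
#'
#' @param layout a [genome_layout()].
#' @param spacing distance between sites in bp.
#' @export
chip_site_grid <- function(layout, spacing = 8000) {
  do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    pos <- seq(spacing / 2, layout$length[i] - 1, by = spacing)
    data.frame(chrom = layout$chrom[i], pos = pos, stringsAsFactors = FALSE)
  }))
}
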