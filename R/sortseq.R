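#' S/G2-M read-count ratio track
#'
#' Depth-normalizes both samples to equal totals, then takes the per-bin
#' ratio `(S / S_total) / (G2 / G2_total)`. Bins whose raw G2 count is
#' below `min_count` are unreliable denominators and are marked missing
#' (`NA`), never 0.
#'
#' @param S,G2 `read_counts` tracks on the same grid.
#' @param min_count minimum raw G2 reads for a bin to be kept.
#' @return a `ratio_track` `bin_track`.
#' @export
compute_ratio <- function(S, G2, min_count = 10) {
  stopifnot_same_grid(S, G2)
  s_tot <- sum(S$value, na.rm = TRUE)
  g_tot <- sum(G2$value, na.rm = TRUE)
  if (s_tot <= 0 || g_tot <= 0) stop_param("a sample has zero total reads")
  ratio <- (S$value / s_tot) / (G2$value / g_tot)
  ratio[is.na(G2$value) | G2$value < min_count | is.na(S$value)] <- NA_real_
  track_like(S, ratio, label = NULL, subclass = "ratio_track")
}

# shared normalization core: affine map sending quantiles (q_lo, q_hi) of
# `ref` to (1, 2) applied to v, or rescale so mean(ref) -> 1.5, then clip
# to [1, 2]. `ref` defaults to v itself; passing a denoised copy keeps the
# anchors from being inflated by per-bin noise.
normalize_values <- function(v, anchor = c("quantile", "mean"),
                             probs = c(0.01, 0.99), ref = v) {
  anchor <- match.arg(anchor)
  ok <- !is.na(ref)
  if (anchor == "quantile") {
    q <- quantile(ref[ok], probs, names = FALSE, type = 7)
    if (diff(q) < 1e-9) stop_param("degenerate track: interquantile range is zero")
    out <- 1 + (v - q[1]) / diff(q)
  } else {
    m <- mean(ref[ok])
    if (m <= 0) stop_param("degenerate track: non-positive mean")
    out <- v / m * 1.5
  }
  pmin(2, pmax(1, out))
}

#' Normalize a raw ratio track onto the \[1.0, 2.0\] copy-number scale
#'
#' Sort-seq profiles are conventionally displayed between 1.0 (latest
#' replicating) and 2.0 (earliest). The default maps the 1st percentile of
#' the raw ratios to 1.0 and the 99th to 2.0 (robust to outlier bins),
#' then clips; `anchor = "mean"` instead rescales the genome mean to 1.5.
#'
#' The two anchor quantiles are estimated on a moving-average-denoised
#' copy of the track (window `anchor_window` kb) while the affine map is
#' applied to the raw values. Without this, Poisson counting noise widens
#' the raw 1%/99% range and the normalized profile's amplitude would
#' shrink as sequencing depth drops — the displayed scale must estimate
#' the signal range, not the noise range. Set `anchor_window = NULL` to
#' anchor on the raw quantiles directly.
#'
#' @param raw a `ratio_track` with at least 100 defined bins.
#' @param anchor `"quantile"` (default) or `"mean"`.
#' @param probs quantile anchors used when `anchor = "quantile"`.
#' @param anchor_window denoising window (kb) for anchor estimation.
#' @param label optional strain label.
#' @return a `copy_number_profile`, missing bins preserved.
#' @export
normalize_profile <- function(raw, anchor = c("quantile", "mean"),
                              probs = c(0.01, 0.99), anchor_window = 15,
                              label = NULL) {
  if (sum(!is.na(raw$value)) < 100) {
    stop_param("need at least 100 defined bins to normalize")
  }
  ref <- raw$value
  if (!is.null(anchor_window)) {
    w_bins <- odd_bins(anchor_window, bin_width(raw))
    if (w_bins > 1) ref <- smooth_values(raw$value, raw$chrom, w_bins)
  }
  v <- normalize_values(raw$value, anchor, probs, ref = ref)
  track_like(raw, v, label = label, subclass = "copy_number_profile")
}

# odd number of bins covering a window given in kb
odd_bins <- function(window_kb, bin_width_bp) {
  w <- max(1L, round(window_kb / bp2kb(bin_width_bp)))
  if (w %% 2 == 0) w <- w + 1L
  w
}

# centered moving average per chromosome, NA-excluding; NA in -> NA out.
# cumulative sums over values and defined-bin counts give O(n) windows,
# shortened at chromosome ends.
smooth_values <- function(value, chrom, w_bins) {
  half <- (w_bins - 1) / 2
  out <- value
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- value[i]
    n <- length(v)
    ok <- !is.na(v)
    cs <- cumsum(c(0, ifelse(ok, v, 0)))
    ck <- cumsum(c(0, as.numeric(ok)))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    k <- ck[hi + 1] - ck[lo]
    sm <- ifelse(k > 0, (cs[hi + 1] - cs[lo]) / k, NA_real_)
    sm[!ok] <- NA_real_
    out[i] <- sm
  }
  out
}

#' Smooth a copy-number profile with a moving average
#'
#' Centered moving average of width `window` kb within each chromosome
#' (no bleed across chromosome boundaries; shortened windows at the ends).
#' Missing bins are excluded from neighbors' window means and stay missing
#' themselves. Averaging values in \[1, 2\] preserves the bound.
#'
#' @param profile a `copy_number_profile`.
#' @param window window width in kb (>= one bin).
#' @export
smooth_profile <- function(profile, window = 15) {
  bw_kb <- bp2kb(bin_width(profile))
  if (window < bw_kb) stop_param("window must be at least one bin wide")
  w_bins <- odd_bins(window, bin_width(profile))
  v <- smooth_values(profile$value, profile$chrom, w_bins)
  out <- track_like(profile, v, label = attr(profile, "label"),
                    subclass = "copy_number_profile")
  attr(out, "smooth_window") <- window
  out
}

#' Differential replication-timing track between two strains
#'
#' Per-bin `a - b` on the normalized scale; positive values mean the locus
#' replicates earlier in `a`. Defined only where both profiles are defined;
#' anti-symmetric by construction.
#'
#' @param a,b `copy_number_profile`s on the same grid.
#' @export
differential_profile <- function(a, b) {
  stopifnot_same_grid(a, b)
  out <- track_like(a, a$value - b$value, subclass = "diff_track")
  attr(out, "strains") <- c(attr(a, "label"), attr(b, "label"))
  out
}

# strict local maxima with prominences, NA-aware, plateau -> leftmost bin.
# prominence of a peak: its height minus the higher of the two minima
# separating it from higher ground (or from the segment end).
local_peaks <- function(v) {
  peaks <- data.frame(idx = integer(0), prominence = numeric(0))
  runs <- rle(!is.na(v))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (seg in which(runs$values)) {
    i0 <- starts[seg]; i1 <- ends[seg]
    x <- v[i0:i1]
    n <- length(x)
    if (n < 2) next
    r <- rle(x)
    re <- cumsum(r$lengths); rs <- re - r$lengths + 1
    m <- length(r$values)
    for (k in seq_len(m)) {
      left_lower <- k > 1 && r$values[k - 1] < r$values[k]
      right_lower <- k < m && r$values[k + 1] < r$values[k]
      if (!(left_lower && right_lower)) next  # interior strict maxima only
      h <- r$values[k]
      lo_l <- h
      for (j in seq(k - 1, 1)) {
        if (r$values[j] > h) break
        lo_l <- min(lo_l, r$values[j])
      }
      lo_r <- h
      for (j in seq(k + 1, m)) {
        if (r$values[j] > h) break
        lo_r <- min(lo_r, r$values[j])
      }
      peaks <- rbind(peaks, data.frame(idx = i0 - 1 + rs[k],
                                       prominence = h - max(lo_l, lo_r)))
    }
  }
  peaks
}

#' Call peaks of a replication-timing profile
#'
#' Local maxima of the profile (earliest-replicating loci) with prominence
#' at least `min_prominence`, per chromosome. On noise-free model profiles
#' these coincide with replication-origin positions; smoothed input is
#' recommended for noisy profiles.
#'
#' @param profile a `copy_number_profile`.
#' @param min_prominence minimum peak prominence in copy-number units.
#' @return data frame `chrom`, `pos` (apex bin center, bp), `value`,
#'   `prominence`.
#' @export
profile_peaks <- function(profile, min_prominence = 0.02) {
  ctr <- track_centers(profile)
  out <- do.call(rbind, lapply(unique(profile$chrom), function(ch) {
    i <- which(profile$chrom == ch)
    pk <- local_peaks(profile$value[i])
    pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
    if (nrow(pk) == 0) return(NULL)
    data.frame(chrom = ch, pos = ctr[i][pk$idx],
               value = profile$value[i][pk$idx],
               prominence = pk$prominence, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      value = numeric(0), prominence = numeric(0))
  }
  rownames(out) <- NULL
  out
}
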