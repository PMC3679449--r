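#' ChIP-qPCR fold enrichment relative to a control locus
#'
#' For each measurement, the IP/whole-cell-extract ratio is divided by the
#' same ratio at a designated control locus in a reference condition, so
#' the control in the reference condition is exactly 1 by construction.
#' Replicate rows (same locus and condition) are each converted and then
#' summarized by mean and SD. An `anchor` of the form
#' `list(locus =, condition =)` overrides the default
#' (control locus, reference condition) anchoring — e.g. anchoring a time
#' course to one locus in one strain at time zero.
#'
#' @param panel data frame with columns `locus`, `condition`, `ip`, `wce`
#'   (quantities > 0) and optionally `cen_dist_kb`.
#' @param control_locus name of the control locus.
#' @param reference_condition name of the reference condition.
#' @param anchor optional `list(locus =, condition =)` anchoring override.
#' @return list with `folds` (per-row fold values) and `summary`
#'   (per locus x condition mean, sd, n).
#' @export
fold_enrichment <- function(panel, control_locus, reference_condition,
                            anchor = NULL) {
  need <- c("locus", "condition", "ip", "wce")
  if (!all(need %in% names(panel))) {
    stop_param("panel needs columns ", paste(need, collapse = ", "))
  }
  if (any(panel$wce <= 0)) stop_param("whole-cell-extract quantities must be > 0")
  if (any(panel$ip <= 0)) stop_param("IP quantities must be > 0")
  a_locus <- if (is.null(anchor)) control_locus else anchor$locus
  a_cond <- if (is.null(anchor)) reference_condition else anchor$condition
  ref <- panel$locus == a_locus & panel$condition == a_cond
  if (!any(ref)) stop_param("anchor (", a_locus, ", ", a_cond, ") absent from panel")
  ratio <- panel$ip / panel$wce
  denom <- mean(ratio[ref])
  folds <- panel
  folds$fold <- ratio / denom
  agg <- aggregate(fold ~ locus + condition, data = folds,
                   FUN = function(z) c(mean = mean(z), sd = if (length(z) > 1) stats::sd(z) else NA_real_, n = length(z)))
  summary <- data.frame(agg[c("locus", "condition")],
                        mean = agg$fold[, "mean"], sd = agg$fold[, "sd"],
                        n = agg$fold[, "n"])
  list(folds = folds, summary = summary)
}

#' Depth-normalized IP/input enrichment track
#'
#' Per-bin `(IP / IP_total) / (input / input_total)`; bins with raw input
#' below `min_input` are marked missing.
#'
#' @param ip,input `read_counts` tracks on the same grid.
#' @param min_input minimum raw input reads per bin.
#' @return an `enrichment_track`.
#' @export
enrichment_track <- function(ip, input, min_input = 10) {
  stopifnot_same_grid(ip, input)
  ip_tot <- sum(ip$value, na.rm = TRUE)
  in_tot <- sum(input$value, na.rm = TRUE)
  if (ip_tot <= 0 || in_tot <= 0) stop_param("a sample has zero total reads")
  ratio <- (ip$value / ip_tot) / (input$value / in_tot)
  ratio[is.na(input$value) | input$value < min_input | is.na(ip$value)] <- NA_real_
  track_like(ip, ratio, subclass = "enrichment_track")
}

#' Call enrichment peaks by threshold and minimum separation
#'
#' Strict local maxima of the track with height at least `threshold`
#' (default: 1.5 times the median of the defined bins); among maxima on
#' the same chromosome closer than `min_separation` kb, only the higher
#' apex is kept (ties to the leftmost). Each retained peak is annotated
#' with its centromere distance.
#'
#' @param track an `enrichment_track` (smoothed or high-depth input
#'   recommended).
#' @param layout a [genome_layout()] supplying centromere positions.
#' @param threshold minimum apex height; `NULL` for the median-based
#'   default.
#' @param min_separation minimum apex separation in kb.
#' @return a `peak_set` data frame: `chrom`, `pos`, `height`,
#'   `cen_dist_kb`.
#' @export
find_peaks <- function(track, layout, threshold = NULL, min_separation = 2) {
  if (is.null(threshold)) {
    threshold <- 1.5 * median(track$value, na.rm = TRUE)
  }
  ctr <- track_centers(track)
  cand <- do.call(rbind, lapply(unique(track$chrom), function(ch) {
    i <- which(track$chrom == ch)
    pk <- local_peaks(track$value[i])
    if (nrow(pk) == 0) return(NULL)
    data.frame(chrom = ch, pos = ctr[i][pk$idx],
               height = track$value[i][pk$idx], stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      height = numeric(0), cen_dist_kb = numeric(0))
  if (is.null(cand)) return(structure(empty, class = c("peak_set", "data.frame")))
  cand <- cand[cand$height >= threshold, , drop = FALSE]
  if (nrow(cand) == 0) return(structure(empty, class = c("peak_set", "data.frame")))

  # greedy separation filter: visit by decreasing height, ties leftmost
  cand <- cand[order(-cand$height, cand$chrom, cand$pos), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    same <- keep & cand$chrom == cand$chrom[k]
    if (!any(same & abs(cand$pos - cand$pos[k]) < kb2bp(min_separation))) {
      keep[k] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$cen_dist_kb <- centromere_distance(layout, out$chrom, out$pos)
  rownames(out) <- NULL
  structure(out, class = c("peak_set", "data.frame"))
}

#' Peak-height ratio between two strains, regressed on centromere distance
#'
#' At each peak apex (called on the first track, e.g. wild type), the
#' ratio of track-`a` height to track-`b` height is computed; peaks whose
#' apex bin is missing in either track are dropped with a warning. The
#' ratio excess over 1 is then fitted against centromere distance with the
#' exponential-decay family of [delay_distance_regression()] — a ratio
#' above 1 near centromeres that decays to 1 along the arms is the
#' signature of a specifically pericentromeric reduction in strain `b`.
#'
#' @param peaks a `peak_set` (from [find_peaks()] on `track_a`).
#' @param track_a,track_b `enrichment_track`s on the same grid.
#' @return list with `table` (per-peak `chrom`, `pos`, `cen_dist_kb`,
#'   `height_a`, `height_b`, `ratio`) and `fit` (a `decay_fit` of
#'   `ratio - 1` vs distance).
#' @export
peak_ratio_regression <- function(peaks, track_a, track_b) {
  stopifnot_same_grid(track_a, track_b)
  i <- track_bin_index(track_a, peaks$chrom, peaks$pos)
  ha <- track_a$value[i]
  hb <- track_b$value[i]
  drop <- is.na(ha) | is.na(hb) | hb <= 0
  if (any(drop)) {
    warning(sum(drop), " peak(s) dropped: apex missing in a track")
  }
  tab <- data.frame(chrom = peaks$chrom, pos = peaks$pos,
                    cen_dist_kb = peaks$cen_dist_kb,
                    height_a = ha, height_b = hb,
                    ratio = ha / hb, stringsAsFactors = FALSE)[!drop, , drop = FALSE]
  rownames(tab) <- NULL
  fit <- if (nrow(tab) >= 4 && length(unique(tab$cen_dist_kb)) >= 2) {
    delay_distance_regression(tab$cen_dist_kb, tab$ratio - 1)
  } else {
    NULL  # too few peaks to support the regression
  }
  list(table = tab, fit = fit)
}
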