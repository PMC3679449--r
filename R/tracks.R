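#' Binned genomic tracks
#'
#' All per-bin data in the package (read counts, timing maps, copy-number
#' profiles, ratio and enrichment tracks) share one representation: a data
#' frame with columns `chrom`, `start`, `end` (0-based, half-open bp
#' coordinates tiling each chromosome) and `value`, plus a `bin_width`
#' attribute and an optional `label`. Missing measurements are `NA`, never
#' 0 — every pipeline stage propagates them explicitly.
#'
#' @param layout a [genome_layout()].
#' @param bin_width bin size in bp.
#' @param value per-bin values recycled over the grid.
#' @param label free-text sample/strain label.
#' @param subclass extra S3 class(es) prepended to `bin_track`.
#' @return a `bin_track` data frame.
#' @export
bin_track <- function(layout, bin_width = 1000, value = NA_real_,
                      label = NULL, subclass = NULL) {
  grid <- layout_bins(layout, bin_width)
  grid$value <- rep_len(value, nrow(grid))
  new_bin_track(grid, bin_width, label, subclass)
}

#' @rdname bin_track
#' @export
layout_bins <- function(layout, bin_width = 1000) {
  if (bin_width <= 0) stop_param("bin_width must be positive")
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    starts <- seq(0, layout$length[i] - 1, by = bin_width)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + bin_width, layout$length[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

new_bin_track <- function(df, bin_width, label = NULL, subclass = NULL) {
  rownames(df) <- NULL
  structure(df,
            bin_width = bin_width, label = label,
            class = c(subclass, "bin_track", "data.frame"))
}

# carry values onto the grid of `template` (same grid assumed checked)
track_like <- function(template, value, label = NULL, subclass = NULL) {
  out <- template[c("chrom", "start", "end")]
  out$value <- value
  new_bin_track(out, attr(template, "bin_width"), label, subclass)
}

#' @rdname bin_track
#' @param track a `bin_track`.
#' @export
track_centers <- function(track) (track$start + track$end) / 2

#' @rdname bin_track
#' @export
bin_width <- function(track) attr(track, "bin_width")

stopifnot_same_grid <- function(a, b) {
  if (!identical(a$chrom, b$chrom) || !identical(a$start, b$start)) {
    stop_param("tracks are on different bin grids")
  }
}

#' Locate the bin index containing each position
#'
#' @param track a `bin_track`.
#' @param chrom,pos query coordinates (bp).
#' @return integer row indices into `track` (`NA` when not covered).
#' @export
track_bin_index <- function(track, chrom, pos) {
  bw <- bin_width(track)
  key <- paste(track$chrom, track$start %/% bw)
  match(paste(as.character(chrom), floor(pos / bw)), key)
}

#' @export
print.bin_track <- function(x, ...) {
  cat(sprintf("<bin_track%s> %d bins of %d bp on %d chromosome(s); %d missing\n",
              if (!is.null(attr(x, "label"))) paste0(" ", attr(x, "label")) else "",
              nrow(x), as.integer(bin_width(x)), length(unique(x$chrom)),
              sum(is.na(x$value))))
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Bin-level read counts for one sequencing sample
#'
#' A `bin_track` whose values are non-negative integer read counts, tagged
#' with its sample type (`"S"`, `"G2"`, `"IP"` or `"input"`).
#'
#' @param layout,bin_width grid definition, as in [bin_track()].
#' @param counts integer counts (>= 0), recycled.
#' @param sample sample label.
#' @export
read_counts <- function(layout, counts, sample, bin_width = 1000) {
  if (any(counts < 0) || any(counts != round(counts), na.rm = TRUE)) {
    stop_param("read counts must be non-negative integers")
  }
  bin_track(layout, bin_width, as.numeric(counts), label = sample,
            subclass = "read_counts")
}
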