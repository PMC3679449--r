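#' Read and write binned tracks as bedGraph
#'
#' Tracks are exchanged in bedGraph (0-based, half-open). Missing bins are
#' omitted on export; on import, supplying the `layout` and `bin_width`
#' reinstates the full grid with `NA` at absent bins, so missingness
#' round-trips.
#'
#' @param track a `bin_track`.
#' @param file path to a bedGraph file.
#' @export
write_bedgraph <- function(track, file) {
  ok <- !is.na(track$value)
  gr <- GenomicRanges::GRanges(
    track$chrom[ok],
    IRanges::IRanges(start = track$start[ok] + 1, end = track$end[ok]),
    score = track$value[ok]
  )
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname write_bedgraph
#' @param layout,bin_width optional grid definition used to reinstate
#'   missing bins.
#' @param subclass S3 subclass for the returned track.
#' @export
read_bedgraph <- function(file, layout = NULL, bin_width = NULL,
                          subclass = NULL) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   value = gr$score, stringsAsFactors = FALSE)
  if (is.null(layout)) {
    bw <- bin_width %||% max(df$end - df$start)
    return(new_bin_track(df, bw, subclass = subclass))
  }
  bw <- bin_width %||% max(df$end - df$start)
  grid <- bin_track(layout, bw, subclass = subclass)
  i <- track_bin_index(grid, df$chrom, df$start)
  grid$value[i[!is.na(i)]] <- df$value[!is.na(i)]
  grid
}

#' Genome layout and origin tables on disk
#'
#' The layout travels as a three-column TSV (`chrom`, `length`, `cen`);
#' origins as a TSV with the full [origin_set()] columns. BED exports of
#' centromere points, origins and peaks are provided for genome browsers.
#'
#' @param layout a [genome_layout()]; `origins` an [origin_set()].
#' @param file output path.
#' @export
write_layout <- function(layout, file) {
  write.table(as.data.frame(layout), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_layout
#' @export
read_layout <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  genome_layout(df$chrom, df$length, df$cen)
}

#' @rdname write_layout
#' @param origins an [origin_set()].
#' @export
write_origins <- function(origins, file) {
  write.table(as.data.frame(origins), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_layout
#' @export
read_origins <- function(file, layout = NULL) {
  df <- read.table(file, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  origin_set(df$chrom, df$pos, df$t_mean, df$t_sigma, df$competence,
             id = df$id, layout = layout)
}

#' @rdname write_layout
#' @export
write_centromeres_bed <- function(layout, file) {
  gr <- GenomicRanges::GRanges(
    layout$chrom, IRanges::IRanges(start = layout$cen + 1, width = 1),
    name = paste0(layout$chrom, "_CEN")
  )
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname write_layout
#' @export
write_origins_bed <- function(origins, file) {
  gr <- GenomicRanges::GRanges(
    origins$chrom, IRanges::IRanges(start = origins$pos + 1, width = 1),
    name = origins$id, score = origins$t_mean
  )
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname write_layout
#' @param peaks a `peak_set` from [find_peaks()].
#' @export
write_peaks_bed <- function(peaks, file) {
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$pos + 1, width = 1),
    name = sprintf("peak_%03d", seq_len(nrow(peaks))), score = peaks$height
  )
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
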