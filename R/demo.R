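#' Default run configuration
#'
#' All tunables of the end-to-end demonstration pipeline, overridable via
#' YAML ([read_run_config()]) or by editing the returned list. Sequencing
#' depth, bin size and smoothing window are free choices of this package
#' (no published values exist for them) and are flagged as such in the
#' shipped config file (`inst/extdata/default-config.yaml`).
#'
#' @return nested named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 7,
    genome = list(n_chrom = 4, chrom_length = 4e5, origin_spacing = 4e4,
                  t_early = 10, t_late = 35),
    kinetics = list(v = 1.5, S_dur = 40, mode = "deterministic",
                    n_cells = 500),
    mutant = list(cutoff_D = 17.5, delay_delta = 10),
    sortseq = list(depth = 300, bin_width = 1000, min_count = 10,
                   smooth_window = 15, anchor = "quantile"),
    chip = list(site_spacing = 8000, amplitude = 2, rho = 0.3,
                lambda_c = 20 / log(2), depth = 300, min_input = 10,
                min_separation = 2),
    fit = list(D_grid = seq(0, 50, by = 2.5),
               delta_grid = seq(0, 30, by = 2.5), window = 100)
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    full <- if (path == "") k else paste(path, k, sep = ".")
    if (!k %in% names(base)) {
      stop_param("unknown config key: ", full)
    }
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else if (is.numeric(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- unlist(user[[k]])  # YAML sequences of mixed int/real
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_config()]; keys not
#' present in the defaults are rejected with a message naming them.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  cfg
}

#' Run the full synthetic analysis chain
#'
#' Reproduces, on synthetic data, the analysis sequence from sorted-cell
#' read counts to the delayed-origin cutoff and pericentromeric ChIP
#' geometry: genome construction, wild-type and mutant replication
#' kinetics, sort-seq count simulation, profile reconstruction
#' (ratio, normalization, smoothing), differential profile, per-origin
#' delays and their distance regression, delay-cutoff fitting, ChIP count
#' simulation, enrichment tracks, peak calling and peak-ratio regression.
#' All outputs land under `outdir` (bedGraph tracks, BED annotations, TSV
#' tables, JSON fits and a JSON summary); every stochastic step is seeded
#' from `config$seed`, so identical configurations give byte-identical
#' outputs.
#'
#' @param config a configuration list, as from [default_config()] /
#'   [read_run_config()].
#' @param outdir writable output directory (created if absent).
#' @param quiet suppress stage messages.
#' @return the report list (also written as `summary.json`), invisibly.
#' @export
run_demo <- function(config = default_config(), outdir, quiet = FALSE) {
  config <- merge_config(default_config(), config)
  if (length(config$fit$D_grid) == 0 || length(config$fit$delta_grid) == 0) {
    stop_param("invalid config: fit.D_grid and fit.delta_grid must be non-empty")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[centrorep] ", ...)
  seed <- config$seed
  sq <- config$sortseq
  kin <- do.call(kinetics_params, config$kinetics)

  say("building genome (", config$genome$n_chrom, " chromosomes)")
  g <- do.call(make_genome, c(config$genome, list(seed = seed)))
  mut_origins <- apply_mutant(g$origins, g$layout,
                              mutant_spec(config$mutant$cutoff_D,
                                          config$mutant$delay_delta))
  write_layout(g$layout, file.path(outdir, "layout.tsv"))
  write_centromeres_bed(g$layout, file.path(outdir, "centromeres.bed"))
  write_origins(g$origins, file.path(outdir, "origins_wt.tsv"))
  write_origins_bed(g$origins, file.path(outdir, "origins_wt.bed"))

  say("simulating sort-seq counts and reconstructing profiles")
  profiles <- list()
  for (strain in c("wt", "mut")) {
    ori <- if (strain == "wt") g$origins else mut_origins
    truth <- copy_number_profile(
      replication_time(g$layout, ori, kin, sq$bin_width), kin, label = strain)
    cts <- simulate_sortseq_counts(truth, depth = sq$depth,
                                   seed = seed + match(strain, c("wt", "mut")))
    prof <- smooth_profile(
      normalize_profile(compute_ratio(cts$S, cts$G2, sq$min_count),
                        anchor = sq$anchor, label = strain),
      window = sq$smooth_window)
    profiles[[strain]] <- prof
    write_bedgraph(prof, file.path(outdir, paste0("profile_", strain, ".bedgraph")))
  }

  diff <- differential_profile(profiles$wt, profiles$mut)
  write_bedgraph(diff, file.path(outdir, "profile_diff.bedgraph"))

  say("per-origin delays and distance regression")
  delays <- origin_delays(profiles$wt, profiles$mut, g$origins, g$layout,
                          S_dur = kin$S_dur)
  write.table(as.data.frame(delays), file.path(outdir, "origin_delays.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  decay <- delay_distance_regression(delays)

  say("fitting the delayed-origin cutoff")
  fit <- fit_delay_cutoff(g$origins, g$layout, profiles$mut, kin,
                          D_grid = config$fit$D_grid,
                          delta_grid = config$fit$delta_grid,
                          window = config$fit$window,
                          smooth_window = sq$smooth_window,
                          anchor = sq$anchor)
  jsonlite::write_json(
    list(cutoff_D_hat = fit$cutoff_D_hat, delta_hat = fit$delta_hat,
         flagged = fit$flagged, objective = fit$objective),
    file.path(outdir, "delay_fit.json"), auto_unbox = TRUE, digits = NA)

  say("ChIP simulation, peak calling and ratio regression")
  cp <- config$chip
  sites <- chip_site_grid(g$layout, cp$site_spacing)
  wt_chip <- simulate_chip_counts(g$layout, sites, cp$amplitude,
                                  mutant = NULL, depth = cp$depth,
                                  seed = seed + 11, bin_width = sq$bin_width)
  mut_chip <- simulate_chip_counts(
    g$layout, sites, cp$amplitude,
    mutant = list(rho = cp$rho, lambda_c = cp$lambda_c),
    depth = cp$depth, seed = seed + 12, bin_width = sq$bin_width)
  tr_wt <- enrichment_track(wt_chip$ip, wt_chip$input, cp$min_input)
  tr_mut <- enrichment_track(mut_chip$ip, mut_chip$input, cp$min_input)
  write_bedgraph(tr_wt, file.path(outdir, "chip_wt.bedgraph"))
  write_bedgraph(tr_mut, file.path(outdir, "chip_mut.bedgraph"))
  peaks <- find_peaks(tr_wt, g$layout, min_separation = cp$min_separation)
  write_peaks_bed(peaks, file.path(outdir, "chip_peaks.bed"))
  prr <- peak_ratio_regression(peaks, tr_wt, tr_mut)
  jsonlite::write_json(
    list(n_peaks = nrow(prr$table),
         fit = prr$fit[c("a", "lambda", "c", "rss", "n")]),
    file.path(outdir, "chip_ratio_fit.json"), auto_unbox = TRUE, digits = NA)

  report <- list(
    config = config,
    n_origins = nrow(g$origins),
    profile_range = range(c(profiles$wt$value, profiles$mut$value),
                          na.rm = TRUE),
    delay_fit = list(cutoff_D_hat = fit$cutoff_D_hat,
                     delta_hat = fit$delta_hat,
                     n_flagged = length(fit$flagged)),
    delay_regression = decay[c("a", "lambda", "c", "rss", "n")],
    chip = list(n_peaks = nrow(prr$table),
                ratio_fit = prr$fit[c("a", "lambda", "c", "rss", "n")])
  )
  jsonlite::write_json(report, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: outputs in ", outdir)
  invisible(report)
}
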