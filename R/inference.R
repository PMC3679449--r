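#' Per-origin replication delays between two strains
#'
#' Evaluates the profile difference `wt(x_i) - mut(x_i)` at each origin's
#' bin. On the normalized scale this difference is in copy-number units
#' (`delay_cn`); multiplying by the S-phase duration converts it to minutes
#' (`delay_min`), the conversion factor being recorded in the result.
#' Origins whose bin is missing in either profile are dropped; the number
#' dropped is returned as the `n_dropped` attribute (with a warning).
#'
#' @param wt,mut `copy_number_profile`s on the same grid.
#' @param origins an [origin_set()].
#' @param layout the matching [genome_layout()].
#' @param S_dur S-phase duration in minutes used for the unit conversion.
#' @return an `origin_delay_table` data frame with columns `id`, `chrom`,
#'   `pos`, `cen_dist_kb`, `delay_cn`, `delay_min`.
#' @export
origin_delays <- function(wt, mut, origins, layout, S_dur = 40) {
  stopifnot_same_grid(wt, mut)
  i <- track_bin_index(wt, origins$chrom, origins$pos)
  delay_cn <- wt$value[i] - mut$value[i]
  tab <- data.frame(
    id = origins$id, chrom = origins$chrom, pos = origins$pos,
    cen_dist_kb = centromere_distance(layout, origins$chrom, origins$pos),
    delay_cn = delay_cn, delay_min = delay_cn * S_dur,
    stringsAsFactors = FALSE
  )
  drop <- is.na(delay_cn)
  if (any(drop)) {
    warning(sum(drop), " origin(s) dropped: profile missing at their bin")
    tab <- tab[!drop, , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(tab, S_dur = S_dur, n_dropped = sum(drop),
            class = c("origin_delay_table", "data.frame"))
}

#' Exponential-decay regression of delay (or enrichment ratio) vs distance
#'
#' Least-squares fit of `y = a * exp(-d / lambda) + c` to a response
#' against centromere distance `d` (kb) — the regression family used for
#' delay-versus-distance and peak-ratio-versus-distance curves, encoding a
#' signal that is largest at the centromere and vanishes along the arms.
#' Initialization is `a = max(y)`, `lambda = 10` kb, `c = 0`
#' (Levenberg-Marquardt, deterministic given the data; a Nelder-Mead
#' fallback guards against singular Jacobians). A constant response returns
#' `a = 0` with zero residual immediately.
#'
#' @param d centromere distances in kb, or an `origin_delay_table`.
#' @param y responses (minutes, copy-number units or ratio excess). When
#'   `d` is an `origin_delay_table`, `y` defaults to its `delay_min`.
#' @param lambda_init initial decay length (kb).
#' @return a `decay_fit`: list with `a`, `lambda`, `c`, `rss`, `n`.
#' @export
delay_distance_regression <- function(d, y = NULL, lambda_init = 10) {
  if (inherits(d, "origin_delay_table")) {
    y <- y %||% d$delay_min
    d <- d$cen_dist_kb
  }
  ok <- !is.na(d) & !is.na(y)
  d <- d[ok]; y <- y[ok]
  if (length(d) < 4 || length(unique(d)) < 2) {
    stop_param("need >= 4 points spanning >= 2 distinct distances")
  }
  if (max(abs(y - mean(y))) < 1e-12) {
    return(new_decay_fit(0, lambda_init, mean(y), 0, length(y)))
  }
  start <- list(a = max(y), lambda = lambda_init, c = 0)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      y ~ a * exp(-d / lambda) + c, start = start,
      lower = c(-Inf, 1e-6, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    p <- coef(m)
    new_decay_fit(p[["a"]], p[["lambda"]], p[["c"]],
                  sum(residuals(m)^2), length(y))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(p) sum((y - (p[1] * exp(-d / exp(p[2])) + p[3]))^2)
    o <- stats::optim(c(start$a, log(start$lambda), start$c), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    fit <- new_decay_fit(o$par[1], exp(o$par[2]), o$par[3], o$value, length(y))
  }
  fit
}

new_decay_fit <- function(a, lambda, c, rss, n) {
  structure(list(a = a, lambda = lambda, c = c, rss = rss, n = n),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> y = %.4g * exp(-d / %.4g kb) + %.4g  (rss %.4g, n %d)\n",
              x$a, x$lambda, x$c, x$rss, x$n))
  invisible(x)
}

#' @rdname delay_distance_regression
#' @param fit a `decay_fit`.
#' @export
predict_decay <- function(fit, d) fit$a * exp(-d / fit$lambda) + fit$c

#' Fit the delayed-origin centromere-distance cutoff
#'
#' Grid search for the cutoff distance `D` and delay `delta` such that
#' delaying initiation of all wild-type origins within `D` kb of their
#' centromere by `delta` minutes recapitulates an observed mutant profile.
#' For each `(D, delta)` the candidate origin set is pushed through the
#' deterministic replication-kinetics model, converted to a copy-number
#' profile, put on the same scale as the observation (same normalization
#' convention and, optionally, the same smoothing window as the observed
#' pipeline) and scored by the sum of squared deviations over bins within
#' `window` kb of a centromere — arm bins carry no information about a
#' pericentromeric delay and would only dilute the objective. Ties are
#' broken toward the smallest `D`, then the smallest `delta`, so a mutant
#' profile identical to wild type yields `D = 0`.
#'
#' @param wt_origins wild-type [origin_set()].
#' @param layout the [genome_layout()].
#' @param mut_profile observed mutant `copy_number_profile` (normalized).
#' @param params [kinetics_params()] (deterministic mode is used).
#' @param D_grid candidate cutoffs in kb.
#' @param delta_grid candidate delays in minutes.
#' @param window half-width (kb) of the pericentromeric scoring window.
#' @param normalize put model profiles through the same \[1, 2\] quantile
#'   normalization as the sort-seq pipeline before scoring (recommended:
#'   sort-seq profiles are relative, so the comparison must be
#'   scale-invariant).
#' @param smooth_window optional smoothing window (kb) applied to model
#'   profiles, matching how `mut_profile` was smoothed; `NULL` for none.
#' @param anchor,probs,anchor_window normalization convention, as in
#'   [normalize_profile()].
#' @return a `delay_fit`: list with `cutoff_D_hat`, `delta_hat`, `flagged`
#'   (ids of origins within the fitted cutoff), `objective`, `grid` (full
#'   objective matrix, `D` by `delta`), `n_bins_scored`.
#' @export
fit_delay_cutoff <- function(wt_origins, layout, mut_profile, params,
                             D_grid = seq(0, 50, by = 2.5),
                             delta_grid = seq(0, 30, by = 2.5),
                             window = 100, normalize = TRUE,
                             smooth_window = NULL,
                             anchor = "quantile", probs = c(0.01, 0.99),
                             anchor_window = 15) {
  if (length(D_grid) == 0 || length(delta_grid) == 0) {
    stop_param("D_grid and delta_grid must be non-empty")
  }
  D_grid <- sort(D_grid); delta_grid <- sort(delta_grid)
  bw <- bin_width(mut_profile)
  ctr <- track_centers(mut_profile)
  v_bp <- kb2bp(params$v)

  # per-chromosome |x - x_i| / v matrices, reused for every grid point
  chrom_rows <- split(seq_len(nrow(mut_profile)), mut_profile$chrom)
  dmat <- list(); oidx <- list()
  for (ch in names(chrom_rows)) {
    rows <- chrom_rows[[ch]]
    oi <- which(wt_origins$chrom == ch)
    if (length(oi) == 0) stop_param("chromosome ", ch, " has no origins")
    dmat[[ch]] <- outer(ctr[rows], wt_origins$pos[oi],
                        function(x, p) abs(x - p) / v_bp)
    oidx[[ch]] <- oi
  }
  o_dist <- centromere_distance(layout, wt_origins$chrom, wt_origins$pos)
  cen_d <- centromere_distance(layout, mut_profile$chrom, ctr)
  score_mask <- cen_d <= window & !is.na(mut_profile$value)
  if (!any(score_mask)) stop_param("no scorable bins within the window")
  w_bins <- if (is.null(smooth_window)) NULL else odd_bins(smooth_window, bw)
  a_bins <- if (is.null(anchor_window)) 1L else odd_bins(anchor_window, bw)

  model_values <- function(t) {
    v <- rep(NA_real_, nrow(mut_profile))
    for (ch in names(chrom_rows)) {
      Tm <- dmat[[ch]] + rep(t[oidx[[ch]]], each = length(chrom_rows[[ch]]))
      v[chrom_rows[[ch]]] <- do.call(pmin, as.data.frame(Tm))
    }
    r <- pmin(2, pmax(1, 2 - v / params$S_dur))
    if (normalize) {
      ref <- if (a_bins > 1) smooth_values(r, mut_profile$chrom, a_bins) else r
      r <- normalize_values(r, anchor, probs, ref = ref)
    }
    if (!is.null(w_bins)) r <- smooth_values(r, mut_profile$chrom, w_bins)
    r
  }

  grid <- matrix(NA_real_, length(D_grid), length(delta_grid),
                 dimnames = list(D = D_grid, delta = delta_grid))
  best <- list(obj = Inf, D = D_grid[1], delta = delta_grid[1])
  for (i in seq_along(D_grid)) {
    delayed <- o_dist <= D_grid[i]
    for (j in seq_along(delta_grid)) {
      t <- wt_origins$t_mean + delta_grid[j] * delayed
      r <- model_values(t)
      obj <- sum((r[score_mask] - mut_profile$value[score_mask])^2)
      grid[i, j] <- obj
      if (obj < best$obj) {
        best <- list(obj = obj, D = D_grid[i], delta = delta_grid[j])
      }
    }
  }
  structure(list(cutoff_D_hat = best$D, delta_hat = best$delta,
                 flagged = wt_origins$id[o_dist <= best$D],
                 objective = best$obj, grid = grid,
                 n_bins_scored = sum(score_mask)),
            class = "delay_fit")
}

#' @export
print.delay_fit <- function(x, ...) {
  cat(sprintf(
    "<delay_fit> cutoff D = %.3g kb, delta = %.3g min; %d origin(s) flagged; objective %.4g over %d bins\n",
    x$cutoff_D_hat, x$delta_hat, length(x$flagged), x$objective,
    x$n_bins_scored))
  invisible(x)
}
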