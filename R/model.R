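#' Replication-kinetics parameters
#'
#' @param v fork velocity in kb/min (> 0).
#' @param S_dur S-phase duration in minutes (> 0).
#' @param mode `"deterministic"` (origins fire exactly at `t_mean`) or
#'   `"stochastic"` (per-cell firing times drawn from a normal truncated at
#'   0, incompetent origins skipped, per-bin mean over `n_cells` cells).
#' @param n_cells Monte-Carlo sample size for stochastic mode.
#' @export
kinetics_params <- function(v = 1.5, S_dur = 40,
                            mode = c("deterministic", "stochastic"),
                            n_cells = 500) {
  mode <- match.arg(mode)
  if (v <= 0 || S_dur <= 0 || n_cells < 1) {
    stop_param("require v > 0, S_dur > 0, n_cells >= 1")
  }
  structure(list(v = v, S_dur = S_dur, mode = mode, n_cells = n_cells),
            class = "kinetics_params")
}

# one truncated-normal draw per origin (truncation at 0)
rtrunc0 <- function(mu, sigma) {
  out <- mu
  s <- sigma > 0
  if (any(s)) {
    lo <- pnorm(0, mu[s], sigma[s])
    out[s] <- qnorm(lo + runif(sum(s)) * (1 - lo), mu[s], sigma[s])
  }
  out
}

# min-rule replication times at positions x (bp) for origins (pos bp, t min)
min_rule <- function(x, pos, t, v_bp) {
  T <- rep(Inf, length(x))
  for (i in seq_along(pos)) {
    T <- pmin(T, t[i] + abs(x - pos[i]) / v_bp)
  }
  T
}

#' Replication-time map from origin parameters
#'
#' Deterministic mode applies the min rule
#' `T(x) = min_i (t_i + |x - x_i| / v)`: a locus is replicated by the first
#' fork to arrive, forks travel at constant velocity `v` from every fired
#' origin, and chromosome ends simply absorb forks. Stochastic mode draws
#' each origin's firing time per cell from `Normal(t_mean, t_sigma)`
#' truncated at 0, skips origins that fail their competence Bernoulli trial,
#' applies the min rule per cell (a cell whose chromosome has no competent
#' origin replicates it at `S_dur`), and returns the per-bin mean over
#' `n_cells` cells.
#'
#' @param layout a [genome_layout()].
#' @param origins an [origin_set()].
#' @param params a [kinetics_params()].
#' @param bin_width output bin size in bp.
#' @param seed optional seed for stochastic mode.
#' @return a `timing_map` `bin_track` of replication times in minutes,
#'   evaluated at bin centers.
#' @export
replication_time <- function(layout, origins, params, bin_width = 1000,
                             seed = NULL) {
  stopifnot(inherits(params, "kinetics_params"))
  grid <- bin_track(layout, bin_width, subclass = "timing_map")
  v_bp <- kb2bp(params$v)
  T_all <- rep(NA_real_, nrow(grid))

  for (ch in layout$chrom) {
    rows <- which(grid$chrom == ch)
    x <- track_centers(grid)[rows]
    o <- origins[origins$chrom == ch, , drop = FALSE]
    if (nrow(o) == 0 && params$mode == "deterministic") {
      stop_param("chromosome ", ch, " has no origins")
    }
    if (params$mode == "deterministic") {
      T_all[rows] <- min_rule(x, o$pos, o$t_mean, v_bp)
    } else {
      if (!is.null(seed)) set.seed(seed + match(ch, layout$chrom))
      acc <- numeric(length(x))
      for (cell in seq_len(params$n_cells)) {
        fired <- runif(nrow(o)) <= o$competence
        if (!any(fired)) {
          acc <- acc + params$S_dur
        } else {
          t_cell <- rtrunc0(o$t_mean[fired], o$t_sigma[fired])
          acc <- acc + min_rule(x, o$pos[fired], t_cell, v_bp)
        }
      }
      T_all[rows] <- acc / params$n_cells
    }
  }
  grid$value <- T_all
  attr(grid, "params") <- params
  grid
}

#' Relative copy-number profile from a timing map
#'
#' In a pool of cells sampled uniformly across S phase, a locus replicated
#' at time `T` has been duplicated in a fraction `1 - T/S_dur` of cells, so
#' its relative copy number is `r(x) = 2 - T(x)/S_dur`, clipped to
#' \[1.0, 2.0\] — the scale on which sort-seq profiles are drawn (2.0 =
#' earliest, 1.0 = latest).
#'
#' @param timing a `timing_map` from [replication_time()] or
#'   [lattice_fork_oracle()].
#' @param params the [kinetics_params()] supplying `S_dur`.
#' @param label optional strain label.
#' @return a `copy_number_profile` `bin_track` with values in \[1, 2\].
#' @export
copy_number_profile <- function(timing, params, label = NULL) {
  r <- pmin(2, pmax(1, 2 - timing$value / params$S_dur))
  out <- track_like(timing, r, label = label, subclass = "copy_number_profile")
  attr(out, "S_dur") <- params$S_dur
  out
}

#' Brute-force lattice fork-propagation oracle
#'
#' Independent check on [replication_time()]: chromosomes are discretized
#' into sites `dx` bp apart and time is stepped in increments of `dt`
#' minutes. At each step, unfired origins whose firing time has passed seed
#' a pair of forks at their site; every fork accumulates `v * dt` of travel
#' and claims the next site each time its accumulated travel exceeds `dx`,
#' dying when it runs off the chromosome or into replicated territory. The
#' first-replication time of each site is recorded and read out at bin
#' centers. Requires the CFL-like condition `v * dt <= dx` so a fork never
#' skips a site within one step; agreement with the analytic min rule is
#' within `dt + dx/v`.
#'
#' Only deterministic firing (at `t_mean`) is simulated; with `t_sigma = 0`
#' and competence 1 this is also the stochastic model's limit.
#'
#' @inheritParams replication_time
#' @param dt time step in minutes.
#' @param dx site spacing in bp.
#' @return a `timing_map` `bin_track`.
#' @export
lattice_fork_oracle <- function(layout, origins, params, dt = 0.2, dx = 500,
                                bin_width = 1000) {
  v_bp <- kb2bp(params$v)
  if (v_bp * dt > dx) stop_param("CFL violated: need v * dt <= dx")
  grid <- bin_track(layout, bin_width, subclass = "timing_map")
  out <- rep(NA_real_, nrow(grid))

  for (ci in seq_len(nrow(layout))) {
    L <- layout$length[ci]
    sites <- seq(dx / 2, L, by = dx)
    ns <- length(sites)
    rep_time <- rep(NA_real_, ns)

    o <- origins[origins$chrom == layout$chrom[ci], , drop = FALSE]
    o_site <- pmin(ns, pmax(1L, round((o$pos - dx / 2) / dx) + 1L))
    o_t <- o$t_mean
    # keep earliest origin per site
    ord <- order(o_site, o_t)
    o_site <- o_site[ord]; o_t <- o_t[ord]
    first <- !duplicated(o_site)
    o_site <- o_site[first]; o_t <- o_t[first]
    unfired <- rep(TRUE, length(o_site))

    f_edge <- integer(0); f_dir <- integer(0); f_prog <- numeric(0)
    t <- 0
    max_t <- max(o_t) + L / v_bp + dt
    while (anyNA(rep_time) && t <= max_t) {
      fire <- which(unfired & o_t <= t)
      for (k in fire) {
        unfired[k] <- FALSE
        s <- o_site[k]
        if (is.na(rep_time[s])) {
          rep_time[s] <- t
          f_edge <- c(f_edge, s, s)
          f_dir <- c(f_dir, -1L, 1L)
          f_prog <- c(f_prog, 0, 0)
        }
      }
      if (length(f_edge)) {
        f_prog <- f_prog + v_bp * dt
        alive <- rep(TRUE, length(f_edge))
        for (k in seq_along(f_edge)) {
          while (f_prog[k] >= dx) {
            nxt <- f_edge[k] + f_dir[k]
            if (nxt < 1 || nxt > ns || !is.na(rep_time[nxt])) {
              alive[k] <- FALSE
              break
            }
            rep_time[nxt] <- t
            f_edge[k] <- nxt
            f_prog[k] <- f_prog[k] - dx
          }
        }
        f_edge <- f_edge[alive]; f_dir <- f_dir[alive]; f_prog <- f_prog[alive]
      }
      t <- t + dt
    }

    rows <- which(grid$chrom == layout$chrom[ci])
    ctr <- track_centers(grid)[rows]
    out[rows] <- rep_time[pmin(ns, pmax(1L, round((ctr - dx / 2) / dx) + 1L))]
  }
  grid$value <- out
  grid
}
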