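#' Wilson score interval for a binomial proportion
#'
#' @param x successes, `n` trials, `conf` confidence level.
#' @param n,conf see above.
#' @return `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

fisher_pairwise <- function(x, n, labels) {
  m <- length(x)
  p <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < j) {
      tab <- matrix(c(x[i], n[i] - x[i], x[j], n[j] - x[j]), 2)
      p[i, j] <- p[j, i] <- fisher.test(tab)$p.value
    }
  }
  p
}

#' Sister-chromatid cohesion: two-dot cell fractions
#'
#' For each condition, the fraction of scored cells showing two separated
#' sister-locus dots (i.e. lost cohesion), with a 95% Wilson score
#' interval, plus two-sided Fisher exact p-values for every pair of
#' conditions.
#'
#' @param counts data frame with columns `condition`, `two_dot`, `total`.
#' @param conf confidence level for the intervals.
#' @return list with `summary` (condition, two_dot, total, proportion,
#'   percent, ci_lower, ci_upper) and `fisher_p` (pairwise matrix).
#' @export
two_dot_fraction <- function(counts, conf = 0.95) {
  if (any(counts$total <= 0)) stop_param("totals must be positive")
  if (any(counts$two_dot < 0 | counts$two_dot > counts$total)) {
    stop_param("two_dot counts must lie in [0, total]")
  }
  ci <- t(mapply(wilson_ci, counts$two_dot, counts$total,
                 MoreArgs = list(conf = conf)))
  prop <- counts$two_dot / counts$total
  summary <- data.frame(condition = counts$condition,
                        two_dot = counts$two_dot, total = counts$total,
                        proportion = prop, percent = 100 * prop,
                        ci_lower = ci[, 1], ci_upper = ci[, 2],
                        stringsAsFactors = FALSE)
  list(summary = summary,
       fisher_p = fisher_pairwise(counts$two_dot, counts$total,
                                  counts$condition))
}

#' Chromosome-loss rates from half-sectored colony counts
#'
#' A colony half-sectored for the marker arose from a loss event at the
#' first division, so `half_sectored / total` estimates the per-division
#' loss rate. Pairwise two-sided Fisher exact tests compare strains. When
#' the roles `control`, `singles` (two single perturbations) and `double`
#' (their combination) are given, a synergy report is added: the double
#' perturbation is flagged synergistic when its excess rate over the
#' control exceeds the sum of the two single-perturbation excesses
#' (departure from additivity of excess rates).
#'
#' @param counts data frame with columns `strain`, `sectored`, `total`.
#' @param control,singles,double optional strain names assigning roles for
#'   the synergy report.
#' @return list with `summary` (strain, sectored, total, rate, ci),
#'   `fisher_p`, and (when roles are given) `synergy` (excess rates,
#'   expected additive rate, observed rate, `synergistic` flag).
#' @export
loss_rate <- function(counts, control = NULL, singles = NULL, double = NULL) {
  if (any(counts$total <= 0)) stop_param("totals must be positive")
  if (any(counts$sectored < 0 | counts$sectored > counts$total)) {
    stop_param("sectored counts must lie in [0, total]")
  }
  rate <- counts$sectored / counts$total
  ci <- t(mapply(wilson_ci, counts$sectored, counts$total))
  summary <- data.frame(strain = counts$strain, sectored = counts$sectored,
                        total = counts$total, rate = rate,
                        ci_lower = ci[, 1], ci_upper = ci[, 2],
                        stringsAsFactors = FALSE)
  out <- list(summary = summary,
              fisher_p = fisher_pairwise(counts$sectored, counts$total,
                                         counts$strain))
  if (!is.null(control) && length(singles) == 2 && !is.null(double)) {
    r <- setNames(rate, counts$strain)
    roles <- c(control, singles, double)
    if (!all(roles %in% counts$strain)) stop_param("unknown strain in roles")
    excess <- r[c(singles, double)] - r[control]
    expected <- r[control] + sum(pmax(0, excess[singles]))
    out$synergy <- list(
      control_rate = unname(r[control]),
      single_excess = unname(excess[singles]),
      double_rate = unname(r[double]),
      expected_additive_rate = unname(expected),
      synergistic = unname(r[double] > expected)
    )
  }
  out
}
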