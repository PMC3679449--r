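# small fixtures shared across tests; everything is built in code

default_kin <- function(...) kinetics_params(...)

# one 200-kb chromosome, centromere mid, origins as given
one_chrom <- function(len = 2e5, cen = len / 2) {
  genome_layout("chrA", len, cen)
}

# the package-default synthetic genome plus its deterministic profiles
demo_pair <- function(spec = mutant_spec()) {
  g <- make_genome()
  k <- default_kin()
  wt <- copy_number_profile(replication_time(g$layout, g$origins, k), k,
                            label = "wt")
  mo <- apply_mutant(g$origins, g$layout, spec)
  mut <- copy_number_profile(replication_time(g$layout, mo, k), k,
                             label = "mut")
  list(g = g, k = k, wt = wt, mut = mut, mut_origins = mo)
}

# independent two-sided Fisher oracle: full hypergeometric enumeration
fisher_enumerate <- function(x1, n1, x2, n2) {
  m <- x1 + x2
  support <- max(0, m - n2):min(m, n1)
  probs <- stats::dhyper(support, n1, n2, m)
  p_obs <- stats::dhyper(x1, n1, n2, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
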