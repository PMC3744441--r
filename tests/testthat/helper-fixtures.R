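# shared fixtures: designs, hyperparameters, small gene tables, and the
# stratified Monte Carlo draws used by integration oracles

asd_design <- function() study_design(n_trios = 932, n_cases = 935,
                                      n_controls = 870)

default_hyper <- function(...) hyperparams(...)

# small two-category gene table with a planted strong gene
toy_table <- function() {
  rbind(
    data.frame(gene = c("gA", "gB", "gC"), category = "LoF",
               mu = c(2e-6, 1e-6, 5e-7), dn = c(2L, 0L, 0L),
               trans = c(1L, 2L, 0L), nontrans = c(0L, 1L, 1L),
               case = c(4L, 0L, 1L), control = c(0L, 0L, 2L)),
    data.frame(gene = c("gA", "gB", "gC"), category = "Mis3",
               mu = c(8e-6, 4e-6, 2e-6), dn = c(1L, 0L, 0L),
               trans = c(0L, 1L, 2L), nontrans = c(1L, 1L, 2L),
               case = c(2L, 1L, 0L), control = c(0L, 1L, 1L)))
}

# stratified inverse-CDF Gamma draws: n strata, one uniform per stratum;
# Monte Carlo (random within strata) but with ~1/n integration error
strat_rgamma <- function(n, shape, rate) {
  stats::qgamma((seq_len(n) - stats::runif(n)) / n, shape, rate = rate)
}

# brute-force oracle for the joint per-gene marginal under H1: quadrature
# over gamma via stats::integrate of [Poisson de novo] x [closed-form
# conjugate case-control given gamma], independent of the package's
# Gauss-Legendre kernel
oracle_log_marg_h1 <- function(x_dn, x1, x0, a, e1, e0, h) {
  s <- h$gamma_mean * h$beta
  f <- function(g)
    stats::dpois(x_dn, a * g) *
      exp(lgamma(h$rho1 + x1 + x0) - lgamma(h$rho1) -
            lgamma(x1 + 1) - lgamma(x0 + 1) +
            (if (x0 > 0) x0 * log(e0) else 0) +
            (if (x1 > 0) x1 * log(e1 * g) else 0) +
            h$rho1 * log(h$nu1) -
            (h$rho1 + x1 + x0) * log(h$nu1 + e0 + e1 * g)) *
      stats::dgamma(g, s, rate = h$beta)
  lo <- stats::qgamma(1e-13, s, rate = h$beta)
  hi <- stats::qgamma(1 - 1e-13, s, rate = h$beta)
  log(stats::integrate(f, lo, hi, rel.tol = 1e-10)$value)
}
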