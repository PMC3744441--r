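# Evaluation experiments: per-gene power at fixed type-I error, genome-wide
# discoveries at a controlled false-discovery proportion, the analytic
# multiplicity-test study, and prior/mutation-rate sensitivity scans.

# simulate n_reps replicate genes at fixed (gamma, mu) and either fixed q
# or q drawn per replicate (single category)
.replicate_counts <- function(params, design, n_reps, q = NULL) {
  if (is.null(q)) q <- params$q
  e1 <- 2 * (design$n_cases + design$n_trios)
  e0 <- 2 * (design$n_controls + design$n_trios)
  data.frame(
    dn = stats::rpois(n_reps, 2 * design$n_trios * params$mu * params$gamma),
    x1 = stats::rpois(n_reps, e1 * q * params$gamma),
    x0 = stats::rpois(n_reps, e0 * q))
}

#' Per-gene power of the competing tests
#'
#' Monte Carlo power of one test at significance level `alpha` for a gene
#' with fixed true parameters: `n_reps` replicate genes are simulated from
#' the count model and the fraction with p <= alpha reported, with its
#' binomial Monte Carlo error. The Bayes test's threshold is derived from
#' its own null pool (supplied, or generated here with `pool_size`
#' replicates at the same mutation rate).
#'
#' @param test One of `"tada"`, `"meta"`, `"denovo"`.
#' @param params A [gene_params()]: the gene's true gamma, q, mu.
#' @param design A [study_design()].
#' @param alpha Type-I error level.
#' @param n_reps Number of simulated replicate genes (>= 1000).
#' @param seed RNG seed.
#' @param hyper [hyperparams()] used by the Bayes test (fixed, independent
#'   of the generating parameters).
#' @param null_pool Optional pre-computed null pool of log10 Bayes factors.
#' @param pool_size Null pool size when `null_pool` is NULL.
#' @param q_from_prior Draw each replicate's allele frequency from the null
#'   frequency prior instead of fixing it at `params$q`. With `gamma = 1`
#'   this simulates the model's composite null exactly, which is the
#'   setting where the Bayes test's type-I error matches `alpha` (a fixed
#'   `q` conditions on information the marginal test does not have).
#' @param n_nodes Quadrature size.
#' @return Data frame: test, power, mc_error, alpha, n_reps.
#' @export
per_gene_power <- function(test = c("tada", "meta", "denovo"), params,
                           design, alpha = 0.001, n_reps = 10000, seed = 1,
                           hyper = hyperparams(), null_pool = NULL,
                           pool_size = 2e5, q_from_prior = FALSE,
                           n_nodes = 32) {
  test <- match.arg(test)
  if (n_reps < 1000) stop("'n_reps' must be at least 1000")
  e1 <- 2 * (design$n_cases + design$n_trios)
  e0 <- 2 * (design$n_controls + design$n_trios)
  a <- 2 * design$n_trios * params$mu
  .with_preserved_rng({
    set.seed(seed)
    q_rep <- if (q_from_prior)
      stats::rgamma(n_reps, hyper$rho0, rate = hyper$nu0) else NULL
    d <- .replicate_counts(params, design, n_reps, q = q_rep)
    p <- switch(test,
      denovo = denovo_test_pvalue(d$dn, params$mu, design),
      meta = {
        p_dn <- denovo_test_pvalue(d$dn, params$mu, design)
        p_cc <- transmission_cc_pvalue(d$x1, d$x0, e1, e0)
        stats::pchisq(-2 * (log(pmax(p_dn, .Machine$double.xmin)) +
                              log(pmax(p_cc, .Machine$double.xmin))),
                      df = 4, lower.tail = FALSE)
      },
      tada = {
        if (is.null(null_pool)) {
          tab1 <- data.frame(gene = "g", category = "LoF", mu = params$mu,
                             dn = 0L, trans = 0L, nontrans = 0L,
                             case = 0L, control = 0L)
          null_pool <- null_bf_pool(tab1, design, hyper, B = pool_size,
                                    seed = seed + 1, n_nodes = n_nodes)
        }
        mm <- .category_log_marginals(d$dn, d$x1, d$x0,
                                      a = rep(a, n_reps), e1 = e1, e0 = e0,
                                      hyper = hyper, joint = TRUE,
                                      n_nodes = n_nodes)
        empirical_pvalue((mm$logP1 - mm$logP0) / log(10), null_pool)
      })
    pow <- mean(p <= alpha)
    data.frame(test = test, power = pow,
               mc_error = sqrt(pow * (1 - pow) / n_reps),
               alpha = alpha, n_reps = n_reps, stringsAsFactors = FALSE)
  })
}

# largest significance cutoff whose realized false-discovery proportion is
# within the target, using the simulation truth (oracle calibration);
# returns the number of true discoveries at that cutoff
.oracle_discoveries <- function(stat, is_risk, fdr_target,
                                decreasing = TRUE) {
  ord <- order(stat, decreasing = decreasing)
  fdp <- cumsum(!is_risk[ord]) / seq_along(ord)
  ok <- which(fdp <= fdr_target)
  if (!length(ok)) return(c(n_disc = 0, true_disc = 0, fdp = 0))
  n <- max(ok)
  c(n_disc = n, true_disc = sum(is_risk[ord][seq_len(n)]), fdp = fdp[n])
}

#' Genome-wide discoveries at controlled false-discovery proportion
#'
#' Simulates a genome under `config`, runs the selected tests, and for each
#' chooses its significance threshold as the most liberal one whose
#' realized false-discovery proportion (known from the simulation truth)
#' stays within `fdr_target` -- the oracle calibration appropriate when
#' truth is available. The Bayes test ranks genes by Bayes factor; the
#' baselines rank by p-value.
#'
#' @param config A [sim_config()].
#' @param tests Subset of `c("tada", "meta", "denovo")`.
#' @param fdr_target Target false-discovery proportion.
#' @param seed RNG seed.
#' @param hyper [hyperparams()] for the Bayes test (held fixed across
#'   simulation settings).
#' @param n_nodes Quadrature size.
#' @return Data frame: test, n_disc, true_disc, fdp, seed.
#' @export
genomewide_experiment <- function(config,
                                  tests = c("tada", "meta", "denovo"),
                                  fdr_target = 0.1, seed = 1,
                                  hyper = hyperparams(), n_nodes = 32) {
  tests <- match.arg(tests, several.ok = TRUE)
  sim <- simulate_genome(config, seed = seed)
  tab <- sim$counts
  design <- config$design
  is_risk <- sim$truth$is_risk[match(unique(tab$gene), sim$truth$gene)]
  e1 <- 2 * (design$n_cases + design$n_trios)
  e0 <- 2 * (design$n_controls + design$n_trios)
  out <- lapply(tests, function(tst) {
    stat <- switch(tst,
      denovo = denovo_test_pvalue(tab$dn, tab$mu, design),
      meta = meta_test(tab, design, category = config$category)$p_meta,
      tada = bayes_factor_gene(tab, design, hyper, joint = TRUE,
                               n_nodes = n_nodes)$log10_bf_total)
    res <- .oracle_discoveries(stat, is_risk, fdr_target,
                               decreasing = (tst == "tada"))
    data.frame(test = tst, n_disc = res["n_disc"],
               true_disc = res["true_disc"], fdp = res["fdp"], seed = seed,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Analytic study of the multiplicity test
#'
#' Expected discoveries and false-discovery rate of the recurrence rule
#' ("call a gene at >= c de novo events") as a function of sample size,
#' computed analytically: each gene is a risk gene with probability `k/m`
#' with Gamma-distributed relative risk, otherwise null, and its
#' recurrence probability is a Poisson tail at rate `2*N*mu*gamma`.
#'
#' @param k Number of risk genes.
#' @param mu_by_gene Per-gene category mutation rates (length m).
#' @param gamma_mean,rr_shape Mean and shape of the relative-risk Gamma
#'   distribution.
#' @param n_grid Trio sample sizes to scan.
#' @param c_threshold Recurrence threshold (2 or 3).
#' @param n_nodes Quadrature size for the relative-risk expectation.
#' @return Data frame: n_trios, c_threshold, e_true, e_false, e_disc, fdr.
#' @export
multiplicity_study <- function(k, mu_by_gene, gamma_mean = 20, rr_shape = 1,
                               n_grid = c(500, 1000, 2000, 5000),
                               c_threshold = 2L, n_nodes = 64) {
  if (!c_threshold %in% 2:3) stop("'c_threshold' must be 2 or 3")
  m <- length(mu_by_gene)
  nd <- .gamma_prior_nodes(gamma_mean, rr_shape / gamma_mean, n = n_nodes)
  out <- lapply(n_grid, function(N) {
    a <- 2 * N * mu_by_gene
    p_null <- stats::ppois(c_threshold - 1, a, lower.tail = FALSE)
    p_risk <- drop(stats::ppois(c_threshold - 1, outer(a, nd$gamma),
                                lower.tail = FALSE) %*% exp(nd$logw))
    e_true <- (k / m) * sum(p_risk)
    e_false <- (1 - k / m) * sum(p_null)
    data.frame(n_trios = N, c_threshold = c_threshold, e_true = e_true,
               e_false = e_false, e_disc = e_true + e_false,
               fdr = if (e_true + e_false > 0) e_false / (e_true + e_false)
                     else 0)
  })
  do.call(rbind, out)
}

#' Sensitivity of a gene's p-value to mutation rate and prior risk
#'
#' Recomputes one gene's Bayes-test p-value across a grid of mutation-rate
#' scalings and prior mean relative risks. Rescaling one gene's mutation
#' rate leaves the genome-wide null reference essentially unchanged, so the
#' scan holds the pool fixed across `mu_factors` and the p-value moves
#' through the Bayes factor alone (non-decreasing in the rate: a larger
#' rate makes the observed de novo events less surprising under the null).
#' Changing the prior mean relative risk changes every Bayes factor,
#' observed and null alike, so the pool is rebuilt per `gamma_means` value
#' (same seed throughout) and the shifts largely cancel -- the p-value is
#' less sensitive to this prior than to the mutation rate.
#'
#' @param rec Gene count table for a single gene (one row per category).
#' @param design A [study_design()].
#' @param hyper A [hyperparams()] or per-category named list.
#' @param mu_factors Mutation-rate multipliers (within \[0.5, 2\]); a
#'   gene-level rate error scales every category's rate together, and the
#'   gene's null reference with it.
#' @param gamma_means Prior mean relative risks to scan for
#'   `gamma_category` (the loss-of-function prior in a standard analysis;
#'   other categories keep their priors).
#' @param gamma_category Category whose risk prior is scanned (defaults to
#'   the table's first category).
#' @param pool_tab Gene table from which the null pool is built (defaults
#'   to `rec`, i.e. the gene's own null; rates are scaled along with the
#'   gene's).
#' @param B Null pool size.
#' @param seed RNG seed for the null pool.
#' @param n_nodes Quadrature size.
#' @return Data frame: mu_factor, gamma_mean, log10_bf, p_value.
#' @export
sensitivity_analysis <- function(rec, design, hyper = hyperparams(),
                                 mu_factors = c(0.5, 1, 2),
                                 gamma_means = c(10, 15, 20),
                                 gamma_category = NULL,
                                 pool_tab = rec, B = 1e5, seed = 1,
                                 n_nodes = 64) {
  rec <- validate_gene_table(rec)
  if (length(unique(rec$gene)) != 1L)
    stop("'rec' must describe a single gene")
  if (any(mu_factors < 0.5 - 1e-12) || any(mu_factors > 2 + 1e-12))
    stop("'mu_factors' must lie within [0.5, 2]")
  hyper <- .as_hyper_list(hyper, unique(rec$category))
  if (is.null(gamma_category)) gamma_category <- rec$category[1]
  if (!gamma_category %in% rec$category)
    stop("'gamma_category' not present in 'rec'")
  res <- lapply(gamma_means, function(gm) {
    h <- hyper
    h[[gamma_category]]$gamma_mean <- gm
    do.call(rbind, lapply(mu_factors, function(f) {
      pt <- pool_tab
      pt$mu <- pt$mu * f
      pool <- null_bf_pool(pt, design, h, B = B, seed = seed,
                           n_nodes = n_nodes)
      r <- rec
      r$mu <- r$mu * f
      bf <- bayes_factor_gene(r, design, h,
                              n_nodes = n_nodes)$log10_bf_total
      data.frame(mu_factor = f, gamma_mean = gm, log10_bf = bf,
                 p_value = empirical_pvalue(bf, pool))
    }))
  })
  do.call(rbind, res)
}
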