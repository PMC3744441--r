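test_that("the mixture log-likelihood matches a per-gene re-summation", {
  set.seed(21)
  cfg <- sim_config(m = 300, k = 30, design = study_design(600, 500, 500),
                    mu = list(median = 1.5e-6, sdlog = 1))
  sim <- simulate_genome(cfg, seed = 3)
  des <- cfg$design
  h <- hyperparams(pi = 0.1)
  got <- mixture_loglik(sim$counts, des, h, "LoF")
  # independent route: scalar quadrature oracle per gene, summed by hand
  e1 <- 2 * (500 + 600); e0 <- 2 * (500 + 600)
  tab <- sim$counts
  ll <- 0
  for (i in seq_len(nrow(tab))) {
    a <- 2 * 600 * tab$mu[i]
    x1 <- tab$case[i] + tab$trans[i]; x0 <- tab$control[i] + tab$nontrans[i]
    p1 <- exp(oracle_log_marg_h1(tab$dn[i], x1, x0, a, e1, e0, h))
    p0 <- dpois(tab$dn[i], a) *
      marginal_casecontrol(x1, x0, des, h, "H0")
    ll <- ll + log(0.1 * p1 + 0.9 * p0)
  }
  expect_equal(got, ll, tolerance = 1e-6)
})

test_that("the mixture collapses to the null sum as pi vanishes", {
  cfg <- sim_config(m = 50, k = 0, design = study_design(500, 0, 0),
                    mu = 2e-6)
  sim <- simulate_genome(cfg, seed = 5)
  des <- cfg$design
  h <- hyperparams(pi = 1e-12)
  ll <- mixture_loglik(sim$counts, des, h, "LoF")
  mm <- tadar:::.category_log_marginals(
    sim$counts$dn, sim$counts$case + sim$counts$trans,
    sim$counts$control + sim$counts$nontrans,
    2 * 500 * sim$counts$mu, 1000, 1000, h)
  expect_equal(ll, sum(mm$logP0), tolerance = 1e-6)
})

test_that("duplicating every gene doubles the log-likelihood", {
  cfg <- sim_config(m = 80, k = 10, design = study_design(500, 300, 300),
                    mu = 2e-6)
  sim <- simulate_genome(cfg, seed = 6)
  des <- cfg$design
  h <- hyperparams(pi = 0.1)
  ll1 <- mixture_loglik(sim$counts, des, h, "LoF")
  tab2 <- sim$counts
  tab2$gene <- paste0(tab2$gene, "_dup")
  ll2 <- mixture_loglik(rbind(sim$counts, tab2), des, h, "LoF")
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
})

test_that("hyperparameter fitting recovers generating values at small scale", {
  # scaled-down recovery: the genome-scale version (18,000 genes, 5
  # replicates) runs in the acceptance suite
  cfg <- sim_config(m = 3000, k = 300,
                    design = study_design(1000, 1000, 1000))
  sim <- simulate_genome(cfg, seed = 13)
  fit <- fit_hyperparameters(sim$counts, cfg$design, pi = 0.1,
                             category = "LoF", n_starts = 3, seed = 2)
  expect_true(fit$converged)
  h <- fit$hyper
  expect_gt(h$gamma_mean, 20 * 0.5)
  expect_lt(h$gamma_mean, 20 * 2)
  expect_lt(abs(h$rho0 / h$nu0 - 1e-3) / 1e-3, 0.25)
  expect_lt(abs(h$rho1 / h$nu1 - 5e-5) / 5e-5, 0.6)
  # the fitted maximum dominates the truth's likelihood (up to tolerance)
  truth_ll <- mixture_loglik(sim$counts, cfg$design,
                             hyperparams(gamma_mean = 20, beta = 0.05,
                                         rho1 = 1, nu1 = 2e4, rho0 = 1,
                                         nu0 = 1e3, pi = 0.1), "LoF")
  expect_gte(fit$loglik, truth_ll - 1e-3)
})

test_that("a null-only genome drives the risk prior toward no signal", {
  cfg <- sim_config(m = 2000, k = 0, design = study_design(1000, 1000, 1000))
  sim <- simulate_genome(cfg, seed = 17)
  fit <- fit_hyperparameters(sim$counts, cfg$design, pi = 0.056,
                             category = "LoF", n_starts = 3, seed = 4)
  # the null frequency prior is still recovered
  expect_lt(abs(fit$hyper$rho0 / fit$hyper$nu0 - 1e-3) / 1e-3, 0.2)
})

test_that("the optimum is stable across start jitter seeds", {
  cfg <- sim_config(m = 800, k = 80, design = study_design(800, 500, 500),
                    mu = 2e-6)
  sim <- simulate_genome(cfg, seed = 19)
  f1 <- fit_hyperparameters(sim$counts, cfg$design, pi = 0.1,
                            category = "LoF", n_starts = 2, seed = 1)
  f2 <- fit_hyperparameters(sim$counts, cfg$design, pi = 0.1,
                            category = "LoF", n_starts = 2, seed = 99)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
})

test_that("data simulated from the fitted model reproduce the count histogram", {
  cfg <- sim_config(m = 2000, k = 200, design = study_design(800, 800, 800))
  sim <- simulate_genome(cfg, seed = 23)
  fit <- fit_hyperparameters(sim$counts, cfg$design, pi = 0.1,
                             category = "LoF", n_starts = 2, seed = 3)
  h <- fit$hyper
  # pseudo-control marginal is negative binomial under either model (the
  # relative risk does not enter the control arm), mixed with weight pi
  e0 <- 2 * (800 + 800)
  x0_grid <- 0:14
  pmf <- 0.1 * dnbinom(x0_grid, size = h$rho1, prob = h$nu1 / (h$nu1 + e0)) +
    0.9 * dnbinom(x0_grid, size = h$rho0, prob = h$nu0 / (h$nu0 + e0))
  probs <- c(pmf, 1 - sum(pmf))
  x0_obs <- sim$counts$control + sim$counts$nontrans
  obs <- c(tabulate(factor(pmin(x0_obs, 15), levels = 0:15)))
  keep <- probs * length(x0_obs) >= 5  # merge sparse tail bins
  if (any(!keep)) {
    obs_k <- c(obs[keep], sum(obs[!keep]))
    probs_k <- c(probs[keep], sum(probs[!keep]))
  } else {
    obs_k <- obs
    probs_k <- probs
  }
  gof <- suppressWarnings(chisq.test(obs_k, p = probs_k))
  expect_gt(gof$p.value, 0.01)
})
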