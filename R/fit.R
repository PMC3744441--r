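# Empirical-Bayes estimation of the prior hyperparameters: the mixture
# marginal likelihood over all genes is maximized per mutation category,
# with the risk-gene fraction pi held fixed.

#' Mixture marginal log-likelihood of a gene table
#'
#' Sum over genes of `log(pi * P(data | H1) + (1 - pi) * P(data | H0))` for
#' one mutation category, the objective maximized by [fit_hyperparameters()].
#'
#' @param tab Gene count table.
#' @param design A [study_design()].
#' @param hyper A [hyperparams()] carrying the `pi` being used.
#' @param category Which category's rows enter the sum.
#' @param joint Share the relative-risk integral across evidence streams.
#' @param n_nodes Quadrature size.
#' @return The log-likelihood (a single number).
#' @export
mixture_loglik <- function(tab, design, hyper, category = "LoF",
                           joint = TRUE, n_nodes = 32) {
  tab <- validate_gene_table(tab)
  i <- which(tab$category == category)
  if (length(i) < 2L) stop("need at least 2 genes in category ", category)
  mm <- .category_log_marginals(
    x_dn = tab$dn[i], x1 = tab$case[i] + tab$trans[i],
    x0 = tab$control[i] + tab$nontrans[i],
    a = 2 * design$n_trios * tab$mu[i],
    e1 = 2 * (design$n_cases + design$n_trios),
    e0 = 2 * (design$n_controls + design$n_trios),
    hyper = hyper, joint = joint, n_nodes = n_nodes)
  mx <- pmax(mm$logP0, mm$logP1)
  terms <- mx + log(hyper$pi * exp(mm$logP1 - mx) +
                      (1 - hyper$pi) * exp(mm$logP0 - mx))
  if (any(!is.finite(terms)))
    stop("non-finite marginal likelihood for gene(s): ",
         paste(utils::head(tab$gene[i][!is.finite(terms)], 5), collapse = ", "))
  sum(terms)
}

# box bounds for the optimizer, on the natural scale:
# (gamma_mean, beta, q1 prior mean, rho1, q0 prior mean, rho0)
.fit_lower <- c(1.1, 1e-3, 1e-7, 1e-3, 1e-7, 1e-3)
.fit_upper <- c(500, 1e3, 0.05, 1e3, 0.05, 1e3)

.theta_to_hyper <- function(theta, pi, w) {
  v <- exp(theta)
  hyperparams(gamma_mean = v[1], beta = v[2],
              rho1 = v[4], nu1 = v[4] / v[3],
              rho0 = v[6], nu0 = v[6] / v[5],
              pi = pi, w = w)
}

#' Fit prior hyperparameters by maximum marginal likelihood
#'
#' Maximizes [mixture_loglik()] over the six free hyperparameters
#' (gamma_mean, beta, and the shape and mean of the two allele-frequency
#' priors), holding `pi` fixed. The search is on log-parameters within box
#' bounds (gamma_mean in \[1.1, 500\], beta in \[1e-3, 1e3\], q-prior means
#' in \[1e-7, 0.05\]), using several short Nelder-Mead explorations from
#' jittered starts followed by an L-BFGS-B polish of the best; the
#' likelihood is smooth but can be flat in beta, which the multi-start
#' guards against.
#'
#' @param tab Gene count table.
#' @param design A [study_design()].
#' @param pi Fixed prior fraction of risk genes (default 1000/18000).
#' @param category Mutation category to fit.
#' @param w Damaging-probability weight stored in the fitted object
#'   (not optimized).
#' @param n_starts Number of jittered exploratory starts.
#' @param n_nodes Quadrature size used during fitting.
#' @param seed Seed for the start jitter.
#' @param joint Share the relative-risk integral across streams.
#' @param start Optional [hyperparams()] supplying the first start.
#' @param maxit_explore,maxit_polish Iteration caps for the two phases.
#' @return A list of class `tada_fit`: `hyper` (fitted [hyperparams()]),
#'   `loglik`, `converged`, `n_starts`, and a `trace` data frame with one
#'   row per start.
#' @export
fit_hyperparameters <- function(tab, design, pi = 1000 / 18000,
                                category = "LoF", w = 1,
                                n_starts = 5, n_nodes = 32, seed = 1,
                                joint = TRUE, start = NULL,
                                maxit_explore = 100, maxit_polish = 200) {
  tab <- validate_gene_table(tab)
  i <- which(tab$category == category)
  if (length(i) < 2L) stop("need at least 2 genes in category ", category)
  lower <- log(.fit_lower); upper <- log(.fit_upper)

  # hoist everything invariant out of the objective: count vectors,
  # exposures, and the (x1, x0) pattern index used by the quadrature kernel
  x_dn <- tab$dn[i]
  x1 <- tab$case[i] + tab$trans[i]
  x0 <- tab$control[i] + tab$nontrans[i]
  a <- 2 * design$n_trios * tab$mu[i]
  e1c <- 2 * (design$n_cases + design$n_trios)
  e0c <- 2 * (design$n_controls + design$n_trios)

  negloglik <- function(theta) {
    theta <- pmin(pmax(theta, lower), upper)
    h <- try(.theta_to_hyper(theta, pi, w), silent = TRUE)
    if (inherits(h, "try-error")) return(1e10)
    mm <- try(.category_log_marginals(x_dn, x1, x0, a, e1c, e0c, h,
                                      joint = joint, n_nodes = n_nodes),
              silent = TRUE)
    if (inherits(mm, "try-error")) return(1e10)
    mx <- pmax(mm$logP0, mm$logP1)
    ll <- sum(mx + log(pi * exp(mm$logP1 - mx) +
                         (1 - pi) * exp(mm$logP0 - mx)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # data-driven default start: pooled carrier frequency anchors the null
  # q prior; the risk prior starts an order of magnitude rarer
  e1 <- 2 * (design$n_cases + design$n_trios)
  e0 <- 2 * (design$n_controls + design$n_trios)
  pooled_q <- if (e1 + e0 > 0)
    max(sum(tab$case[i] + tab$trans[i] + tab$control[i] + tab$nontrans[i]) /
          ((e1 + e0) * length(i)), 1e-6) else 1e-3
  base_start <- if (is.null(start))
    log(c(15, 1, max(pooled_q / 10, 2e-7), 1, pooled_q, 1))
  else with(start, log(c(gamma_mean, beta, rho1 / nu1, rho1, rho0 / nu0, rho0)))
  base_start <- pmin(pmax(base_start, lower), upper)

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(k) {
    if (k == 1) base_start
    else pmin(pmax(base_start + stats::runif(6, -1, 1), lower), upper)
  })

  explore <- lapply(starts, function(th)
    stats::optim(th, negloglik, method = "Nelder-Mead",
                 control = list(maxit = maxit_explore)))
  vals <- vapply(explore, `[[`, numeric(1), "value")
  best <- explore[[which.min(vals)]]
  polish <- stats::optim(pmin(pmax(best$par, lower), upper), negloglik,
                         method = "L-BFGS-B", lower = lower, upper = upper,
                         control = list(maxit = maxit_polish, factr = 1e7))
  if (polish$value > best$value) polish <- best
  if (min(vals) >= 1e10 && polish$value >= 1e10)
    stop("all optimizer starts failed; trace: ",
         paste(signif(vals, 4), collapse = ", "))

  structure(list(
    hyper = .theta_to_hyper(polish$par, pi, w),
    loglik = -polish$value,
    converged = isTRUE(polish$convergence == 0),
    n_starts = n_starts,
    trace = data.frame(start = seq_len(n_starts), loglik = -vals)),
    class = "tada_fit")
}

#' @export
print.tada_fit <- function(x, ...) {
  cat(sprintf("Empirical-Bayes fit: loglik = %.3f (%s, %d starts)\n",
              x$loglik, if (x$converged) "converged" else "not converged",
              x$n_starts))
  print(x$hyper)
  invisible(x)
}
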