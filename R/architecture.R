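# Genetic-architecture estimation from de novo data: the enrichment
# identity linking the number of risk genes and the mean relative risk, the
# expected multi-hit-gene curve and its inversion, and hierarchical-Bayes
# refinement of the risk-gene count.

#' Number of risk genes implied by de novo enrichment
#'
#' If de novo damaging events are `lambda_enrich`-fold enriched in probands
#' relative to unaffected siblings, and risk genes carry mean relative risk
#' `gamma_mean`, then (to first order, treating mutation rates as
#' exchangeable across genes) `k = m * (lambda - 1) / (gamma_mean - 1)`:
#' larger per-gene effects require fewer genes to produce the same overall
#' enrichment.
#'
#' @param m Total number of genes (e.g. 18000).
#' @param lambda_enrich Proband/sibling fold enrichment (>= 1).
#' @param gamma_mean Mean relative risk across risk genes (> 1).
#' @return Implied number of risk genes `k`.
#' @examples
#' enrichment_to_k(18000, 2, 19)  # 1000
#' @export
enrichment_to_k <- function(m, lambda_enrich, gamma_mean) {
  if (gamma_mean <= 1) stop("'gamma_mean' must exceed 1")
  if (lambda_enrich < 1) stop("'lambda_enrich' must be at least 1")
  m * (lambda_enrich - 1) / (gamma_mean - 1)
}

#' Mean relative risk implied by de novo enrichment
#'
#' Inverts the curve of [enrichment_to_k()] for `gamma_mean` at a given
#' number of risk genes `k`, by root finding on the identity.
#'
#' @inheritParams enrichment_to_k
#' @param k Number of risk genes (0 < k <= m).
#' @return The mean relative risk on the curve.
#' @examples
#' enrichment_to_gamma(18000, 2, 1000)  # 19
#' @export
enrichment_to_gamma <- function(m, lambda_enrich, k) {
  if (k <= 0 || k > m) stop("'k' must lie in (0, m]")
  if (lambda_enrich <= 1) return(Inf)
  stats::uniroot(function(g) enrichment_to_k(m, lambda_enrich, g) - k,
                 lower = 1 + 1e-9, upper = 1e9, tol = 1e-10)$root
}

#' Expected number of multi-hit genes
#'
#' Expected count of genes with at least 2 de novo events in `n_trios`
#' trios, when `k` of the genes are risk genes with relative risks drawn
#' from a Gamma distribution with mean `gamma_mean` and shape `rr_shape`
#' (shape 1, i.e. unit coefficient of variation, by default). Each gene's
#' de novo count is Poisson with rate `2 * n_trios * mu * gamma`; the
#' relative-risk expectation is taken by quadrature, or by Monte Carlo when
#' `n_mc` is given (deterministic under `seed`). Heterogeneity in `mu` and
#' `gamma` raises the expectation relative to the equal-rate approximation
#' (tail probabilities are convex in the rate), so ignoring it
#' underestimates the number of risk genes consistent with an observed
#' multi-hit count.
#'
#' @param k Number of risk genes.
#' @param mu_by_gene Per-gene category mutation rates (length m).
#' @param n_trios Number of trios.
#' @param gamma_mean Mean relative risk of risk genes.
#' @param rr_shape Shape of the Gamma relative-risk distribution
#'   (shape = 1/CV^2).
#' @param n_mc If non-NULL, number of Monte Carlo relative-risk draws.
#' @param seed Seed for the Monte Carlo path.
#' @param n_nodes Quadrature size for the relative-risk expectation.
#' @return Expected number of multi-hit genes.
#' @export
expected_multihit <- function(k, mu_by_gene, n_trios, gamma_mean = 20,
                              rr_shape = 1, n_mc = NULL, seed = 1,
                              n_nodes = 64) {
  m <- length(mu_by_gene)
  if (k > m) stop("'k' cannot exceed the number of genes")
  if (any(mu_by_gene <= 0)) stop("mutation rates must be positive")
  a <- 2 * n_trios * mu_by_gene
  p_null <- stats::ppois(1, a, lower.tail = FALSE)
  if (k == 0) return(sum(p_null))
  p2 <- function(gam) stats::ppois(1, outer(a, gam), lower.tail = FALSE)
  if (is.null(n_mc)) {
    nd <- .gamma_prior_nodes(gamma_mean, rr_shape / gamma_mean, n = n_nodes)
    p_risk <- drop(p2(nd$gamma) %*% exp(nd$logw))
  } else {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    gam <- stats::rgamma(n_mc, rr_shape, rate = rr_shape / gamma_mean)
    p_risk <- rowMeans(p2(gam))
  }
  (k / m) * sum(p_risk) + (1 - k / m) * sum(p_null)
}

# expected multi-hit count with gamma_mean tied to k through the
# enrichment identity at fixed fold enrichment
.multihit_curve <- function(k, mu_by_gene, n_trios, m, lambda_enrich,
                            rr_shape = 1, n_nodes = 64) {
  expected_multihit(k, mu_by_gene, n_trios,
                    gamma_mean = enrichment_to_gamma(m, lambda_enrich, k),
                    rr_shape = rr_shape, n_nodes = n_nodes)
}

#' Plausible range of the number of risk genes from multi-hit counts
#'
#' Inverts the expected-multi-hit curve -- with the mean relative risk tied
#' to `k` through the enrichment identity at fixed fold enrichment -- at the
#' endpoints of a plausibility band around the observed multi-hit count.
#' For moderate-to-large `k` the expectation decreases in `k` (more risk
#' genes at fixed enrichment means weaker per-gene effects, hence fewer
#' recurrences); at very small `k` the implied relative risks are so large
#' that recurrence saturates and the curve instead rises with `k`, so the
#' inversion is restricted to the decreasing branch beyond the curve's
#' maximum, located on a log-spaced grid before bisecting (tolerance: 1
#' gene). Monotonicity on the branch is verified numerically.
#'
#' @param band Numeric `(low, high)` band of multi-hit counts deemed
#'   consistent with the observation (e.g. `c(4, 6)` around an observed 5).
#' @param mu_by_gene Per-gene mutation rates.
#' @param n_trios Number of trios.
#' @param lambda_enrich Proband/sibling fold enrichment.
#' @param rr_shape Shape of the Gamma relative-risk distribution.
#' @param k_min,k_max Search range for k.
#' @return Named vector `c(k_low, k_high)` (k_low from the band's upper
#'   endpoint, since the curve is decreasing).
#' @export
k_interval <- function(band, mu_by_gene, n_trios, lambda_enrich = 2,
                       rr_shape = 1, k_min = 10,
                       k_max = length(mu_by_gene)) {
  if (length(band) != 2L || band[1] > band[2])
    stop("'band' must be an ordered (low, high) pair")
  m <- length(mu_by_gene)
  f <- function(k) .multihit_curve(k, mu_by_gene, n_trios, m, lambda_enrich,
                                   rr_shape)
  # locate the decreasing branch: coarse log grid, start past the argmax
  grid <- pmin(pmax(exp(seq(log(k_min), log(k_max), length.out = 25)),
                    k_min), k_max)
  fg <- vapply(grid, f, numeric(1))
  peak <- which.max(fg)
  if (peak == length(grid))
    stop("multi-hit curve has no decreasing branch on this range")
  k_min <- grid[peak]
  if (any(diff(fg[peak:length(grid)]) > 1e-9))
    stop("multi-hit curve is not decreasing beyond its maximum")
  f_lo <- fg[peak]; f_hi <- fg[length(fg)]
  if (band[2] > f_lo || band[1] < f_hi)
    stop(sprintf("band [%g, %g] outside curve range [%g, %g]",
                 band[1], band[2], f_hi, f_lo))
  invert <- function(target) {
    lo <- k_min; hi <- k_max
    while (hi - lo > 1) {
      mid <- (lo + hi) / 2
      if (f(mid) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  c(k_low = invert(band[2]), k_high = invert(band[1]))
}

#' Refine the number of risk genes with the hierarchical model
#'
#' Profiles the mixture marginal likelihood over a grid of candidate
#' risk-gene counts: for each `k` the prior fraction is set to `k/m`, the
#' hyperparameters are refit, and the maximized log-likelihood recorded; the
#' grid argmax is returned. Successive grid points warm-start from the
#' previous optimum (plus the default multi-start), since neighboring `k`
#' give nearby optima.
#'
#' @param tab Gene count table.
#' @param design A [study_design()].
#' @param k_grid Candidate numbers of risk genes (e.g. from [k_interval()]).
#' @param m Total number of genes behind the table.
#' @param category Mutation category to fit.
#' @param n_starts Starts per grid point (warm start counts as one).
#' @param ... Passed to [fit_hyperparameters()].
#' @return A list: `k_hat`, `profile` (data frame of k, loglik, converged),
#'   and `fit` (the winning `tada_fit`).
#' @export
refine_k_hb <- function(tab, design, k_grid, m, category = "LoF",
                        n_starts = 2, ...) {
  if (length(k_grid) < 1L) stop("'k_grid' must be nonempty")
  fits <- vector("list", length(k_grid))
  prev <- NULL
  for (j in seq_along(k_grid)) {
    fits[[j]] <- fit_hyperparameters(tab, design, pi = k_grid[j] / m,
                                     category = category,
                                     n_starts = n_starts, start = prev$hyper,
                                     ...)
    prev <- fits[[j]]
  }
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (any(!conv))
    warning("non-converged fits at k = ",
            paste(k_grid[!conv], collapse = ", "), " excluded")
  use <- if (any(conv)) conv else rep(TRUE, length(k_grid))
  best <- which(use)[which.max(ll[use])]
  list(k_hat = k_grid[best],
       profile = data.frame(k = k_grid, loglik = ll, converged = conv),
       fit = fits[[best]])
}

#' Enrichment of de novo events in probands relative to siblings
#'
#' Fold enrichment computed as the ratio of total proband de novo events to
#' sibling events, after rescaling the sibling total by `sibling_scale` to
#' account for unequal cohort sizes or capture (e.g. the ratio of silent
#' de novo counts).
#'
#' @param proband_total Total de novo events in probands.
#' @param sibling_total Total de novo events in unaffected siblings.
#' @param sibling_scale Multiplier applied to the sibling total.
#' @return The fold enrichment.
#' @export
fold_enrichment <- function(proband_total, sibling_total,
                            sibling_scale = 1) {
  if (sibling_total * sibling_scale <= 0)
    stop("scaled sibling total must be positive")
  proband_total / (sibling_total * sibling_scale)
}
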