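# Marginal likelihoods and Bayes factors of the hierarchical count model.
#
# All likelihoods are computed and carried in natural-log space; user-facing
# Bayes factors are reported as log10. The relative-risk integral under H1
# has no closed form once the case-control arm is included, and is done by
# Gauss-Legendre quadrature on log(gamma) over the central prior mass
# (the integrand is smooth and unimodal there).

# x * log(y) with the 0 * log(0) = 0 convention
.xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

# row-wise log-sum-exp of a matrix, -Inf-safe
.logsumexp_rows <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  out <- mx + log(rowSums(exp(M - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# Gauss-Legendre nodes on log(gamma) for the Gamma(gamma_mean*beta, beta)
# prior, covering all but `mass_tail` of the prior mass. Returns gamma at the
# nodes and log-weights absorbing the prior density and the log-scale
# Jacobian, so that  integral f(g) prior(g) dg  ~=  sum exp(logw) * f(gamma).
.gamma_prior_nodes <- function(gamma_mean, beta, n = 64, mass_tail = 1e-10) {
  s <- gamma_mean * beta
  lo <- max(stats::qgamma(mass_tail / 2, s, rate = beta), 1e-12)
  hi <- stats::qgamma(1 - mass_tail / 2, s, rate = beta)
  gl <- pracma::gaussLegendre(n, log(lo), log(hi))
  g <- exp(gl$x)
  list(gamma = g,
       logw = log(gl$w) + stats::dgamma(g, s, rate = beta, log = TRUE) + gl$x)
}

# log P(x_dn | model) for de novo counts; a = 2*N*mu. Vectorized over x, a.
# H1 integrates Pois(x | a*gamma) against the Gamma(gamma_mean*beta, beta)
# prior on gamma, which is available in closed form (a negative-binomial-type
# expression).
.log_marg_dn <- function(x, a, gamma_mean, beta, model = c("H1", "H0")) {
  model <- match.arg(model)
  if (model == "H0") return(stats::dpois(x, a, log = TRUE))
  s <- gamma_mean * beta
  lgamma(s + x) - lgamma(s) - lgamma(x + 1) +
    .xlogy(x, a / (a + beta)) + s * (log(beta) - log(a + beta))
}

# log P(x1, x0 | gamma, q-prior Gamma(rho, nu)): both arms share one q,
# integrated conjugately. gamma multiplies the pseudo-case exposure e1.
# Vectorized over x1, x0 (gamma scalar) or over gamma (x scalar).
.log_marg_cc_given_gamma <- function(x1, x0, e1, e0, rho, nu, gamma = 1) {
  n_ev <- x1 + x0
  E1 <- e1 * gamma
  lgamma(rho + n_ev) - lgamma(rho) - lgamma(x1 + 1) - lgamma(x0 + 1) +
    .xlogy(x0, e0) + .xlogy(x1, E1) +
    rho * log(nu) - (rho + n_ev) * log(nu + e0 + E1)
}

# Core vectorized marginals for one category. Given per-gene counts and
# de novo rate scale a = 2*N*mu, returns the per-gene log marginal
# likelihoods under H0 and H1 plus the per-stream pieces. The case-control
# part depends on genes only through (x1, x0), so it is evaluated on the
# unique count pairs and indexed back; the de novo part is a dense
# genes-by-nodes computation.
.category_log_marginals <- function(x_dn, x1, x0, a, e1, e0, hyper,
                                    joint = TRUE, n_nodes = 64) {
  m <- length(x_dn)
  nd <- .gamma_prior_nodes(hyper$gamma_mean, hyper$beta, n = n_nodes)
  g <- nd$gamma
  logw <- nd$logw

  logP0_dn <- stats::dpois(x_dn, a, log = TRUE)
  logP1_dn <- .log_marg_dn(x_dn, a, hyper$gamma_mean, hyper$beta, "H1")
  logP0_cc <- .log_marg_cc_given_gamma(x1, x0, e1, e0, hyper$rho0, hyper$nu0)

  # unique (x1, x0) pairs: U x J matrix of conditional cc log-likelihoods
  pair_id <- paste(x1, x0, sep = ":")
  u <- !duplicated(pair_id)
  ux1 <- x1[u]; ux0 <- x0[u]
  idx <- match(pair_id, pair_id[u])
  n_ev <- ux1 + ux0
  const_u <- lgamma(hyper$rho1 + n_ev) - lgamma(hyper$rho1) -
    lgamma(ux1 + 1) - lgamma(ux0 + 1) + .xlogy(ux0, e0) + .xlogy(ux1, e1) +
    hyper$rho1 * log(hyper$nu1)
  Ldenom <- log(hyper$nu1 + e0 + e1 * g)              # length J
  cc1_uj <- const_u + outer(ux1, log(g)) -
    outer(hyper$rho1 + n_ev, Ldenom) +
    if (e1 == 0) ifelse(ux1 > 0, -Inf, 0) else 0
  # (e1 == 0 with x1 > 0 is impossible data; .xlogy already gave 0 for the
  #  x1*log(e1) term, so patch the -Inf in explicitly)

  logP1_cc <- .logsumexp_rows(matrix(logw, nrow = sum(u), ncol = n_nodes,
                                     byrow = TRUE) + cc1_uj)[idx]

  if (joint) {
    # one shared gamma integral across the de novo and case-control streams
    dn_const <- .xlogy(x_dn, a) - lgamma(x_dn + 1)
    M <- outer(x_dn, log(g)) - outer(a, g) + cc1_uj[idx, , drop = FALSE]
    M <- M + rep(logw, each = m)
    logP1 <- .logsumexp_rows(M) + dn_const
  } else {
    logP1 <- logP1_dn + logP1_cc
  }
  list(logP0 = logP0_dn + logP0_cc, logP1 = logP1,
       logP0_dn = logP0_dn, logP1_dn = logP1_dn,
       logP0_cc = logP0_cc, logP1_cc = logP1_cc)
}

# mixture-of-experts shrinkage of a Bayes factor toward 1:
# BF_adj = w * BF + (1 - w), computed stably from log(BF)
.adjust_log_bf <- function(log_bf, w) {
  if (w >= 1) return(log_bf)
  m0 <- pmax(log_bf, 0)
  log(w * exp(log_bf - m0) + (1 - w) * exp(-m0)) + m0
}

.as_hyper_list <- function(hyper, categories) {
  if (inherits(hyper, "tada_hyper"))
    hyper <- stats::setNames(rep(list(hyper), length(categories)), categories)
  missing_h <- setdiff(categories, names(hyper))
  if (length(missing_h))
    stop("no hyperparameters supplied for category(s): ",
         paste(missing_h, collapse = ", "))
  hyper
}

#' Marginal likelihood of a de novo count
#'
#' Probability of observing `x` de novo events in a gene with category
#' mutation rate `mu` across `design$n_trios` trios. Under the null the
#' count is Poisson with rate `2*N*mu`; under the risk-gene model the
#' relative risk is integrated against its Gamma prior, giving a closed
#' negative-binomial-type form.
#'
#' @param x De novo count(s).
#' @param mu Category mutation rate(s) per chromosome per generation.
#' @param design A [study_design()].
#' @param hyper A [hyperparams()] object (used under `"H1"`).
#' @param model `"H0"` or `"H1"`.
#' @param log Return the log likelihood?
#' @return Likelihood value(s), vectorized over `x` and `mu`.
#' @export
marginal_denovo <- function(x, mu, design, hyper = hyperparams(),
                            model = c("H0", "H1"), log = FALSE) {
  model <- match.arg(model)
  a <- 2 * design$n_trios * mu
  out <- .log_marg_dn(x, a, hyper$gamma_mean, hyper$beta, model)
  if (log) out else exp(out)
}

#' Marginal likelihood of combined case-control counts
#'
#' Joint probability of the pseudo-case count `x1 = case + transmitted` and
#' pseudo-control count `x0 = control + nontransmitted`, integrating the
#' shared allele frequency q against its conjugate Gamma prior. Under H0
#' (gamma = 1) the result is closed form; under H1 the relative risk is
#' additionally integrated by adaptive quadrature (node count doubled until
#' the log-likelihood changes by less than `tol`).
#'
#' @param x1,x0 Pseudo-case and pseudo-control counts.
#' @param design A [study_design()].
#' @param hyper A [hyperparams()].
#' @param model `"H0"` or `"H1"`.
#' @param log Return the log likelihood?
#' @param n_nodes Starting quadrature size for the H1 integral.
#' @param tol Relative tolerance for the adaptive H1 integral.
#' @return Likelihood value(s).
#' @export
marginal_casecontrol <- function(x1, x0, design, hyper = hyperparams(),
                                 model = c("H0", "H1"), log = FALSE,
                                 n_nodes = 64, tol = 1e-6) {
  model <- match.arg(model)
  e1 <- 2 * (design$n_cases + design$n_trios)
  e0 <- 2 * (design$n_controls + design$n_trios)
  if (any(x1 > 0 & e1 == 0) || any(x0 > 0 & e0 == 0))
    stop("positive counts with zero exposure are impossible data")
  n_obs <- max(length(x1), length(x0))
  x1 <- rep_len(x1, n_obs)
  x0 <- rep_len(x0, n_obs)
  if (model == "H0") {
    out <- .log_marg_cc_given_gamma(x1, x0, e1, e0, hyper$rho0, hyper$nu0)
  } else {
    eval_at <- function(n) {
      nd <- .gamma_prior_nodes(hyper$gamma_mean, hyper$beta, n = n)
      vapply(seq_along(x1), function(i) {
        v <- nd$logw + .log_marg_cc_given_gamma(
          x1[i], x0[i], e1, e0, hyper$rho1, hyper$nu1, gamma = nd$gamma)
        mx <- max(v)
        if (!is.finite(mx)) -Inf else mx + log(sum(exp(v - mx)))
      }, numeric(1))
    }
    out <- eval_at(n_nodes)
    repeat {
      n_nodes <- 2L * n_nodes
      out2 <- eval_at(n_nodes)
      if (all(abs(out2 - out) <= tol * pmax(1, abs(out))) || n_nodes >= 2048) {
        if (n_nodes >= 2048 && any(abs(out2 - out) > tol * pmax(1, abs(out))))
          stop("gamma quadrature failed to converge; last change ",
               max(abs(out2 - out)))
        out <- out2
        break
      }
      out <- out2
    }
  }
  if (log) out else exp(out)
}

#' Per-category Bayes factors for a gene count table
#'
#' For every row (gene x category) of the table, computes the Bayes factor
#' contrasting the risk-gene model H1 against the null H0, split into the de
#' novo and case-control evidence streams. With `joint = TRUE` (default) the
#' two streams share a single relative-risk integral, as the model is
#' written; `joint = FALSE` multiplies independently integrated stream Bayes
#' factors, the cheaper factorized approximation.
#'
#' @param tab Gene count table (see [validate_gene_table()]).
#' @param design A [study_design()].
#' @param hyper A [hyperparams()] applied to every category, or a named list
#'   of one per category.
#' @param joint Share one relative-risk integral across streams?
#' @param n_nodes Quadrature size for the relative-risk integral.
#' @return `tab` with columns `log10_bf_dn`, `log10_bf_cc`, `log10_bf`
#'   (joint category BF) and `log10_bf_adj` (after shrinking by the
#'   category's damaging-probability weight `w`).
#' @export
category_bayes_factors <- function(tab, design, hyper = hyperparams(),
                                   joint = TRUE, n_nodes = 64) {
  tab <- validate_gene_table(tab)
  hyper <- .as_hyper_list(hyper, unique(tab$category))
  e1 <- 2 * (design$n_cases + design$n_trios)
  e0 <- 2 * (design$n_controls + design$n_trios)
  tab$log10_bf_dn <- tab$log10_bf_cc <- tab$log10_bf <-
    tab$log10_bf_adj <- NA_real_
  for (cat in unique(tab$category)) {
    i <- which(tab$category == cat)
    h <- hyper[[cat]]
    mm <- .category_log_marginals(
      x_dn = tab$dn[i], x1 = tab$case[i] + tab$trans[i],
      x0 = tab$control[i] + tab$nontrans[i],
      a = 2 * design$n_trios * tab$mu[i], e1 = e1, e0 = e0,
      hyper = h, joint = joint, n_nodes = n_nodes)
    lbf <- mm$logP1 - mm$logP0
    tab$log10_bf_dn[i] <- (mm$logP1_dn - mm$logP0_dn) / log(10)
    tab$log10_bf_cc[i] <- (mm$logP1_cc - mm$logP0_cc) / log(10)
    tab$log10_bf[i] <- lbf / log(10)
    tab$log10_bf_adj[i] <- .adjust_log_bf(lbf, h$w) / log(10)
  }
  tab
}

#' Total Bayes factor per gene
#'
#' Combines the per-category Bayes factors of [category_bayes_factors()]
#' into one total per gene: categories are treated as independent evidence,
#' so the total BF is the product of the per-category BFs, each first shrunk
#' toward 1 by its damaging-probability weight `w` (for a predicted-damaging
#' missense category, `BF_adj = w * BF + (1 - w)`, reflecting that only a
#' fraction `w` of such variants are truly damaging).
#'
#' @inheritParams category_bayes_factors
#' @return A data frame with one row per gene: per-category adjusted log10
#'   Bayes factors (columns `log10_bf.<category>`) and their sum
#'   `log10_bf_total`.
#' @export
bayes_factor_gene <- function(tab, design, hyper = hyperparams(),
                              joint = TRUE, n_nodes = 64) {
  bf <- category_bayes_factors(tab, design, hyper, joint = joint,
                               n_nodes = n_nodes)
  genes <- unique(bf$gene)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  total <- numeric(length(genes))
  for (cat in unique(bf$category)) {
    i <- match(genes, bf$gene[bf$category == cat])
    v <- bf$log10_bf_adj[bf$category == cat][i]
    absent <- is.na(v)
    if (any(absent))
      message(sum(absent), " gene(s) lack '", cat,
              "' data; their ", cat, " Bayes factor is set to 1")
    v[absent] <- 0  # no evidence from a missing category
    out[[paste0("log10_bf.", cat)]] <- v
    total <- total + v
  }
  out$log10_bf_total <- total
  out
}

#' Plug-in approximation to the gene Bayes factor
#'
#' A likelihood-ratio-style approximation in which the gene parameters are
#' replaced by Bayesian posterior-mean point estimates rather than
#' integrated out. Each estimate is a conjugate posterior mean -- a weighted
#' average of the count-based estimate x/exposure and the prior mean rho/nu
#' with weight nu/(nu + exposure) on the prior; under H1 the frequency and
#' relative-risk estimates condition on each other, so a few fixed-point
#' sweeps of the two conditional posterior means are taken (they converge
#' immediately at these count sizes). Cheap, and close to the exact Bayes
#' factor in rank for genes that carry data; for empty genes it is near 0
#' on the log scale while the exact Bayes factor reflects the prior-mean
#' difference of the two frequency priors.
#'
#' @inheritParams category_bayes_factors
#' @return `tab` with a `log10_bf_approx` column.
#' @export
approx_bayes_factor <- function(tab, design, hyper = hyperparams()) {
  tab <- validate_gene_table(tab)
  hyper <- .as_hyper_list(hyper, unique(tab$category))
  e1 <- 2 * (design$n_cases + design$n_trios)
  e0 <- 2 * (design$n_controls + design$n_trios)
  tab$log10_bf_approx <- NA_real_
  for (cat in unique(tab$category)) {
    i <- which(tab$category == cat)
    h <- hyper[[cat]]
    x_dn <- tab$dn[i]
    x1 <- tab$case[i] + tab$trans[i]
    x0 <- tab$control[i] + tab$nontrans[i]
    a <- 2 * design$n_trios * tab$mu[i]
    q0_hat <- (h$rho0 + x1 + x0) / (h$nu0 + e1 + e0)
    s <- h$gamma_mean * h$beta
    g_hat <- rep(h$gamma_mean, length(x_dn))
    for (sweep in 1:3) {
      q1_hat <- (h$rho1 + x1 + x0) / (h$nu1 + e1 * g_hat + e0)
      g_hat <- (s + x_dn + x1) / (h$beta + a + e1 * q1_hat)
    }
    l1 <- stats::dpois(x_dn, a * g_hat, log = TRUE) +
      stats::dpois(x1, e1 * q1_hat * g_hat, log = TRUE) +
      stats::dpois(x0, e0 * q1_hat, log = TRUE)
    l0 <- stats::dpois(x_dn, a, log = TRUE) +
      stats::dpois(x1, e1 * q0_hat, log = TRUE) +
      stats::dpois(x0, e0 * q0_hat, log = TRUE)
    tab$log10_bf_approx[i] <- (l1 - l0) / log(10)
  }
  tab
}
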