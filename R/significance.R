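# Null-simulation p-values for Bayes factors, Benjamini-Hochberg FDR, and a
# genomic-control inflation diagnostic.

#' Simulate a genome-wide null reference distribution of Bayes factors
#'
#' Draws `B` null genes: each replicate picks a gene uniformly from the
#' input table (inheriting its category mutation rates), draws an allele
#' frequency from the fitted null prior per category, generates counts from
#' the null Poisson rates, and computes the gene's total Bayes factor with
#' the same hyperparameters used for the observed data. The pooled sample is
#' the reference against which observed Bayes factors are ranked into
#' p-values; pooling across genes matches the genome-wide Q-Q usage (a
#' per-gene null can be had by passing a single-gene table).
#'
#' @param tab Gene count table (supplies the gene list and mutation rates).
#' @param design A [study_design()].
#' @param hyper A [hyperparams()] or named per-category list.
#' @param B Number of null replicates (default 1e6; fewer than 1e4 limits
#'   p-value resolution and triggers a warning).
#' @param seed RNG seed; equal seeds give identical pools.
#' @param denovo_only Restrict the Bayes factor to the de novo stream (the
#'   null for the de-novo-only test).
#' @param joint Share the relative-risk integral across streams.
#' @param n_nodes Quadrature size.
#' @param chunk_size Replicates processed per vectorized block.
#' @return Sorted numeric vector of null total log10 Bayes factors.
#' @export
null_bf_pool <- function(tab, design, hyper = hyperparams(), B = 1e6,
                         seed = 1, denovo_only = FALSE, joint = TRUE,
                         n_nodes = 64, chunk_size = 5e4) {
  tab <- validate_gene_table(tab)
  if (B < 1e4)
    warning("null pool of size ", B, " gives coarse p-value resolution")
  cats <- unique(tab$category)
  hyper <- .as_hyper_list(hyper, cats)
  e1 <- 2 * (design$n_cases + design$n_trios)
  e0 <- 2 * (design$n_controls + design$n_trios)
  genes <- unique(tab$gene)
  mu_mat <- sapply(cats, function(cat) {
    v <- tab$mu[tab$category == cat][match(genes, tab$gene[tab$category == cat])]
    ifelse(is.na(v), 0, v)  # gene missing a category contributes BF = 1
  })
  mu_mat <- matrix(mu_mat, nrow = length(genes),
                   dimnames = list(NULL, cats))

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  B <- as.integer(B)
  out <- numeric(B)
  done <- 0L
  while (done < B) {
    nb <- min(chunk_size, B - done)
    gi <- sample.int(length(genes), nb, replace = TRUE)
    total <- numeric(nb)
    for (cat in cats) {
      h <- hyper[[cat]]
      a <- 2 * design$n_trios * mu_mat[gi, cat]
      x_dn <- stats::rpois(nb, a)
      if (denovo_only) {
        x1 <- x0 <- integer(nb)
      } else {
        q <- stats::rgamma(nb, h$rho0, rate = h$nu0)
        x1 <- stats::rpois(nb, e1 * q)
        x0 <- stats::rpois(nb, e0 * q)
      }
      mm <- .category_log_marginals(x_dn, x1, x0, a, e1, e0, h,
                                    joint = joint, n_nodes = n_nodes)
      lbf <- if (denovo_only) mm$logP1_dn - mm$logP0_dn else mm$logP1 - mm$logP0
      absent <- mu_mat[gi, cat] == 0
      lbf[absent] <- 0
      total <- total + .adjust_log_bf(lbf, h$w)
    }
    out[(done + 1L):(done + nb)] <- total / log(10)
    done <- done + nb
  }
  sort(out)
}

#' Empirical p-value of an observed statistic against a null pool
#'
#' `p = (1 + #\{pool >= observed\}) / (1 + |pool|)`, with ties counted as
#' exceedances, so p is never 0 and is floored at `1/(1 + |pool|)`.
#'
#' @param log10_bf Observed statistic(s) (vectorized).
#' @param pool Null sample, sorted ascending (as returned by
#'   [null_bf_pool()]; unsorted input is sorted here).
#' @return p-value(s) in (0, 1\].
#' @export
empirical_pvalue <- function(log10_bf, pool) {
  if (is.unsorted(pool)) pool <- sort(pool)
  n <- length(pool)
  n_below <- findInterval(log10_bf, pool, left.open = TRUE)  # #{pool < obs}
  (1 + (n - n_below)) / (1 + n)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment via [stats::p.adjust()], with input
#' validation (p must lie in (0, 1\], no missing values).
#'
#' @param pvalues Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must be finite and in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Genomic-control inflation factor
#'
#' Maps p-values to 1-df chi-square quantiles and returns the ratio of their
#' median to the null median (`qchisq(0.5, 1)` = 0.4549...). Lambda near 1
#' indicates no systematic inflation, e.g. from population stratification.
#'
#' @param pvalues Numeric p-values; values of 0 are clamped to `p_floor`
#'   with a warning.
#' @param p_floor Replacement for p = 0 (use `1/(1 + pool size)` when the
#'   p-values came from [empirical_pvalue()]).
#' @return The inflation factor lambda.
#' @export
genomic_control <- function(pvalues, p_floor = .Machine$double.xmin) {
  if (length(pvalues) < 100)
    warning("fewer than 100 p-values; lambda estimate is unstable")
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must be finite and in [0, 1]")
  if (any(pvalues == 0)) {
    warning("p-values of 0 clamped to ", p_floor)
    pvalues[pvalues == 0] <- p_floor
  }
  stats <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(stats) / stats::qchisq(0.5, df = 1)
}
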