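# The comparison tests: recurrence (multiplicity) test, Poisson de novo
# test, Fisher-exact transmission/case-control test, the Fisher-combined
# meta test, and the de-novo-only Bayes test.

#' Multiplicity (recurrence) test
#'
#' Declares a gene a risk gene when it sustains at least `c_threshold`
#' independent de novo events in the sample -- the single genome-wide
#' threshold rule used by early exome trio studies.
#'
#' @param x_dn De novo count(s).
#' @param c_threshold Recurrence threshold (at least 2).
#' @return Logical: `x_dn >= c_threshold`.
#' @export
multiplicity_test <- function(x_dn, c_threshold = 2L) {
  if (c_threshold < 2) stop("'c_threshold' must be at least 2")
  x_dn >= c_threshold
}

#' Poisson de novo test
#'
#' Upper-tail p-value for observing `x_dn` or more de novo events when the
#' count is Poisson with gene-specific rate `2 * N * mu`; the gene's own
#' mutation rate replaces the single genome-wide threshold of the
#' multiplicity test. A count of 0 gives p = 1.
#'
#' @param x_dn De novo count(s).
#' @param mu Category mutation rate(s).
#' @param design A [study_design()].
#' @return p-value(s).
#' @export
denovo_test_pvalue <- function(x_dn, mu, design) {
  if (any(mu <= 0)) stop("'mu' must be positive")
  stats::ppois(x_dn - 1, 2 * design$n_trios * mu, lower.tail = FALSE)
}

#' One-sided Fisher exact test on pseudo-case/control counts
#'
#' Treats transmitted/nontransmitted and case/control carriers as one 2x2
#' table `[[x1, e1 - x1], [x0, e0 - x0]]` with chromosome-count exposures
#' and tests for excess in the pseudo-case arm (the model is one-sided in
#' the adverse allele). Computed from the hypergeometric tail, which is the
#' one-sided Fisher exact p-value.
#'
#' @param x1,x0 Pseudo-case and pseudo-control counts (vectorized).
#' @param e1,e0 Chromosome-count exposures of the two arms.
#' @return p-value(s).
#' @export
transmission_cc_pvalue <- function(x1, x0, e1, e0) {
  if (any(e1 != round(e1)) || any(e0 != round(e0)))
    stop("exposures must be whole chromosome counts")
  if (any(x1 > e1) || any(x0 > e0))
    stop("counts cannot exceed their exposures")
  stats::phyper(x1 - 1, m = e1, n = e0, k = x1 + x0, lower.tail = FALSE)
}

#' Combine p-values by Fisher's method
#'
#' `-2 * sum(log(p))` referred to the upper tail of a chi-square with
#' `2 * length(p)` degrees of freedom.
#'
#' @param pvalues p-values in (0, 1]; zeros must be floored by the caller.
#' @return Combined p-value.
#' @export
fisher_combine <- function(pvalues) {
  if (any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]; floor zeros before combining")
  stats::pchisq(-2 * sum(log(pvalues)), df = 2 * length(pvalues),
                lower.tail = FALSE)
}

#' Meta test: de novo and inherited/case-control evidence combined
#'
#' Per gene and category, combines the Poisson de novo p-value with the
#' one-sided Fisher exact p-value on the merged transmission/case-control
#' table using Fisher's method (exactly two p-values per gene). The de novo
#' p is floored at the smallest positive double before combination; p = 1
#' passes through exactly.
#'
#' @param tab Gene count table.
#' @param design A [study_design()].
#' @param category Category to test.
#' @return Data frame: gene, `p_dn`, `p_cc`, `p_meta`.
#' @export
meta_test <- function(tab, design, category = "LoF") {
  tab <- validate_gene_table(tab)
  i <- which(tab$category == category)
  e1 <- 2 * (design$n_cases + design$n_trios)
  e0 <- 2 * (design$n_controls + design$n_trios)
  p_dn <- denovo_test_pvalue(tab$dn[i], tab$mu[i], design)
  p_cc <- transmission_cc_pvalue(tab$case[i] + tab$trans[i],
                                 tab$control[i] + tab$nontrans[i], e1, e0)
  stat <- -2 * (log(pmax(p_dn, .Machine$double.xmin)) +
                  log(pmax(p_cc, .Machine$double.xmin)))
  data.frame(gene = tab$gene[i], p_dn = p_dn, p_cc = p_cc,
             p_meta = stats::pchisq(stat, df = 4, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' De-novo-only Bayes test
#'
#' The full hierarchical test restricted to the de novo evidence stream:
#' per-category closed-form de novo Bayes factors (shrunk by each
#' category's damaging-probability weight), multiplied across categories,
#' with significance from a de-novo-only null simulation pool.
#'
#' @param tab Gene count table.
#' @param design A [study_design()].
#' @param hyper A [hyperparams()] or per-category named list.
#' @param B Null pool size.
#' @param seed RNG seed for the null pool.
#' @return Data frame: gene, per-category `log10_bf.<cat>`,
#'   `log10_bf_total`, `p_value`, `q_value`.
#' @export
tada_denovo <- function(tab, design, hyper = hyperparams(), B = 1e5,
                        seed = 1) {
  tab <- validate_gene_table(tab)
  cats <- unique(tab$category)
  hyper <- .as_hyper_list(hyper, cats)
  genes <- unique(tab$gene)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  total <- numeric(length(genes))
  for (cat in cats) {
    h <- hyper[[cat]]
    rows <- tab[tab$category == cat, ]
    i <- match(genes, rows$gene)
    a <- 2 * design$n_trios * rows$mu[i]
    lbf <- .log_marg_dn(rows$dn[i], a, h$gamma_mean, h$beta, "H1") -
      stats::dpois(rows$dn[i], a, log = TRUE)
    lbf[is.na(lbf)] <- 0
    v <- .adjust_log_bf(lbf, h$w) / log(10)
    out[[paste0("log10_bf.", cat)]] <- v
    total <- total + v
  }
  out$log10_bf_total <- total
  pool <- null_bf_pool(tab, design, hyper, B = B, seed = seed,
                       denovo_only = TRUE)
  out$p_value <- empirical_pvalue(out$log10_bf_total, pool)
  out$q_value <- bh_adjust(out$p_value)
  out
}
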