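#' Study design: sample sizes and mutation categories
#'
#' Describes the sampled cohorts that produced a gene count table: the number
#' of sequenced family trios (source of de novo and transmitted /
#' nontransmitted counts), the numbers of unrelated cases and controls, and
#' the mutation categories analyzed (by default loss-of-function and
#' probably-damaging missense).
#'
#' @param n_trios Number of trios (father, mother, affected child), `N`.
#' @param n_cases Number of unrelated affected subjects, `N1`.
#' @param n_controls Number of unrelated control subjects, `N0`.
#' @param categories Character vector of mutation category labels.
#'
#' @return An object of class `study_design`.
#' @examples
#' study_design(n_trios = 932, n_cases = 935, n_controls = 870)
#' @export
study_design <- function(n_trios, n_cases = 0L, n_controls = 0L,
                         categories = c("LoF", "Mis3")) {
  for (nm in c("n_trios", "n_cases", "n_controls")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v))
      stop(sprintf("'%s' must be a single nonnegative integer", nm))
  }
  if (n_trios + n_cases + n_controls <= 0)
    stop("at least one of n_trios, n_cases + n_controls must be positive")
  if (length(categories) < 1L || anyDuplicated(categories) ||
      any(!nzchar(categories)))
    stop("'categories' must be a nonempty set of unique, nonempty labels")
  structure(
    list(n_trios = as.integer(n_trios), n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls),
         categories = as.character(categories)),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$n_trios, "trios,", x$n_cases, "cases,",
      x$n_controls, "controls\n")
  cat("Categories:", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' Prior hyperparameters for one mutation category
#'
#' The hierarchical model places Gamma priors on the two gene-level
#' parameters. Under the risk-gene model H1 the relative risk gamma follows
#' Gamma(gamma_mean * beta, beta), parameterized so its mean is `gamma_mean`
#' and `beta` acts as a precision (pseudo-count); the allele frequency q
#' follows Gamma(rho1, nu1). Under the null model H0 gamma is fixed at 1 and
#' q follows Gamma(rho0, nu0). `pi` is the prior fraction of risk genes and
#' `w` the probability that a variant in this category is truly damaging
#' (1 for LoF; below 1 for bioinformatically predicted missense categories,
#' whose Bayes factors get shrunk toward 1 accordingly).
#'
#' @param gamma_mean Mean relative risk under H1 (> 1).
#' @param beta Precision of the Gamma prior on the relative risk (> 0).
#' @param rho1,nu1 Shape and rate of the Gamma prior on q under H1.
#' @param rho0,nu0 Shape and rate of the Gamma prior on q under H0.
#' @param pi Prior fraction of risk genes, in (0, 1).
#' @param w Probability a variant of this category is truly damaging, in
#'   (0, 1].
#'
#' @return An object of class `tada_hyper`.
#' @examples
#' hyperparams(gamma_mean = 20, beta = 1)
#' @export
hyperparams <- function(gamma_mean = 20, beta = 1,
                        rho1 = 1, nu1 = 2e4,
                        rho0 = 1, nu0 = 1e3,
                        pi = 1000 / 18000, w = 1) {
  vals <- c(gamma_mean = gamma_mean, beta = beta, rho1 = rho1, nu1 = nu1,
            rho0 = rho0, nu0 = nu0, pi = pi, w = w)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hyperparameters must be positive and finite")
  if (gamma_mean <= 1) stop("'gamma_mean' must exceed 1 (1 is the null)")
  if (pi >= 1) stop("'pi' must lie in (0, 1)")
  if (w > 1) stop("'w' must lie in (0, 1]")
  for (m in c(rho1 / nu1, rho0 / nu0))
    if (m <= 0 || m > 0.05)
      stop("prior mean of q (rho/nu) must lie in (0, 0.05]: got ", m)
  structure(as.list(vals), class = "tada_hyper")
}

#' @export
print.tada_hyper <- function(x, ...) {
  cat(sprintf(
    "Hyperparameters: gamma_mean=%.4g beta=%.4g | q|H1 ~ G(%.3g, %.4g) (mean %.3g) | q|H0 ~ G(%.3g, %.4g) (mean %.3g) | pi=%.4g w=%.3g\n",
    x$gamma_mean, x$beta, x$rho1, x$nu1, x$rho1 / x$nu1,
    x$rho0, x$nu0, x$rho0 / x$nu0, x$pi, x$w))
  invisible(x)
}

#' Per-gene parameters of the generative count model
#'
#' @param gamma Relative risk of the damaging "allele" (1 = null gene).
#' @param q Population frequency of the damaging allele (rare: q <= 0.05).
#' @param mu Mutation rate per chromosome per generation for this gene and
#'   category.
#'
#' @return An object of class `gene_params`.
#' @export
gene_params <- function(gamma, q, mu) {
  if (any(!is.finite(c(gamma, q, mu)))) stop("parameters must be finite")
  if (gamma < 0) stop("'gamma' must be >= 0")
  if (mu <= 0) stop("'mu' must be positive")
  if (q <= 0) stop("'q' must be positive")
  if (q > 0.05)
    warning("q = ", q, " exceeds 0.05; the rare-variant approximation of ",
            "the count model is unreliable")
  structure(list(gamma = gamma, q = q, mu = mu), class = "gene_params")
}

# required columns of a gene count table (long format: one row per
# gene x category)
.gene_table_cols <- c("gene", "category", "mu", "dn", "trans", "nontrans",
                      "case", "control")

#' Validate a gene count table
#'
#' A gene count table is a data frame with one row per gene and mutation
#' category, holding the gene's category-specific mutation rate `mu` and the
#' observed counts: `dn` (de novo events), `trans` / `nontrans` (transmitted
#' and nontransmitted variants in trios), `case` / `control` (carrier counts
#' in unrelated cases and controls). The pseudo-case and pseudo-control
#' counts used by the association model are the derived sums
#' `x1 = case + trans` and `x0 = control + nontrans`.
#'
#' @param tab Data frame to validate.
#' @return The validated data frame (invisibly unchanged), with counts cast
#'   to integer.
#' @export
validate_gene_table <- function(tab) {
  if (!is.data.frame(tab)) stop("gene table must be a data frame")
  missing_cols <- setdiff(.gene_table_cols, names(tab))
  if (length(missing_cols))
    stop("gene table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab[c("gene", "category")]))
    stop("duplicate (gene, category) rows in gene table")
  if (any(!is.finite(tab$mu)) || any(tab$mu <= 0))
    stop("'mu' must be positive and finite for every row")
  for (cc in c("dn", "trans", "nontrans", "case", "control")) {
    v <- tab[[cc]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
      stop(sprintf("column '%s' must hold nonnegative integer counts", cc))
    tab[[cc]] <- as.integer(round(v))
  }
  tab$gene <- as.character(tab$gene)
  tab$category <- as.character(tab$category)
  tab
}
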