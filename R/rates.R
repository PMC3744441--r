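#' Poisson rates of the gene-level count model
#'
#' For a gene with mutation rate `mu`, damaging-allele frequency `q` and
#' relative risk `gamma`, the observed counts follow (approximately) Poisson
#' distributions: de novo events in `N` trios at rate `2*N*mu*gamma`;
#' transmitted variants at `2*N*q*gamma` and nontransmitted at `2*N*q`; case
#' and control carriers at `2*N1*q*gamma` and `2*N0*q`. Because transmitted
#' counts behave like case data with sample size `N`, the combined
#' pseudo-case count `x1 = case + trans` has rate `2*(N1+N)*q*gamma` and the
#' pseudo-control count `x0 = control + nontrans` has rate `2*(N0+N)*q`. The
#' first-order constants live only here, so the whole package shares them.
#'
#' @param params A [gene_params()] object (or list with gamma, q, mu).
#' @param design A [study_design()] object.
#'
#' @return A list of class `rate_set` with elements `r_dn` (de novo rate),
#'   `r_case_arm`, `r_ctrl_arm` (combined pseudo-case and pseudo-control
#'   rates), and the exposures `e1 = 2*(N1+N)`, `e0 = 2*(N0+N)` in
#'   person-chromosome units.
#' @examples
#' compute_rates(gene_params(gamma = 20, q = 5e-5, mu = 1e-6),
#'               study_design(932, 935, 870))
#' @export
compute_rates <- function(params, design) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(params$gamma) || is.null(params$q) || is.null(params$mu))
    stop("'params' must carry gamma, q and mu")
  if (params$mu <= 0) stop("'mu' must be positive")
  e1 <- 2 * (design$n_cases + design$n_trios)
  e0 <- 2 * (design$n_controls + design$n_trios)
  structure(
    list(r_dn = 2 * design$n_trios * params$mu * params$gamma,
         r_case_arm = e1 * params$q * params$gamma,
         r_ctrl_arm = e0 * params$q,
         e1 = e1, e0 = e0),
    class = "rate_set")
}

#' Category-specific mutation rate from a total gene mutation rate
#'
#' Per-gene mutation rates are typically estimated for all point mutations
#' together (from gene length and base content) and then apportioned to a
#' category (LoF, damaging missense, ...) by multiplying with the fraction
#' of mutations of that type. The default LoF fraction, 34/461, is the
#' proportion of LoF variants among de novo single-nucleotide variants
#' observed in unaffected siblings of ASD probands; fractions for other
#' categories are supplied analogously from such control counts.
#'
#' @param mu_total Total per-gene mutation rate(s); vectorized.
#' @param category Category label to extract.
#' @param fractions Named numeric vector mapping category labels to the
#'   fraction of mutations of that type; fractions must lie in `[0, 1]` and
#'   sum to at most 1.
#'
#' @return `mu_total * fractions[category]`.
#' @examples
#' scale_mutation_rate(1e-5, "LoF")
#' @export
scale_mutation_rate <- function(mu_total, category,
                                fractions = c(LoF = 34 / 461)) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("'fractions' must be a named vector")
  if (any(fractions < 0) || any(fractions > 1) || sum(fractions) > 1)
    stop("'fractions' must lie in [0, 1] and sum to at most 1")
  if (any(mu_total < 0)) stop("'mu_total' must be nonnegative")
  if (!category %in% names(fractions))
    stop("unknown category '", category, "'; known: ",
         paste(names(fractions), collapse = ", "))
  unname(mu_total * fractions[[category]])
}

#' Aggregate a variant-level table into a gene count table
#'
#' Applies the standard preprocessing filters and collapses variant rows to
#' per-gene, per-category counts. Variants at population frequency at or
#' above `freq_threshold` are removed as common; genes whose control LoF
#' count exceeds `control_lof_max` are dropped entirely (genes tolerating
#' many LoF alleles in controls are unlikely to be risk genes, and they
#' distort the frequency priors). If the table carries an `individual`
#' column, multiple qualifying variants of one individual in the same gene
#' and category collapse to a single carrier count, matching the model's
#' treatment of all damaging variants in a gene as one "allele".
#'
#' @param variants Data frame with columns `gene`, `category`, `origin`
#'   (one of `denovo`, `transmitted`, `nontransmitted`, `case`, `control`),
#'   optionally `frequency` (population frequency; missing treated as rare)
#'   and `individual`.
#' @param mu_table Data frame with columns `gene`, `category`, `mu` giving
#'   the category-level mutation rate for every gene to keep; genes absent
#'   from `mu_table` are dropped with a warning.
#' @param freq_threshold Variants with `frequency >= freq_threshold` are
#'   excluded (default 0.01).
#' @param control_lof_max Genes with more than this many control LoF events
#'   are removed (default 10).
#'
#' @return A validated gene count table (see [validate_gene_table()]) with
#'   one row per retained gene and category present in `mu_table`.
#' @export
preprocess_counts <- function(variants, mu_table, freq_threshold = 0.01,
                              control_lof_max = 10L) {
  origins <- c("denovo", "transmitted", "nontransmitted", "case", "control")
  need <- c("gene", "category", "origin")
  if (!all(need %in% names(variants)))
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  if (nrow(variants) == 0L) {
    warning("empty variant table; returning empty gene table")
    variants$frequency <- numeric(0)
  }
  bad <- setdiff(unique(variants$origin), origins)
  if (length(bad))
    stop("unknown origin label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(origins, collapse = ", "))
  if (!"frequency" %in% names(variants)) variants$frequency <- 0
  variants$frequency[is.na(variants$frequency)] <- 0
  variants <- variants[variants$frequency < freq_threshold, , drop = FALSE]

  # one count per carrier individual per gene x category x origin
  if ("individual" %in% names(variants)) {
    key <- c("gene", "category", "origin", "individual")
    variants <- variants[!duplicated(variants[key]), , drop = FALSE]
  }

  key <- paste(mu_table$gene, mu_table$category, sep = "\r")
  pick <- function(origin) {
    vv <- variants[variants$origin == origin, , drop = FALSE]
    cnt <- table(paste(vv$gene, vv$category, sep = "\r"))
    v <- as.integer(cnt[key])
    ifelse(is.na(v), 0L, v)
  }
  tab <- data.frame(gene = mu_table$gene, category = mu_table$category,
                    mu = mu_table$mu,
                    dn = pick("denovo"), trans = pick("transmitted"),
                    nontrans = pick("nontransmitted"),
                    case = pick("case"), control = pick("control"),
                    stringsAsFactors = FALSE)

  dropped <- setdiff(unique(variants$gene), unique(mu_table$gene))
  if (length(dropped))
    warning("dropping variants in genes without mutation rates: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")

  lof_ctrl <- tab$control[tab$category == "LoF"]
  names(lof_ctrl) <- tab$gene[tab$category == "LoF"]
  too_many <- names(lof_ctrl)[lof_ctrl > control_lof_max]
  tab <- tab[!tab$gene %in% too_many, , drop = FALSE]
  rownames(tab) <- NULL
  validate_gene_table(tab)
}
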