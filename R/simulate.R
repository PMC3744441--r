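# Genome-wide synthetic data generation: risk-gene assignment, per-gene
# relative risks and allele frequencies (independently or under
# mutation-selection balance), and Poisson count generation with
# reproducible per-gene substreams.

#' Configuration of a simulated genome
#'
#' Defaults describe the rare-variant architecture inferred for ASD from
#' exome trio data: 1,000 risk genes among 18,000, mean relative risk 20
#' with unit coefficient of variation, risk-gene damaging-allele
#' frequencies averaging 5e-5 (rarer, reflecting stronger purifying
#' selection) against 1e-3 for other genes, and per-gene category mutation
#' rates drawn log-normally (median 1.5e-6, sdlog 1, giving a mean near
#' 2.5e-6 and about 0.09 expected de novo events per child genome-wide).
#'
#' @param m Total number of genes.
#' @param k Number of risk genes.
#' @param design A [study_design()].
#' @param gamma_mean Mean relative risk of risk genes.
#' @param gamma_shape Shape of the Gamma relative-risk distribution
#'   (1 = unit coefficient of variation).
#' @param q_risk_mean,q_risk_shape Mean and shape of the Gamma distribution
#'   of damaging-allele frequencies in risk genes.
#' @param q_null_mean,q_null_shape Same for non-risk genes.
#' @param mu Mutation-rate source: a single rate, a length-`m` vector, or a
#'   list `list(median=, sdlog=)` for log-normal rates.
#' @param mode `"independent"` (gamma and q drawn independently) or
#'   `"mutation_selection"` (q = c * mu / gamma with c solved so that mean
#'   frequency and risk match the configured values).
#' @param category Category label stamped on the generated table.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(m = 18000, k = 1000,
                       design = study_design(n_trios = 1000, n_cases = 1000,
                                             n_controls = 1000),
                       gamma_mean = 20, gamma_shape = 1,
                       q_risk_mean = 5e-5, q_risk_shape = 1,
                       q_null_mean = 1e-3, q_null_shape = 1,
                       mu = list(median = 1.5e-6, sdlog = 1),
                       mode = c("independent", "mutation_selection"),
                       category = "LoF") {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "study_design"))
  if (k > m || k < 0) stop("'k' must lie in [0, m]")
  for (v in c(gamma_mean, gamma_shape, q_risk_mean, q_risk_shape,
              q_null_mean, q_null_shape))
    if (!is.finite(v) || v <= 0) stop("all simulation parameters must be positive")
  if (is.numeric(mu)) {
    if (!length(mu) %in% c(1L, m)) stop("'mu' vector must have length 1 or m")
    if (any(mu <= 0)) stop("'mu' must be positive")
  } else if (!is.list(mu) || !all(c("median", "sdlog") %in% names(mu)))
    stop("'mu' must be numeric or list(median=, sdlog=)")
  structure(list(m = as.integer(m), k = as.integer(k), design = design,
                 gamma_mean = gamma_mean, gamma_shape = gamma_shape,
                 q_risk_mean = q_risk_mean, q_risk_shape = q_risk_shape,
                 q_null_mean = q_null_mean, q_null_shape = q_null_shape,
                 mu = mu, mode = mode, category = category),
            class = "sim_config")
}

# deterministic per-gene substream seed: a fixed-point LCG-style mix of the
# master seed and gene index, exact in double precision and below 2^31
.gene_seed <- function(seed, idx) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + idx * 96731) %%
               2147483629) + 1L
}

.with_preserved_rng <- function(expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  expr
}

#' Draw per-gene truth parameters for a simulated genome
#'
#' Samples which genes are risk genes, their relative risks, allele
#' frequencies and mutation rates. In `mutation_selection` mode the
#' frequency of a risk gene is `q = c * mu / gamma` (mutation-selection
#' balance: high-risk alleles are held at lower frequency), with `c` solved
#' from the configured means (`c = q_risk_mean * gamma_mean / mean(mu)`);
#' frequencies are clamped at 0.05 with a warning.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return Data frame: gene, is_risk, gamma, q, mu.
#' @export
sample_gene_params <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m; k <- config$k
  .with_preserved_rng({
    set.seed(seed)
    mu <- if (is.numeric(config$mu)) rep_len(config$mu, m)
    else stats::rlnorm(m, meanlog = log(config$mu$median),
                       sdlog = config$mu$sdlog)
    is_risk <- rep(FALSE, m)
    if (k > 0) is_risk[sample.int(m, k)] <- TRUE
    gamma <- rep(1, m)
    if (k > 0)
      gamma[is_risk] <- stats::rgamma(
        k, config$gamma_shape, rate = config$gamma_shape / config$gamma_mean)
    q <- stats::rgamma(m, config$q_null_shape,
                       rate = config$q_null_shape / config$q_null_mean)
    if (k > 0) {
      if (config$mode == "independent") {
        q[is_risk] <- stats::rgamma(
          k, config$q_risk_shape,
          rate = config$q_risk_shape / config$q_risk_mean)
      } else {
        cc <- config$q_risk_mean * config$gamma_mean / mean(mu)
        q[is_risk] <- cc * mu[is_risk] / gamma[is_risk]
      }
    }
    if (any(q > 0.05)) {
      warning(sum(q > 0.05), " gene(s) with q > 0.05 clamped to 0.05")
      q[q > 0.05] <- 0.05
    }
    data.frame(gene = sprintf("g%05d", seq_len(m)), is_risk = is_risk,
               gamma = gamma, q = q, mu = mu, stringsAsFactors = FALSE)
  })
}

#' Generate observed counts for a simulated genome
#'
#' Draws each gene's de novo, transmitted, nontransmitted, case and control
#' counts from the Poisson rates of [compute_rates()], using a dedicated
#' RNG substream per gene keyed on `(seed, gene index)` -- so any subset of
#' genes reproduces exactly the counts it would have in the full run,
#' independent of ordering.
#'
#' @param params Data frame from [sample_gene_params()].
#' @param design A [study_design()].
#' @param seed Master RNG seed.
#' @param category Category label for the resulting gene table.
#' @return A gene count table (see [validate_gene_table()]).
#' @export
generate_genome_counts <- function(params, design, seed = 1,
                                   category = "LoF") {
  N <- design$n_trios
  m <- nrow(params)
  counts <- matrix(0L, nrow = m, ncol = 5)
  .with_preserved_rng({
    for (i in seq_len(m)) {
      set.seed(.gene_seed(seed, i))
      g <- params$gamma[i]; q <- params$q[i]; mu <- params$mu[i]
      counts[i, ] <- stats::rpois(5, c(
        2 * N * mu * g,                    # de novo
        2 * N * q * g,                     # transmitted
        2 * N * q,                         # nontransmitted
        2 * design$n_cases * q * g,        # case carriers
        2 * design$n_controls * q))        # control carriers
    }
  })
  validate_gene_table(data.frame(
    gene = params$gene, category = category, mu = params$mu,
    dn = counts[, 1], trans = counts[, 2], nontrans = counts[, 3],
    case = counts[, 4], control = counts[, 5], stringsAsFactors = FALSE))
}

#' Simulate a full genome: truth parameters plus observed counts
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (parameters use `seed`, counts use `seed + 1`
#'   substreams).
#' @return A list of class `sim_genome`: `truth` (per-gene parameters),
#'   `counts` (gene table), and `config`.
#' @export
simulate_genome <- function(config, seed = 1) {
  params <- sample_gene_params(config, seed = seed)
  counts <- generate_genome_counts(params, config$design, seed = seed + 1,
                                   category = config$category)
  structure(list(truth = params, counts = counts, config = config),
            class = "sim_genome")
}

#' Simulate de novo counts for an unaffected-sibling cohort
#'
#' Draws per-gene de novo counts at the null rate `2 * N * mu` (no
#' enrichment), the reference cohort for estimating fold enrichment of
#' proband de novo events.
#'
#' @param config A [sim_config()] (its `design$n_trios` is the number of
#'   sibling genomes).
#' @param seed RNG seed.
#' @param mu_by_gene Optional per-gene rates (defaults to a fresh draw from
#'   the config's mu source under `seed`; pass the proband genome's `mu` to
#'   share rates between cohorts).
#' @return Data frame: gene, mu, dn.
#' @export
simulate_sibling_cohort <- function(config, seed = 1, mu_by_gene = NULL) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m
  .with_preserved_rng({
    set.seed(seed)
    mu <- if (!is.null(mu_by_gene)) rep_len(mu_by_gene, m)
    else if (is.numeric(config$mu)) rep_len(config$mu, m)
    else stats::rlnorm(m, meanlog = log(config$mu$median),
                       sdlog = config$mu$sdlog)
    data.frame(gene = sprintf("g%05d", seq_len(m)), mu = mu,
               dn = stats::rpois(m, 2 * config$design$n_trios * mu),
               stringsAsFactors = FALSE)
  })
}
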