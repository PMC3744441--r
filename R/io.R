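# Readers, writers, configuration, and the end-to-end analysis pipeline
# (fit -> Bayes factors -> null p-values -> BH -> report).

#' Read a gene count table from TSV
#'
#' Expects a tab-separated file with header columns `gene`, `category`,
#' `mu`, `dn`, `trans`, `nontrans`, `case`, `control` (one row per gene and
#' category). Validation failures are reported with the offending file
#' line(s).
#'
#' @param path Path to the TSV file.
#' @return A validated gene count table.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = TRUE)
  missing_cols <- setdiff(.gene_table_cols, names(tab))
  if (length(missing_cols))
    stop("'", path, "' is missing columns: ",
         paste(missing_cols, collapse = ", "))
  dup <- duplicated(tab[c("gene", "category")])
  if (any(dup))
    stop("'", path, "' has duplicate (gene, category) rows at line(s): ",
         paste(utils::head(which(dup) + 1L, 5), collapse = ", "))
  for (cc in c("dn", "trans", "nontrans", "case", "control")) {
    bad <- which(is.na(tab[[cc]]) | tab[[cc]] < 0 |
                   tab[[cc]] != round(tab[[cc]]))
    if (length(bad))
      stop("'", path, "' column '", cc,
           "' has invalid counts at line(s): ",
           paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  bad_mu <- which(!is.finite(tab$mu) | tab$mu <= 0)
  if (length(bad_mu))
    stop("'", path, "' has non-positive mutation rates at line(s): ",
         paste(utils::head(bad_mu + 1L, 5), collapse = ", "))
  validate_gene_table(tab)
}

#' Write a gene count table (or any results data frame) as TSV
#'
#' @param tab Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.known_config_keys <- c("design", "pi", "hyper", "freq_threshold",
                        "control_lof_max", "null_pool_size", "joint",
                        "n_nodes", "seed", "w", "sim")

#' Read an analysis configuration from YAML
#'
#' Recognized top-level keys: `design` (n_trios, n_cases, n_controls,
#' categories), `pi`, `hyper` (per-category hyperparameter lists), `w`
#' (per-category damaging-probability weights), `freq_threshold`,
#' `control_lof_max`, `null_pool_size`, `joint`, `n_nodes`, `seed`, and
#' `sim` (passed to [sim_config()]). Unknown keys raise an error before any
#' computation starts.
#'
#' @param path Path to a YAML file.
#' @return A named list with a `design` entry upgraded to [study_design()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known: ", paste(.known_config_keys, collapse = ", "))
  if (!is.null(cfg$design))
    cfg$design <- do.call(study_design, cfg$design)
  if (!is.null(cfg$hyper))
    cfg$hyper <- lapply(cfg$hyper, function(h) do.call(hyperparams, h))
  cfg
}

#' Run the full association analysis on a gene count table
#'
#' Orchestrates the pipeline used for real data: per-category
#' empirical-Bayes fits (unless fitted hyperparameters are supplied), joint
#' per-gene Bayes factors with the damaging-probability adjustment for
#' missense-type categories, null-simulation p-values, Benjamini-Hochberg
#' q-values, and a genomic-control diagnostic, plus a ranked top-genes
#' table.
#'
#' @param tab Gene count table.
#' @param design A [study_design()].
#' @param pi Prior fraction of risk genes (used when fitting).
#' @param hyper Optional fitted [hyperparams()] (single or per-category
#'   named list); when NULL each category is fit by
#'   [fit_hyperparameters()].
#' @param w Named per-category damaging-probability weights (categories not
#'   named get 1); default gives predicted-damaging missense ("Mis3")
#'   weight 0.5.
#' @param null_pool_size Null replicates for the p-value reference.
#' @param joint Share the relative-risk integral across evidence streams.
#' @param n_nodes Quadrature size.
#' @param seed RNG seed (null pool and fit starts).
#' @param top_n Rows in the ranked top-genes table.
#' @return A list of class `tada_analysis`: `results` (per-gene table with
#'   log10 BFs, p and q values), `top` (head of the ranking with
#'   per-category counts and the de novo test p-value), `hyper`, `fits`,
#'   and `summary` (lambda, counts at q < 0.1/0.2/0.3, pool size, seed).
#' @export
run_full_analysis <- function(tab, design, pi = 1000 / 18000, hyper = NULL,
                              w = c(Mis3 = 0.5), null_pool_size = 1e5,
                              joint = TRUE, n_nodes = 32, seed = 1,
                              top_n = 20) {
  tab <- validate_gene_table(tab)
  cats <- unique(tab$category)
  fits <- NULL
  if (is.null(hyper)) {
    fits <- lapply(cats, function(cat) {
      w_cat <- if (cat %in% names(w)) w[[cat]] else 1
      fit_hyperparameters(tab, design, pi = pi, category = cat, w = w_cat,
                          seed = seed, joint = joint, n_nodes = n_nodes)
    })
    names(fits) <- cats
    hyper <- lapply(fits, `[[`, "hyper")
  } else {
    hyper <- .as_hyper_list(hyper, cats)
  }

  bf <- bayes_factor_gene(tab, design, hyper, joint = joint,
                          n_nodes = n_nodes)
  pool <- null_bf_pool(tab, design, hyper, B = null_pool_size, seed = seed,
                       joint = joint, n_nodes = n_nodes)
  bf$p_value <- empirical_pvalue(bf$log10_bf_total, pool)
  bf$q_value <- bh_adjust(bf$p_value)
  lambda <- genomic_control(bf$p_value)

  ord <- order(bf$p_value, -bf$log10_bf_total)
  top <- bf[utils::head(ord, top_n), , drop = FALSE]
  # per-category counts + de novo test p for the headline table
  for (cat in cats) {
    rows <- tab[tab$category == cat, ]
    i <- match(top$gene, rows$gene)
    for (cc in c("dn", "trans", "nontrans", "case", "control"))
      top[[paste(cc, cat, sep = ".")]] <- rows[[cc]][i]
    top[[paste0("p_dn.", cat)]] <-
      ifelse(is.na(i), NA,
             denovo_test_pvalue(rows$dn[i], rows$mu[i], design))
  }
  rownames(top) <- NULL

  structure(list(
    results = bf, top = top, hyper = hyper, fits = fits,
    summary = list(
      lambda = lambda,
      n_genes = nrow(bf),
      n_q_0.1 = sum(bf$q_value < 0.1),
      n_q_0.2 = sum(bf$q_value < 0.2),
      n_q_0.3 = sum(bf$q_value < 0.3),
      null_pool_size = null_pool_size,
      seed = seed)),
    class = "tada_analysis")
}

#' @export
print.tada_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Gene-level Bayes association analysis: %d genes, lambda = %.3f\n",
    s$n_genes, s$lambda))
  cat(sprintf("Genes at q < 0.1 / 0.2 / 0.3: %d / %d / %d\n",
              s$n_q_0.1, s$n_q_0.2, s$n_q_0.3))
  cat("Top genes:\n")
  print(utils::head(x$top[, c("gene", "log10_bf_total", "p_value",
                              "q_value")], 10))
  invisible(x)
}

#' Write analysis results and summary to disk
#'
#' @param analysis A `tada_analysis` from [run_full_analysis()].
#' @param prefix Output path prefix; writes `<prefix>_results.tsv`,
#'   `<prefix>_top.tsv` and `<prefix>_summary.json`.
#' @return The three paths, invisibly.
#' @export
write_analysis <- function(analysis, prefix) {
  stopifnot(inherits(analysis, "tada_analysis"))
  paths <- c(results = paste0(prefix, "_results.tsv"),
             top = paste0(prefix, "_top.tsv"),
             summary = paste0(prefix, "_summary.json"))
  write_gene_table(analysis$results, paths[["results"]])
  write_gene_table(analysis$top, paths[["top"]])
  summary_out <- analysis$summary
  summary_out$hyper <- lapply(analysis$hyper, unclass)
  jsonlite::write_json(summary_out, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
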