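test_that("Poisson rates follow the count model arithmetic", {
  r <- compute_rates(gene_params(gamma = 20, q = 5e-5, mu = 1e-6),
                     study_design(932, 935, 870))
  expect_equal(r$r_dn, 2 * 932 * 1e-6 * 20)
  expect_equal(r$r_dn, 0.03728, tolerance = 1e-12)
  expect_equal(r$e1, 3734)
  expect_equal(r$e0, 3604)
  expect_equal(r$r_case_arm, 3734 * 5e-5 * 20)
  expect_equal(r$r_ctrl_arm, 3604 * 5e-5)
})

test_that("null genes have symmetric arms and trios-only designs balance", {
  des <- study_design(500)
  r <- compute_rates(gene_params(gamma = 1, q = 3e-4, mu = 1e-6), des)
  expect_equal(r$r_case_arm, r$r_ctrl_arm)
  expect_equal(r$e1, r$e0)
  # per-exposure symmetry also holds with N1 = N0
  r2 <- compute_rates(gene_params(gamma = 1, q = 3e-4, mu = 1e-6),
                      study_design(100, 250, 250))
  expect_equal(r2$r_case_arm / r2$e1, r2$r_ctrl_arm / r2$e0)
})

test_that("rates vanish at zero exposure and scale linearly", {
  des0 <- study_design(0, 1, 0)  # only a single case sequenced
  r0 <- compute_rates(gene_params(gamma = 1, q = 1e-3, mu = 1e-6),
                      study_design(0, 0, 1))
  expect_equal(r0$r_dn, 0)
  expect_equal(r0$r_case_arm, 0)
  # linearity in N, mu, q and gamma, over a deterministic parameter sweep
  base <- list(gamma = 3, q = 2e-4, mu = 1.3e-6)
  r1 <- compute_rates(base, study_design(400, 200, 300))
  for (f in c(2, 5)) {
    expect_equal(compute_rates(modifyList(base, list(mu = base$mu * f)),
                               study_design(400, 200, 300))$r_dn,
                 f * r1$r_dn)
    expect_equal(compute_rates(modifyList(base, list(q = base$q * f)),
                               study_design(400, 200, 300))$r_ctrl_arm,
                 f * r1$r_ctrl_arm)
    expect_equal(compute_rates(base, study_design(400 * f, 200, 300))$r_dn,
                 f * r1$r_dn)
  }
  expect_error(compute_rates(list(gamma = 1, q = 1e-3, mu = 0),
                             study_design(10)), "mu")
  expect_warning(gene_params(2, 0.2, 1e-6), "0.05")
})

test_that("category mutation rates are the total rate times the fraction", {
  expect_equal(scale_mutation_rate(1e-5, "LoF"), 1e-5 * 34 / 461)
  expect_equal(scale_mutation_rate(1e-5, "LoF"), 7.375e-7,
               tolerance = 1e-4)
  expect_equal(scale_mutation_rate(0, "LoF"), 0)
  fr <- c(LoF = 34 / 461, Mis3 = 0.2)
  expect_equal(scale_mutation_rate(2e-6, "Mis3", fr), 4e-7)
  expect_error(scale_mutation_rate(1e-5, "Silent", fr), "Silent")
  expect_error(scale_mutation_rate(1e-5, "LoF", c(LoF = 0.5, Mis3 = 0.6)),
               "sum")
})

test_that("variant aggregation applies the frequency and control-LoF filters", {
  mu_tab <- data.frame(gene = c("G1", "G2"), category = "LoF", mu = 1e-6)
  v <- data.frame(
    gene = c(rep("G1", 4), rep("G2", 12)),
    category = "LoF",
    origin = c("denovo", "denovo", "denovo", "transmitted",
               "denovo", rep("control", 11)),
    frequency = c(rep(0, 4), 0.02, rep(0, 11)))
  # G2: 11 control LoF events -> whole gene removed; its frequency-0.02
  # de novo variant is excluded anyway
  tab <- preprocess_counts(v, mu_tab)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$gene, "G1")
  expect_equal(tab$dn, 3L)
  expect_equal(tab$trans, 1L)
  # raising the control cap keeps G2, minus the common variant
  tab2 <- preprocess_counts(v, mu_tab, control_lof_max = 11)
  expect_equal(tab2$control[tab2$gene == "G2"], 11L)
  expect_equal(tab2$dn[tab2$gene == "G2"], 0L)
  expect_error(preprocess_counts(
    data.frame(gene = "G1", category = "LoF", origin = "sibling"),
    mu_tab), "origin")
  expect_warning(preprocess_counts(
    data.frame(gene = character(), category = character(),
               origin = character()), mu_tab), "empty")
})

test_that("multiple variants in one individual collapse to one carrier", {
  mu_tab <- data.frame(gene = "G1", category = "LoF", mu = 1e-6)
  v <- data.frame(gene = "G1", category = "LoF", origin = "case",
                  frequency = 0, individual = c("s1", "s1", "s2"))
  expect_equal(preprocess_counts(v, mu_tab)$case, 2L)
})

test_that("simulated counts match their generating rates", {
  cfg <- sim_config(m = 4000, k = 0, q_null_mean = 1e-3,
                    design = study_design(500, 400, 600),
                    mu = 2e-6)
  sim <- simulate_genome(cfg, seed = 7)
  tab <- sim$counts
  # de novo: rate 2*N*mu identical across genes
  rate_dn <- 2 * 500 * 2e-6
  se_dn <- sqrt(rate_dn / nrow(tab))
  expect_lt(abs(mean(tab$dn) - rate_dn), 3 * se_dn)
  # nontransmitted arm: Poisson mixture over q, mean e0_trio * q_mean
  m_nt <- 2 * 500 * 1e-3
  se_nt <- sd(tab$nontrans) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$nontrans) - m_nt), 3 * se_nt)
  m_ctrl <- 2 * 600 * 1e-3
  se_ctrl <- sd(tab$control) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$control) - m_ctrl), 3 * se_ctrl)
})
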