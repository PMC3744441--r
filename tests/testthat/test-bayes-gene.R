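test_that("joint gene Bayes factor matches an independent quadrature oracle", {
  des <- asd_design()
  h <- hyperparams(gamma_mean = 20, beta = 1, rho1 = 1, nu1 = 2e4,
                   rho0 = 1, nu0 = 1e3)
  e1 <- 2 * (935 + 932); e0 <- 2 * (870 + 932)
  cases <- list(c(2, 5, 0, 2e-6), c(0, 2, 0, 1e-6), c(1, 0, 3, 5e-7),
                c(0, 0, 0, 1e-6), c(3, 1, 1, 4e-6))
  for (cs in cases) {
    tab <- data.frame(gene = "g", category = "LoF", mu = cs[4],
                      dn = cs[1], trans = 0, nontrans = 0,
                      case = cs[2], control = cs[3])
    got <- bayes_factor_gene(tab, des, h)$log10_bf_total
    a <- 2 * 932 * cs[4]
    l1 <- oracle_log_marg_h1(cs[1], cs[2], cs[3], a, e1, e0, h)
    l0 <- dpois(cs[1], a, log = TRUE) +
      marginal_casecontrol(cs[2], cs[3], des, h, "H0", log = TRUE)
    expect_equal(got, (l1 - l0) / log(10), tolerance = 1e-6)
  }
})

test_that("a multi-hit gene with case support outranks transmission-only", {
  # counts styled on the two headline genes: (dn=2, trans=1, case=4) versus
  # (dn=0, trans=2) at equal mutation rate
  des <- asd_design()
  tab <- data.frame(gene = c("hitA", "transB"), category = "LoF", mu = 1e-6,
                    dn = c(2L, 0L), trans = c(1L, 2L), nontrans = 0L,
                    case = c(4L, 0L), control = 0L)
  bf <- bayes_factor_gene(tab, des, hyperparams())
  expect_gt(bf$log10_bf_total[1], bf$log10_bf_total[2])
  expect_gt(bf$log10_bf_total[1], 2)  # strong evidence
})

test_that("joint and factorized integration agree closely in rank", {
  set.seed(31)
  n <- 200
  tab <- data.frame(
    gene = paste0("g", 1:n), category = "LoF",
    mu = rlnorm(n, log(1.5e-6), 1),
    dn = rpois(n, 0.3), trans = rpois(n, 0.5), nontrans = rpois(n, 0.5),
    case = rpois(n, 0.5), control = rpois(n, 0.5))
  des <- study_design(1000, 1000, 1000)
  h <- hyperparams()
  bj <- bayes_factor_gene(tab, des, h, joint = TRUE)$log10_bf_total
  bf <- bayes_factor_gene(tab, des, h, joint = FALSE)$log10_bf_total
  expect_gt(cor(bj, bf), 0.99)
  expect_lt(max(abs(bj - bf)), 1)  # same order of magnitude gene by gene
})

test_that("evidence is monotone in the counts", {
  des <- study_design(1000, 1000, 1000)
  h <- hyperparams()
  base <- data.frame(gene = "g", category = "LoF", mu = 1e-6,
                     dn = 0L, trans = 0L, nontrans = 0L, case = 0L,
                     control = 0L)
  bf_at <- function(dn = 0, case = 0, control = 0) {
    b <- base; b$dn <- dn; b$case <- case; b$control <- control
    bayes_factor_gene(b, des, h)$log10_bf_total
  }
  expect_true(all(diff(sapply(0:4, function(x) bf_at(dn = x))) > 0))
  expect_true(all(diff(sapply(0:5, function(x) bf_at(case = x))) > 0))
  expect_true(all(diff(sapply(0:5, function(x) bf_at(control = x))) < 0))
})

test_that("the damaging-probability weight shrinks missense evidence", {
  des <- asd_design()
  tab <- toy_table()
  h1 <- list(LoF = hyperparams(w = 1), Mis3 = hyperparams(w = 1))
  h5 <- list(LoF = hyperparams(w = 1), Mis3 = hyperparams(w = 0.5))
  h0 <- list(LoF = hyperparams(w = 1), Mis3 = hyperparams(w = 1e-12))
  b1 <- category_bayes_factors(tab, des, h1)
  expect_equal(b1$log10_bf_adj, b1$log10_bf)  # w = 1: plain product
  b0 <- bayes_factor_gene(tab, des, h0)
  bL <- bayes_factor_gene(tab[tab$category == "LoF", ], des,
                          hyperparams(w = 1))
  # w -> 0 makes the missense category evidence-free
  expect_equal(b0$log10_bf_total, bL$log10_bf_total, tolerance = 1e-9)
  b5 <- bayes_factor_gene(tab, des, h5)
  expect_equal(b5$log10_bf_total, b5$log10_bf.LoF + b5$log10_bf.Mis3)
})

test_that("a category without data contributes a unit Bayes factor", {
  des <- asd_design()
  tab <- toy_table()
  tab <- tab[!(tab$gene == "gC" & tab$category == "Mis3"), ]
  expect_message(bf <- bayes_factor_gene(tab, des, hyperparams()),
                 "lack")
  expect_equal(bf$log10_bf.Mis3[bf$gene == "gC"], 0)
})

test_that("no data at all gives a unit total Bayes factor", {
  # no trios and two token case/control subjects with nothing observed and
  # a vanishing mutation rate: nothing to learn from
  des <- study_design(0, 1, 1)
  tab <- data.frame(gene = "g", category = "LoF", mu = 1e-12,
                    dn = 0L, trans = 0L, nontrans = 0L, case = 0L,
                    control = 0L)
  h <- hyperparams(rho1 = 1, nu1 = 1e7, rho0 = 1, nu0 = 1e7)
  expect_equal(bayes_factor_gene(tab, des, h)$log10_bf_total, 0,
               tolerance = 1e-4)
})

test_that("plug-in Bayes factor shrinks estimates toward the prior", {
  des <- study_design(0, 500, 500)  # exposures e1 = e0 = 1000
  h <- hyperparams(rho0 = 0.5, nu0 = 500, rho1 = 1, nu1 = 2e4)
  # nu0 = (e1+e0)/4: prior weight nu/(nu+exposure) = 0.2 on the prior mean
  expect_equal(h$nu0 / (h$nu0 + 1000 + 1000), 0.2)
  tab <- data.frame(gene = "g", category = "LoF", mu = 1e-6, dn = 0L,
                    trans = 0L, nontrans = 0L, case = 3L, control = 1L)
  got <- approx_bayes_factor(tab, des, h)$log10_bf_approx
  # independent arithmetic: posterior means + Poisson likelihood ratio
  q0 <- 0.2 * (0.5 / 500) + 0.8 * (4 / 2000)
  expect_equal(q0, (h$rho0 + 4) / (h$nu0 + 2000))
  g1 <- 20
  for (sweep in 1:3) {
    q1 <- (h$rho1 + 3 + 1) / (h$nu1 + 1000 * g1 + 1000)
    g1 <- (20 * 1 + 0 + 3) / (1 + 0 + 1000 * q1)
  }
  l1 <- dpois(3, 1000 * q1 * g1, log = TRUE) +
    dpois(1, 1000 * q1, log = TRUE)
  l0 <- dpois(3, 1000 * q0, log = TRUE) + dpois(1, 1000 * q0, log = TRUE)
  expect_equal(got, (l1 - l0) / log(10), tolerance = 1e-10)
})

test_that("plug-in and exact Bayes factors agree in sign almost always", {
  set.seed(32)
  cfg <- sim_config(m = 100, k = 30, design = study_design(1000, 1000, 1000),
                    mu = 2e-6)
  sim <- simulate_genome(cfg, seed = 9)
  des <- cfg$design
  h <- hyperparams()
  exact <- bayes_factor_gene(sim$counts, des, h)$log10_bf_total
  appr <- approx_bayes_factor(sim$counts, des, h)$log10_bf_approx
  # the plug-in is a data-driven approximation: compare on genes carrying at
  # least one observed event (for empty genes the exact BF reduces to the
  # prior-mean difference of the frequency priors, which no point estimate
  # can mimic) and away from the knife edge
  cnts <- with(sim$counts, dn + trans + nontrans + case + control)
  informative <- cnts > 0 & abs(exact) > 0.05
  expect_gt(sum(informative), 50)
  agree <- mean(sign(exact[informative]) == sign(appr[informative]))
  expect_gte(agree, 0.9)
  expect_gt(cor(exact[informative], appr[informative]), 0.9)
})
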