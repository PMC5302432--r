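test_that("closed forms recover degenerate structures exactly", {
  # noise-free additive data: zero interaction and residual variance
  d <- additive_met()
  vc <- fit_varcomp(d, "yield", method = "anova")
  expect_equal(vc$sigma2_ge, 0)
  expect_equal(vc$sigma2_eps, 0)
  expect_gt(vc$sigma2_g, 0)

  # identical genotypes: zero genotypic variance
  same <- additive_met(g = c(A = 0, B = 0, C = 0))
  vc0 <- fit_varcomp(same, "yield", method = "anova")
  expect_equal(vc0$sigma2_g, 0)
})

test_that("EM-REML equals ANOVA closed forms on balanced interior data", {
  # ANOVA estimators equal REML for balanced data when no component is
  # truncated; these datasets have strictly positive ANOVA estimates.
  for (seed in c(42, 43, 45)) {
    sim <- generate_met(sim_config(n_genotypes = 10, n_environments = 3,
                                   seed = seed))
    va <- fit_varcomp(sim$data, "yield", method = "anova")
    expect_gt(va$sigma2_ge, 0)   # interior case
    ve <- fit_varcomp(sim$data, "yield", method = "em_reml")
    expect_true(ve$converged)
    expect_equal(ve$sigma2_g, va$sigma2_g, tolerance = 1e-6)
    expect_equal(ve$sigma2_ge, va$sigma2_ge, tolerance = 1e-6)
    expect_equal(ve$sigma2_eps, va$sigma2_eps, tolerance = 1e-6)
  }
})

test_that("EM-REML agrees with lme4 when a component hits the boundary", {
  # With a negative ANOVA interaction estimate the constrained REML
  # optimum lies at sigma2_ge = 0, where truncated ANOVA and REML differ;
  # the EM path must agree with an independent REML fit there.
  sim <- generate_met(sim_config(n_genotypes = 10, n_environments = 3,
                                 seed = 41))
  expect_equal(fit_varcomp(sim$data, "yield", method = "anova")$sigma2_ge, 0)
  ve <- fit_varcomp(sim$data, "yield", method = "em_reml")
  fit <- suppressMessages(lme4::lmer(
    yield_kg_ha ~ environment + (1 | genotype) + (1 | genotype:environment),
    data = sim$data$records, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ref <- setNames(vc$vcov, vc$grp)
  expect_equal(ve$sigma2_g, unname(ref["genotype"]), tolerance = 1e-3)
  expect_equal(ve$sigma2_eps, unname(ref["Residual"]), tolerance = 1e-3)
  expect_lt(ve$sigma2_ge / ve$sigma2_eps, 1e-2)
})

test_that("EM-REML matches lme4 REML on unbalanced data", {
  sim <- generate_met(sim_config(n_genotypes = 10, n_environments = 3,
                                 n_replicates = 3, seed = 43))
  rec <- sim$data$records[-c(5, 22, 47), ]
  d <- met_dataset(rec)
  ve <- fit_varcomp(d, "yield", method = "em_reml")
  expect_equal(ve$method, "em_reml")
  fit <- lme4::lmer(
    yield_kg_ha ~ environment + (1 | genotype) + (1 | genotype:environment),
    data = rec, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ref <- setNames(vc$vcov, vc$grp)
  expect_equal(ve$sigma2_g, unname(ref["genotype"]), tolerance = 1e-3)
  expect_equal(ve$sigma2_ge, unname(ref["genotype:environment"]),
               tolerance = 1e-2)
  expect_equal(ve$sigma2_eps, unname(ref["Residual"]), tolerance = 1e-3)
})

test_that("Monte-Carlo recovery of genotypic variance within 10%", {
  est <- vapply(1:200, function(s) {
    sim <- generate_met(sim_config(n_genotypes = 30, n_environments = 5,
                                   n_replicates = 2, sigma_g = 400,
                                   sigma_eps = 200,
                                   interaction_lambdas = c(400),
                                   seed = 1000 + s))
    fit_varcomp(sim$data, "yield", method = "anova")$sigma2_g
  }, numeric(1))
  expect_equal(mean(est), 160000, tolerance = 0.10)
})

test_that("BLUP shrinkage limits behave as expected", {
  sim <- generate_met(sim_config(n_genotypes = 8, n_environments = 3,
                                 seed = 44))
  d <- sim$data
  tm <- cell_means(d, "yield")

  # sigma2_g = 0: genotype BLUPs vanish, GV = environment means only
  vc0 <- structure(list(sigma2_g = 0, sigma2_ge = 0,
                        sigma2_eps = 1000, method = "anova_closed_form",
                        converged = TRUE, n_iterations = 0L,
                        trait = "yield_kg_ha"), class = "met_varcomp")
  gv0 <- predict_genotypic_values(vc0, d, "yield")
  expect_equal(max(abs(gv0$genotype_blup)), 0)
  expect_equal(unname(apply(gv0$gv, 2, function(x) diff(range(x)))),
               rep(0, 3))

  # sigma2_g, sigma2_ge -> large: GV approaches the cell means
  vcInf <- structure(list(sigma2_g = 1e12, sigma2_ge = 1e12,
                          sigma2_eps = 1, method = "anova_closed_form",
                          converged = TRUE, n_iterations = 0L,
                          trait = "yield_kg_ha"), class = "met_varcomp")
  gvInf <- predict_genotypic_values(vcInf, d, "yield")
  expect_equal(unname(gvInf$gv), unname(tm$values), tolerance = 1e-4)
})

test_that("genotype BLUPs correlate with the generating effects", {
  sim <- generate_met(sim_config(n_genotypes = 30, n_environments = 3,
                                 n_replicates = 2, sigma_g = 400,
                                 sigma_eps = 200,
                                 interaction_lambdas = numeric(0), seed = 45))
  bs <- blup_stability(sim$data, "yield")
  expect_gt(cor(bs$gv$genotype_blup, sim$truth$genotype_effects), 0.9)
})

test_that("HMGV/RPGV/HMRPGV hand examples", {
  mk_gv <- function(V, env_means) {
    structure(list(gv = V, env_means = env_means,
                   genotype_blup = setNames(rep(0, nrow(V)), rownames(V)),
                   mu_hat = mean(env_means), vc = NULL, trait = "t",
                   nonpositive = character(0)), class = "gv_table")
  }
  # constant genotype: HMGV = c, both relative statistics = 1
  V <- matrix(5, 2, 3, dimnames = list(c("A", "B"), c("E1", "E2", "E3")))
  st <- hmgv_rpgv_hmrpgv(mk_gv(V, c(E1 = 5, E2 = 5, E3 = 5)))
  expect_equal(st$HMGV, c(5, 5))
  expect_equal(st$RPGV, c(1, 1))
  expect_equal(st$HMRPGV, c(1, 1))

  # two environments, GV (4, 4), env means (2, 8)
  V2 <- matrix(4, 1, 2, dimnames = list("A", c("E1", "E2")))
  st2 <- hmgv_rpgv_hmrpgv(mk_gv(V2, c(E1 = 2, E2 = 8)))
  expect_equal(st2$HMGV, 4)
  expect_equal(st2$RPGV, 1.25)
  expect_equal(st2$HMRPGV, 0.8)

  # proportional genotype GV = k * mu_j: RPGV = HMRPGV = k exactly
  mu <- c(E1 = 3, E2 = 6, E3 = 9)
  V3 <- rbind(A = 1.4 * mu, B = 0.7 * mu)
  st3 <- hmgv_rpgv_hmrpgv(mk_gv(V3, mu))
  expect_equal(st3$RPGV, c(1.4, 0.7))
  expect_equal(st3$HMRPGV, c(1.4, 0.7))
  expect_equal(st3$genotype, c("A", "B"))  # ranked by HMRPGV descending

  # nonpositive GV is an error naming the genotype
  V4 <- rbind(A = c(-1, 2), B = c(3, 4))
  colnames(V4) <- c("E1", "E2")
  g4 <- suppressWarnings(mk_gv(V4, c(E1 = 1, E2 = 3)))
  g4$nonpositive <- "A"
  expect_error(hmgv_rpgv_hmrpgv(g4), "A")
})

test_that("harmonic-arithmetic inequalities hold on fitted tables", {
  for (seed in 46:48) {
    sim <- generate_met(sim_config(n_genotypes = 12, seed = seed))
    bs <- blup_stability(sim$data, "yield")
    am <- rowMeans(bs$gv$gv)[bs$stats$genotype]
    expect_true(all(bs$stats$HMGV <= am + 1e-9))
    expect_true(all(bs$stats$HMRPGV <= bs$stats$RPGV + 1e-12))
  }
})

test_that("scale equivariance of the stability statistics", {
  sim <- generate_met(sim_config(n_genotypes = 8, seed = 49))
  rec <- sim$data$records
  rec2 <- rec
  rec2$yield_kg_ha <- rec2$yield_kg_ha * 3
  b1 <- blup_stability(sim$data, "yield")
  b2 <- blup_stability(met_dataset(rec2), "yield")
  expect_equal(b2$stats$HMGV, 3 * b1$stats$HMGV, tolerance = 1e-8)
  expect_equal(b2$stats$RPGV, b1$stats$RPGV, tolerance = 1e-8)
  expect_equal(b2$stats$HMRPGV, b1$stats$HMRPGV, tolerance = 1e-8)
  expect_equal(b2$stats$genotype, b1$stats$genotype)
})

test_that("with zero interaction the HMRPGV ranking follows genotype means", {
  sim <- generate_met(sim_config(n_genotypes = 15, sigma_eps = 100,
                                 interaction_lambdas = numeric(0), seed = 50))
  bs <- blup_stability(sim$data, "yield")
  gs <- genotype_summary(sim$data, "yield")
  mean_order <- gs$genotype[order(-gs$mean_yield, gs$genotype)]
  expect_equal(bs$stats$genotype, mean_order)
})

test_that("single environment is rejected", {
  d <- met_dataset(tiny_records())
  expect_error(fit_varcomp(d, "yield"), "2 genotypes and 2 environments")
})
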