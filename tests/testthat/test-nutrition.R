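test_that("dehulling scales hulled yields only", {
  expect_equal(dehull_adjust(4000, TRUE, 0.75), 3000)
  expect_equal(dehull_adjust(4000, FALSE, 0.75), 4000)
  # inverse of the correction on the published T. monococcum mean
  expect_equal(dehull_adjust(2027 / 0.75, TRUE, 0.75), 2027)
  expect_error(dehull_adjust(4000, TRUE, 1.5), "factor")
  expect_error(dehull_adjust(-1, TRUE, 0.75), "yield")
})

test_that("nutritional yield formula and linearity", {
  expect_equal(nutritional_yield(6920, 38.0, 12), 60.04, tolerance = 1e-4)
  expect_equal(nutritional_yield(8190, 4.6, 0.9), 114.68, tolerance = 1e-4)
  expect_equal(nutritional_yield(0, 50, 12), 0)
  y <- nutritional_yield(5000, 40, 12)
  expect_equal(nutritional_yield(10000, 40, 12), 2 * y)  # linear in yield
  expect_equal(nutritional_yield(5000, 80, 12), 2 * y)   # linear in conc
  expect_equal(nutritional_yield(5000, 40, 6), 2 * y)    # halve DRI
  expect_error(nutritional_yield(5000, 40, 0), "dri")
})

test_that("amount_for_dri and its round-trip identity", {
  expect_equal(amount_for_dri(49.0, 12), 244.9, tolerance = 1e-3)
  expect_equal(amount_for_dri(1000, 1), 1)
  expect_error(amount_for_dri(0, 12), "undefined")
  for (conc in c(34.6, 49.0, 1399)) {
    for (dri in c(0.9, 12, 315)) {
      expect_equal(amount_for_dri(conc, dri) * conc / 1000, dri)
    }
  }
})

test_that("add_nutritional_yield dehulls before computing and checks minerals", {
  rec <- tiny_records()
  rec$group <- c("Spelt", "Spelt", "Cultivar", "Cultivar")
  d <- add_nutritional_yield(met_dataset(rec), analysis_config(dri = c(Fe = 12)))
  expect_equal(d$records$yield_adj_kg_ha,
               rec$yield_kg_ha * c(0.75, 0.75, 1, 1))
  expect_equal(d$records$ny_Fe,
               d$records$yield_adj_kg_ha * rec$conc_Fe_mg_kg / (12 * 365))
  expect_error(
    add_nutritional_yield(met_dataset(tiny_records()),
                          analysis_config(dri = c(Zn = 8))),
    "not present")
})

test_that("genotype and population summaries follow per-plot averaging", {
  d <- add_nutritional_yield(met_dataset(tiny_records()),
                             analysis_config(dri = c(Fe = 12)))
  gs <- genotype_summary(d, c("yield", "ny_Fe"))
  expect_equal(gs$mean_yield, c(4000, 3850))
  expect_equal(gs$sd_yield, c(sd(c(3000, 5000)), sd(c(3800, 3900))))
  # per-plot mean NY differs from NY of the means when yield and conc covary
  expect_equal(gs$mean_ny_Fe[1],
               mean(c(3000 * 40, 5000 * 42) / (12 * 365)))
  expect_false(isTRUE(all.equal(gs$mean_ny_Fe[1],
                                nutritional_yield(4000, 41, 12))))
  pop <- population_summary(gs)
  expect_equal(unname(pop["yield"]), mean(c(4000, 3850)))

  same <- tiny_records()
  same$yield_kg_ha <- 4000
  same$conc_Fe_mg_kg <- 40
  gs0 <- genotype_summary(met_dataset(same), "yield")
  expect_equal(gs0$sd_yield, c(0, 0))
})

test_that("population means over the published genotype table reproduce 39/63", {
  tab <- ekhaga_genotype_means()
  expect_equal(round(mean(tab$ny_Fe)), 39)
  expect_equal(round(mean(tab$ny_Cu)), 63)
  expect_equal(mean(tab$ny_Cu), 62.9, tolerance = 1e-3)
})

test_that("trait correlations behave on degenerate and exact cases", {
  sim <- generate_met(sim_config(n_genotypes = 10, seed = 21))
  d <- add_nutritional_yield(sim$data)
  tc <- trait_correlations(d, c("yield", "ny_Fe", "ny_Zn"))
  expect_equal(diag(tc$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(tc$r, t(tc$r))
  expect_true(all(tc$p[upper.tri(tc$p)] >= 0 & tc$p[upper.tri(tc$p)] <= 1))

  # constant concentration: NY is proportional to yield, r exactly 1
  # (no hulled genotypes, so the adjusted yield is the raw yield)
  rec <- generate_met(sim_config(n_genotypes = 6, hulled_fraction = 0,
                                 seed = 22))$data$records
  rec$conc_Fe_mg_kg <- 40
  d2 <- add_nutritional_yield(met_dataset(rec), analysis_config(dri = c(Fe = 12)))
  tc2 <- trait_correlations(d2, c("yield", "ny_Fe"))
  expect_equal(tc2$r["yield", "ny_Fe"], 1)

  # anti-ordered pair
  rec$conc_Fe_mg_kg <- max(rec$yield_kg_ha) + 1 - rec$yield_kg_ha
  d3 <- met_dataset(rec)
  tc3 <- trait_correlations(d3, c("yield", "Fe"))
  expect_equal(tc3$r["yield", "Fe"], -1)

  # zero-variance trait flagged as missing
  rec$conc_Fe_mg_kg <- 40
  expect_warning(tc4 <- trait_correlations(met_dataset(rec), c("yield", "Fe")),
                 "zero variance")
  expect_true(is.na(tc4$r["yield", "Fe"]))
})

test_that("variance partition decomposes the total sum of squares", {
  # additive noise-free data: all variation is genotype + environment
  d <- additive_met()
  vp <- variance_partition(d, "yield")
  expect_equal(sum(vp$proportions), 1)
  expect_equal(unname(vp$proportions["ge"]), 0, tolerance = 1e-12)
  expect_equal(unname(vp$proportions["residual"]), 0, tolerance = 1e-12)
  expect_equal(unname(vp$proportions["genotype"] + vp$proportions["environment"]),
               1, tolerance = 1e-12)

  # constant data: proportions undefined
  const <- additive_met(g = c(A = 0, B = 0, C = 0), e = c(E1 = 0, E2 = 0))
  expect_warning(vpc <- variance_partition(const, "yield"), "undefined")
  expect_true(all(is.na(vpc$proportions)))

  # genotype-dominant generator: genotype share exceeds environment share
  sim <- generate_met(sim_config(n_genotypes = 15, sigma_g = 900,
                                 sigma_env = 100, sigma_eps = 200,
                                 interaction_lambdas = numeric(0), seed = 23))
  vps <- variance_partition(sim$data, "yield")
  expect_gt(vps$proportions["genotype"], vps$proportions["environment"])
  expect_true(all(vps$proportions >= 0 & vps$proportions <= 1))
  expect_equal(sum(vps$proportions), 1)

  # single replicate: interaction and residual confounded, with warning
  one_rep <- met_dataset(additive_met(reps = 1)$records)
  expect_warning(vp1 <- variance_partition(one_rep, "yield"), "confounded")
  expect_true("ge_plus_residual" %in% names(vp1$proportions))
})
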