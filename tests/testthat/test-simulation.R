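# Genotype/exposure/phenotype generators and simulated external studies.

test_that("dosages follow Binomial(2, MAF) under Hardy-Weinberg", {
  G <- simulate_genotypes(100000, 0.5, seed = 61)
  expect_lt(abs(mean(G$dosages) - 1), 0.01)  # mean dosage 2 * MAF
  # rare allele: carrier count within 3 binomial SDs of expectation
  G2 <- simulate_genotypes(1000, 0.01, seed = 62)
  carriers <- sum(G2$dosages[, 1] > 0)
  p_carrier <- 1 - 0.99^2
  expect_lt(abs(carriers - 1000 * p_carrier),
            3 * sqrt(1000 * p_carrier * (1 - p_carrier)) + 1e-9)
  expect_error(simulate_genotypes(10, 0.6), "0, 0.5")
  expect_error(simulate_genotypes(10, 0), "0, 0.5")
})

test_that("observed MAF converges to the specified MAF for every SNP", {
  mafs <- c(0.05, 0.1, 0.25, 0.45)
  G <- simulate_genotypes(20000, mafs, seed = 63)
  se3 <- 3 * sqrt(mafs * (1 - mafs) / (2 * 20000))
  expect_true(all(abs(G$maf - mafs) < se3))
})

test_that("generators are deterministic given the seed", {
  expect_equal(simulate_genotypes(50, c(0.2, 0.4), seed = 64)$dosages,
               simulate_genotypes(50, c(0.2, 0.4), seed = 64)$dosages)
  expect_equal(simulate_exposure(50, "normal", seed = 64),
               simulate_exposure(50, "normal", seed = 64))
  cfg <- scenario_config(n = 100, scenario = "a")
  d1 <- simulate_scenario(cfg, seed = 64)
  d2 <- simulate_scenario(cfg, seed = 64)
  expect_equal(d1$genotypes$dosages, d2$genotypes$dosages)
  expect_equal(d1$phenotype, d2$phenotype)
})

test_that("exposure distributions have the right moments", {
  e <- simulate_exposure(1e5, "bernoulli", seed = 65)
  expect_true(all(e %in% c(0, 1)))
  expect_lt(abs(mean(e) - 0.5), 0.005)
  z <- simulate_exposure(1e5, "normal", seed = 65)
  expect_lt(abs(sd(z) - 1), 0.01)
})

test_that("a scenario with no effects is pure gaussian noise", {
  cfg <- scenario_config(n = 1e5, scenario = "a", interaction_effect = 0,
                         noise_sd = 1.5)
  dat <- simulate_scenario(cfg, seed = 66)
  expect_lt(abs(var(dat$phenotype) / 1.5^2 - 1), 0.05)
  expect_equal(dat$truth$interaction_sign, 0)
})

test_that("predominant-interaction scenario has effect 1.5 and implicit marginal 0.75", {
  cfg <- scenario_config(n = 50000, k_risk = 6, k_noise = 0, scenario = "a")
  dat <- simulate_scenario(cfg, seed = 67)
  D <- recode_genotypes(dat$genotypes, "dominant")$dosages
  E <- dat$exposure
  # joint regression on all D_j and D_j * E: interaction coefficients 1.5
  Xint <- D * E
  fit <- lm(dat$phenotype ~ D + Xint)
  ints <- coef(fit)[grep("Xint", names(coef(fit)))]
  expect_true(all(abs(ints - 1.5) < 0.05))
  # marginal-only regression: E[1.5 * D * E | D] = 0.75 * D under Bernoulli(0.5)
  fitm <- lm(dat$phenotype ~ D)
  margs <- coef(fitm)[-1]
  expect_true(all(abs(margs - 0.75) < 0.05))
})

test_that("centered continuous exposure removes the implicit marginal effect", {
  cfg <- scenario_config(n = 50000, k_risk = 3, k_noise = 0, scenario = "a",
                         exposure_dist = "normal")
  dat <- simulate_scenario(cfg, seed = 68)
  D <- recode_genotypes(dat$genotypes, "dominant")$dosages
  margs <- coef(lm(dat$phenotype ~ D))[-1]
  expect_true(all(abs(margs) < 0.05))
})

test_that("predominant-marginal scenario carries 1.5 marginal and 0.75 interaction", {
  cfg <- scenario_config(n = 50000, k_risk = 3, k_noise = 0, scenario = "b")
  dat <- simulate_scenario(cfg, seed = 69)
  D <- recode_genotypes(dat$genotypes, "dominant")$dosages
  E <- dat$exposure
  cf <- coef(lm(dat$phenotype ~ D * E))
  main <- cf[grep("^D.*[^E]$", names(cf))]
  inter <- cf[grep(":E$", names(cf))]
  expect_length(main, 3); expect_length(inter, 3)
  expect_true(all(abs(main - 1.5) < 0.05))
  expect_true(all(abs(inter - 0.75) < 0.1))
})

test_that("null scenario has marginal effects but zero interaction", {
  cfg <- scenario_config(n = 50000, k_risk = 3, k_noise = 0, scenario = "null")
  dat <- simulate_scenario(cfg, seed = 70)
  expect_equal(dat$truth$interaction, rep(0, 3))
  expect_equal(dat$truth$marginal, rep(1.5, 3))
  expect_equal(dat$truth$interaction_sign, 0)
  D <- recode_genotypes(dat$genotypes, "dominant")$dosages
  E <- dat$exposure
  cf <- coef(lm(dat$phenotype ~ D * E))
  expect_true(all(abs(cf[grep(":E$", names(cf))]) < 0.1))
})

test_that("binomial family draws outcomes from the logistic model", {
  cfg <- scenario_config(n = 50000, k_risk = 2, k_noise = 0, scenario = "b",
                         family = "binomial")
  dat <- simulate_scenario(cfg, seed = 71)
  expect_true(all(dat$phenotype %in% c(0, 1)))
  D <- recode_genotypes(dat$genotypes, "dominant")$dosages
  E <- dat$exposure
  cf <- coef(glm(dat$phenotype ~ D * E, family = binomial()))
  main <- cf[grep("^D.*[^E]$", names(cf))]
  expect_true(all(abs(main - 1.5) < 0.15))
})

test_that("k_risk larger than the SNP panel is an error", {
  G <- simulate_genotypes(50, c(0.2, 0.3), seed = 72)
  E <- rbinom(50, 1, 0.5)
  cfg <- scenario_config(n = 50, k_risk = 6, k_noise = 0, scenario = "a")
  expect_error(simulate_phenotype(G, E, cfg), "k_risk")
})

test_that("perfect external weights converge to the true marginal effects", {
  # external study from the same distribution; univariate marginal effects
  # of risk SNPs approach the implicit marginal effect 0.75 at large n
  cfg <- scenario_config(n = 50000, k_risk = 3, k_noise = 3, scenario = "a")
  ext <- simulate_external_weights(external_study_config("perfect"), cfg,
                                   seed = 73)
  w <- ext$weights$weights
  expect_true(all(abs(w[1:3] - 0.75) < 0.1))
  expect_true(all(abs(w[4:6]) < 0.05))
  expect_equal(ext$weights$provenance, "external")
  # perfect mode leaves the sample-generating scenario untouched
  expect_equal(ext$sample_cfg$risk_multiplier, rep(1, 3))
  expect_equal(ext$sample_cfg$active_risk, rep(TRUE, 3))
})

test_that("underestimating mode inflates the sample effects by 30%", {
  cfg <- scenario_config(n = 1000, scenario = "a")
  ext <- simulate_external_weights(external_study_config("underestimating"),
                                   cfg, seed = 74)
  expect_equal(ext$sample_cfg$risk_multiplier, rep(1.3, 6))
})

test_that("overestimating mode leaves one active risk SNP in the sample", {
  cfg <- scenario_config(n = 1000, scenario = "a")
  ext <- simulate_external_weights(external_study_config("overestimating"),
                                   cfg, seed = 75)
  expect_equal(sum(ext$sample_cfg$active_risk), 1)
  expect_equal(sum(!ext$sample_cfg$active_risk), 5)
  # the inactive SNPs then truly carry no effect in the sample data
  eff <- grsxe:::scenario_effects(ext$sample_cfg)
  expect_equal(sum(eff$interaction != 0), 1)
})

test_that("external study size is size_factor times the sample size", {
  cfg <- scenario_config(n = 3000, scenario = "a")
  ext <- simulate_external_weights(external_study_config("perfect",
                                                         size_factor = 4),
                                   cfg, seed = 76)
  expect_equal(nrow(ext$external$genotypes$dosages), 12000)
  # shared MAFs describe the same SNP panel in both studies
  expect_length(ext$mafs, 12)
})
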