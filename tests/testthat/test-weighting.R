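# Penalized weighting: closed-form oracles, shrinkage behavior, splits and
# the three weighting regimes.

test_that("unpenalized fit (lambda = 0) matches the normal-equation OLS oracle", {
  set.seed(21)
  n <- 100; k <- 3
  G <- simulate_genotypes(n, c(0.2, 0.35, 0.45))
  y <- 0.5 + drop(G$dosages %*% c(1.2, -0.7, 0.3)) + rnorm(n)
  oracle <- ols_oracle(G$dosages, y)
  fit <- fit_penalized_marginal(G, y, alpha = 0.5, lambda = 0)
  expect_equal(fit$intercept, unname(oracle[1]), tolerance = 1e-4)
  expect_equal(unname(fit$snp_main), unname(oracle[-1]), tolerance = 1e-4)
  # interaction variant at lambda = 0 also matches OLS on the full design
  E <- rbinom(n, 1, 0.5)
  y2 <- y + 0.8 * G$dosages[, 1] * E
  X <- cbind(G$dosages, E, G$dosages * E)
  oracle2 <- ols_oracle(X, y2)
  fit2 <- fit_penalized_interaction(G, E, y2, alpha = 0.5, lambda = 0)
  expect_equal(unname(c(fit2$intercept, fit2$snp_main, fit2$env_main,
                        fit2$snp_env_interaction)),
               unname(oracle2), tolerance = 1e-4)
})

test_that("scalar ridge fit matches its documented closed form", {
  # Under the implementation's objective scaling the gaussian loss is
  # 1/(2n) RSS with the outcome standardized internally by its 1/n-scale
  # standard deviation, so for a single predictor standardized to unit
  # 1/n-variance the ridge (alpha = 0) solution at a fixed penalty lambda
  # is beta_ols / (1 + lambda / sd_n(y)) — equivalently
  # beta_ols * n / (n + c * lambda) with scaling constant c = n / sd_n(y).
  set.seed(22)
  n <- 200
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))  # sd_n = 1
  y <- 2 + 1.5 * x + rnorm(n)
  beta_ols <- unname(ols_oracle(x, y)[2])
  sdy <- sqrt(mean((y - mean(y))^2))
  for (lam in c(0.1, 0.5, 2)) {
    fit <- fit_penalized_marginal(matrix(x, ncol = 1), y, alpha = 0,
                                  lambda = lam)
    expect_equal(unname(fit$snp_main), beta_ols / (1 + lam / sdy),
                 tolerance = 1e-4)
  }
})

test_that("null signal shrinks to the zero vector at the 1-SE lambda", {
  set.seed(23)
  G <- simulate_genotypes(500, runif(12, 0.05, 0.45))
  y <- rnorm(500)
  fit <- fit_penalized_marginal(G, y, alpha = 0.5, cv_folds = 10, seed = 23)
  expect_lte(sum(fit$snp_main != 0), 1)  # allow at most one spurious pick
})

test_that("interaction fit recovers a pure exposure effect at large n", {
  set.seed(24)
  n <- 5000
  G <- simulate_genotypes(n, runif(6, 0.1, 0.45))
  E <- rnorm(n)
  y <- 2 * E + rnorm(n)
  # with an unpenalized exposure main effect the attribution is unique:
  # gamma absorbs the whole effect and every product term is dropped
  fit_free <- fit_penalized_interaction(G, E, y, alpha = 0.5, seed = 24,
                                        penalize_env = FALSE)
  expect_lt(abs(fit_free$env_main - 2), 0.1)
  expect_true(all(fit_free$snp_env_interaction == 0))
  # under the default (gamma penalized alongside delta) the nonnegative
  # product columns G_j*E are collinear with E, so the elastic net spreads
  # the exposure effect across them; the identifiable quantity is the
  # effective exposure slope at the mean genotype
  fit <- fit_penalized_interaction(G, E, y, alpha = 0.5, seed = 24)
  eff <- fit$env_main + sum(fit$snp_env_interaction * colMeans(G$dosages))
  expect_lt(abs(eff - 2), 0.1)
  expect_true(fit$env_main > 0 && fit$env_main <= 2)
})

test_that("interaction fit recovers predominant-interaction structure", {
  # 6 risk SNPs with interaction effect 1.5, 6 noise SNPs, n = 5000
  cfg <- scenario_config(n = 5000, k_risk = 6, k_noise = 6, scenario = "a")
  dat <- simulate_scenario(cfg, seed = 2501)
  Gd <- recode_genotypes(dat$genotypes, "dominant")
  fit <- fit_penalized_interaction(Gd, dat$exposure, dat$phenotype,
                                   alpha = 0.5, seed = 2501)
  delta <- fit$snp_env_interaction
  expect_true(all(delta[1:6] > 0))
  expect_gte(sum(delta[7:12] == 0), 4)
})

test_that("interaction fit rejects constant nonzero exposure, accepts all-zero", {
  G <- make_small_genotypes(60)
  y <- rnorm(60)
  expect_error(fit_penalized_interaction(G, rep(2, 60), y, lambda = 0.1),
               "constant")
  expect_silent(fit_penalized_interaction(G, rep(0, 60), y, lambda = 0.1))
})

test_that("with an all-zero exposure the SNP path nests the marginal fit", {
  set.seed(26)
  G <- simulate_genotypes(150, c(0.2, 0.3, 0.4, 0.25))
  y <- drop(G$dosages %*% c(1, 0, -0.5, 0)) + rnorm(150)
  fm <- fit_penalized_marginal(G, y, alpha = 0.5, seed = 26)
  fi <- fit_penalized_interaction(G, rep(0, 150), y, alpha = 0.5, seed = 26)
  expect_equal(fi$lambda_path, fm$lambda_path)
  bm <- as.matrix(coef(fm$glmnet$glmnet.fit))
  bi <- as.matrix(coef(fi$glmnet$glmnet.fit))
  expect_equal(bi[rownames(bm), ], bm, tolerance = 1e-8)
  expect_true(all(bi["E", ] == 0))
})

test_that("penalized objective at the fit never exceeds the objective at zero", {
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 120
    G <- simulate_genotypes(n, runif(5, 0.1, 0.45))
    y <- drop(G$dosages %*% rnorm(5, 0, 0.5)) + rnorm(n)
    fit <- fit_penalized_marginal(G, y, alpha = 0.5, seed = 400 + s)
    x <- G$dosages
    obj_fit <- grsxe:::penalized_objective(fit$intercept, fit$snp_main, x, y,
                                           fit$lambda_chosen, 0.5)
    obj_zero <- grsxe:::penalized_objective(mean(y), rep(0, 5), x, y,
                                            fit$lambda_chosen, 0.5)
    expect_lte(obj_fit, obj_zero + 1e-8)
  }
})

test_that("make_split partitions n samples at the requested ratio", {
  s <- make_split(3000, c(1, 1), seed = 1)
  expect_equal(length(s$train_indices), 1500)
  expect_equal(length(s$test_indices), 1500)
  s2 <- make_split(400, c(1, 3), seed = 1)
  expect_equal(length(s2$train_indices), 100)
  expect_equal(length(s2$test_indices), 300)
  # partition property
  expect_length(intersect(s2$train_indices, s2$test_indices), 0)
  expect_setequal(c(s2$train_indices, s2$test_indices), 1:400)
  # determinism
  expect_equal(make_split(100, c(1, 2), seed = 9)$train_indices,
               make_split(100, c(1, 2), seed = 9)$train_indices)
  expect_error(make_split(5, c(1, 9)), "degenerate|smaller")
  expect_error(make_split(100, c(0, 1)), "positive")
})

test_that("marginal-internal weights wrap the full-sample penalized fit", {
  cfg <- scenario_config(n = 600, k_risk = 3, k_noise = 3, scenario = "b")
  dat <- simulate_scenario(cfg, seed = 31)
  res <- weights_marginal_internal(recode_genotypes(dat$genotypes, "dominant"),
                                   dat$phenotype, seed = 31)
  expect_s3_class(res$weights, "weight_vector")
  expect_equal(res$weights$provenance, "marginal-internal")
  expect_length(res$weights, 6)
  expect_equal(unname(res$weights$weights), unname(res$fit$snp_main))
})

test_that("interaction-training weights come from the training split only and are deterministic", {
  cfg <- scenario_config(n = 800, k_risk = 6, k_noise = 6, scenario = "a")
  dat <- simulate_scenario(cfg, seed = 32)
  Gd <- recode_genotypes(dat$genotypes, "dominant")
  r1 <- weights_interaction_training(Gd, dat$exposure, dat$phenotype,
                                     ratio = c(1, 1), seed = 32)
  r2 <- weights_interaction_training(Gd, dat$exposure, dat$phenotype,
                                     ratio = c(1, 1), seed = 32)
  expect_equal(r1$weights$weights, r2$weights$weights)
  expect_equal(r1$split$train_indices, r2$split$train_indices)
  expect_equal(r1$weights$provenance, "interaction-training")
  # refitting on the training subset reproduces the stored fit
  refit <- fit_penalized_interaction(Gd$dosages[r1$split$train_indices, ],
                                     dat$exposure[r1$split$train_indices],
                                     dat$phenotype[r1$split$train_indices],
                                     seed = 32)
  expect_equal(refit$snp_env_interaction, r1$fit$snp_env_interaction)
})

test_that("over-shrunk interaction weights are flagged degenerate with a warning", {
  set.seed(33)
  G <- simulate_genotypes(300, runif(6, 0.1, 0.4))
  E <- rbinom(300, 1, 0.5)
  y <- rnorm(300)  # nothing to find
  expect_warning(
    res <- weights_interaction_training(G, E, y, ratio = c(1, 1), seed = 33),
    "degenerate")
  expect_true(res$degenerate)
  expect_true(all(res$weights$weights == 0))
})
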