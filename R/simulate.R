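#' Scenario configuration for the simulation study
#'
#' Describes one simulated GxE study: `k_risk` dominant-acting risk SNPs
#' followed by `k_noise` noise SNPs (no effect), minor allele frequencies
#' drawn uniformly from `maf_range` (or fixed at `risk_maf` for the risk
#' SNPs), a Bernoulli(0.5) or standard-normal exposure, and a phenotype
#' generated under one of three scenarios:
#'
#' \describe{
#'   \item{`"predominant-interaction"`}{each risk SNP interacts with the
#'     exposure with effect `interaction_effect` (default 1.5) and carries
#'     no explicit main effect. With the Bernoulli(0.5) exposure this
#'     induces an implicit marginal effect of `interaction_effect / 2` per
#'     risk SNP (a smaller, not explicitly set, marginal effect).}
#'   \item{`"predominant-marginal"`}{each risk SNP has marginal effect
#'     `marginal_effect` (default 1.5) plus a smaller interaction of
#'     `secondary_effect_fraction * marginal_effect` (default 0.75).}
#'   \item{`"null"`}{marginal effects as in `"predominant-marginal"` but no
#'     interaction at all — the null hypothesis for type-I-error studies.}
#' }
#'
#' @param n number of samples.
#' @param k_risk number of risk SNPs (default 6).
#' @param k_noise number of noise SNPs (default 6).
#' @param maf_range range for uniform MAF draws (default `c(0.01, 0.45)`).
#' @param risk_maf optional fixed MAF applied to every risk SNP (MAF sweeps);
#'   noise-SNP MAFs stay random.
#' @param scenario `"predominant-interaction"`, `"predominant-marginal"` or
#'   `"null"` (aliases `"a"` and `"b"` are accepted).
#' @param interaction_effect interaction effect per risk SNP in the
#'   predominant-interaction scenario (default 1.5).
#' @param marginal_effect marginal effect per risk SNP in the
#'   predominant-marginal and null scenarios (default 1.5).
#' @param secondary_effect_fraction fraction of `marginal_effect` used as
#'   the secondary interaction effect in the predominant-marginal scenario
#'   (default 0.5).
#' @param exposure_dist `"bernoulli"` (Bernoulli(0.5), default) or
#'   `"normal"` (standard normal).
#' @param noise_sd standard deviation of the gaussian phenotype noise
#'   (default 1).
#' @param family `"gaussian"` (default) or `"binomial"` (phenotype drawn
#'   Bernoulli(logit^-1(linear predictor))).
#' @param risk_multiplier scalar or per-risk-SNP multiplier applied to the
#'   effects (used to make a study sample's effects larger than an external
#'   study's; default 1).
#' @param active_risk logical mask of length `k_risk`: which risk SNPs carry
#'   effects (used for overestimating external weights; default all).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n, k_risk = 6, k_noise = 6,
                            maf_range = c(0.01, 0.45), risk_maf = NULL,
                            scenario = c("predominant-interaction",
                                         "predominant-marginal", "null",
                                         "a", "b"),
                            interaction_effect = 1.5, marginal_effect = 1.5,
                            secondary_effect_fraction = 0.5,
                            exposure_dist = c("bernoulli", "normal"),
                            noise_sd = 1,
                            family = c("gaussian", "binomial"),
                            risk_multiplier = 1,
                            active_risk = NULL) {
  scenario <- match.arg(scenario)
  scenario <- switch(scenario, a = "predominant-interaction",
                     b = "predominant-marginal", scenario)
  exposure_dist <- match.arg(exposure_dist)
  family <- match.arg(family)
  stopifnot(n >= 1, k_risk >= 1, k_noise >= 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            noise_sd > 0,
            is.finite(interaction_effect), is.finite(marginal_effect))
  if (!is.null(risk_maf))
    stopifnot(all(risk_maf > 0), all(risk_maf <= 0.5))
  if (is.null(active_risk)) active_risk <- rep(TRUE, k_risk)
  stopifnot(length(active_risk) == k_risk)
  risk_multiplier <- rep_len(risk_multiplier, k_risk)
  structure(list(n = as.integer(n), k_risk = as.integer(k_risk),
                 k_noise = as.integer(k_noise),
                 maf_range = maf_range, risk_maf = risk_maf,
                 scenario = scenario,
                 interaction_effect = interaction_effect,
                 marginal_effect = marginal_effect,
                 secondary_effect_fraction = secondary_effect_fraction,
                 exposure_dist = exposure_dist, noise_sd = noise_sd,
                 family = family,
                 risk_multiplier = risk_multiplier,
                 active_risk = active_risk),
            class = "scenario_config")
}

#' Simulate independent SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Dosages are drawn independently per SNP as Binomial(2, MAF).
#'
#' @param n number of samples.
#' @param mafs vector of minor allele frequencies in (0, 0.5\].
#' @param seed optional integer seed.
#' @param snp_ids optional SNP ids (default `snp1..k`).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, mafs, seed = NULL, snp_ids = NULL) {
  if (any(mafs <= 0 | mafs > 0.5))
    stop("MAFs must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  k <- length(mafs)
  d <- vapply(mafs, function(p) rbinom(n, 2L, p), numeric(n))
  if (n == 1L) d <- matrix(d, nrow = 1L)
  genotype_matrix(d, snp_ids = snp_ids %||% paste0("snp", seq_len(k)))
}

#' Simulate an environmental exposure
#'
#' @param n number of samples.
#' @param dist `"bernoulli"` (Bernoulli(0.5)) or `"normal"` (standard
#'   normal).
#' @param seed optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_exposure <- function(n, dist = c("bernoulli", "normal"), seed = NULL) {
  dist <- match.arg(dist)
  if (!is.null(seed)) set.seed(seed)
  switch(dist,
         bernoulli = rbinom(n, 1L, 0.5),
         normal = rnorm(n))
}

# per-risk-SNP effect sizes implied by a scenario_config
scenario_effects <- function(cfg) {
  act <- as.numeric(cfg$active_risk) * cfg$risk_multiplier
  switch(cfg$scenario,
         "predominant-interaction" = list(
           marginal = rep(0, cfg$k_risk),
           interaction = cfg$interaction_effect * act),
         "predominant-marginal" = list(
           marginal = cfg$marginal_effect * act,
           interaction = cfg$secondary_effect_fraction * cfg$marginal_effect * act),
         "null" = list(
           marginal = cfg$marginal_effect * act,
           interaction = rep(0, cfg$k_risk)))
}

#' Simulate a phenotype from genotypes and exposure under a scenario
#'
#' Risk SNPs are the first `k_risk` columns of `G` by convention and act
#' dominantly: with `D_j` the dominant indicator of risk SNP j, the linear
#' predictor is `sum_j beta_j D_ij + sum_j delta_j D_ij E_i` with
#' `(beta, delta)` determined by the scenario (see [scenario_config()]).
#' Gaussian family adds N(0, noise_sd^2) noise; binomial family draws
#' Bernoulli(logit^-1(linear predictor)).
#'
#' @param G a [genotype_matrix()] with at least `cfg$k_risk` SNPs.
#' @param E exposure vector.
#' @param cfg a [scenario_config()].
#' @param seed optional integer seed (for the noise draw).
#' @return Numeric phenotype vector with attribute `"truth"`: a list with
#'   the per-risk-SNP `marginal` and `interaction` effects and
#'   `interaction_sign` (+1, -1 or 0).
#' @export
simulate_phenotype <- function(G, E, cfg, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "scenario_config"))
  n <- nrow(G$dosages)
  if (length(E) != n) stop("exposure length does not match genotype rows")
  if (cfg$k_risk > ncol(G$dosages))
    stop("k_risk exceeds the number of SNPs in G")
  if (!is.null(seed)) set.seed(seed)
  D <- recode_genotypes(G[, seq_len(cfg$k_risk)], "dominant")$dosages
  eff <- scenario_effects(cfg)
  lp <- drop(D %*% eff$marginal) + drop((D * E) %*% eff$interaction)
  y <- if (cfg$family == "gaussian")
    lp + rnorm(n, 0, cfg$noise_sd)
  else
    rbinom(n, 1L, plogis(lp))
  s <- sum(eff$interaction)
  attr(y, "truth") <- list(marginal = eff$marginal,
                           interaction = eff$interaction,
                           interaction_sign = sign(s))
  y
}

#' Simulate one complete study dataset under a scenario
#'
#' Draws MAFs, genotypes, exposure and phenotype in one call. Risk SNPs are
#' named `risk1..k_risk`, noise SNPs `noise1..k_noise`.
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of `(cfg, seed)`.
#' @param mafs optional vector of MAFs (length `k_risk + k_noise`) to reuse
#'   (e.g. shared between a study sample and a simulated external study);
#'   drawn from `cfg` when `NULL`.
#' @return List with `genotypes`, `exposure`, `phenotype`, `mafs`, `truth`.
#' @export
simulate_scenario <- function(cfg, seed = NULL, mafs = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  k <- cfg$k_risk + cfg$k_noise
  if (is.null(mafs)) {
    risk_mafs <- if (!is.null(cfg$risk_maf)) rep_len(cfg$risk_maf, cfg$k_risk)
    else runif(cfg$k_risk, cfg$maf_range[1], cfg$maf_range[2])
    noise_mafs <- if (cfg$k_noise > 0)
      runif(cfg$k_noise, cfg$maf_range[1], cfg$maf_range[2]) else numeric(0)
    mafs <- c(risk_mafs, noise_mafs)
  }
  stopifnot(length(mafs) == k)
  ids <- c(paste0("risk", seq_len(cfg$k_risk)),
           if (cfg$k_noise > 0) paste0("noise", seq_len(cfg$k_noise)))
  G <- simulate_genotypes(cfg$n, mafs, snp_ids = ids)
  E <- simulate_exposure(cfg$n, cfg$exposure_dist)
  y <- simulate_phenotype(G, E, cfg)
  list(genotypes = G, exposure = E, phenotype = as.numeric(y),
       mafs = mafs, truth = attr(y, "truth"))
}

#' Configuration of a simulated external weight study
#'
#' Controls how well simulated external weights fit the study sample:
#' \describe{
#'   \item{`"perfect"`}{the external study is drawn from exactly the same
#'     generating process as the study sample.}
#'   \item{`"underestimating"`}{the study sample's risk-SNP effects are
#'     `inflation` times (default 1.3, i.e. 30\% larger than) the external
#'     study's, so the external weights underestimate the sample effects.}
#'   \item{`"overestimating"`}{only `active_risk_snps_in_sample` (default
#'     1) of the external study's risk SNPs carry any effect in the study
#'     sample, so external weights overestimate the remaining SNPs.}
#' }
#'
#' @param mode `"perfect"`, `"underestimating"` or `"overestimating"`.
#' @param size_factor external sample size as a multiple of the study
#'   sample size (1 or 4 in the evaluated scenarios).
#' @param inflation effect inflation in the study sample for
#'   `"underestimating"` (default 1.3).
#' @param active_risk_snps_in_sample number of external risk SNPs with a
#'   real effect in the study sample for `"overestimating"` (default 1).
#' @return A list of class `external_study_config`.
#' @export
external_study_config <- function(mode = c("perfect", "underestimating",
                                           "overestimating"),
                                  size_factor = 1, inflation = 1.3,
                                  active_risk_snps_in_sample = 1) {
  mode <- match.arg(mode)
  stopifnot(size_factor >= 1, inflation > 0, active_risk_snps_in_sample >= 1)
  structure(list(mode = mode, size_factor = as.integer(size_factor),
                 inflation = inflation,
                 active_risk_snps_in_sample = as.integer(active_risk_snps_in_sample)),
            class = "external_study_config")
}

#' Simulate an external study and estimate external GRS weights from it
#'
#' Generates an external dataset of `size_factor * n` samples from the
#' sample-generating scenario, estimates each SNP's marginal genetic effect
#' by a univariate regression of the outcome on the (coded) dosage, and
#' returns those coefficients as an external weight vector. The returned
#' `sample_cfg` is the scenario the study sample itself should then be
#' generated from: identical for `"perfect"` weights, effect-inflated for
#' `"underestimating"`, and with most risk SNPs switched off for
#' `"overestimating"`.
#'
#' @param cfg an [external_study_config()].
#' @param sample_cfg the study sample's [scenario_config()].
#' @param seed optional integer seed.
#' @param mafs optional shared MAF vector (drawn when `NULL`); the study
#'   sample should reuse the returned `mafs` so both studies describe the
#'   same SNP panel.
#' @param coding coding used for the marginal-effect regressions (default
#'   `"dominant"`, matching the generating model).
#' @return List with `weights` (a [weight_vector()], provenance
#'   `"external"`), `external` (list `genotypes`, `exposure`, `phenotype`),
#'   `mafs` and `sample_cfg` (possibly modified copy).
#' @export
simulate_external_weights <- function(cfg, sample_cfg, seed = NULL,
                                      mafs = NULL,
                                      coding = c("dominant", "additive",
                                                 "recessive")) {
  stopifnot(inherits(cfg, "external_study_config"),
            inherits(sample_cfg, "scenario_config"))
  coding <- match.arg(coding)
  if (!is.null(seed)) set.seed(seed)
  ext_cfg <- sample_cfg
  ext_cfg$n <- sample_cfg$n * cfg$size_factor
  # the external study always carries the full, uninflated effects
  ext_cfg$risk_multiplier <- rep(1, ext_cfg$k_risk)
  ext_cfg$active_risk <- rep(TRUE, ext_cfg$k_risk)
  ext <- simulate_scenario(ext_cfg, mafs = mafs)

  Gc <- recode_genotypes(ext$genotypes, coding)
  w <- apply(Gc$dosages, 2L, function(g) {
    if (var(g) == 0) return(0)
    unname(coef(lm(ext$phenotype ~ g))[2L])
  })
  out_cfg <- sample_cfg
  if (cfg$mode == "underestimating") {
    out_cfg$risk_multiplier <- rep(cfg$inflation, sample_cfg$k_risk)
  } else if (cfg$mode == "overestimating") {
    act <- rep(FALSE, sample_cfg$k_risk)
    act[seq_len(min(cfg$active_risk_snps_in_sample, sample_cfg$k_risk))] <- TRUE
    out_cfg$active_risk <- act
  }
  list(weights = weight_vector(w, Gc$snp_ids, provenance = "external",
                               scale_note = sprintf(
                                 "univariate marginal effects, %s coding, external n = %d",
                                 coding, ext_cfg$n)),
       external = ext, mafs = ext$mafs, sample_cfg = out_cfg)
}
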