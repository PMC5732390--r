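#' Monte-Carlo standard error of an estimated proportion
#'
#' `sqrt(p (1 - p) / R)` — the binomial standard error of a power,
#' type-I-error or sign-misspecification estimate based on R replications.
#' At p = 0.9 and R = 100 this is 0.03, i.e. about three percentage points.
#'
#' @param p proportion in \[0, 1\].
#' @param R number of replications (>= 1).
#' @return The standard error (same scale as `p`).
#' @export
mc_standard_error <- function(p, R) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(R < 1)) stop("R must be >= 1")
  sqrt(p * (1 - p) / R)
}

#' Bonferroni adjustment for single-SNP interaction reports
#'
#' Reporting utility for per-SNP analyses alongside a GRS analysis: raw
#' p-values multiplied by the number of SNPs tested, capped at 1. The GRS
#' pipeline itself performs a single interaction test per sample and needs
#' no correction.
#'
#' @param p vector of raw p-values.
#' @param m number of tests (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  pmin(p * m, 1)
}

# derive per-replicate seeds from the master seed; prefix-stable so that
# extending R keeps the first replicates identical
replicate_seeds <- function(seed, R) {
  set.seed(seed)
  sample.int(2147483646L, R, replace = TRUE)
}

classify_replicate <- function(fit, truth_sign, level) {
  if (fit$degenerate)
    return(list(class = "degenerate", p = NA_real_, est = NA_real_))
  p <- fit$test$p_value
  est <- fit$test$estimate
  cls <- if (p >= level) "non-significant"
  else if (truth_sign == 0) "significant"       # null scenario: any rejection
  else if (sign(est) == truth_sign) "true-positive"
  else "sign-misspecified"
  list(class = cls, p = p, est = est)
}

#' Run replicated simulations through a weighting pipeline
#'
#' For each of `R` replicates: simulate a dataset under `scenario_cfg`,
#' build GRS weights by the chosen regime, test the GRSxE interaction (on
#' the disjoint test split for interaction-training; on the full sample
#' otherwise) and classify the result as true-positive (p below `level`
#' with the correct interaction sign), sign-misspecified (significant,
#' wrong sign) or non-significant. Replicates with a degenerate
#' (constant) GRS are counted as non-significant and tallied separately,
#' never dropped. Power is the true-positive proportion; under the null
#' scenario `type1_error` is the proportion significant regardless of
#' sign.
#'
#' Replicate seeds are derived from `seed` by a fixed stream, so two runs
#' with identical configuration and seed are identical, runs with larger
#' `R` extend smaller ones, and different methods or ratios evaluated at
#' the same master seed see identical simulated datasets (common random
#' numbers).
#'
#' @param scenario_cfg a [scenario_config()].
#' @param method weighting regime (see [grs_gxe()]).
#' @param R number of replications.
#' @param seed master integer seed.
#' @param ratio train:test ratio for interaction-training.
#' @param alpha elastic-net mixing parameter.
#' @param cv_folds CV folds for the penalized fits.
#' @param coding mode-of-inheritance coding used for weighting and scoring
#'   (default `"dominant"`, matching the generating model).
#' @param external_cfg an [external_study_config()] (external method only;
#'   defaults to perfect weights, size factor 1).
#' @param level significance threshold (default 0.05, two-sided).
#' @return An object of class `evaluation_summary`: list with `method`,
#'   `scenario`, `replications`, `power`, `type1_error` (`NA` unless null
#'   scenario), `sign_misspec`, `significant_fraction`, `n_degenerate`,
#'   `ratio`, `level`, `config_hash`, `seed`, plus per-replicate
#'   `classifications` and `p_values`.
#' @export
run_replications <- function(scenario_cfg, method = c("interaction-training",
                                                      "marginal-internal",
                                                      "external"),
                             R, seed, ratio = c(1, 1), alpha = 0.5,
                             cv_folds = 10,
                             coding = c("dominant", "additive", "recessive"),
                             external_cfg = NULL, level = 0.05) {
  method <- match.arg(method)
  coding <- match.arg(coding)
  stopifnot(inherits(scenario_cfg, "scenario_config"), R >= 1)
  if (method == "external" && is.null(external_cfg))
    external_cfg <- external_study_config("perfect")

  seeds <- replicate_seeds(seed, R)
  cls <- character(R)
  pvals <- numeric(R)

  for (r in seq_len(R)) {
    if (method == "external") {
      ext <- simulate_external_weights(external_cfg, scenario_cfg,
                                       seed = seeds[r], coding = coding)
      dat <- simulate_scenario(ext$sample_cfg, mafs = ext$mafs)
      fit <- grs_gxe(dat$genotypes, dat$exposure, dat$phenotype,
                     method = "external", weights = ext$weights,
                     coding = coding, family = scenario_cfg$family,
                     seed = seeds[r])
    } else {
      dat <- simulate_scenario(scenario_cfg, seed = seeds[r])
      fit <- grs_gxe(dat$genotypes, dat$exposure, dat$phenotype,
                     method = method, coding = coding,
                     family = scenario_cfg$family, ratio = ratio,
                     alpha = alpha, cv_folds = cv_folds, seed = seeds[r])
    }
    res <- classify_replicate(fit, dat$truth$interaction_sign, level)
    cls[r] <- res$class
    pvals[r] <- res$p
  }

  is_null_scenario <- scenario_cfg$scenario == "null"
  sig <- mean(cls %in% c("true-positive", "sign-misspecified", "significant"))
  power <- mean(cls == "true-positive")
  sign_misspec <- mean(cls == "sign-misspecified")

  cfg_for_hash <- list(scenario = unclass(scenario_cfg), method = method,
                       ratio = ratio, alpha = alpha, cv_folds = cv_folds,
                       coding = coding, level = level, R = R, seed = seed)
  structure(list(method = method,
                 scenario = scenario_cfg$scenario,
                 replications = as.integer(R),
                 power = if (is_null_scenario) NA_real_ else power,
                 type1_error = if (is_null_scenario) sig else NA_real_,
                 sign_misspec = if (is_null_scenario) NA_real_ else sign_misspec,
                 significant_fraction = sig,
                 n_degenerate = sum(cls == "degenerate"),
                 ratio = paste(ratio, collapse = ":"),
                 level = level,
                 config_hash = config_hash(cfg_for_hash),
                 seed = as.integer(seed),
                 truth_sign = if (is_null_scenario) 0L else 1L,
                 classifications = cls,
                 p_values = pvals),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("evaluation_summary: %s | %s | ratio %s | R = %d\n",
              x$method, x$scenario, x$ratio, x$replications))
  if (!is.na(x$power))
    cat(sprintf("  power = %.3f (MC SE %.3f), sign-misspec = %.3f, significant = %.3f\n",
                x$power, mc_standard_error(x$power, x$replications),
                x$sign_misspec, x$significant_fraction))
  if (!is.na(x$type1_error))
    cat(sprintf("  type I error = %.3f (MC SE %.3f)\n",
                x$type1_error, mc_standard_error(x$type1_error, x$replications)))
  if (x$n_degenerate > 0)
    cat(sprintf("  degenerate-GRS replicates: %d\n", x$n_degenerate))
  invisible(x)
}

#' @export
as.data.frame.evaluation_summary <- function(x, ...) {
  data.frame(method = x$method, scenario = x$scenario,
             ratio = x$ratio, replications = x$replications,
             power = x$power, type1_error = x$type1_error,
             sign_misspec = x$sign_misspec,
             significant_fraction = x$significant_fraction,
             n_degenerate = x$n_degenerate, level = x$level,
             config_hash = x$config_hash, seed = x$seed,
             stringsAsFactors = FALSE)
}

summaries_to_table <- function(lst, extra = NULL) {
  tab <- do.call(rbind, lapply(lst, as.data.frame))
  if (!is.null(extra)) tab <- cbind(extra, tab)
  rownames(tab) <- NULL
  tab
}

#' Sweep the train:test balance of the interaction-training approach
#'
#' Evaluates [run_replications()] for the interaction-training regime at a
#' series of train:test ratios. All ratios share the same master seed and
#' hence identical simulated datasets (common random numbers), which
#' sharpens between-ratio comparisons.
#'
#' @param ratios list of integer pairs, e.g. `list(c(19, 1), c(1, 1),
#'   c(1, 19))`.
#' @inheritParams run_replications
#' @return A data.frame with one row per ratio (columns as in
#'   `as.data.frame.evaluation_summary`). The full summaries are attached
#'   as attribute `"summaries"`, keyed by ratio string.
#' @export
sweep_balance <- function(ratios, scenario_cfg, R, seed, alpha = 0.5,
                          cv_folds = 10, coding = "dominant", level = 0.05) {
  stopifnot(length(ratios) >= 1)
  sums <- lapply(ratios, function(rt)
    run_replications(scenario_cfg, method = "interaction-training", R = R,
                     seed = seed, ratio = rt, alpha = alpha,
                     cv_folds = cv_folds, coding = coding, level = level))
  names(sums) <- vapply(ratios, paste, "", collapse = ":")
  tab <- summaries_to_table(sums)
  attr(tab, "summaries") <- sums
  tab
}

#' Sweep the risk-SNP minor allele frequency
#'
#' Fixes all risk-SNP MAFs to each value of `maf_values` in turn (noise-SNP
#' MAFs stay random) and evaluates each weighting method. Methods and MAF
#' values share the master seed (common random numbers across methods at
#' each MAF).
#'
#' @param maf_values numeric vector of MAFs in (0, 0.5\].
#' @param methods character vector of weighting regimes.
#' @inheritParams run_replications
#' @return A data.frame with `length(maf_values) * length(methods)` rows,
#'   with a `maf` column; full summaries attached as attribute
#'   `"summaries"`.
#' @export
sweep_maf <- function(maf_values, scenario_cfg,
                      methods = c("interaction-training", "marginal-internal"),
                      R, seed, ratio = c(1, 1), alpha = 0.5, cv_folds = 10,
                      coding = "dominant", external_cfg = NULL, level = 0.05) {
  stopifnot(length(maf_values) >= 1, all(maf_values > 0 & maf_values <= 0.5))
  grid <- expand.grid(maf = maf_values, method = methods,
                      stringsAsFactors = FALSE)
  sums <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- scenario_cfg
    cfg$risk_maf <- grid$maf[i]
    sums[[i]] <- run_replications(cfg, method = grid$method[i], R = R,
                                  seed = seed, ratio = ratio, alpha = alpha,
                                  cv_folds = cv_folds, coding = coding,
                                  external_cfg = external_cfg, level = level)
  }
  names(sums) <- paste(grid$method, grid$maf, sep = "@")
  tab <- summaries_to_table(sums, extra = data.frame(maf = grid$maf))
  attr(tab, "summaries") <- sums
  tab
}
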