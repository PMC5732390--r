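#' Wald test of the GRSxE interaction in a generalized linear model
#'
#' Fits `y ~ GRS + E + GRS:E (+ covariates)` by maximum likelihood
#' (gaussian: identity link; binomial: logit link) and reports the Wald
#' estimate, standard error and two-sided p-value for the GRSxE product
#' term. Gaussian inference uses the t reference with residual degrees of
#' freedom; binomial inference uses the normal reference.
#'
#' @param grs a `grs_vector` from [compute_grs()] or a plain numeric vector.
#' @param E numeric exposure vector.
#' @param y outcome vector (numeric, or 0/1 for binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param covariates optional numeric matrix or data.frame of adjustment
#'   covariates (entered additively).
#' @return An object of class `gxe_test`: list with `estimate`, `std_error`,
#'   `p_value`, `sign` (`"+"`, `"-"` or `"0"`), `statistic`, `df`
#'   (residual df, gaussian only), `family`, `n_used`, `covariate_names`,
#'   `converged`.
#' @examples
#' set.seed(1)
#' grs <- rnorm(50); E <- rbinom(50, 1, 0.5)
#' y <- 1 + 2 * grs + 3 * E + 4 * grs * E + rnorm(50, sd = 0.1)
#' test_grs_by_e(grs, E, y)
#' @export
test_grs_by_e <- function(grs, E, y, family = c("gaussian", "binomial"),
                          covariates = NULL) {
  family <- match.arg(family)
  g <- if (inherits(grs, "grs_vector")) unname(grs$values) else as.numeric(grs)
  E <- as.numeric(E)
  y <- as.numeric(y)
  if (length(g) != length(E) || length(g) != length(y))
    stop("grs, E and y must have the same length")
  if (family == "binomial" && !all(y[!is.na(y)] %in% c(0, 1)))
    stop("binomial family requires a 0/1 outcome")

  dat <- data.frame(.y = y, .grs = g, .E = E)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_names <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n_used <- nrow(dat)
  if (n_used < length(cov_names) + 5L)
    stop("too few complete observations for the interaction model")
  if (var(dat$.grs) == 0)
    stop("degenerate GRS: the risk score is constant, the GRSxE interaction cannot be tested")
  if (var(dat$.E) == 0)
    stop("constant exposure: the GRSxE interaction cannot be tested")

  rhs <- paste(c(".grs * .E", cov_names), collapse = " + ")
  fml <- as.formula(paste(".y ~", rhs))

  if (family == "gaussian") {
    fit <- lm(fml, data = dat)
    check_rank(fit)
    sm <- summary(fit)$coefficients
    row <- sm[".grs:.E", ]
    estimate <- unname(row[1L]); se <- unname(row[2L])
    stat <- unname(row[3L]); p <- unname(row[4L])
    df <- fit$df.residual
    converged <- TRUE
  } else {
    fit <- suppressWarnings(glm(fml, data = dat, family = stats::binomial()))
    check_rank(fit)
    sm <- summary(fit)$coefficients
    row <- sm[".grs:.E", ]
    estimate <- unname(row[1L]); se <- unname(row[2L])
    stat <- unname(row[3L]); p <- unname(row[4L])
    df <- NA_integer_
    # huge SEs flag quasi-separation / non-convergence
    converged <- fit$converged && is.finite(se) && se < 1e3 * (abs(estimate) + 1)
  }

  structure(list(estimate = estimate,
                 std_error = se,
                 statistic = stat,
                 p_value = p,
                 sign = if (estimate > 0) "+" else if (estimate < 0) "-" else "0",
                 df = df,
                 family = family,
                 n_used = n_used,
                 covariate_names = cov_names,
                 converged = converged,
                 model = fit),
            class = "gxe_test")
}

check_rank <- function(fit) {
  a <- is.na(coef(fit))
  if (any(a))
    stop("rank-deficient interaction model; collinear columns: ",
         paste(names(coef(fit))[a], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.gxe_test <- function(x, ...) {
  cat(sprintf("GRSxE interaction Wald test (%s family, n = %d)\n",
              x$family, x$n_used))
  cat(sprintf("  estimate = %.4g  SE = %.4g  %s = %.3f  p = %.4g  sign %s\n",
              x$estimate, x$std_error,
              if (x$family == "gaussian") "t" else "z",
              x$statistic, x$p_value, x$sign))
  if (!x$converged) cat("  WARNING: model did not converge cleanly\n")
  if (length(x$covariate_names))
    cat("  adjusted for:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a weighted-GRS gene-environment interaction model
#'
#' The top-level modelling interface: builds a weighted genetic risk score
#' under one of three weighting regimes and tests its interaction with an
#' environmental exposure in a GLM.
#'
#' \describe{
#'   \item{`"external"`}{weights supplied by the caller (e.g. log odds
#'     ratios from an independent study); scored and tested on the full
#'     sample.}
#'   \item{`"marginal-internal"`}{penalized marginal SNP effects estimated
#'     on the full sample serve as weights; scored and tested on the full
#'     sample.}
#'   \item{`"interaction-training"`}{the sample is split `ratio`
#'     train:test; penalized SNPxE interaction coefficients estimated on
#'     the training part serve as weights; the score is formed and the
#'     GRSxE interaction tested on the disjoint test part only.}
#' }
#'
#' @param genotypes a [genotype_matrix()].
#' @param exposure numeric exposure vector, one value per sample.
#' @param outcome outcome vector (numeric, or 0/1 for `family =
#'   "binomial"`).
#' @param method weighting regime; see Details.
#' @param weights a [weight_vector()] (required for `method = "external"`,
#'   ignored otherwise).
#' @param coding mode-of-inheritance recode applied to the dosages before
#'   weighting and scoring; `"additive"` (default), `"dominant"` or
#'   `"recessive"`.
#' @param family `"gaussian"` or `"binomial"`.
#' @param ratio train:test split ratio for `"interaction-training"`.
#' @param alpha elastic-net mixing parameter for the internal regimes.
#' @param cv_folds CV folds for the penalized fits.
#' @param penalize_env penalize the exposure main effect in the
#'   interaction-training fit (default `TRUE`).
#' @param covariates optional covariate matrix/data.frame for the GLM
#'   (rows matching the tested samples are selected automatically).
#' @param seed integer seed controlling the split and CV folds.
#' @return An object of class `grs_gxe`: list with `method`, `weights`,
#'   `grs`, `test` (a `gxe_test`, or `NULL` if degenerate), `split`
#'   (interaction-training only), `fit` (the `penalized_fit`, internal
#'   regimes only), `degenerate`, `coding`, `family`, `n`, `n_tested`,
#'   `call`.
#' @examples
#' set.seed(42)
#' G <- simulate_genotypes(400, mafs = runif(12, 0.05, 0.45))
#' E <- simulate_exposure(400, "bernoulli")
#' y <- drop(recode_genotypes(G, "dominant")$dosages[, 1:3] %*% rep(1.5, 3)) * E +
#'   rnorm(400)
#' fit <- grs_gxe(G, E, y, method = "interaction-training",
#'                coding = "dominant", seed = 7)
#' print(fit)
#' @export
grs_gxe <- function(genotypes, exposure, outcome,
                    method = c("interaction-training", "marginal-internal",
                               "external"),
                    weights = NULL,
                    coding = c("additive", "dominant", "recessive"),
                    family = c("gaussian", "binomial"),
                    ratio = c(1, 1), alpha = 0.5, cv_folds = 10,
                    penalize_env = TRUE, covariates = NULL, seed = NULL) {
  method <- match.arg(method)
  coding <- match.arg(coding)
  family <- match.arg(family)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$dosages)
  if (length(exposure) != n || length(outcome) != n)
    stop("exposure and outcome must have one value per sample")

  Gc <- recode_genotypes(genotypes, coding)
  split <- NULL
  fit <- NULL
  degenerate <- FALSE

  if (method == "external") {
    if (is.null(weights)) stop("method = \"external\" requires a weight_vector")
    w <- align_weights(weights, Gc$snp_ids)
    test_idx <- seq_len(n)
  } else if (method == "marginal-internal") {
    res <- weights_marginal_internal(Gc, outcome, alpha = alpha,
                                     cv_folds = cv_folds, seed = seed,
                                     family = family)
    w <- res$weights
    fit <- res$fit
    test_idx <- seq_len(n)
  } else {
    res <- withCallingHandlers(
      weights_interaction_training(Gc, exposure, outcome, ratio = ratio,
                                   alpha = alpha, cv_folds = cv_folds,
                                   seed = seed, family = family,
                                   penalize_env = penalize_env),
      warning = function(wrn) {
        if (grepl("degenerate GRS", conditionMessage(wrn)))
          invokeRestart("muffleWarning")
      })
    w <- res$weights
    fit <- res$fit
    split <- res$split
    test_idx <- split$test_indices
  }

  grs <- compute_grs(Gc[test_idx, ], w)
  degenerate <- var(grs$values, na.rm = TRUE) == 0
  test <- NULL
  if (!degenerate) {
    cov_sub <- if (!is.null(covariates))
      as.data.frame(covariates)[test_idx, , drop = FALSE]
    test <- test_grs_by_e(grs, exposure[test_idx], outcome[test_idx],
                          family = family, covariates = cov_sub)
  }

  structure(list(method = method, weights = w, grs = grs, test = test,
                 split = split, fit = fit, degenerate = degenerate,
                 coding = coding, family = family,
                 n = n, n_tested = length(test_idx),
                 alpha = alpha, ratio = if (method == "interaction-training") ratio,
                 seed = seed, call = match.call()),
            class = "grs_gxe")
}

#' @export
print.grs_gxe <- function(x, ...) {
  cat("Weighted-GRS gene-environment interaction model\n")
  cat(sprintf("  weighting: %s | coding: %s | family: %s\n",
              x$method, x$coding, x$family))
  if (!is.null(x$split))
    cat(sprintf("  split %d:%d — train n = %d, test n = %d\n",
                x$ratio[1], x$ratio[2],
                length(x$split$train_indices), length(x$split$test_indices)))
  else
    cat(sprintf("  scored and tested on the full sample (n = %d)\n", x$n))
  if (x$degenerate) {
    cat("  DEGENERATE GRS: all weights zero / constant score; no test performed\n")
  } else {
    cat(sprintf("  GRSxE: estimate = %.4g, SE = %.4g, p = %.4g (sign %s)\n",
                x$test$estimate, x$test$std_error, x$test$p_value, x$test$sign))
  }
  invisible(x)
}

#' @export
summary.grs_gxe <- function(object, ...) {
  w <- object$weights$weights
  out <- list(method = object$method,
              coding = object$coding,
              family = object$family,
              n = object$n,
              n_tested = object$n_tested,
              n_snps = length(w),
              n_nonzero_weights = sum(w != 0),
              weights = w,
              degenerate = object$degenerate,
              test = object$test)
  class(out) <- "summary.grs_gxe"
  out
}

#' @export
print.summary.grs_gxe <- function(x, ...) {
  cat(sprintf("grs_gxe summary — %s weights, %s coding, %s family\n",
              x$method, x$coding, x$family))
  cat(sprintf("  samples: %d total, %d tested; SNPs: %d (%d nonzero weights)\n",
              x$n, x$n_tested, x$n_snps, x$n_nonzero_weights))
  cat("  weights:\n")
  print(round(x$weights, 4))
  if (x$degenerate) cat("  degenerate GRS — no interaction test\n") else print(x$test)
  invisible(x)
}

#' @export
coef.grs_gxe <- function(object, ...) {
  if (object$degenerate) return(NULL)
  coef(object$test$model)
}
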