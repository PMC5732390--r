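#' @importFrom stats coef predict rnorm rbinom runif var sd lm glm pt pnorm
#'   as.formula setNames plogis
NULL

as_dosage_matrix <- function(G) {
  if (inherits(G, "genotype_matrix")) G$dosages
  else as.matrix(G)
}

# glmnet fit at a fixed lambda (including 0), with the target lambda placed
# on the path so no interpolation is involved; tight threshold because these
# fits back oracle comparisons.
glmnet_fixed_lambda <- function(x, y, alpha, lambda, family, penalty.factor) {
  fit0 <- glmnet::glmnet(x, y, alpha = alpha, family = family,
                         penalty.factor = penalty.factor)
  path <- fit0$lambda
  path <- path[path > max(lambda, 1e-8)]
  lambda_seq <- c(path, if (lambda > 0) lambda else c(min(c(path, 1)) / 10, 0))
  fit <- glmnet::glmnet(x, y, alpha = alpha, family = family,
                        lambda = lambda_seq, thresh = 1e-14, maxit = 1e6,
                        penalty.factor = penalty.factor)
  list(fit = fit, s = lambda)
}

penalized_fit_result <- function(beta_all, intercept, k, has_env, alpha,
                                 lambda_chosen, lambda_rule, cv_folds,
                                 lambda_path, family, n, snp_ids, glmnet_fit) {
  snp_main <- setNames(beta_all[seq_len(k)], snp_ids)
  env_main <- NULL
  snp_env <- NULL
  if (has_env) {
    env_main <- unname(beta_all[k + 1L])
    snp_env <- setNames(beta_all[(k + 2L):(2L * k + 1L)], snp_ids)
  }
  structure(list(intercept = unname(intercept),
                 snp_main = snp_main,
                 env_main = env_main,
                 snp_env_interaction = snp_env,
                 alpha = alpha,
                 lambda_chosen = lambda_chosen,
                 lambda_rule = lambda_rule,
                 cv_folds = cv_folds,
                 lambda_path = lambda_path,
                 family = family,
                 n = n,
                 glmnet = glmnet_fit),
            class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  k <- length(x$snp_main)
  cat(sprintf("penalized_fit (%s, alpha = %.2f): %d SNPs%s, n = %d\n",
              x$family, x$alpha, k,
              if (!is.null(x$snp_env_interaction)) " + exposure + SNPxE terms" else "",
              x$n))
  cat(sprintf("  lambda = %.6g (%s)\n", x$lambda_chosen, x$lambda_rule))
  nz <- sum(x$snp_main != 0)
  cat(sprintf("  nonzero SNP main effects: %d/%d\n", nz, k))
  if (!is.null(x$snp_env_interaction))
    cat(sprintf("  nonzero SNPxE interactions: %d/%d\n",
                sum(x$snp_env_interaction != 0), k))
  invisible(x)
}

#' @export
coef.penalized_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$snp_main,
    if (!is.null(object$env_main)) c(E = object$env_main),
    if (!is.null(object$snp_env_interaction))
      setNames(object$snp_env_interaction,
               paste0(names(object$snp_env_interaction), ":E")))
}

# Elastic-net objective on the 1/(2n) loss scale used throughout:
#   1/(2n) * RSS + lambda * sum_j pf_j * (0.5*(1-alpha)*b_j^2 + alpha*|b_j|)
# (gaussian family; used by tests for objective monotonicity checks)
penalized_objective <- function(intercept, beta, x, y, lambda, alpha,
                                penalty.factor = rep(1, length(beta))) {
  n <- length(y)
  rss <- sum((y - intercept - drop(x %*% beta))^2)
  pen <- sum(penalty.factor * (0.5 * (1 - alpha) * beta^2 + alpha * abs(beta)))
  rss / (2 * n) + lambda * pen
}

elastic_net_fit <- function(x, y, alpha, cv_folds, seed, family, lambda,
                            penalty.factor = rep(1, ncol(x))) {
  n <- nrow(x)
  force(penalty.factor)
  # glmnet requires >= 2 columns; pad single-predictor fits with a zero
  # column whose coefficient is necessarily zero, then drop it
  padded <- ncol(x) == 1L
  if (padded) {
    x <- cbind(x, .pad = 0)
    penalty.factor <- c(penalty.factor, 1)
  }
  strip_pad <- function(res) {
    if (padded) res$beta <- res$beta[-length(res$beta)]
    res
  }
  if (!is.null(lambda)) {
    fx <- glmnet_fixed_lambda(x, y, alpha, lambda, family, penalty.factor)
    cf <- as.numeric(coef(fx$fit, s = fx$s))
    return(strip_pad(list(intercept = cf[1L], beta = cf[-1L],
                          lambda_chosen = lambda, lambda_rule = "fixed",
                          lambda_path = fx$fit$lambda, glmnet = fx$fit)))
  }
  if (!is.null(seed)) set.seed(seed)
  foldid <- sample(rep(seq_len(cv_folds), length.out = n))
  # The CV-selected lambda (min or 1-SE) sits near the top of the default
  # path; truncating the path at lambda_max/100 and thinning it to 50
  # values leaves the selection essentially unchanged while skipping the
  # dense small-lambda fits. Selection fits use a relaxed convergence
  # threshold; fixed-lambda (oracle-grade) fits use a tight one instead.
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(x, y, alpha = alpha, family = family,
                      foldid = foldid, penalty.factor = penalty.factor,
                      nlambda = 50, lambda.min.ratio = 0.01,
                      thresh = 1e-5),
    warning = function(w) {
      # tiny training subsets (extreme train:test ratios) trip glmnet's
      # small-class advisory; degenerate fits are handled downstream
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- as.numeric(coef(cv, s = "lambda.1se"))
  strip_pad(list(intercept = cf[1L], beta = cf[-1L],
                 lambda_chosen = cv$lambda.1se, lambda_rule = "within-1SE-of-min",
                 lambda_path = cv$lambda, glmnet = cv))
}

#' Penalized fit of marginal SNP effects (elastic net)
#'
#' Estimates intercept and per-SNP coefficients by minimizing the penalized
#' residual sum of squares with the elastic-net penalty
#' `lambda * sum_j (0.5*(1-alpha)*beta_j^2 + alpha*|beta_j|)`. `alpha = 1`
#' is the lasso, `alpha = 0` ridge regression. Following glmnet, the loss is
#' scaled by `1/(2n)`, predictors are standardized internally and
#' coefficients returned on the original dosage scale. When `lambda` is
#' `NULL`, it is chosen by K-fold cross-validation as the largest lambda
#' whose mean CV error is within one standard error of the minimum.
#'
#' @param G a [genotype_matrix()] or plain dosage matrix (recode beforehand
#'   for non-additive modes of inheritance).
#' @param y numeric outcome vector (gaussian family) or 0/1 vector
#'   (binomial family, penalized logistic deviance in place of RSS).
#' @param alpha elastic-net mixing parameter in \[0, 1\]; default 0.5.
#' @param cv_folds number of CV folds (default 10).
#' @param seed integer seed controlling the CV fold assignment.
#' @param family `"gaussian"` (default) or `"binomial"`.
#' @param lambda optional fixed penalty value (skips CV); `0` gives the
#'   unpenalized (maximum-likelihood) fit.
#' @return An object of class `penalized_fit` with elements `intercept`,
#'   `snp_main` (named coefficient vector), `alpha`, `lambda_chosen`,
#'   `lambda_rule`, `cv_folds`, `lambda_path`.
#' @export
fit_penalized_marginal <- function(G, y, alpha = 0.5, cv_folds = 10,
                                   seed = NULL, family = c("gaussian", "binomial"),
                                   lambda = NULL) {
  family <- match.arg(family)
  x <- as_dosage_matrix(G)
  y <- as.numeric(y)
  check_penalized_inputs(x, y, alpha, cv_folds, lambda, family)
  fit <- elastic_net_fit(x, y, alpha, cv_folds, seed, family, lambda)
  penalized_fit_result(fit$beta, fit$intercept, ncol(x), has_env = FALSE,
                       alpha, fit$lambda_chosen, fit$lambda_rule,
                       if (is.null(lambda)) cv_folds else NA_integer_,
                       fit$lambda_path, family, nrow(x),
                       colnames(x) %||% paste0("snp", seq_len(ncol(x))),
                       fit$glmnet)
}

check_penalized_inputs <- function(x, y, alpha, cv_folds, lambda, family) {
  if (length(y) != nrow(x)) stop("length of y does not match number of samples")
  if (var(y) == 0) stop("outcome y is constant; nothing to fit")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (is.null(lambda)) {
    if (cv_folds < 3) stop("cv_folds must be >= 3")
    if (nrow(x) <= cv_folds) stop("need n > cv_folds samples for cross-validation")
  }
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial family requires a 0/1 outcome")
  invisible(TRUE)
}

#' Penalized joint fit of SNP, exposure and SNPxE interaction effects
#'
#' Fits intercept, k SNP main effects, the exposure main effect and k
#' product (SNP x exposure) terms in one elastic-net regression. Product
#' columns are formed on the dosage scale first and then standardized like
#' any other predictor. All of the SNP, exposure and interaction
#' coefficients are penalized; set `penalize_env = FALSE` to exempt the
#' exposure main effect from the penalty. The interaction coefficients
#' (`snp_env_interaction`) are the weight candidates for the
#' interaction-training GRS.
#'
#' An all-zero exposure is accepted as a degenerate reference case (the
#' exposure and product columns are then zero predictors and the SNP
#' coefficient path reduces to the marginal fit); any other constant
#' exposure is an error because the interaction is unidentifiable.
#'
#' @inheritParams fit_penalized_marginal
#' @param E numeric exposure vector.
#' @param penalize_env penalize the exposure main effect (default `TRUE`).
#' @return A `penalized_fit` with `env_main` and `snp_env_interaction`
#'   filled in.
#' @export
fit_penalized_interaction <- function(G, E, y, alpha = 0.5, cv_folds = 10,
                                      seed = NULL,
                                      family = c("gaussian", "binomial"),
                                      lambda = NULL, penalize_env = TRUE) {
  family <- match.arg(family)
  x <- as_dosage_matrix(G)
  E <- as.numeric(E)
  if (length(E) != nrow(x)) stop("length of E does not match number of samples")
  if (var(E) == 0 && any(E != 0))
    stop("exposure E is constant; the interaction is unidentifiable")
  y <- as.numeric(y)
  check_penalized_inputs(x, y, alpha, cv_folds, lambda, family)
  k <- ncol(x)
  snp_ids <- colnames(x) %||% paste0("snp", seq_len(k))
  xe <- x * E
  xx <- cbind(x, E, xe)
  colnames(xx) <- c(snp_ids, "E", paste0(snp_ids, ":E"))
  pf <- rep(1, ncol(xx))
  if (!penalize_env) pf[k + 1L] <- 0
  fit <- elastic_net_fit(xx, y, alpha, cv_folds, seed, family, lambda,
                         penalty.factor = pf)
  penalized_fit_result(fit$beta, fit$intercept, k, has_env = TRUE,
                       alpha, fit$lambda_chosen, fit$lambda_rule,
                       if (is.null(lambda)) cv_folds else NA_integer_,
                       fit$lambda_path, family, nrow(x), snp_ids, fit$glmnet)
}

#' Random train/test split of n samples at a given ratio
#'
#' @param n number of samples.
#' @param ratio integer pair `c(train, test)`; e.g. `c(1, 1)` for an even
#'   split, `c(1, 3)` for a training set a third the size of the test set.
#' @param seed integer seed for the uniform random partition.
#' @return An object of class `split_plan`: list with sorted integer index
#'   vectors `train_indices` and `test_indices` (a disjoint partition of
#'   `1:n`), `ratio` and `seed`. `|train| = round(n * r_train / (r_train +
#'   r_test))`.
#' @export
make_split <- function(n, ratio = c(1, 1), seed = NULL) {
  ratio <- as.integer(ratio)
  if (length(ratio) != 2L || any(is.na(ratio)) || any(ratio < 1L))
    stop("ratio must be two positive integers")
  if (n < sum(ratio)) stop("n is smaller than the sum of the ratio parts")
  n_train <- round(n * ratio[1L] / sum(ratio))
  if (n_train == 0L || n_train == n)
    stop("degenerate split: one part would be empty")
  if (!is.null(seed)) set.seed(seed)
  train <- sort(sample.int(n, n_train))
  structure(list(train_indices = train,
                 test_indices = setdiff(seq_len(n), train),
                 ratio = ratio, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan %d:%d — train n = %d, test n = %d\n",
              x$ratio[1], x$ratio[2],
              length(x$train_indices), length(x$test_indices)))
  invisible(x)
}

#' GRS weights from internal marginal SNP effects
#'
#' The marginal-internal weighting regime: fit the penalized marginal model
#' on the full study sample and take the SNP coefficients as GRS weights.
#' Appropriate when the SNPs were selected for hypothesized marginal
#' effects.
#'
#' @inheritParams fit_penalized_marginal
#' @return A list with `weights` (a [weight_vector()], provenance
#'   `"marginal-internal"`) and `fit` (the underlying `penalized_fit`).
#' @export
weights_marginal_internal <- function(G, y, alpha = 0.5, cv_folds = 10,
                                      seed = NULL,
                                      family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  fit <- fit_penalized_marginal(G, y, alpha = alpha, cv_folds = cv_folds,
                                seed = seed, family = family)
  w <- weight_vector(fit$snp_main, names(fit$snp_main),
                     provenance = "marginal-internal",
                     scale_note = sprintf("penalized %s coefficients", family))
  list(weights = w, fit = fit)
}

#' GRS weights from SNPxE interaction terms estimated on a training split
#'
#' The interaction-training regime: split the sample at `ratio`, fit the
#' joint penalized model with SNPxE product terms on the training part only,
#' and use the estimated interaction coefficients as GRS weights. Scoring
#' and the GRSxE test must then use only the disjoint test part (returned in
#' the `split` element) so the weights are independent of the data they are
#' applied to.
#'
#' If every interaction coefficient is shrunk to exactly zero the weights
#' are returned with a warning and `degenerate = TRUE`; a downstream test on
#' the resulting constant GRS must report a degenerate GRS rather than a
#' p-value.
#'
#' @inheritParams fit_penalized_interaction
#' @param ratio train:test integer pair, as in [make_split()].
#' @return A list with `weights` (a [weight_vector()], provenance
#'   `"interaction-training"`), `split` (the [make_split()] plan), `fit`,
#'   and `degenerate` (logical).
#' @export
weights_interaction_training <- function(G, E, y, ratio = c(1, 1),
                                         alpha = 0.5, cv_folds = 10,
                                         seed = NULL,
                                         family = c("gaussian", "binomial"),
                                         penalize_env = TRUE) {
  family <- match.arg(family)
  x <- as_dosage_matrix(G)
  n <- nrow(x)
  split <- make_split(n, ratio = ratio, seed = seed)
  if (length(split$train_indices) <= cv_folds)
    stop("training subset too small for ", cv_folds, "-fold cross-validation")
  fit <- fit_penalized_interaction(x[split$train_indices, , drop = FALSE],
                                   E[split$train_indices],
                                   y[split$train_indices],
                                   alpha = alpha, cv_folds = cv_folds,
                                   seed = seed, family = family,
                                   penalize_env = penalize_env)
  delta <- fit$snp_env_interaction
  degenerate <- all(delta == 0)
  if (degenerate)
    warning("all interaction coefficients shrunk to zero: degenerate GRS weights")
  w <- weight_vector(delta, names(delta),
                     provenance = "interaction-training",
                     scale_note = "penalized SNPxE interaction coefficients (training split)")
  list(weights = w, split = split, fit = fit, degenerate = degenerate)
}
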