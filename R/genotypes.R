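#' Genotype matrix container
#'
#' Holds an n x k matrix of allele-count dosages (0, 1, 2; `NA` for missing)
#' together with sample ids, SNP ids, the observed minor allele frequency of
#' each SNP, and (optionally) the risk allele. Dosages count risk alleles, so
#' a weighted genetic risk score is a plain weighted row sum over this matrix.
#'
#' @param dosages numeric matrix (samples x SNPs) with entries in \{0, 1, 2\}
#'   or `NA`.
#' @param sample_ids character vector of row ids; defaults to rownames or
#'   `sample1..n`.
#' @param snp_ids character vector of column ids; defaults to colnames or
#'   `snp1..k`.
#' @param risk_allele optional character vector (one nucleotide per SNP, or
#'   `NA`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `sample_ids`, `snp_ids`, `maf` (observed, minor-allele
#'   oriented, in \[0, 0.5\]) and `risk_allele`.
#' @examples
#' G <- genotype_matrix(matrix(c(0, 1, 2, 1, 0, 2), nrow = 3))
#' G$maf
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, snp_ids = NULL,
                            risk_allele = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 1L || ncol(dosages) < 1L)
    stop("genotype matrix must have at least one sample and one SNP")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop(sprintf("dosage values must be 0, 1, 2 or NA; found %s at entry [%d, %d]",
                 format(dosages[idx]),
                 row(dosages)[idx], col(dosages)[idx]))
  }
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids))
    sample_ids <- rownames(dosages) %||% paste0("sample", seq_len(nrow(dosages)))
  if (is.null(snp_ids))
    snp_ids <- colnames(dosages) %||% paste0("snp", seq_len(ncol(dosages)))
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != nrow(dosages))
    stop("length of sample_ids does not match number of rows")
  if (length(snp_ids) != ncol(dosages))
    stop("length of snp_ids does not match number of columns")
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP ids: ", paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  if (!is.null(risk_allele) && length(risk_allele) != ncol(dosages))
    stop("length of risk_allele does not match number of SNPs")
  dimnames(dosages) <- list(sample_ids, snp_ids)
  p <- colMeans(dosages, na.rm = TRUE) / 2
  structure(list(dosages = dosages,
                 sample_ids = sample_ids,
                 snp_ids = snp_ids,
                 maf = unname(pmin(p, 1 - p)),
                 risk_allele = risk_allele),
            class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  observed MAF: %s\n",
              paste(format(round(x$maf, 3)), collapse = " ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param x a [genotype_matrix()].
#' @param i,j sample / SNP index (integer, logical or id character vector).
#' @param ... ignored.
#' @param drop ignored; the result is always a `genotype_matrix`.
#' @return A `genotype_matrix` restricted to the selected rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  d <- x$dosages[i, j, drop = FALSE]
  genotype_matrix(d,
                  sample_ids = rownames(d),
                  snp_ids = colnames(d),
                  risk_allele = if (!is.null(x$risk_allele))
                    x$risk_allele[match(colnames(d), x$snp_ids)])
}

#' Recode genotype dosages under a mode of inheritance
#'
#' Additive coding leaves the 0/1/2 allele counts as they are; dominant
#' coding maps \{0, 1, 2\} to \{0, 1, 1\} (effect present with at least one
#' risk allele); recessive coding maps to \{0, 0, 1\}.
#'
#' @param G a [genotype_matrix()].
#' @param coding one of `"additive"`, `"dominant"`, `"recessive"`.
#' @return A `genotype_matrix` with recoded dosages. Note the `maf` field is
#'   recomputed from the recoded values and is a carrier frequency under
#'   dominant/recessive coding, not an allele frequency.
#' @examples
#' G <- genotype_matrix(matrix(c(0, 1, 2), ncol = 1))
#' recode_genotypes(G, "dominant")$dosages[, 1]  # 0 1 1
#' @export
recode_genotypes <- function(G, coding = c("additive", "dominant", "recessive")) {
  stopifnot(inherits(G, "genotype_matrix"))
  coding <- match.arg(coding)
  d <- G$dosages
  d <- switch(coding,
              additive  = d,
              dominant  = ifelse(d >= 1, 1, d),
              recessive = ifelse(d >= 2, 1, 0 * d))
  out <- genotype_matrix(d, sample_ids = G$sample_ids, snp_ids = G$snp_ids,
                         risk_allele = G$risk_allele)
  attr(out, "coding") <- coding
  out
}

#' Weight vector for a genetic risk score
#'
#' @param weights numeric vector of per-SNP weights (finite).
#' @param snp_ids character vector of SNP ids, same length as `weights`.
#' @param provenance where the weights came from: `"external"` (independent
#'   study), `"marginal-internal"` (penalized marginal SNP effects estimated
#'   in the study sample) or `"interaction-training"` (penalized SNPxE
#'   interaction coefficients from a training split).
#' @param scale_note free-text note on the scale (e.g. `"log-OR"`).
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(weights, snp_ids,
                          provenance = c("external", "marginal-internal",
                                         "interaction-training"),
                          scale_note = "") {
  provenance <- match.arg(provenance)
  weights <- as.numeric(weights)
  snp_ids <- as.character(snp_ids)
  if (length(weights) != length(snp_ids))
    stop("weights and snp_ids must have the same length")
  if (any(!is.finite(weights)))
    stop("weights must be finite")
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP ids in weight vector")
  names(weights) <- snp_ids
  structure(list(weights = weights, snp_ids = snp_ids,
                 provenance = provenance, scale_note = scale_note),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("weight_vector (%s): %d SNPs\n", x$provenance, length(x$weights)))
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
length.weight_vector <- function(x) length(x$weights)

#' Align a weight vector to a SNP panel
#'
#' Reorders weights to match `snp_ids`; weights for SNPs absent from the
#' panel are dropped with a warning. SNPs in the panel without a weight are
#' an error (a score cannot be formed).
#'
#' @param w a [weight_vector()].
#' @param snp_ids target SNP id ordering (e.g. `G$snp_ids`).
#' @return A `weight_vector` aligned to `snp_ids`.
#' @export
align_weights <- function(w, snp_ids) {
  stopifnot(inherits(w, "weight_vector"))
  snp_ids <- as.character(snp_ids)
  extra <- setdiff(w$snp_ids, snp_ids)
  if (length(extra))
    warning("dropping weights for SNPs absent from the genotype panel: ",
            paste(extra, collapse = ", "))
  missing <- setdiff(snp_ids, w$snp_ids)
  if (length(missing))
    stop("no weight available for SNPs: ", paste(missing, collapse = ", "))
  weight_vector(w$weights[snp_ids], snp_ids,
                provenance = w$provenance, scale_note = w$scale_note)
}

#' Compute a weighted genetic risk score
#'
#' The score for subject i is the weighted sum over SNPs of the (possibly
#' recoded) risk-allele dosage, `GRS_i = sum_j w_j g_ij`. No normalization by
#' the number of SNPs or the weight sum is applied. Samples with a missing
#' dosage at any weighted SNP get an `NA` score.
#'
#' @param G a [genotype_matrix()] (recode first with [recode_genotypes()] if
#'   a non-additive mode of inheritance is wanted).
#' @param w a [weight_vector()] whose SNP ids must match `G$snp_ids` as a
#'   set; it is aligned by id before scoring.
#' @return An object of class `grs_vector`: list with `values` (named by
#'   sample id), `provenance` and `coding` (the coding attribute of `G`, if
#'   recoded; `"additive"` otherwise).
#' @examples
#' G <- genotype_matrix(matrix(c(1, 0, 1), nrow = 1),
#'                      snp_ids = c("rs1138272", "rs1695", "rs1800629"))
#' w <- weight_vector(c(0.40, -0.09, 0.04), G$snp_ids, "external", "log-OR")
#' compute_grs(G, w)$values  # 0.44
#' @export
compute_grs <- function(G, w) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(w, "weight_vector"))
  if (!setequal(w$snp_ids, G$snp_ids)) {
    off <- c(setdiff(w$snp_ids, G$snp_ids), setdiff(G$snp_ids, w$snp_ids))
    stop("SNP id mismatch between weights and genotypes: ",
         paste(off, collapse = ", "))
  }
  w <- align_weights(w, G$snp_ids)
  vals <- drop(G$dosages %*% w$weights)
  names(vals) <- G$sample_ids
  structure(list(values = vals,
                 provenance = w$provenance,
                 coding = attr(G, "coding") %||% "additive"),
            class = "grs_vector")
}

#' @export
print.grs_vector <- function(x, ...) {
  cat(sprintf("grs_vector (%s weights, %s coding): n = %d\n",
              x$provenance, x$coding, length(x$values)))
  print(summary(unname(x$values)))
  invisible(x)
}
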