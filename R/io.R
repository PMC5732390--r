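#' Read a genotype dosage matrix from a dosage table or VCF
#'
#' The dosage-table dialect is a pruned PLINK `.raw`-style table: a header
#' row of SNP ids, first column the sample id, remaining columns allele
#' counts in \{0, 1, 2\} with `NA` for missing, tab- or comma-delimited
#' (sniffed from the header). For VCF input the dosage is the count of ALT
#' alleles in the GT field; multi-allelic records are rejected (the methods
#' here are defined for biallelic SNPs).
#'
#' @param path file path.
#' @param format `"dosage-table"` or `"vcf"`.
#' @return A [genotype_matrix()]. Missing genotypes stay `NA`; they are not
#'   imputed.
#' @export
read_genotypes <- function(path, format = c("dosage-table", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "dosage-table" = read_dosage_table(path),
         "vcf" = read_vcf_genotypes(path))
}

read_dosage_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header, fixed = TRUE) && !grepl("\t", header, fixed = TRUE))
    "," else "\t"
  nfield <- utils::count.fields(path, sep = sep, quote = "")
  if (length(nfield) < 2L) stop("no data rows in ", path)
  bad <- which(nfield != nfield[1L])
  if (length(bad))
    stop(sprintf("malformed row in %s: line %d has %d fields, expected %d",
                 path, bad[1L], nfield[bad[1L]], nfield[1L]))
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, colClasses = "character",
                           na.strings = "NA")
  if (ncol(tab) < 2L) stop("dosage table needs a sample-id column and >=1 SNP column")
  sample_ids <- tab[[1L]]
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = dimnames(mat)))
  notnum <- !is.na(mat) & is.na(num)
  if (any(notnum))
    stop("non-numeric dosage value: ", mat[which(notnum)[1L]])
  out_of_domain <- !is.na(num) & !(num %in% c(0, 1, 2))
  if (any(out_of_domain)) {
    idx <- which(out_of_domain)[1L]
    stop(sprintf("dosage value outside {0,1,2} in %s (SNP %s, sample %s): %s",
                 path, colnames(num)[col(num)[idx]], sample_ids[row(num)[idx]],
                 format(num[idx])))
  }
  genotype_matrix(num, sample_ids = sample_ids, snp_ids = colnames(num))
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic VCF records are not supported: ",
         paste(fix[multi, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  # count ALT alleles from unphased or phased diploid calls
  count_alt <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  dos <- apply(gt, c(1, 2), count_alt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(t(dos), sample_ids = colnames(gt), snp_ids = ids,
                  risk_allele = unname(alt))
}

#' Write a genotype matrix as a dosage table
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, sep = "\t") {
  stopifnot(inherits(G, "genotype_matrix"))
  tab <- data.frame(sample_id = G$sample_ids, G$dosages,
                    check.names = FALSE, row.names = NULL)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-SNP weights from a tab-separated weight file
#'
#' Expected columns: `snp_id`, `weight`, and optionally `risk_allele`.
#' Weights are typically log odds ratios (binary outcomes) or linear
#' regression coefficients (quantitative outcomes) for the marginal SNP
#' effects reported by an external study.
#'
#' @param path file path.
#' @param snp_ids optional SNP panel to align against: weights are reordered
#'   to this id list, file entries absent from the panel are dropped with a
#'   warning, and panel SNPs without a weight raise an error.
#' @param provenance provenance tag for the returned vector.
#' @return A [weight_vector()].
#' @export
read_weights <- function(path, snp_ids = NULL, provenance = "external") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  if (nrow(tab) == 0L) stop("no weight records in ", path)
  need <- c("snp_id", "weight")
  if (!all(need %in% names(tab)))
    stop("weight file must have columns snp_id and weight; found: ",
         paste(names(tab), collapse = ", "))
  if (anyDuplicated(tab$snp_id))
    stop("duplicate snp_id in weight file: ",
         paste(unique(tab$snp_id[duplicated(tab$snp_id)]), collapse = ", "))
  wt <- suppressWarnings(as.numeric(tab$weight))
  if (any(is.na(wt)))
    stop("non-numeric weight for SNP ",
         tab$snp_id[which(is.na(wt))[1L]])
  w <- weight_vector(wt, tab$snp_id, provenance = provenance)
  if (!is.null(snp_ids)) w <- align_weights(w, snp_ids)
  w
}

#' Write a weight vector to a tab-separated weight file
#'
#' @param w a [weight_vector()].
#' @param path output file path.
#' @param risk_allele optional per-SNP risk allele column.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path, risk_allele = NULL) {
  stopifnot(inherits(w, "weight_vector"))
  tab <- data.frame(snp_id = w$snp_ids,
                    risk_allele = risk_allele %||% rep("NA", length(w$weights)),
                    weight = format(w$weights, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample table (sample_id, value)
#'
#' Used for exposure and phenotype tables.
#'
#' @param path file path to a TSV with columns `sample_id` and `value`.
#' @param sample_ids optional sample ordering to align to (error on missing
#'   samples).
#' @return Named numeric vector.
#' @export
read_sample_table <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE)
  if (!all(c("sample_id", "value") %in% names(tab)))
    stop("sample table must have columns sample_id and value")
  v <- as.numeric(tab$value)
  names(v) <- as.character(tab$sample_id)
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(v))
    if (length(missing))
      stop("samples missing from ", path, ": ", paste(missing, collapse = ", "))
    v <- v[as.character(sample_ids)]
  }
  v
}

#' Write a two-column sample table
#'
#' @param values named numeric vector (names are sample ids).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(values, path) {
  tab <- data.frame(sample_id = names(values) %||% seq_along(values),
                    value = format(unname(values), digits = 17, trim = TRUE,
                                   scientific = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a YAML run configuration
#'
#' Recognized top-level fields: `weighting_method` (external |
#' marginal-internal | interaction-training), `coding` (additive | dominant
#' | recessive), `family` (gaussian | binomial), `alpha` in \[0, 1\],
#' `split_ratio` (two positive integers, train:test), `cv_folds`, `seed`,
#' and an optional `simulation` block passed to [scenario_config()].
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config` (with defaults filled in).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  cfg$weighting_method <- cfg$weighting_method %||% "interaction-training"
  if (!cfg$weighting_method %in% c("external", "marginal-internal", "interaction-training"))
    stop("invalid weighting_method: ", cfg$weighting_method)
  cfg$coding <- cfg$coding %||% "additive"
  if (!cfg$coding %in% c("additive", "dominant", "recessive"))
    stop("invalid coding: ", cfg$coding)
  cfg$family <- cfg$family %||% "gaussian"
  if (!cfg$family %in% c("gaussian", "binomial"))
    stop("invalid family: ", cfg$family)
  cfg$alpha <- cfg$alpha %||% 0.5
  if (!is.numeric(cfg$alpha) || length(cfg$alpha) != 1L ||
      cfg$alpha < 0 || cfg$alpha > 1)
    stop("alpha must be a single number in [0, 1]; got ", cfg$alpha)
  cfg$split_ratio <- as.integer(cfg$split_ratio %||% c(1L, 1L))
  if (length(cfg$split_ratio) != 2L || any(cfg$split_ratio < 1L))
    stop("split_ratio must be two integers >= 1")
  cfg$cv_folds <- as.integer(cfg$cv_folds %||% 10L)
  if (cfg$cv_folds < 3L) stop("cv_folds must be >= 3")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    # YAML 1.1 parses the bare keys n/y as booleans; map them back
    names(sim)[names(sim) == "FALSE"] <- "n"
    names(sim)[names(sim) == "TRUE"] <- "y"
    # a bare "scenario: null" parses as NULL and would silently fall back
    # to the default; require the quoted string
    if (is.null(sim$scenario) && "scenario" %in% names(sim))
      stop("simulation scenario is null/empty; quote it in YAML (\"null\")")
    cfg$simulation <- do.call(scenario_config, sim)
  }
  class(cfg) <- "run_config"
  cfg
}

# Polynomial rolling hash over the JSON serialization (mod 2^31 - 1);
# reproducibility bookkeeping only, not cryptographic.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null", force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
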