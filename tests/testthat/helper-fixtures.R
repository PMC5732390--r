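# Small fixtures built in code, shared across test files.

# 3-sample x 3-SNP panel matching the published external-weight example
# (GSTP1 rs1138272, GSTP1 rs1695, TNF rs1800629).
gst_tnf_snp_ids <- c("rs1138272", "rs1695", "rs1800629")
gst_tnf_weights <- c(0.40, -0.09, 0.04)  # ln(1.49), ln(0.91), ln(1.04), rounded

make_published_weight_file <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("snp_id\trisk_allele\tweight",
               "rs1138272\tT\t0.40",
               "rs1695\tG\t-0.09",
               "rs1800629\tA\t0.04"),
             path)
  path
}

make_small_genotypes <- function(n = 20, mafs = c(0.3, 0.2, 0.4), seed = 101,
                                 snp_ids = NULL) {
  simulate_genotypes(n, mafs, seed = seed, snp_ids = snp_ids)
}

# deterministic tiny VCF with known GT fields
make_tiny_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "11\t67352689\trs1695\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "11\t67353579\trs1138272\tC\tT\t.\tPASS\t.\tGT\t0/1\t0|1\t./.",
    "6\t31543031\trs1800629\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1"),
    path)
  path
}

# closed-form OLS with intercept: solve the normal equations directly
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  drop(solve(crossprod(X), crossprod(X, y)))
}
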