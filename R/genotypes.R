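#' Describe a panel of biallelic SNPs
#'
#' Builds the per-SNP metadata table used throughout the package: one row per
#' SNP with its identifier, position, coded/other allele and minor allele
#' frequency. The coded allele is the allele counted by the 0/1/2 dosage.
#'
#' @param n_snps Number of SNPs to describe.
#' @param maf Minor allele frequencies, recycled to `n_snps`; each in
#'   \[0, 0.5\]. Default draws uniformly from \[0.05, 0.5\].
#' @param chrom Chromosome labels, recycled.
#' @param seed Integer seed used when `maf` is drawn at random.
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `coded_allele`,
#'   `other_allele`, `maf`.
#' @examples
#' snp_panel(5, maf = c(0.1, 0.2, 0.3, 0.4, 0.5))
#' @export
snp_panel <- function(n_snps, maf = NULL, chrom = "1", seed = 1L) {
  stopifnot(n_snps >= 1)
  if (is.null(maf)) {
    maf <- withr::with_seed(seed, stats::runif(n_snps, 0.05, 0.5))
  }
  maf <- rep_len(maf, n_snps)
  if (any(maf < 0 | maf > 0.5)) {
    stop("`maf` must lie in [0, 0.5]", call. = FALSE)
  }
  alleles <- c("A", "C", "G", "T")
  coded <- withr::with_seed(seed + 1L, sample(alleles, n_snps, replace = TRUE))
  other <- withr::with_seed(seed + 2L, vapply(coded, function(a) {
    sample(setdiff(alleles, a), 1L)
  }, character(1), USE.NAMES = FALSE))
  tibble::tibble(
    snp_id = sprintf("rs%06d", seq_len(n_snps)),
    chrom = rep_len(as.character(chrom), n_snps),
    pos = seq_len(n_snps) * 1000L,
    coded_allele = coded,
    other_allele = other,
    maf = maf
  )
}

validate_snp_meta <- function(snps) {
  req <- c("snp_id", "chrom", "pos", "coded_allele", "other_allele", "maf")
  missing <- setdiff(req, names(snps))
  if (length(missing)) {
    stop("SNP metadata lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id in SNP metadata", call. = FALSE)
  }
  if (any(snps$coded_allele == snps$other_allele)) {
    stop("coded_allele must differ from other_allele", call. = FALSE)
  }
  if (any(snps$maf < 0 | snps$maf > 0.5)) {
    stop("maf outside [0, 0.5]", call. = FALSE)
  }
  invisible(snps)
}

#' Construct a genotype matrix object
#'
#' The shared currency of both cohorts: a samples x SNPs dosage matrix in
#' \[0, 2\] (fractional values allowed for imputed dosages, `NA` for missing)
#' plus the SNP metadata of [snp_panel()].
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns.
#' @param snps SNP metadata tibble (one row per column of `dosages`).
#' @param samples Character vector of sample identifiers (defaults to
#'   rownames of `dosages`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snps, samples = rownames(dosages)) {
  validate_snp_meta(snps)
  dosages <- as.matrix(dosages)
  if (is.null(samples)) {
    samples <- sprintf("S%05d", seq_len(nrow(dosages)))
  }
  if (nrow(dosages) != length(samples)) {
    stop("dosage rows do not match sample list", call. = FALSE)
  }
  if (ncol(dosages) != nrow(snps)) {
    stop("dosage columns do not match SNP metadata rows", call. = FALSE)
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  dimnames(dosages) <- list(samples, snps$snp_id)
  structure(
    list(dosages = dosages, snps = snps, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$samples), " samples x ",
      nrow(x$snps), " SNPs\n", sep = "")
  n_miss <- sum(is.na(x$dosages))
  if (n_miss > 0) cat("  missing dosages: ", n_miss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Simulate unlinked biallelic genotypes
#'
#' Dosages are drawn independently as Binomial(2, maf) per SNP, i.e. sites in
#' Hardy-Weinberg equilibrium with no linkage disequilibrium. Missingness can
#' be injected completely at random.
#'
#' @param n_samples Number of samples.
#' @param snps SNP metadata from [snp_panel()].
#' @param seed Integer seed; the draw is bit-reproducible.
#' @param missing_rate Fraction of entries set to `NA`, missing completely at
#'   random. Default 0.
#' @return A [genotype_matrix()].
#' @examples
#' g <- simulate_genotypes(100, snp_panel(10), seed = 1)
#' @export
simulate_genotypes <- function(n_samples, snps, seed, missing_rate = 0) {
  stopifnot(n_samples >= 1)
  if (nrow(snps) == 0) stop("empty SNP panel", call. = FALSE)
  validate_snp_meta(snps)
  dos <- withr::with_seed(seed, {
    m <- vapply(snps$maf, function(f) {
      stats::rbinom(n_samples, 2L, f)
    }, numeric(n_samples))
    if (n_samples == 1) m <- matrix(m, nrow = 1)
    if (missing_rate > 0) {
      drop <- stats::runif(length(m)) < missing_rate
      m[drop] <- NA_real_
    }
    m
  })
  genotype_matrix(dos, snps, samples = sprintf("S%05d", seq_len(n_samples)))
}

# Center by 2*allele frequency and scale to unit variance; mean-imputes
# missing entries first. Constant columns get sd NA and are the caller's
# problem. Returns list(X, center, scale).
standardize_dosages <- function(gm) {
  X <- gm$dosages
  af <- colMeans(X, na.rm = TRUE) / 2
  ctr <- 2 * af
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- ctr[j]
  }
  X <- sweep(X, 2, ctr, "-")
  s <- sqrt(colSums(X^2) / (nrow(X) - 1))
  list(X = X, center = ctr, scale = s)
}
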