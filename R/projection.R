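flip_strand <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Align a weight set to a target cohort's alleles
#'
#' Matches weights to target SNPs by `snp_id`, reconciling allele order and
#' strand. A swapped coded/other pair negates the weight (the centering in
#' [project_scores()] absorbs the constant offset); strand-complement
#' matches are resolved by complementing; strand-ambiguous palindromic SNPs
#' (A/T or C/G) whose target minor-allele frequency falls inside the
#' ambiguity window cannot be oriented reliably and are dropped. Allele
#' pairs compatible with no orientation are dropped and logged, not fatal.
#'
#' @param weights Weight tibble from [compute_weights()] (or read from TSV).
#' @param target_snps Target SNP metadata with `snp_id`, `coded_allele`,
#'   `other_allele` and `maf` columns.
#' @param maf_window Ambiguity window for palindromic SNPs, default
#'   `c(0.4, 0.6)` on the coded-allele frequency.
#' @param drop_ambiguous Set `FALSE` to keep palindromic SNPs inside the
#'   window (matched by literal allele identity).
#' @return A list: `weights` (aligned tibble, coded allele now on the target
#'   orientation) and `report` (counts plus a per-SNP disposition table).
#' @export
align_alleles <- function(weights, target_snps,
                          maf_window = c(0.4, 0.6), drop_ambiguous = TRUE) {
  if (anyDuplicated(weights$snp_id)) {
    stop("duplicate snp_id in weight set", call. = FALSE)
  }
  if (anyDuplicated(target_snps$snp_id)) {
    stop("duplicate snp_id in target SNPs", call. = FALSE)
  }
  tgt <- target_snps[match(weights$snp_id, target_snps$snp_id), ]
  n <- nrow(weights)
  disposition <- character(n)
  w_out <- weights$w
  coded <- weights$coded_allele
  other <- weights$other_allele

  for (i in seq_len(n)) {
    if (is.na(tgt$snp_id[i])) {
      disposition[i] <- "missing_in_target"
      next
    }
    cw <- weights$coded_allele[i]; ow <- weights$other_allele[i]
    ct <- tgt$coded_allele[i]; ot <- tgt$other_allele[i]
    pal <- is_palindromic(cw, ow)
    if (pal && drop_ambiguous) {
      f <- tgt$maf[i]
      cf <- c(f, 1 - f) # coded-allele frequency, either orientation
      if (any(cf >= maf_window[1] & cf <= maf_window[2])) {
        disposition[i] <- "ambiguous"
        next
      }
    }
    if (ct == cw && ot == ow) {
      disposition[i] <- "same"
    } else if (ct == ow && ot == cw) {
      disposition[i] <- "flipped"
      w_out[i] <- -w_out[i]
    } else if (!pal && flip_strand(ct) == cw && flip_strand(ot) == ow) {
      disposition[i] <- "strand_same"
    } else if (!pal && flip_strand(ct) == ow && flip_strand(ot) == cw) {
      disposition[i] <- "strand_flipped"
      w_out[i] <- -w_out[i]
    } else {
      disposition[i] <- "incompatible"
      next
    }
    coded[i] <- ct
    other[i] <- ot
  }

  matched <- disposition %in% c("same", "flipped", "strand_same",
                                "strand_flipped")
  aligned <- weights[matched, ]
  aligned$w <- w_out[matched]
  aligned$coded_allele <- coded[matched]
  aligned$other_allele <- other[matched]
  report <- list(
    n_matched = sum(matched),
    n_flipped = sum(disposition %in% c("flipped", "strand_flipped")),
    n_dropped_ambiguous = sum(disposition %in% c("ambiguous",
                                                 "incompatible")),
    n_missing_in_target = sum(disposition == "missing_in_target"),
    dispositions = tibble::tibble(snp_id = weights$snp_id,
                                  disposition = disposition)
  )
  list(weights = aligned, report = report)
}

#' Project SNP weights into genetically predicted biomarker scores
#'
#' The predicted phenotype for each sample is the sum over SNPs of the
#' coded-allele dosage (0/1/2, fractional for imputed data) times the SNP
#' weight. Missing dosages are mean-imputed at twice the sample allele
#' frequency, which preserves the score expectation. Scores are then
#' standardized to mean 0 and standard deviation 1 in the target cohort, so
#' downstream odds ratios are per standard deviation of the predictor.
#'
#' @param target A [genotype_matrix()] for the target cohort.
#' @param weights Aligned weight tibble (`snp_id`, `w`, allele columns); all
#'   its SNPs must be present in the target.
#' @param label Biomarker label carried on the result.
#' @return A tibble of class `score_vector`: `sample_id`, `raw`,
#'   `standardized`.
#' @examples
#' g <- simulate_genotypes(50, snp_panel(10), seed = 1)
#' w <- dplyr::mutate(g$snps, w = rnorm(10))
#' project_scores(g, w)
#' @export
project_scores <- function(target, weights, label = "biomarker") {
  stopifnot(inherits(target, "genotype_matrix"))
  if (nrow(weights) == 0) stop("zero aligned SNPs", call. = FALSE)
  idx <- match(weights$snp_id, target$snps$snp_id)
  if (anyNA(idx)) {
    stop("weights reference SNPs absent from the target: ",
         paste(utils::head(weights$snp_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  X <- target$dosages[, idx, drop = FALSE]
  if (anyNA(X)) {
    af2 <- colMeans(X, na.rm = TRUE)
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- af2[j]
    }
  }
  raw <- unname(drop(X %*% weights$w))
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) {
    stop("raw scores have zero variance; standardization undefined",
         call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = target$samples,
    raw = raw,
    standardized = (raw - mean(raw)) / s
  )
  attr(out, "biomarker") <- label
  attr(out, "n_snps") <- nrow(weights)
  class(out) <- c("score_vector", class(out))
  out
}
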