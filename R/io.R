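default_meta_path <- function(path) {
  sub("\\.tsv$", ".meta.tsv", path)
}

#' Write a genotype matrix as a dosage TSV (with metadata sidecar)
#'
#' The dosage file has a `sample_id` column followed by one column per SNP
#' (header = snp_id); the sidecar TSV carries `snp_id`, `chrom`, `pos`,
#' `coded_allele`, `other_allele`, `maf`. Round-trips losslessly through
#' [read_dosage_tsv()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output dosage TSV path.
#' @param meta_path Sidecar path; default replaces `.tsv` with `.meta.tsv`.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(gm, path, meta_path = default_meta_path(path)) {
  df <- tibble::as_tibble(gm$dosages)
  df <- dplyr::bind_cols(tibble::tibble(sample_id = gm$samples), df)
  readr::write_tsv(df, path)
  readr::write_tsv(gm$snps, meta_path)
  invisible(path)
}

#' Read a dosage TSV written by [write_dosage_tsv()]
#'
#' @param path Dosage TSV path.
#' @param meta_path Sidecar metadata TSV path.
#' @return A [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path, meta_path = default_meta_path(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(meta_path)) {
    stop("no such metadata sidecar: ", meta_path, call. = FALSE)
  }
  df <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      sample_id = readr::col_character(),
                      .default = readr::col_double()
                    ))
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop("malformed dosage TSV at line ", probs$row[1] + 1L, " of ", path,
         call. = FALSE)
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            snp_id = readr::col_character(),
                            chrom = readr::col_character(),
                            pos = readr::col_integer(),
                            coded_allele = readr::col_character(),
                            other_allele = readr::col_character(),
                            maf = readr::col_double()
                          ))
  dosage_cols <- setdiff(names(df), "sample_id")
  if (!identical(dosage_cols, meta$snp_id)) {
    stop("dosage columns do not match the metadata sidecar", call. = FALSE)
  }
  genotype_matrix(as.matrix(df[dosage_cols]), meta, df$sample_id)
}

#' Write a genotype matrix as a minimal VCF 4.2 with DS dosages
#'
#' One record per SNP with `REF = other_allele`, `ALT = coded_allele` and a
#' `DS` FORMAT field holding the coded-allele dosage; missing dosages are
#' written as `.`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Coded allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  snps <- gm$snps
  for (j in seq_len(nrow(snps))) {
    ds <- gm$dosages[, j]
    ds_str <- ifelse(is.na(ds), ".", formatC(ds, format = "g", digits = 6))
    writeLines(paste(c(snps$chrom[j], snps$pos[j], snps$snp_id[j],
                       snps$other_allele[j], snps$coded_allele[j],
                       ".", "PASS", ".", "DS", ds_str),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF dosages come from the `DS` FORMAT field when present; otherwise they
#' fall back to counting coded (ALT) alleles in `GT`. The coded allele is
#' the ALT allele; `maf` is computed from the sample allele frequency.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage_tsv"`.
#' @param meta_path Sidecar path for the dosage TSV dialect.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv"),
                           meta_path = default_meta_path(path)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  }
  if (format == "dosage_tsv") {
    return(read_dosage_tsv(path, meta_path))
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  fmt <- vcf@gt[, 1]
  has_ds <- all(grepl("DS", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(gt) || all(is.na(gt))) {
      stop("VCF has neither DS nor GT fields: ", path, call. = FALSE)
    }
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(strsplit(g, "[/|]")[[1]] == "1")
    })
  }
  dos <- t(ds) # samples x snps
  af <- colMeans(dos, na.rm = TRUE) / 2
  snps <- tibble::tibble(
    snp_id = fix[, "ID"],
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    coded_allele = fix[, "ALT"],
    other_allele = fix[, "REF"],
    maf = pmin(af, 1 - af)
  )
  genotype_matrix(dos, snps, rownames(dos))
}

#' Read/write phecode occurrence tables
#'
#' Long CSV: `sample_id`, `phecode`, `count`.
#'
#' @param x Occurrence tibble.
#' @param path CSV path.
#' @return The tibble (reader) or `path` invisibly (writer).
#' @export
write_occurrences <- function(x, path) {
  readr::write_csv(x[, c("sample_id", "phecode", "count")], path)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    phecode = readr::col_character(),
    count = readr::col_integer()
  ))
}

#' Read/write phecode definition tables
#'
#' CSV dialect: `phecode`, `label`, `exclusion_codes` (semicolon-joined),
#' `sex_restriction`. The reader returns the list-column form used by
#' [assemble_case_control()].
#'
#' @param x Definition tibble with an `exclusion_codes` list-column.
#' @param path CSV path.
#' @return The tibble (reader) or `path` invisibly (writer).
#' @export
write_phecode_definitions <- function(x, path) {
  flat <- dplyr::mutate(x, exclusion_codes = vapply(
    .data$exclusion_codes, paste, character(1), collapse = ";"))
  readr::write_csv(flat, path)
  invisible(path)
}

#' @rdname write_phecode_definitions
#' @export
read_phecode_definitions <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    phecode = readr::col_character(),
    label = readr::col_character(),
    exclusion_codes = readr::col_character(),
    sex_restriction = readr::col_character()
  ))
  df$exclusion_codes <- lapply(df$exclusion_codes, function(s) {
    if (is.na(s) || s == "") character() else strsplit(s, ";")[[1]]
  })
  df
}

#' Read/write SNP weight tables
#'
#' TSV with fixed column order: `snp_id`, `chrom`, `pos`, `coded_allele`,
#' `other_allele`, `alpha`, `beta`, `gamma`, `w`.
#'
#' @param x Weight tibble from [compute_weights()].
#' @param path TSV path.
#' @return The tibble (reader) or `path` invisibly (writer).
#' @export
write_weights_tsv <- function(x, path) {
  cols <- c("snp_id", "chrom", "pos", "coded_allele", "other_allele",
            "alpha", "beta", "gamma", "w")
  readr::write_tsv(x[, cols], path)
  invisible(path)
}

#' @rdname write_weights_tsv
#' @export
read_weights_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    coded_allele = readr::col_character(),
    other_allele = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Write association-scan results as TSV
#'
#' @param results Annotated results tibble.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}

#' Write standardized scores as TSV
#'
#' @param scores A [project_scores()] result.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  readr::write_tsv(tibble::as_tibble(scores), path)
  invisible(path)
}

#' Write a model-fit report as JSON
#'
#' Posterior medians and 95 percent intervals for PVE, PGE and the
#' large-effect count, the sampler configuration, and any dropped SNPs.
#'
#' @param fit A [fit_bslmm()] result.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(list(
    summary = as.list(fit$summary),
    config = fit$config[c("n_steps", "n_burn", "thin", "seed", "s_max")],
    dropped_snps = fit$dropped_snps
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write an allele-alignment report as JSON
#'
#' @param report The `report` element of [align_alleles()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(report, path) {
  jsonlite::write_json(list(
    n_matched = report$n_matched,
    n_flipped = report$n_flipped,
    n_dropped_ambiguous = report$n_dropped_ambiguous,
    n_missing_in_target = report$n_missing_in_target,
    dispositions = report$dispositions
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
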