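#' Define a phecode phenotype
#'
#' @param phecode Phecode string.
#' @param label Human-readable label.
#' @param exclusion_codes Phecodes "closely related" to this one; samples
#'   carrying them (but not the phecode itself) are excluded from controls.
#' @param sex_restriction `"both"`, `"male"` or `"female"`. Phenotypes
#'   restricted to a single sex are rejected from the scan.
#' @return One-row tibble with an `exclusion_codes` list-column.
#' @export
phecode_definition <- function(phecode, label = phecode,
                               exclusion_codes = character(),
                               sex_restriction = "both") {
  sex_restriction <- match.arg(sex_restriction, c("both", "male", "female"))
  tibble::tibble(phecode = as.character(phecode), label = label,
                 exclusion_codes = list(as.character(exclusion_codes)),
                 sex_restriction = sex_restriction)
}

#' Assemble the case/control set for one phecode phenotype
#'
#' Cases are samples with one or more occurrences of the phecode. Samples
#' whose only relevant occurrences are of closely related (exclusion)
#' phecodes are excluded — neither case nor control. Controls must fall
#' within the birth-decade range observed among cases. Any site contributing
#' fewer than `min_site_cases` cases is excluded wholesale for this
#' phenotype. Single-sex phenotypes are rejected, as are phenotypes with
#' fewer than `min_cases` cases after exclusions.
#'
#' @param occurrences Long occurrence tibble (`sample_id`, `phecode`,
#'   `count`).
#' @param definition One-row [phecode_definition()].
#' @param covariates Covariate table defining the cohort (`sample_id`,
#'   `sex`, `birth_decade`, `site`, ...).
#' @param min_cases Minimum case count for the phenotype to be analyzed
#'   (default 300).
#' @param min_site_cases Minimum per-site case count (default 10).
#' @return A list of class `case_control`: `phecode`, `status` tibble
#'   (`sample_id`, `status` in case/control/excluded), `n_cases`,
#'   `n_controls`, `site_case_counts`, `birth_decade_range`, `rejected`,
#'   `reject_reason`.
#' @export
assemble_case_control <- function(occurrences, definition, covariates,
                                  min_cases = 300, min_site_cases = 10) {
  if (nrow(definition) != 1) {
    stop("definition must be a single phecode row", call. = FALSE)
  }
  if (nrow(covariates) == 0) stop("empty cohort", call. = FALSE)
  code <- definition$phecode
  excl <- definition$exclusion_codes[[1]]

  reject <- function(reason) {
    structure(list(phecode = code, status = NULL, n_cases = 0L,
                   n_controls = 0L, site_case_counts = NULL,
                   birth_decade_range = NULL, rejected = TRUE,
                   reject_reason = reason),
              class = "case_control")
  }
  if (definition$sex_restriction != "both") {
    return(reject("single-sex phenotype"))
  }

  occ <- dplyr::filter(occurrences, .data$sample_id %in% covariates$sample_id)
  if (!code %in% occ$phecode) {
    stop("unknown phecode (no occurrences in cohort): ", code,
         call. = FALSE)
  }
  case_ids <- unique(occ$sample_id[occ$phecode == code])
  excl_ids <- setdiff(unique(occ$sample_id[occ$phecode %in% excl]), case_ids)

  status <- tibble::tibble(sample_id = covariates$sample_id,
                           status = "control")
  status$status[status$sample_id %in% case_ids] <- "case"
  status$status[status$sample_id %in% excl_ids] <- "excluded"

  cov <- dplyr::left_join(status, covariates, by = "sample_id")

  # Sites with too few cases are excluded wholesale for this phenotype.
  site_counts <- cov |>
    dplyr::filter(.data$status == "case") |>
    dplyr::count(.data$site, name = "n_cases")
  bad_sites <- c(
    site_counts$site[site_counts$n_cases < min_site_cases],
    setdiff(unique(cov$site), site_counts$site)
  )
  cov$status[cov$site %in% bad_sites] <- "excluded"

  # Controls outside the birth-decade range of the remaining cases.
  case_decades <- cov$birth_decade[cov$status == "case"]
  bd_range <- if (length(case_decades)) range(case_decades) else c(NA, NA)
  if (length(case_decades)) {
    out_of_range <- cov$status == "control" &
      (cov$birth_decade < bd_range[1] | cov$birth_decade > bd_range[2])
    cov$status[out_of_range] <- "excluded"
  }

  n_cases <- sum(cov$status == "case")
  n_controls <- sum(cov$status == "control")
  if (n_cases < min_cases) {
    res <- reject(sprintf("only %d cases (minimum %d)", n_cases, min_cases))
    res$n_cases <- n_cases
    return(res)
  }
  structure(list(
    phecode = code,
    status = tibble::tibble(sample_id = cov$sample_id, status = cov$status),
    n_cases = n_cases,
    n_controls = n_controls,
    site_case_counts = site_counts,
    birth_decade_range = bd_range,
    rejected = FALSE,
    reject_reason = NA_character_
  ), class = "case_control")
}

# Regression covariate frame: birth decade as a factor (a cohort-matching
# variable, not a linear trend), site/platform as factors, constant columns
# dropped (single-site or single-platform analysis sets).
build_covariate_frame <- function(covariates) {
  df <- dplyr::select(covariates, -dplyr::any_of("sample_id"))
  if ("birth_decade" %in% names(df)) {
    df$birth_decade <- factor(df$birth_decade)
  }
  for (col in intersect(c("site", "platform"), names(df))) {
    df[[col]] <- factor(df[[col]])
  }
  keep <- vapply(df, function(x) length(unique(x)) > 1, logical(1))
  df[, keep, drop = FALSE]
}

#' Logistic association between a case/control status and a score
#'
#' Maximum-likelihood logistic regression of status on the standardized
#' score plus covariates, with a Wald p-value and 95 percent confidence
#' interval for the score coefficient. Complete or quasi-complete separation
#' is detected and flagged (`converged = FALSE`) with estimates withheld
#' rather than reported at implausible magnitude.
#'
#' @param status Binary vector (1 = case).
#' @param score Standardized score vector.
#' @param covariates Optional covariate data frame (already sample-aligned).
#' @return One-row tibble: `beta`, `se`, `or`, `ci_low`, `ci_high`, `p`,
#'   `converged`.
#' @export
fit_logistic <- function(status, score, covariates = NULL) {
  if (length(unique(status)) < 2) {
    stop("status has a single class", call. = FALSE)
  }
  df <- data.frame(.status = status, .score = score)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    df <- cbind(df, as.data.frame(covariates))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.status ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- summary(fit)$coefficients
  converged <- fit$converged && !separated &&
    ".score" %in% rownames(cf) && cf[".score", "Std. Error"] < 50
  if (!converged) {
    return(tibble::tibble(beta = NA_real_, se = NA_real_, or = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p = NA_real_, converged = FALSE))
  }
  beta <- cf[".score", "Estimate"]
  se <- cf[".score", "Std. Error"]
  tibble::tibble(
    beta = beta, se = se, or = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = cf[".score", "Pr(>|z|)"], converged = TRUE
  )
}

#' Run a phenome-wide association scan for one predicted biomarker
#'
#' Serially tests the standardized genetically predicted biomarker against
#' each assembled phenotype with multivariable logistic regression. Odds
#' ratios are per standard deviation of the score. Results are ranked by
#' ascending p within the biomarker (ties by descending absolute effect,
#' then phecode); non-converged fits are retained with their flag but
#' excluded from ranking.
#'
#' @param scores A [project_scores()] result.
#' @param assignments List of [assemble_case_control()] results (rejected
#'   ones are skipped). Duplicate phecodes are an error.
#' @param covariates Covariate table (`sample_id` plus regression columns).
#' @param label Biomarker label for the result rows.
#' @return Tibble with one row per analyzed phenotype: `biomarker`,
#'   `phecode`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `p`, `n_cases`,
#'   `n_controls`, `converged`, `rank`.
#' @export
run_phewas <- function(scores, assignments, covariates,
                       label = attr(scores, "biomarker") %||% "biomarker") {
  if (inherits(assignments, "case_control")) assignments <- list(assignments)
  assignments <- Filter(function(a) !a$rejected, assignments)
  if (length(assignments) == 0) {
    stop("no analyzable phenotype assignments", call. = FALSE)
  }
  codes <- vapply(assignments, `[[`, character(1), "phecode")
  if (anyDuplicated(codes)) {
    stop("duplicate phecode among assignments: ",
         codes[duplicated(codes)][1], call. = FALSE)
  }
  score_map <- stats::setNames(scores$standardized, scores$sample_id)
  rows <- purrr::map(assignments, function(a) {
    st <- dplyr::filter(a$status, .data$status != "excluded")
    st$y <- as.integer(st$status == "case")
    st$score <- score_map[st$sample_id]
    cov <- covariates[match(st$sample_id, covariates$sample_id), ]
    cf <- build_covariate_frame(cov)
    res <- fit_logistic(st$y, st$score, cf)
    dplyr::mutate(res, biomarker = label, phecode = a$phecode,
                  n_cases = a$n_cases, n_controls = a$n_controls,
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  ord <- order(out$p, -abs(out$beta), out$phecode, na.last = TRUE)
  rank <- integer(nrow(out))
  rank[ord] <- seq_len(nrow(out))
  rank[!out$converged] <- NA_integer_
  out$rank <- rank
  dplyr::select(out, "biomarker", "phecode", "beta", "se", "or",
                "ci_low", "ci_high", "p", "n_cases", "n_controls",
                "converged", "rank")
}

#' Bonferroni and Benjamini-Hochberg annotation of scan results
#'
#' The experiment-wide Bonferroni threshold is
#' `alpha / (n_biomarkers * n_phenotypes)`. Benjamini-Hochberg step-up
#' q-values are computed within the configured family — per biomarker across
#' its phenotypes by default, or globally across all rows.
#'
#' @param results Tibble from [run_phewas()] (possibly several biomarkers
#'   bound together).
#' @param n_biomarkers Number of biomarkers in the experiment.
#' @param n_phenotypes Number of phenotypes tested per biomarker; defaults
#'   to the largest per-biomarker row count in `results`.
#' @param alpha Experiment-wide type-I error budget (default 0.05).
#' @param fdr_q FDR discovery threshold (default 0.1).
#' @param fdr_family `"per_biomarker"` or `"global"`.
#' @return A list: `results` (annotated with `q`, `bonferroni_significant`,
#'   `fdr_significant`), `bonferroni_threshold`, `alpha`, `fdr_q`.
#' @examples
#' adjust_multiplicity(
#'   tibble::tibble(biomarker = "b", phecode = "1", p = 0.01,
#'                  converged = TRUE),
#'   n_biomarkers = 53, n_phenotypes = 1139
#' )$bonferroni_threshold
#' @export
adjust_multiplicity <- function(results, n_biomarkers,
                                n_phenotypes = NULL, alpha = 0.05,
                                fdr_q = 0.1,
                                fdr_family = c("per_biomarker", "global")) {
  fdr_family <- match.arg(fdr_family)
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  stopifnot(n_biomarkers >= 1)
  if (is.null(n_phenotypes)) {
    n_phenotypes <- max(table(results$biomarker))
  }
  stopifnot(n_phenotypes >= 1)
  threshold <- alpha / (n_biomarkers * n_phenotypes)
  grouping <- if (fdr_family == "per_biomarker") results$biomarker else "all"
  q <- rep(NA_real_, nrow(results))
  for (g in unique(grouping)) {
    sel <- grouping == g & results$converged & !is.na(results$p)
    q[sel] <- stats::p.adjust(results$p[sel], method = "BH")
  }
  results$q <- q
  results$bonferroni_significant <- !is.na(results$p) & results$p < threshold
  results$fdr_significant <- !is.na(q) & q < fdr_q
  list(results = results, bonferroni_threshold = threshold,
       alpha = alpha, fdr_q = fdr_q)
}

#' Evaluate prespecified positive-control pairs
#'
#' For each biomarker with prespecified positive-control phecodes, checks
#' whether any control phecode (a) passes the experiment-wide Bonferroni
#' threshold, (b) sits among the top `rank_cutoff` strongest associations,
#' or (c) passes the FDR threshold. Categories are not mutually exclusive.
#' Control phecodes absent from the results are untestable and excluded
#' from the denominators.
#'
#' @param adjusted Output of [adjust_multiplicity()].
#' @param control_spec Tibble: `biomarker`, `control_phecodes` (list-column
#'   or semicolon-joined string).
#' @param rank_cutoff Top-rank cutoff (default 5).
#' @return A list: `pairs` (per-biomarker logical flags and `testable`) and
#'   `summary` (percentage of testable pairs per category).
#' @export
evaluate_positive_controls <- function(adjusted, control_spec,
                                       rank_cutoff = 5) {
  if (nrow(control_spec) == 0) stop("empty positive-control spec",
                                    call. = FALSE)
  res <- adjusted$results
  if (!is.list(control_spec$control_phecodes)) {
    control_spec$control_phecodes <-
      strsplit(as.character(control_spec$control_phecodes), ";")
  }
  pairs <- purrr::pmap(control_spec, function(biomarker, control_phecodes,
                                              ...) {
    sub <- res[res$biomarker == biomarker &
                 res$phecode %in% control_phecodes, ]
    if (nrow(sub) == 0) {
      return(tibble::tibble(biomarker = biomarker, testable = FALSE,
                            bonferroni = NA, top_rank = NA, fdr = NA,
                            none = NA))
    }
    bonf <- any(sub$bonferroni_significant, na.rm = TRUE)
    topr <- any(!is.na(sub$rank) & sub$rank <= rank_cutoff)
    fdr <- any(sub$fdr_significant, na.rm = TRUE)
    tibble::tibble(biomarker = biomarker, testable = TRUE,
                   bonferroni = bonf, top_rank = topr, fdr = fdr,
                   none = !(bonf || topr || fdr))
  })
  pairs <- dplyr::bind_rows(pairs)
  testable <- dplyr::filter(pairs, .data$testable)
  denom <- max(nrow(testable), 1L)
  summary <- tibble::tibble(
    category = c("bonferroni", "top_rank", "fdr", "none"),
    n = c(sum(testable$bonferroni), sum(testable$top_rank),
          sum(testable$fdr), sum(testable$none)),
    pct = 100 * .data$n / denom
  )
  list(pairs = pairs, summary = summary)
}

#' Skewness of PheWAS regression coefficients
#'
#' Measures asymmetric enrichment of positive versus negative associations:
#' `(sum(beta^3)/n) / (sum(beta^2)/n)^(3/2)` over the retained
#' coefficients. To capture the mass of weak associations, low-powered
#' phenotypes are kept down to `min_cases`, while strong associations
#' (FDR q below `fdr_q`) are excluded.
#'
#' @param results Annotated results tibble (from [adjust_multiplicity()],
#'   i.e. with `q`), or any tibble with `beta`, `n_cases`, `converged`.
#' @param min_cases Retain phenotypes with more than this many cases
#'   (default 150).
#' @param exclude_fdr Drop FDR-significant associations (default `TRUE`).
#' @param fdr_q FDR threshold used for the exclusion.
#' @return The skewness value, with attributes `n_retained`; `NA` (with a
#'   warning) when every retained beta is zero.
#' @export
compute_skewness <- function(results, min_cases = 150, exclude_fdr = TRUE,
                             fdr_q = 0.1) {
  keep <- results$converged & !is.na(results$beta) &
    results$n_cases > min_cases
  if (exclude_fdr && "q" %in% names(results)) {
    keep <- keep & !(!is.na(results$q) & results$q < fdr_q)
  }
  b <- results$beta[keep]
  n <- length(b)
  if (n < 3) stop("fewer than 3 retained coefficients", call. = FALSE)
  if (all(b == 0)) {
    warning("all retained coefficients are zero; skewness undefined",
            call. = FALSE)
    return(structure(NA_real_, n_retained = n))
  }
  structure((sum(b^3) / n) / (sum(b^2) / n)^(3 / 2), n_retained = n)
}

#' Stratified association analysis
#'
#' Fits the score-phenotype logistic model independently within the two
#' levels of a binary stratifier (e.g. type 2 diabetes status), removing the
#' stratifier from the covariates. A stratum whose analysis set has a single
#' class is flagged unavailable rather than fatal.
#'
#' @param scores A [project_scores()] result.
#' @param assignment One [assemble_case_control()] result.
#' @param covariates Covariate table.
#' @param stratifier Named per-sample binary vector (names = sample ids), or
#'   the name of a binary covariate column.
#' @return Tibble with one row per stratum plus the fit columns and an
#'   `available` flag.
#' @export
stratified_association <- function(scores, assignment, covariates,
                                   stratifier) {
  if (is.character(stratifier) && length(stratifier) == 1) {
    strat <- stats::setNames(covariates[[stratifier]],
                             covariates$sample_id)
    covariates <- dplyr::select(covariates, -dplyr::all_of(stratifier))
  } else {
    strat <- stratifier
  }
  if (length(unique(strat)) < 2) {
    stop("stratifier is constant", call. = FALSE)
  }
  st <- dplyr::filter(assignment$status, .data$status != "excluded")
  st$y <- as.integer(st$status == "case")
  st$score <- stats::setNames(scores$standardized,
                              scores$sample_id)[st$sample_id]
  st$stratum <- strat[st$sample_id]
  purrr::map(sort(unique(st$stratum)), function(lev) {
    sub <- st[st$stratum == lev, ]
    cov <- covariates[match(sub$sample_id, covariates$sample_id), ]
    if (length(unique(sub$y)) < 2 || nrow(sub) < 10) {
      return(tibble::tibble(stratum = lev, available = FALSE,
                            beta = NA_real_, se = NA_real_, or = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p = NA_real_, converged = FALSE,
                            n_cases = sum(sub$y), n_controls = sum(!sub$y)))
    }
    res <- fit_logistic(sub$y, sub$score, build_covariate_frame(cov))
    dplyr::mutate(res, stratum = lev, available = TRUE,
                  n_cases = sum(sub$y), n_controls = sum(sub$y == 0L),
                  .before = 1)
  }) |> dplyr::bind_rows()
}

#' Cross-cohort direction concordance
#'
#' Joins two result sets on phecode, keeps pairs where the second cohort
#' shows a nominal association (`p < p_filter`), and reports the fraction
#' with matching coefficient sign — the feasibility check used when the
#' second cohort is too small for well-powered replication.
#'
#' @param results_a,results_b Result tibbles with `phecode`, `beta`, `p`.
#' @param p_filter Nominal significance filter applied to `results_b`
#'   (default 0.1).
#' @return One-row tibble: `concordance` (fraction, `NA` if no pairs
#'   survive the filter) and `n_pairs`.
#' @export
direction_concordance <- function(results_a, results_b, p_filter = 0.1) {
  joined <- dplyr::inner_join(
    dplyr::select(results_a, "phecode", beta_a = "beta"),
    dplyr::select(results_b, "phecode", beta_b = "beta", p_b = "p"),
    by = "phecode"
  )
  joined <- dplyr::filter(joined, !is.na(.data$p_b),
                          .data$p_b < p_filter,
                          !is.na(.data$beta_a), !is.na(.data$beta_b))
  if (nrow(joined) == 0) {
    warning("no pairs survive the p filter; concordance undefined",
            call. = FALSE)
    return(tibble::tibble(concordance = NA_real_, n_pairs = 0L))
  }
  tibble::tibble(
    concordance = mean(sign(joined$beta_a) == sign(joined$beta_b)),
    n_pairs = nrow(joined)
  )
}
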