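#' Configure an end-to-end pipeline run
#'
#' Bundles the two cohorts, the phenotype definitions, the sampler
#' configuration and the selection thresholds for [run_pipeline()]. Each
#' cohort input may be the in-memory object or a file path in one of the
#' package's dialects (dosage TSV / VCF for genotypes, CSV for occurrence
#' and definition tables); paths are loaded at validation time.
#'
#' @param measurement_genotypes,measurement_trait,measurement_covariates
#'   The measurement cohort: genotypes, quantitative biomarker vector (or a
#'   one-column TSV path), covariate table used for residualization.
#' @param target_genotypes,target_covariates,target_occurrences The target
#'   cohort: genotypes, covariate table, phecode occurrence table.
#' @param phecode_definitions Definition table (or CSV path).
#' @param positive_controls Optional positive-control spec tibble
#'   (`biomarker`, `control_phecodes`).
#' @param biomarker Label for the biomarker.
#' @param adjust_cols Covariate columns used to residualize the trait.
#' @param mcmc A [bslmm_config()].
#' @param alpha,fdr_q,min_cases,min_site_cases,rank_cutoff,p_filter
#'   Selection thresholds.
#' @param n_biomarkers Experiment-wide biomarker count for the Bonferroni
#'   denominator.
#' @param fdr_family `"per_biomarker"` or `"global"`.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(measurement_genotypes, measurement_trait,
                            measurement_covariates,
                            target_genotypes, target_covariates,
                            target_occurrences, phecode_definitions,
                            positive_controls = NULL,
                            biomarker = "biomarker",
                            adjust_cols = c("sex", "pc_1", "pc_2"),
                            mcmc = bslmm_config(),
                            alpha = 0.05, fdr_q = 0.1, min_cases = 300,
                            min_site_cases = 10, rank_cutoff = 5,
                            p_filter = 0.1, n_biomarkers = 1,
                            fdr_family = "per_biomarker",
                            seed = 1L, out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1, fdr_q > 0, fdr_q < 1,
            min_cases >= 1, min_site_cases >= 0, rank_cutoff >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

# Derive a per-stage seed from the global one so each stage is individually
# reproducible; the derivation hashes the stage name into a small offset.
stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 131L) %% 2147483647L
}

load_input <- function(x, loader) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("input file not found: ", x, call. = FALSE)
    loader(x)
  } else {
    x
  }
}

validate_pipeline_config <- function(config) {
  config$measurement_genotypes <-
    load_input(config$measurement_genotypes, read_genotypes)
  config$target_genotypes <-
    load_input(config$target_genotypes, read_genotypes)
  config$measurement_covariates <-
    load_input(config$measurement_covariates,
               function(p) readr::read_tsv(p, show_col_types = FALSE))
  config$target_covariates <-
    load_input(config$target_covariates,
               function(p) readr::read_tsv(p, show_col_types = FALSE))
  config$target_occurrences <-
    load_input(config$target_occurrences, read_occurrences)
  config$phecode_definitions <-
    load_input(config$phecode_definitions, read_phecode_definitions)
  config$measurement_trait <-
    load_input(config$measurement_trait,
               function(p) readr::read_tsv(p, show_col_types = FALSE)[[1]])
  if (length(config$measurement_trait) !=
      length(config$measurement_genotypes$samples)) {
    stop("trait length does not match the measurement cohort",
         call. = FALSE)
  }
  missing_cols <- setdiff(config$adjust_cols,
                          names(config$measurement_covariates))
  if (length(missing_cols)) {
    stop("adjust_cols absent from measurement covariates: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  config
}

#' Run the full biomarker-to-phenome pipeline
#'
#' Executes residualize, model fit, weight computation, allele alignment,
#' score projection, case/control assembly, the phenome scan, multiplicity
#' adjustment, positive-control evaluation and the skewness diagnostic, in
#' that order, logging each stage. Fully deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage log lines.
#' @return A list with all stage outputs (`fit`, `weights`, `alignment`,
#'   `scores`, `assignments`, `results`, `bonferroni_threshold`,
#'   `positive_controls`, `skewness`) and a `manifest` (config echo, input
#'   hashes, package version, per-stage wall time, warnings).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  config <- validate_pipeline_config(config)
  timings <- list()
  warnings_log <- character()
  note <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  resid <- run_stage("residualize", {
    cov <- config$measurement_covariates[, config$adjust_cols, drop = FALSE]
    residualize(config$measurement_trait, cov)
  })
  note("residualize", "trait adjusted for covariates")

  fit <- run_stage("fit_bslmm", {
    mc <- config$mcmc
    mc$seed <- stage_seed(config$seed, "fit_bslmm")
    fit_bslmm(config$measurement_genotypes, resid, mc)
  })
  note("fit_bslmm", sprintf("PVE %.3f, PGE %.3f", fit$summary$pve,
                            fit$summary$pge))

  weights <- run_stage("compute_weights", compute_weights(fit))

  alignment <- run_stage("align_alleles", {
    tgt_snps <- config$target_genotypes$snps
    align_alleles(weights, tgt_snps)
  })
  note("align_alleles",
       sprintf("%d matched, %d flipped, %d ambiguous, %d missing",
               alignment$report$n_matched, alignment$report$n_flipped,
               alignment$report$n_dropped_ambiguous,
               alignment$report$n_missing_in_target))

  scores <- run_stage("project_scores", {
    project_scores(config$target_genotypes, alignment$weights,
                   label = config$biomarker)
  })

  assignments <- run_stage("assemble_case_control", {
    defs <- config$phecode_definitions
    lapply(seq_len(nrow(defs)), function(i) {
      assemble_case_control(config$target_occurrences, defs[i, ],
                            config$target_covariates,
                            min_cases = config$min_cases,
                            min_site_cases = config$min_site_cases)
    })
  })
  n_rejected <- sum(vapply(assignments, `[[`, logical(1), "rejected"))
  note("assemble_case_control",
       sprintf("%d phenotypes, %d rejected", length(assignments),
               n_rejected))

  results <- run_stage("run_phewas", {
    run_phewas(scores, assignments, config$target_covariates,
               label = config$biomarker)
  })
  adjusted <- run_stage("adjust_multiplicity", {
    adjust_multiplicity(results, n_biomarkers = config$n_biomarkers,
                        alpha = config$alpha, fdr_q = config$fdr_q,
                        fdr_family = config$fdr_family)
  })
  note("adjust_multiplicity",
       sprintf("Bonferroni threshold %.3g", adjusted$bonferroni_threshold))

  controls <- NULL
  if (!is.null(config$positive_controls)) {
    controls <- run_stage("evaluate_positive_controls", {
      evaluate_positive_controls(adjusted, config$positive_controls,
                                 rank_cutoff = config$rank_cutoff)
    })
  }
  skewness <- run_stage("compute_skewness", {
    tryCatch(compute_skewness(adjusted$results,
                              fdr_q = config$fdr_q),
             error = function(e) NA_real_)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("phebridge")),
    seed = config$seed,
    biomarker = config$biomarker,
    input_hashes = list(
      measurement_genotypes = rlang::hash(config$measurement_genotypes),
      target_genotypes = rlang::hash(config$target_genotypes),
      occurrences = rlang::hash(config$target_occurrences)
    ),
    thresholds = config[c("alpha", "fdr_q", "min_cases", "min_site_cases",
                          "rank_cutoff", "p_filter", "n_biomarkers")],
    stage_seconds = timings,
    warnings = warnings_log
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    write_weights_tsv(weights, file.path(od, "weights.tsv"))
    write_scores_tsv(scores, file.path(od, "scores.tsv"))
    write_results_tsv(adjusted$results, file.path(od, "results.tsv"))
    write_fit_report(fit, file.path(od, "fit_report.json"))
    write_alignment_report(alignment$report,
                           file.path(od, "alignment.json"))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(fit = fit, weights = weights, alignment = alignment,
       scores = scores, assignments = assignments,
       results = adjusted$results,
       bonferroni_threshold = adjusted$bonferroni_threshold,
       positive_controls = controls, skewness = skewness,
       manifest = manifest)
}
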