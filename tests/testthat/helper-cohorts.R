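# Shared fixture builders: everything is generated in code at test time.

make_training_cohort <- function(n = 500, p = 1000, pve = 0.5, pge = 0.8,
                                 n_large = 10, n_poly = 500, seed = 1,
                                 mode = "exact") {
  panel <- snp_panel(p, seed = seed)
  g <- simulate_genotypes(n, panel, seed = seed + 1)
  bm <- simulate_biomarker(g, arch_spec(pve, pge, n_large, n_poly,
                                        seed = seed + 2, mode = mode))
  list(genotypes = g, biomarker = bm, panel = panel)
}

# Target cohort with one planted diagnosis and null companions, plus the
# true genetic value recomputed from the training truth on target dosages.
make_target_cohort <- function(panel, effects, n = 4000, n_null = 49,
                               planted_code = "250.1", planted_log_or = 0.5,
                               prevalence = 0.1, seed = 10) {
  g <- simulate_genotypes(n, panel, seed = seed)
  cov <- simulate_covariates(g$samples, seed = seed + 1)
  Xc <- scale(g$dosages, scale = FALSE)
  gv <- drop(Xc %*% effects$effect)
  specs <- c(
    list(diagnosis_spec(planted_code, prevalence,
                        genetic_log_or = planted_log_or)),
    lapply(seq_len(n_null), function(i) {
      diagnosis_spec(sprintf("%03d", i), prevalence, genetic_log_or = 0)
    })
  )
  occ <- simulate_diagnoses(gv, specs, cov, seed = seed + 2)
  defs <- dplyr::bind_rows(lapply(specs, function(s) {
    phecode_definition(s$phecode)
  }))
  list(genotypes = g, covariates = cov, occurrences = occ,
       definitions = defs, genetic_value = gv, planted_code = planted_code)
}

make_assignments <- function(target, min_cases = 100, min_site_cases = 0) {
  lapply(seq_len(nrow(target$definitions)), function(i) {
    assemble_case_control(target$occurrences, target$definitions[i, ],
                          target$covariates, min_cases = min_cases,
                          min_site_cases = min_site_cases)
  })
}

# Minimal association-result rows for the selection/diagnostic operations.
make_results <- function(betas, n_cases = 500, q = NA_real_,
                         biomarker = "bm", p = 0.5) {
  tibble::tibble(
    biomarker = biomarker,
    phecode = sprintf("%05.1f", seq_along(betas)),
    beta = betas, se = 0.05, or = exp(betas),
    ci_low = exp(betas - 0.1), ci_high = exp(betas + 0.1),
    p = rep_len(p, length(betas)), n_cases = n_cases, n_controls = 2000,
    converged = TRUE, rank = seq_along(betas), q = q
  )
}

# Count density modes with a prominence rule: peaks of the kernel density
# separated by a dip below 60% of the smaller peak.
n_modes <- function(x, adjust = 0.6) {
  d <- stats::density(x, adjust = adjust)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  peaks <- peaks[y[peaks] > 0.05 * max(y)]
  if (length(peaks) < 2) return(length(peaks))
  kept <- peaks[1]
  for (i in seq_along(peaks)[-1]) {
    valley <- min(y[kept[length(kept)]:peaks[i]])
    if (valley < 0.6 * min(y[kept[length(kept)]], y[peaks[i]])) {
      kept <- c(kept, peaks[i])
    } else if (y[peaks[i]] > y[kept[length(kept)]]) {
      kept[length(kept)] <- peaks[i]
    }
  }
  length(kept)
}

# Independent step-up oracle for Benjamini-Hochberg q-values.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in seq(n, 1)) {
    val <- min(prev, p[ord[i]] * n / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}
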