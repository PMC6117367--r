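tiny_cohort <- function(n = 40, sites = "s1", decades = c(1940, 1950)) {
  tibble::tibble(
    sample_id = sprintf("P%03d", seq_len(n)),
    sex = rep_len(c(0, 1), n),
    birth_decade = rep_len(decades, n),
    site = rep_len(sites, n),
    pc_1 = 0
  )
}

test_that("case, exclusion and birth-decade rules assign statuses", {
  cov <- tiny_cohort(n = 40, decades = c(1940, 1950, 1990))
  occ <- tibble::tibble(
    sample_id = c("P001", "P002", "P004"),
    phecode = c("401", "401.1", "401"),
    count = c(1L, 2L, 3L)
  )
  def <- phecode_definition("401", exclusion_codes = "401.1")
  # cases P001 and P004 (both born 1940); P002 excluded (related code only);
  # samples born 1990 fall outside the case birth-decade range
  cc <- assemble_case_control(occ, def, cov, min_cases = 1,
                              min_site_cases = 0)
  st <- setNames(cc$status$status, cc$status$sample_id)
  expect_equal(unname(st[c("P001", "P004")]), c("case", "case"))
  expect_equal(unname(st["P002"]), "excluded")
  born90 <- cov$sample_id[cov$birth_decade == 1990 &
                            !cov$sample_id %in% c("P001", "P002", "P004")]
  expect_true(all(st[born90] == "excluded"))
  expect_equal(cc$n_cases, 2)
  # controls never intersect cases; excluded appear in neither
  expect_length(intersect(cc$status$sample_id[st == "case"],
                          cc$status$sample_id[st == "control"]), 0)
})

test_that("thresholds, sites and sex restrictions reject phenotypes", {
  cov <- tiny_cohort(n = 600, sites = c("s1", "s2"))
  cases <- cov$sample_id[1:299]
  occ <- tibble::tibble(sample_id = cases, phecode = "008", count = 1L)
  def <- phecode_definition("008")
  expect_true(assemble_case_control(occ, def, cov, min_cases = 300,
                                    min_site_cases = 0)$rejected)
  expect_false(assemble_case_control(occ, def, cov, min_cases = 299,
                                     min_site_cases = 0)$rejected)

  # a site with fewer than min_site_cases cases is excluded wholesale
  occ_site <- tibble::tibble(
    sample_id = c(cov$sample_id[cov$site == "s1"][1:20],
                  cov$sample_id[cov$site == "s2"][1:5]),
    phecode = "008", count = 1L
  )
  cc <- assemble_case_control(occ_site, def, cov, min_cases = 1,
                              min_site_cases = 10)
  s2 <- cov$sample_id[cov$site == "s2"]
  expect_true(all(cc$status$status[cc$status$sample_id %in% s2] ==
                    "excluded"))
  expect_equal(cc$n_cases, 20)

  expect_true(assemble_case_control(
    occ, phecode_definition("008", sex_restriction = "female"), cov
  )$rejected)
  expect_error(assemble_case_control(occ, phecode_definition("999"), cov),
               "unknown phecode")
  expect_error(assemble_case_control(occ, def, cov[0, ]), "empty cohort")
})

test_that("the logistic fit matches the closed-form 2x2 odds ratio", {
  status <- rep(c(1, 1, 1, 0, 0, 0, 1, 0), times = c(30, 10, 5, 25, 40, 5, 3, 2))
  score <- rep(c(1, 0, 1, 0, 1, 0, 0, 1), times = c(30, 10, 5, 25, 40, 5, 3, 2))
  tab <- table(score, status)
  log_or <- log(tab["1", "1"] * tab["0", "0"] /
                  (tab["1", "0"] * tab["0", "1"]))
  fit <- fit_logistic(status, score)
  expect_lt(abs(fit$beta - log_or), 1e-6)
  expect_equal(fit$or, exp(fit$beta))
  expect_true(fit$ci_low < fit$or && fit$or < fit$ci_high)
})

test_that("permuted scores give uniform p-values", {
  withr::with_seed(7, {
    status <- rbinom(300, 1, 0.3)
    ps <- vapply(1:500, function(i) {
      fit_logistic(status, rnorm(300))$p
    }, numeric(1))
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("separation is flagged, not reported at face value", {
  status <- c(rep(0, 20), rep(1, 20))
  score <- c(rnorm(20, -3), rnorm(20, 3))
  fit <- fit_logistic(status, score)
  expect_false(fit$converged)
  expect_true(is.na(fit$beta))
  expect_error(fit_logistic(rep(1, 10), rnorm(10)), "single class")
})

test_that("the scan ranks the planted phenotype first and flags duplicates", {
  coh <- make_training_cohort(n = 600, p = 200, n_large = 8, n_poly = 100,
                              seed = 111)
  fit <- fit_bslmm(coh$genotypes, coh$biomarker$trait,
                   bslmm_config(n_steps = 10000, seed = 112))
  tgt <- make_target_cohort(coh$panel, coh$biomarker$effects, n = 3000,
                            n_null = 20, seed = 113)
  al <- align_alleles(compute_weights(fit), tgt$genotypes$snps)
  sc <- project_scores(tgt$genotypes, al$weights, label = "bm")
  asg <- make_assignments(tgt)
  res <- run_phewas(sc, asg, tgt$covariates)
  expect_equal(res$phecode[which(res$rank == 1)], tgt$planted_code)
  expect_true(all(diff(res$p[order(res$rank)]) >= 0))
  expect_error(run_phewas(sc, c(asg, asg[1]), tgt$covariates), "duplicate")

  # OR-per-SD convention: doubling the raw score scale changes nothing
  sc2 <- sc
  sc2$raw <- sc$raw * 2
  sc2$standardized <- (sc2$raw - mean(sc2$raw)) / sd(sc2$raw)
  res2 <- run_phewas(sc2, asg, tgt$covariates)
  expect_equal(res$beta, res2$beta, tolerance = 1e-8)
})

test_that("Bonferroni thresholds reproduce the experiment-wide arithmetic", {
  res <- make_results(rep(0.1, 4), p = c(0.01, 0.02, 0.03, 0.04))
  adj <- adjust_multiplicity(res, n_biomarkers = 53, n_phenotypes = 1139)
  expect_equal(adj$bonferroni_threshold, 0.05 / (53 * 1139))
  expect_equal(signif(adj$bonferroni_threshold, 3), 8.28e-7)
  expect_equal(adj$results$q, rep(0.04, 4)) # step-up collapses this ladder

  ones <- adjust_multiplicity(make_results(rep(0.1, 5), p = 1),
                              n_biomarkers = 1)
  expect_true(all(ones$results$q == 1))
  expect_false(any(ones$results$bonferroni_significant))
  expect_false(any(ones$results$fdr_significant))
  expect_error(adjust_multiplicity(make_results(numeric(0)), 1), "empty")
})

test_that("q-values match a brute-force step-up oracle and are monotone", {
  for (i in 1:25) {
    n <- withr::with_seed(500 + i, sample(2:20, 1))
    p <- withr::with_seed(600 + i, runif(n)^2)
    res <- make_results(rep(0.1, n), p = p)
    q <- adjust_multiplicity(res, n_biomarkers = 1)$results$q
    expect_lt(max(abs(q - bh_oracle(p))), 1e-12)
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("null scores are calibrated at the nominal type-I rate", {
  n <- 2000
  cov <- withr::with_seed(131, tibble::tibble(
    sample_id = sprintf("P%04d", 1:n),
    sex = rbinom(n, 1, 0.5),
    birth_decade = sample(c(1940, 1950, 1960), n, replace = TRUE),
    site = "s1", pc_1 = rnorm(n)
  ))
  score <- withr::with_seed(132, rnorm(n))
  ps <- withr::with_seed(133, vapply(1:200, function(i) {
    status <- rbinom(n, 1, 0.1)
    fit_logistic(status, score, cov[, c("sex", "pc_1")])$p
  }, numeric(1)))
  frac <- mean(ps < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("the false-discovery proportion at q < 0.1 is controlled", {
  fdp <- vapply(1:50, function(s) {
    withr::with_seed(700 + s, {
      n <- 5000
      score <- rnorm(n)
      truth <- c(rep(TRUE, 5), rep(FALSE, 45))
      ps <- vapply(seq_along(truth), function(i) {
        eta <- qlogis(0.1) + if (truth[i]) 0.4 * score else 0
        status <- rbinom(n, 1, plogis(eta))
        fit_logistic(status, score)$p
      }, numeric(1))
      q <- bh_oracle(ps)
      disc <- q < 0.1
      if (!any(disc)) 0 else sum(disc & !truth) / sum(disc)
    })
  }, numeric(1))
  expect_lte(mean(fdp), 0.2)
})

test_that("positive-control categories nest and untestable pairs drop out", {
  res <- make_results(c(2, 0.1, 0.05), p = c(1e-9, 0.2, 0.5))
  adj <- adjust_multiplicity(res, n_biomarkers = 1, n_phenotypes = 3)
  spec <- tibble::tibble(
    biomarker = c("bm", "bm", "other"),
    control_phecodes = list(res$phecode[1], "nope", "nope")
  )
  ev <- evaluate_positive_controls(adj, spec)
  hit <- ev$pairs[ev$pairs$testable & !is.na(ev$pairs$bonferroni), ]
  expect_true(hit$bonferroni[1])
  expect_true(hit$top_rank[1])
  expect_true(hit$fdr[1]) # Bonferroni passes imply FDR passes here
  expect_equal(sum(ev$pairs$testable), 1)
  expect_equal(ev$summary$pct[ev$summary$category == "top_rank"], 100)
  expect_error(evaluate_positive_controls(adj, spec[0, ]), "empty")
})

test_that("skewness obeys its algebraic identities", {
  expect_equal(as.numeric(compute_skewness(make_results(c(-0.4, 0, 0.4)))), 0)
  expect_equal(as.numeric(compute_skewness(make_results(rep(0.3, 5)))), 1)
  b <- withr::with_seed(141, rnorm(30, 0.2))
  s1 <- as.numeric(compute_skewness(make_results(b)))
  expect_equal(as.numeric(compute_skewness(make_results(-b))), -s1)
  expect_equal(as.numeric(compute_skewness(make_results(3.7 * b))), s1,
               tolerance = 1e-10)
  # case-count and FDR filters
  few <- make_results(c(1, 1, 1, -9), n_cases = c(500, 500, 500, 100))
  expect_equal(as.numeric(compute_skewness(few)), 1)
  strong <- make_results(c(0.3, 0.3, 0.3, -9), q = c(0.5, 0.5, 0.5, 0.001))
  expect_equal(as.numeric(compute_skewness(strong)), 1)
  expect_error(compute_skewness(make_results(c(1, 2))), "fewer than 3")
  expect_warning(z <- compute_skewness(make_results(rep(0, 5))), "zero")
  expect_true(is.na(z))
})

test_that("stratified fits recover homogeneous and stratum-specific effects", {
  n <- 8000
  cov <- withr::with_seed(151, tibble::tibble(
    sample_id = sprintf("P%05d", 1:n),
    sex = rbinom(n, 1, 0.5),
    birth_decade = sample(c(1940, 1950), n, replace = TRUE),
    site = "s1",
    t2d = rbinom(n, 1, 0.5)
  ))
  score <- withr::with_seed(152, rnorm(n))
  make_cc <- function(status) {
    structure(list(
      phecode = "038",
      status = tibble::tibble(sample_id = cov$sample_id,
                              status = ifelse(status == 1, "case",
                                              "control")),
      n_cases = sum(status), n_controls = sum(status == 0),
      rejected = FALSE
    ), class = "case_control")
  }
  scores <- tibble::tibble(sample_id = cov$sample_id, raw = score,
                           standardized = score)

  # homogeneous effect: the stratum estimates agree
  status <- withr::with_seed(153,
    rbinom(n, 1, plogis(qlogis(0.15) + 0.4 * score)))
  hom <- stratified_association(scores, make_cc(status), cov, "t2d")
  expect_true(all(hom$available))
  expect_true(hom$or[1] >= hom$ci_low[2] && hom$or[1] <= hom$ci_high[2])
  expect_true(hom$or[2] >= hom$ci_low[1] && hom$or[2] <= hom$ci_high[1])

  # effect planted in one stratum only
  eta <- qlogis(0.15) + ifelse(cov$t2d == 1, 0.5, 0) * score
  status2 <- withr::with_seed(154, rbinom(n, 1, plogis(eta)))
  het <- stratified_association(scores, make_cc(status2), cov, "t2d")
  expect_lt(het$p[het$stratum == 1], 0.05)
  expect_gt(het$p[het$stratum == 0], 0.05)

  cov_const <- dplyr::mutate(cov, t2d = 1)
  expect_error(stratified_association(scores, make_cc(status), cov_const,
                                      "t2d"), "constant")
})

test_that("direction concordance counts sign agreement after the p filter", {
  a <- make_results(c(0.5, -0.3, 0.2, 0.1), p = c(0.01, 0.02, 0.5, 0.03))
  expect_equal(direction_concordance(a, a)$concordance, 1)
  b <- a
  b$beta <- -b$beta
  expect_equal(direction_concordance(a, b)$concordance, 0)
  # rows failing p_b < 0.1 leave the denominator
  expect_equal(direction_concordance(a, a)$n_pairs, 3)
  strict <- a
  strict$p <- 1
  expect_warning(out <- direction_concordance(a, strict), "undefined")
  expect_true(is.na(out$concordance))
})
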