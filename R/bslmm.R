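#' Residualize a trait on covariates by ordinary least squares
#'
#' The biomarker is adjusted for covariates (e.g. age, sex and leading
#' principal components) by linear regression before model fitting; the
#' residuals are what the sparse mixed model sees.
#'
#' @param trait Per-sample numeric vector.
#' @param covariates Data frame (or matrix) of covariate columns; an
#'   intercept is always added. `NULL` or zero columns means intercept only.
#' @return Numeric residual vector, orthogonal to the intercept and to every
#'   covariate column.
#' @examples
#' residualize(rnorm(10), data.frame(age = 1:10))
#' @export
residualize <- function(trait, covariates = NULL) {
  n <- length(trait)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(trait - mean(trait))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  if (anyNA(covariates) || anyNA(trait)) {
    stop("missing values in trait or covariates", call. = FALSE)
  }
  mm <- stats::model.matrix(~., data = covariates)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("covariate matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  as.numeric(qr.resid(qr_mm, trait))
}

#' Configure the sparse mixed-model sampler
#'
#' Defaults follow the production schedule: 100,000 sampling steps with the
#' first half discarded and posterior summaries taken as medians over the
#' retained draws. Hyperparameter priors are uniform: h and rho on \[0, 1\],
#' log10(pi) on \[log10(1/p), 0\].
#'
#' @param n_steps Total Markov chain steps.
#' @param n_burn Discarded initial steps; default `n_steps / 2`.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chains are bit-reproducible.
#' @param s_max Cap on the size of the sparse inclusion set.
#' @param fix_rho Fix the sparse-fraction hyperparameter at a value (0
#'   disables the sparse component entirely, leaving a pure linear mixed
#'   model); `NULL` leaves it free.
#' @param step_h,step_rho,step_pi Metropolis proposal half-widths.
#' @return A list of class `bslmm_config`.
#' @export
bslmm_config <- function(n_steps = 100000, n_burn = NULL, thin = 10,
                         seed = 1L, s_max = 300, fix_rho = NULL,
                         step_h = 0.08, step_rho = 0.1, step_pi = 0.3) {
  if (is.null(n_burn)) n_burn <- n_steps %/% 2
  stopifnot(n_burn < n_steps, thin >= 1)
  if (!is.null(fix_rho)) stopifnot(fix_rho >= 0, fix_rho <= 1)
  structure(list(n_steps = as.integer(n_steps), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), seed = as.integer(seed),
                 s_max = as.integer(s_max), fix_rho = fix_rho,
                 step_h = step_h, step_rho = step_rho, step_pi = step_pi),
            class = "bslmm_config")
}

#' Fit the Bayesian sparse linear mixed model
#'
#' Models the residualized biomarker as `y = X beta + u + e`, where each SNP
#' effect `beta_i` follows a spike-and-slab mixture (a point mass at zero
#' with prior inclusion probability pi, a normal slab otherwise) and `u` is a
#' polygenic random effect with covariance proportional to the relatedness
#' matrix `K = X X'/p` on column-standardized genotypes. A
#' Metropolis-within-Gibbs chain moves over the hyperparameters
#' (h, rho, log10 pi) and the inclusion set, with effect sizes and the
#' residual precision integrated out analytically in the eigenbasis of `K`.
#'
#' Posterior summaries: `pve` is the h chain (total proportion of variance
#' explained), `pge` the rho chain (large-effect share of the genetic
#' variance), `n_gamma` the inclusion-set size. Per-SNP outputs are the
#' polygenic effect posterior mean `alpha`, the sparse effect posterior mean
#' given inclusion `beta`, and the posterior inclusion probability `gamma`,
#' all back-transformed to the per-allele (raw 0/1/2 dosage) scale.
#'
#' @param genotypes A [genotype_matrix()]. Missing dosages are mean-imputed;
#'   constant columns are dropped with a warning and recorded in the fit.
#' @param y Residualized trait vector.
#' @param config A [bslmm_config()].
#' @return An object of class `bslmm_fit`; see [tidy.bslmm_fit()] and
#'   [glance.bslmm_fit()].
#' @export
fit_bslmm <- function(genotypes, y, config = bslmm_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- length(y)
  if (n != length(genotypes$samples)) {
    stop("length of y does not match the genotype samples", call. = FALSE)
  }
  if (nrow(genotypes$snps) < 2) stop("need at least 2 SNPs", call. = FALSE)
  if (stats::sd(y) == 0) stop("y is constant", call. = FALSE)

  std <- standardize_dosages(genotypes)
  keep <- which(std$scale > 0)
  dropped <- genotypes$snps$snp_id[std$scale == 0 | is.na(std$scale)]
  if (length(dropped)) {
    warning(length(dropped), " constant SNP column(s) dropped",
            call. = FALSE)
    keep <- which(std$scale > 0 & !is.na(std$scale))
  }
  X <- sweep(std$X[, keep, drop = FALSE], 2, std$scale[keep], "/")
  p <- ncol(X)
  yc <- y - mean(y)

  K <- tcrossprod(X) / p
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  UtX <- crossprod(eig$vectors, X)
  Uty <- drop(crossprod(eig$vectors, yc))

  fix_rho <- if (is.null(config$fix_rho)) -1 else config$fix_rho
  mc <- .bslmm_mcmc(UtX, Uty, d,
                    config$n_steps, config$n_burn, config$thin,
                    log10(1 / p), 0, fix_rho,
                    min(config$s_max, p),
                    config$step_h, config$step_rho, config$step_pi,
                    config$seed)

  pip <- as.numeric(mc$pip)
  # mc$beta is the marginal mean E[beta * I(included)]; convert to the
  # conditional mean given inclusion so that w = alpha + beta * gamma
  # reproduces the marginal sparse contribution.
  beta_cond <- ifelse(pip > 0, as.numeric(mc$beta) / pip, 0)

  # Back-transform standardized-scale effects to per-allele effects.
  alpha_raw <- beta_raw <- gamma_raw <- numeric(nrow(genotypes$snps))
  alpha_raw[keep] <- as.numeric(mc$alpha) / std$scale[keep]
  beta_raw[keep] <- beta_cond / std$scale[keep]
  gamma_raw[keep] <- pip

  qsum <- function(x) {
    stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  }
  hq <- qsum(mc$h); rq <- qsum(mc$rho); mq <- qsum(as.numeric(mc$n_gamma))
  chains <- tibble::tibble(
    draw = seq_along(mc$h),
    h = as.numeric(mc$h), rho = as.numeric(mc$rho),
    log10_pi = as.numeric(mc$log10_pi), n_gamma = as.integer(mc$n_gamma)
  )
  structure(list(
    summary = tibble::tibble(
      pve = hq[1], pve_lo = hq[2], pve_hi = hq[3],
      pge = rq[1], pge_lo = rq[2], pge_hi = rq[3],
      n_gamma = mq[1], n_gamma_lo = mq[2], n_gamma_hi = mq[3],
      n_samples = n, n_snps = p,
      accept_hyper = mc$accept_hyper, accept_gamma = mc$accept_gamma,
      ess_h = ess(chains$h)
    ),
    snps = tibble::tibble(
      snp_id = genotypes$snps$snp_id,
      chrom = genotypes$snps$chrom,
      pos = genotypes$snps$pos,
      coded_allele = genotypes$snps$coded_allele,
      other_allele = genotypes$snps$other_allele,
      alpha = alpha_raw, beta = beta_raw, gamma = gamma_raw
    ),
    chains = chains,
    dropped_snps = dropped,
    config = config
  ), class = "bslmm_fit")
}

# Effective sample size from the initial positive sequence of
# autocorrelations (Geyer-style truncation).
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' @export
print.bslmm_fit <- function(x, ...) {
  s <- x$summary
  cat("<bslmm_fit> ", s$n_samples, " samples, ", s$n_snps, " SNPs\n",
      sprintf("  PVE %.3f [%.3f, %.3f]  PGE %.3f [%.3f, %.3f]  n_gamma %g\n",
              s$pve, s$pve_lo, s$pve_hi, s$pge, s$pge_lo, s$pge_hi,
              s$n_gamma), sep = "")
  invisible(x)
}

#' Per-SNP projection weights from a fitted model
#'
#' Combines the polygenic posterior mean with the sparse effect weighted by
#' its posterior inclusion probability: `w = alpha + beta * gamma`. Weights
#' apply to raw coded-allele dosages and carry the coded allele used during
#' fitting.
#'
#' @param fit A [fit_bslmm()] result.
#' @param snp_meta Optional SNP metadata to verify against the fit (must
#'   cover the same SNPs in the same order).
#' @return A tibble: `snp_id`, `chrom`, `pos`, `coded_allele`,
#'   `other_allele`, `alpha`, `beta`, `gamma`, `w`.
#' @export
compute_weights <- function(fit, snp_meta = NULL) {
  stopifnot(inherits(fit, "bslmm_fit"))
  snps <- fit$snps
  if (!is.null(snp_meta)) {
    if (nrow(snp_meta) != nrow(snps) ||
        !identical(snp_meta$snp_id, snps$snp_id)) {
      stop("snp_meta does not match the fitted SNPs", call. = FALSE)
    }
  }
  dplyr::mutate(snps, w = .data$alpha + .data$beta * .data$gamma)
}

#' Holdout estimate of the percent of PVE captured by the predictor
#'
#' Randomly removes `holdout_n` samples, fits the model on the remainder,
#' projects the held-out genotypes through the resulting weights, and
#' reports 100 x (R-squared of the held-out trait on the predicted score) /
#' (posterior median PVE): how much of the estimated genetic variance the
#' predictor actually recovers out of sample.
#'
#' @param genotypes A [genotype_matrix()] for the full cohort.
#' @param y Residualized trait for the full cohort.
#' @param config A [bslmm_config()] for the training fit.
#' @param holdout_n Held-out sample count (default 500).
#' @param seed Seed for the holdout split.
#' @return One-row tibble: `pct_pve`, `r2`, `pve`, `holdout_n`, `defined`
#'   (`FALSE` when the fitted PVE is numerically zero, in which case
#'   `pct_pve` is `NA` rather than a division blow-up).
#' @export
estimate_pct_pve <- function(genotypes, y, config = bslmm_config(),
                             holdout_n = 500, seed = 1L) {
  n <- length(genotypes$samples)
  if (holdout_n >= n - 50) {
    stop("holdout_n too large for the cohort", call. = FALSE)
  }
  hold <- withr::with_seed(seed, sample.int(n, holdout_n))
  train <- setdiff(seq_len(n), hold)
  sub <- function(idx) {
    genotype_matrix(genotypes$dosages[idx, , drop = FALSE], genotypes$snps,
                    genotypes$samples[idx])
  }
  fit <- fit_bslmm(sub(train), y[train], config)
  wts <- compute_weights(fit)
  sc <- project_scores(sub(hold), wts)
  r2 <- stats::cor(y[hold], sc$raw)^2
  pve <- fit$summary$pve
  if (pve < 1e-6) {
    return(tibble::tibble(pct_pve = NA_real_, r2 = r2, pve = pve,
                          holdout_n = holdout_n, defined = FALSE))
  }
  tibble::tibble(pct_pve = 100 * r2 / pve, r2 = r2, pve = pve,
                 holdout_n = holdout_n, defined = TRUE)
}
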