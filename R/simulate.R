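#' Specify a genetic architecture for a simulated biomarker
#'
#' The architecture is described by the proportion of phenotype variance
#' explained by all SNPs jointly (`pve`), the proportion of that genetic
#' variance carried by a handful of large-effect SNPs (`pge`), and the counts
#' of large-effect and small-effect causal SNPs.
#'
#' @param pve Proportion of phenotype variance explained by genetics, in
#'   \[0, 1\].
#' @param pge Proportion of the genetic variance from large-effect SNPs, in
#'   \[0, 1\].
#' @param n_large Number of large-effect causal SNPs.
#' @param n_poly Number of small-effect (polygenic) causal SNPs.
#' @param seed Integer seed.
#' @param mode `"exact"` rescales components so the realized in-sample
#'   variance fractions equal `pve`/`pge` to machine precision; `"sampled"`
#'   draws effects from the implied normals so realized fractions vary
#'   around the targets.
#' @return A list of class `arch_spec`.
#' @export
arch_spec <- function(pve, pge, n_large, n_poly, seed = 1L,
                      mode = c("exact", "sampled")) {
  mode <- match.arg(mode)
  if (pve < 0 || pve > 1) stop("pve must lie in [0, 1]", call. = FALSE)
  if (pge < 0 || pge > 1) stop("pge must lie in [0, 1]", call. = FALSE)
  if (pge > 0 && pve > 0 && n_large < 1) {
    stop("pge > 0 requires n_large >= 1", call. = FALSE)
  }
  structure(list(pve = pve, pge = pge, n_large = n_large, n_poly = n_poly,
                 seed = as.integer(seed), mode = mode),
            class = "arch_spec")
}

#' Simulate a quantitative biomarker with known genetic architecture
#'
#' Generates trait = large-effect component + polygenic component + Gaussian
#' noise over the supplied genotypes. In `"exact"` mode the three components
#' are orthogonalized and rescaled in-sample so that the realized PVE and PGE
#' equal the requested values to machine precision and the trait has unit
#' variance; this gives downstream estimators a sharp known truth.
#'
#' @param genotypes A [genotype_matrix()].
#' @param arch An [arch_spec()].
#' @return A list with `trait` (per-sample vector), `genetic_value` (the true
#'   per-sample genetic component), `effects` (tibble of per-SNP true effects
#'   on centered dosages), and realized `pve`/`pge`.
#' @examples
#' g <- simulate_genotypes(200, snp_panel(50), seed = 1)
#' b <- simulate_biomarker(g, arch_spec(0.5, 0.8, n_large = 5, n_poly = 20))
#' @export
simulate_biomarker <- function(genotypes, arch) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(arch, "arch_spec"))
  p <- nrow(genotypes$snps)
  n <- length(genotypes$samples)
  if (arch$n_large + arch$n_poly > p) {
    stop("n_large + n_poly exceeds the number of SNPs", call. = FALSE)
  }
  withr::with_seed(arch$seed, {
    X <- genotypes$dosages
    X[is.na(X)] <- 0
    X <- scale(X, center = TRUE, scale = FALSE)
    causal <- sample.int(p, arch$n_large + arch$n_poly)
    idx_l <- causal[seq_len(arch$n_large)]
    idx_p <- setdiff(causal, idx_l)
    b <- numeric(p)

    want_large <- arch$pve > 0 && arch$pge > 0 && arch$n_large > 0
    want_poly <- arch$pve > 0 && arch$pge < 1 && arch$n_poly > 0
    L <- P <- numeric(n)
    b_l <- b_p <- NULL
    if (want_large) {
      b_l <- stats::rnorm(arch$n_large)
      L <- drop(X[, idx_l, drop = FALSE] %*% b_l)
    }
    if (want_poly) {
      b_p <- stats::rnorm(arch$n_poly)
      P <- drop(X[, idx_p, drop = FALSE] %*% b_p)
    }
    eps <- stats::rnorm(n)

    if (arch$mode == "exact") {
      # Orthogonalize P against L, then noise against both, then rescale each
      # component so the in-sample variance decomposition is exact.
      c_pl <- 0
      if (want_large && want_poly && stats::var(L) > 0) {
        c_pl <- stats::cov(P, L) / stats::var(L)
        P <- P - c_pl * L
      }
      v_l <- if (want_large) arch$pve * arch$pge else 0
      v_p <- if (want_poly) arch$pve * (1 - arch$pge) else 0
      s_l <- if (want_large && stats::var(L) > 0) sqrt(v_l / stats::var(L)) else 0
      s_p <- if (want_poly && stats::var(P) > 0) sqrt(v_p / stats::var(P)) else 0
      L <- s_l * L
      P <- s_p * P
      g <- L + P
      fit <- stats::lm.fit(cbind(1, L, P), eps)
      e <- fit$residuals
      e <- e * sqrt((1 - arch$pve) / stats::var(e))
      if (want_large) {
        b[idx_l] <- b_l * s_l
        if (c_pl != 0) b[idx_l] <- b[idx_l] - c_pl * b_l * s_p
      }
      if (want_poly) b[idx_p] <- b_p * s_p
    } else {
      # Sampled mode: scale by expected (population) component variances.
      colv <- 2 * genotypes$snps$maf * (1 - genotypes$snps$maf)
      s_l <- s_p <- 0
      if (want_large) {
        ev <- sum(colv[idx_l])
        s_l <- sqrt(arch$pve * arch$pge / ev)
      }
      if (want_poly) {
        ev <- sum(colv[idx_p])
        s_p <- sqrt(arch$pve * (1 - arch$pge) / ev)
      }
      L <- s_l * L
      P <- s_p * P
      g <- L + P
      e <- eps * sqrt(1 - arch$pve)
      if (want_large) b[idx_l] <- b_l * s_l
      if (want_poly) b[idx_p] <- b_p * s_p
    }
    trait <- g + e
    realized_pve <- if (stats::var(trait) > 0) stats::var(g) / stats::var(trait) else 0
    realized_pge <- if (stats::var(g) > 0) stats::var(L) / stats::var(g) else 0
    list(
      trait = as.numeric(trait),
      genetic_value = as.numeric(g),
      effects = tibble::tibble(
        snp_id = genotypes$snps$snp_id,
        effect = b,
        is_large = seq_len(p) %in% idx_l,
        is_poly = seq_len(p) %in% idx_p
      ),
      pve = realized_pve,
      pge = realized_pge
    )
  })
}

#' Simulate a covariate table
#'
#' One row per sample: binary sex (1 = female), birth decade, site and
#' genotyping platform labels, and `n_pcs` standard-normal principal
#' component columns.
#'
#' @param samples Character vector of sample ids.
#' @param seed Integer seed.
#' @param n_pcs,n_sites,n_platforms Numbers of PC columns, sites, platforms.
#' @return A tibble keyed by `sample_id`.
#' @export
simulate_covariates <- function(samples, seed, n_pcs = 3, n_sites = 3,
                                n_platforms = 2) {
  n <- length(samples)
  withr::with_seed(seed, {
    cov <- tibble::tibble(
      sample_id = samples,
      sex = stats::rbinom(n, 1, 0.5),
      birth_decade = sample(seq(1920L, 1980L, by = 10L), n, replace = TRUE),
      site = sample(paste0("site", seq_len(n_sites)), n, replace = TRUE),
      platform = sample(paste0("chip", seq_len(n_platforms)), n, replace = TRUE)
    )
    pcs <- matrix(stats::rnorm(n * n_pcs), n, n_pcs,
                  dimnames = list(NULL, paste0("pc_", seq_len(n_pcs))))
    dplyr::bind_cols(cov, tibble::as_tibble(pcs))
  })
}

#' Specify a simulated diagnosis
#'
#' @param phecode Phecode string for the phenotype.
#' @param prevalence Target case fraction among eligible samples, in (0, 1).
#' @param genetic_log_or Log odds ratio on disease liability per standard
#'   deviation of the biomarker's true genetic value.
#' @param exclusion_codes Phecodes "closely related" to this one; carriers
#'   are barred from the control group downstream.
#' @param sex_restriction One of `"both"`, `"male"`, `"female"`.
#' @return A list of class `diagnosis_spec`.
#' @export
diagnosis_spec <- function(phecode, prevalence, genetic_log_or = 0,
                           exclusion_codes = character(),
                           sex_restriction = "both") {
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }
  sex_restriction <- match.arg(sex_restriction, c("both", "male", "female"))
  structure(list(phecode = as.character(phecode), prevalence = prevalence,
                 genetic_log_or = genetic_log_or,
                 exclusion_codes = as.character(exclusion_codes),
                 sex_restriction = sex_restriction),
            class = "diagnosis_spec")
}

#' Simulate phecode occurrences from a liability model
#'
#' Case status for each diagnosis is drawn from a logistic model on the
#' standardized true genetic value, with the intercept solved numerically so
#' the expected prevalence matches the specification. The logistic link is
#' chosen deliberately: planted log odds ratios are then recoverable on their
#' own scale by the downstream logistic phenome scan. Sex-restricted codes
#' are assigned only to the eligible sex. To exercise control exclusion
#' downstream, each exclusion code is also assigned to a random fraction of
#' non-case samples.
#'
#' @param genetic_value Per-sample true genetic value (from
#'   [simulate_biomarker()]).
#' @param specs A list of [diagnosis_spec()] objects.
#' @param covariates Covariate table with `sample_id` and `sex`.
#' @param seed Integer seed.
#' @param exclusion_rate Fraction of non-case samples receiving each
#'   exclusion code.
#' @return Long occurrence tibble: `sample_id`, `phecode`, `count`.
#' @export
simulate_diagnoses <- function(genetic_value, specs, covariates, seed,
                               exclusion_rate = 0.05) {
  if (inherits(specs, "diagnosis_spec")) specs <- list(specs)
  if (length(specs) == 0) stop("no diagnosis specs supplied", call. = FALSE)
  n <- length(genetic_value)
  stopifnot(nrow(covariates) == n)
  z <- if (stats::sd(genetic_value) > 0) {
    as.numeric(scale(genetic_value))
  } else {
    rep(0, n)
  }
  withr::with_seed(seed, {
    rows <- purrr::map(specs, function(sp) {
      eligible <- switch(sp$sex_restriction,
        both = rep(TRUE, n),
        female = covariates$sex == 1,
        male = covariates$sex == 0
      )
      ze <- z[eligible]
      b0 <- stats::uniroot(
        function(b) mean(stats::plogis(b + sp$genetic_log_or * ze)) -
          sp$prevalence,
        interval = c(-30, 30), tol = 1e-10
      )$root
      pr <- stats::plogis(b0 + sp$genetic_log_or * ze)
      status <- rep(0L, n)
      status[eligible] <- stats::rbinom(sum(eligible), 1L, pr)
      case_ids <- covariates$sample_id[status == 1L]
      out <- list(tibble::tibble(
        sample_id = case_ids,
        phecode = sp$phecode,
        count = 1L + stats::rpois(length(case_ids), 0.5)
      ))
      for (ex in sp$exclusion_codes) {
        non_case <- covariates$sample_id[status == 0L]
        pick <- non_case[stats::runif(length(non_case)) < exclusion_rate]
        if (length(pick)) {
          out <- c(out, list(tibble::tibble(
            sample_id = pick, phecode = ex, count = 1L
          )))
        }
      }
      dplyr::bind_rows(out)
    })
    dplyr::bind_rows(rows)
  })
}
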