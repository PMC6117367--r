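test_that("residualization centers, zeroes exact fits and is orthogonal", {
  set.seed(1)
  y <- rnorm(100)
  expect_equal(residualize(y, NULL), y - mean(y))

  cov <- data.frame(age = rnorm(100), sex = rbinom(100, 1, 0.5))
  exact <- 2 + 0.5 * cov$age - 1.2 * cov$sex
  expect_lt(max(abs(residualize(exact, cov))), 1e-10)

  r <- residualize(y, cov)
  for (col in cov) {
    expect_lt(abs(sum(r * col)),
              1e-8 * sqrt(sum(col^2)) * sqrt(sum(y^2)))
  }
  expect_lt(abs(sum(r)), 1e-8)
})

test_that("rank-deficient covariates fail naming the collinear column", {
  set.seed(2)
  cov <- data.frame(a = rnorm(50))
  cov$b <- 2 * cov$a
  expect_error(residualize(rnorm(50), cov), "b")
})

test_that("weights obey w = alpha + beta * gamma row-wise", {
  fake <- structure(list(snps = tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3"), chrom = "1", pos = 1:3,
    coded_allele = "A", other_allele = "G",
    alpha = c(0.01, 0.02, 0), beta = c(0.5, 0.3, 0.7),
    gamma = c(0.2, 0, 1)
  )), class = "bslmm_fit")
  w <- compute_weights(fake)
  expect_equal(w$w, c(0.11, 0.02, 0.7))
  expect_equal(w$w[2], w$alpha[2]) # gamma = 0 leaves the polygenic part
  expect_equal(w$w[3], w$beta[3])  # alpha = 0, gamma = 1 gives the slab
  bad_meta <- fake$snps[c(2, 1, 3), ]
  expect_error(compute_weights(fake, bad_meta), "match")
})

test_that("chains are bit-reproducible under a fixed seed", {
  coh <- make_training_cohort(n = 120, p = 60, n_large = 3, n_poly = 30,
                              seed = 11)
  cfg <- bslmm_config(n_steps = 3000, seed = 42)
  f1 <- fit_bslmm(coh$genotypes, coh$biomarker$trait, cfg)
  f2 <- fit_bslmm(coh$genotypes, coh$biomarker$trait, cfg)
  expect_identical(f1$chains, f2$chains)
  expect_identical(tidy(f1), tidy(f2))
  f3 <- fit_bslmm(coh$genotypes, coh$biomarker$trait,
                  bslmm_config(n_steps = 3000, seed = 43))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("posterior summaries stay inside their natural ranges", {
  coh <- make_training_cohort(n = 150, p = 80, n_large = 2, n_poly = 40,
                              seed = 21)
  fit <- fit_bslmm(coh$genotypes, coh$biomarker$trait,
                   bslmm_config(n_steps = 4000, seed = 1))
  s <- glance(fit)
  expect_true(s$pve >= 0 && s$pve <= 1)
  expect_true(s$pge >= 0 && s$pge <= 1)
  expect_true(s$n_gamma >= 0 && s$n_gamma <= s$n_snps)
  expect_true(all(fit$snps$gamma >= 0 & fit$snps$gamma <= 1))
})

test_that("a pure-noise trait yields a small posterior PVE", {
  g <- simulate_genotypes(300, snp_panel(200, seed = 31), seed = 32)
  y <- withr::with_seed(33, rnorm(300))
  fit <- fit_bslmm(g, y, bslmm_config(n_steps = 10000, seed = 34))
  expect_lt(glance(fit)$pve, 0.15)
})

test_that("constant columns are dropped with a warning; constant y errors", {
  panel <- snp_panel(10, maf = c(0, rep(0.3, 9)))
  g <- simulate_genotypes(100, panel, seed = 41)
  y <- withr::with_seed(42, rnorm(100))
  expect_warning(
    fit <- fit_bslmm(g, y, bslmm_config(n_steps = 1000, seed = 1)),
    "constant"
  )
  expect_equal(fit$dropped_snps, panel$snp_id[1])
  expect_equal(fit$snps$gamma[1], 0)
  expect_error(fit_bslmm(g, rep(1, 100)), "constant")
})

test_that("with the sparse component off, weights match the analytic BLUP", {
  coh <- make_training_cohort(n = 150, p = 120, pve = 0.4, pge = 0,
                              n_large = 0, n_poly = 80, seed = 51)
  fit <- fit_bslmm(coh$genotypes, coh$biomarker$trait,
                   bslmm_config(n_steps = 6000, seed = 52, fix_rho = 0))
  w <- compute_weights(fit)
  expect_true(all(w$gamma == 0))
  X <- scale(coh$genotypes$dosages)
  y <- coh$biomarker$trait - mean(coh$biomarker$trait)
  h <- glance(fit)$pve
  sb2 <- h / (1 - h)
  K <- tcrossprod(X) / ncol(X)
  blup <- drop((sb2 / ncol(X)) *
                 crossprod(X, solve(diag(nrow(X)) + sb2 * K, y))) /
    attr(X, "scaled:scale")
  expect_gt(cor(blup, w$w), 0.99)
})

test_that("an overwhelming single causal SNP earns a high inclusion probability", {
  panel <- snp_panel(2, maf = c(0.3, 0.3))
  g <- simulate_genotypes(2000, panel, seed = 61)
  bm <- simulate_biomarker(g, arch_spec(0.5, 1, n_large = 1, n_poly = 0,
                                        seed = 62))
  fit <- fit_bslmm(g, bm$trait, bslmm_config(n_steps = 20000, seed = 63))
  causal <- which(bm$effects$is_large)

  # Exact posterior by enumerating the four inclusion sets and integrating
  # the hyperparameters on a grid. With p = 2 the polygenic term can absorb
  # part of a single-SNP signal (the relatedness matrix is half that SNP),
  # which caps the inclusion probability below 1 even for huge effects.
  X <- scale(g$dosages)
  y <- bm$trait - mean(bm$trait)
  n <- length(y)
  K <- tcrossprod(X) / 2
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  UtX <- crossprod(eig$vectors, X)
  Uty <- drop(crossprod(eig$vectors, y))
  loglik <- function(idx, h, rho, pi) {
    sb2 <- h * (1 - rho) / (1 - h)
    hinv <- 1 / (1 + sb2 * d)
    ldH <- -sum(log(hinv))
    yHy <- sum(Uty^2 * hinv)
    m <- length(idx)
    if (m == 0) return(-0.5 * ldH - n / 2 * log(yHy))
    sa2 <- h * rho / ((1 - h) * pi * 2)
    Xg <- UtX[, idx, drop = FALSE]
    Xh <- Xg * hinv
    M <- crossprod(Xg, Xh) + diag(1 / sa2, m)
    v <- crossprod(Xh, Uty)
    q <- yHy - drop(crossprod(v, solve(M, v)))
    if (q <= 0) return(NA_real_)
    as.numeric(-0.5 * (ldH + m * log(sa2) + determinant(M)$modulus) -
                 n / 2 * log(q))
  }
  hs <- seq(0.005, 0.995, length.out = 60)
  rhos <- seq(0.005, 0.995, length.out = 60)
  l10s <- seq(log10(0.5), 0, length.out = 12)
  sets <- list(integer(0), 1L, 2L, c(1L, 2L))
  tot <- vapply(sets, function(idx) {
    m <- length(idx)
    acc <- vapply(hs, function(h) {
      vapply(rhos, function(rho) {
        vapply(l10s, function(l) {
          pi <- 10^l
          loglik(idx, h, rho, pi) + m * log(pi) + (2 - m) * log(1 - pi)
        }, numeric(1))
      }, numeric(length(l10s)))
    }, matrix(0, length(l10s), length(rhos)))
    mx <- max(acc, na.rm = TRUE)
    mx + log(mean(exp(acc - mx), na.rm = TRUE))
  }, numeric(1))
  post <- exp(tot - max(tot))
  post <- post / sum(post)
  exact_pip <- sum(post[vapply(sets, function(s) causal %in% s,
                               logical(1))])
  expect_gt(exact_pip, 0.8)
  expect_gt(fit$snps$gamma[causal], 0.8)
  expect_lt(abs(fit$snps$gamma[causal] - exact_pip), 0.06)
})

test_that("posterior median PVE is monotone in the simulated PVE", {
  med <- vapply(c(0.1, 0.5, 0.9), function(pve) {
    fits <- vapply(1:10, function(s) {
      coh <- make_training_cohort(n = 200, p = 150, pve = pve, pge = 0.5,
                                  n_large = 5, n_poly = 80, seed = 70 + s)
      glance(fit_bslmm(coh$genotypes, coh$biomarker$trait,
                       bslmm_config(n_steps = 5000, seed = s)))$pve
    }, numeric(1))
    mean(fits)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("holdout %PVE approaches 100 for the true genetic predictor and is deterministic", {
  coh <- make_training_cohort(n = 600, p = 200, pve = 0.5, pge = 0.8,
                              n_large = 5, n_poly = 100, seed = 81)
  cfg <- bslmm_config(n_steps = 8000, seed = 1)
  r1 <- estimate_pct_pve(coh$genotypes, coh$biomarker$trait, cfg,
                         holdout_n = 150, seed = 9)
  r2 <- estimate_pct_pve(coh$genotypes, coh$biomarker$trait, cfg,
                         holdout_n = 150, seed = 9)
  expect_identical(r1, r2)
  expect_true(r1$defined)
  expect_gt(r1$pct_pve, 0)

  # upper reference: the holdout's own true genetic value explains ~PVE of y,
  # so scoring with the true effects puts %PVE near 100
  hold <- withr::with_seed(9, sample.int(600, 150))
  gv <- coh$biomarker$genetic_value[hold]
  y <- coh$biomarker$trait[hold]
  ref <- 100 * cor(y, gv)^2 / 0.5
  expect_gt(ref, 70)

  # permutation null: shuffled weights explain essentially nothing
  fit <- fit_bslmm(coh$genotypes, coh$biomarker$trait, cfg)
  w <- compute_weights(fit)
  sub <- genotype_matrix(coh$genotypes$dosages[hold, ], coh$genotypes$snps,
                         coh$genotypes$samples[hold])
  null_pct <- vapply(1:20, function(s) {
    ws <- w
    ws$w <- withr::with_seed(100 + s, sample(ws$w))
    sc <- project_scores(sub, ws)
    100 * cor(y, sc$raw)^2 / glance(fit)$pve
  }, numeric(1))
  expect_lt(mean(null_pct), 5)
})
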