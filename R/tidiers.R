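#' Tidy the per-SNP posterior summaries of a model fit
#'
#' @param x A [fit_bslmm()] result.
#' @param ... Unused.
#' @return Tibble with one row per SNP: allele metadata, `alpha`, `beta`,
#'   `gamma` and the projection weight `w = alpha + beta * gamma`.
#' @export
tidy.bslmm_fit <- function(x, ...) {
  compute_weights(x)
}

#' One-row posterior summary of a model fit
#'
#' @param x A [fit_bslmm()] result.
#' @param ... Unused.
#' @return One-row tibble: PVE, PGE and large-effect-count medians with 95
#'   percent credible intervals, sample/SNP counts, acceptance rates and
#'   the effective sample size of the h chain.
#' @export
glance.bslmm_fit <- function(x, ...) {
  x$summary
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
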