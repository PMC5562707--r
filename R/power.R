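#' Detectable causal effect (explained variance) of a two-sample design
#'
#' On standardized scales the smallest causal effect detectable with the
#' requested power at a two-sided significance level is
#' \deqn{\beta_{det} = \frac{z_{1-\alpha/2} + z_{power}}
#'                          {\sqrt{n_{outcome} \, R^2_{GX}}},}
#' where \eqn{R^2_{GX}} is the variance of the exposure explained by the
#' instruments ([explainedVariance()]) and the sample size is that of
#' the outcome dataset (the ratio estimate's variance involves the
#' outcome dataset only). Because on standardized scales
#' \eqn{\beta_{causal}^2} equals the variance of the outcome explained
#' by the exposure, the returned value \eqn{\beta_{det}^2} is the
#' detectable causal \eqn{R^2}.
#'
#' @param alpha Two-sided significance level, e.g. 0.05/8 = 0.00625 when
#'   eight correlated trait blocks are tested.
#' @param power Target power in (0, 1), e.g. 0.8.
#' @param nOutcome Sample size of the outcome GWAS.
#' @param r2GX Instrument explained variance on the exposure, in (0, 1).
#' @return Detectable causal \eqn{R^2} as a fraction in (0, 1).
#' @examples
#' # an 0.0676 instrument R2 and a 13,813-sample outcome GWAS allow
#' # detection of causal effects explaining >= 1.37% of the outcome
#' detectableCausalR2(0.00625, 0.8, 13813, 0.0676)
#' @export
detectableCausalR2 <- function(alpha, power, nOutcome, r2GX) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            nOutcome > 0, r2GX > 0, r2GX < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  (z / sqrt(nOutcome * r2GX))^2
}

#' Power to detect a given standardized causal effect
#'
#' Two-sided normal-approximation power of the two-sample design:
#' \deqn{\Phi\big({-z_{1-\alpha/2}} + |\beta| \sqrt{n R^2_{GX}}\big) +
#'       \Phi\big({-z_{1-\alpha/2}} - |\beta| \sqrt{n R^2_{GX}}\big).}
#' At \eqn{\beta = 0} this returns the test size \eqn{\alpha}; it is the
#' inverse of [detectableCausalR2()] in the sense that the power at
#' \eqn{\beta = \sqrt{R^2_{det}}} recovers the target power (up to the
#' negligible opposite-tail term).
#'
#' @param alpha Two-sided significance level.
#' @param nOutcome Sample size of the outcome GWAS.
#' @param r2GX Instrument explained variance on the exposure.
#' @param betaCausal Standardized causal effect.
#' @return Power in (0, 1).
#' @export
powerAtEffect <- function(alpha, nOutcome, r2GX, betaCausal) {
  stopifnot(alpha > 0, alpha < 1, nOutcome > 0, r2GX > 0, r2GX < 1)
  zq <- stats::qnorm(1 - alpha / 2)
  shift <- abs(betaCausal) * sqrt(nOutcome * r2GX)
  stats::pnorm(-zq + shift) + stats::pnorm(-zq - shift)
}

#' Batch power analysis
#'
#' Evaluates [detectableCausalR2()] (and, when a `beta` column is
#' present, [powerAtEffect()]) for a table of design queries, producing
#' a design-summary table with results both as fractions and as
#' percentages.
#'
#' @param queries `data.frame` with columns `alpha`, `power`,
#'   `n_outcome`, `r2_gx` (fractions) and optionally `beta`.
#' @return The input with appended columns `detectable_r2` (fraction),
#'   `detectable_r2_pct` (percent) and, when `beta` is supplied,
#'   `power_at_beta` (fraction).
#' @export
powerTable <- function(queries) {
  required <- c("alpha", "power", "n_outcome", "r2_gx")
  missing <- setdiff(required, names(queries))
  if (length(missing))
    stop(sprintf("configuration error: missing column(s): %s",
                 paste(missing, collapse = ", ")))
  out <- queries
  out$detectable_r2 <- mapply(detectableCausalR2, queries$alpha,
                              queries$power, queries$n_outcome,
                              queries$r2_gx)
  out$detectable_r2_pct <- 100 * out$detectable_r2
  if ("beta" %in% names(queries))
    out$power_at_beta <- mapply(powerAtEffect, queries$alpha,
                                queries$n_outcome, queries$r2_gx,
                                queries$beta)
  out
}
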