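CI_Z <- 1.959964  # two-sided 95% normal multiplier

.newEstimate <- function(method, beta, se, pvalue, nSNPs, ciMult = CI_Z,
                         intercept = NA_real_, interceptSE = NA_real_,
                         interceptP = NA_real_, Q = NA_real_,
                         Qdf = NA_real_, Qp = NA_real_,
                         flags = character(0)) {
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - ciMult * se, ciHigh = beta + ciMult * se,
      pvalue = pvalue, nSNPs = as.integer(nSNPs), intercept = intercept,
      interceptSE = interceptSE, interceptP = interceptP, Q = Q,
      Qdf = Qdf, Qp = Qp, flags = flags)
}

#' Per-SNP ratio (Wald) estimates
#'
#' For each SNP the causal-effect ratio \eqn{\Gamma_j / \gamma_j} with
#' first-order standard error \eqn{\sigma_{Yj} / |\gamma_j|}. The
#' uncertainty of the SNP-exposure estimate is ignored here, consistent
#' with assessing the no-measurement-error assumption separately via
#' [i2GX()].
#'
#' @param panel A `HarmonizedPanel`.
#' @return `data.frame` with columns `rsid`, `ratio`, `se`.
#' @export
ratioEstimates <- function(panel) {
  stopifnot(is(panel, "HarmonizedPanel"))
  df <- panel@data
  if (nrow(df) == 0L) stop("input error: empty panel")
  if (any(df$gamma == 0)) stop("input error: zero SNP-exposure effect")
  data.frame(rsid = df$rsid, ratio = df$Gamma / df$gamma,
             se = df$sigma_y / abs(df$gamma), stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines the per-SNP ratio estimates with inverse-variance weights,
#' equivalently a weighted regression of the SNP-outcome betas on the
#' SNP-exposure betas through the origin:
#' \deqn{\hat\beta = \frac{\sum_j \gamma_j \Gamma_j \sigma_{Yj}^{-2}}
#'                        {\sum_j \gamma_j^2 \sigma_{Yj}^{-2}},
#'       \qquad \mathrm{SE} = \Big(\sum_j \gamma_j^2 \sigma_{Yj}^{-2}\Big)^{-1/2}.}
#' The fixed-effect SE is the default; with `randomEffects = TRUE` it is
#' inflated multiplicatively by \eqn{\max(1, \sqrt{Q/(k-1)})}. The 95%
#' CI uses the normal multiplier 1.959964 and the p-value the standard
#' normal.
#'
#' @param panel A `HarmonizedPanel` (>= 1 SNP; Q needs >= 2).
#' @param randomEffects Logical; multiplicative random-effects SE.
#' @return An [`MREstimate`][MREstimate-class] with method `"ivw"`.
#' @examples
#' p <- makePanel(c("a", "b", "c"), gamma = c(0.1, 0.2, 0.3),
#'                sigma_x = 0.01, Gamma = c(0.03, 0.05, 0.08),
#'                sigma_y = 0.01)
#' mrIVW(p)
#' @export
mrIVW <- function(panel, randomEffects = FALSE) {
  stopifnot(is(panel, "HarmonizedPanel"))
  df <- panel@data
  k <- nrow(df)
  if (k == 0L) stop("input error: empty panel")
  w <- df$sigma_y^-2
  denom <- sum(w * df$gamma^2)
  beta <- sum(w * df$gamma * df$Gamma) / denom
  se <- sqrt(1 / denom)
  Q <- Qdf <- Qp <- NA_real_
  flags <- character(0)
  if (k >= 2L) {
    Q <- sum(w * (df$Gamma - beta * df$gamma)^2)
    Qdf <- k - 1
    Qp <- stats::pchisq(Q, df = Qdf, lower.tail = FALSE)
    if (randomEffects) {
      se <- se * max(1, sqrt(Q / (k - 1)))
      flags <- "random_effects"
    }
  }
  pvalue <- 2 * stats::pnorm(-abs(beta / se))
  .newEstimate("ivw", beta, se, pvalue, k, Q = Q, Qdf = Qdf, Qp = Qp,
               flags = flags)
}

.wlsEgger <- function(gamma, Gamma, w) {
  # closed-form weighted LS of Gamma on gamma with intercept
  sw <- sum(w); swx <- sum(w * gamma); swy <- sum(w * Gamma)
  swxx <- sum(w * gamma^2); swxy <- sum(w * gamma * Gamma)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- Gamma - intercept - slope * gamma
  rss <- sum(w * resid^2)
  list(slope = slope, intercept = intercept, rss = rss,
       var_slope = sw / det, var_intercept = swxx / det)
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome betas on the SNP-exposure
#' betas with an unconstrained intercept, weights
#' \eqn{\sigma_{Yj}^{-2}}. The slope estimates the causal effect and
#' remains consistent under directional pleiotropy provided InSIDE
#' holds; the intercept estimates the average directional (pleiotropic)
#' bias. Standard errors scale the weighted-regression covariance by
#' \eqn{\max(1, Q/(k-2))} (multiplicative residual dispersion, never
#' deflated below the fixed-effect model); p-values and 95% CIs use a
#' t distribution with \eqn{k - 2} degrees of freedom.
#'
#' @param panel A `HarmonizedPanel` with at least 3 SNPs.
#' @return An `MREstimate` with method `"egger"` and the intercept
#'   block populated.
#' @export
mrEgger <- function(panel) {
  stopifnot(is(panel, "HarmonizedPanel"))
  df <- panel@data
  k <- nrow(df)
  if (k < 3L) stop("input error: MR-Egger needs at least 3 instruments")
  w <- df$sigma_y^-2
  fit <- .wlsEgger(df$gamma, df$Gamma, w)
  disp <- max(1, fit$rss / (k - 2))
  se <- sqrt(fit$var_slope * disp)
  se_int <- sqrt(fit$var_intercept * disp)
  tq <- stats::qt(0.975, df = k - 2)
  p <- 2 * stats::pt(-abs(fit$slope / se), df = k - 2)
  p_int <- 2 * stats::pt(-abs(fit$intercept / se_int), df = k - 2)
  .newEstimate("egger", fit$slope, se, p, k, ciMult = tq,
               intercept = fit$intercept, interceptSE = se_int,
               interceptP = p_int, Q = fit$rss, Qdf = k - 2,
               Qp = stats::pchisq(fit$rss, df = k - 2, lower.tail = FALSE))
}

.weightedMedian <- function(values, weights) {
  o <- order(values)
  v <- values[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w)
  p <- s - w / 2
  if (0.5 <= p[1]) return(v[1])
  if (0.5 >= p[length(p)]) return(v[length(v)])
  stats::approx(p, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' Orders the per-SNP ratio estimates and takes the median of their
#' inverse-variance-weighted empirical distribution: with normalized
#' weights \eqn{w_j} on the sorted ratios and running sums \eqn{S_j},
#' the estimate interpolates the sorted ratios linearly at the
#' cumulative midpoint positions \eqn{p_j = S_j - w_j/2} evaluated at
#' \eqn{p = 1/2}. Consistent when at least half the total weight comes
#' from valid instruments. The SE comes from a parametric bootstrap:
#' each replicate redraws \eqn{\gamma_j \sim N(\hat\gamma_j, \sigma_{Xj}^2)}
#' and \eqn{\Gamma_j \sim N(\hat\Gamma_j, \sigma_{Yj}^2)} and recomputes
#' the weighted median; the SE is the standard deviation across
#' replicates, with normal-based CI and p-value.
#'
#' @param panel A `HarmonizedPanel` with at least 3 SNPs.
#' @param nBoot Number of bootstrap replicates (>= 100, default 10000).
#' @param seed Integer seed for the bootstrap (mandatory, for
#'   reproducibility).
#' @return An `MREstimate` with method `"weighted_median"`.
#' @export
mrMedian <- function(panel, nBoot = 10000L, seed) {
  stopifnot(is(panel, "HarmonizedPanel"))
  if (missing(seed)) stop("configuration error: bootstrap seed is required")
  df <- panel@data
  k <- nrow(df)
  if (k < 3L) stop("input error: weighted median needs at least 3 instruments")
  if (nBoot < 100L) stop("configuration error: nBoot must be at least 100")
  ratios <- df$Gamma / df$gamma
  se_r <- df$sigma_y / abs(df$gamma)
  est <- .weightedMedian(ratios, se_r^-2)

  boot <- withr_seed(seed, {
    vapply(seq_len(nBoot), function(b) {
      g <- stats::rnorm(k, df$gamma, df$sigma_x)
      G <- stats::rnorm(k, df$Gamma, df$sigma_y)
      ok <- g != 0
      .weightedMedian(G[ok] / g[ok], (df$sigma_y[ok] / abs(g[ok]))^-2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  pvalue <- 2 * stats::pnorm(-abs(est / se))
  .newEstimate("weighted_median", est, se, pvalue, k)
}

#' Multivariable inverse-variance-weighted estimate
#'
#' Regresses the SNP-outcome betas on the betas of several exposures
#' simultaneously (weighted least squares without intercept, weights
#' \eqn{\sigma_{Yj}^{-2}}), returning the coefficient of
#' `targetExposure` — the direct causal effect of that exposure with
#' the others held fixed. Inference uses a t distribution with
#' \eqn{k - m} degrees of freedom (m exposures), with the residual
#' dispersion scaled by \eqn{\max(1, Q/(k-m))} as in [mrEgger()].
#'
#' @param exposureBetas Numeric matrix (SNPs x exposures) with column
#'   names; rows aligned with `Gamma`.
#' @param Gamma,sigmaY SNP-outcome betas and their SEs.
#' @param targetExposure Column name of the exposure of interest.
#' @return An `MREstimate` with method `"mv_ivw"`.
#' @export
mrMVIVW <- function(exposureBetas, Gamma, sigmaY, targetExposure) {
  X <- as.matrix(exposureBetas)
  if (is.null(colnames(X))) stop("exposureBetas needs column names")
  if (!targetExposure %in% colnames(X))
    stop(sprintf("unknown target exposure '%s'", targetExposure))
  k <- nrow(X); m <- ncol(X)
  stopifnot(length(Gamma) == k, length(sigmaY) == k, all(sigmaY > 0))
  if (k < m + 1L)
    stop(sprintf("input error: need at least %d SNPs for %d exposures",
                 m + 1L, m))
  qrX <- qr(X)
  if (qrX$rank < m) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):m]]
    stop(sprintf("numerical error: collinear exposure(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  w <- sigmaY^-2
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  coef <- solve(XtWX, XtW %*% Gamma)
  resid <- Gamma - as.vector(X %*% coef)
  disp <- max(1, sum(w * resid^2) / (k - m))
  covb <- solve(XtWX) * disp
  i <- match(targetExposure, colnames(X))
  beta <- coef[i]
  se <- sqrt(covb[i, i])
  tq <- stats::qt(0.975, df = k - m)
  p <- 2 * stats::pt(-abs(beta / se), df = k - m)
  .newEstimate("mv_ivw", beta, se, p, k, ciMult = tq,
               flags = sprintf("adjusted_for:%s",
                               paste(setdiff(colnames(X), targetExposure),
                                     collapse = "+")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded helpers do not disturb enclosing
#' simulations.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
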