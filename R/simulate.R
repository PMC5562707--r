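#' Derive a child seed from a global seed
#'
#' Deterministic Lehmer-style mixing so every stochastic stage of a
#' pipeline run draws from its own stream while remaining reproducible
#' from one global seed. Results stay within 32-bit integer range.
#'
#' @param seed Integer global seed.
#' @param offset Integer stream index.
#' @return Integer child seed.
#' @export
deriveSeed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 16807 + 1) %%
               2147483629)
}

#' Generate a synthetic two-sample summary-statistics panel
#'
#' Emulates the two-sample design: per SNP \eqn{j}, a minor-allele
#' frequency \eqn{maf_j \sim U(\mathrm{mafRange})}, a true SNP-exposure
#' effect \eqn{\gamma_j \sim N(\mu_\gamma, \sigma_\gamma)} truncated
#' positive (so the orientation invariant holds by construction), a
#' pleiotropic direct effect \eqn{\alpha_j} (zero for valid SNPs, drawn
#' \eqn{N(\mu_\alpha, \sigma_\alpha)} for the invalid fraction,
#' independently of \eqn{\gamma_j} so InSIDE holds), and a true
#' SNP-outcome effect \eqn{\Gamma_j = \beta \gamma_j + \alpha_j}.
#' Standard errors follow the standardized-GWAS form
#' \eqn{\sigma = 1/\sqrt{2 n \, maf(1-maf)}} with the respective sample
#' size, and the observed estimates are drawn independently (two
#' separate samples) around the true values. SNPs whose observed
#' exposure estimate is not positive are dropped with a provenance note
#' (mirroring the selection of exposure-increasing genome-wide-
#' significant instruments); this is vanishingly rare at the default
#' sample sizes.
#'
#' @param cfg A [`SimPanelConfig`][SimPanelConfig-class].
#' @return List with elements `panel` (a `HarmonizedPanel`) and `truth`
#'   (list with `betaCausal`, `gamma`, `alpha`, `invalid` rsids, `maf`,
#'   and the rsids retained after the positivity drop).
#' @examples
#' sim <- simulatePanel(SimPanelConfig(k = 10, seed = 7))
#' mrIVW(sim$panel)
#' @export
simulatePanel <- function(cfg) {
  stopifnot(is(cfg, "SimPanelConfig"))
  validObject(cfg)
  k <- cfg@k
  withr_seed(cfg@seed, {
    maf <- stats::runif(k, cfg@mafRange[1], cfg@mafRange[2])
    gamma <- stats::rnorm(k, cfg@gammaMean, cfg@gammaSD)
    while (any(gamma <= 0))
      gamma[gamma <= 0] <- stats::rnorm(sum(gamma <= 0), cfg@gammaMean,
                                        cfg@gammaSD)
    n_invalid <- as.integer(round(cfg@invalidFraction * k))
    alpha <- numeric(k)
    invalid <- logical(k)
    if (cfg@pleiotropyMode != "none" && n_invalid > 0L) {
      invalid[sample.int(k, n_invalid)] <- TRUE
      mu <- if (cfg@pleiotropyMode == "balanced") 0 else cfg@alphaMean
      alpha[invalid] <- stats::rnorm(n_invalid, mu, cfg@alphaSD)
    }
    Gamma_true <- cfg@betaCausal * gamma + alpha
    sigma_x <- 1 / sqrt(2 * cfg@nExposure * maf * (1 - maf))
    sigma_y <- 1 / sqrt(2 * cfg@nOutcome * maf * (1 - maf))
    g_obs <- stats::rnorm(k, gamma, sigma_x)
    G_obs <- stats::rnorm(k, Gamma_true, sigma_y)
  })
  rsid <- sprintf("rs%05d", seq_len(k))
  keep <- g_obs > 0
  notes <- character(0)
  if (any(!keep))
    notes <- sprintf("dropped %d SNP(s) with non-positive observed exposure effect",
                     sum(!keep))
  panel <- makePanel(rsid[keep], g_obs[keep], sigma_x[keep], G_obs[keep],
                     sigma_y[keep], eaf = maf[keep],
                     exposure = "sim_exposure", outcome = "sim_outcome",
                     provenance = notes)
  list(panel = panel,
       truth = list(betaCausal = cfg@betaCausal, gamma = gamma,
                    alpha = alpha, invalid = rsid[invalid], maf = maf,
                    retained = rsid[keep]))
}

#' Generate a synthetic multi-exposure panel
#'
#' Test bed for the multivariable estimator. Independent latent effects
#' \eqn{Z} (one column per exposure, truncated-positive normal for the
#' first column so the panel orientation is well defined) are mixed
#' through `crossLoadings` into true exposure effects
#' \eqn{B = Z L^\top}; the outcome is
#' \eqn{\Gamma_j = B_j \cdot \mathrm{causalVector}}. Observed exposure
#' and outcome estimates add independent noise with the
#' standardized-GWAS standard errors, emulating the overlapping,
#' correlated instrument sets of lipid panels.
#'
#' @param cfg A `SimPanelConfig` (its `k`, sample sizes, `mafRange`,
#'   `gammaMean`, `gammaSD` and `seed` are used).
#' @param nExposures Number of exposures (>= 2).
#' @param causalVector True causal effects, one per exposure.
#' @param crossLoadings Mixing matrix (`nExposures` square; default
#'   identity). Must be non-singular.
#' @return List with `exposureBetas` (observed matrix, columns `X1..Xm`),
#'   `sigmaX` (matrix of exposure SEs), `Gamma`, `sigmaY`, `rsid`, and
#'   `truth` (true `B`, `causalVector`, `crossLoadings`).
#' @export
simulateMVPanel <- function(cfg, nExposures = 2L,
                            causalVector = c(0.6, -0.2),
                            crossLoadings = NULL) {
  stopifnot(is(cfg, "SimPanelConfig"))
  validObject(cfg)
  m <- as.integer(nExposures)
  if (m < 2L) stop("input error: need at least 2 exposures")
  if (length(causalVector) != m)
    stop("input error: causalVector length must match nExposures")
  if (is.null(crossLoadings)) crossLoadings <- diag(m)
  L <- as.matrix(crossLoadings)
  if (nrow(L) != m || ncol(L) != m)
    stop("input error: crossLoadings must be an nExposures-square matrix")
  if (abs(det(L)) < 1e-12)
    stop("input error: singular cross-loadings matrix")
  k <- cfg@k
  withr_seed(cfg@seed, {
    maf <- stats::runif(k, cfg@mafRange[1], cfg@mafRange[2])
    Z <- matrix(stats::rnorm(k * m, cfg@gammaMean, cfg@gammaSD), k, m)
    while (any(Z[, 1] <= 0))
      Z[Z[, 1] <= 0, 1] <- stats::rnorm(sum(Z[, 1] <= 0), cfg@gammaMean,
                                        cfg@gammaSD)
    B <- Z %*% t(L)
    Gamma_true <- as.vector(B %*% causalVector)
    sx <- 1 / sqrt(2 * cfg@nExposure * maf * (1 - maf))
    sy <- 1 / sqrt(2 * cfg@nOutcome * maf * (1 - maf))
    Bobs <- B + matrix(stats::rnorm(k * m, 0, sx), k, m)
    Gobs <- stats::rnorm(k, Gamma_true, sy)
  })
  colnames(Bobs) <- paste0("X", seq_len(m))
  list(exposureBetas = Bobs,
       sigmaX = matrix(sx, k, m, dimnames = list(NULL, colnames(Bobs))),
       Gamma = Gobs, sigmaY = sy, rsid = sprintf("rs%05d", seq_len(k)),
       truth = list(B = B, causalVector = causalVector,
                    crossLoadings = L))
}

#' Write a simulated panel as a summary-statistics table pair
#'
#' Serializes a simulated `HarmonizedPanel` into two tab-delimited
#' summary-statistics tables (exposure and outcome) in the dialect
#' [readAssociations()] reads, so simulated data can exercise the full
#' file-based pipeline round trip. Alleles are emitted as A (effect,
#' exposure-increasing) / G (other).
#'
#' @param panel A `HarmonizedPanel`.
#' @param exposurePath,outcomePath Output paths.
#' @param nExposure,nOutcome Sample sizes written to the `n` column.
#' @return Invisibly, the two paths.
#' @export
writePanelTables <- function(panel, exposurePath, outcomePath,
                             nExposure = NA, nOutcome = NA) {
  df <- panel@data
  mk <- function(beta, se, n) data.frame(
    SNP = df$rsid, effect_allele = "A", other_allele = "G", eaf = df$eaf,
    beta = beta, se = se,
    pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300), n = n,
    stringsAsFactors = FALSE)
  utils::write.table(mk(df$gamma, df$sigma_x, nExposure), exposurePath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mk(df$Gamma, df$sigma_y, nOutcome), outcomePath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(exposurePath, outcomePath))
}
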