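#' @import methods
NULL

VALID_ALLELES <- c("A", "C", "G", "T")

.checkAssocData <- function(df) {
  required <- c("rsid", "effect_allele", "other_allele", "eaf",
                "beta", "se", "pvalue", "n")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    return(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  msgs <- character(0)
  if (nrow(df) > 0L) {
    if (!all(df$effect_allele %in% VALID_ALLELES) ||
        !all(df$other_allele %in% VALID_ALLELES))
      msgs <- c(msgs, "alleles must be single nucleotides A/C/G/T")
    if (any(df$effect_allele == df$other_allele))
      msgs <- c(msgs, "effect and other allele must differ")
    if (any(!is.finite(df$se)) || any(df$se <= 0))
      msgs <- c(msgs, "all standard errors must be positive")
    bad_eaf <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
    if (any(bad_eaf))
      msgs <- c(msgs, "eaf must lie in [0, 1] when present")
    bad_p <- !is.na(df$pvalue) & (df$pvalue <= 0 | df$pvalue > 1)
    if (any(bad_p))
      msgs <- c(msgs, "p-values must lie in (0, 1] when present")
    bad_n <- !is.na(df$n) & df$n <= 0
    if (any(bad_n))
      msgs <- c(msgs, "sample sizes must be positive when present")
  }
  if (length(msgs)) msgs else TRUE
}

#' Per-SNP association records for one trait
#'
#' Holds one GWAS summary-statistics record per SNP: effect and other
#' allele, effect-allele frequency, the per-allele effect estimate on the
#' trait scale, its standard error, p-value and sample size. Rows failing
#' the record invariants are rejected at load time (see
#' [readAssociations()]), so a valid object always satisfies: positive
#' standard errors, alleles drawn from A/C/G/T with effect != other
#' allele, frequencies in \eqn{[0, 1]} when present.
#'
#' @slot trait Trait label, e.g. `"HDL-C"`.
#' @slot data `data.frame` with columns `rsid`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @slot nDropped Number of input rows rejected while reading.
#'
#' @seealso [readAssociations()], [harmonizePanel()]
#' @export
setClass("AssociationTable",
  representation(trait = "character", data = "data.frame",
                 nDropped = "integer"),
  prototype(trait = "trait",
            data = data.frame(rsid = character(0),
                              effect_allele = character(0),
                              other_allele = character(0),
                              eaf = numeric(0), beta = numeric(0),
                              se = numeric(0), pvalue = numeric(0),
                              n = numeric(0)),
            nDropped = 0L),
  validity = function(object) .checkAssocData(object@data))

#' Harmonized exposure-outcome panel
#'
#' The unit every estimator consumes: aligned SNP-exposure / SNP-outcome
#' estimate pairs, oriented so each SNP's effect allele increases the
#' exposure (`gamma > 0` for every record). Built by [harmonizePanel()]
#' or [simulatePanel()].
#'
#' @slot exposure,outcome Trait labels.
#' @slot data `data.frame` with columns `rsid`, `gamma` (SNP-exposure
#'   beta), `sigma_x` (its SE), `Gamma` (SNP-outcome beta), `sigma_y`
#'   (its SE), `eaf` (exposure-increasing allele frequency, `NA` when
#'   unknown).
#' @slot provenance Free-text notes of flips and drops performed during
#'   harmonization or filtering.
#'
#' @export
setClass("HarmonizedPanel",
  representation(exposure = "character", outcome = "character",
                 data = "data.frame", provenance = "character"),
  prototype(exposure = "exposure", outcome = "outcome",
            data = data.frame(rsid = character(0), gamma = numeric(0),
                              sigma_x = numeric(0), Gamma = numeric(0),
                              sigma_y = numeric(0), eaf = numeric(0)),
            provenance = character(0)),
  validity = function(object) {
    df <- object@data
    required <- c("rsid", "gamma", "sigma_x", "Gamma", "sigma_y", "eaf")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L)
      return(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
    msgs <- character(0)
    if (nrow(df) > 0L) {
      if (any(df$gamma <= 0))
        msgs <- c(msgs, "all gamma must be strictly positive (orientation invariant)")
      if (anyDuplicated(df$rsid))
        msgs <- c(msgs, "rsids must be unique")
      if (any(df$sigma_x <= 0) || any(df$sigma_y <= 0))
        msgs <- c(msgs, "sigma_x and sigma_y must be positive")
    }
    if (length(msgs)) msgs else TRUE
  })

#' Pairwise linkage-disequilibrium table
#'
#' Symmetric lookup of pairwise r-squared values, read from a
#' three-column table with [readLDTable()]. Pairs are stored in
#' canonical (sorted) order; duplicates collapse to the maximum r2; a
#' SNP's r2 with itself is always 1.
#'
#' @slot data `data.frame` with columns `snp1`, `snp2`, `r2`
#'   (`snp1 < snp2` lexicographically).
#'
#' @seealso [ldR2()], [excludeOverlap()]
#' @export
setClass("LDTable",
  representation(data = "data.frame"),
  prototype(data = data.frame(snp1 = character(0), snp2 = character(0),
                              r2 = numeric(0))),
  validity = function(object) {
    df <- object@data
    if (!all(c("snp1", "snp2", "r2") %in% names(df)))
      return("LD table needs columns snp1, snp2, r2")
    if (nrow(df) > 0L) {
      if (any(df$r2 < 0 | df$r2 > 1)) return("r2 values must lie in [0, 1]")
      if (any(df$snp1 >= df$snp2)) return("pairs must be stored in sorted order")
    }
    TRUE
  })

#' Causal-effect estimate
#'
#' Uniform result record returned by every estimator: method tag, causal
#' effect per unit increase in the exposure, standard error, 95%
#' confidence bounds, p-value and the number of SNPs used. MR-Egger
#' results additionally carry the intercept block (the directional-
#' pleiotropy estimate); other methods leave it `NA`. `Q`/`Qdf`/`Qp`
#' hold the Cochran heterogeneity statistic where one is defined.
#'
#' @slot method One of `"ratio"`, `"ivw"`, `"egger"`, `"egger_simex"`,
#'   `"weighted_median"`, `"mv_ivw"`.
#' @slot beta,se,ciLow,ciHigh,pvalue Estimate, SE, 95% CI and two-sided
#'   p-value.
#' @slot nSNPs Number of instruments used.
#' @slot intercept,interceptSE,interceptP MR-Egger intercept block.
#' @slot Q,Qdf,Qp Cochran's Q, its degrees of freedom and p-value.
#' @slot flags Model notes, e.g. `"random_effects"` or `"approximate_se"`.
#'
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pvalue = "numeric",
                 nSNPs = "integer", intercept = "numeric",
                 interceptSE = "numeric", interceptP = "numeric",
                 Q = "numeric", Qdf = "numeric", Qp = "numeric",
                 flags = "character"),
  prototype(method = "ivw", beta = NA_real_, se = NA_real_,
            ciLow = NA_real_, ciHigh = NA_real_, pvalue = NA_real_,
            nSNPs = 0L, intercept = NA_real_, interceptSE = NA_real_,
            interceptP = NA_real_, Q = NA_real_, Qdf = NA_real_,
            Qp = NA_real_, flags = character(0)),
  validity = function(object) {
    msgs <- character(0)
    if (!object@method %in% c("ratio", "ivw", "egger", "egger_simex",
                              "weighted_median", "mv_ivw"))
      msgs <- c(msgs, sprintf("unknown method '%s'", object@method))
    if (is.finite(object@se) && object@se <= 0)
      msgs <- c(msgs, "se must be positive")
    if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
        (object@ciLow > object@beta || object@beta > object@ciHigh))
      msgs <- c(msgs, "confidence interval must bracket the estimate")
    if (object@method %in% c("egger", "egger_simex") &&
        !is.finite(object@intercept))
      msgs <- c(msgs, "egger estimates must carry an intercept block")
    if (length(msgs)) msgs else TRUE
  })

#' Heterogeneity-filter trace
#'
#' Ordered record of the SNPs removed by the stepwise Cochran-Q filter
#' ([qrsFilter()]): for each removal, the panel-level Q and its p-value
#' just before the SNP was dropped, plus the final Q/p and the retained
#' SNP set. `converged` is `FALSE` when the 2-SNP floor was reached with
#' the heterogeneity test still significant.
#'
#' @slot removed `data.frame` with columns `rsid`, `Q_before`,
#'   `p_before` in removal order.
#' @slot finalQ,finalP Q statistic and p-value of the retained panel.
#' @slot retained Character vector of retained rsids.
#' @slot converged Logical.
#'
#' @export
setClass("FilterTrace",
  representation(removed = "data.frame", finalQ = "numeric",
                 finalP = "numeric", retained = "character",
                 converged = "logical"),
  prototype(removed = data.frame(rsid = character(0), Q_before = numeric(0),
                                 p_before = numeric(0)),
            finalQ = NA_real_, finalP = NA_real_, retained = character(0),
            converged = TRUE),
  validity = function(object) {
    if (length(intersect(object@removed$rsid, object@retained)) > 0L)
      return("removed and retained SNP sets must be disjoint")
    TRUE
  })

#' Synthetic two-sample panel configuration
#'
#' Full parameterization of the synthetic summary-statistics generator
#' ([simulatePanel()]): number of SNPs, the two GWAS sample sizes, the
#' true causal effect, the minor-allele-frequency range, the
#' distribution of true SNP-exposure effects (truncated positive so the
#' orientation invariant holds by construction), and the pleiotropy
#' architecture. In `"balanced"` mode the pleiotropic effects are forced
#' to have mean zero; `"directional"` mode draws them around
#' `alphaMean`, independently of instrument strength (InSIDE).
#'
#' @slot k Number of SNPs (>= 2).
#' @slot nExposure,nOutcome GWAS sample sizes of the two non-overlapping
#'   samples.
#' @slot betaCausal True causal effect of the exposure on the outcome.
#' @slot mafRange Length-2 range within (0, 0.5].
#' @slot gammaMean,gammaSD Normal parameters of the true SNP-exposure
#'   effects before positive truncation.
#' @slot pleiotropyMode `"none"`, `"balanced"` or `"directional"`.
#' @slot invalidFraction Fraction of SNPs given a direct (pleiotropic)
#'   outcome effect; `invalidFraction * k` must round to an integer.
#' @slot alphaMean,alphaSD Normal parameters of the pleiotropic effects.
#' @slot seed Integer seed; identical configurations reproduce
#'   bit-identical panels.
#'
#' @export
setClass("SimPanelConfig",
  representation(k = "integer", nExposure = "numeric", nOutcome = "numeric",
                 betaCausal = "numeric", mafRange = "numeric",
                 gammaMean = "numeric", gammaSD = "numeric",
                 pleiotropyMode = "character", invalidFraction = "numeric",
                 alphaMean = "numeric", alphaSD = "numeric",
                 seed = "integer"),
  prototype(k = 50L, nExposure = 50000, nOutcome = 50000,
            betaCausal = 0.1, mafRange = c(0.1, 0.5), gammaMean = 0.1,
            gammaSD = 0.1, pleiotropyMode = "none", invalidFraction = 0,
            alphaMean = 0.02, alphaSD = 0.01, seed = 1L),
  validity = function(object) {
    msgs <- character(0)
    if (object@k < 2L) msgs <- c(msgs, "k must be at least 2")
    if (object@nExposure <= 0 || object@nOutcome <= 0)
      msgs <- c(msgs, "sample sizes must be positive")
    if (length(object@mafRange) != 2L ||
        object@mafRange[1] <= 0 || object@mafRange[2] > 0.5 ||
        object@mafRange[1] > object@mafRange[2])
      msgs <- c(msgs, "mafRange must be an interval within (0, 0.5]")
    if (!object@pleiotropyMode %in% c("none", "balanced", "directional"))
      msgs <- c(msgs, "pleiotropyMode must be none, balanced or directional")
    if (object@invalidFraction < 0 || object@invalidFraction > 1)
      msgs <- c(msgs, "invalidFraction must lie in [0, 1]")
    n_inv <- object@invalidFraction * object@k
    if (abs(n_inv - round(n_inv)) > 1e-8)
      msgs <- c(msgs, "invalidFraction * k must be an integer count")
    if (object@pleiotropyMode == "balanced" && object@alphaMean != 0)
      msgs <- c(msgs, "balanced pleiotropy requires alphaMean = 0")
    if (length(msgs)) msgs else TRUE
  })

#' SIMEX settings for the corrected MR-Egger estimate
#'
#' Parameterization of the simulation-extrapolation correction
#' ([mrEggerSimex()]): the grid of noise-inflation multipliers, the
#' number of perturbation replicates per grid point, the order of the
#' extrapolating polynomial (1 = linear, 2 = quadratic) and the seed.
#'
#' @slot lambdas Increasing positive grid of inflation levels.
#' @slot nSim Replicates per lambda (>= 100).
#' @slot extrapolant Polynomial order, 1 or 2.
#' @slot seed Integer seed.
#'
#' @export
setClass("SimexSettings",
  representation(lambdas = "numeric", nSim = "integer",
                 extrapolant = "integer", seed = "integer"),
  prototype(lambdas = c(0.5, 1.0, 1.5, 2.0), nSim = 1000L,
            extrapolant = 2L, seed = 1L),
  validity = function(object) {
    msgs <- character(0)
    if (length(object@lambdas) == 0L || any(object@lambdas <= 0))
      msgs <- c(msgs, "lambdas must be nonempty and positive")
    if (is.unsorted(object@lambdas, strictly = TRUE))
      msgs <- c(msgs, "lambdas must be strictly increasing")
    if (object@nSim < 100L) msgs <- c(msgs, "nSim must be at least 100")
    if (!object@extrapolant %in% c(1L, 2L))
      msgs <- c(msgs, "extrapolant order must be 1 or 2")
    if (length(msgs)) msgs else TRUE
  })

#' @describeIn SimPanelConfig Constructor with study-like defaults.
#' @param ... Slot values overriding the defaults.
#' @export
SimPanelConfig <- function(...) {
  args <- list(...)
  for (nm in c("k", "seed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SimPanelConfig"), args))
}

#' @describeIn SimexSettings Constructor with the standard configuration.
#' @param ... Slot values overriding the defaults.
#' @export
SimexSettings <- function(...) {
  args <- list(...)
  for (nm in c("nSim", "extrapolant", "seed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SimexSettings"), args))
}
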