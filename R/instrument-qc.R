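#' Variance of a trait explained by a set of instruments
#'
#' Sums the per-SNP coefficients of determination
#' \deqn{R^2 = \sum_i \beta_i^2 \, 2\,\mathrm{MAF}_i(1-\mathrm{MAF}_i) / \mathrm{var}(X),}
#' where \eqn{2\,\mathrm{MAF}(1-\mathrm{MAF})} is the variance of an
#' additively coded biallelic genotype under Hardy-Weinberg equilibrium
#' and \eqn{\mathrm{var}(X) = 1} for traits analyzed in SD units. The
#' minor-allele frequency is `min(eaf, 1 - eaf)` (the product is
#' symmetric, so this equals using `eaf` directly).
#'
#' Genome-wide-significant, mutually independent instruments correspond
#' to a per-variant F statistic above 30, so weak-instrument bias is
#' negligible for panels selected that way; F itself cannot be computed
#' from two-sample summary data.
#'
#' @param assocs An `AssociationTable` (every record must have `eaf`).
#' @param varX Variance of the trait (1 for standardized traits).
#' @return Fraction of variance explained, in \eqn{[0, 1]}.
#' @examples
#' tab <- new("AssociationTable", trait = "X", data = data.frame(
#'   rsid = "rs1", effect_allele = "A", other_allele = "G", eaf = 0.5,
#'   beta = 1, se = 0.1, pvalue = 1e-9, n = 1e5))
#' explainedVariance(tab)  # 1^2 * 2 * 0.25 = 0.5
#' @export
explainedVariance <- function(assocs, varX = 1) {
  stopifnot(is(assocs, "AssociationTable"), varX > 0)
  df <- assocs@data
  miss <- is.na(df$eaf)
  if (any(miss))
    stop(sprintf("input error: missing eaf for %s",
                 paste(df$rsid[miss], collapse = ", ")))
  maf <- pmin(df$eaf, 1 - df$eaf)
  sum(df$beta^2 * 2 * maf * (1 - maf)) / varX
}

#' Exclude instruments overlapping other traits' instrument sets
#'
#' Removes from a harmonized panel any SNP that (a) appears verbatim in
#' any of the named other-trait SNP lists, or (b) is an LD proxy
#' (\eqn{r^2 >} `r2Threshold`, strict) of a SNP in those lists. Use
#' `restrictTo` to consult only a subset of the lists, e.g. only
#' non-lipid traits when the lipid instrument sets deliberately overlap
#' and are instead handled by multivariable adjustment.
#'
#' @param panel A `HarmonizedPanel`.
#' @param otherTraitSNPs Named list of character vectors of rsids.
#' @param ld Optional [`LDTable`][LDTable-class] for proxy lookups.
#' @param r2Threshold Proxies require `r2 > r2Threshold` (default 0.8).
#' @param restrictTo Optional character vector of list names to consult.
#' @return List with elements `panel` (the filtered `HarmonizedPanel`,
#'   possibly empty, in which case a note is added) and `log`
#'   (`data.frame` with columns `rsid`, `reason`, `trigger`).
#' @export
excludeOverlap <- function(panel, otherTraitSNPs, ld = NULL,
                           r2Threshold = 0.8, restrictTo = NULL) {
  stopifnot(is(panel, "HarmonizedPanel"),
            r2Threshold > 0, r2Threshold <= 1)
  if (!is.null(restrictTo)) {
    unknown <- setdiff(restrictTo, names(otherTraitSNPs))
    if (length(unknown))
      stop(sprintf("unknown trait list(s): %s", paste(unknown, collapse = ", ")))
    otherTraitSNPs <- otherTraitSNPs[restrictTo]
  }
  rsids <- panel@data$rsid
  log <- data.frame(rsid = character(0), reason = character(0),
                    trigger = character(0), stringsAsFactors = FALSE)
  remove <- logical(length(rsids))
  for (trait in names(otherTraitSNPs)) {
    listed <- otherTraitSNPs[[trait]]
    hit <- rsids %in% listed & !remove
    if (any(hit)) {
      remove[hit] <- TRUE
      log <- rbind(log, data.frame(rsid = rsids[hit], reason = "overlap",
                                   trigger = trait, stringsAsFactors = FALSE))
    }
    if (!is.null(ld) && length(listed) > 0L) {
      for (j in which(!remove)) {
        r2 <- ldR2(ld, rsids[j], listed)
        prox <- which(!is.na(r2) & r2 > r2Threshold & listed != rsids[j])
        if (length(prox) > 0L) {
          remove[j] <- TRUE
          log <- rbind(log, data.frame(
            rsid = rsids[j], reason = "ld_proxy",
            trigger = sprintf("%s:%s(r2=%.3g)", trait, listed[prox[1]],
                              r2[prox[1]]),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  note <- if (all(remove) && length(remove) > 0L)
    "cross-trait exclusion removed every SNP" else NULL
  list(panel = .subsetPanel(panel, !remove, note), log = log)
}

.ivwBetaQ <- function(gamma, Gamma, sigma_y) {
  w <- sigma_y^-2
  beta <- sum(w * gamma * Gamma) / sum(w * gamma^2)
  contrib <- w * (Gamma - beta * gamma)^2
  list(beta = beta, Q = sum(contrib), contrib = contrib)
}

#' Stepwise Cochran-Q heterogeneity filter
#'
#' Iteratively refits the fixed-effect IVW model and tests per-SNP
#' homogeneity of the causal estimates with Cochran's
#' \deqn{Q = \sum_j w_j (\Gamma_j - \hat\beta \gamma_j)^2, \qquad w_j = \sigma_{Yj}^{-2},}
#' against a chi-squared distribution with \eqn{k - 1} degrees of
#' freedom. While the test is significant at `pThreshold`, the SNP with
#' the largest individual Q contribution is removed (ties broken by
#' lexicographically smaller rsid) and the model refit. Stops when
#' \eqn{p \ge} `pThreshold` or when only two SNPs remain (a Q test
#' needs at least two); hitting that floor with the test still
#' significant sets `converged = FALSE` on the trace with a warning
#' rather than an error.
#'
#' This mirrors stepwise downward genetic-risk-score model selection:
#' SNPs whose effect on the outcome is not mediated by the exposure
#' break the homogeneity of the per-SNP causal estimates and are
#' candidates for exclusion as potentially pleiotropic.
#'
#' @param panel A `HarmonizedPanel` with at least two SNPs.
#' @param pThreshold Significance threshold of the heterogeneity test
#'   (default 0.05).
#' @return List with elements `panel` (filtered `HarmonizedPanel`) and
#'   `trace` (a [`FilterTrace`][FilterTrace-class]).
#' @export
qrsFilter <- function(panel, pThreshold = 0.05) {
  stopifnot(is(panel, "HarmonizedPanel"),
            pThreshold > 0, pThreshold < 1)
  df <- panel@data
  if (nrow(df) < 2L)
    stop("input error: heterogeneity filtering needs at least 2 SNPs")
  removed <- data.frame(rsid = character(0), Q_before = numeric(0),
                        p_before = numeric(0), stringsAsFactors = FALSE)
  converged <- TRUE
  repeat {
    fit <- .ivwBetaQ(df$gamma, df$Gamma, df$sigma_y)
    p <- stats::pchisq(fit$Q, df = nrow(df) - 1L, lower.tail = FALSE)
    if (p >= pThreshold) break
    if (nrow(df) <= 2L) {
      converged <- FALSE
      warning("heterogeneity still significant at the 2-SNP floor")
      break
    }
    worst <- order(-fit$contrib, df$rsid)[1L]
    removed <- rbind(removed, data.frame(rsid = df$rsid[worst],
                                         Q_before = fit$Q, p_before = p,
                                         stringsAsFactors = FALSE))
    df <- df[-worst, , drop = FALSE]
  }
  trace <- new("FilterTrace", removed = removed, finalQ = fit$Q, finalP = p,
               retained = df$rsid, converged = converged)
  out <- .subsetPanel(panel, panel@data$rsid %in% df$rsid,
                      if (nrow(removed) > 0L)
                        sprintf("Q filter removed %d SNP(s): %s",
                                nrow(removed),
                                paste(removed$rsid, collapse = ", "))
                      else NULL)
  list(panel = out, trace = trace)
}
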