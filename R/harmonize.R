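.complement <- function(a) chartr("ACGT", "TGCA", a)

.isPalindromic <- function(ea, oa) ea == .complement(oa)

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects two association tables on rsid, aligns the outcome
#' estimates to the exposure's effect allele (sign-flipping the outcome
#' beta and complementing its frequency when the alleles are swapped,
#' with strand-complement matches resolved for non-palindromic SNPs),
#' and orients every record towards the exposure-increasing allele so
#' that every SNP-exposure beta in the result is strictly positive.
#'
#' Palindromic SNPs (A/T or C/G) cannot be aligned by allele letters
#' alone. They are kept and aligned by comparing effect-allele
#' frequencies when both are available and both fall outside
#' `ambiguityBand` (default \eqn{[0.42, 0.58]}); otherwise they are
#' dropped with a note. SNPs whose allele pairs are irreconcilable and
#' SNPs with a zero exposure beta are dropped and logged in the
#' `provenance` slot.
#'
#' @param exposure,outcome `AssociationTable` objects.
#' @param ambiguityBand Length-2 frequency band within which palindromic
#'   SNPs are considered unalignable.
#' @return A [`HarmonizedPanel`][HarmonizedPanel-class].
#' @examples
#' exp <- new("AssociationTable", trait = "X", data = data.frame(
#'   rsid = "rs1", effect_allele = "A", other_allele = "G", eaf = 0.3,
#'   beta = -0.1, se = 0.01, pvalue = 1e-9, n = 1e5))
#' out <- new("AssociationTable", trait = "Y", data = data.frame(
#'   rsid = "rs1", effect_allele = "G", other_allele = "A", eaf = 0.7,
#'   beta = 0.05, se = 0.02, pvalue = 0.01, n = 5e4))
#' snpData(harmonizePanel(exp, out))  # gamma 0.1, Gamma 0.05, eaf 0.7
#' @export
harmonizePanel <- function(exposure, outcome, ambiguityBand = c(0.42, 0.58)) {
  stopifnot(is(exposure, "AssociationTable"), is(outcome, "AssociationTable"))
  ex <- exposure@data
  ou <- outcome@data
  if (nrow(ex) == 0L || nrow(ou) == 0L)
    stop("input error: empty association table")
  common <- intersect(ex$rsid, ou$rsid)
  if (length(common) == 0L)
    stop(sprintf("input error: no shared SNPs between '%s' and '%s'",
                 exposure@trait, outcome@trait))
  ex <- ex[match(common, ex$rsid), , drop = FALSE]
  ou <- ou[match(common, ou$rsid), , drop = FALSE]
  notes <- character(0)

  k <- length(common)
  keep <- rep(TRUE, k)
  Gamma <- ou$beta
  eaf_out <- ou$eaf
  for (j in seq_len(k)) {
    eea <- ex$effect_allele[j]; eoa <- ex$other_allele[j]
    oea <- ou$effect_allele[j]; ooa <- ou$other_allele[j]
    if (.isPalindromic(eea, eoa)) {
      same_pair <- setequal(c(oea, ooa), c(eea, eoa))
      fx <- ex$eaf[j]
      fo <- if (!same_pair) NA_real_
            else if (oea == eea) ou$eaf[j] else 1 - ou$eaf[j]
      ambiguous <- is.na(fx) || is.na(fo) ||
        (fx >= ambiguityBand[1] && fx <= ambiguityBand[2]) ||
        (fo >= ambiguityBand[1] && fo <= ambiguityBand[2])
      if (!same_pair || ambiguous) {
        keep[j] <- FALSE
        notes <- c(notes, sprintf("dropped %s: unalignable palindromic SNP",
                                  ex$rsid[j]))
        next
      }
      if (sign(fx - 0.5) != sign(fo - 0.5)) {
        # frequencies disagree: the outcome study reports the opposite
        # strand orientation, so the lettered match is actually a flip
        Gamma[j] <- -Gamma[j]
        fo <- 1 - fo
        notes <- c(notes, sprintf("flipped %s by allele frequency (palindromic)",
                                  ex$rsid[j]))
      }
      eaf_out[j] <- fo
    } else {
      if (oea == eea && ooa == eoa) {
        # aligned as-is
      } else if (oea == eoa && ooa == eea) {
        Gamma[j] <- -Gamma[j]
        eaf_out[j] <- 1 - eaf_out[j]
      } else if (oea == .complement(eea) && ooa == .complement(eoa)) {
        # opposite strand, same orientation
      } else if (oea == .complement(eoa) && ooa == .complement(eea)) {
        Gamma[j] <- -Gamma[j]
        eaf_out[j] <- 1 - eaf_out[j]
      } else {
        keep[j] <- FALSE
        notes <- c(notes, sprintf("dropped %s: allele mismatch (%s/%s vs %s/%s)",
                                  ex$rsid[j], eea, eoa, oea, ooa))
        next
      }
    }
  }

  gamma <- ex$beta
  eaf <- ex$eaf
  flip <- keep & gamma < 0
  gamma[flip] <- -gamma[flip]
  Gamma[flip] <- -Gamma[flip]
  eaf[flip] <- 1 - eaf[flip]
  if (any(flip))
    notes <- c(notes, sprintf("oriented %d SNP(s) to the exposure-increasing allele",
                              sum(flip)))
  zero <- keep & gamma == 0
  if (any(zero)) {
    keep[zero] <- FALSE
    notes <- c(notes, sprintf("dropped %s: zero exposure effect",
                              ex$rsid[zero]))
  }

  df <- data.frame(rsid = ex$rsid[keep], gamma = gamma[keep],
                   sigma_x = ex$se[keep], Gamma = Gamma[keep],
                   sigma_y = ou$se[keep], eaf = eaf[keep],
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  new("HarmonizedPanel", exposure = exposure@trait, outcome = outcome@trait,
      data = df, provenance = notes)
}

#' Build a harmonized panel directly from estimate vectors
#'
#' Convenience constructor used by simulations and tests, bypassing
#' allele bookkeeping. All `gamma` must already be positive.
#'
#' @param rsid Character vector of SNP identifiers.
#' @param gamma,sigma_x SNP-exposure estimates and SEs.
#' @param Gamma,sigma_y SNP-outcome estimates and SEs.
#' @param eaf Optional effect-allele frequencies.
#' @param exposure,outcome Trait labels.
#' @param provenance Optional notes.
#' @return A `HarmonizedPanel`.
#' @export
makePanel <- function(rsid, gamma, sigma_x, Gamma, sigma_y, eaf = NA_real_,
                      exposure = "exposure", outcome = "outcome",
                      provenance = character(0)) {
  df <- data.frame(rsid = as.character(rsid), gamma = gamma,
                   sigma_x = sigma_x, Gamma = Gamma, sigma_y = sigma_y,
                   eaf = rep_len(eaf, length(rsid)),
                   stringsAsFactors = FALSE)
  new("HarmonizedPanel", exposure = exposure, outcome = outcome, data = df,
      provenance = provenance)
}

.subsetPanel <- function(panel, keep, note = NULL) {
  df <- panel@data[keep, , drop = FALSE]
  rownames(df) <- NULL
  new("HarmonizedPanel", exposure = panel@exposure, outcome = panel@outcome,
      data = df,
      provenance = c(panel@provenance, if (is.null(note)) character(0) else note))
}

#' Write the per-(exposure, outcome, method) analysis report
#'
#' Writes the report `data.frame` produced by
#' [runBidirectionalAnalysis()] as a tab-delimited file with one row per
#' (exposure, outcome, method) result.
#'
#' @param report Report `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
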