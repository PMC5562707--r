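#' Assemble a bidirectional analysis plan
#'
#' @param pairs List of pairs; each pair is a list with elements
#'   `exposure` and `outcome` (each an `AssociationTable` or a file
#'   path), optional `covariates` (named list of `AssociationTable`s /
#'   paths for multivariable adjustment, exposure side), and optional
#'   `columnMap`.
#' @param methods Subset of `c("ivw", "egger", "weighted_median",
#'   "mv_ivw", "egger_simex")`.
#' @param alpha Significance threshold; the default 0.05/8 corresponds
#'   to eight tests over four correlated trait blocks and should be
#'   adapted to the trait set under analysis.
#' @param qrsFilter Apply the stepwise heterogeneity filter before
#'   estimation.
#' @param crossTrait Optional list with elements `lists` (named rsid
#'   vectors), optional `ld` (`LDTable` or path) and `r2Threshold`.
#' @param excludeSNPs Character vector of rsids to drop by name from
#'   every panel (e.g. a known pleiotropic variant).
#' @param randomEffects Logical, passed to [mrIVW()].
#' @param nBoot Bootstrap replicates for the weighted median.
#' @param simex A `SimexSettings` object for `"egger_simex"`.
#' @param seed Global seed; child seeds are derived per pair, direction
#'   and method.
#' @return A list of class `"AnalysisPlan"`.
#' @export
analysisPlan <- function(pairs, methods = c("ivw", "egger", "weighted_median"),
                         alpha = 0.05 / 8, qrsFilter = FALSE,
                         crossTrait = NULL, excludeSNPs = character(0),
                         randomEffects = FALSE, nBoot = 1000L,
                         simex = SimexSettings(), seed = 1L) {
  known <- c("ivw", "egger", "weighted_median", "mv_ivw", "egger_simex")
  bad <- setdiff(methods, known)
  if (length(bad))
    stop(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  stopifnot(alpha > 0, alpha < 1, length(pairs) >= 1L)
  if ("mv_ivw" %in% methods &&
      !any(vapply(pairs, function(p) !is.null(p$covariates), logical(1))))
    stop("configuration error: mv_ivw requires covariate tables")
  structure(list(pairs = pairs, methods = methods, alpha = alpha,
                 qrsFilter = qrsFilter, crossTrait = crossTrait,
                 excludeSNPs = excludeSNPs, randomEffects = randomEffects,
                 nBoot = as.integer(nBoot), simex = simex,
                 seed = as.integer(seed)),
            class = "AnalysisPlan")
}

.resolveTable <- function(x, columnMap = NULL, trait = NULL) {
  if (is(x, "AssociationTable")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(readAssociations(x, columnMap = columnMap,
                            trait = if (is.null(trait)) basename(x) else trait))
  stop("input error: expected an AssociationTable or a file path")
}

.methodMinSNPs <- c(ivw = 1L, egger = 3L, weighted_median = 3L,
                    egger_simex = 3L)

.runMethodsOneDirection <- function(panel, plan, covTabs, direction_id, log) {
  rows <- list()
  for (mi in seq_along(plan$methods)) {
    method <- plan$methods[mi]
    seed_m <- deriveSeed(plan$seed, direction_id * 100L + mi)
    if (method == "mv_ivw") {
      if (is.null(covTabs)) {
        log(sprintf("skip mv_ivw for %s -> %s: no covariate tables",
                    panel@exposure, panel@outcome))
        next
      }
      # covTabs holds data.frames (rsid, beta) already oriented to the
      # exposure-increasing allele (see .alignCovariates)
      covCols <- lapply(covTabs, function(tb)
        tb$beta[match(panel@data$rsid, tb$rsid)])
      X <- cbind(panel@data$gamma, do.call(cbind, covCols))
      colnames(X) <- c(panel@exposure, names(covTabs))
      if (any(is.na(X))) {
        keep <- stats::complete.cases(X)
        log(sprintf("mv_ivw %s -> %s: %d SNP(s) without covariate betas dropped",
                    panel@exposure, panel@outcome, sum(!keep)))
        X <- X[keep, , drop = FALSE]
        Gm <- panel@data$Gamma[keep]; sy <- panel@data$sigma_y[keep]
      } else {
        Gm <- panel@data$Gamma; sy <- panel@data$sigma_y
      }
      if (nrow(X) < ncol(X) + 1L) {
        log(sprintf("skip mv_ivw for %s -> %s: only %d SNP(s) for %d exposures",
                    panel@exposure, panel@outcome, nrow(X), ncol(X)))
        next
      }
      est <- mrMVIVW(X, Gm, sy, targetExposure = panel@exposure)
    } else {
      need <- .methodMinSNPs[[method]]
      if (nSNPs(panel) < need) {
        log(sprintf("skip %s for %s -> %s: %d SNP(s) available, %d required",
                    method, panel@exposure, panel@outcome, nSNPs(panel), need))
        next
      }
      est <- switch(method,
        ivw = mrIVW(panel, randomEffects = plan$randomEffects),
        egger = mrEgger(panel),
        weighted_median = mrMedian(panel, nBoot = plan$nBoot, seed = seed_m),
        egger_simex = {
          s <- plan$simex
          s@seed <- seed_m
          mrEggerSimex(panel, s)
        })
    }
    row <- cbind(data.frame(exposure = panel@exposure,
                            outcome = panel@outcome,
                            stringsAsFactors = FALSE),
                 as.data.frame(est))
    row$significant <- row$pvalue < plan$alpha
    rows[[length(rows) + 1L]] <- row
    log(sprintf("ran %s for %s -> %s: beta=%.4g p=%.3g (%d SNPs)",
                method, panel@exposure, panel@outcome, est@beta,
                est@pvalue, est@nSNPs))
  }
  rows
}

# orient each covariate table's betas to the exposure-increasing allele
# by harmonizing it against the exposure table; returns data.frames
# (rsid, beta) per covariate
.alignCovariates <- function(exposure, covTabs, log) {
  out <- lapply(names(covTabs), function(nm) {
    hp <- harmonizePanel(exposure, covTabs[[nm]])
    data.frame(rsid = hp@data$rsid, beta = hp@data$Gamma,
               stringsAsFactors = FALSE)
  })
  names(out) <- names(covTabs)
  out
}

.preparePanel <- function(exposure, outcome, plan, log) {
  panel <- harmonizePanel(exposure, outcome)
  log(sprintf("harmonized %s -> %s: %d SNP(s)", panel@exposure,
              panel@outcome, nSNPs(panel)))
  if (length(plan$excludeSNPs) > 0L) {
    hit <- panel@data$rsid %in% plan$excludeSNPs
    if (any(hit)) {
      panel <- .subsetPanel(panel, !hit,
                            sprintf("excluded by name: %s",
                                    paste(panel@data$rsid[hit], collapse = ", ")))
      log(sprintf("named exclusion removed %d SNP(s)", sum(hit)))
    }
  }
  if (!is.null(plan$crossTrait)) {
    ct <- plan$crossTrait
    ld <- ct$ld
    if (is.character(ld)) ld <- readLDTable(ld)
    res <- excludeOverlap(panel, ct$lists, ld = ld,
                          r2Threshold = if (is.null(ct$r2Threshold)) 0.8
                                        else ct$r2Threshold,
                          restrictTo = ct$restrictTo)
    log(sprintf("cross-trait exclusion removed %d SNP(s)", nrow(res$log)))
    panel <- res$panel
  }
  trace <- NULL
  if (isTRUE(plan$qrsFilter) && nSNPs(panel) >= 2L) {
    res <- qrsFilter(panel)
    trace <- res$trace
    log(sprintf("Q filter removed %d SNP(s), final Q p = %.3g",
                nrow(trace@removed), trace@finalP))
    panel <- res$panel
  }
  list(panel = panel, trace = trace)
}

#' Run the bidirectional analysis
#'
#' For each (exposure, outcome) pair, harmonizes and analyzes both
#' causal directions: first the stated exposure on the outcome, then
#' the reverse. Optional sensitivity steps (named SNP exclusion,
#' cross-trait/LD-proxy exclusion, stepwise Q filtering) are applied to
#' a copy of each direction's panel before estimation. Methods whose
#' minimum instrument count exceeds the available SNPs are skipped with
#' a logged reason (with very few instruments only the IVW estimate is
#' meaningful); multivariable adjustment runs only in the forward
#' direction, where the covariate tables refer to the exposure side.
#' Every result row is annotated with `significant = pvalue < alpha`.
#'
#' @param plan An [analysisPlan()].
#' @return List with `report` (`data.frame`, one row per executed
#'   (exposure, outcome, method)), `traces` (named list of
#'   `FilterTrace`s from Q filtering) and `log` (character vector, one
#'   structured line per stage).
#' @export
runBidirectionalAnalysis <- function(plan) {
  stopifnot(inherits(plan, "AnalysisPlan"))
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  rows <- list()
  traces <- list()
  for (pi in seq_along(plan$pairs)) {
    pair <- plan$pairs[[pi]]
    cmap <- pair$columnMap
    exposure <- .resolveTable(pair$exposure, cmap, pair$exposureName)
    outcome <- .resolveTable(pair$outcome, cmap, pair$outcomeName)
    covTabs <- NULL
    if (!is.null(pair$covariates)) {
      covRaw <- lapply(pair$covariates, .resolveTable, columnMap = cmap)
      if (is.null(names(covRaw)) || any(!nzchar(names(covRaw))))
        names(covRaw) <- vapply(covRaw, function(tb) tb@trait, "")
      covTabs <- .alignCovariates(exposure, covRaw, log)
    }
    for (dir_i in 1:2) {
      ex <- if (dir_i == 1L) exposure else outcome
      ou <- if (dir_i == 1L) outcome else exposure
      prep <- tryCatch(.preparePanel(ex, ou, plan, log),
                       error = function(e) {
                         log(sprintf("skip %s -> %s: %s", ex@trait, ou@trait,
                                     conditionMessage(e)))
                         NULL
                       })
      if (is.null(prep)) next
      if (!is.null(prep$trace))
        traces[[sprintf("%s->%s", ex@trait, ou@trait)]] <- prep$trace
      dir_rows <- .runMethodsOneDirection(
        prep$panel, plan, if (dir_i == 1L) covTabs else NULL,
        direction_id = pi * 10L + dir_i, log = log)
      rows <- c(rows, dir_rows)
    }
  }
  if (length(rows) == 0L) {
    warning("no method could be run for any pair")
    report <- data.frame()
  } else {
    report <- do.call(rbind, rows)
    rownames(report) <- NULL
  }
  list(report = report, traces = traces, log = log_lines)
}

#' Read an analysis plan from a YAML configuration file
#'
#' The configuration names the input tables, methods, sensitivity
#' flags, significance threshold and seed:
#' \preformatted{
#' pairs:
#'   - exposure: hdl.tsv
#'     outcome: apoa4.tsv
#'     covariates: {LDL: ldl.tsv, TG: tg.tsv}
#' methods: [ivw, egger, weighted_median]
#' alpha: 0.00625
#' qrs_filter: true
#' exclude_snps: [rs964184]
#' seed: 42
#' }
#'
#' @param path Path to the YAML file.
#' @return An `AnalysisPlan`.
#' @export
readAnalysisPlan <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pairs) || length(cfg$pairs) == 0L)
    stop("configuration error: plan needs at least one pair")
  base <- dirname(normalizePath(path))
  fix_path <- function(p)
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p)))
      file.path(base, p) else p
  pairs <- lapply(cfg$pairs, function(p) {
    p$exposure <- fix_path(p$exposure)
    p$outcome <- fix_path(p$outcome)
    if (!is.null(p$covariates)) p$covariates <- lapply(p$covariates, fix_path)
    if (!is.null(p$column_map)) p$columnMap <- unlist(p$column_map)
    p
  })
  ct <- NULL
  if (!is.null(cfg$cross_trait)) {
    ct <- list(lists = lapply(cfg$cross_trait$lists, function(x) {
      if (is.character(x) && length(x) == 1L && file.exists(fix_path(x)))
        readLines(fix_path(x)) else as.character(x)
    }),
    ld = if (!is.null(cfg$cross_trait$ld)) fix_path(cfg$cross_trait$ld),
    r2Threshold = cfg$cross_trait$r2_threshold,
    restrictTo = cfg$cross_trait$restrict_to)
  }
  analysisPlan(
    pairs = pairs,
    methods = if (is.null(cfg$methods)) c("ivw", "egger", "weighted_median")
              else unlist(cfg$methods),
    alpha = if (is.null(cfg$alpha)) 0.05 / 8 else cfg$alpha,
    qrsFilter = isTRUE(cfg$qrs_filter),
    crossTrait = ct,
    excludeSNPs = if (is.null(cfg$exclude_snps)) character(0)
                  else unlist(cfg$exclude_snps),
    randomEffects = isTRUE(cfg$random_effects),
    nBoot = if (is.null(cfg$n_boot)) 1000L else cfg$n_boot,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}
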