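#' Default column mapping for summary-statistics tables
#'
#' Maps the canonical field names to the column headers expected in the
#' input file. Override individual entries via the `columnMap` argument
#' of [readAssociations()].
#'
#' @return Named character vector (field name -> column header).
#' @export
defaultColumnMap <- function() {
  c(rsid = "SNP", effect_allele = "effect_allele",
    other_allele = "other_allele", eaf = "eaf", beta = "beta", se = "se",
    pvalue = "pval", n = "n")
}

.readDelimited <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited table with a header row into an
#' [`AssociationTable`][AssociationTable-class]. Rows violating the
#' per-record invariants (non-positive SE, invalid or identical alleles,
#' frequencies outside \eqn{[0,1]}, p-values outside \eqn{(0,1]},
#' non-positive n, non-finite beta) are dropped, with the count reported
#' in a message and stored in the `nDropped` slot. Alleles are
#' upper-cased. The `eaf`, `pvalue` and `n` columns are optional and
#' filled with `NA` when absent from the file.
#'
#' @param path Path to the delimited text file.
#' @param columnMap Named character vector overriding entries of
#'   [defaultColumnMap()].
#' @param trait Trait label stored with the table.
#' @return An `AssociationTable`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(
#'   data.frame(SNP = c("rs1", "rs2"), effect_allele = c("a", "c"),
#'              other_allele = c("g", "t"), eaf = c(0.2, 0.4),
#'              beta = c(0.1, -0.05), se = c(0.01, 0.02),
#'              pval = c(1e-9, 1e-8), n = 10000),
#'   tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' readAssociations(tf, trait = "demo")
#' @export
readAssociations <- function(path, columnMap = NULL, trait = "trait") {
  cmap <- defaultColumnMap()
  if (!is.null(columnMap)) {
    unknown <- setdiff(names(columnMap), names(cmap))
    if (length(unknown))
      stop(sprintf("unknown column-map fields: %s",
                   paste(unknown, collapse = ", ")))
    cmap[names(columnMap)] <- columnMap
  }
  raw <- .readDelimited(path)
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  missing <- mandatory[!cmap[mandatory] %in% names(raw)]
  if (length(missing))
    stop(sprintf("configuration error: mapped column(s) absent from %s: %s",
                 path, paste(cmap[missing], collapse = ", ")))
  get_col <- function(field, default = NA_real_) {
    col <- cmap[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  df <- data.frame(
    rsid = as.character(get_col("rsid")),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele = toupper(as.character(get_col("other_allele"))),
    eaf = suppressWarnings(as.numeric(get_col("eaf"))),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    pvalue = suppressWarnings(as.numeric(get_col("pvalue"))),
    n = suppressWarnings(as.numeric(get_col("n"))),
    stringsAsFactors = FALSE)

  ok <- df$effect_allele %in% VALID_ALLELES &
    df$other_allele %in% VALID_ALLELES &
    df$effect_allele != df$other_allele &
    is.finite(df$beta) & is.finite(df$se) & df$se > 0 &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)) &
    (is.na(df$pvalue) | (df$pvalue > 0 & df$pvalue <= 1)) &
    (is.na(df$n) | df$n > 0)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message(sprintf("readAssociations: dropped %d invalid row(s) from %s",
                    n_dropped, path))
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) == 0L)
    stop(sprintf("input error: no valid association rows in %s", path))
  new("AssociationTable", trait = trait, data = df,
      nDropped = as.integer(n_dropped))
}

#' Read a pairwise LD (r-squared) table
#'
#' Reads a three-column (snp1, snp2, r2) delimited table into a
#' symmetric [`LDTable`][LDTable-class]. Duplicate pairs (in either
#' order) collapse to the maximum r2.
#'
#' @param path Path to the delimited text file.
#' @return An `LDTable`.
#' @export
readLDTable <- function(path) {
  raw <- .readDelimited(path)
  if (ncol(raw) < 3L)
    stop("input error: LD table needs three columns (snp1, snp2, r2)")
  df <- data.frame(snp1 = as.character(raw[[1]]),
                   snp2 = as.character(raw[[2]]),
                   r2 = as.numeric(raw[[3]]), stringsAsFactors = FALSE)
  if (any(!is.finite(df$r2)) || any(df$r2 < 0 | df$r2 > 1))
    stop("input error: r2 values must lie in [0, 1]")
  a <- pmin(df$snp1, df$snp2)
  b <- pmax(df$snp1, df$snp2)
  keep <- a != b           # self-pairs are implicit (r2 = 1)
  df <- data.frame(snp1 = a[keep], snp2 = b[keep], r2 = df$r2[keep],
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    key <- paste(df$snp1, df$snp2, sep = "\r")
    r2 <- tapply(df$r2, key, max)
    parts <- strsplit(names(r2), "\r", fixed = TRUE)
    df <- data.frame(snp1 = vapply(parts, `[`, "", 1L),
                     snp2 = vapply(parts, `[`, "", 2L),
                     r2 = as.numeric(r2), stringsAsFactors = FALSE)
    rownames(df) <- NULL
  }
  new("LDTable", data = df)
}

#' Query pairwise r-squared
#'
#' Symmetric lookup into an [`LDTable`][LDTable-class]. A SNP paired
#' with itself returns 1; absent pairs return `NA`.
#'
#' @param ld An `LDTable`.
#' @param a,b Character vectors of rsids (recycled to common length).
#' @return Numeric vector of r2 values.
#' @export
ldR2 <- function(ld, a, b) {
  stopifnot(is(ld, "LDTable"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab_key <- paste(ld@data$snp1, ld@data$snp2, sep = "\r")
  out <- ld@data$r2[match(key, tab_key)]
  out[a == b] <- 1
  out
}
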