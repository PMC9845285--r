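#' @keywords internal
"_PACKAGE"

# Canonical summary-statistics columns used throughout the package.
SUMSTATS_COLS <- c("snp", "effect_allele", "other_allele", "eaf",
                   "beta", "se", "pval", "n")

VALID_BASES <- c("A", "C", "G", "T")

#' Validate a data frame of GWAS summary statistics
#'
#' Checks every row against the per-variant invariants (single-base alleles,
#' effect allele distinct from the other allele, frequency strictly inside
#' (0,1), positive standard error, p-value in (0,1], sample size at least 2).
#' Failing rows are dropped, not fatal: real summary files are dirty and a
#' silent drop is the only alternative to a logged one.
#'
#' @param df data frame with the canonical columns
#'   `snp, effect_allele, other_allele, eaf, beta, se, pval, n`.
#' @return The validated rows, alleles upper-cased, with a `removal_log`
#'   attribute: a data frame of `row`, `snp`, `reason` for every dropped row.
#' @export
validate_summary_records <- function(df) {
  missing <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[SUMSTATS_COLS]
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- why
  }
  flag(is.na(df$snp) | !nzchar(df$snp), "missing variant id")
  flag(!(df$effect_allele %in% VALID_BASES) |
         !(df$other_allele %in% VALID_BASES), "invalid allele")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(!is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1, "eaf out of range")
  flag(!is.finite(df$beta), "non-numeric beta")
  flag(!is.finite(df$se) | df$se <= 0, "se not positive")
  flag(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1, "pval out of range")
  flag(!is.finite(df$n) | df$n < 2, "n below 2")

  bad <- !is.na(reason)
  log <- data.frame(row = which(bad),
                    snp = as.character(df$snp[bad]),
                    reason = reason[bad],
                    stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_log") <- log
  out
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited file with a header, maps its columns onto
#' the canonical names, and validates every row.  Rows failing validation are
#' dropped and recorded in the `removal_log` attribute with row number and
#' reason; allele characters are upper-cased.
#'
#' @param path path to the file. The delimiter is sniffed from the header line
#'   (tab wins over comma).
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(effect_allele = "A1", pval = "P")`.
#'   Canonical names absent from the map are looked up verbatim.
#' @return data frame of validated records (see
#'   [validate_summary_records()]).
#' @export
read_summary_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  if (nrow(raw) == 0) stop("empty file: ", path)

  map <- stats::setNames(SUMSTATS_COLS, SUMSTATS_COLS)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), SUMSTATS_COLS)
    if (length(unknown) > 0) {
      stop("column_map has unknown canonical name(s): ",
           paste(unknown, collapse = ", "))
    }
    map[names(column_map)] <- column_map
  }
  absent <- map[!(map %in% names(raw))]
  if (length(absent) > 0) {
    stop("mapped column(s) not found in file: ",
         paste(sprintf("%s (for %s)", absent, names(absent)), collapse = ", "))
  }
  df <- stats::setNames(raw[unname(map)], names(map))
  validate_summary_records(df)
}

#' Select genome-wide-significant instruments
#'
#' Keeps records with p-value strictly below the threshold (the conventional
#' genome-wide cut is p < 5e-8; boundary values are excluded). Order is
#' preserved and an empty result is allowed.
#'
#' @param records summary-statistics data frame.
#' @param p_threshold significance threshold in (0, 1]; default `5e-8`.
#' @return The significant subset of `records`.
#' @export
select_instruments <- function(records, p_threshold = 5e-8) {
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1,
            p_threshold > 0, p_threshold <= 1)
  out <- records[records$pval < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD pruning of instruments
#'
#' Visits records in ascending p-value order and keeps a record iff its
#' pairwise r-squared with every already-kept record is below the threshold.
#' The LD matrix is an explicit input (no reference panel is consulted); the
#' synthetic generator can emit one aligned to its records.
#'
#' @param records summary-statistics data frame.
#' @param ld_r2_matrix symmetric matrix of pairwise r-squared in `[0,1]`,
#'   rows/columns aligned with (and ideally named by) `records$snp`.
#' @param r2_threshold prune threshold; default 0.01.
#' @return Kept records (original row order), with a `prune_log` attribute
#'   listing each pruned `snp` and the retained partner that excluded it.
#' @export
ld_prune <- function(records, ld_r2_matrix, r2_threshold = 0.01) {
  k <- nrow(records)
  ld_r2_matrix <- as.matrix(ld_r2_matrix)
  if (!all(dim(ld_r2_matrix) == c(k, k))) {
    stop("LD matrix dimensions (", paste(dim(ld_r2_matrix), collapse = "x"),
         ") do not match the number of records (", k, ")")
  }
  order_idx <- order(records$pval)
  kept <- integer(0)
  log <- data.frame(snp = character(0), retained_partner = character(0),
                    r2 = numeric(0), stringsAsFactors = FALSE)
  for (i in order_idx) {
    r2_with_kept <- ld_r2_matrix[i, kept]
    if (all(r2_with_kept < r2_threshold)) {
      kept <- c(kept, i)
    } else {
      partner <- kept[which.max(r2_with_kept)]
      log <- rbind(log, data.frame(
        snp = records$snp[i], retained_partner = records$snp[partner],
        r2 = max(r2_with_kept), stringsAsFactors = FALSE))
    }
  }
  out <- records[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "prune_log") <- log
  out
}

#' Proportion of trait variance explained by one SNP
#'
#' For a standardized (rank-inverse-normalized) trait,
#' \deqn{R^2 = \frac{2\beta^2 q(1-q)}{2\beta^2 q(1-q) + se(\beta)^2 \, 2N\, q(1-q)}}
#' with \eqn{q} the minor-allele frequency. Files carry the effect-allele
#' frequency, so MAF is taken as `min(eaf, 1 - eaf)` (the formula is symmetric
#' in q vs 1-q anyway). Vectorized over records.
#'
#' @param records summary-statistics data frame (uses `beta`, `eaf`, `se`, `n`).
#' @return numeric vector of per-SNP R-squared values in `[0, 1]`.
#' @export
variance_explained <- function(records) {
  maf <- pmin(records$eaf, 1 - records$eaf)
  num <- 2 * records$beta^2 * maf * (1 - maf)
  den <- num + records$se^2 * 2 * records$n * maf * (1 - maf)
  num / den
}

#' Instrument-strength F statistic
#'
#' \deqn{F = \frac{R^2 (N - 1 - k)}{(1 - R^2)\, k}} where `r2_total` is the
#' total variance explained by the k instruments in a study of size N. The
#' weak-instrument convention flags F < 10.
#'
#' @param r2_total total variance explained, in `[0, 1)`.
#' @param n exposure-study sample size; must exceed `k + 1`.
#' @param k number of instruments.
#' @return the F statistic (non-negative scalar).
#' @export
f_statistic <- function(r2_total, n, k) {
  stopifnot(r2_total >= 0, k >= 1)
  if (r2_total >= 1) stop("r2_total must be < 1")
  if (n <= k + 1) stop("n must exceed k + 1")
  r2_total * (n - 1 - k) / ((1 - r2_total) * k)
}

#' Bundle instruments with strength statistics
#'
#' Aggregate R-squared is the sum of per-SNP R-squared (independence is a
#' fair assumption after pruning at r-squared < 0.01); the F statistic uses
#' the median reported sample size across the instruments.
#'
#' @param records pruned, significant instruments for one exposure.
#' @param exposure_name label for the exposure.
#' @return An `instrument_set`: list with `exposure_name`, `records`,
#'   `r2_total`, `f_stat`, `k`.
#' @export
instrument_set <- function(records, exposure_name = "exposure") {
  if (nrow(records) == 0) stop("no instruments for ", exposure_name)
  if (anyDuplicated(records$snp)) {
    stop("duplicate variant ids in instrument set for ", exposure_name)
  }
  k <- nrow(records)
  r2_total <- sum(variance_explained(records))
  n <- stats::median(records$n)
  structure(
    list(exposure_name = exposure_name, records = records,
         r2_total = r2_total,
         f_stat = f_statistic(r2_total, n, k), k = k),
    class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d SNP(s), R2 = %.4f, F = %.1f\n",
              x$exposure_name, x$k, x$r2_total, x$f_stat))
  invisible(x)
}
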