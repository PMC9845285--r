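# Panel orchestration: a panel of exposures against a panel of outcomes,
# with per-cell failure isolation, Bonferroni flags across exposures within
# each outcome, and full audit logs.

#' Build a run configuration
#'
#' @param exposures named list; each element a summary-statistics data frame
#'   or a file path.
#' @param outcomes named list like `exposures`.
#' @param outcome_types named character vector ("risk" or "survival") per
#'   outcome; default "risk". Survival outcomes are handled identically
#'   (betas are log-hazards; the exponentiated column is then an HR).
#' @param ld_matrices optional named list (per exposure) of LD r-squared
#'   matrices or file paths; exposures without one are assumed independent.
#' @param p_threshold instrument-selection threshold; default 5e-8.
#' @param r2_threshold LD prune threshold; default 0.01.
#' @param af_window palindromic intermediate-AF window; default (0.42, 0.58).
#' @param allow_strand_flip rescue non-palindromic mismatches by strand
#'   complement.
#' @param bonferroni_m Bonferroni family size; default the number of
#'   exposures in the panel (applied within each outcome).
#' @param egger,weighted_median,heterogeneity sensitivity toggles.
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed seed for the weighted-median bootstrap; required when that
#'   estimator is enabled.
#' @param column_map optional column map applied when reading files.
#' @return a `run_config` list.
#' @export
run_config <- function(exposures, outcomes, outcome_types = NULL,
                       ld_matrices = NULL,
                       p_threshold = 5e-8, r2_threshold = 0.01,
                       af_window = c(0.42, 0.58), allow_strand_flip = TRUE,
                       bonferroni_m = NULL,
                       egger = TRUE, weighted_median = TRUE,
                       heterogeneity = TRUE, n_boot = 1000,
                       seed = NULL, column_map = NULL) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            !is.null(names(exposures)), !is.null(names(outcomes)))
  if (is.null(outcome_types)) {
    outcome_types <- stats::setNames(rep("risk", length(outcomes)),
                                     names(outcomes))
  }
  if (is.null(bonferroni_m)) bonferroni_m <- length(exposures)
  if (weighted_median && is.null(seed)) {
    stop("a seed is required when the weighted-median estimator is enabled")
  }
  for (x in c(exposures, outcomes, if (!is.null(ld_matrices)) ld_matrices)) {
    if (is.character(x) && !file.exists(x)) stop("file not found: ", x)
  }
  structure(
    list(exposures = exposures, outcomes = outcomes,
         outcome_types = outcome_types, ld_matrices = ld_matrices,
         p_threshold = p_threshold, r2_threshold = r2_threshold,
         af_window = af_window, allow_strand_flip = allow_strand_flip,
         bonferroni_m = bonferroni_m, egger = egger,
         weighted_median = weighted_median, heterogeneity = heterogeneity,
         n_boot = n_boot, seed = seed, column_map = column_map),
    class = "run_config")
}

#' Read a run configuration from a flat key-value file
#'
#' Lines are `key = value` (or tab-separated); `#` starts a comment.
#' Exposures, outcomes and LD matrices are listed as
#' `exposure:NAME = path`, `outcome:NAME = path`,
#' `outcome:NAME:survival = path`, `ld:NAME = path`; the scalar keys are the
#' [run_config()] arguments (`p_threshold`, `r2_threshold`,
#' `palindrome_af_low`, `palindrome_af_high`, `allow_strand_flip`,
#' `bonferroni_m`, `egger`, `weighted_median`, `heterogeneity`, `n_boot`,
#' `seed`).
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=\t]+?)[ \t]*(?:=|\t)[ \t]*(.+)$",
                                  lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop("unparseable config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))

  exposures <- list(); outcomes <- list(); types <- character(0)
  lds <- list(); scalars <- list()
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], ":", fixed = TRUE)[[1]]
    if (parts[1] == "exposure") {
      exposures[[parts[2]]] <- vals[i]
    } else if (parts[1] == "outcome") {
      outcomes[[parts[2]]] <- vals[i]
      types[parts[2]] <- if (length(parts) >= 3) parts[3] else "risk"
    } else if (parts[1] == "ld") {
      lds[[parts[2]]] <- vals[i]
    } else {
      scalars[[keys[i]]] <- vals[i]
    }
  }
  num <- function(key, default) {
    if (!is.null(scalars[[key]])) as.numeric(scalars[[key]]) else default
  }
  flag <- function(key, default) {
    if (!is.null(scalars[[key]])) {
      tolower(scalars[[key]]) %in% c("true", "1", "yes")
    } else default
  }
  run_config(
    exposures = exposures, outcomes = outcomes, outcome_types = types,
    ld_matrices = if (length(lds)) lds else NULL,
    p_threshold = num("p_threshold", 5e-8),
    r2_threshold = num("r2_threshold", 0.01),
    af_window = c(num("palindrome_af_low", 0.42),
                  num("palindrome_af_high", 0.58)),
    allow_strand_flip = flag("allow_strand_flip", TRUE),
    bonferroni_m = if (!is.null(scalars$bonferroni_m)) {
      as.numeric(scalars$bonferroni_m)
    } else NULL,
    egger = flag("egger", TRUE),
    weighted_median = flag("weighted_median", TRUE),
    heterogeneity = flag("heterogeneity", TRUE),
    n_boot = num("n_boot", 1000),
    seed = if (!is.null(scalars$seed)) as.integer(scalars$seed) else NULL)
}

load_records <- function(x, column_map = NULL) {
  if (is.character(x)) read_summary_table(x, column_map) else x
}

load_ld <- function(x) {
  if (is.null(x)) NULL else if (is.character(x)) read_ld_matrix(x) else x
}

# One exposure x outcome cell: select -> prune -> harmonize -> estimate.
scan_cell <- function(exp_records, out_records, ld, config,
                      exposure_name, outcome_name) {
  sig <- select_instruments(exp_records, config$p_threshold)
  if (nrow(sig) == 0) stop("no genome-wide-significant instruments")
  if (!is.null(ld)) {
    idx <- match(sig$snp, exp_records$snp)
    sig <- ld_prune(sig, ld[idx, idx, drop = FALSE], config$r2_threshold)
  }
  iset <- instrument_set(sig, exposure_name)
  hset <- harmonize_dataset(iset, out_records, af_window = config$af_window,
                            allow_strand_flip = config$allow_strand_flip,
                            outcome_name = outcome_name)
  k <- hset$n_final
  if (k == 0) stop("no instruments survived harmonization")

  primary <- if (k == 1) wald_ratio(harmonized_pairs(hset)) else
    ivw_fixed(hset)
  ests <- list(primary)
  if (config$egger && k >= 3) {
    egg <- mr_egger(hset)
    ests <- c(ests, list(egg$slope, egg$intercept))
  }
  if (config$weighted_median && k >= 3) {
    ests <- c(ests, list(weighted_median(hset, n_boot = config$n_boot,
                                         seed = config$seed)))
  }
  rows <- do.call(rbind, lapply(ests, as.data.frame))
  rows <- cbind(exposure = exposure_name, outcome = outcome_name,
                outcome_type = config$outcome_types[[outcome_name]],
                rows, stringsAsFactors = FALSE)
  rows$q <- NA_real_; rows$i2 <- NA_real_
  if (config$heterogeneity && k >= 2) {
    het <- cochran_q_i2(hset, primary$beta)
    is_primary <- rows$method %in% c("ivw_fixed", "wald")
    rows$q[is_primary] <- het$q
    rows$i2[is_primary] <- het$i2
  }
  list(rows = rows, harmonized = hset, instruments = iset)
}

#' Run the full exposure-by-outcome MR scan
#'
#' For each exposure x outcome cell: select instruments, LD-prune, harmonize,
#' estimate (fixed-effect IVW, or the Wald ratio when a single instrument
#' survives), run the enabled sensitivity estimators where the instrument
#' count permits (>= 3 for MR-Egger and the weighted median), quantify
#' heterogeneity, and flag Bonferroni significance across exposures within
#' each outcome. A failing cell is recorded and skipped — one bad exposure
#' never kills the scan.
#'
#' @param config a `run_config`.
#' @return results data frame (one row per estimate) with columns
#'   `exposure, outcome, outcome_type, method, n_snps, beta, se, or_or_hr,
#'   ci_low, ci_high, exp_ci_low, exp_ci_high, pval, pval_bonferroni,
#'   bonferroni_flag, q, i2`; attributes `harmonized` (named list of
#'   `harmonized_set`s per cell), `instruments` (per exposure), and
#'   `failures` (data frame of skipped cells).
#' @export
run_mr_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  exposures <- lapply(config$exposures, load_records, config$column_map)
  outcomes <- lapply(config$outcomes, load_records, config$column_map)
  lds <- lapply(stats::setNames(names(exposures), names(exposures)),
                function(nm) load_ld(config$ld_matrices[[nm]]))

  all_rows <- list(); harmonized <- list(); instruments <- list()
  failures <- data.frame(exposure = character(0), outcome = character(0),
                         error = character(0), stringsAsFactors = FALSE)
  for (out_nm in names(outcomes)) {
    for (exp_nm in names(exposures)) {
      cell <- tryCatch(
        scan_cell(exposures[[exp_nm]], outcomes[[out_nm]], lds[[exp_nm]],
                  config, exp_nm, out_nm),
        error = function(e) e)
      if (inherits(cell, "error")) {
        failures <- rbind(failures, data.frame(
          exposure = exp_nm, outcome = out_nm,
          error = conditionMessage(cell), stringsAsFactors = FALSE))
        next
      }
      key <- paste(exp_nm, out_nm, sep = " -> ")
      all_rows[[key]] <- cell$rows
      harmonized[[key]] <- cell$harmonized
      instruments[[exp_nm]] <- cell$instruments
    }
  }
  if (length(all_rows) == 0) stop("every cell of the scan failed")
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL

  results$pval_bonferroni <- NA_real_
  results$bonferroni_flag <- NA
  is_primary <- results$method %in% c("ivw_fixed", "wald")
  for (out_nm in unique(results$outcome)) {
    sel <- is_primary & results$outcome == out_nm
    bf <- bonferroni_flag(results$pval[sel], config$bonferroni_m)
    results$pval_bonferroni[sel] <- bf$p_adjusted
    results$bonferroni_flag[sel] <- bf$flag
  }
  attr(results, "harmonized") <- harmonized
  attr(results, "instruments") <- instruments
  attr(results, "failures") <- failures
  results
}

#' Significance stars at the conventional 0.05 / 0.01 / 0.001 cuts
#'
#' @param p numeric vector of p-values.
#' @return character vector: `***` for p < 0.001, `**` for p < 0.01,
#'   `*` for p < 0.05, empty otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Forest-plot input tables, one per outcome
#'
#' Emits the exponentiated estimate (OR for risk outcomes, HR for survival)
#' with its exponentiated CI bounds and significance stars, the shape a
#' forest-plot panel consumes.
#'
#' @param results output of [run_mr_scan()].
#' @param dir optional directory; when given, each outcome's table is written
#'   as `forest_<outcome>.tsv`.
#' @return named list of per-outcome data frames.
#' @export
write_forest_inputs <- function(results, dir = NULL) {
  out <- lapply(split(results, results$outcome), function(df) {
    data.frame(exposure = df$exposure, outcome = df$outcome,
               effect_label = ifelse(df$outcome_type == "survival",
                                     "HR", "OR"),
               method = df$method, n_snps = df$n_snps,
               or_or_hr = df$or_or_hr,
               ci_low = df$exp_ci_low, ci_high = df$exp_ci_high,
               pval = df$pval,
               stars = significance_stars(df$pval),
               stringsAsFactors = FALSE)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out)) {
      utils::write.table(out[[nm]],
                         file.path(dir, paste0("forest_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' Write the full results table
#'
#' Tab-delimited, one row per estimate, the columns of [run_mr_scan()].
#'
#' @param results output of [run_mr_scan()].
#' @param path output path.
#' @export
write_results_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
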