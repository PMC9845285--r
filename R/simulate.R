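# Synthetic GWAS summary statistics and cohorts with known ground truth.
# Every stochastic entry point takes a mandatory seed through the scenario;
# the caller's RNG state is saved and restored, and exposure, outcome and
# cohort draws use separate derived streams so the two samples are
# independent, as two-sample MR assumes.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  expr
}

# Offsets deriving the per-stage RNG streams from the scenario seed.
SEED_OFFSET_OUTCOME <- 500009L
SEED_OFFSET_COHORT <- 1000003L

#' Define a simulation scenario
#'
#' The scenario fixes the data-generating process shared by the generator
#' functions: k instruments act on a standardized exposure which acts
#' linearly on the outcome (log-odds scale) with causal effect `theta`;
#' an `invalid_fraction` of instruments additionally carries a horizontal
#' pleiotropic effect drawn from N(`pleiotropy_mean`, `pleiotropy_sd`)
#' (mean forced to 0 under `pleiotropy_mode = "balanced"`). Defaults emulate
#' a plasma-proteome pQTL study (N = 3,301) against a large case-control
#' outcome GWAS (N = 247,173), with exposure effects strong enough to put
#' instrument F statistics in the tens-to-hundreds range.
#'
#' @param k instrument count (>= 1).
#' @param n_exp,n_out exposure / outcome study sample sizes.
#' @param theta true causal effect per SD of exposure (log-OR scale);
#'   default log(0.89), a protective effect of the size reported for CCL5.
#' @param maf_range range for effect-allele frequencies (uniform draw).
#' @param beta_exp_mean,beta_exp_sd distribution of true exposure effects.
#' @param pleiotropy_mode one of "none", "balanced", "directional".
#' @param pleiotropy_mean,pleiotropy_sd pleiotropic-effect distribution.
#' @param invalid_fraction fraction of instruments receiving pleiotropy.
#' @param palindromic_fraction fraction of instruments given A/T or C/G
#'   allele pairs.
#' @param intermediate_af_fraction fraction *of the palindromic instruments*
#'   forced to an intermediate (near-0.5) allele frequency, so they are
#'   unresolvable at harmonization.
#' @param af_window intermediate-frequency window the fixtures are built
#'   around; intermediate palindromes are drawn well inside it, other
#'   palindromes well outside.
#' @param seed mandatory integer seed; there is no entropy default.
#' @return a `mr_scenario` list.
#' @export
mr_scenario <- function(k,
                        n_exp = 3301,
                        n_out = 247173,
                        theta = log(0.89),
                        maf_range = c(0.1, 0.9),
                        beta_exp_mean = 0.3,
                        beta_exp_sd = 0.1,
                        pleiotropy_mode = c("none", "balanced", "directional"),
                        pleiotropy_mean = 0,
                        pleiotropy_sd = 0,
                        invalid_fraction = 0,
                        palindromic_fraction = 0,
                        intermediate_af_fraction = 0,
                        af_window = c(0.42, 0.58),
                        seed) {
  if (missing(seed)) stop("mr_scenario requires an explicit seed")
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (pleiotropy_mode == "balanced") pleiotropy_mean <- 0
  if (pleiotropy_mode == "none") invalid_fraction <- 0
  stopifnot(k >= 1, n_exp >= 2, n_out >= 2,
            invalid_fraction >= 0, invalid_fraction <= 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            intermediate_af_fraction >= 0, intermediate_af_fraction <= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] < maf_range[2])
  structure(
    list(k = as.integer(k), n_exp = n_exp, n_out = n_out, theta = theta,
         maf_range = maf_range,
         beta_exp_mean = beta_exp_mean, beta_exp_sd = beta_exp_sd,
         pleiotropy_mode = pleiotropy_mode,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         invalid_fraction = invalid_fraction,
         palindromic_fraction = palindromic_fraction,
         intermediate_af_fraction = intermediate_af_fraction,
         af_window = af_window, seed = as.integer(seed)),
    class = "mr_scenario")
}

# GWAS standard error for a standardized trait: se = 1/sqrt(2N p (1-p)).
gwas_se <- function(n, eaf) 1 / sqrt(2 * n * eaf * (1 - eaf))

# Draw allele pairs: the first n_palin variants get palindromic pairs.
draw_allele_pairs <- function(k, n_palin) {
  palin_pool <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  nonpal_pool <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                       c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
  pairs <- matrix("", k, 2)
  if (n_palin > 0) {
    pairs[seq_len(n_palin), ] <-
      palin_pool[sample.int(4, n_palin, replace = TRUE), ]
  }
  if (n_palin < k) {
    pairs[(n_palin + 1):k, ] <-
      nonpal_pool[sample.int(8, k - n_palin, replace = TRUE), ]
  }
  pairs
}

# Uniform draw from maf_range excluding a margin around the AF window, so
# non-intermediate palindromes stay unambiguously outside the window.
draw_eaf_outside_window <- function(n, maf_range, af_window, margin = 0.02) {
  lo_seg <- c(maf_range[1], min(maf_range[2], af_window[1] - margin))
  hi_seg <- c(max(maf_range[1], af_window[2] + margin), maf_range[2])
  segs <- list(lo_seg, hi_seg)
  lens <- vapply(segs, function(s) max(0, s[2] - s[1]), numeric(1))
  if (sum(lens) <= 0) stop("maf_range leaves no room outside the AF window")
  pick <- sample.int(2, n, replace = TRUE, prob = lens / sum(lens))
  vapply(seq_len(n), function(i) {
    s <- segs[[pick[i]]]
    stats::runif(1, s[1], s[2])
  }, numeric(1))
}

#' Simulate exposure (pQTL) summary statistics
#'
#' Draws true per-SNP exposure effects from N(beta_exp_mean, beta_exp_sd),
#' allele pairs with the requested palindromic fraction (of which the
#' requested sub-fraction sits at intermediate frequency, inside the AF
#' window; the remaining palindromes are drawn outside it), frequencies
#' uniform over `maf_range`, analytic standard errors
#' se = 1/sqrt(2 N p (1-p)), observed effects true + N(0, se), and two-sided
#' normal p-values. Deterministic under the scenario seed.
#'
#' @param scenario an `mr_scenario`.
#' @return summary-statistics data frame with a `truth` attribute
#'   (`snp`, `beta_true`) and the `scenario` attached.
#' @export
simulate_exposure_summary <- function(scenario) {
  stopifnot(inherits(scenario, "mr_scenario"))
  k <- scenario$k
  with_local_seed(scenario$seed, {
    n_palin <- round(k * scenario$palindromic_fraction)
    n_inter <- round(n_palin * scenario$intermediate_af_fraction)
    alleles <- draw_allele_pairs(k, n_palin)
    win <- scenario$af_window
    core <- c(win[1] + 0.6 * (0.5 - win[1]), win[2] - 0.6 * (win[2] - 0.5))
    eaf <- numeric(k)
    if (n_inter > 0) eaf[seq_len(n_inter)] <- stats::runif(n_inter, core[1],
                                                           core[2])
    if (n_palin > n_inter) {
      idx <- (n_inter + 1):n_palin
      eaf[idx] <- draw_eaf_outside_window(length(idx), scenario$maf_range, win)
    }
    if (n_palin < k) {
      idx <- (n_palin + 1):k
      eaf[idx] <- stats::runif(length(idx), scenario$maf_range[1],
                               scenario$maf_range[2])
    }
    beta_true <- stats::rnorm(k, scenario$beta_exp_mean, scenario$beta_exp_sd)
    se <- gwas_se(scenario$n_exp, eaf)
    beta <- beta_true + stats::rnorm(k, 0, se)
    records <- data.frame(
      snp = sprintf("rs%06d", seq_len(k)),
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = beta, se = se,
      pval = 2 * stats::pnorm(-abs(beta / se)),
      n = scenario$n_exp, stringsAsFactors = FALSE)
    attr(records, "truth") <- data.frame(snp = records$snp,
                                         beta_true = beta_true,
                                         stringsAsFactors = FALSE)
    attr(records, "scenario") <- scenario
    records
  })
}

#' Simulate outcome summary statistics under a linear causal model
#'
#' The true outcome effect of instrument j is theta * beta_true_j + alpha_j,
#' where alpha_j = 0 for valid instruments and alpha_j ~
#' N(pleiotropy_mean, pleiotropy_sd) for the `invalid_fraction` chosen at
#' random (mean 0 under balanced pleiotropy). Observed effects add
#' N(0, se_out) noise with se_out from the outcome sample size and the same
#' allele frequencies; variant ids and allele labels match the exposure file
#' exactly. The outcome draws use an RNG stream separate from the exposure's,
#' enforcing two-sample independence.
#'
#' @param exposure records from [simulate_exposure_summary()] (carries the
#'   scenario and truth).
#' @param scenario optional scenario override; defaults to the one attached
#'   to `exposure`.
#' @return summary-statistics data frame with a `truth` attribute
#'   (`snp`, `beta_true_out`, `alpha`, `is_invalid`).
#' @export
simulate_outcome_summary <- function(exposure, scenario = NULL) {
  if (is.null(scenario)) scenario <- attr(exposure, "scenario")
  stopifnot(inherits(scenario, "mr_scenario"))
  truth <- attr(exposure, "truth")
  if (is.null(truth)) stop("exposure records carry no truth attribute")
  k <- nrow(exposure)
  with_local_seed(scenario$seed + SEED_OFFSET_OUTCOME, {
    alpha <- numeric(k)
    n_invalid <- round(k * scenario$invalid_fraction)
    if (n_invalid > 0 && scenario$pleiotropy_mode != "none") {
      invalid <- sample.int(k, n_invalid)
      alpha[invalid] <- stats::rnorm(n_invalid, scenario$pleiotropy_mean,
                                     scenario$pleiotropy_sd)
    }
    beta_true_out <- scenario$theta * truth$beta_true + alpha
    se <- gwas_se(scenario$n_out, exposure$eaf)
    beta <- beta_true_out + stats::rnorm(k, 0, se)
    records <- data.frame(
      snp = exposure$snp,
      effect_allele = exposure$effect_allele,
      other_allele = exposure$other_allele,
      eaf = exposure$eaf, beta = beta, se = se,
      pval = 2 * stats::pnorm(-abs(beta / se)),
      n = scenario$n_out, stringsAsFactors = FALSE)
    attr(records, "truth") <- data.frame(
      snp = records$snp, beta_true_out = beta_true_out, alpha = alpha,
      is_invalid = alpha != 0, stringsAsFactors = FALSE)
    attr(records, "scenario") <- scenario
    records
  })
}

#' Simulate an individual-level cohort for PRS analyses
#'
#' Genotype dosages are drawn per variant as Binomial(2, eaf) using the
#' exposure records' frequencies; the true PRS is the dosage-weighted sum of
#' true exposure effects; a binary outcome is drawn from a logistic model
#' with the stated log-odds coefficient per SD of PRS. Deterministic under
#' the scenario seed (its own derived RNG stream).
#'
#' @param exposure records from [simulate_exposure_summary()].
#' @param n_individuals cohort size (>= 10).
#' @param prs_log_or log-odds of outcome per SD of true PRS.
#' @param baseline_prev outcome prevalence at the mean PRS.
#' @return list with `dosages` (matrix with `counted_allele` attribute,
#'   suitable for [compute_prs()]), `outcome` (0/1 vector), `profile` (the
#'   true-effect `prs_profile`), and `prs_true`.
#' @export
simulate_cohort <- function(exposure, n_individuals, prs_log_or = 0,
                            baseline_prev = 0.1) {
  scenario <- attr(exposure, "scenario")
  truth <- attr(exposure, "truth")
  stopifnot(inherits(scenario, "mr_scenario"), !is.null(truth),
            n_individuals >= 10)
  k <- nrow(exposure)
  with_local_seed(scenario$seed + SEED_OFFSET_COHORT, {
    dosages <- vapply(seq_len(k), function(j) {
      stats::rbinom(n_individuals, 2, exposure$eaf[j])
    }, numeric(n_individuals))
    dimnames(dosages) <- list(sprintf("ind%05d", seq_len(n_individuals)),
                              exposure$snp)
    attr(dosages, "counted_allele") <- stats::setNames(
      exposure$effect_allele, exposure$snp)
    prs_true <- drop(dosages %*% truth$beta_true)
    z <- if (stats::sd(prs_true) > 0) {
      (prs_true - mean(prs_true)) / stats::sd(prs_true)
    } else rep(0, n_individuals)
    eta <- stats::qlogis(baseline_prev) + prs_log_or * z
    outcome <- stats::rbinom(n_individuals, 1, stats::plogis(eta))
    list(dosages = dosages, outcome = outcome,
         profile = prs_profile(exposure$snp, exposure$effect_allele,
                               truth$beta_true, name = "true-effect PRS"),
         prs_true = prs_true)
  })
}

#' Block-structured LD matrix for pruning fixtures
#'
#' Builds a symmetric r-squared matrix of LD blocks: within-block pairs share
#' `within_r2`, across-block pairs `between_r2`, diagonal 1.
#'
#' @param block_sizes integer vector of block sizes (sums to the number of
#'   variants).
#' @param within_r2,between_r2 r-squared inside / between blocks.
#' @return square numeric matrix.
#' @export
ld_block_matrix <- function(block_sizes, within_r2 = 0.9,
                            between_r2 = 0.001) {
  k <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  m <- matrix(between_r2, k, k)
  same <- outer(block, block, "==")
  m[same] <- within_r2
  diag(m) <- 1
  m
}

#' Write summary statistics in the canonical dialect
#'
#' Tab-delimited with the canonical header, readable back by
#' [read_summary_table()].
#'
#' @param records summary-statistics data frame.
#' @param path output path.
#' @export
write_summary_table <- function(records, path) {
  utils::write.table(records[SUMSTATS_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a square LD matrix as a tab-delimited table
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  m
}

#' @rdname read_ld_matrix
#' @param m square numeric matrix.
#' @export
write_ld_matrix <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
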