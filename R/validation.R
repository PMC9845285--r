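# Simulation experiments validating the estimator suite against known truth.
# These are the package's own calibration studies: tests and the
# reproduction script both call them, so the numbers they report are always
# recomputed from scratch.

# Derive a bounded per-replicate seed vector from one master seed.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(2^30, n))
}

#' Closed-form estimators versus weighted-least-squares oracles
#'
#' Generates random harmonized sets and compares the closed-form IVW and
#' MR-Egger estimates against independent `stats::lm` weighted fits (IVW
#' against origin-constrained WLS with the residual dispersion divided out
#' of the SE; Egger against intercept WLS).
#'
#' @param n_sets number of random sets.
#' @param k_range instrument counts to draw from.
#' @param seed master seed.
#' @return list with `max_beta_dev`, `max_se_dev` (worst absolute deviations
#'   across all compared quantities) and `n_sets`.
#' @export
mr_oracle_deviation <- function(n_sets = 100, k_range = 3:30, seed = 1) {
  dev_beta <- dev_se <- 0
  with_local_seed(seed, {
    for (i in seq_len(n_sets)) {
      k <- sample(k_range, 1)
      p <- data.frame(beta_exp = stats::rnorm(k, 0.3, 0.1),
                      se_exp = stats::runif(k, 0.01, 0.05),
                      beta_out = stats::rnorm(k, 0.05, 0.03),
                      se_out = stats::runif(k, 0.005, 0.03))
      w <- 1 / p$se_out^2
      iv <- ivw_fixed(p)
      f0 <- stats::lm(beta_out ~ 0 + beta_exp, data = p, weights = w)
      s0 <- summary(f0)
      dev_beta <- max(dev_beta, abs(iv$beta - unname(stats::coef(f0))))
      dev_se <- max(dev_se, abs(iv$se - s0$coef[1, 2] / s0$sigma))

      eg <- mr_egger(p)
      # orient exactly as the estimator does before fitting the oracle
      s <- ifelse(p$beta_exp < 0, -1, 1)
      f1 <- stats::lm(I(s * beta_out) ~ I(s * beta_exp), data = p,
                      weights = w)
      s1 <- summary(f1)
      dev_beta <- max(dev_beta,
                      abs(eg$intercept$beta - unname(stats::coef(f1)[1])),
                      abs(eg$slope$beta - unname(stats::coef(f1)[2])))
      dev_se <- max(dev_se,
                    abs(eg$intercept$se - s1$coef[1, 2]),
                    abs(eg$slope$se - s1$coef[2, 2]))
    }
  })
  list(max_beta_dev = dev_beta, max_se_dev = dev_se, n_sets = n_sets)
}

# Simulate one exposure/outcome pair under a scenario and harmonize it.
simulate_harmonized <- function(scenario) {
  ex <- simulate_exposure_summary(scenario)
  ou <- simulate_outcome_summary(ex)
  harmonize_dataset(select_instruments(ex), ou)
}

#' Parameter-recovery experiment for the fixed-effect IVW estimator
#'
#' Replicates a two-sample design with known causal effect and averages the
#' IVW estimate. The exposure sample is made large so exposure measurement
#' error (and with it regression dilution) is negligible at the Monte-Carlo
#' resolution of the experiment — the check isolates estimator bias.
#'
#' @param n_rep replicates.
#' @param theta true causal effect; default log(0.89).
#' @param k,n_exp,n_out scenario sizes.
#' @param seed master seed.
#' @return list with `mean_est`, `mc_se` (SE of the mean), `z`
#'   (standardized deviation from truth), `theta`, `n_rep`.
#' @export
mr_recovery <- function(n_rep = 200, theta = log(0.89), k = 20,
                        n_exp = 50000, n_out = 200000, seed = 1) {
  seeds <- derive_seeds(seed, n_rep)
  est <- vapply(seq_len(n_rep), function(r) {
    sc <- mr_scenario(k = k, n_exp = n_exp, n_out = n_out, theta = theta,
                      seed = seeds[r])
    ivw_fixed(simulate_harmonized(sc))$beta
  }, numeric(1))
  mc_se <- stats::sd(est) / sqrt(n_rep)
  list(mean_est = mean(est), mc_se = mc_se,
       z = (mean(est) - theta) / mc_se, theta = theta, n_rep = n_rep)
}

#' Type-I error and CI coverage of IVW under the null
#'
#' Replicates the null model (no causal effect, no pleiotropy) and records
#' the two-sided rejection rate at alpha = 0.05 and the 95% CI coverage of
#' zero.
#'
#' @param n_rep replicates.
#' @param k instruments per replicate.
#' @param seed master seed.
#' @return list with `rejection_rate`, `coverage`, `n_rep`.
#' @export
mr_calibration <- function(n_rep = 500, k = 20, seed = 1) {
  seeds <- derive_seeds(seed, n_rep)
  reject <- cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sc <- mr_scenario(k = k, theta = 0, seed = seeds[r])
    iv <- ivw_fixed(simulate_harmonized(sc))
    reject[r] <- iv$pvalue < 0.05
    cover[r] <- iv$ci_low <= 0 && 0 <= iv$ci_high
  }
  list(rejection_rate = mean(reject), coverage = mean(cover), n_rep = n_rep)
}

#' Robustness to invalid instruments with directional pleiotropy
#'
#' Replicates a scenario in which a fraction of instruments carries a
#' directional pleiotropic effect, then compares the weighted median's
#' absolute bias against IVW's, and checks whether the Egger intercept's 95%
#' CI covers the population mean pleiotropy
#' (`invalid_fraction * pleiotropy_mean`, since valid instruments contribute
#' zero).
#'
#' @param n_rep replicates.
#' @param k instruments per replicate.
#' @param theta true causal effect.
#' @param invalid_fraction fraction of pleiotropic instruments.
#' @param pleiotropy_mean,pleiotropy_sd pleiotropic-effect distribution.
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed master seed.
#' @return list with `wm_beats_ivw` (fraction of replicates where the
#'   weighted median is closer to truth), `egger_intercept_coverage`,
#'   `mean_ivw_bias`, `mean_wm_bias`, `n_rep`.
#' @export
mr_robustness <- function(n_rep = 200, k = 50, theta = 0.2,
                          invalid_fraction = 0.4, pleiotropy_mean = 0.05,
                          pleiotropy_sd = 0.02, n_boot = 100, seed = 1) {
  seeds <- derive_seeds(seed, n_rep)
  alpha_bar <- invalid_fraction * pleiotropy_mean
  wm_wins <- cover <- logical(n_rep)
  ivw_bias <- wm_bias <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sc <- mr_scenario(k = k, theta = theta,
                      pleiotropy_mode = "directional",
                      pleiotropy_mean = pleiotropy_mean,
                      pleiotropy_sd = pleiotropy_sd,
                      invalid_fraction = invalid_fraction, seed = seeds[r])
    hs <- simulate_harmonized(sc)
    iv <- ivw_fixed(hs)
    wm <- weighted_median(hs, n_boot = n_boot, seed = seeds[r] + 1L)
    eg <- mr_egger(hs)
    ivw_bias[r] <- iv$beta - theta
    wm_bias[r] <- wm$beta - theta
    wm_wins[r] <- abs(wm_bias[r]) < abs(ivw_bias[r])
    cover[r] <- eg$intercept$ci_low <= alpha_bar &&
      alpha_bar <= eg$intercept$ci_high
  }
  list(wm_beats_ivw = mean(wm_wins),
       egger_intercept_coverage = mean(cover),
       mean_ivw_bias = mean(ivw_bias), mean_wm_bias = mean(wm_bias),
       true_pleiotropy_mean = alpha_bar, n_rep = n_rep)
}

#' Monte-Carlo check of the Wald-ratio delta-method SE
#'
#' Draws exposure and outcome effects from their Gaussians and compares the
#' empirical SD of the ratio with the first-order delta approximation.
#'
#' @param beta_exp,se_exp,beta_out,se_out the instrument.
#' @param n_draws Monte-Carlo draws.
#' @param seed master seed.
#' @return list with `delta_se`, `mc_sd`, `ratio` (delta / MC).
#' @export
wald_delta_mc <- function(beta_exp = 0.4, se_exp = 0.02,
                          beta_out = 0.08, se_out = 0.03,
                          n_draws = 1e6, seed = 1) {
  est <- wald_ratio(data.frame(beta_exp = beta_exp, se_exp = se_exp,
                               beta_out = beta_out, se_out = se_out))
  mc_sd <- with_local_seed(seed, {
    stats::sd(stats::rnorm(n_draws, beta_out, se_out) /
                stats::rnorm(n_draws, beta_exp, se_exp))
  })
  list(delta_se = est$se, mc_sd = mc_sd, ratio = est$se / mc_sd)
}

#' The 91-instrument harmonization attrition fixture
#'
#' Builds the panel-sized fixture: 91 instruments of which 14 are
#' palindromic and exactly half of those sit at intermediate allele
#' frequency, so harmonization removes exactly 7 and keeps 84.
#'
#' @param seed scenario seed (any seed reproduces the counts; the draws
#'   differ).
#' @return the `harmonized_set`.
#' @export
attrition_fixture <- function(seed = 42) {
  sc <- mr_scenario(k = 91, palindromic_fraction = 14 / 91,
                    intermediate_af_fraction = 0.5, seed = seed)
  ex <- simulate_exposure_summary(sc)
  harmonize_dataset(ex, simulate_outcome_summary(ex))
}
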