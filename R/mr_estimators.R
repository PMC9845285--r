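# Causal-effect estimator suite: Wald ratio, fixed-effect IVW, MR-Egger,
# weighted median, Cochran's Q / I2, Bonferroni flags.

Z95 <- stats::qnorm(0.975)

# Package a point estimate as an MR estimate with normal-theory CI/p and the
# exponentiated scale (reported as OR for risk outcomes, HR for survival).
new_mr_estimate <- function(method, beta, se, n_snps) {
  structure(
    list(method = method, beta = beta, se = se,
         ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
         pvalue = 2 * stats::pnorm(-abs(beta / se)),
         n_snps = n_snps,
         exp_beta = exp(beta),
         exp_ci_low = exp(beta - Z95 * se),
         exp_ci_high = exp(beta + Z95 * se)),
    class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], exp(beta) = %.3f [%.3f, %.3f], p = %.3g, k = %d\n",
    x$method, x$beta, x$se, x$ci_low, x$ci_high,
    x$exp_beta, x$exp_ci_low, x$exp_ci_high, x$pvalue, x$n_snps))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             or_or_hr = x$exp_beta, ci_low = x$ci_low, ci_high = x$ci_high,
             exp_ci_low = x$exp_ci_low, exp_ci_high = x$exp_ci_high,
             pval = x$pvalue, stringsAsFactors = FALSE)
}

# Resolve the usable pairs from either a harmonized_set or a plain pairs
# data frame (beta_exp, se_exp, beta_out, se_out columns).
usable_pairs <- function(x) {
  if (inherits(x, "harmonized_set")) return(harmonized_pairs(x))
  if (!is.null(x$action)) return(x[x$action != "removed", , drop = FALSE])
  x
}

# First-order delta-method variance of the per-SNP ratio beta_out/beta_exp.
ratio_delta_var <- function(beta_exp, se_exp, beta_out, se_out) {
  se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4
}

#' Wald ratio estimate from a single instrument
#'
#' The single-SNP causal estimate beta_out / beta_exp, with the first-order
#' delta-method standard error
#' \deqn{se = \sqrt{se_{out}^2/\beta_{exp}^2 +
#'   \beta_{out}^2\, se_{exp}^2/\beta_{exp}^4}.}
#'
#' @param pair one-row harmonized pair (or list) with `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @return an `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(pair) {
  pair <- usable_pairs(pair)
  if (is.data.frame(pair) && nrow(pair) != 1) {
    stop("wald_ratio takes exactly one instrument")
  }
  if (pair$beta_exp == 0) stop("null instrument: beta_exp = 0")
  beta <- pair$beta_out / pair$beta_exp
  se <- sqrt(ratio_delta_var(pair$beta_exp, pair$se_exp,
                             pair$beta_out, pair$se_out))
  new_mr_estimate("wald", beta, se, 1L)
}

#' Fixed-effect inverse-variance-weighted estimate
#'
#' The fixed-effect meta-analysis of per-SNP ratios with outcome-variance
#' weights:
#' \deqn{\beta_{IVW} = \frac{\sum_i \beta_{exp,i}\beta_{out,i}\sigma_{out,i}^{-2}}
#'   {\sum_i \beta_{exp,i}^2 \sigma_{out,i}^{-2}}, \qquad
#'   se(\beta_{IVW}) = \frac{1}{\sqrt{\sum_i \beta_{exp,i}^2\sigma_{out,i}^{-2}}}.}
#' Equivalent to weighted least squares of beta_out on beta_exp through the
#' origin with weights 1/se_out^2 (and residual variance fixed at 1). The
#' weights deliberately ignore exposure error; with a single instrument the
#' point estimate reduces to the Wald ratio.
#'
#' @param hset a `harmonized_set` or pairs data frame.
#' @return an `mr_estimate` with method `"ivw_fixed"`.
#' @export
ivw_fixed <- function(hset) {
  p <- usable_pairs(hset)
  if (nrow(p) < 1) stop("no instruments")
  w <- 1 / p$se_out^2
  denom <- sum(p$beta_exp^2 * w)
  beta <- sum(p$beta_exp * p$beta_out * w) / denom
  new_mr_estimate("ivw_fixed", beta, 1 / sqrt(denom), nrow(p))
}

# Closed-form weighted least squares with intercept: returns coefficients,
# their standard errors (residual-variance scaled, as in summary.lm) and the
# residual dispersion sigma.
wls_with_intercept <- function(x, y, w) {
  X <- cbind(intercept = 1, slope = x)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * y)
  coefs <- solve(XtWX, XtWy)
  resid <- y - X %*% coefs
  df <- length(y) - 2L
  sigma2 <- sum(w * resid^2) / df
  se <- sqrt(diag(solve(XtWX)) * sigma2)
  list(coef = drop(coefs), se = se, sigma = sqrt(sigma2), df = df)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept, weights 1/se_out^2. Instruments are first oriented so
#' every exposure effect is non-negative (outcome effect sign-flipped
#' accordingly), which makes the intercept interpretable as directional
#' pleiotropy. Standard errors are scaled by the weighted residual
#' dispersion, so the intercept's uncertainty reflects the pleiotropy
#' scatter; p-values are two-sided normal, consistent with the CI formula.
#'
#' @param hset a `harmonized_set` or pairs data frame with at least 3 usable
#'   pairs.
#' @return list with elements `slope` and `intercept`, each an
#'   `mr_estimate` (methods `"egger_slope"`, `"egger_intercept"`).
#' @export
mr_egger <- function(hset) {
  p <- usable_pairs(hset)
  if (nrow(p) < 3) stop("insufficient instruments for Egger (need >= 3)")
  flip <- sign(p$beta_exp)
  flip[flip == 0] <- 1
  x <- p$beta_exp * flip
  y <- p$beta_out * flip
  fit <- wls_with_intercept(x, y, 1 / p$se_out^2)
  list(
    slope = new_mr_estimate("egger_slope", fit$coef[["slope"]],
                            fit$se[["slope"]], nrow(p)),
    intercept = new_mr_estimate("egger_intercept", fit$coef[["intercept"]],
                                fit$se[["intercept"]], nrow(p)))
}

# Weighted median of values: sort, take the value at normalized cumulative
# weight 0.5 using the percentile convention p_i = (cumsum(w) - w_i/2) / sum(w)
# with linear interpolation between bracketing order statistics.
weighted_median_point <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(v[1])
  if (0.5 >= p[length(p)]) return(v[length(v)])
  stats::approx(p, v, xout = 0.5)$y
}

#' Weighted-median causal estimate
#'
#' The causal estimate at the 50th weighted percentile of the per-SNP Wald
#' ratios, with weights the inverse delta-method ratio variances. Consistent
#' even when up to half the instrument weight is invalid. The standard error
#' comes from a parametric bootstrap: exposure and outcome effects are
#' redrawn from their Gaussians, the weighted median recomputed, and the SE
#' taken as the standard deviation of the bootstrap estimates.
#'
#' @param hset a `harmonized_set` or pairs data frame with >= 3 usable pairs.
#' @param n_boot bootstrap replicates (>= 100; default 1000).
#' @param seed mandatory integer seed for the bootstrap.
#' @return an `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(hset, n_boot = 1000, seed) {
  if (missing(seed)) stop("weighted_median requires an explicit seed")
  p <- usable_pairs(hset)
  k <- nrow(p)
  if (k < 3) stop("insufficient instruments for weighted median (need >= 3)")
  stopifnot(n_boot >= 100)
  ratios <- p$beta_out / p$beta_exp
  w <- 1 / ratio_delta_var(p$beta_exp, p$se_exp, p$beta_out, p$se_out)
  beta <- weighted_median_point(ratios, w)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bx <- stats::rnorm(k, p$beta_exp, p$se_exp)
    by <- stats::rnorm(k, p$beta_out, p$se_out)
    rb <- by / bx
    wb <- 1 / ratio_delta_var(bx, p$se_exp, by, p$se_out)
    boot[b] <- weighted_median_point(rb, wb)
  }
  new_mr_estimate("weighted_median", beta, stats::sd(boot), k)
}

#' Cochran's Q and I-squared heterogeneity across instruments
#'
#' \deqn{Q = \sum_i w_i (r_i - \beta)^2} over per-SNP ratios r_i with
#' inverse delta-method-variance weights; df = k - 1;
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100} (floored at zero).
#'
#' @param hset a `harmonized_set` or pairs data frame with >= 2 usable pairs.
#' @param overall_beta the pooled estimate (normally from [ivw_fixed()]).
#' @return list with `q`, `df`, `i2` (percentage), and `q_pvalue` (chi-squared
#'   reference, reported only — never a filter).
#' @export
cochran_q_i2 <- function(hset, overall_beta) {
  p <- usable_pairs(hset)
  k <- nrow(p)
  if (k < 2) stop("heterogeneity requires >= 2 instruments")
  ratios <- p$beta_out / p$beta_exp
  w <- 1 / ratio_delta_var(p$beta_exp, p$se_exp, p$beta_out, p$se_out)
  q <- sum(w * (ratios - overall_beta)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  list(q = q, df = df, i2 = i2,
       q_pvalue = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Bonferroni correction flags across an exposure panel
#'
#' @param pvalues numeric vector of per-test p-values.
#' @param m number of tests in the family; default 30, the size of the
#'   chemokine panel.
#' @return list with `flag` (TRUE iff p < 0.05/m, strict) and `p_adjusted`
#'   (min(1, p * m)).
#' @export
bonferroni_flag <- function(pvalues, m = 30) {
  stopifnot(m >= 1)
  list(flag = pvalues < 0.05 / m,
       p_adjusted = pmin(1, pvalues * m))
}
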