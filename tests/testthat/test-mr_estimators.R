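test_that("the Wald ratio and its delta-method SE follow the closed form", {
  est <- wald_ratio(make_pairs(0.5, 0.1, se_exp = 0.02, se_out = 0.01))
  expect_equal(est$beta, 0.2)
  expect_equal(est$method, "wald")
  expect_equal(est$ci_low, est$beta - qnorm(0.975) * est$se)
  expect_equal(est$exp_beta, exp(0.2))

  # with no exposure error the delta SE collapses to se_out / |beta_exp|
  est0 <- wald_ratio(make_pairs(0.5, 0.1, se_exp = 0, se_out = 0.05))
  expect_equal(est0$se, 0.1)

  expect_error(wald_ratio(make_pairs(0, 0.1)), "null instrument")
})

test_that("the delta-method SE agrees with a Monte-Carlo ratio SD within 2%", {
  pair <- make_pairs(0.4, 0.08, se_exp = 0.02, se_out = 0.03)
  est <- wald_ratio(pair)
  set.seed(4242)
  n <- 1e6
  mc <- rnorm(n, 0.08, 0.03) / rnorm(n, 0.4, 0.02)
  expect_equal(est$se, sd(mc), tolerance = 0.02)
})

test_that("fixed-effect IVW reduces to the Wald ratio at k = 1 and to consensus on equal ratios", {
  pair <- make_pairs(0.5, 0.1, se_exp = 0.02, se_out = 0.01)
  expect_equal(ivw_fixed(pair)$beta, wald_ratio(pair)$beta, tolerance = 1e-12)
  # the fixed-effect SE uses outcome error only: se_out / |beta_exp|
  expect_equal(ivw_fixed(pair)$se, 0.01 / 0.5, tolerance = 1e-12)

  two <- make_pairs(c(0.5, 0.2), c(0.1, 0.04), se_out = c(0.01, 0.03))
  expect_equal(ivw_fixed(two)$beta, 0.2, tolerance = 1e-12)

  expect_error(ivw_fixed(make_pairs(numeric(0), numeric(0))),
               "no instruments")
})

test_that("IVW equals origin-constrained WLS and Egger equals intercept WLS", {
  set.seed(21)
  for (i in 1:20) {
    p <- random_pairs(sample(3:30, 1))
    w <- 1 / p$se_out^2

    iv <- ivw_fixed(p)
    fit0 <- lm(beta_out ~ 0 + beta_exp, data = p, weights = w)
    expect_equal(iv$beta, unname(coef(fit0)), tolerance = 1e-10)
    # fixed-effect SE = WLS SE with the residual dispersion divided out
    expect_equal(iv$se, summary(fit0)$coef[1, 2] / summary(fit0)$sigma,
                 tolerance = 1e-10)

    eg <- mr_egger(p)
    # orientation (beta_exp >= 0) is part of the estimator's definition;
    # the oracle regression sees the identically oriented data
    s <- ifelse(p$beta_exp < 0, -1, 1)
    fit1 <- lm(I(s * beta_out) ~ I(s * beta_exp), weights = w, data = p)
    expect_equal(eg$intercept$beta, unname(coef(fit1)[1]), tolerance = 1e-10)
    expect_equal(eg$slope$beta, unname(coef(fit1)[2]), tolerance = 1e-10)
    expect_equal(eg$slope$se, summary(fit1)$coef[2, 2], tolerance = 1e-10)
    expect_equal(eg$intercept$se, summary(fit1)$coef[1, 2], tolerance = 1e-10)
  }
})

test_that("Egger recovers exact lines and demands three instruments", {
  x <- c(0.2, 0.3, 0.5, 0.7)
  on_origin <- make_pairs(x, 0.3 * x)
  eg <- mr_egger(on_origin)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-12)
  expect_equal(eg$intercept$beta, 0, tolerance = 1e-12)

  affine <- make_pairs(x, 0.1 + 0.3 * x)
  eg2 <- mr_egger(affine)
  expect_equal(eg2$slope$beta, 0.3, tolerance = 1e-12)
  expect_equal(eg2$intercept$beta, 0.1, tolerance = 1e-12)

  # orientation: sign-flipping an instrument's coding must not move the fit
  flipped <- affine
  flipped$beta_exp[2] <- -flipped$beta_exp[2]
  flipped$beta_out[2] <- -flipped$beta_out[2]
  eg3 <- mr_egger(flipped)
  expect_equal(eg3$slope$beta, eg2$slope$beta, tolerance = 1e-12)
  expect_equal(eg3$intercept$beta, eg2$intercept$beta, tolerance = 1e-12)

  expect_error(mr_egger(make_pairs(c(0.2, 0.3), c(0.1, 0.2))),
               "insufficient")
})

test_that("Egger detects directional pleiotropy that biases IVW", {
  sc <- mr_scenario(k = 50, pleiotropy_mode = "directional",
                    pleiotropy_mean = 0.05, pleiotropy_sd = 0.02,
                    invalid_fraction = 1, theta = 0.2, seed = 314)
  ex <- simulate_exposure_summary(sc)
  ou <- simulate_outcome_summary(ex)
  hs <- harmonize_dataset(ex, ou)

  eg <- mr_egger(hs)
  expect_lt(abs(eg$intercept$beta - 0.05), 2 * eg$intercept$se)

  iv <- ivw_fixed(hs)
  expect_gt(iv$beta - 0.2, 4 * iv$se)   # IVW clearly biased upward
})

test_that("the weighted median follows the declared cumulative-weight interpolation rule", {
  # degenerate: all ratios equal
  eq <- make_pairs(c(0.2, 0.4, 0.8), c(0.2, 0.4, 0.8) * 0.3)
  expect_equal(weighted_median(eq, n_boot = 100, seed = 1)$beta, 0.3,
               tolerance = 1e-12)

  # three sorted ratios {0.1, 0.2, 0.4} with normalized weights
  # {0.2, 0.3, 0.5}: brute-force evaluation of p_i = cumsum(w) - w/2 puts the
  # 0.5 quantile between the 2nd and 3rd order statistics at 0.275
  v <- c(0.1, 0.2, 0.4); w <- c(0.2, 0.3, 0.5)
  p <- cumsum(w) - w / 2
  j <- max(which(p < 0.5))
  brute <- v[j] + (0.5 - p[j]) / (p[j + 1] - p[j]) * (v[j + 1] - v[j])
  expect_equal(brute, 0.275)
  # construct pairs whose ratios and delta-method weights reproduce v, w:
  # se_exp = 0, beta_exp = 1 makes ratio = beta_out, var = se_out^2
  pr <- make_pairs(c(1, 1, 1), v, se_exp = 0, se_out = 1 / sqrt(w))
  expect_equal(weighted_median(pr, n_boot = 100, seed = 1)$beta, brute,
               tolerance = 1e-12)

  expect_error(weighted_median(eq[1:2, ], n_boot = 100, seed = 1),
               "insufficient")
  expect_error(weighted_median(eq, n_boot = 100), "seed")
})

test_that("the weighted median stays within the ratio range and its bootstrap is seed-stable", {
  set.seed(77)
  for (i in 1:10) {
    p <- random_pairs(sample(3:15, 1))
    est <- weighted_median(p, n_boot = 100, seed = i)
    ratios <- p$beta_out / p$beta_exp
    expect_gte(est$beta, min(ratios))
    expect_lte(est$beta, max(ratios))
    est2 <- weighted_median(p, n_boot = 100, seed = i)
    expect_identical(est$se, est2$se)
  }
})

test_that("Cochran's Q and I2 follow their definitions, flooring at zero", {
  eq <- make_pairs(c(0.2, 0.4, 0.8), c(0.2, 0.4, 0.8) * 0.3, se_exp = 0)
  het <- cochran_q_i2(eq, 0.3)
  expect_equal(het$q, 0)
  expect_equal(het$i2, 0)

  set.seed(5)
  p <- random_pairs(6)
  b <- ivw_fixed(p)$beta
  het <- cochran_q_i2(p, b)
  ratios <- p$beta_out / p$beta_exp
  w <- 1 / (p$se_out^2 / p$beta_exp^2 + p$beta_out^2 * p$se_exp^2 / p$beta_exp^4)
  expect_equal(het$q, sum(w * (ratios - b)^2), tolerance = 1e-12)
  expect_equal(het$df, 5)
  expect_equal(het$i2, max(0, (het$q - het$df) / het$q) * 100)
  if (het$q > het$df) expect_gt(het$i2, 0)

  # near-identical ratios with huge SEs: Q < df must floor I2 at 0
  quiet <- make_pairs(c(1, 1, 1, 1), c(0.30, 0.31, 0.29, 0.30),
                      se_exp = 0, se_out = 5)
  expect_equal(cochran_q_i2(quiet, 0.3)$i2, 0)

  expect_error(cochran_q_i2(eq[1, ], 0.3), ">= 2")
})

test_that("Bonferroni flags use a strict threshold and cap adjusted p at 1", {
  bf <- bonferroni_flag(0.05 / 30, m = 30)
  expect_false(bf$flag)
  bf2 <- bonferroni_flag(1e-6, m = 30)
  expect_true(bf2$flag)
  expect_equal(bf2$p_adjusted, 3e-5)
  bf3 <- bonferroni_flag(rep(1, 4), m = 30)
  expect_false(any(bf3$flag))
  expect_equal(bf3$p_adjusted, rep(1, 4))
})

test_that("IVW is scale-equivariant and all estimators ignore instrument order", {
  set.seed(9)
  p <- random_pairs(12)
  base <- ivw_fixed(p)$beta

  out_scaled <- transform(p, beta_out = 3 * beta_out, se_out = 3 * se_out)
  expect_equal(ivw_fixed(out_scaled)$beta, 3 * base, tolerance = 1e-12)
  exp_scaled <- transform(p, beta_exp = 2 * beta_exp, se_exp = 2 * se_exp)
  expect_equal(ivw_fixed(exp_scaled)$beta, base / 2, tolerance = 1e-12)

  perm <- p[sample(nrow(p)), ]
  expect_equal(ivw_fixed(perm)$beta, base, tolerance = 1e-12)
  expect_equal(mr_egger(perm)$slope$beta, mr_egger(p)$slope$beta,
               tolerance = 1e-12)
  expect_equal(weighted_median(perm, n_boot = 100, seed = 3)$beta,
               weighted_median(p, n_boot = 100, seed = 3)$beta,
               tolerance = 1e-12)
})
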