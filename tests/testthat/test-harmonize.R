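test_that("palindrome detection and the intermediate-frequency window follow their definitions", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))

  expect_true(has_intermediate_af(0.50))
  expect_false(has_intermediate_af(0.10))
  expect_false(has_intermediate_af(0.42))   # open interval
  expect_false(has_intermediate_af(0.58))
  expect_true(has_intermediate_af(0.30, window = c(0.25, 0.75)))
})

test_that("harmonize_pair aligns, flips, rescues or removes as the allele geometry dictates", {
  ex <- make_records(1, effect_allele = "A", other_allele = "G",
                     eaf = 0.3, beta = 0.1)
  mk_out <- function(ea, oa, eaf = 0.3, beta = 0.05) {
    make_records(1, effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta)
  }

  kept <- harmonize_pair(ex, mk_out("A", "G"))
  expect_equal(kept$action, "kept")
  expect_equal(kept$beta_out, 0.05)

  flip <- harmonize_pair(ex, mk_out("G", "A", eaf = 0.7))
  expect_equal(flip$action, "flipped")
  expect_equal(flip$beta_out, -0.05)
  expect_equal(flip$eaf_out, 0.3)

  # strand-complement rescue: T/C is A/G on the other strand
  comp <- harmonize_pair(ex, mk_out("T", "C"))
  expect_equal(comp$action, "kept")
  comp_sw <- harmonize_pair(ex, mk_out("C", "T", eaf = 0.7))
  expect_equal(comp_sw$action, "flipped")
  norescue <- harmonize_pair(ex, mk_out("T", "C"), allow_strand_flip = FALSE)
  expect_equal(norescue$action, "removed")
  expect_equal(norescue$reason, "allele mismatch")

  mism <- harmonize_pair(ex, mk_out("A", "C"))
  expect_equal(mism$action, "removed")
  expect_equal(mism$reason, "allele mismatch")

  expect_error(
    harmonize_pair(ex, transform(mk_out("A", "G"), snp = "rs999")),
    "mismatch")
})

test_that("palindromic pairs are removed at intermediate AF (in either study) and frequency-aligned otherwise", {
  pal <- function(eaf_exp, eaf_out, beta_out = 0.05) {
    ex <- make_records(1, effect_allele = "A", other_allele = "T",
                       eaf = eaf_exp, beta = 0.1)
    ou <- make_records(1, effect_allele = "A", other_allele = "T",
                       eaf = eaf_out, beta = beta_out)
    harmonize_pair(ex, ou)
  }
  rm1 <- pal(0.50, 0.49)
  expect_equal(rm1$action, "removed")
  expect_equal(rm1$reason, "palindromic intermediate AF")
  expect_equal(pal(0.30, 0.45)$action, "removed")   # intermediate in outcome only

  same_side <- pal(0.30, 0.28)
  expect_equal(same_side$action, "kept")
  expect_equal(same_side$beta_out, 0.05)

  opp_side <- pal(0.30, 0.72)
  expect_equal(opp_side$action, "flipped")
  expect_equal(opp_side$beta_out, -0.05)
  expect_equal(opp_side$eaf_out, 0.28)

  # palindromic exposure vs non-palindromic outcome alleles: irreconcilable
  ex <- make_records(1, effect_allele = "A", other_allele = "T", eaf = 0.3)
  ou <- make_records(1, effect_allele = "C", other_allele = "G", eaf = 0.3)
  expect_equal(harmonize_pair(ex, ou)$action, "removed")
})

test_that("the 91-instrument fixture reproduces the 7-removal attrition to 84", {
  sc <- mr_scenario(k = 91, palindromic_fraction = 14 / 91,
                    intermediate_af_fraction = 0.5, seed = 42)
  ex <- simulate_exposure_summary(sc)
  ou <- simulate_outcome_summary(ex)
  hs <- harmonize_dataset(ex, ou)

  expect_equal(hs$n_input, 91)
  expect_equal(hs$n_final, 84)
  expect_equal(hs$n_removed, 7)
  removed <- hs$pairs[hs$pairs$action == "removed", ]
  expect_equal(nrow(removed), 7)
  expect_true(all(removed$reason == "palindromic intermediate AF"))

  log_path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonization_log(hs, log_path)
  log <- read.delim(log_path)
  expect_equal(sum(log$action == "removed"), 7)
  flipped <- log[log$action == "flipped", ]
  expect_equal(flipped$beta_out_after, -flipped$beta_out_before)
})

test_that("instruments missing from the outcome are removed with that reason; pre-matched sets lose nothing", {
  ex <- make_records(10, snp = sprintf("rs%03d", 1:10))
  ou <- ex[1:8, ]
  hs <- harmonize_dataset(ex, ou)
  expect_equal(hs$n_removed, 2)
  expect_true(all(hs$pairs$reason[9:10] == "missing in outcome"))
  expect_equal(hs$n_input, hs$n_final + hs$n_removed)

  hs2 <- harmonize_dataset(ex, ex)
  expect_equal(hs2$n_removed, 0)
  expect_true(all(hs2$pairs$action == "kept"))
})

test_that("harmonization counts always balance and re-harmonizing its own output is the identity", {
  for (seed in 1:8) {
    sc <- mr_scenario(k = 30, palindromic_fraction = 0.3,
                      intermediate_af_fraction = 0.4, seed = seed)
    ex <- simulate_exposure_summary(sc)
    ou <- simulate_outcome_summary(ex)
    # perturb some outcome codings so flips actually occur
    set.seed(seed)
    swap <- sample(30, 10)
    ou[swap, ] <- recode_alleles(ou[swap, ])
    hs <- harmonize_dataset(ex, ou)
    expect_equal(hs$n_input, hs$n_final + hs$n_removed)

    pairs <- harmonized_pairs(hs)
    hs2 <- harmonize_dataset(records_from_pairs(pairs, "exp"),
                             records_from_pairs(pairs, "out"))
    expect_equal(hs2$n_removed, 0)
    expect_true(all(hs2$pairs$action == "kept"))
    expect_equal(hs2$pairs$beta_out, pairs$beta_out, tolerance = 1e-15)
  }
})

test_that("MR estimates are invariant to allele recoding of either input", {
  sc <- mr_scenario(k = 25, palindromic_fraction = 0.2,
                    intermediate_af_fraction = 0, seed = 7)
  ex <- simulate_exposure_summary(sc)
  ou <- simulate_outcome_summary(ex)
  base <- harmonize_dataset(ex, ou)
  ref_ivw <- ivw_fixed(base)
  ref_egger <- mr_egger(base)
  ref_wm <- weighted_median(base, n_boot = 200, seed = 99)

  set.seed(7)
  for (side in c("outcome", "exposure", "both")) {
    ex2 <- ex; ou2 <- ou
    if (side %in% c("outcome", "both")) {
      i <- sample(25, 12); ou2[i, ] <- recode_alleles(ou2[i, ])
    }
    if (side %in% c("exposure", "both")) {
      i <- sample(25, 12); ex2[i, ] <- recode_alleles(ex2[i, ])
    }
    hs <- harmonize_dataset(ex2, ou2)
    expect_equal(hs$n_final, base$n_final)
    expect_equal(ivw_fixed(hs)$beta, ref_ivw$beta, tolerance = 1e-12)
    expect_equal(ivw_fixed(hs)$se, ref_ivw$se, tolerance = 1e-12)
    eg <- mr_egger(hs)
    expect_equal(eg$slope$beta, ref_egger$slope$beta, tolerance = 1e-12)
    expect_equal(eg$intercept$beta, ref_egger$intercept$beta,
                 tolerance = 1e-12)
    expect_equal(weighted_median(hs, n_boot = 200, seed = 99)$beta,
                 ref_wm$beta, tolerance = 1e-12)
  }
})
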