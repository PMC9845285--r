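# Builders for small summary-statistics fixtures used across the suite.

make_records <- function(n = 3, snp = sprintf("rs%03d", seq_len(n)),
                         effect_allele = rep("A", n),
                         other_allele = rep("G", n),
                         eaf = rep(0.3, n), beta = rep(0.1, n),
                         se = rep(0.01, n), pval = rep(1e-9, n),
                         N = rep(10000, n)) {
  data.frame(snp = snp, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta, se = se,
             pval = pval, n = N, stringsAsFactors = FALSE)
}

make_pairs <- function(beta_exp, beta_out, se_exp = 0.02, se_out = 0.01) {
  k <- length(beta_exp)
  data.frame(snp = sprintf("rs%03d", seq_len(k)),
             beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
             beta_out = beta_out, se_out = rep_len(se_out, k),
             stringsAsFactors = FALSE)
}

random_pairs <- function(k) {
  make_pairs(beta_exp = rnorm(k, 0.3, 0.1),
             beta_out = rnorm(k, 0.05, 0.03),
             se_exp = runif(k, 0.01, 0.05),
             se_out = runif(k, 0.005, 0.03))
}

# Rebuild exposure/outcome record frames from a harmonized set's usable
# pairs, for idempotence checks.
records_from_pairs <- function(pairs, side = c("exp", "out")) {
  side <- match.arg(side)
  if (side == "exp") {
    data.frame(snp = pairs$snp, effect_allele = pairs$effect_allele,
               other_allele = pairs$other_allele, eaf = pairs$eaf_exp,
               beta = pairs$beta_exp, se = pairs$se_exp,
               pval = 1e-9, n = 10000, stringsAsFactors = FALSE)
  } else {
    data.frame(snp = pairs$snp, effect_allele = pairs$effect_allele,
               other_allele = pairs$other_allele, eaf = pairs$eaf_out,
               beta = pairs$beta_out, se = pairs$se_out,
               pval = 0.5, n = pairs$n_out, stringsAsFactors = FALSE)
  }
}

# Swap every record's allele coding: effect <-> other, beta negated,
# frequency complemented. Estimates must be invariant to this relabeling.
recode_alleles <- function(records) {
  transform(records,
            effect_allele = other_allele, other_allele = effect_allele,
            beta = -beta, eaf = 1 - eaf)
}
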