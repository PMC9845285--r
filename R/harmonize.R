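# Allele harmonization: express exposure and outcome effects on the same
# effect allele before any estimator touches them.

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so strand cannot be
#' resolved from allele labels alone.
#'
#' @param effect_allele,other_allele single bases (vectorized).
#' @return logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  unname(DNA_COMPLEMENT[effect_allele] == other_allele)
}

#' Is an effect-allele frequency "intermediate"?
#'
#' Palindromic SNPs can only be aligned by allele frequency, which fails when
#' the frequency is too close to 0.5. The default open window (0.42, 0.58) is
#' the conventional two-sample-MR choice.
#'
#' @param eaf effect-allele frequency (vectorized).
#' @param window length-2 numeric `(lo, hi)`, open interval.
#' @return logical vector.
#' @export
has_intermediate_af <- function(eaf, window = c(0.42, 0.58)) {
  stopifnot(length(window) == 2, window[1] > 0, window[2] < 1,
            window[1] < window[2])
  eaf > window[1] & eaf < window[2]
}

# Harmonize a single exposure/outcome record pair. Returns a one-row data
# frame carrying the aligned triplet plus the audit fields.
#' Harmonize one exposure/outcome pair of records
#'
#' Aligns the outcome effect onto the exposure's effect allele:
#' exact allele match is kept as-is; swapped alleles flip the outcome beta
#' and complement its frequency; non-palindromic mismatches may be rescued by
#' strand complement (then matched or flipped); palindromic SNPs with an
#' intermediate frequency in either study are removed (strand is
#' unresolvable), and palindromic SNPs with informative frequencies are
#' aligned by frequency agreement (same side of 0.5 means same allele).
#'
#' @param exp_rec,out_rec one-row summary-statistics data frames for the same
#'   variant.
#' @param af_window intermediate-frequency window for palindromic removal.
#' @param allow_strand_flip rescue non-palindromic allele mismatches by
#'   complementing the outcome alleles (default TRUE). Palindromic pairs are
#'   never complement-rescued (uninterpretable).
#' @return one-row data frame: `snp, effect_allele, other_allele, eaf_exp,
#'   eaf_out, beta_exp, se_exp, beta_out, se_out, n_out, action, reason`
#'   where `action` is one of kept/flipped/removed.
#' @export
harmonize_pair <- function(exp_rec, out_rec, af_window = c(0.42, 0.58),
                           allow_strand_flip = TRUE) {
  if (exp_rec$snp != out_rec$snp) {
    stop("variant id mismatch: ", exp_rec$snp, " vs ", out_rec$snp)
  }
  ea_e <- exp_rec$effect_allele; oa_e <- exp_rec$other_allele
  ea_o <- out_rec$effect_allele; oa_o <- out_rec$other_allele
  palin <- is_palindromic(ea_e, oa_e)

  result <- function(action, reason = "", flip = FALSE) {
    beta_out <- if (flip) -out_rec$beta else out_rec$beta
    eaf_out <- if (flip) 1 - out_rec$eaf else out_rec$eaf
    data.frame(snp = exp_rec$snp,
               effect_allele = ea_e, other_allele = oa_e,
               eaf_exp = exp_rec$eaf, eaf_out = eaf_out,
               beta_exp = exp_rec$beta, se_exp = exp_rec$se,
               beta_out = beta_out, se_out = out_rec$se,
               n_out = out_rec$n,
               action = action, reason = reason,
               stringsAsFactors = FALSE)
  }

  if (palin) {
    same_set <- (ea_o == ea_e && oa_o == oa_e) || (ea_o == oa_e && oa_o == ea_e)
    if (!same_set) return(result("removed", "allele mismatch"))
    if (has_intermediate_af(exp_rec$eaf, af_window) ||
        has_intermediate_af(out_rec$eaf, af_window)) {
      return(result("removed", "palindromic intermediate AF"))
    }
    # Frequencies are informative: the outcome's effect allele is the
    # exposure's effect allele iff the frequencies sit on the same side of 0.5.
    same_side <- (exp_rec$eaf < 0.5) == (out_rec$eaf < 0.5)
    if (same_side) return(result("kept")) else return(result("flipped",
                                                             flip = TRUE))
  }

  if (ea_o == ea_e && oa_o == oa_e) return(result("kept"))
  if (ea_o == oa_e && oa_o == ea_e) return(result("flipped", flip = TRUE))
  if (allow_strand_flip) {
    ea_oc <- unname(DNA_COMPLEMENT[ea_o]); oa_oc <- unname(DNA_COMPLEMENT[oa_o])
    if (ea_oc == ea_e && oa_oc == oa_e) return(result("kept"))
    if (ea_oc == oa_e && oa_oc == ea_e) return(result("flipped", flip = TRUE))
  }
  result("removed", "allele mismatch")
}

#' Harmonize an instrument set against outcome summary statistics
#'
#' Applies [harmonize_pair()] to every instrument; instruments absent from
#' the outcome file are removed with reason "missing in outcome". The full
#' audit trail (every action and removal reason) is retained in the returned
#' object, so no instrument is silently dropped.
#'
#' @param instruments an `instrument_set` or a summary-statistics data frame
#'   of selected instruments.
#' @param outcome_records outcome summary statistics (indexed by `snp`).
#' @param af_window,allow_strand_flip see [harmonize_pair()].
#' @param exposure_name,outcome_name labels for reporting.
#' @return A `harmonized_set`: list with `exposure_name`, `outcome_name`,
#'   `pairs` (the per-variant audit data frame), and counts `n_input`,
#'   `n_removed`, `n_final`.
#' @export
harmonize_dataset <- function(instruments, outcome_records,
                              af_window = c(0.42, 0.58),
                              allow_strand_flip = TRUE,
                              exposure_name = NULL, outcome_name = "outcome") {
  if (inherits(instruments, "instrument_set")) {
    if (is.null(exposure_name)) exposure_name <- instruments$exposure_name
    records <- instruments$records
  } else {
    if (is.null(exposure_name)) exposure_name <- "exposure"
    records <- instruments
  }
  out_idx <- match(records$snp, outcome_records$snp)
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    exp_rec <- records[i, ]
    if (is.na(out_idx[i])) {
      rows[[i]] <- data.frame(
        snp = exp_rec$snp, effect_allele = exp_rec$effect_allele,
        other_allele = exp_rec$other_allele,
        eaf_exp = exp_rec$eaf, eaf_out = NA_real_,
        beta_exp = exp_rec$beta, se_exp = exp_rec$se,
        beta_out = NA_real_, se_out = NA_real_, n_out = NA_real_,
        action = "removed", reason = "missing in outcome",
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- harmonize_pair(exp_rec, outcome_records[out_idx[i], ],
                                  af_window = af_window,
                                  allow_strand_flip = allow_strand_flip)
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  structure(
    list(exposure_name = exposure_name, outcome_name = outcome_name,
         pairs = pairs,
         n_input = nrow(pairs),
         n_removed = sum(pairs$action == "removed"),
         n_final = sum(pairs$action != "removed")),
    class = "harmonized_set")
}

#' Usable (non-removed) pairs of a harmonized set
#' @param hset a `harmonized_set`.
#' @return data frame of pairs with `action != "removed"`.
#' @export
harmonized_pairs <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  out <- hset$pairs[hset$pairs$action != "removed", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the harmonization audit log
#'
#' Tab-delimited `variant_id  action  reason  beta_out_before
#' beta_out_after` (before/after differ only for flipped records).
#'
#' @param hset a `harmonized_set`.
#' @param path output file path.
#' @export
write_harmonization_log <- function(hset, path) {
  p <- hset$pairs
  before <- ifelse(p$action == "flipped", -p$beta_out, p$beta_out)
  log <- data.frame(variant_id = p$snp, action = p$action, reason = p$reason,
                    beta_out_before = before, beta_out_after = p$beta_out)
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(log)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set %s -> %s: %d input, %d removed, %d final\n",
              x$exposure_name, x$outcome_name,
              x$n_input, x$n_removed, x$n_final))
  invisible(x)
}
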