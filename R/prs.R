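# Weighted polygenic risk scores from per-individual allele dosages,
# and tertile categorization.

#' Construct a PRS weight profile
#'
#' A profile is the list of (variant, effect allele, per-allele weight)
#' triplets entering the score PRS = sum_k beta_k x_k. The weight source is
#' an explicit choice of the analyst: for a chemokine PRS the natural weights
#' are the pQTL effects of the instruments on the chemokine, but
#' disease-association log-odds weights are equally accepted — the profile
#' does not care where its betas come from.
#'
#' @param snp character vector of variant ids (must be unique).
#' @param effect_allele counted allele per variant.
#' @param weight finite per-allele weight per variant.
#' @param name profile label.
#' @return a `prs_profile` data frame with attributes `name`.
#' @export
prs_profile <- function(snp, effect_allele, weight, name = "PRS") {
  stopifnot(length(snp) == length(effect_allele),
            length(snp) == length(weight))
  if (anyDuplicated(snp)) stop("duplicate variant ids in PRS profile")
  if (!all(is.finite(weight))) stop("non-finite PRS weight")
  out <- data.frame(snp = as.character(snp),
                    effect_allele = toupper(as.character(effect_allele)),
                    weight = as.numeric(weight),
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("prs_profile", "data.frame")
  out
}

#' Read a PRS weights file
#'
#' Tab-delimited with header `snp  effect_allele  weight`.
#'
#' @param path file path.
#' @param name profile label.
#' @return a `prs_profile`.
#' @export
read_prs_weights <- function(path, name = "PRS") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "effect_allele", "weight")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("weights file lacks column(s): ",
                            paste(missing, collapse = ", "))
  prs_profile(df$snp, df$effect_allele, df$weight, name = name)
}

#' Read a dosage matrix
#'
#' Tab-delimited; first column is the individual id, remaining columns are
#' named `variantID_countedAllele` with dosages in [0, 2].
#'
#' @param path file path.
#' @return numeric matrix (individuals x variants) with rownames the
#'   individual ids, colnames the variant ids, and a `counted_allele`
#'   attribute (named character vector per variant).
#' @export
read_dosage_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[-1])
  header <- colnames(mat)
  parts <- regmatches(header, regexpr("_[ACGT]$", header))
  if (length(parts) != length(header)) {
    stop("dosage column names must look like variantID_countedAllele")
  }
  counted <- substring(parts, 2)
  snps <- substring(header, 1, nchar(header) - 2)
  dimnames(mat) <- list(ids, snps)
  attr(mat, "counted_allele") <- stats::setNames(counted, snps)
  mat
}

#' Compute weighted polygenic risk scores
#'
#' Per individual, PRS = sum_k beta_k x_k over the profile's variants, with
#' x_k the dosage of the profile's effect allele. Dosage columns counted on
#' the opposite allele are reconciled as 2 - x (a counted allele equal to the
#' effect allele or its strand complement is taken as already aligned).
#' Profile variants absent from the matrix are skipped and reported in the
#' `skipped` attribute.
#'
#' @param profile a `prs_profile`.
#' @param dosages numeric matrix (individuals x variants, colnames = variant
#'   ids, dosages in [0,2]) with a `counted_allele` attribute, e.g. from
#'   [read_dosage_matrix()]; if the attribute is missing the counted alleles
#'   are assumed to be the profile's effect alleles.
#' @return named numeric vector of scores (one per individual) with a
#'   `skipped` attribute listing profile variants not in the matrix.
#' @export
compute_prs <- function(profile, dosages) {
  stopifnot(inherits(profile, "prs_profile"), is.matrix(dosages))
  present <- profile$snp %in% colnames(dosages)
  skipped <- profile$snp[!present]
  prof <- profile[present, , drop = FALSE]
  if (nrow(prof) == 0) stop("no overlap between profile and dosage matrix")
  x <- dosages[, prof$snp, drop = FALSE]
  counted <- attr(dosages, "counted_allele")
  if (!is.null(counted)) {
    counted <- counted[prof$snp]
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    aligned <- counted == prof$effect_allele |
      unname(comp[counted]) == prof$effect_allele
    if (any(!aligned)) {
      x[, !aligned] <- 2 - x[, !aligned, drop = FALSE]
    }
  }
  scores <- drop(x %*% prof$weight)
  names(scores) <- rownames(dosages)
  attr(scores, "skipped") <- skipped
  scores
}

#' Categorize scores into tertiles
#'
#' Cut points are the empirical 1/3 and 2/3 quantiles of the scores. Ties at
#' a boundary all go to the lower tertile (assignment is by `<=` against the
#' cut points), keeping the rule deterministic.
#'
#' @param scores numeric vector (>= 3 individuals).
#' @return factor with levels T1, T2, T3 (named like `scores`).
#' @export
assign_tertiles <- function(scores) {
  if (length(scores) < 3) stop("tertiles require >= 3 individuals")
  if (length(unique(scores)) == 1) {
    warning("all scores identical; every individual assigned T1")
    return(stats::setNames(factor(rep("T1", length(scores)),
                                  levels = c("T1", "T2", "T3")),
                           names(scores)))
  }
  cuts <- stats::quantile(scores, c(1 / 3, 2 / 3), names = FALSE)
  lab <- ifelse(scores <= cuts[1], "T1", ifelse(scores <= cuts[2], "T2", "T3"))
  stats::setNames(factor(lab, levels = c("T1", "T2", "T3")), names(scores))
}

#' Score a cohort and write the analysis-ready PRS table
#'
#' @param profile a `prs_profile`.
#' @param dosages dosage matrix (see [compute_prs()]).
#' @param path optional output path for the tab-delimited
#'   `individual_id  prs  tertile` table.
#' @return data frame `individual_id`, `prs`, `tertile` (invisibly when
#'   written to `path`).
#' @export
prs_table <- function(profile, dosages, path = NULL) {
  scores <- compute_prs(profile, dosages)
  out <- data.frame(individual_id = names(scores),
                    prs = as.numeric(scores),
                    tertile = as.character(assign_tertiles(scores)),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
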