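#!/usr/bin/env Rscript
# Build the synthetic chemokine panel: six pQTL exposure files (one with a
# CCL5-sized protective effect on the risk outcome, one with a CCL19-sized
# effect on the survival outcome, the rest null), pooled risk and survival
# outcome files, per-exposure LD matrices, and the scan config.
#
# Everything downstream (02_mr_scan.R, 04_prs.R) reads only these files, so
# the whole analysis is reproducible from this one seeded script.

suppressPackageStartupMessages(library(chemomr))

out_dir <- "results/sim_data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
base_seed <- 20260925L

panel <- list(
  # name            k   theta_risk   theta_surv
  CCL5like  = list(k = 12, risk = log(0.89), surv = 0),
  CCL19like = list(k = 9,  risk = 0,         surv = log(0.85)),
  CXCL8like = list(k = 6,  risk = 0,         surv = 0),
  CCL2like  = list(k = 15, risk = 0,         surv = 0),
  CXCL10like = list(k = 4, risk = 0,         surv = 0),
  CCL11like = list(k = 8,  risk = 0,         surv = 0))

risk_parts <- list(); surv_parts <- list()
cfg_lines <- c("# synthetic chemokine panel scan")
for (i in seq_along(panel)) {
  nm <- names(panel)[i]; p <- panel[[i]]
  seed <- base_seed + i
  sc <- mr_scenario(k = p$k, palindromic_fraction = 0.2,
                    intermediate_af_fraction = 0.25, seed = seed)
  ex <- simulate_exposure_summary(sc)
  ids <- sprintf("%s_%s", nm, ex$snp)
  ex$snp <- ids
  truth <- attr(ex, "truth"); truth$snp <- ids; attr(ex, "truth") <- truth

  exp_path <- file.path(out_dir, paste0("exposure_", nm, ".tsv"))
  write_summary_table(ex, exp_path)

  # independent instruments except one tight pair in the first exposure,
  # so the scan exercises LD pruning
  ld <- diag(p$k)
  if (i == 1) ld[1, 2] <- ld[2, 1] <- 0.95
  dimnames(ld) <- list(ex$snp, ex$snp)
  ld_path <- file.path(out_dir, paste0("ld_", nm, ".tsv"))
  write_ld_matrix(ld, ld_path)

  risk_parts[[nm]] <- simulate_outcome_summary(
    ex, mr_scenario(k = p$k, theta = p$risk, n_out = 247173,
                    seed = seed + 50L))
  surv_parts[[nm]] <- simulate_outcome_summary(
    ex, mr_scenario(k = p$k, theta = p$surv, n_out = 96661,
                    seed = seed + 90L))
  cfg_lines <- c(cfg_lines,
                 paste0("exposure:", nm, " = ", exp_path),
                 paste0("ld:", nm, " = ", ld_path))
}

risk_path <- file.path(out_dir, "outcome_risk.tsv")
surv_path <- file.path(out_dir, "outcome_survival.tsv")
write_summary_table(do.call(rbind, risk_parts), risk_path)
write_summary_table(do.call(rbind, surv_parts), surv_path)

cfg_lines <- c(cfg_lines,
               paste0("outcome:risk = ", risk_path),
               paste0("outcome:survival:survival = ", surv_path),
               "p_threshold = 5e-8",
               "r2_threshold = 0.01",
               "bonferroni_m = 6",
               "n_boot = 500",
               paste0("seed = ", base_seed))
writeLines(cfg_lines, file.path(out_dir, "scan.cfg"))

cat("Simulated", length(panel), "exposures;",
    sum(vapply(panel, `[[`, numeric(1), "k")), "instruments total.\n")
cat("True effects: CCL5like OR", sprintf("%.2f", exp(panel$CCL5like$risk)),
    "on risk; CCL19like HR", sprintf("%.2f", exp(panel$CCL19like$surv)),
    "on survival; all others null.\n")
cat("Files and scan config written under", out_dir, "\n")
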