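#!/usr/bin/env Rscript
# Deconvolution of membrane transport kinetics from noiseless synthetic
# bidirectional assays: the generator truth plays the role of the unknown
# cell biology, and the staged fit must recover it from the measured
# donor/receiver concentrations alone. Writes estimate-vs-truth tables.

library(gutpbpk)

dir.create("results", showWarnings = FALSE)

fit_one <- function(name, compound, truth, template, free, fixed) {
  ds <- generate_transwell_dataset(truth, compound, template)
  spec <- fit_spec(free = free, fixed = fixed)
  fit <- suppressWarnings(fit_transport_kinetics_staged(ds, compound, spec))
  tab <- data.frame(
    parameter = free,
    truth = unlist(unclass(truth)[free]),
    estimate = unlist(unclass(fit$estimates)[free]),
    se = fit$standard_errors[free],
    row.names = NULL)
  tab$rel_error <- abs(tab$estimate - tab$truth) / abs(tab$truth)
  write_tidy_csv(tab, sprintf("results/fit_%s.csv", name))
  cat(sprintf("%s: objective %.3g, Km_CA %.4g (truth %.4g, %.2f%% off)\n",
              name, fit$objective, fit$estimates$Km_CA, truth$Km_CA,
              100 * abs(fit$estimates$Km_CA - truth$Km_CA) / truth$Km_CA))
  invisible(fit)
}

fit_one(
  "digoxin", digoxin_compound(), digoxin_kinetics(),
  assay_template(donor_concs = c(0.3, 1, 3, 10, 30, 100),
                 donor_pH_levels = 6.5, replicates = 1, noise_cv = 0),
  free = c("CL_diff", "Vmax_CA", "Km_CA", "Vmax_CB", "Km_CB"),
  fixed = list(CL_AC = 0, CL_BC = 0, alpha_AC = 0, alpha_CA = 0,
               alpha_BC = 0, alpha_CB = 0))

fit_one(
  "talinolol", talinolol_compound(), talinolol_kinetics(),
  assay_template(replicates = 1, noise_cv = 0),
  free = c("CL_diff", "CL_BC", "Vmax_CA", "Km_CA", "Vmax_CB", "Km_CB",
           "alpha_CA", "alpha_BC", "alpha_CB"),
  fixed = list(CL_AC = 0, alpha_AC = 0))

cat("wrote results/fit_digoxin.csv and results/fit_talinolol.csv\n")
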