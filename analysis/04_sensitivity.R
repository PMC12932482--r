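#!/usr/bin/env Rscript
# Regional sensitivity analysis of the talinolol absorption profile: which
# segment-by-process scaling factors reshape the plasma curve, and the
# specific combination (apical uptake and basolateral efflux lowered in the
# lower jejunum, raised in the lower ileum) that turns the single-peaked
# baseline into a dual-peaked profile.

library(gutpbpk)

dir.create("results", showWarnings = FALSE)

tal <- talinolol_compound()
kin <- talinolol_invivo_kinetics()
gut <- build_default_gut()
sys <- talinolol_systemic()
dose <- dose_event("oral", 100)

# joint scan over the two key segments (apical uptake axis)
axes <- list(
  list(segment = "jejunum_2", process = "AC", factors = c(0.1, 1, 10)),
  list(segment = "ileum_4", process = "AC", factors = c(0.1, 1, 10)))
scan <- sensitivity_scan(gut, kin, sys, tal, axes, dose, t_end = 24)
write_tidy_csv(scan, "results/sensitivity_scan.csv")

# the dual-peak demonstration: x0.1 on jejunum_2 AC+CB, x10 on ileum_4
base <- simulate_pk(sys, gut, kin, tal, dose, t_end = 24)
pert <- simulate_pk(sys, dual_peak_perturbation(gut), kin, tal, dose,
                    t_end = 24)
write_tidy_csv(pert[, c("time_h", "plasma_ng_ml")],
               "results/talinolol_dual_peak.csv")

pk_base <- detect_peaks(base)
pk_pert <- detect_peaks(pert)
cat(sprintf("baseline: %d peak(s) at %s h\n", nrow(pk_base$peaks),
            paste(round(pk_base$peaks$time_h, 2), collapse = ", ")))
cat(sprintf("jejunum_2 x0.1 + ileum_4 x10 (AC and CB): %d peaks at %s h\n",
            nrow(pk_pert$peaks),
            paste(round(pk_pert$peaks$time_h, 2), collapse = ", ")))

# single-segment controls with the same factors stay single-peaked
controls <- expand.grid(
  segment = c("duodenum", "jejunum_1", "ileum_1", "ileum_2", "ileum_3"),
  factor = c(0.1, 10), stringsAsFactors = FALSE)
controls$n_peaks <- vapply(seq_len(nrow(controls)), function(i) {
  g <- scale_segment(gut, controls$segment[i], "AC", controls$factor[i])
  g <- scale_segment(g, controls$segment[i], "CB", controls$factor[i])
  nrow(detect_peaks(simulate_pk(sys, g, kin, tal, dose,
                                t_end = 24))$peaks)
}, integer(1))
write_tidy_csv(controls, "results/single_segment_controls.csv")
cat(sprintf("single-segment controls: peak counts %s\n",
            paste(unique(controls$n_peaks), collapse = ", ")))
cat("wrote results/sensitivity_scan.csv and companions\n")
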