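test_that("ddi_spec validates mechanism-specific fields", {
  expect_error(ddi_spec("competitive_inhibition", "CA"), "Ki")
  expect_error(ddi_spec("competitive_inhibition", "CA", Ki = 1), "inhibitor")
  expect_error(ddi_spec("induction", "CA"), "induction_fold")
  expect_silent(ddi_spec("full_inhibition", "CA"))
})

test_that("apply_ddi is pure and its neutral settings are identities", {
  gut <- build_default_gut()
  kin <- digoxin_invivo_kinetics()
  ind1 <- ddi_spec("induction", "CA", induction_fold = 1.0)
  out <- apply_ddi(gut, kin, ind1)
  expect_equal(out$gut, gut)
  expect_equal(out$kinetics, kin)

  comp0 <- ddi_spec("competitive_inhibition", "CA", Ki = 2,
                    inhibitor_conc_uM = 0)
  out0 <- apply_ddi(gut, kin, comp0)
  expect_equal(out0$kinetics, kin)

  ind <- ddi_spec("induction", "CA", segments = "ileum_4",
                  induction_fold = 1.7)
  a <- apply_ddi(gut, kin, ind)
  b <- apply_ddi(gut, kin, ind)
  expect_equal(a, b)                        # repeatable
  expect_equal(gut$segments[[8]]$pgp_abundance_factor,
               build_default_gut()$segments[[8]]$pgp_abundance_factor)
  expect_equal(a$gut$segments[[8]]$pgp_abundance_factor,
               1.7 * gut$segments[[8]]$pgp_abundance_factor)
})

test_that("competitive inhibition at saturating inhibitor equals full shutdown", {
  gut <- build_default_gut()
  kin <- digoxin_invivo_kinetics()
  dig <- digoxin_compound()
  full <- apply_ddi(gut, kin, ddi_spec("full_inhibition", "CA"))
  comp <- apply_ddi(gut, kin, ddi_spec("competitive_inhibition", "CA",
                                       Ki = 1, inhibitor_conc_uM = 1e9))
  st <- gut_initial_state(gut, 1000)
  st[grep("^ent_", names(st))] <- 50
  d_full <- gut_rhs(st, full$gut, full$kinetics, dig)$deriv
  d_comp <- gut_rhs(st, comp$gut, comp$kinetics, dig)$deriv
  expect_equal(unname(d_comp), unname(d_full), tolerance = 1e-6)
})

test_that("peak detection handles canonical profile shapes", {
  t <- seq(0, 12, by = 0.05)
  mono <- data.frame(time_h = t, plasma_ng_ml = 80 * exp(-0.4 * t))
  expect_equal(nrow(detect_peaks(mono)$peaks), 1)

  fx <- generate_two_peak_fixture()
  two <- detect_peaks(data.frame(time_h = fx$times,
                                 plasma_ng_ml = fx$conc))
  expect_equal(nrow(two$peaks), 2)
  expect_equal(two$peaks$time_h, fx$true_peak_times, tolerance = 0.1)
  expect_true(all(diff(two$peaks$time_h) > 0))

  zero <- data.frame(time_h = t, plasma_ng_ml = rep(0, length(t)))
  expect_equal(nrow(detect_peaks(zero)$peaks), 0)
  expect_error(detect_peaks(data.frame(time_h = 1:2,
                                       plasma_ng_ml = c(0, 1))), "three")
})

test_that("peak detection agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  fx <- generate_two_peak_fixture()
  ours <- detect_peaks(data.frame(time_h = fx$times,
                                  plasma_ng_ml = fx$conc),
                       prominence_threshold = 0.05)
  ref <- pracma::findpeaks(fx$conc, minpeakheight = 0.05 * max(fx$conc),
                           minpeakdistance = 10)
  expect_equal(nrow(ours$peaks), nrow(ref))
  expect_equal(sort(fx$times[ref[, 2]]), ours$peaks$time_h,
               tolerance = 0.05)
})

test_that("peak count is invariant to uniform dose rescaling of a linear profile", {
  fx <- generate_two_peak_fixture()
  for (scale in c(0.1, 1, 10)) {
    pk <- detect_peaks(data.frame(time_h = fx$times,
                                  plasma_ng_ml = fx$conc * scale))
    expect_equal(nrow(pk$peaks), 2)
  }
})

test_that("sensitivity scan reproduces the baseline at an all-unity grid point", {
  tal <- talinolol_compound()
  kin <- talinolol_invivo_kinetics()
  gut <- build_default_gut()
  sys <- talinolol_systemic()
  dose <- dose_event("oral", 100)
  axes <- list(list(segment = "jejunum_2", process = "AC", factors = 1))
  scan <- sensitivity_scan(gut, kin, sys, tal, axes, dose, t_end = 24)
  expect_equal(nrow(scan), 1)
  expect_true(scan$ok)
  base <- simulate_pk(sys, gut, kin, tal, dose, t_end = 24)
  expect_equal(scan$AUC, nca_metrics(base)$AUC, tolerance = 1e-10)
  expect_equal(scan$n_peaks, nrow(detect_peaks(base)$peaks))
})

test_that("regional factors act locally: jejunal scaling moves the early phase, ileal the late", {
  tal <- talinolol_compound()
  kin <- talinolol_invivo_kinetics()
  gut <- build_default_gut()
  sys <- talinolol_systemic()
  dose <- dose_event("oral", 100)
  base <- simulate_pk(sys, gut, kin, tal, dose, t_end = 24)
  jej <- simulate_pk(sys, scale_segment(gut, "jejunum_2", "AC", 0.1), kin,
                     tal, dose, t_end = 24)
  ile <- simulate_pk(sys, scale_segment(gut, "ileum_4", "AC", 10), kin,
                     tal, dose, t_end = 24)
  early <- function(s) nca_metrics(s, c(0, 2))$AUC
  late <- function(s) nca_metrics(s, c(4, 24))$AUC
  # jejunal down-scaling depresses the early exposure more than the late
  expect_gt(abs(early(jej) - early(base)) / early(base),
            abs(late(jej) - late(base)) / late(base) * 0.8)
  expect_lt(early(jej), early(base))
  # ileal up-scaling raises late exposure while the early phase moves little
  expect_gt(late(ile), late(base))
  expect_lt(abs(early(ile) - early(base)) / early(base), 0.05)
})
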