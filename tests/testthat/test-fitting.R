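make_small_dataset <- function(kinetics, compound,
                               concs = c(0.3, 3, 30, 300),
                               pH_levels = 6.5, noise = 0, seed = 1) {
  generate_transwell_dataset(
    kinetics, compound,
    assay_template(donor_concs = concs, donor_pH_levels = pH_levels,
                   replicates = 1, noise_cv = noise, seed = seed))
}

test_that("passive-only data pin the diffusion clearance and park Vmax at its bound", {
  neutral <- compound("probe", "neutral", mol_weight = 300)
  truth <- transport_kinetics(CL_diff = 5)
  ds <- make_small_dataset(truth, neutral)
  spec <- fit_spec(free = c("CL_diff", "Vmax_CA", "Km_CA"),
                   fixed = list(CL_AC = 0, CL_BC = 0, Vmax_CB = 0,
                                Km_CB = 1, alpha_AC = 0, alpha_CA = 0,
                                alpha_BC = 0, alpha_CB = 0),
                   lower = c(Vmax_CA = 1e-4))
  start <- transport_kinetics(CL_diff = 1, Vmax_CA = 0.5, Km_CA = 5)
  fit <- suppressWarnings(
    fit_transport_kinetics(ds, neutral, spec, start = start))
  expect_equal(fit$estimates$CL_diff, 5, tolerance = 1e-4)
  # efflux is absent from the data: its capacity collapses to the bound and
  # is flagged rather than silently dropped
  expect_equal(fit$estimates$Vmax_CA, 1e-4, tolerance = 1e-2)
  expect_true(fit$at_bound[["Vmax_CA"]])
})

test_that("free parameters are recovered from noiseless synthetic data", {
  tal <- talinolol_compound()
  truth <- talinolol_kinetics()
  ds <- make_small_dataset(truth, tal)
  spec <- fit_spec(
    free = c("CL_diff", "Vmax_CA", "Km_CA"),
    fixed = list(CL_AC = 0, CL_BC = truth$CL_BC, Vmax_CB = truth$Vmax_CB,
                 Km_CB = truth$Km_CB, alpha_AC = 0,
                 alpha_CA = truth$alpha_CA, alpha_BC = truth$alpha_BC,
                 alpha_CB = truth$alpha_CB))
  start <- talinolol_kinetics(CL_diff = 3, Vmax_CA = 40, Km_CA = 5)
  fit <- suppressWarnings(
    fit_transport_kinetics(ds, tal, spec, start = start))
  for (p in spec$free) {
    expect_equal(fit$estimates[[p]], truth[[p]], tolerance = 0.05,
                 label = p)
  }
})

test_that("the objective is invariant to dataset row order", {
  tal <- talinolol_compound()
  ds <- make_small_dataset(talinolol_kinetics(), tal)
  probe <- talinolol_kinetics(CL_diff = 5, Vmax_CA = 20)
  ssr_of <- function(d) {
    bp <- gutpbpk:::make_batch_predictor(d, tal)
    p <- bp(probe)
    sum((log(pmax(p, 1e-12)) - log(pmax(d$conc_uM, 1e-12)))^2)
  }
  set.seed(7)
  shuffled <- ds[sample(nrow(ds)), ]
  expect_equal(ssr_of(ds), ssr_of(shuffled), tolerance = 1e-10)
})

test_that("non-identifiable specifications are flagged, not silent", {
  tal <- talinolol_compound()
  ds <- make_small_dataset(talinolol_kinetics(), tal, concs = 10)
  spec <- fit_spec(free = c("Vmax_CA", "Km_CA"),
                   fixed = list(CL_AC = 0))
  expect_warning(
    gutpbpk:::check_identifiability_warnings(ds, spec),
    "not identifiable")
  ds_ab <- ds[ds$direction == "AB", ]
  expect_warning(
    gutpbpk:::check_identifiability_warnings(ds_ab,
                                             fit_spec(free = "CL_diff")),
    "direction")
})

test_that("identifiability profile has its minimum at truth and flags flat axes", {
  tal <- talinolol_compound()
  truth <- talinolol_kinetics()
  ds <- make_small_dataset(truth, tal)
  fixed <- list(CL_AC = 0, CL_BC = truth$CL_BC, Vmax_CB = truth$Vmax_CB,
                Km_CB = truth$Km_CB, alpha_AC = 0,
                alpha_CA = truth$alpha_CA, alpha_BC = truth$alpha_BC,
                alpha_CB = truth$alpha_CB)
  spec <- fit_spec(free = c("CL_diff", "Km_CA"), fixed = fixed)
  fit <- suppressWarnings(
    fit_transport_kinetics(ds, tal, spec, start = truth))
  grid <- truth$Km_CA * c(0.5, 0.8, 1, 1.25, 2)
  prof <- suppressWarnings(
    profile_identifiability(fit, ds, tal, "Km_CA", grid))
  expect_equal(grid[which.min(prof$objective)], truth$Km_CA)
  expect_false(attr(prof, "flat"))
  expect_error(profile_identifiability(fit, ds, tal, "Km_CA", numeric(0)),
               "empty")

  # alpha_AC multiplies a clearance fixed at zero: profile must be flat
  spec2 <- fit_spec(free = c("CL_diff", "alpha_AC"),
                    fixed = fixed[names(fixed) != "alpha_AC"])
  fit2 <- suppressWarnings(
    fit_transport_kinetics(ds, tal, spec2, start = truth))
  prof2 <- suppressWarnings(
    profile_identifiability(fit2, ds, tal, "alpha_AC",
                            c(-5, 0, 5, 10)))
  expect_true(attr(prof2, "flat"))
})

test_that("profile curvature is consistent with the reported standard error", {
  tal <- talinolol_compound()
  truth <- talinolol_kinetics()
  ds <- make_small_dataset(truth, tal, noise = 0.05, seed = 11)
  fixed <- list(CL_AC = 0, CL_BC = truth$CL_BC, Vmax_CB = truth$Vmax_CB,
                Km_CB = truth$Km_CB, alpha_AC = 0,
                alpha_CA = truth$alpha_CA, alpha_BC = truth$alpha_BC,
                alpha_CB = truth$alpha_CB)
  spec <- fit_spec(free = c("CL_diff", "Vmax_CA"), fixed = fixed)
  fit <- suppressWarnings(
    fit_transport_kinetics(ds, tal, spec, start = truth))
  v_hat <- fit$estimates$Vmax_CA
  se_fit <- fit$standard_errors[["Vmax_CA"]]
  v <- v_hat * 1.2
  prof <- suppressWarnings(
    profile_identifiability(fit, ds, tal, "Vmax_CA", v))
  sigma2 <- fit$objective / (fit$n_obs - length(spec$free))
  se_prof <- (v - v_hat) / sqrt((prof$objective[1] - fit$objective) / sigma2)
  expect_gt(se_prof / se_fit, 0.5)
  expect_lt(se_prof / se_fit, 2)
})

test_that("median recovery bias under 5% measurement noise stays within 15%", {
  dig <- digoxin_compound()
  truth <- digoxin_kinetics()
  fixed <- list(CL_AC = 0, CL_BC = 0, Vmax_CB = truth$Vmax_CB,
                Km_CB = truth$Km_CB, alpha_AC = 0, alpha_CA = 0,
                alpha_BC = 0, alpha_CB = 0)
  spec <- fit_spec(free = c("CL_diff", "Vmax_CA", "Km_CA"), fixed = fixed)
  start <- digoxin_kinetics(CL_diff = 0.5, Vmax_CA = 10, Km_CA = 8)
  est <- t(vapply(1:20, function(seed) {
    ds <- make_small_dataset(truth, dig, concs = c(0.3, 1, 3, 10, 30, 100),
                             noise = 0.05, seed = seed)
    fit <- suppressWarnings(
      fit_transport_kinetics(ds, dig, spec, start = start))
    c(Km_CA = fit$estimates$Km_CA, Vmax_CA = fit$estimates$Vmax_CA)
  }, c(Km_CA = 0, Vmax_CA = 0)))
  expect_lt(abs(stats::median(est[, "Km_CA"]) - truth$Km_CA) / truth$Km_CA,
            0.15)
  expect_lt(abs(stats::median(est[, "Vmax_CA"]) - truth$Vmax_CA) /
              truth$Vmax_CA, 0.15)
})
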