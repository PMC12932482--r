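test_that("default gut physiology encodes the regional gradients", {
  gut <- build_default_gut()
  nm <- vapply(gut$segments, `[[`, character(1), "name")
  expect_equal(nm, gut_segment_names())
  expect_equal(gut$segments[[1]]$surface_area, 0)

  pgp <- vapply(gut$segments, `[[`, numeric(1), "pgp_abundance_factor")
  names(pgp) <- nm
  si <- pgp[c("duodenum", "jejunum_1", "jejunum_2", "ileum_1", "ileum_2",
              "ileum_3", "ileum_4")]
  expect_true(all(diff(si) > 0))
  # duodenum-to-distal-ileum abundance span around 9-fold
  expect_gt(pgp[["ileum_4"]] / pgp[["duodenum"]], 8)
  expect_lt(pgp[["ileum_4"]] / pgp[["duodenum"]], 10)

  # apical efflux pH activity: unity in the jejunum, ~4.2-fold distally
  ph <- vapply(gut$segments, `[[`, numeric(1), "luminal_pH")
  names(ph) <- nm
  expect_equal(ph_activity_factor(19.3, ph[["jejunum_1"]]), 1.0)
  expect_equal(signif(ph_activity_factor(19.3, ph[["ileum_4"]]), 3), 4.18)

  for (s in gut$segments) {
    expect_equal(c(s$SF_AC, s$SF_BC, s$SF_CB, s$SF_CA), rep(1, 4))
  }
  # small-intestinal transit sums to ~3.5 h
  si_transit <- sum(vapply(gut$segments[2:8], `[[`, numeric(1),
                           "transit_time"))
  expect_equal(si_transit, 3.51, tolerance = 0.15)
})

test_that("gut RHS conserves mass and vanishes at zero state", {
  gut <- build_default_gut()
  kin <- talinolol_invivo_kinetics()
  tal <- talinolol_compound()
  st0 <- gut_initial_state(gut, 0)
  g0 <- gut_rhs(st0, gut, kin, tal)
  expect_true(all(g0$deriv == 0))

  set.seed(99)
  for (i in 1:4) {
    st <- gut_initial_state(gut, 0)
    st[] <- stats::runif(length(st), 0, 1e4)
    for (blood in c(0, 2.5)) {
      g <- gut_rhs(st, gut, kin, tal, blood_conc_unbound_uM = blood)
      # transit, absorption, loss and the portal ledger balance exactly
      expect_lt(abs(sum(g$deriv)), 1e-7 * sum(abs(g$deriv)))
    }
  }
})

test_that("vectorized gut RHS equals the reference implementation", {
  gut <- build_default_gut()
  kin <- talinolol_invivo_kinetics()
  tal <- talinolol_compound()
  cf <- gutpbpk:::gut_coefficients(gut, kin, tal)
  set.seed(5)
  for (i in 1:5) {
    st <- gut_initial_state(gut, 0)
    st[] <- stats::runif(length(st), 0, 5e3)
    blood <- stats::runif(1, 0, 3)
    ref <- gut_rhs(st, gut, kin, tal, blood_conc_unbound_uM = blood)
    fast <- gutpbpk:::gut_rhs_fast(unname(st), cf, blood_unb = blood)
    expect_equal(unname(ref$deriv), unname(fast), tolerance = 1e-12)
  }
})

test_that("scale_segment is pure and validates its inputs", {
  gut <- build_default_gut()
  g1 <- scale_segment(gut, "jejunum_2", "AC", 1)
  expect_equal(g1, gut)
  g2 <- scale_segment(gut, "jejunum_2", "AC", 0.1)
  expect_equal(g2$segments[[4]]$SF_AC, 0.1)
  expect_equal(gut$segments[[4]]$SF_AC, 1)  # original untouched
  expect_error(scale_segment(gut, "pylorus", "AC", 2), "unknown segment")
  expect_error(scale_segment(gut, "ileum_1", "XY", 2), "unknown process")
})

test_that("transporter abundance and SF_CA scale interchangeably", {
  tal <- talinolol_compound()
  kin <- talinolol_invivo_kinetics()
  sys <- talinolol_systemic()
  phys <- default_gut_physiology()
  phys$pgp_abundance_factor[phys$name == "ileum_2"] <-
    2 * phys$pgp_abundance_factor[phys$name == "ileum_2"]
  via_abundance <- build_default_gut(phys)
  via_sf <- scale_segment(build_default_gut(), "ileum_2", "CA", 2)
  dose <- dose_event("oral", 100)
  s1 <- simulate_pk(sys, via_abundance, kin, tal, dose, t_end = 12)
  s2 <- simulate_pk(sys, via_sf, kin, tal, dose, t_end = 12)
  expect_equal(s1$plasma_ng_ml, s2$plasma_ng_ml, tolerance = 1e-8)
})

test_that("removing apical efflux increases the fraction absorbed", {
  dig <- digoxin_compound()
  kin <- digoxin_invivo_kinetics()
  gut <- build_default_gut()
  sys <- digoxin_systemic()
  dose <- dose_event("oral", 0.5)
  base <- simulate_pk(sys, gut, kin, dig, dose, t_end = 24)
  no_efflux <- simulate_pk(sys, gut, digoxin_invivo_kinetics(Vmax_CA = 0),
                           dig, dose, t_end = 24)
  f <- function(s) utils::tail(s$portal_cum, 1) / attr(s, "dose_nmol")
  expect_gt(f(no_efflux), f(base))
})

test_that("the first-order dissolution hook delays luminal appearance", {
  tal <- talinolol_compound()
  kin <- talinolol_invivo_kinetics()
  sys <- talinolol_systemic()
  fast <- build_default_gut()
  slow <- build_default_gut(dissolution = "first_order", k_diss = 0.5)
  dose <- dose_event("oral", 100)
  s_fast <- simulate_pk(sys, fast, kin, tal, dose, t_end = 6)
  s_slow <- simulate_pk(sys, slow, kin, tal, dose, t_end = 6)
  # solid pool drains first-order and the early plasma rise is delayed
  expect_gt(s_slow$sol_stomach[2], 0)
  expect_true(all(s_fast$sol_stomach == 0))
  expect_lt(nca_metrics(s_slow, c(0, 2))$AUC,
            nca_metrics(s_fast, c(0, 2))$AUC)
  expect_lt(attr(s_slow, "audit"), 1e-6)
})

test_that("passive-only absorption increases monotonically with CL_diff", {
  neutral <- compound("probe", "neutral", mol_weight = 300)
  gut <- build_default_gut()
  sys <- talinolol_systemic()
  dose <- dose_event("oral", 10)
  f_of <- function(cl) {
    kin <- transport_kinetics(CL_diff = cl)
    s <- simulate_pk(sys, gut, kin, neutral, dose, t_end = 24)
    utils::tail(s$portal_cum, 1) / attr(s, "dose_nmol")
  }
  fs <- vapply(c(0.05, 0.5, 5), f_of, numeric(1))
  expect_true(all(diff(fs) > 0))
})
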