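test_that("transwell RHS vanishes at zero state and at diffusion equilibrium", {
  kin <- talinolol_kinetics()
  des <- transwell_design("apical", 10)
  tal <- talinolol_compound()
  expect_equal(unname(transwell_rhs(c(0, 0, 0), kin, des, tal)),
               c(0, 0, 0))

  # neutral compound, passive only, equal concentrations everywhere
  neutral <- compound("probe", "neutral", mol_weight = 300)
  passive <- transport_kinetics(CL_diff = 5)
  conc <- 7.3
  state <- conc * c(des$V_A, des$V_C, des$V_B)
  expect_equal(unname(transwell_rhs(state, passive, des, neutral)),
               c(0, 0, 0), tolerance = 1e-12)
  expect_error(transwell_rhs(c(-1, 0, 0), kin, des, tal), "non-negative")
})

test_that("saturable efflux plateaus at the pH-scaled Vmax", {
  kin <- digoxin_kinetics()
  des <- transwell_design("apical", 10)
  dig <- digoxin_compound()
  big <- 1e6 * kin$Km_CA * des$V_C
  d <- transwell_rhs(c(0, big, 0), kin, des, dig)
  passive_out <- unionized_fraction(dig, des$pH_cell) * dig$fu_cell *
    kin$CL_diff * big / des$V_C
  mm_flux <- d[["dX_A"]] / des$area - passive_out
  expect_equal(mm_flux, kin$Vmax_CA, tolerance = 1e-5)
})

test_that("adaptive integration matches a brute-force RK4 oracle", {
  tal <- talinolol_compound()
  kin <- talinolol_kinetics()
  for (cfg in list(list(side = "apical", conc = 10, pH_A = 6.5, pH_B = 7.4),
                   list(side = "basolateral", conc = 1, pH_A = 7.4,
                        pH_B = 6.5))) {
    des <- transwell_design(cfg$side, cfg$conc, pH_A = cfg$pH_A,
                            pH_B = cfg$pH_B)
    oracle <- rk4_transwell(kin, des, tal, h = 0.02)
    traj <- simulate_transwell(kin, des, tal)
    for (i in seq_len(nrow(oracle))) {
      row <- traj_pre_sample(traj, oracle[i, "time"])
      expect_equal(row$X_B, unname(oracle[i, "X_B"]), tolerance = 1e-3)
      expect_equal(row$X_A, unname(oracle[i, "X_A"]), tolerance = 1e-3)
    }
  }
})

test_that("mass is conserved through sampling events across random kinetics", {
  set.seed(42)
  tal <- talinolol_compound()
  for (i in 1:6) {
    kin <- transport_kinetics(
      CL_diff = runif(1, 0.1, 20), CL_AC = runif(1, 0, 2),
      CL_BC = runif(1, 0, 2),
      Vmax_CA = runif(1, 0, 30), Km_CA = runif(1, 0.2, 10),
      Vmax_CB = runif(1, 0, 30), Km_CB = runif(1, 1, 100),
      alpha_CA = runif(1, 0, 20), alpha_BC = runif(1, 0, 8),
      alpha_CB = runif(1, 0, 20))
    side <- if (i %% 2 == 0) "apical" else "basolateral"
    des <- transwell_design(side, runif(1, 0.3, 300),
                            pH_A = runif(1, 5, 7.4))
    traj <- simulate_transwell(kin, des, tal)
    dose <- attr(traj, "dose")
    total <- traj$X_A + traj$X_C + traj$X_B + traj$rem_A + traj$rem_B
    expect_lt(max(abs(total - dose)) / dose, 1e-6)
  }
})

test_that("passive transport of a neutral compound equilibrates all chambers", {
  neutral <- compound("probe", "neutral", mol_weight = 300)
  passive <- transport_kinetics(CL_diff = 5)
  des <- transwell_design("apical", 50, sample_times = c(0, 10))
  traj <- simulate_transwell(passive, des, neutral, t_end = 2e4, dt = 100)
  last <- traj[nrow(traj), ]
  concs <- c(last$X_A / des$V_A, last$X_C / des$V_C, last$X_B / des$V_B)
  expect_lt(diff(range(concs)) / mean(concs), 1e-4)
})

test_that("zero dose gives an identically zero trajectory", {
  des <- transwell_design("apical", 0)
  traj <- simulate_transwell(talinolol_kinetics(), des,
                             talinolol_compound())
  expect_true(all(traj$X_A == 0 & traj$X_C == 0 & traj$X_B == 0))
})

test_that("apparent permeability matches its closed form on linear data", {
  des <- transwell_design("apical", 20)
  s <- 0.013  # uM/min cumulative receiver slope
  papp <- apparent_permeability(c(60, 120) * s, des, times = c(60, 120))
  expect_equal(papp, s * des$V_B / (des$area * des$donor_conc) * 1e-3 / 60)
  expect_equal(apparent_permeability(c(0.4, 0.4), des, times = c(60, 120)),
               0)
  des0 <- transwell_design("apical", 0)
  expect_error(apparent_permeability(c(1, 2), des0), "positive")
})

test_that("efflux ratio arithmetic and guards", {
  expect_equal(efflux_ratio(2e-6, 2e-6), 1.0)
  expect_error(efflux_ratio(1e-6, 0), "positive")
})

test_that("simulated efflux ratio is non-decreasing in apical pH", {
  tal <- talinolol_compound()
  kin <- talinolol_kinetics()
  ers <- vapply(c(5.0, 6.5, 7.4), function(ph) {
    ab <- simulate_transwell(kin, transwell_design("apical", 10, pH_A = ph),
                             tal)
    ba <- simulate_transwell(kin, transwell_design("basolateral", 10,
                                                   pH_A = ph), tal)
    efflux_ratio(assay_papp(ba), assay_papp(ab))
  }, numeric(1))
  expect_true(all(diff(ers) >= 0))
})

test_that("lean measurement path agrees with the full trajectory simulator", {
  tal <- talinolol_compound()
  kin <- talinolol_kinetics()
  for (cfg in list(list("apical", 10, 6.5, 7.4),
                   list("basolateral", 0.3, 7.4, 5.0))) {
    des <- transwell_design(cfg[[1]], cfg[[2]], pH_A = cfg[[3]],
                            pH_B = cfg[[4]])
    m1 <- transwell_measurements(simulate_transwell(kin, des, tal))
    m2 <- gutpbpk:::simulate_condition_measurements(kin, des, tal)
    k1 <- paste(m1$time_min, m1$chamber)
    k2 <- paste(m2$time_min, m2$chamber)
    expect_equal(m2$conc_uM, m1$conc_uM[match(k2, k1)], tolerance = 1e-6)
  }
})
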