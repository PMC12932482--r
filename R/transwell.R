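#' Transwell assay design
#'
#' Geometry and sampling schedule of a bidirectional monolayer permeability
#' assay: 200 uL apical and 1000 uL basolateral chamber on a 0.33 cm2 insert,
#' cell volume 0.908 uL, dosing on either side, donor sampled (10 uL) at
#' every sample time including t = 0 and receiver sampled (100 uL) at the
#' later time points, with removed buffer replaced by blank buffer.
#'
#' @param donor_side `"apical"` or `"basolateral"`.
#' @param donor_conc donor concentration at t = 0 (`D0`), uM.
#' @param pH_A,pH_B apical and basolateral chamber pH.
#' @param V_A,V_B,V_C chamber and cell volumes, uL.
#' @param area monolayer area, cm2.
#' @param sample_times sampling times, min, strictly increasing from 0.
#' @param donor_sample_vol,receiver_sample_vol sample volumes, uL.
#' @param replacement replace sampled volume with blank buffer (default TRUE;
#'   FALSE is not currently modeled and is rejected).
#' @param pH_cell intracellular pH used for passive terms (default 7.4).
#' @return object of class `transwell_design`.
#' @export
transwell_design <- function(donor_side = c("apical", "basolateral"),
                             donor_conc,
                             pH_A = 6.5, pH_B = 7.4,
                             V_A = 200, V_B = 1000, V_C = 0.908,
                             area = 0.33,
                             sample_times = c(0, 60, 120),
                             donor_sample_vol = 10,
                             receiver_sample_vol = 100,
                             replacement = TRUE,
                             pH_cell = 7.4) {
  donor_side <- match.arg(donor_side)
  stopifnot(V_A > 0, V_B > 0, V_C > 0, area > 0, donor_conc >= 0)
  if (!isTRUE(replacement)) {
    stop("only the replacement sampling protocol is modeled", call. = FALSE)
  }
  if (sample_times[1] != 0 || is.unsorted(sample_times, strictly = TRUE)) {
    stop("sample_times must be strictly increasing and start at 0",
         call. = FALSE)
  }
  d_vol <- if (donor_side == "apical") V_A else V_B
  r_vol <- if (donor_side == "apical") V_B else V_A
  if (donor_sample_vol >= d_vol || receiver_sample_vol >= r_vol) {
    stop("sample volumes must be smaller than the sampled chamber",
         call. = FALSE)
  }
  structure(
    list(donor_side = donor_side, donor_conc = donor_conc,
         pH_A = pH_A, pH_B = pH_B, V_A = V_A, V_B = V_B, V_C = V_C,
         area = area, sample_times = sample_times,
         donor_sample_vol = donor_sample_vol,
         receiver_sample_vol = receiver_sample_vol,
         replacement = TRUE, pH_cell = pH_cell),
    class = "transwell_design")
}

#' Right-hand side of the three-compartment transwell model
#'
#' Amount derivatives (pmol/min) of the apical, cell, and basolateral
#' compartments. Per-area fluxes are:
#' `J(A->C) = (f_CA_AC * CL_AC + f_un(pH_A) * CL_diff) * C_A`,
#' `J(C->A) = f_act(alpha_CA, pH_A) * Vmax_CA * C_C/(Km_CA + C_C) +
#'   f_un(pH_cell) * fu_cell * CL_diff * C_C`, and symmetrically on the
#' basolateral membrane, each multiplied by the monolayer area. Saturable
#' efflux is driven by the total intracellular concentration `C_C = X_C/V_C`.
#'
#' @param state numeric vector `c(X_A, X_C, X_B)`, amounts in pmol.
#' @param kinetics a [transport_kinetics()] object.
#' @param design a [transwell_design()] object.
#' @param compound a [compound()] object.
#' @return named numeric vector `c(dX_A, dX_C, dX_B)` in pmol/min.
#' @export
transwell_rhs <- function(state, kinetics, design, compound) {
  if (any(state < -1e-9)) {
    stop("state amounts must be non-negative", call. = FALSE)
  }
  state <- pmax(state, 0)
  k <- kinetics; d <- design
  C_A <- state[1] / d$V_A
  C_C <- state[2] / d$V_C
  C_B <- state[3] / d$V_B
  f_un_A <- unionized_fraction(compound, d$pH_A)
  f_un_B <- unionized_fraction(compound, d$pH_B)
  f_un_C <- unionized_fraction(compound, d$pH_cell)
  pass_cell <- f_un_C * compound$fu_cell * k$CL_diff

  J_AC <- (ph_activity_factor(k$alpha_AC, d$pH_A, k$pH_ref) * k$CL_AC +
             f_un_A * k$CL_diff) * C_A
  J_CA <- ph_activity_factor(k$alpha_CA, d$pH_A, k$pH_ref) * k$Vmax_CA *
    C_C / (k$Km_CA + C_C) + pass_cell * C_C
  J_BC <- (ph_activity_factor(k$alpha_BC, d$pH_B, k$pH_ref) * k$CL_BC +
             f_un_B * k$CL_diff) * C_B
  J_CB <- ph_activity_factor(k$alpha_CB, d$pH_B, k$pH_ref) * k$Vmax_CB *
    C_C / (k$Km_CB + C_C) + pass_cell * C_C

  dX_A <- d$area * (J_CA - J_AC)
  dX_B <- d$area * (J_CB - J_BC)
  c(dX_A = dX_A, dX_C = -(dX_A + dX_B), dX_B = dX_B)
}

#' Simulate a transwell assay with sampling events
#'
#' Stiff integration of [transwell_rhs()] with the sampling protocol applied
#' at each sample time: the sampled volume's share of the chamber amount is
#' removed and the chamber is topped up with blank buffer (volume unchanged,
#' contents diluted). The donor chamber is sampled at every sample time
#' (including t = 0, applied to the initial condition); the receiver chamber
#' at every sample time after 0. All removals are ledgered so that
#' `X_A + X_C + X_B + removals` equals the initial dose at all times.
#'
#' @inheritParams transwell_rhs
#' @param t_end end of integration, min (default: last sample time).
#' @param dt output resolution, min.
#' @param rtol,atol solver tolerances.
#' @return object of class `transwell_trajectory`: a data.frame with columns
#'   `time`, `X_A`, `X_C`, `X_B`, `rem_A`, `rem_B` (pmol) and attributes
#'   `design`, `dose` (pmol) and `measurements` (see
#'   [transwell_measurements()]).
#' @export
simulate_transwell <- function(kinetics, design, compound, t_end = NULL,
                               dt = 1, rtol = 1e-8, atol = 1e-10) {
  d <- design
  if (is.null(t_end)) t_end <- max(d$sample_times)
  stopifnot(t_end >= max(d$sample_times))
  donor_ap <- d$donor_side == "apical"
  dose <- d$donor_conc * (if (donor_ap) d$V_A else d$V_B)

  state <- c(X_A = if (donor_ap) dose else 0, X_C = 0,
             X_B = if (donor_ap) 0 else dose)
  rem <- c(rem_A = 0, rem_B = 0)
  meas <- list()

  sample_chamber <- function(chamber, t, vol) {
    V <- if (chamber == "A") d$V_A else d$V_B
    X <- state[[if (chamber == "A") "X_A" else "X_B"]]
    removed <- X * vol / V
    state[[if (chamber == "A") "X_A" else "X_B"]] <<- X - removed
    rem[[if (chamber == "A") "rem_A" else "rem_B"]] <<-
      rem[[if (chamber == "A") "rem_A" else "rem_B"]] + removed
    meas[[length(meas) + 1]] <<- data.frame(
      time_min = t,
      chamber = if ((chamber == "A") == donor_ap) "donor" else "receiver",
      side = if (chamber == "A") "apical" else "basolateral",
      conc_uM = X / V, removed_pmol = removed)
  }

  # fold pH factors and unionized fractions into constant coefficients for
  # the compiled kernel (pure arithmetic; identical to transwell_rhs())
  k <- kinetics
  f_un_C <- unionized_fraction(compound, d$pH_cell)
  parms <- c(
    d$V_A, d$V_C, d$V_B, d$area,
    ph_activity_factor(k$alpha_AC, d$pH_A, k$pH_ref) * k$CL_AC +
      unionized_fraction(compound, d$pH_A) * k$CL_diff,
    ph_activity_factor(k$alpha_BC, d$pH_B, k$pH_ref) * k$CL_BC +
      unionized_fraction(compound, d$pH_B) * k$CL_diff,
    f_un_C * compound$fu_cell * k$CL_diff,
    ph_activity_factor(k$alpha_CA, d$pH_A, k$pH_ref) * k$Vmax_CA, k$Km_CA,
    ph_activity_factor(k$alpha_CB, d$pH_B, k$pH_ref) * k$Vmax_CB, k$Km_CB)

  # t = 0: donor sampled before integration starts
  sample_chamber(if (donor_ap) "A" else "B", 0, d$donor_sample_vol)

  bounds <- unique(c(d$sample_times, t_end))
  out <- NULL
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    times <- unique(c(seq(t0, t1, by = dt), t1))
    sol <- deSolve::lsoda(y = state, times = times,
                          func = "transwell_derivs", dllname = "gutpbpk",
                          initfunc = "transwell_init", parms = parms,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("transwell ODE integration failed between t = ", t0, " and ", t1,
           " min (istate ", attr(sol, "istate")[1], ")", call. = FALSE)
    }
    seg <- as.data.frame(sol)
    names(seg)[1] <- "time"
    seg$rem_A <- rem[["rem_A"]]; seg$rem_B <- rem[["rem_B"]]
    out <- rbind(out, if (i == 1) seg else seg[-1, ])
    state <- pmax(unlist(seg[nrow(seg), c("X_A", "X_C", "X_B")]), 0)
    names(state) <- c("X_A", "X_C", "X_B")
    if (t1 %in% d$sample_times && t1 > 0) {
      sample_chamber(if (donor_ap) "A" else "B", t1, d$donor_sample_vol)
      sample_chamber(if (donor_ap) "B" else "A", t1, d$receiver_sample_vol)
    }
  }
  # final post-sampling ledger row so the trajectory ends in audited state
  tail_row <- out[nrow(out), ]
  tail_row[c("X_A", "X_C", "X_B")] <- state
  tail_row$rem_A <- rem[["rem_A"]]; tail_row$rem_B <- rem[["rem_B"]]
  out <- rbind(out, tail_row)
  rownames(out) <- NULL

  structure(out,
            design = d, dose = dose,
            measurements = do.call(rbind, meas),
            class = c("transwell_trajectory", "data.frame"))
}

# Lean measurement-only simulation used inside fitting objectives: one
# lsoda call with sampling expressed as multiplicative events, output only
# just-before-sampling states. Numerically equivalent to
# simulate_transwell() + transwell_measurements() (asserted by tests).
simulate_condition_measurements <- function(kinetics, design, compound,
                                            rtol = 1e-8, atol = 1e-10) {
  d <- design
  donor_ap <- d$donor_side == "apical"
  dose <- d$donor_conc * (if (donor_ap) d$V_A else d$V_B)
  V_d <- if (donor_ap) d$V_A else d$V_B
  V_r <- if (donor_ap) d$V_B else d$V_A
  i_d <- if (donor_ap) 1L else 3L
  i_r <- if (donor_ap) 3L else 1L

  k <- kinetics
  parms <- c(
    d$V_A, d$V_C, d$V_B, d$area,
    ph_activity_factor(k$alpha_AC, d$pH_A, k$pH_ref) * k$CL_AC +
      unionized_fraction(compound, d$pH_A) * k$CL_diff,
    ph_activity_factor(k$alpha_BC, d$pH_B, k$pH_ref) * k$CL_BC +
      unionized_fraction(compound, d$pH_B) * k$CL_diff,
    unionized_fraction(compound, d$pH_cell) * compound$fu_cell * k$CL_diff,
    ph_activity_factor(k$alpha_CA, d$pH_A, k$pH_ref) * k$Vmax_CA, k$Km_CA,
    ph_activity_factor(k$alpha_CB, d$pH_B, k$pH_ref) * k$Vmax_CB, k$Km_CB)

  st <- d$sample_times[d$sample_times > 0]
  y0 <- numeric(3)
  y0[i_d] <- dose * (1 - d$donor_sample_vol / V_d)  # t = 0 donor sample
  eps <- 1e-6
  times <- sort(unique(c(0, st - eps, st)))
  ev <- rbind(
    data.frame(var = i_d, time = st, value = 1 - d$donor_sample_vol / V_d,
               method = "multiply"),
    data.frame(var = i_r, time = st, value = 1 - d$receiver_sample_vol / V_r,
               method = "multiply"))
  names(y0) <- c("1", "2", "3")
  ev$var <- as.character(ev$var)
  ev <- ev[order(ev$time, ev$var), ]
  sol <- deSolve::lsoda(y = y0, times = times, func = "transwell_derivs",
                        dllname = "gutpbpk", initfunc = "transwell_init",
                        parms = parms, rtol = rtol, atol = atol,
                        events = list(data = ev))
  if (attr(sol, "istate")[1] < 0) {
    stop("transwell integration failed", call. = FALSE)
  }
  pre <- sol[match(st - eps, sol[, 1]), , drop = FALSE]
  rbind(
    data.frame(time_min = 0, chamber = "donor", conc_uM = d$donor_conc),
    data.frame(time_min = st, chamber = "donor",
               conc_uM = pre[, 1 + i_d] / V_d),
    data.frame(time_min = st, chamber = "receiver",
               conc_uM = pre[, 1 + i_r] / V_r))
}

#' Sampled concentrations of a simulated transwell assay
#'
#' The measurement table of a trajectory: for each sampling event, the
#' chamber concentration immediately before the sample was drawn and the
#' amount removed. These are the quantities a bioanalytical readout reports.
#'
#' @param trajectory a [simulate_transwell()] result.
#' @return data.frame with columns `time_min`, `chamber` (donor/receiver),
#'   `side`, `conc_uM`, `removed_pmol`.
#' @export
transwell_measurements <- function(trajectory) {
  attr(trajectory, "measurements")
}

#' Sampling-corrected cumulative receiver concentration
#'
#' Reconstructs the cumulative receiver concentration by adding back the
#' material removed at earlier receiver sampling events (removed amount
#' divided by receiver volume), as required before applying the apparent
#' permeability formula.
#'
#' @param trajectory a [simulate_transwell()] result.
#' @return data.frame with columns `time_min` and `cum_conc_uM`.
#' @export
cumulative_receiver_conc <- function(trajectory) {
  d <- attr(trajectory, "design")
  m <- transwell_measurements(trajectory)
  rec <- m[m$chamber == "receiver", , drop = FALSE]
  V_r <- if (d$donor_side == "apical") d$V_B else d$V_A
  rec <- rec[order(rec$time_min), ]
  prior_removed <- c(0, cumsum(rec$removed_pmol)[-nrow(rec)])
  data.frame(time_min = rec$time_min,
             cum_conc_uM = rec$conc_uM + prior_removed / V_r)
}

#' Apparent permeability (Papp)
#'
#' `Papp = (dR/dt) * V_r / (A * D0)` where `dR/dt` is the slope of the
#' sampling-corrected cumulative receiver concentration between the two
#' measurement times, `V_r` the receiver volume, `A` the monolayer area and
#' `D0` the measured donor concentration at t = 0. The natural units
#' (uL/min/cm2) are converted to cm/s (1 uL/min/cm2 = 1e-3/60 cm/s).
#'
#' @param receiver_conc cumulative receiver concentrations (uM) at `times`,
#'   typically from [cumulative_receiver_conc()].
#' @param design a [transwell_design()] (supplies `V_r`, `A`, `D0`).
#' @param times measurement times, min (default: post-zero sample times).
#' @return Papp in cm/s.
#' @export
apparent_permeability <- function(receiver_conc, design,
                                  times = design$sample_times[design$sample_times > 0]) {
  stopifnot(length(receiver_conc) == 2, length(times) == 2)
  if (design$donor_conc <= 0) {
    stop("donor concentration D0 must be positive", call. = FALSE)
  }
  V_r <- if (design$donor_side == "apical") design$V_B else design$V_A
  slope <- diff(receiver_conc) / diff(times)          # uM/min
  papp_ul_min_cm2 <- slope * V_r / (design$area * design$donor_conc)
  papp_ul_min_cm2 * 1e-3 / 60                         # cm/s
}

#' Papp of a simulated assay
#'
#' Convenience wrapper: extracts the corrected cumulative receiver
#' concentrations from a trajectory and applies [apparent_permeability()].
#'
#' @param trajectory a [simulate_transwell()] result.
#' @return Papp in cm/s.
#' @export
assay_papp <- function(trajectory) {
  cc <- cumulative_receiver_conc(trajectory)
  apparent_permeability(cc$cum_conc_uM, attr(trajectory, "design"),
                        cc$time_min)
}

#' Efflux ratio
#'
#' Ratio of basolateral-to-apical over apical-to-basolateral apparent
#' permeability; values well above unity indicate active apical efflux.
#'
#' @param papp_BA,papp_AB apparent permeabilities, cm/s.
#' @return dimensionless ratio.
#' @examples
#' efflux_ratio(8.60e-6, 0.37e-6)  # ~23.2
#' @export
efflux_ratio <- function(papp_BA, papp_AB) {
  if (any(papp_AB <= 0)) {
    stop("papp_AB must be positive", call. = FALSE)
  }
  papp_BA / papp_AB
}
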