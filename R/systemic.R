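#' Whole-body disposition model
#'
#' Minimal physiological disposition: venous and arterial blood, portal
#' (splanchnic) blood, liver, kidney, and one lumped peripheral tissue, all
#' perfusion-limited. The liver receives portal plus hepatic-arterial
#' inflow (oral first pass) and clears by a well-stirred intrinsic
#' clearance; renal clearance acts on the unbound plasma concentration in
#' kidney outflow. Amounts are in nmol, volumes in mL, flows in mL/h;
#' concentrations are blood concentrations (nmol/mL = uM) and plasma values
#' derive via the blood:plasma ratio.
#'
#' @param V named volumes (mL): `venous`, `arterial`, `portal`, `liver`,
#'   `kidney`, `rest`.
#' @param Q named blood flows (mL/h): `portal`, `hepatic_artery`, `kidney`,
#'   `rest` (cardiac output is their sum plus hepatic venous return).
#' @param Kp named tissue:blood partition coefficients: `liver`, `kidney`,
#'   `rest`.
#' @param CL_hepatic_int hepatic intrinsic clearance, mL/h (on unbound
#'   plasma).
#' @param CL_renal renal clearance, mL/h (on unbound plasma).
#' @param blood_plasma_ratio blood:plasma concentration ratio.
#' @return object of class `systemic_model`.
#' @export
systemic_model <- function(V = c(venous = 3000, arterial = 1400,
                                 portal = 1000, liver = 1800,
                                 kidney = 300, rest = 35000),
                           Q = c(portal = 70000, hepatic_artery = 18000,
                                 kidney = 66000, rest = 236000),
                           Kp = c(liver = 4, kidney = 4, rest = 6),
                           CL_hepatic_int = 14000,
                           CL_renal = 8000,
                           blood_plasma_ratio = 1) {
  need_v <- c("venous", "arterial", "portal", "liver", "kidney", "rest")
  need_q <- c("portal", "hepatic_artery", "kidney", "rest")
  stopifnot(all(need_v %in% names(V)), all(need_q %in% names(Q)),
            all(V[need_v] > 0), all(Q[need_q] > 0),
            all(Kp > 0), CL_hepatic_int >= 0, CL_renal >= 0,
            blood_plasma_ratio > 0)
  structure(list(V = V, Q = Q, Kp = Kp,
                 CL_hepatic_int = CL_hepatic_int, CL_renal = CL_renal,
                 blood_plasma_ratio = blood_plasma_ratio),
            class = "systemic_model")
}

#' Talinolol disposition defaults
#'
#' Generic physiological disposition calibrated to talinolol's reported
#' systemic behavior (steady-state distribution volume around 230 L,
#' total clearance around 13 L/h with roughly 60:40 renal:hepatic split,
#' terminal half-life near 12 h).
#' @return a `systemic_model`.
#' @export
talinolol_systemic <- function() {
  systemic_model(Q = c(portal = 70000, hepatic_artery = 18000,
                       kidney = 66000, rest = 30000),
                 Kp = c(liver = 4, kidney = 4, rest = 6.2),
                 CL_hepatic_int = 14300 / 0.45, CL_renal = 8000 / 0.45)
}

#' Digoxin disposition defaults
#'
#' Generic physiological disposition calibrated to digoxin's systemic
#' behavior (distribution volume around 470 L, clearance around 9 L/h,
#' predominantly renal, terminal half-life beyond 30 h).
#' @return a `systemic_model`.
#' @export
digoxin_systemic <- function() {
  systemic_model(Kp = c(liver = 8, kidney = 8, rest = 13),
                 CL_hepatic_int = 2700 / 0.75, CL_renal = 7000 / 0.75)
}

#' Dose event
#'
#' @param route `"oral"`, `"iv_bolus"`, or `"iv_infusion"`.
#' @param amount_mg dose, mg.
#' @param start_time start, h.
#' @param duration infusion duration, h (infusion only).
#' @return object of class `dose_event`.
#' @export
dose_event <- function(route = c("oral", "iv_bolus", "iv_infusion"),
                       amount_mg, start_time = 0, duration = NULL) {
  route <- match.arg(route)
  stopifnot(amount_mg > 0, start_time >= 0)
  if (route == "iv_infusion") {
    if (is.null(duration) || duration <= 0) {
      stop("iv_infusion requires a positive duration", call. = FALSE)
    }
  } else duration <- 0
  structure(list(route = route, amount_mg = amount_mg,
                 start_time = start_time, duration = duration),
            class = "dose_event")
}

systemic_state_names <- function() {
  c("ven", "art", "por", "liv", "kid", "res", "el_hep", "el_ren")
}

#' Simulate oral and/or intravenous pharmacokinetics
#'
#' Joint stiff integration of the segmental gut model and the systemic
#' disposition model. Oral doses enter the stomach, IV doses the venous
#' blood; the net basolateral enterocyte flux drains into the portal blood
#' compartment ahead of the liver (first pass). Plasma concentration is the
#' venous blood concentration divided by the blood:plasma ratio, converted
#' to ng/mL via the molecular weight. The result carries a whole-system
#' mass-balance audit (dose versus all compartments plus fecal, degraded,
#' metabolized and eliminated amounts).
#'
#' @param systemic a [systemic_model()].
#' @param gut a `gut_model` (may be NULL for IV-only simulation of a
#'   gut-free reduction; oral doses then error).
#' @param kinetics a [transport_kinetics()].
#' @param compound a [compound()].
#' @param doses list of [dose_event()]s.
#' @param t_end simulation end, h.
#' @param dt reporting grid resolution, h.
#' @param rtol,atol solver tolerances.
#' @return object of class `sim_result`: data.frame (`time_h`,
#'   `plasma_ng_ml`, one column per state) with attributes `audit`
#'   (relative mass-balance error over the grid), `dose_nmol`, `models`.
#' @export
simulate_pk <- function(systemic, gut, kinetics, compound, doses,
                        t_end = 24, dt = 0.05, rtol = 1e-8, atol = 1e-8) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  stopifnot(length(doses) >= 1)
  mw <- compound$mol_weight
  stopifnot(is.finite(mw), mw > 0)
  has_gut <- !is.null(gut)

  gut_names <- if (has_gut) gut_state_names(gut) else character(0)
  state <- stats::setNames(numeric(length(gut_names) + 8),
                           c(gut_names, systemic_state_names()))

  ev_rows <- list(); infusions <- list()
  for (dose in doses) {
    amt <- dose$amount_mg * 1e6 / mw   # nmol
    if (dose$route == "oral") {
      if (!has_gut) stop("oral dosing requires a gut model", call. = FALSE)
      var <- if (gut$dissolution == "immediate") "lum_stomach" else
        "sol_stomach"
      if (dose$start_time == 0) {
        state[[var]] <- state[[var]] + amt
      } else {
        ev_rows[[length(ev_rows) + 1]] <-
          data.frame(var = var, time = dose$start_time, value = amt,
                     method = "add")
      }
    } else if (dose$route == "iv_bolus") {
      if (dose$start_time == 0) {
        state[["ven"]] <- state[["ven"]] + amt
      } else {
        ev_rows[[length(ev_rows) + 1]] <-
          data.frame(var = "ven", time = dose$start_time, value = amt,
                     method = "add")
      }
    } else {
      infusions[[length(infusions) + 1]] <-
        list(rate = amt / dose$duration, t0 = dose$start_time,
             t1 = dose$start_time + dose$duration)
    }
  }
  total_dose <- sum(vapply(doses, function(d) d$amount_mg * 1e6 / mw,
                           numeric(1)))

  s <- systemic
  fu_b <- compound$fu_plasma / s$blood_plasma_ratio  # unbound fraction in blood
  ng <- length(gut_names)
  i_ven <- ng + 1L; i_art <- ng + 2L; i_por <- ng + 3L; i_liv <- ng + 4L
  i_kid <- ng + 5L; i_res <- ng + 6L; i_ehep <- ng + 7L; i_eren <- ng + 8L
  V_ven <- s$V[["venous"]]; V_art <- s$V[["arterial"]]
  V_por <- s$V[["portal"]]
  VK_liv <- s$V[["liver"]] * s$Kp[["liver"]]
  VK_kid <- s$V[["kidney"]] * s$Kp[["kidney"]]
  VK_res <- s$V[["rest"]] * s$Kp[["rest"]]
  Q_pv <- s$Q[["portal"]]; Q_ha <- s$Q[["hepatic_artery"]]
  Q_k <- s$Q[["kidney"]]; Q_r <- s$Q[["rest"]]
  Q_h <- Q_pv + Q_ha; Q_co <- Q_h + Q_k + Q_r
  cf <- if (has_gut) gut_coefficients(gut, kinetics, compound) else NULL

  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    C_ven <- y[i_ven] / V_ven
    C_art <- y[i_art] / V_art
    C_por <- y[i_por] / V_por
    C_liv_out <- y[i_liv] / VK_liv
    C_kid_out <- y[i_kid] / VK_kid
    C_res_out <- y[i_res] / VK_res

    if (has_gut) {
      # unbound plasma concentration at the basolateral face is the
      # portal/villous blood concentration over BP ratio times fu_plasma
      dg <- gut_rhs_fast(y[seq_len(ng)], cf, blood_unb = C_por * fu_b)
      portal_rate <- dg[ng - 2L]   # portal_cum derivative
    } else {
      dg <- numeric(0)
      portal_rate <- 0
    }

    d_ven <- Q_h * C_liv_out + Q_k * C_kid_out + Q_r * C_res_out -
      Q_co * C_ven
    for (inf in infusions) {
      if (t >= inf$t0 && t < inf$t1) d_ven <- d_ven + inf$rate
    }
    elim_hep <- s$CL_hepatic_int * fu_b * C_liv_out
    elim_ren <- s$CL_renal * fu_b * C_kid_out
    list(c(dg,
           d_ven,
           Q_co * (C_ven - C_art),
           Q_pv * (C_art - C_por) + portal_rate,
           Q_pv * C_por + Q_ha * C_art - Q_h * C_liv_out - elim_hep,
           Q_k * (C_art - C_kid_out) - elim_ren,
           Q_r * (C_art - C_res_out),
           elim_hep,
           elim_ren))
  }

  times <- seq(0, t_end, by = dt)
  events <- if (length(ev_rows)) {
    list(data = do.call(rbind, ev_rows))
  } else NULL
  sol <- deSolve::lsoda(y = state, times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol, events = events,
                        maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) {
    stop("PK integration failed (istate ", attr(sol, "istate")[1], "); ",
         "final state: ",
         paste(utils::head(signif(sol[nrow(sol), -1], 3), 12),
               collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(sol)
  names(out)[1] <- "time_h"
  out$plasma_ng_ml <- out$ven / s$V[["venous"]] / s$blood_plasma_ratio * mw

  # mass audit: everything except bookkeeping (portal_cum)
  mass_cols <- setdiff(names(out), c("time_h", "plasma_ng_ml", "portal_cum"))
  infused <- vapply(out$time_h, function(t) {
    sum(vapply(infusions, function(inf) {
      inf$rate * max(min(t, inf$t1) - inf$t0, 0)
    }, numeric(1)))
  }, numeric(1))
  # a bolus landing at t > 0 is applied by the solver event *after* the
  # output row at that time, so it counts as dosed only strictly later
  dosed <- vapply(out$time_h, function(t) {
    sum(vapply(doses, function(d) {
      if (d$route == "iv_infusion") 0 else
        if ((d$start_time == 0 && t >= 0) || t > d$start_time) {
          d$amount_mg * 1e6 / mw
        } else 0
    }, numeric(1)))
  }, numeric(1)) + infused
  total <- rowSums(out[, mass_cols, drop = FALSE])
  audit <- max(abs(total - dosed) / max(total_dose, 1e-12))

  structure(out, audit = audit, dose_nmol = total_dose,
            models = list(systemic = s, gut = gut, kinetics = kinetics,
                          compound = compound, doses = doses),
            class = c("sim_result", "data.frame"))
}

#' Non-compartmental metrics of a simulated profile
#'
#' Linear-trapezoidal AUC of the plasma concentration over the interval,
#' with Cmax/Tmax read from the reporting grid.
#'
#' @param result a [simulate_pk()] result.
#' @param interval numeric length-2, h; default the full simulated range.
#' @return list with `AUC` (ng.h/mL), `Cmax` (ng/mL), `Tmax` (h).
#' @export
nca_metrics <- function(result, interval = range(result$time_h)) {
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  sel <- result$time_h >= interval[1] & result$time_h <= interval[2]
  if (sum(sel) < 2) stop("interval contains fewer than two grid points",
                         call. = FALSE)
  t <- result$time_h[sel]; c_ <- result$plasma_ng_ml[sel]
  auc <- sum(diff(t) * (utils::head(c_, -1) + utils::tail(c_, -1)) / 2)
  i <- which.max(c_)
  list(AUC = auc, Cmax = c_[i], Tmax = t[i])
}
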