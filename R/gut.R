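#' Gut segment
#'
#' One well-stirred luminal segment with an associated enterocyte layer.
#' `pgp_abundance_factor` rescales the apical efflux capacity relative to
#' the proximal-jejunum reference; `SF_*` are user-facing regional scaling
#' factors of the four transport processes (apical uptake AC, basolateral
#' uptake BC, basolateral efflux CB, apical efflux CA), all defaulting to 1.
#'
#' @param name segment name (one of the canonical nine; see
#'   [gut_segment_names()]).
#' @param luminal_pH luminal pH.
#' @param transit_time mean transit time, h.
#' @param surface_area absorptive mucosal surface area, cm2 (0 for stomach).
#' @param luminal_volume luminal fluid volume, mL.
#' @param enterocyte_volume enterocyte layer volume, mL.
#' @param pgp_abundance_factor relative apical-efflux-transporter abundance.
#' @param SF_AC,SF_BC,SF_CB,SF_CA regional scaling factors (>= 0).
#' @return object of class `gut_segment`.
#' @export
gut_segment <- function(name, luminal_pH, transit_time, surface_area,
                        luminal_volume, enterocyte_volume = 0,
                        pgp_abundance_factor = 1,
                        SF_AC = 1, SF_BC = 1, SF_CB = 1, SF_CA = 1) {
  stopifnot(name %in% gut_segment_names(), transit_time > 0,
            surface_area >= 0, luminal_volume > 0, enterocyte_volume >= 0,
            pgp_abundance_factor >= 0,
            SF_AC >= 0, SF_BC >= 0, SF_CB >= 0, SF_CA >= 0)
  structure(list(name = name, luminal_pH = luminal_pH,
                 transit_time = transit_time, surface_area = surface_area,
                 luminal_volume = luminal_volume,
                 enterocyte_volume = enterocyte_volume,
                 pgp_abundance_factor = pgp_abundance_factor,
                 SF_AC = SF_AC, SF_BC = SF_BC, SF_CB = SF_CB, SF_CA = SF_CA),
            class = "gut_segment")
}

#' Canonical segment names, proximal to distal
#' @return character vector of the nine segment names.
#' @export
gut_segment_names <- function() {
  c("stomach", "duodenum", "jejunum_1", "jejunum_2",
    "ileum_1", "ileum_2", "ileum_3", "ileum_4", "colon")
}

#' Gut model
#'
#' Ordered chain of the nine canonical segments with first-order luminal
#' transit (rate 1/transit_time per segment), an immediate or first-order
#' dissolution hook, optional luminal degradation, and an optional
#' enterocyte metabolism hook.
#'
#' @param segments list of [gut_segment()]s, proximal to distal; must start
#'   with the stomach and end with the colon.
#' @param dissolution `"immediate"` or `"first_order"`.
#' @param k_diss dissolution rate constant, 1/h (first-order only).
#' @param luminal_degradation luminal loss rate constant, 1/h.
#' @param clint_gut enterocyte intrinsic metabolic clearance, mL/h per cm2.
#' @param pH_cell intracellular pH (passive terms), default 7.4.
#' @param pH_blood blood-side pH at which basolateral processes are
#'   evaluated (fixed 7.4; blood pH does not fluctuate like luminal pH).
#' @return object of class `gut_model`.
#' @export
gut_model <- function(segments, dissolution = c("immediate", "first_order"),
                      k_diss = 2, luminal_degradation = 0, clint_gut = 0,
                      pH_cell = 7.4, pH_blood = 7.4) {
  dissolution <- match.arg(dissolution)
  nm <- vapply(segments, `[[`, character(1), "name")
  if (nm[1] != "stomach" || nm[length(nm)] != "colon" ||
      sum(nm == "stomach") != 1 || sum(nm == "colon") != 1) {
    stop("segments must run stomach -> ... -> colon with exactly one of each",
         call. = FALSE)
  }
  if (is.unsorted(match(nm, gut_segment_names()))) {
    stop("segments must be ordered proximal to distal", call. = FALSE)
  }
  structure(list(segments = segments, dissolution = dissolution,
                 k_diss = k_diss, luminal_degradation = luminal_degradation,
                 clint_gut = clint_gut, pH_cell = pH_cell,
                 pH_blood = pH_blood),
            class = "gut_model")
}

#' Default human gut physiology
#'
#' Nine-segment fasted-state physiology assembled from standard human GI
#' references: luminal pH rising from ~6.0 in the duodenum to ~7.0 in the
#' distal ileum, small-intestinal transit summing to 3.5 h, smooth
#' (cylindrical-scale) mucosal surface areas, and an apical efflux
#' transporter abundance gradient rising from the duodenum (0.4) to the
#' distal ileum (3.7; ~9.2-fold duodenum-to-ileum span) relative to the
#' proximal jejunum.
#'
#' @return data.frame, one row per segment.
#' @export
default_gut_physiology <- function() {
  data.frame(
    name = gut_segment_names(),
    luminal_pH = c(2.0, 6.0, 6.5, 6.5, 6.8, 7.0, 7.0, 7.0, 6.8),
    transit_time = c(0.25, 0.26, 0.70, 0.60, 0.60, 0.50, 0.45, 0.70, 12),
    surface_area = c(0, 300, 450, 400, 120, 100, 90, 120, 20),
    luminal_volume = c(250, 15, 30, 25, 20, 15, 10, 10, 50),
    enterocyte_volume = c(0, 8, 15, 13, 9, 7, 5, 4, 6),
    pgp_abundance_factor = c(0, 0.4, 0.7, 1.0, 2.0, 2.8, 3.3, 3.7, 2.0))
}

#' Build the default nine-segment gut model
#'
#' [gut_model()] over [default_gut_physiology()] with all scaling factors at
#' 1 and immediate dissolution (appropriate for a rapidly dissolving
#' compound; pass `dissolution = "first_order"` to engage the dissolution
#' hook).
#'
#' @param physiology physiology table in the format of
#'   [default_gut_physiology()].
#' @param ... passed to [gut_model()].
#' @return a `gut_model`.
#' @export
build_default_gut <- function(physiology = default_gut_physiology(), ...) {
  segs <- lapply(seq_len(nrow(physiology)), function(i) {
    p <- physiology[i, ]
    gut_segment(p$name, p$luminal_pH, p$transit_time, p$surface_area,
                p$luminal_volume, p$enterocyte_volume,
                p$pgp_abundance_factor)
  })
  gut_model(segs, ...)
}

#' Rescale one transport process in one segment
#'
#' Multiplies the segment's scaling factor for the given process by
#' `factor`, returning a modified copy (the input model is untouched).
#'
#' @param gut a `gut_model`.
#' @param segment_name segment to modify.
#' @param process one of `"AC"`, `"BC"`, `"CB"`, `"CA"`.
#' @param factor multiplicative factor, >= 0.
#' @return a new `gut_model`.
#' @export
scale_segment <- function(gut, segment_name, process, factor) {
  stopifnot(inherits(gut, "gut_model"), factor >= 0)
  if (!process %in% c("AC", "BC", "CB", "CA")) {
    stop("unknown process '", process, "'", call. = FALSE)
  }
  nm <- vapply(gut$segments, `[[`, character(1), "name")
  i <- match(segment_name, nm)
  if (is.na(i)) stop("unknown segment '", segment_name, "'", call. = FALSE)
  field <- paste0("SF_", process)
  gut$segments[[i]][[field]] <- gut$segments[[i]][[field]] * factor
  gut
}

# unit bridges: clearances uL/min/cm2 -> mL/h/cm2; Vmax pmol/min/cm2 ->
# nmol/h/cm2 (both x 60/1000)
.cl_mlh <- function(cl_ul_min) cl_ul_min * 0.06
.vmax_nmolh <- function(v_pmol_min) v_pmol_min * 0.06

gut_state_names <- function(gut) {
  nm <- vapply(gut$segments, `[[`, character(1), "name")
  ent <- nm[-1]   # all but stomach carry an enterocyte layer
  c(paste0("sol_", nm), paste0("lum_", nm), paste0("ent_", ent),
    "fecal", "portal_cum", "gut_met", "lum_deg")
}

#' Right-hand side of the segmental gut model
#'
#' Amount derivatives (nmol/h) for all gut states given the current state,
#' the transport kinetics, the compound, and the blood-side unbound plasma
#' concentration that drives basolateral exchange. Luminal transit is
#' first-order along the chain; the colon empties to fecal loss. Apical
#' fluxes use the segment's luminal pH (pH-power scaling and
#' Henderson-Hasselbalch); basolateral fluxes are evaluated at fixed blood
#' pH 7.4. Saturable efflux processes are driven by the total enterocyte
#' concentration; the apical efflux capacity is additionally multiplied by
#' the segment's transporter abundance factor.
#'
#' @param state named numeric vector over [gut_state_names()]; amounts in
#'   nmol.
#' @param gut a `gut_model`.
#' @param kinetics a [transport_kinetics()].
#' @param compound a [compound()].
#' @param blood_conc_unbound_uM unbound plasma concentration at the
#'   basolateral face, uM.
#' @return list: `deriv` (named vector, nmol/h), `portal_rate` (net nmol/h
#'   delivered to portal blood; negative when blood-to-enterocyte uptake
#'   dominates).
#' @export
gut_rhs <- function(state, gut, kinetics, compound,
                    blood_conc_unbound_uM = 0) {
  if (any(state < -1e-6)) {
    stop("gut state amounts must be non-negative", call. = FALSE)
  }
  state <- pmax(state, 0)
  k <- kinetics
  segs <- gut$segments
  n <- length(segs)
  nm <- vapply(segs, `[[`, character(1), "name")
  d <- stats::setNames(numeric(length(state)), names(state))

  f_un_cell <- unionized_fraction(compound, gut$pH_cell)
  f_un_blood <- unionized_fraction(compound, gut$pH_blood)
  pass_cell_out <- f_un_cell * compound$fu_cell * .cl_mlh(k$CL_diff)
  cl_bc_blood <- ph_activity_factor(k$alpha_BC, gut$pH_blood, k$pH_ref) *
    .cl_mlh(k$CL_BC)
  vmax_cb_blood <- ph_activity_factor(k$alpha_CB, gut$pH_blood, k$pH_ref) *
    .vmax_nmolh(k$Vmax_CB)
  pass_blood_in <- f_un_blood * .cl_mlh(k$CL_diff)

  portal <- 0
  for (i in seq_len(n)) {
    s <- segs[[i]]
    sol <- state[[paste0("sol_", s$name)]]
    lum <- state[[paste0("lum_", s$name)]]
    k_t <- 1 / s$transit_time

    # dissolution
    diss <- if (gut$dissolution == "immediate") 0 else gut$k_diss * sol
    d[[paste0("sol_", s$name)]] <- d[[paste0("sol_", s$name)]] - diss -
      k_t * sol
    if (i < n) {
      d[[paste0("sol_", nm[i + 1])]] <- d[[paste0("sol_", nm[i + 1])]] +
        k_t * sol
    } else {
      d[["fecal"]] <- d[["fecal"]] + k_t * sol
    }
    d[[paste0("lum_", s$name)]] <- d[[paste0("lum_", s$name)]] + diss -
      k_t * lum - gut$luminal_degradation * lum
    d[["lum_deg"]] <- d[["lum_deg"]] + gut$luminal_degradation * lum
    if (i < n) {
      d[[paste0("lum_", nm[i + 1])]] <- d[[paste0("lum_", nm[i + 1])]] +
        k_t * lum
    } else {
      d[["fecal"]] <- d[["fecal"]] + k_t * lum
    }

    if (s$surface_area <= 0 || s$enterocyte_volume <= 0) next
    ent <- state[[paste0("ent_", s$name)]]
    C_lum <- lum / s$luminal_volume
    C_ent <- ent / s$enterocyte_volume
    A <- s$surface_area
    pH_l <- s$luminal_pH
    f_un_lum <- unionized_fraction(compound, pH_l)

    uptake_ap <- (s$SF_AC *
                    ph_activity_factor(k$alpha_AC, pH_l, k$pH_ref) *
                    .cl_mlh(k$CL_AC) +
                    f_un_lum * .cl_mlh(k$CL_diff)) * A * C_lum
    efflux_ap <- (s$SF_CA * s$pgp_abundance_factor *
                    ph_activity_factor(k$alpha_CA, pH_l, k$pH_ref) *
                    .vmax_nmolh(k$Vmax_CA) * C_ent / (k$Km_CA + C_ent) +
                    pass_cell_out * C_ent) * A
    efflux_ba <- (s$SF_CB * vmax_cb_blood * C_ent / (k$Km_CB + C_ent) +
                    pass_cell_out * C_ent) * A
    uptake_ba <- (s$SF_BC * cl_bc_blood + pass_blood_in) * A *
      blood_conc_unbound_uM
    metab <- gut$clint_gut * A * C_ent

    d[[paste0("lum_", s$name)]] <- d[[paste0("lum_", s$name)]] -
      uptake_ap + efflux_ap
    d[[paste0("ent_", s$name)]] <- uptake_ap - efflux_ap - efflux_ba +
      uptake_ba - metab
    d[["gut_met"]] <- d[["gut_met"]] + metab
    portal <- portal + efflux_ba - uptake_ba
  }
  d[["portal_cum"]] <- portal
  list(deriv = d, portal_rate = portal)
}

# Precomputed per-segment coefficients for the fast RHS used inside
# simulate_pk(). All pH factors, unionized fractions, unit bridges and
# scaling factors are folded in once; the hot path is pure arithmetic.
# Equivalent to gut_rhs() (asserted by tests).
gut_coefficients <- function(gut, kinetics, compound) {
  k <- kinetics
  segs <- gut$segments
  n <- length(segs)
  f_un_cell <- unionized_fraction(compound, gut$pH_cell)
  f_un_blood <- unionized_fraction(compound, gut$pH_blood)
  pass_cell_out <- f_un_cell * compound$fu_cell * .cl_mlh(k$CL_diff)
  cl_bc_blood <- ph_activity_factor(k$alpha_BC, gut$pH_blood, k$pH_ref) *
    .cl_mlh(k$CL_BC)
  vmax_cb_blood <- ph_activity_factor(k$alpha_CB, gut$pH_blood, k$pH_ref) *
    .vmax_nmolh(k$Vmax_CB)
  pass_blood_in <- f_un_blood * .cl_mlh(k$CL_diff)

  g <- function(f) vapply(segs, `[[`, numeric(1), f)
  pH_l <- g("luminal_pH"); A <- g("surface_area")
  active <- A > 0 & g("enterocyte_volume") > 0
  fact <- function(alpha) (pH_l / k$pH_ref)^alpha
  list(
    n = n, active = which(active),
    k_t = 1 / g("transit_time"),
    V_lum = g("luminal_volume"),
    V_ent = ifelse(g("enterocyte_volume") > 0, g("enterocyte_volume"), 1),
    # uptake_lin * C_lum -> nmol/h into enterocyte
    uptake_lin = (g("SF_AC") * fact(k$alpha_AC) * .cl_mlh(k$CL_AC) +
                    unionized_fraction(compound, pH_l) * .cl_mlh(k$CL_diff)) *
      A * active,
    eff_vmax = g("SF_CA") * g("pgp_abundance_factor") * fact(k$alpha_CA) *
      .vmax_nmolh(k$Vmax_CA) * A * active,
    km_ca = k$Km_CA,
    pass_out = pass_cell_out * A * active,
    baso_vmax = g("SF_CB") * vmax_cb_blood * A * active,
    km_cb = k$Km_CB,
    baso_up = (g("SF_BC") * cl_bc_blood + pass_blood_in) * A * active,
    met = gut$clint_gut * A * active,
    k_deg = gut$luminal_degradation,
    k_diss = if (gut$dissolution == "immediate") 0 else gut$k_diss)
}

# state layout for the fast path: sol(1..n), lum(1..n), ent(2..n), then
# fecal, portal_cum, gut_met, lum_deg -- matching gut_state_names() order
gut_rhs_fast <- function(y, cf, blood_unb = 0) {
  n <- cf$n
  sol <- y[1:n]; lum <- y[(n + 1):(2 * n)]
  ent_full <- c(0, y[(2 * n + 1):(3 * n - 1)])
  diss <- cf$k_diss * sol
  out_sol <- cf$k_t * sol
  out_lum <- cf$k_t * lum
  C_lum <- lum / cf$V_lum
  C_ent <- ent_full / cf$V_ent
  uptake <- cf$uptake_lin * C_lum
  eff_ap <- cf$eff_vmax * C_ent / (cf$km_ca + C_ent) + cf$pass_out * C_ent
  eff_ba <- cf$baso_vmax * C_ent / (cf$km_cb + C_ent) + cf$pass_out * C_ent
  up_ba <- cf$baso_up * blood_unb
  metab <- cf$met * C_ent

  d_sol <- -diss - out_sol + c(0, out_sol[-n])
  d_lum <- diss - out_lum - cf$k_deg * lum + c(0, out_lum[-n]) -
    uptake + eff_ap
  d_ent_full <- uptake - eff_ap - eff_ba + up_ba - metab
  portal <- sum(eff_ba - up_ba)
  c(d_sol, d_lum, d_ent_full[-1],
    out_sol[n] + out_lum[n],               # fecal
    portal,                                 # portal_cum
    sum(metab),                             # gut_met
    cf$k_deg * sum(lum))                    # lum_deg
}

#' Initial gut state for an oral dose
#'
#' Zero state with the dose placed in the stomach: in the dissolved luminal
#' pool for immediate dissolution, otherwise in the solid pool.
#'
#' @param gut a `gut_model`.
#' @param dose_nmol oral dose, nmol (0 for no oral dose).
#' @return named numeric state vector.
#' @export
gut_initial_state <- function(gut, dose_nmol = 0) {
  st <- stats::setNames(numeric(length(gut_state_names(gut))),
                        gut_state_names(gut))
  if (dose_nmol > 0) {
    slot <- if (gut$dissolution == "immediate") "lum_stomach" else
      "sol_stomach"
    st[[slot]] <- dose_nmol
  }
  st
}
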