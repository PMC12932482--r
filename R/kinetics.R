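#' Membrane transport kinetics
#'
#' Per-membrane transport parameters of the three-compartment (apical / cell /
#' basolateral) monolayer model, all expressed per cm2 of monolayer at the
#' reference pH:
#'
#' * `CL_diff` (uL/min/cm2): passive diffusion clearance of the *unionized*
#'   species, identical on both membranes.
#' * `CL_AC`, `CL_BC` (uL/min/cm2): carrier-mediated (linear) uptake
#'   clearances into the cell across the apical and basolateral membranes.
#' * `Vmax_CA`, `Km_CA`: saturable efflux from cell to apical (P-gp-like),
#'   pmol/min/cm2 and uM.
#' * `Vmax_CB`, `Km_CB`: saturable efflux from cell to basolateral,
#'   pmol/min/cm2 and uM.
#' * `alpha_AC`, `alpha_CA`, `alpha_BC`, `alpha_CB`: dimensionless pH-power
#'   exponents; each active process is multiplied by
#'   `(pH/pH_ref)^alpha` at the pH of the membrane it faces
#'   (see [ph_activity_factor()]).
#'
#' Saturable efflux is driven by the *total* intracellular concentration;
#' the unbound fraction `fu_cell` applies to passive terms only.
#'
#' @param CL_diff,CL_AC,CL_BC clearances, uL/min/cm2 (>= 0).
#' @param Vmax_CA,Vmax_CB efflux capacities, pmol/min/cm2 (>= 0).
#' @param Km_CA,Km_CB Michaelis constants, uM (> 0 where paired Vmax > 0).
#' @param alpha_AC,alpha_CA,alpha_BC,alpha_CB pH exponents (finite).
#' @param pH_ref reference pH for the power law (default 6.5).
#' @return object of class `transport_kinetics`.
#' @export
transport_kinetics <- function(CL_diff = 0, CL_AC = 0, CL_BC = 0,
                               Vmax_CA = 0, Km_CA = 1,
                               Vmax_CB = 0, Km_CB = 1,
                               alpha_AC = 0, alpha_CA = 0,
                               alpha_BC = 0, alpha_CB = 0,
                               pH_ref = 6.5) {
  k <- list(CL_diff = CL_diff, CL_AC = CL_AC, CL_BC = CL_BC,
            Vmax_CA = Vmax_CA, Km_CA = Km_CA,
            Vmax_CB = Vmax_CB, Km_CB = Km_CB,
            alpha_AC = alpha_AC, alpha_CA = alpha_CA,
            alpha_BC = alpha_BC, alpha_CB = alpha_CB,
            pH_ref = pH_ref)
  validate_kinetics(k)
  structure(k, class = "transport_kinetics")
}

validate_kinetics <- function(k) {
  nonneg <- c("CL_diff", "CL_AC", "CL_BC", "Vmax_CA", "Vmax_CB")
  for (f in nonneg) {
    if (!is.finite(k[[f]]) || k[[f]] < 0) {
      stop("kinetics field '", f, "' must be finite and >= 0", call. = FALSE)
    }
  }
  if (k$Vmax_CA > 0 && k$Km_CA <= 0) {
    stop("Km_CA must be > 0 when Vmax_CA > 0", call. = FALSE)
  }
  if (k$Vmax_CB > 0 && k$Km_CB <= 0) {
    stop("Km_CB must be > 0 when Vmax_CB > 0", call. = FALSE)
  }
  alphas <- c(k$alpha_AC, k$alpha_CA, k$alpha_BC, k$alpha_CB)
  if (!all(is.finite(alphas))) stop("alpha exponents must be finite",
                                    call. = FALSE)
  stopifnot(k$pH_ref > 0)
  invisible(k)
}

#' Names of the estimable kinetic parameters
#' @return character vector of field names of [transport_kinetics()] that can
#'   be fixed or estimated by [fit_transport_kinetics()].
#' @export
kinetics_parameter_names <- function() {
  c("CL_diff", "CL_AC", "CL_BC", "Vmax_CA", "Km_CA", "Vmax_CB", "Km_CB",
    "alpha_AC", "alpha_CA", "alpha_BC", "alpha_CB")
}

#' @export
print.transport_kinetics <- function(x, ...) {
  cat("<transport_kinetics> (per cm2, anchored at pH", x$pH_ref, ")\n")
  cat(sprintf("  CL_diff %.4g  CL_AC %.4g  CL_BC %.4g  uL/min/cm2\n",
              x$CL_diff, x$CL_AC, x$CL_BC))
  cat(sprintf("  Vmax_CA %.4g (Km %.4g uM)  Vmax_CB %.4g (Km %.4g uM)\n",
              x$Vmax_CA, x$Km_CA, x$Vmax_CB, x$Km_CB))
  cat(sprintf("  alpha: AC %.3g  CA %.3g  BC %.3g  CB %.3g\n",
              x$alpha_AC, x$alpha_CA, x$alpha_BC, x$alpha_CB))
  invisible(x)
}

#' Caco-2 transport kinetics of talinolol
#'
#' Monolayer estimates from the three-compartment deconvolution of
#' bidirectional Caco-2 assays: passive diffusion 9.44 uL/min/cm2 (unionized
#' species), no apical uptake, basolateral uptake 0.0391 uL/min/cm2, apical
#' efflux Vmax 11.4 pmol/min/cm2 with Km 0.567 uM, basolateral efflux Vmax
#' 8.10 pmol/min/cm2 with Km 48.2 uM, and pH exponents 19.3 / 4.65 / 20.1
#' for apical efflux, basolateral uptake and basolateral efflux.
#'
#' @param ... overrides passed to [transport_kinetics()].
#' @return a `transport_kinetics` object.
#' @export
talinolol_kinetics <- function(...) {
  args <- utils::modifyList(
    list(CL_diff = 9.44, CL_AC = 0, CL_BC = 0.0391,
         Vmax_CA = 11.4, Km_CA = 0.567,
         Vmax_CB = 8.10, Km_CB = 48.2,
         alpha_AC = 0, alpha_CA = 19.3, alpha_BC = 4.65, alpha_CB = 20.1),
    list(...))
  do.call(transport_kinetics, args)
}

#' Caco-2 transport kinetics of digoxin
#'
#' Monolayer estimates: passive diffusion 0.162 uL/min/cm2, no active uptake
#' on either membrane, apical efflux Vmax 22.1 pmol/min/cm2 with Km 2.43 uM,
#' weak basolateral efflux (Vmax 0.00305 pmol/min/cm2, Km 658 uM). Digoxin
#' transport showed no pH dependence, so all exponents are 0.
#'
#' @param ... overrides passed to [transport_kinetics()].
#' @return a `transport_kinetics` object.
#' @export
digoxin_kinetics <- function(...) {
  args <- utils::modifyList(
    list(CL_diff = 0.162, CL_AC = 0, CL_BC = 0,
         Vmax_CA = 22.1, Km_CA = 2.43,
         Vmax_CB = 0.00305, Km_CB = 658),
    list(...))
  do.call(transport_kinetics, args)
}

#' In-vivo gut kinetics of talinolol
#'
#' Starts from [talinolol_kinetics()] and applies the in-vivo refinements
#' that monolayer data cannot supply:
#'
#' * an active apical uptake clearance (`cl_ac_invivo`, default
#'   0.838 uL/min/cm2), estimated in vivo because apical uptake was
#'   negligible in the monolayer yet required to reproduce oral exposure;
#' * efflux linearization: talinolol shows dose-linear pharmacokinetics at
#'   oral doses of 50-100 mg, so in vivo both efflux systems operate far
#'   below saturation at luminal concentrations. The translation therefore
#'   preserves the monolayer efflux *clearances* (Vmax/Km, e.g. apical
#'   11.4/0.567 = 20.1 uL/min/cm2 at the reference pH) while scaling Vmax
#'   and Km jointly by `linear_range_scale` so the Michaelis-Menten terms
#'   stay linear over in-vivo concentrations;
#' * a calibrated in-vivo basolateral efflux clearance (`cl_cb_invivo`, the
#'   effective Vmax_CB/Km_CB *at blood pH 7.4*, default 15 uL/min/cm2). As
#'   with digoxin, the monolayer basolateral capacity underestimates the
#'   in-vivo machinery by orders of magnitude, so this is a named
#'   calibration override (see [digoxin_invivo_kinetics()]).
#'
#' Basolateral processes are evaluated at fixed blood-side pH 7.4 by the gut
#' model; the stored `Vmax_CB` is back-converted so that its pH-7.4
#' clearance equals `cl_cb_invivo`.
#'
#' @param cl_ac_invivo in-vivo apical uptake clearance, uL/min/cm2.
#' @param cl_cb_invivo in-vivo basolateral efflux clearance at pH 7.4,
#'   uL/min/cm2.
#' @param linear_range_scale joint Vmax/Km scale factor keeping efflux in
#'   the linear range in vivo.
#' @param ... further overrides passed to [transport_kinetics()].
#' @return a `transport_kinetics` object.
#' @export
talinolol_invivo_kinetics <- function(cl_ac_invivo = 0.838,
                                      cl_cb_invivo = 15,
                                      linear_range_scale = 1000, ...) {
  base <- talinolol_kinetics()
  km_cb <- base$Km_CB * linear_range_scale
  vmax_cb_ref <- cl_cb_invivo * km_cb /
    ph_activity_factor(base$alpha_CB, 7.4, base$pH_ref)
  talinolol_kinetics(
    CL_AC = cl_ac_invivo,
    Vmax_CA = base$Vmax_CA * linear_range_scale,
    Km_CA = base$Km_CA * linear_range_scale,
    Vmax_CB = vmax_cb_ref,
    Km_CB = km_cb, ...)
}

#' In-vivo gut kinetics of digoxin
#'
#' [digoxin_kinetics()] with the basolateral efflux capacity replaced by the
#' in-vivo estimate of 6470 pmol/min/cm2 (fitted against oral plasma
#' profiles; the monolayer value of 0.00305 pmol/min/cm2 cannot support
#' in-vivo absorption).
#'
#' @param vmax_cb_invivo in-vivo basolateral efflux capacity, pmol/min/cm2.
#' @param ... further overrides passed to [transport_kinetics()].
#' @return a `transport_kinetics` object.
#' @export
digoxin_invivo_kinetics <- function(vmax_cb_invivo = 6470, ...) {
  digoxin_kinetics(Vmax_CB = vmax_cb_invivo, ...)
}
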