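#' Compound physicochemical properties
#'
#' Container for the ionization and binding properties that drive passive
#' membrane permeation. Only the unionized species is assumed to cross lipid
#' membranes, so the Henderson-Hasselbalch unionized fraction at the local pH
#' multiplies every passive diffusion clearance downstream.
#'
#' @param name compound name.
#' @param ionization_class one of `"neutral"`, `"monoprotic_base"`,
#'   `"monoprotic_acid"`.
#' @param pKa acid dissociation constant; required unless neutral.
#' @param fu_cell unbound fraction in cell water (0, 1]. Defaults to 1 when the
#'   intracellular binding of the compound is unknown.
#' @param fu_plasma unbound fraction in plasma (0, 1].
#' @param mol_weight molecular weight, g/mol.
#' @return object of class `compound`.
#' @export
compound <- function(name,
                     ionization_class = c("neutral", "monoprotic_base",
                                          "monoprotic_acid"),
                     pKa = NULL,
                     fu_cell = 1,
                     fu_plasma = 1,
                     mol_weight = NA_real_) {
  ionization_class <- match.arg(ionization_class)
  if (ionization_class != "neutral" && is.null(pKa)) {
    stop("pKa must be supplied for ionization_class '", ionization_class, "'",
         call. = FALSE)
  }
  if (ionization_class == "neutral" && !is.null(pKa)) {
    stop("pKa must be absent for a neutral compound", call. = FALSE)
  }
  stopifnot(fu_cell > 0, fu_cell <= 1, fu_plasma > 0, fu_plasma <= 1)
  structure(
    list(name = name,
         ionization_class = ionization_class,
         pKa = if (is.null(pKa)) NA_real_ else as.numeric(pKa),
         fu_cell = fu_cell,
         fu_plasma = fu_plasma,
         mol_weight = mol_weight),
    class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat("<compound>", x$name, "\n")
  cat("  class:", x$ionization_class,
      if (!is.na(x$pKa)) paste0("(pKa ", x$pKa, ")"), "\n")
  cat("  fu_cell:", x$fu_cell, " fu_plasma:", x$fu_plasma,
      " MW:", x$mol_weight, "g/mol\n")
  invisible(x)
}

#' Unionized fraction at a given pH (Henderson-Hasselbalch)
#'
#' For a monoprotic base the unionized fraction is `1/(1 + 10^(pKa - pH))`,
#' for a monoprotic acid `1/(1 + 10^(pH - pKa))`, and 1 for a neutral
#' compound. Vectorized over `pH`.
#'
#' @param compound a [compound()] object.
#' @param pH pH value(s), in \[0, 14\].
#' @return unionized fraction(s) in (0, 1\].
#' @examples
#' tal <- talinolol_compound()
#' unionized_fraction(tal, 6.5)  # ~0.00112
#' @export
unionized_fraction <- function(compound, pH) {
  stopifnot(inherits(compound, "compound"))
  if (any(pH < 0 | pH > 14)) {
    stop("pH must lie in [0, 14]", call. = FALSE)
  }
  switch(compound$ionization_class,
    neutral = rep(1, length(pH)),
    monoprotic_base = 1 / (1 + 10^(compound$pKa - pH)),
    monoprotic_acid = 1 / (1 + 10^(pH - compound$pKa)))
}

#' pH-power activity factor for a transport process
#'
#' Transporter activity is modeled as a power of the pH ratio relative to a
#' reference pH: `(pH / pH_ref)^alpha`. `alpha = 0` gives a factor of 1
#' (pH-independent process); positive `alpha` gives activity increasing with
#' pH. The reference pH is 6.5 (the upper-intestinal / assay donor pH at
#' which clearances are anchored).
#'
#' @param alpha dimensionless exponent (one per transport process).
#' @param pH pH at which to evaluate the factor; must be > 0.
#' @param pH_ref reference pH (default 6.5).
#' @return multiplicative activity factor(s), > 0.
#' @examples
#' ph_activity_factor(19.3, 7.0)        # ~4.18-fold
#' ph_activity_factor(4.65, 7.4)        # ~1.83-fold
#' @export
ph_activity_factor <- function(alpha, pH, pH_ref = 6.5) {
  if (any(pH <= 0)) stop("pH must be positive", call. = FALSE)
  stopifnot(pH_ref > 0, is.finite(alpha))
  (pH / pH_ref)^alpha
}

#' Talinolol physicochemical defaults
#'
#' Monoprotic base; the default pKa of 9.45 reproduces the unionized fraction
#' of 0.00112 at pH 6.5 used to derive the passive diffusion clearance of the
#' unionized species. `fu_cell` defaults to 1 (intracellular binding
#' unspecified); all values are plain fields and can be overridden.
#'
#' @param ... overrides passed to [compound()].
#' @return a [compound()] object.
#' @export
talinolol_compound <- function(...) {
  args <- utils::modifyList(
    list(name = "talinolol", ionization_class = "monoprotic_base",
         pKa = 9.45, fu_cell = 1, fu_plasma = 0.45, mol_weight = 363.5),
    list(...))
  do.call(compound, args)
}

#' Digoxin physicochemical defaults
#'
#' Treated as neutral over the physiological pH range (no relevant ionizable
#' group), so its passive permeation is pH-independent.
#'
#' @param ... overrides passed to [compound()].
#' @return a [compound()] object.
#' @export
digoxin_compound <- function(...) {
  args <- utils::modifyList(
    list(name = "digoxin", ionization_class = "neutral",
         fu_cell = 1, fu_plasma = 0.75, mol_weight = 780.9),
    list(...))
  do.call(compound, args)
}
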