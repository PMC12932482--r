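#' Bidirectional assay design template
#'
#' The condition grid of a bidirectional transwell study: donor
#' concentrations, donor pH levels (receiver held at 7.4), both transport
#' directions, duplicate wells, and an optional efflux-inhibitor arm. The
#' defaults follow the talinolol study design (0.3-300 uM, donor pH 5.0-7.4);
#' use `donor_concs = c(0.3, ..., 100)` for a digoxin-like design.
#'
#' @param donor_concs donor concentrations, uM.
#' @param donor_pH_levels donor-side pH levels applied at `ph_probe_conc`.
#' @param ph_probe_conc donor concentration used for the pH arms, uM.
#' @param receiver_pH receiver-side pH.
#' @param directions subset of `c("AB", "BA")`.
#' @param replicates wells per condition.
#' @param inhibitor_arms subset of `c("none", "pgp_inhibited")`; the
#'   inhibited arm suppresses both saturable efflux processes by
#'   `inhibition_fraction`.
#' @param inhibition_fraction fraction of efflux suppressed in the inhibitor
#'   arm (default 1 = complete suppression).
#' @param noise_cv multiplicative lognormal measurement noise CV (0 = exact).
#' @param seed RNG seed for the noise.
#' @return object of class `assay_template`.
#' @export
assay_template <- function(donor_concs = c(0.3, 1, 3, 10, 30, 100, 300),
                           donor_pH_levels = c(5.0, 6.0, 6.5, 7.0, 7.4),
                           ph_probe_conc = 10,
                           receiver_pH = 7.4,
                           directions = c("AB", "BA"),
                           replicates = 2,
                           inhibitor_arms = "none",
                           inhibition_fraction = 1,
                           noise_cv = 0,
                           seed = 1L) {
  stopifnot(replicates >= 1, noise_cv >= 0, all(donor_concs > 0),
            all(directions %in% c("AB", "BA")),
            all(inhibitor_arms %in% c("none", "pgp_inhibited")),
            inhibition_fraction >= 0, inhibition_fraction <= 1)
  structure(
    list(donor_concs = donor_concs, donor_pH_levels = donor_pH_levels,
         ph_probe_conc = ph_probe_conc, receiver_pH = receiver_pH,
         directions = directions, replicates = replicates,
         inhibitor_arms = inhibitor_arms,
         inhibition_fraction = inhibition_fraction,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "assay_template")
}

#' Condition grid of an assay template
#'
#' One row per simulated condition: the concentration series at the
#' reference donor pH 6.5 plus pH arms at the probe concentration (donor pH
#' levels other than 6.5), crossed with directions and inhibitor arms.
#'
#' @param template an [assay_template()].
#' @return data.frame with columns `direction`, `donor_conc_uM`, `pH_donor`,
#'   `pH_receiver`, `inhibitor_flag`.
#' @export
assay_conditions <- function(template) {
  tt <- template
  conc_grid <- expand.grid(donor_conc_uM = tt$donor_concs, pH_donor = 6.5,
                           KEEP.OUT.ATTRS = FALSE)
  ph_extra <- setdiff(tt$donor_pH_levels, 6.5)
  if (length(ph_extra)) {
    conc_grid <- rbind(conc_grid,
                       expand.grid(donor_conc_uM = tt$ph_probe_conc,
                                   pH_donor = ph_extra,
                                   KEEP.OUT.ATTRS = FALSE))
  }
  grid <- merge(conc_grid,
                expand.grid(direction = tt$directions,
                            inhibitor_flag = tt$inhibitor_arms,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  grid$pH_receiver <- tt$receiver_pH
  grid[order(grid$direction, grid$inhibitor_flag, grid$pH_donor,
             grid$donor_conc_uM),
       c("direction", "donor_conc_uM", "pH_donor", "pH_receiver",
         "inhibitor_flag")]
}

condition_design <- function(cond, base_design = NULL) {
  args <- list(
    donor_side = if (cond$direction == "AB") "apical" else "basolateral",
    donor_conc = cond$donor_conc_uM)
  if (cond$direction == "AB") {
    args$pH_A <- cond$pH_donor; args$pH_B <- cond$pH_receiver
  } else {
    args$pH_B <- cond$pH_donor; args$pH_A <- cond$pH_receiver
  }
  if (!is.null(base_design)) {
    keep <- setdiff(names(base_design), names(args))
    args <- c(args, base_design[keep])
    args$replacement <- NULL
    args <- c(args, list(replacement = TRUE))
  }
  do.call(transwell_design, args)
}

apply_inhibitor <- function(kinetics, fraction) {
  kinetics$Vmax_CA <- kinetics$Vmax_CA * (1 - fraction)
  kinetics$Vmax_CB <- kinetics$Vmax_CB * (1 - fraction)
  kinetics
}

#' Generate a synthetic bidirectional transwell dataset
#'
#' Simulates every condition of the template with the full sampling protocol
#' and emits the tidy assay schema. Multiplicative lognormal noise with the
#' template's CV is applied to the measured concentrations (mean-preserving;
#' seeded, so regeneration is bit-identical). With `noise_cv = 0` the data
#' lie exactly on the forward model.
#'
#' @param kinetics ground-truth [transport_kinetics()].
#' @param compound a [compound()].
#' @param template an [assay_template()].
#' @param base_design optional [transwell_design()] supplying non-default
#'   geometry; donor side, concentration and pH come from the template.
#' @return data.frame (class `transwell_dataset`) with columns `well_id`,
#'   `direction`, `donor_conc_uM`, `pH_donor`, `pH_receiver`,
#'   `inhibitor_flag`, `time_min`, `chamber`, `conc_uM`.
#' @export
generate_transwell_dataset <- function(kinetics, compound, template,
                                       base_design = NULL) {
  conds <- assay_conditions(template)
  sigma <- sqrt(log(1 + template$noise_cv^2))
  rows <- vector("list", nrow(conds) * template$replicates)
  ri <- 0L
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(template$seed)
  for (i in seq_len(nrow(conds))) {
    cond <- conds[i, ]
    kin <- if (cond$inhibitor_flag == "pgp_inhibited") {
      apply_inhibitor(kinetics, template$inhibition_fraction)
    } else kinetics
    des <- condition_design(cond, base_design)
    traj <- simulate_transwell(kin, des, compound)
    m <- transwell_measurements(traj)
    for (rep in seq_len(template$replicates)) {
      conc <- m$conc_uM
      if (sigma > 0) {
        conc <- conc * exp(stats::rnorm(length(conc), 0, sigma) - sigma^2 / 2)
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        well_id = sprintf("%s_pH%.1f_c%g_%s_r%d", cond$direction,
                          cond$pH_donor, cond$donor_conc_uM,
                          cond$inhibitor_flag, rep),
        direction = cond$direction,
        donor_conc_uM = cond$donor_conc_uM,
        pH_donor = cond$pH_donor,
        pH_receiver = cond$pH_receiver,
        inhibitor_flag = cond$inhibitor_flag,
        time_min = m$time_min,
        chamber = m$chamber,
        conc_uM = conc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("transwell_dataset", "data.frame")
  out
}

#' Two-peak plasma-profile fixture
#'
#' Deterministic plasma curve built from one or two first-order
#' absorption/elimination (Bateman) components with individual lag times,
#' emulating a dual-peak oral profile (defaults place the peaks near 1 h and
#' 4 h). Ground-truth analytic peak times are stored for recovery tests. If
#' the components merge into a single detectable peak, the fixture is
#' returned with `merged = TRUE` rather than failing.
#'
#' @param components list of lists with fields `amplitude` (ng/mL scale),
#'   `ka`, `ke` (1/h) and `lag` (h).
#' @param times output grid, h.
#' @param noise_cv multiplicative lognormal noise CV (0 = none).
#' @param seed RNG seed used when `noise_cv > 0`.
#' @return list of class `plasma_fixture` with `times`, `conc`,
#'   `true_peak_times`, `merged`, and the generating `params`.
#' @export
generate_two_peak_fixture <- function(components = list(
                                        list(amplitude = 50, ka = 6, ke = 1.2,
                                             lag = 0.45),
                                        list(amplitude = 60, ka = 5, ke = 0.35,
                                             lag = 3.55)),
                                      times = seq(0, 12, by = 0.05),
                                      noise_cv = 0, seed = 1L) {
  stopifnot(length(components) >= 1)
  conc <- numeric(length(times))
  true_peaks <- numeric(0)
  for (cmp in components) {
    stopifnot(cmp$ka > 0, cmp$ke > 0, cmp$ka != cmp$ke, cmp$amplitude >= 0)
    tt <- pmax(times - cmp$lag, 0)
    bateman <- cmp$amplitude * cmp$ka / (cmp$ka - cmp$ke) *
      (exp(-cmp$ke * tt) - exp(-cmp$ka * tt))
    conc <- conc + bateman
    if (cmp$amplitude > 0) {
      true_peaks <- c(true_peaks,
                      cmp$lag + log(cmp$ka / cmp$ke) / (cmp$ka - cmp$ke))
    }
  }
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    conc <- conc * exp(stats::rnorm(length(conc), 0, sigma) - sigma^2 / 2)
  }
  fixture <- structure(
    list(times = times, conc = conc,
         true_peak_times = sort(true_peaks),
         merged = FALSE,
         params = list(components = components, noise_cv = noise_cv,
                       seed = seed)),
    class = "plasma_fixture")
  if (length(true_peaks) > 1) {
    pk <- detect_peaks(data.frame(time_h = times, plasma_ng_ml = conc))
    fixture$merged <- nrow(pk$peaks) < length(true_peaks)
  }
  fixture
}
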