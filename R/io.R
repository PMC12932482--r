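#' Read a bidirectional transwell dataset from CSV
#'
#' Expects the tidy assay schema: `well_id`, `direction`, `donor_conc_uM`,
#' `pH_donor`, `pH_receiver`, `inhibitor_flag`, `time_min`, `chamber`,
#' `conc_uM`.
#'
#' @param path CSV file path.
#' @return a `transwell_dataset` data.frame.
#' @export
read_transwell_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "direction", "donor_conc_uM", "pH_donor",
            "pH_receiver", "inhibitor_flag", "time_min", "chamber",
            "conc_uM")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("transwell CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  class(d) <- c("transwell_dataset", "data.frame")
  d
}

#' Write a transwell dataset or trajectory to CSV
#' @param x a data.frame (dataset, trajectory, or scan table).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# schema of the structured run configuration; field names carry units
run_config_schema <- function() {
  list(
    compound = c("name", "ionization_class", "pka", "fu_cell", "fu_plasma",
                 "mol_weight_g_mol"),
    kinetics = c("cl_diff_ul_min_cm2", "cl_ac_ul_min_cm2",
                 "cl_bc_ul_min_cm2", "vmax_ca_pmol_min_cm2", "km_ca_um",
                 "vmax_cb_pmol_min_cm2", "km_cb_um", "alpha_ac", "alpha_ca",
                 "alpha_bc", "alpha_cb", "ph_ref"),
    gut = c("physiology", "dissolution", "k_diss_per_h",
            "luminal_degradation_per_h", "clint_gut_ml_h_cm2"),
    systemic = c("volumes_ml", "flows_ml_h", "kp", "cl_hepatic_int_ml_h",
                 "cl_renal_ml_h", "blood_plasma_ratio"),
    doses = c("route", "amount_mg", "start_time_h", "duration_h"),
    simulation = c("t_end_h", "dt_h", "rtol", "atol"),
    run = c("seed", "output_dir"))
}

#' Load and validate a structured run configuration
#'
#' YAML (or JSON) configuration with explicit units in field names. Unknown
#' keys are rejected with the offending name; basic unit sanity (positive
#' volumes, fractions in (0, 1]) is enforced at load. Defaults are filled
#' for any omitted section.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` config file.
#' @return validated config list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  schema <- run_config_schema()
  unknown_top <- setdiff(names(cfg), names(schema))
  if (length(unknown_top)) {
    stop("unknown config section(s): ", paste(unknown_top, collapse = ", "),
         call. = FALSE)
  }
  for (sec in intersect(names(cfg), setdiff(names(schema), "doses"))) {
    bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(bad)) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "),
           "; expected one of: ", paste(schema[[sec]], collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(cfg$doses)) {
    for (i in seq_along(cfg$doses)) {
      bad <- setdiff(names(cfg$doses[[i]]), schema$doses)
      if (length(bad)) {
        stop("unknown key(s) in doses[", i, "]: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      if (!is.null(cfg$doses[[i]]$amount_mg) &&
          cfg$doses[[i]]$amount_mg <= 0) {
        stop("doses[", i, "]: amount_mg must be > 0 (mg)", call. = FALSE)
      }
    }
  }
  check_positive <- function(sec, key, value) {
    if (!is.null(value) && any(value <= 0)) {
      stop("config field '", sec, ".", key,
           "' must be positive (check units in the field name)",
           call. = FALSE)
    }
  }
  if (!is.null(cfg$systemic)) {
    check_positive("systemic", "volumes_ml", unlist(cfg$systemic$volumes_ml))
    check_positive("systemic", "flows_ml_h", unlist(cfg$systemic$flows_ml_h))
  }
  if (!is.null(cfg$compound)) {
    for (key in c("fu_cell", "fu_plasma")) {
      v <- cfg$compound[[key]]
      if (!is.null(v) && (v <= 0 || v > 1)) {
        stop("config field 'compound.", key, "' must lie in (0, 1]",
             call. = FALSE)
      }
    }
  }
  if (!is.null(cfg$gut$physiology)) {
    phys <- as.data.frame(do.call(rbind, lapply(cfg$gut$physiology,
                                                as.data.frame)))
    for (key in c("transit_time", "luminal_volume")) {
      check_positive("gut.physiology", key, phys[[key]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#' @param cfg a `run_config` (or plain list).
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Materialize model objects from a run configuration
#'
#' @param cfg a [load_run_config()] result.
#' @return list with `compound`, `kinetics`, `gut`, `systemic`, `doses`,
#'   `simulation` (grid/tolerance settings), `seed`.
#' @export
build_models_from_config <- function(cfg) {
  comp <- if (is.null(cfg$compound)) talinolol_compound() else {
    compound(name = cfg$compound$name %||% "compound",
             ionization_class = cfg$compound$ionization_class %||% "neutral",
             pKa = cfg$compound$pka,
             fu_cell = cfg$compound$fu_cell %||% 1,
             fu_plasma = cfg$compound$fu_plasma %||% 1,
             mol_weight = cfg$compound$mol_weight_g_mol %||% NA_real_)
  }
  kin <- if (is.null(cfg$kinetics)) talinolol_invivo_kinetics() else {
    kk <- cfg$kinetics
    transport_kinetics(
      CL_diff = kk$cl_diff_ul_min_cm2 %||% 0,
      CL_AC = kk$cl_ac_ul_min_cm2 %||% 0,
      CL_BC = kk$cl_bc_ul_min_cm2 %||% 0,
      Vmax_CA = kk$vmax_ca_pmol_min_cm2 %||% 0,
      Km_CA = kk$km_ca_um %||% 1,
      Vmax_CB = kk$vmax_cb_pmol_min_cm2 %||% 0,
      Km_CB = kk$km_cb_um %||% 1,
      alpha_AC = kk$alpha_ac %||% 0, alpha_CA = kk$alpha_ca %||% 0,
      alpha_BC = kk$alpha_bc %||% 0, alpha_CB = kk$alpha_cb %||% 0,
      pH_ref = kk$ph_ref %||% 6.5)
  }
  gut <- if (is.null(cfg$gut)) build_default_gut() else {
    phys <- if (is.null(cfg$gut$physiology)) default_gut_physiology() else {
      as.data.frame(do.call(rbind, lapply(cfg$gut$physiology, function(r) {
        as.data.frame(r, stringsAsFactors = FALSE)
      })))
    }
    build_default_gut(
      physiology = phys,
      dissolution = cfg$gut$dissolution %||% "immediate",
      k_diss = cfg$gut$k_diss_per_h %||% 2,
      luminal_degradation = cfg$gut$luminal_degradation_per_h %||% 0,
      clint_gut = cfg$gut$clint_gut_ml_h_cm2 %||% 0)
  }
  sys <- if (is.null(cfg$systemic)) talinolol_systemic() else {
    ss <- cfg$systemic
    systemic_model(
      V = unlist(ss$volumes_ml %||%
                   as.list(formals(systemic_model)$V)[-1]),
      Q = unlist(ss$flows_ml_h %||%
                   as.list(formals(systemic_model)$Q)[-1]),
      Kp = unlist(ss$kp %||% list(liver = 4, kidney = 4, rest = 6)),
      CL_hepatic_int = ss$cl_hepatic_int_ml_h %||% 14000,
      CL_renal = ss$cl_renal_ml_h %||% 8000,
      blood_plasma_ratio = ss$blood_plasma_ratio %||% 1)
  }
  doses <- if (is.null(cfg$doses)) {
    list(dose_event("oral", 100))
  } else {
    lapply(cfg$doses, function(d) {
      dose_event(route = d$route %||% "oral",
                 amount_mg = d$amount_mg,
                 start_time = d$start_time_h %||% 0,
                 duration = d$duration_h)
    })
  }
  list(compound = comp, kinetics = kin, gut = gut, systemic = sys,
       doses = doses,
       simulation = list(t_end = cfg$simulation$t_end_h %||% 24,
                         dt = cfg$simulation$dt_h %||% 0.05,
                         rtol = cfg$simulation$rtol %||% 1e-8,
                         atol = cfg$simulation$atol %||% 1e-8),
       seed = cfg$run$seed %||% 1L,
       output_dir = cfg$run$output_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run pipeline stages from a configuration
#'
#' Orchestrates the analysis stages over one configuration: `fit`
#' (synthesize a noiseless assay from the configured kinetics and refit it),
#' `simulate` (oral PK simulation), `sensitivity` (the dual-peak regional
#' scan), and `ddi` (abundance induction of the apical efflux transporter).
#' Every run writes a manifest (stages, seed, package version, input hash,
#' wall time) sufficient to reproduce the outputs.
#'
#' @param cfg a [load_run_config()] result (or path to one).
#' @param stages subset of `c("fit", "simulate", "sensitivity", "ddi")`.
#' @param out_dir output directory (default from the config).
#' @return invisible list of stage results; files are written to `out_dir`.
#' @export
run_pipeline <- function(cfg, stages = c("simulate"), out_dir = NULL) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(all(stages %in% c("fit", "simulate", "sensitivity", "ddi")))
  m <- build_models_from_config(cfg)
  if (is.null(out_dir)) out_dir <- m$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  results <- list()

  if ("fit" %in% stages) {
    template <- assay_template(noise_cv = 0, replicates = 1,
                               seed = m$seed)
    ds <- generate_transwell_dataset(m$kinetics, m$compound, template)
    spec <- fit_spec(free = c("CL_diff", "Vmax_CA", "Km_CA"),
                     fixed = list(CL_AC = 0), start = m$kinetics)
    fit <- fit_transport_kinetics(ds, m$compound, spec, start = m$kinetics)
    jsonlite::write_json(
      list(estimates = unclass(fit$estimates),
           standard_errors = as.list(fit$standard_errors),
           objective = fit$objective, converged = fit$convergence_flag),
      file.path(out_dir, "fit_result.json"), auto_unbox = TRUE, digits = NA)
    write_tidy_csv(ds, file.path(out_dir, "fit_dataset.csv"))
    results$fit <- fit
  }
  sim <- NULL
  if (any(c("simulate", "sensitivity", "ddi") %in% stages)) {
    sim <- simulate_pk(m$systemic, m$gut, m$kinetics, m$compound, m$doses,
                       t_end = m$simulation$t_end, dt = m$simulation$dt,
                       rtol = m$simulation$rtol, atol = m$simulation$atol)
  }
  if ("simulate" %in% stages) {
    write_tidy_csv(sim[, c("time_h", "plasma_ng_ml")],
                   file.path(out_dir, "plasma_profile.csv"))
    results$simulate <- sim
  }
  if ("sensitivity" %in% stages) {
    axes <- list(list(segment = "jejunum_2", process = "AC",
                      factors = c(0.1, 1)),
                 list(segment = "ileum_4", process = "AC",
                      factors = c(1, 10)))
    scan <- sensitivity_scan(m$gut, m$kinetics, m$systemic, m$compound,
                             axes, m$doses, t_end = m$simulation$t_end)
    write_tidy_csv(scan, file.path(out_dir, "sensitivity_scan.csv"))
    results$sensitivity <- scan
  }
  if ("ddi" %in% stages) {
    spec <- ddi_spec("induction", "CA",
                     segments = setdiff(gut_segment_names(),
                                        c("stomach", "colon")),
                     induction_fold = 1.7)
    pert <- apply_ddi(m$gut, m$kinetics, spec)
    sim_ddi <- simulate_pk(m$systemic, pert$gut, pert$kinetics, m$compound,
                           m$doses, t_end = m$simulation$t_end,
                           dt = m$simulation$dt)
    ratio <- nca_metrics(sim_ddi)$AUC / nca_metrics(sim)$AUC
    jsonlite::write_json(list(auc_ratio = ratio),
                         file.path(out_dir, "ddi_result.json"),
                         auto_unbox = TRUE, digits = NA)
    results$ddi <- list(ratio = ratio, sim = sim_ddi)
  }

  manifest <- list(
    stages = stages,
    seed = m$seed,
    package_version = as.character(utils::packageVersion("gutpbpk")),
    config_hash = sum(utf8ToInt(paste(deparse(unclass(cfg)),
                                      collapse = ""))),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(results)
}
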