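#' Patient-style boundary data
#'
#' The clinical quantities the simulator consumes: serum LDL/HDL, blood
#' monocyte count, inlet velocity, outlet pressure, hypertension status
#' (which selects the adventitial pressure and the adventitial LDL
#' coefficient) and the interscan period that sets the simulated horizon.
#'
#' @param serum_ldl_mg_dl,serum_hdl_mg_dl Serum concentrations, mg/dL.
#' @param blood_monocytes_per_m3 Blood monocyte concentration, cells/m^3.
#' @param inlet_mean_velocity_m_s Mean inlet blood velocity, m/s.
#' @param outlet_pressure_mmhg Outlet (distal) blood pressure, mmHg.
#' @param hypertensive Logical.
#' @param interscan_period_years Simulated horizon, years.
#' @param ldl_molar_mass_kg_mol,hdl_molar_mass_kg_mol Effective molar
#'   masses used to convert mg/dL to mol/m^3.
#' @return An object of class `patient_boundary_data`.
#' @export
patient_boundary_data <- function(serum_ldl_mg_dl = 108.16,
                                  serum_hdl_mg_dl = 55.96,
                                  blood_monocytes_per_m3 = 5e11,
                                  inlet_mean_velocity_m_s = 0.15,
                                  outlet_pressure_mmhg = 100,
                                  hypertensive = FALSE,
                                  interscan_period_years = 6.1,
                                  ldl_molar_mass_kg_mol = 386.65,
                                  hdl_molar_mass_kg_mol = 175) {
  stopifnot(serum_ldl_mg_dl >= 0, serum_hdl_mg_dl >= 0,
            blood_monocytes_per_m3 >= 0, inlet_mean_velocity_m_s >= 0,
            outlet_pressure_mmhg > 0, interscan_period_years > 0)
  structure(list(serum_ldl_mg_dl = serum_ldl_mg_dl,
                 serum_hdl_mg_dl = serum_hdl_mg_dl,
                 blood_monocytes_per_m3 = blood_monocytes_per_m3,
                 inlet_mean_velocity_m_s = inlet_mean_velocity_m_s,
                 outlet_pressure_mmhg = outlet_pressure_mmhg,
                 hypertensive = isTRUE(hypertensive),
                 interscan_period_years = interscan_period_years,
                 ldl_molar_mass_kg_mol = ldl_molar_mass_kg_mol,
                 hdl_molar_mass_kg_mol = hdl_molar_mass_kg_mol),
            class = "patient_boundary_data")
}

#' Simulation configuration
#'
#' Bundles the geometry spec, patient boundary data and every parameter
#' block, plus orchestration options. Serializes to YAML with
#' [write_config()] / [read_config()] (round-trip identical).
#'
#' @param geometry An [artery_spec()].
#' @param patient A [patient_boundary_data()].
#' @param kinetics,endothelium,wall,blood,volumes,material Parameter blocks.
#' @param growth_mode `"kinematic"` or `"elastic"`.
#' @param dv_cap Clamp on the plaque volume ratio.
#' @param macro_step_months Macro time step, months.
#' @param seed Integer seed recorded with the run.
#' @param out_dir Optional output directory for artifacts.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = artery_spec(),
                              patient = patient_boundary_data(),
                              kinetics = kinetic_parameters(),
                              endothelium = endothelial_parameters(),
                              wall = porous_wall_properties(),
                              blood = blood_properties(),
                              volumes = cellular_volumes(),
                              material = wall_material(),
                              growth_mode = c("kinematic", "elastic"),
                              dv_cap = 0.95,
                              macro_step_months = 1,
                              seed = 1L,
                              out_dir = NULL) {
  growth_mode <- match.arg(growth_mode)
  structure(list(geometry = geometry, patient = patient, kinetics = kinetics,
                 endothelium = endothelium, wall = wall, blood = blood,
                 volumes = volumes, material = material,
                 growth_mode = growth_mode, dv_cap = dv_cap,
                 macro_step_months = macro_step_months,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "simulation_config")
}

#' Write / read a simulation configuration (YAML)
#'
#' @param config A [simulation_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the reconstructed `simulation_config`.
#' @name config_io
NULL

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$geometry
  lst <- list(
    geometry = list(length_mm = g$length_mm, lumen_radius_mm = g$lumen_radius_mm,
                    wall_thickness_mm = g$wall_thickness_mm,
                    stenoses = if (nrow(g$stenoses)) lapply(seq_len(nrow(g$stenoses)),
                      function(i) as.list(g$stenoses[i, ])) else list(),
                    edge_length_mm = g$edge_length_mm, seed = g$seed),
    patient = unclass(config$patient),
    kinetics = c(unclass(config$kinetics)),
    endothelium = unclass(config$endothelium),
    wall = unclass(config$wall),
    blood = unclass(config$blood),
    volumes = unclass(config$volumes),
    material = unclass(config$material),
    growth_mode = config$growth_mode,
    dv_cap = config$dv_cap,
    macro_step_months = config$macro_step_months,
    seed = config$seed
  )
  attributes(lst$kinetics) <- list(names = names(lst$kinetics))
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname config_io
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- yaml::read_yaml(path)
  g <- lst$geometry
  sten <- if (length(g$stenoses)) {
    dplyr::bind_rows(lapply(g$stenoses, tibble::as_tibble))
  } else NULL
  simulation_config(
    geometry = artery_spec(g$length_mm, g$lumen_radius_mm, g$wall_thickness_mm,
                           sten, g$edge_length_mm, seed = g$seed),
    patient = do.call(patient_boundary_data, lst$patient[
      setdiff(names(lst$patient), character(0))]),
    kinetics = do.call(kinetic_parameters, lst$kinetics),
    endothelium = do.call(endothelial_parameters, lst$endothelium),
    wall = do.call(porous_wall_properties, lst$wall),
    blood = do.call(blood_properties, lst$blood),
    volumes = do.call(cellular_volumes, lst$volumes),
    material = do.call(wall_material, lst$material),
    growth_mode = lst$growth_mode,
    dv_cap = lst$dv_cap,
    macro_step_months = lst$macro_step_months,
    seed = lst$seed
  )
}

#' Run the full three-level plaque-growth simulation
#'
#' Orchestrates the pipeline end to end, one-way coupled:
#' (1) steady lumen flow and endothelial shear stress; (2) per-face
#' endothelial transport state and transmural Darcy filtration; (3) monthly
#' species marching over the interscan period; (4) plaque volume ratio,
#' directional strain and wall thickening applied once at the end; (5)
#' baseline-versus-deformed sub-segment morphometrics. The flow is never
#' re-solved on the deformed geometry.
#'
#' @param config A [simulation_config()].
#' @param keep_fields Keep full per-cell species fields in the result.
#' @return An object of class `simulation_result` with components `mesh`,
#'   `flow`, `ess`, `endo`, `wall_flow`, `species` (final state), `series`
#'   (monthly means), `growth`, `comparison` and `provenance`. If
#'   `config$out_dir` is set, VTK/CSV/JSON artifacts and a manifest are
#'   written there.
#' @export
run_plaque_growth <- function(config, keep_fields = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  pt <- config$patient
  kp <- config$kinetics
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  mesh <- stage("geometry", generate_synthetic_artery(config$geometry))
  flow <- stage("hemodynamics", solve_lumen_flow(
    mesh, config$blood, pt$inlet_mean_velocity_m_s,
    mmhg_to_pa(pt$outlet_pressure_mmhg)))
  ess <- stage("hemodynamics", compute_ess(flow, mesh))
  p_adv <- mmhg_to_pa(if (pt$hypertensive) {
    kp$adventitia_pressure_hypertensive_mmhg
  } else {
    kp$adventitia_pressure_normal_mmhg
  })
  c_ldl <- mg_dl_to_mol_m3(pt$serum_ldl_mg_dl, pt$ldl_molar_mass_kg_mol)
  c_hdl <- mg_dl_to_mol_m3(pt$serum_hdl_mg_dl, pt$hdl_molar_mass_kg_mol)
  p_lumen_face <- stats::approx(mm_to_m(mesh$z_mm), flow$p_z_pa,
                                xout = mm_to_m(ess$z_mm))$y
  endo <- stage("endothelium", endothelial_state(
    ess, config$endothelium, p_lumen_face, p_adv,
    c_ldl, c_hdl, pt$blood_monocytes_per_m3))
  wall_flow <- stage("wall_flow", solve_plasma_flow(
    mesh, config$wall,
    endothelial_bc = list(type = "velocity", value = endo$j_v_m_s),
    adventitia_pressure_pa = p_adv))
  coef_adv <- if (pt$hypertensive) {
    kp$adventitia_ldl_coef_hypertensive
  } else {
    kp$adventitia_ldl_coef_normal
  }
  bc <- species_bc(c_ldl, c_hdl, pt$blood_monocytes_per_m3,
                   adventitia = list(ldl = coef_adv * c_ldl,
                                     hdl = coef_adv * c_hdl))
  st <- species_state(mesh, kp)
  sim <- stage("inflammation", simulate_species(
    st, mesh, wall_flow, endo, kp, config$endothelium, bc,
    duration_s = years_to_seconds(pt$interscan_period_years),
    macro_step_s = months_to_seconds(config$macro_step_months),
    porosity = config$wall$porosity))
  dv <- stage("growth", plaque_volume_ratio(sim$state, config$volumes,
                                            cap = config$dv_cap))
  growth <- stage("growth", apply_wall_thickening(
    mesh, directional_strain(dv), config$material, mode = config$growth_mode))
  comparison <- stage("morphometrics",
                      compare_geometries(mesh, growth$deformed))
  provenance <- list(
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("atherosim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed
  )
  res <- structure(list(
    mesh = mesh, flow = flow, ess = ess, endo = endo, wall_flow = wall_flow,
    species = if (keep_fields) sim$state else NULL,
    series = sim$series, dv_over_v = dv, growth = growth,
    comparison = comparison, config = config, provenance = provenance
  ), class = "simulation_result")
  if (!is.null(config$out_dir)) write_result_artifacts(res, config$out_dir)
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>\n")
  cat(sprintf("  %d monthly steps, ESS %.3g..%.3g Pa\n",
              max(x$series$month), min(x$ess$ess_pa), max(x$ess$ess_pa)))
  print(x$comparison$summary)
  invisible(x)
}

#' @export
glance.simulation_result <- function(x, ...) {
  s <- x$comparison$summary
  tibble::tibble(
    months = max(x$series$month),
    mean_ess_pa = mean(x$ess$ess_pa),
    lumen_area_change_mm2 = s$mean_change[s$metric == "lumen_area"],
    wall_area_change_mm2 = s$mean_change[s$metric == "wall_area"],
    plaque_burden_change_pct = s$mean_change[s$metric == "plaque_burden"],
    config_hash = x$provenance$config_hash
  )
}

# write VTK fields, CSV summaries and a JSON manifest for a finished run
write_result_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  nz <- length(res$mesh$z_mm) - 1L
  n_lum <- nz * (ncol(res$mesh$lumen_r_mm) - 1L)
  pad <- function(wall_vec) c(rep(NA_real_, n_lum), wall_vec)
  cd <- list(dv_over_v = pad(as.vector(res$dv_over_v)))
  for (sp in colnames(res$species)) cd[[sp]] <- pad(res$species[, sp])
  cd <- lapply(cd, function(v) ifelse(is.na(v), -1, v))
  paths$baseline_vtk <- file.path(out_dir, "baseline.vtk")
  write_vtk(res$mesh, paths$baseline_vtk, cell_data = cd)
  paths$deformed_vtk <- file.path(out_dir, "deformed.vtk")
  write_vtk(res$growth$deformed, paths$deformed_vtk)
  paths$endothelium_csv <- file.path(out_dir, "endothelial_state.csv")
  utils::write.csv(res$endo, paths$endothelium_csv, row.names = FALSE)
  paths$ess_csv <- file.path(out_dir, "ess.csv")
  utils::write.csv(res$ess, paths$ess_csv, row.names = FALSE)
  paths$segments_csv <- file.path(out_dir, "segments.csv")
  utils::write.csv(res$comparison$segments, paths$segments_csv, row.names = FALSE)
  paths$series_csv <- file.path(out_dir, "species_series.csv")
  utils::write.csv(res$series, paths$series_csv, row.names = FALSE)
  paths$summary_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(summary = res$comparison$summary,
                            provenance = res$provenance),
                       paths$summary_json, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    created = res$provenance$timestamp,
    config_hash = res$provenance$config_hash,
    package_version = res$provenance$package_version,
    files = lapply(paths, function(p) list(path = basename(p),
                                           config_hash = res$provenance$config_hash))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Bundled demo configuration: stenosed coronary segment, cohort-mean patient
#'
#' A 30 mm segment with one 40 percent Gaussian stenosis at mid-length and
#' the printed-default model parameters; patient boundary data are the
#' cohort means (LDL 108.16, HDL 55.96 mg/dL, interscan period 6.1 years).
#'
#' @param edge_length_mm Mesh resolution (default 0.25 mm demo resolution).
#' @param interscan_period_years Simulated horizon.
#' @return A [simulation_config()].
#' @export
demo_config <- function(edge_length_mm = 0.25, interscan_period_years = 6.1) {
  simulation_config(
    geometry = artery_spec(
      length_mm = 30, lumen_radius_mm = 1.5, wall_thickness_mm = 0.75,
      stenoses = tibble::tibble(position_mm = 15, depth_fraction = 0.4,
                                width_mm = 2),
      edge_length_mm = edge_length_mm),
    patient = patient_boundary_data(
      interscan_period_years = interscan_period_years)
  )
}
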