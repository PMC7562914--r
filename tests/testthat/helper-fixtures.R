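# shared fixtures, computed once per test run and cached
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

straight_mesh <- function(edge = 0.25) {
  fixture(paste0("straight_", edge),
          generate_synthetic_artery(artery_spec(edge_length_mm = edge)))
}

stenosed_spec <- function(edge = 0.25) {
  artery_spec(stenoses = tibble::tibble(position_mm = 15, depth_fraction = 0.4,
                                        width_mm = 2),
              edge_length_mm = edge)
}

stenosed_mesh <- function(edge = 0.25) {
  fixture(paste0("stenosed_", edge),
          generate_synthetic_artery(stenosed_spec(edge)))
}

straight_flow <- function(edge = 0.25, v = 0.2) {
  fixture(paste0("flow_", edge, "_", v),
          solve_lumen_flow(straight_mesh(edge), inlet_mean_velocity = v))
}

# kinetic parameters with all diffusivities zeroed (pure-reaction runs)
reaction_only_params <- function(...) {
  kinetic_parameters(D_LDL_wall = 0, D_HDL_wall = 0, D_OxLDL_wall = 0,
                     D_cytokine_wall = 0, D_monocyte = 0,
                     D_macrophage_wall = 0, ...)
}

# a uniform-shear endothelial state for driving the species system directly
uniform_endo_state <- function(mesh, wss = 1, p_lumen = 13332, p_adv = 2333,
                               c_ldl = 2.8e-3, c_hdl = 3.2e-3, c_mono = 5e11,
                               ep = endothelial_parameters()) {
  wssf <- compute_ess(solve_lumen_flow(mesh, inlet_mean_velocity = 0))
  wssf$ess_pa <- rep(wss, nrow(wssf))
  endothelial_state(wssf, ep, p_lumen, p_adv, c_ldl, c_hdl, c_mono)
}

# the bundled demo run (shared by the mechanism and morphometric checks)
demo_result <- function() {
  fixture("demo_result", run_plaque_growth(demo_config()))
}

# per-3mm-segment means of a wall cell field and of the ESS field
segment_mean_field <- function(res, field) {
  st <- res$species
  dims <- attr(st, "dims")
  f <- matrix(st[, field], dims["nz"], dims["nr"])
  zc <- (res$mesh$z_mm[-1] + res$mesh$z_mm[-length(res$mesh$z_mm)]) / 2
  seg <- pmin(floor(zc / 3) + 1, 10)
  tapply(rowMeans(f), seg, mean)
}

segment_mean_ess <- function(res) {
  seg <- pmin(floor(res$ess$z_mm / 3) + 1, 10)
  tapply(res$ess$ess_pa, seg, mean)
}
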