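#' @keywords internal
species_names <- function() {
  c("ldl", "hdl", "oxldl", "monocytes", "macrophages", "foam",
    "cytokines", "csmc", "ssmc", "collagen")
}

#' Wall species state
#'
#' Ten concentration fields on the wall cells: LDL, HDL, OxLDL (mol/m^3),
#' monocytes, macrophages, foam cells, contractile and synthetic SMCs
#' (cells/m^3), cytokines (mol/m^3) and collagen (g/m^3). Contractile SMCs
#' start at their intima concentration, everything else at zero.
#'
#' @param mesh An `artery_mesh`.
#' @param params A [kinetic_parameters()].
#' @return An object of class `species_state`: a matrix (wall cells x 10
#'   species) with attributes `dims` (nz, nr) and `time_s`.
#' @export
species_state <- function(mesh, params = kinetic_parameters()) {
  nz <- length(mesh$z_mm) - 1L
  nr <- ncol(mesh$wall_r_mm) - 1L
  C <- matrix(0, nz * nr, 10, dimnames = list(NULL, species_names()))
  C[, "csmc"] <- params$c_SMC_0
  structure(C, dims = c(nz = nz, nr = nr), time_s = 0,
            class = c("species_state", "matrix", "array"))
}

#' @export
print.species_state <- function(x, ...) {
  cat("<species_state>", nrow(x), "wall cells, t =",
      format(attr(x, "time_s") / 86400, digits = 4), "days\n")
  m <- colMeans(x)
  for (nm in names(m)) cat(sprintf("  %-12s mean %.4g\n", nm, m[nm]))
  invisible(x)
}

#' Mean concentration of each species, as a tibble
#' @param x A `species_state`.
#' @param ... Unused.
#' @return One row per species with mean/min/max over wall cells.
#' @export
tidy.species_state <- function(x, ...) {
  tibble::tibble(
    species = colnames(x),
    mean = colMeans(x),
    min = apply(x, 2, min),
    max = apply(x, 2, max),
    time_s = attr(x, "time_s")
  )
}

#' HDL protection factor for LDL oxidation
#'
#' Relative reduction of the LDL oxidation rate due to HDL:
#' `-3e-5 c_LDL^2 + 5e-4 c_LDL + 1.0056`, floored at 0.
#'
#' @param c_ldl LDL concentration, mol/m^3 (>= 0).
#' @return Dimensionless protection factor.
#' @export
hdl_protection <- function(c_ldl) {
  if (any(c_ldl < 0)) stop("c_LDL must be >= 0")
  pmax(-3e-5 * c_ldl^2 + 5e-4 * c_ldl + 1.0056, 0)
}

#' Pointwise reaction source terms of the inflammation network
#'
#' Right-hand sides of the ten species equations (porosity-scaled, i.e. the
#' rates of `gamma * c`): HDL-protected LDL/HDL oxidation, OxLDL production
#' and macrophage uptake, monocyte apoptosis and differentiation, foam-cell
#' formation, cytokine turnover, cytokine-driven contractile-to-synthetic
#' SMC switching (which conserves total SMC), and collagen secretion and
#' degradation. The OxLDL production term deliberately excludes the HDL
#' protection factor, mirroring the printed source/sink asymmetry.
#'
#' @param state A `species_state`, or any matrix / data frame with the ten
#'   species columns.
#' @param params A [kinetic_parameters()].
#' @param porosity Wall porosity gamma.
#' @return A matrix of source terms, one column per species, units
#'   d(gamma c)/dt.
#' @export
reaction_rhs <- function(state, params = kinetic_parameters(), porosity = 0.96) {
  C <- as.matrix(as.data.frame(unclass(state))[, species_names(), drop = FALSE])
  if (any(C < 0)) stop("negative input concentration in reaction_rhs")
  g <- porosity
  prot <- hdl_protection(C[, "ldl"])
  r_sw <- params$base_switch_rate_per_s *
    (1 + exp(-params$S_r * C[, "cytokines"] / params$c_c_max))
  out <- cbind(
    ldl = -g * prot * params$r_LDL * C[, "ldl"],
    hdl = -g * prot * params$r_HDL * C[, "hdl"],
    oxldl = g * params$r_LDL * C[, "ldl"] -
      g * params$k_2 * C[, "oxldl"] * C[, "macrophages"],
    monocytes = -g * (params$m_d + params$d_m) * C[, "monocytes"],
    macrophages = g * params$d_m * C[, "monocytes"] -
      g * params$k_1 * C[, "oxldl"] * C[, "macrophages"],
    foam = g * params$k_1 * C[, "oxldl"] * C[, "macrophages"],
    cytokines = -g * params$d_c * C[, "cytokines"] +
      g * params$d_r * C[, "oxldl"] * C[, "macrophages"],
    csmc = -g * r_sw * C[, "csmc"],
    ssmc = g * r_sw * C[, "csmc"],
    collagen = g * params$g_r * C[, "ssmc"] - g * params$d_g * C[, "collagen"]
  )
  out
}

# exact update of dc/dt = S - lam*c over dt; returns c(dt) and int_0^dt c
lin_step <- function(c0, S, lam, dt) {
  n <- max(length(c0), length(S), length(lam))
  c0 <- rep_len(c0, n)
  S <- rep_len(S, n)
  lam <- rep_len(lam, n)
  x <- lam * dt
  small <- x < 1e-10
  E <- exp(-x)
  c1 <- ifelse(small,
               c0 + (S - lam * c0) * dt,
               S / ifelse(lam > 0, lam, 1) * (1 - E) + c0 * E)
  intc <- ifelse(small,
                 c0 * dt + (S - lam * c0) * dt^2 / 2,
                 (S * dt - (c1 - c0)) / ifelse(lam > 0, lam, 1))
  list(c1 = pmax(c1, 0), int = pmax(intc, 0))
}

# one semi-analytic reaction substep over dt for all cells.
# C: cells x species; src: volumetric source rates dc/dt (same shape or NULL);
# frozen: character vector of species held fixed.
react_step <- function(C, params, dt, src = NULL, frozen = character(0)) {
  if (is.null(src)) src <- matrix(0, nrow(C), 10, dimnames = list(NULL, colnames(C)))
  C0 <- C
  prot <- hdl_protection(C[, "ldl"])
  # LDL / HDL with protection-scaled first-order oxidation
  L <- lin_step(C[, "ldl"], src[, "ldl"], prot * params$r_LDL, dt)
  H <- lin_step(C[, "hdl"], src[, "hdl"], prot * params$r_HDL, dt)
  # monocytes: apoptosis + differentiation, exact partition into macrophages
  lam_mono <- params$m_d + params$d_m
  Mo <- lin_step(C[, "monocytes"], src[, "monocytes"], lam_mono, dt)
  G_mac <- params$d_m * Mo$int / dt
  # macrophages with frozen OxLDL partner; uptake routed exactly to foam
  lam_mac <- params$k_1 * C[, "oxldl"]
  Ma <- lin_step(C[, "macrophages"], G_mac, lam_mac, dt)
  foam_gain <- pmax(G_mac * dt - (Ma$c1 - C[, "macrophages"]), 0)
  mac_mean <- Ma$int / dt
  # OxLDL: production from integrated LDL decay (no protection factor, as
  # printed), uptake with mean macrophage level
  S_ox <- params$r_LDL * L$int / dt + src[, "oxldl"]
  Ox <- lin_step(C[, "oxldl"], S_ox, params$k_2 * mac_mean, dt)
  ox_mean <- Ox$int / dt
  # cytokines
  Cy <- lin_step(C[, "cytokines"], params$d_r * ox_mean * mac_mean +
                   src[, "cytokines"], params$d_c, dt)
  # SMC phenotype switch: exact transfer, conserves total SMC
  r_sw <- params$base_switch_rate_per_s *
    (1 + exp(-params$S_r * C[, "cytokines"] / params$c_c_max))
  f <- exp(-r_sw * dt)
  csmc1 <- C[, "csmc"] * f
  ssmc1 <- C[, "ssmc"] + C[, "csmc"] * (1 - f)
  # collagen from mean synthetic SMC level
  Co <- lin_step(C[, "collagen"],
                 params$g_r * (C[, "ssmc"] + ssmc1) / 2 + src[, "collagen"],
                 params$d_g, dt)
  C[, "ldl"] <- L$c1; C[, "hdl"] <- H$c1; C[, "oxldl"] <- Ox$c1
  C[, "monocytes"] <- Mo$c1; C[, "macrophages"] <- Ma$c1
  C[, "foam"] <- C[, "foam"] + foam_gain
  C[, "cytokines"] <- Cy$c1
  C[, "csmc"] <- csmc1; C[, "ssmc"] <- ssmc1; C[, "collagen"] <- Co$c1
  if (length(frozen)) C[, frozen] <- C0[, frozen]
  C
}

#' Species boundary conditions
#'
#' Lumen-side concentrations feeding the endothelial fluxes and the
#' adventitial Dirichlet values. `adventitia = NULL` seals the outer
#' boundary (used for conservation checks); otherwise LDL and HDL are held
#' at `coefficient x lumen concentration` there.
#'
#' @param c_ldl_lumen,c_hdl_lumen Lumen concentrations, mol/m^3.
#' @param c_mono_lumen Blood monocytes, cells/m^3.
#' @param adventitia Named list with `ldl` and `hdl` values (mol/m^3), or
#'   `NULL` for a sealed adventitia.
#' @param endothelium_sealed If `TRUE`, no endothelial fluxes are applied.
#' @return A `species_bc` list.
#' @export
species_bc <- function(c_ldl_lumen = 0, c_hdl_lumen = 0, c_mono_lumen = 0,
                       adventitia = NULL, endothelium_sealed = FALSE) {
  structure(list(c_ldl_lumen = c_ldl_lumen, c_hdl_lumen = c_hdl_lumen,
                 c_mono_lumen = c_mono_lumen, adventitia = adventitia,
                 endothelium_sealed = endothelium_sealed),
            class = "species_bc")
}

# build the finite-volume transport operators for the wall grid:
# conservative diffusion matrices (per diffusivity), upwind advection from
# the Darcy face fluxes, endothelial face areas and cell volumes.
build_transport_ops <- function(mesh, wall_flow, params, porosity) {
  rw <- mm_to_m(mesh$wall_r_mm)
  z <- mm_to_m(mesh$z_mm)
  nz <- length(z) - 1L
  nr <- ncol(rw) - 1L
  dz <- diff(z)
  r_face <- (rw[-1, , drop = FALSE] + rw[-(nz + 1L), , drop = FALSE]) / 2
  r_cell <- (r_face[, -1, drop = FALSE] + r_face[, -(nr + 1L), drop = FALSE]) / 2
  cid <- function(i, j) i + (j - 1L) * nz
  V <- numeric(nz * nr)
  for (j in seq_len(nr)) {
    V[cid(seq_len(nz), j)] <- pi * (r_face[, j + 1L]^2 - r_face[, j]^2) * dz
  }
  # unit-diffusivity conservative Laplacian (multiply by species D)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(a, b, v) { ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v) }
  for (j in seq_len(nr - 1L)) {
    Tr <- 2 * pi * dz / log(r_cell[, j + 1L] / r_cell[, j])
    a <- cid(seq_len(nz), j); b <- cid(seq_len(nz), j + 1L)
    add(a, a, -Tr / V[a]); add(a, b, Tr / V[a])
    add(b, b, -Tr / V[b]); add(b, a, Tr / V[b])
  }
  for (j in seq_len(nr)) {
    i <- seq_len(nz - 1L)
    rin <- (r_face[i, j] + r_face[i + 1L, j]) / 2
    rout <- (r_face[i, j + 1L] + r_face[i + 1L, j + 1L]) / 2
    Az <- pi * (rout^2 - rin^2)
    Tz <- Az / ((dz[i] + dz[i + 1L]) / 2)
    a <- cid(i, j); b <- cid(i + 1L, j)
    add(a, a, -Tz / V[a]); add(a, b, Tz / V[a])
    add(b, b, -Tz / V[b]); add(b, a, Tz / V[b])
  }
  Lap1 <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nz * nr, nz * nr))
  # adventitia Dirichlet exchange (unit diffusivity): rate and value slot
  T_adv <- 2 * pi * dz / log(r_face[, nr + 1L] / r_cell[, nr])
  adv_cells <- cid(seq_len(nz), nr)
  # advection: face volumetric flows (m^3/s), intrinsic velocity = U/porosity
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  if (!is.null(wall_flow)) {
    for (j in 2:nr) {  # internal radial faces
      q <- wall_flow$u_r_face[, j] * 2 * pi * r_face[, j] * dz / porosity
      a <- cid(seq_len(nz), j - 1L); b <- cid(seq_len(nz), j)
      qp <- pmax(q, 0); qm <- pmin(q, 0)  # + outward a->b
      add(a, a, -qp / V[a]); add(b, a, qp / V[b])
      add(b, b, qm / V[b]); add(a, b, -qm / V[a])
    }
    for (j in seq_len(nr)) {  # internal axial faces
      i <- seq_len(nz - 1L)
      rin <- (r_face[i, j] + r_face[i + 1L, j]) / 2
      rout <- (r_face[i, j + 1L] + r_face[i + 1L, j + 1L]) / 2
      Az <- pi * (rout^2 - rin^2)
      q <- wall_flow$u_z_face[i + 1L, j] * Az / porosity
      a <- cid(i, j); b <- cid(i + 1L, j)
      qp <- pmax(q, 0); qm <- pmin(q, 0)
      add(a, a, -qp / V[a]); add(b, a, qp / V[b])
      add(b, b, qm / V[b]); add(a, b, -qm / V[a])
    }
    # adventitia outflow carries the cell concentration out
    q_out <- pmax(wall_flow$u_r_face[, nr + 1L], 0) * 2 * pi *
      r_face[, nr + 1L] * dz / porosity
    add(adv_cells, adv_cells, -q_out / V[adv_cells])
  }
  Adv1 <- Matrix::sparseMatrix(i = if (length(ii)) ii else 1,
                               j = if (length(jj)) jj else 1,
                               x = if (length(xx)) xx else 0,
                               dims = c(nz * nr, nz * nr))
  A_endo <- 2 * pi * r_face[, 1] * dz
  endo_cells <- cid(seq_len(nz), 1L)
  list(nz = nz, nr = nr, V = V, Lap1 = Lap1, Adv1 = Adv1,
       T_adv = T_adv, adv_cells = adv_cells,
       A_endo = A_endo, endo_cells = endo_cells)
}

# per-species diffusivities, m^2/s
species_diffusivities <- function(params) {
  c(ldl = params$D_LDL_wall, hdl = params$D_HDL_wall,
    oxldl = params$D_OxLDL_wall, monocytes = params$D_monocyte,
    macrophages = params$D_macrophage_wall, foam = 0,
    cytokines = params$D_cytokine_wall, csmc = 0, ssmc = 0, collagen = 0)
}

advected_species <- function() c("ldl", "hdl", "oxldl")

#' Advance the wall species system by one macro time step
#'
#' Operator-split update over `dt_s`: explicit conservative finite-volume
#' diffusion (and upwind porous advection for the lipoproteins), endothelial
#' Kedem-Katchalsky boundary sources, adventitial Dirichlet exchange for
#' LDL/HDL, and the reaction network integrated by an exact-linear
#' (exponential) scheme. The macro step is subdivided automatically to
#' satisfy the explicit stability limits and a splitting-accuracy cap; all
#' updates preserve nonnegativity.
#'
#' @param state A `species_state`.
#' @param mesh The `artery_mesh` the state lives on.
#' @param wall_flow A [solve_plasma_flow()] result (or `NULL` for no
#'   advection).
#' @param endo An [endothelial_state()] (or `NULL` for sealed endothelium).
#' @param params A [kinetic_parameters()].
#' @param endo_params An [endothelial_parameters()] (for the flux formulas
#'   re-evaluated against the evolving wall concentrations).
#' @param bc A [species_bc()].
#' @param dt_s Macro step length, s (> 0).
#' @param porosity Wall porosity gamma.
#' @param frozen Character vector of species held fixed (diagnostics).
#' @param ops Transport operators from a previous call (performance).
#' @param max_substeps Error guard on the automatic subdivision.
#' @return The advanced `species_state`.
#' @export
step_species <- function(state, mesh, wall_flow = NULL, endo = NULL,
                         params = kinetic_parameters(),
                         endo_params = endothelial_parameters(),
                         bc = species_bc(), dt_s,
                         porosity = 0.96, frozen = character(0),
                         ops = NULL, max_substeps = 1e6) {
  stopifnot(dt_s > 0)
  if (is.null(ops)) ops <- build_transport_ops(mesh, wall_flow, params, porosity)
  C <- unclass(state)
  attrs <- attributes(state)
  D <- species_diffusivities(params)
  # stability limits
  diag_lap <- -Matrix::diag(ops$Lap1)
  dt_diff <- 0.8 / max(diag_lap * max(D), 1e-30)
  diag_adv <- -pmin(Matrix::diag(ops$Adv1), 0)
  dt_adv <- if (max(diag_adv) > 0) 0.8 / max(diag_adv) else Inf
  dt_sub <- min(dt_diff, dt_adv, 21600, dt_s)
  n_sub <- ceiling(dt_s / dt_sub)
  if (n_sub > max_substeps) {
    stop(sprintf("stability requires %d substeps (> %d); refine dt or mesh",
                 n_sub, max_substeps))
  }
  h <- dt_s / n_sub
  nz <- ops$nz
  ec <- ops$endo_cells
  sf <- ops$A_endo / (porosity * ops$V[ec])  # face source scale, 1/m
  k_m_mmhg <- endo_params$k_m_um / endo_params$o2_solubility_um_per_mmhg
  m_r_s <- endo_params$m_r_m3_mol_day / 86400
  for (s in seq_len(n_sub)) {
    # transport (explicit, conservative)
    Cprev <- C
    Cn <- C
    for (sp in colnames(C)) {
      if (D[[sp]] > 0) {
        Cn[, sp] <- Cn[, sp] + h * D[[sp]] * as.numeric(ops$Lap1 %*% C[, sp])
      }
      if (sp %in% advected_species() && !is.null(wall_flow)) {
        Cn[, sp] <- Cn[, sp] + h * as.numeric(ops$Adv1 %*% C[, sp])
      }
    }
    # adventitia Dirichlet exchange for lipoproteins
    if (!is.null(bc$adventitia)) {
      for (sp in intersect(names(bc$adventitia), colnames(C))) {
        Cn[ops$adv_cells, sp] <- Cn[ops$adv_cells, sp] +
          h * D[[sp]] * ops$T_adv / (porosity * ops$V[ops$adv_cells]) *
            porosity * (bc$adventitia[[sp]] - C[ops$adv_cells, sp])
      }
    }
    Cn <- pmax(Cn, 0)
    # endothelial sources (Kedem-Katchalsky, re-evaluated on current state)
    src <- matrix(0, nrow(C), 10, dimnames = list(NULL, colnames(C)))
    if (!is.null(endo) && !isTRUE(bc$endothelium_sealed)) {
      dp_perm <- endo$dp_m_s
      jv <- endo$j_v_m_s
      cw_l <- Cn[ec, "ldl"]; cw_h <- Cn[ec, "hdl"]; cw_ox <- Cn[ec, "oxldl"]
      js_l <- solute_flux(dp_perm, bc$c_ldl_lumen - cw_l, endo_params$sigma_f,
                          jv, (bc$c_ldl_lumen + cw_l) / 2)
      js_h <- solute_flux(dp_perm, bc$c_hdl_lumen - cw_h, endo_params$sigma_f,
                          jv, (bc$c_hdl_lumen + cw_h) / 2)
      jm <- monocyte_flux(endo$wss_pa, cw_ox, bc$c_mono_lumen, m_r_s,
                          endo_params$wss0_pa)
      src[ec, "ldl"] <- js_l * sf
      src[ec, "hdl"] <- js_h * sf
      src[ec, "monocytes"] <- jm * sf
    }
    C <- react_step(Cn, params, h, src = src, frozen = frozen)
    if (length(frozen)) C[, frozen] <- Cprev[, frozen]
    if (anyNA(C)) stop("NaN encountered in species update")
  }
  attrs$time_s <- attrs$time_s + dt_s
  attributes(C) <- attrs
  C
}

#' Well-mixed (0-D) reaction integrator
#'
#' Integrates the reaction network plus lumped boundary source rates with
#' adaptive error control (deSolve::lsoda, relative tolerance 1e-8). Serves
#' as the independent oracle for the spatial reaction operator.
#'
#' @param params A [kinetic_parameters()].
#' @param boundary_fluxes Named numeric vector of constant volumetric source
#'   rates (units of dc/dt), or `function(t, c)` returning such a vector, or
#'   `NULL`.
#' @param duration_s Integration time, s (> 0).
#' @param init Named initial concentrations; defaults to the standard
#'   initial state (contractile SMCs at their intima concentration).
#' @param porosity Wall porosity gamma.
#' @param frozen Character vector of species held fixed.
#' @param n_out Number of output times.
#' @param rtol Relative tolerance.
#' @return A tibble: `time_s` plus one column per species.
#' @export
simulate_wellmixed <- function(params = kinetic_parameters(),
                               boundary_fluxes = NULL, duration_s,
                               init = NULL, porosity = 0.96,
                               frozen = character(0), n_out = 200,
                               rtol = 1e-8) {
  stopifnot(duration_s > 0)
  y0 <- stats::setNames(rep(0, 10), species_names())
  y0["csmc"] <- params$c_SMC_0
  if (!is.null(init)) y0[names(init)] <- unlist(init)
  fluxfun <- if (is.null(boundary_fluxes)) {
    function(t, c) NULL
  } else if (is.function(boundary_fluxes)) {
    boundary_fluxes
  } else {
    function(t, c) boundary_fluxes
  }
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    rates <- reaction_rhs(matrix(y, 1, dimnames = list(NULL, species_names())),
                          params, porosity)[1, ] / porosity
    fl <- fluxfun(t, y)
    if (!is.null(fl)) rates[names(fl)] <- rates[names(fl)] + fl
    if (length(frozen)) rates[frozen] <- 0
    list(rates)
  }
  times <- seq(0, duration_s, length.out = n_out + 1)
  # near-pure relative control: species magnitudes span ~20 decades
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = 1e-25)
  res <- tibble::as_tibble(as.data.frame(out))
  names(res)[1] <- "time_s"
  if (attr(out, "istate")[1] < 0) stop("well-mixed integrator failed")
  res
}

#' March the species system over the simulation horizon
#'
#' Repeated [step_species()] macro steps (monthly by default), recording the
#' per-species wall means after each step.
#'
#' @inheritParams step_species
#' @param duration_s Total simulated time, s.
#' @param macro_step_s Macro step, s (default one month).
#' @return A list: final `state` and a tibble `series` (month, time_s, one
#'   column per species mean).
#' @export
simulate_species <- function(state, mesh, wall_flow, endo,
                             params = kinetic_parameters(),
                             endo_params = endothelial_parameters(),
                             bc = species_bc(), duration_s,
                             macro_step_s = months_to_seconds(1),
                             porosity = 0.96) {
  ops <- build_transport_ops(mesh, wall_flow, params, porosity)
  n_steps <- max(1L, round(duration_s / macro_step_s))
  rows <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    state <- step_species(state, mesh, wall_flow, endo, params, endo_params,
                          bc, dt_s = macro_step_s, porosity = porosity,
                          ops = ops)
    rows[[k]] <- tibble::tibble(month = k, time_s = attr(state, "time_s"),
                                !!!as.list(colMeans(state)))
  }
  list(state = state, series = dplyr::bind_rows(rows))
}
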