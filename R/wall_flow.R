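#' Area porosity tensor
#'
#' For an isotropic porous medium of volume porosity `gamma`, the area
#' porosity tensor is `K^ij = gamma * delta^ij`.
#'
#' @param gamma Volume porosity in (0, 1].
#' @return A 3x3 diagonal matrix.
#' @export
area_porosity_tensor <- function(gamma) {
  if (!(is.numeric(gamma) && length(gamma) == 1 && gamma > 0 && gamma <= 1)) {
    stop("porosity gamma must be a single number in (0, 1]")
  }
  diag(gamma, 3)
}

#' Transmural plasma filtration through the porous wall (Darcy limit)
#'
#' Solves the steady pressure problem `div( (K_perm/mu) grad p ) = 0` on the
#' wall annulus by a conservative finite-volume scheme with exact radial
#' two-point transmissibilities (`T = k 2 pi dz / ln(r2/r1)`), so pure
#' radial filtration reproduces the analytic cylindrical solution to
#' round-off. The Darcy velocity is `U = -(K_perm/mu) grad p` by
#' construction.
#'
#' Boundary conditions: a prescribed filtration velocity (from the
#' Kedem-Katchalsky volume flux) or a prescribed pressure on the
#' endothelium; prescribed pressure on the adventitia (or sealed); zero
#' normal flow on the wall ends.
#'
#' @param mesh An `artery_mesh`.
#' @param props A [porous_wall_properties()].
#' @param endothelial_bc A list: `list(type = "velocity", value = v)` with
#'   `v` the inward filtration velocity (m/s, positive into the wall) per
#'   endothelial face (length 1 or nz), or `list(type = "pressure",
#'   value = p_pa)`.
#' @param adventitia_pressure_pa Adventitia pressure, Pa, or `NULL` to seal
#'   the adventitia (then a nonzero net endothelial inflow is inconsistent
#'   and raises an error).
#' @return An object of class `wall_flow_solution`: cell pressures `p_pa`
#'   (nz x nr matrix), radial face velocities `u_r_face` (nz x (nr+1), m/s,
#'   positive outward), cell-centred velocity magnitudes, and flux
#'   summaries.
#' @export
solve_plasma_flow <- function(mesh, props = porous_wall_properties(),
                              endothelial_bc = list(type = "velocity", value = 0),
                              adventitia_pressure_pa = mmhg_to_pa(17.5)) {
  stopifnot(inherits(mesh, "artery_mesh"), inherits(props, "porous_wall_properties"))
  k <- props$darcian_permeability_m2 / props$plasma_viscosity_pa_s  # m^2/(Pa s)
  rw <- mm_to_m(mesh$wall_r_mm)       # (nz+1) x (nrw+1) node radii
  z <- mm_to_m(mesh$z_mm)
  nz <- length(z) - 1L
  nr <- ncol(rw) - 1L
  dz <- diff(z)
  # face radii averaged axially; cell representative radii
  r_face <- (rw[-1, , drop = FALSE] + rw[-(nz + 1L), , drop = FALSE]) / 2  # nz x (nr+1)
  r_cell <- (r_face[, -1, drop = FALSE] + r_face[, -(nr + 1L), drop = FALSE]) / 2
  ncell <- nz * nr
  cid <- function(i, j) i + (j - 1L) * nz

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(ncell)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v)
  }
  # radial internal faces between (i,j) and (i,j+1)
  for (j in seq_len(nr - 1L)) {
    i <- seq_len(nz)
    Tr <- k * 2 * pi * dz / log(r_cell[, j + 1L] / r_cell[, j])
    a <- cid(i, j); b <- cid(i, j + 1L)
    add(a, a, Tr); add(a, b, -Tr); add(b, b, Tr); add(b, a, -Tr)
  }
  # axial internal faces between (i,j) and (i+1,j)
  for (j in seq_len(nr)) {
    i <- seq_len(nz - 1L)
    rin <- (r_face[i, j] + r_face[i + 1L, j]) / 2
    rout <- (r_face[i, j + 1L] + r_face[i + 1L, j + 1L]) / 2
    Az <- pi * (rout^2 - rin^2)
    Tz <- k * Az / ((dz[i] + dz[i + 1L]) / 2)
    a <- cid(i, j); b <- cid(i + 1L, j)
    add(a, a, Tz); add(a, b, -Tz); add(b, b, Tz); add(b, a, -Tz)
  }
  # endothelium boundary (inner face of j = 1)
  A_endo <- 2 * pi * r_face[, 1] * dz
  if (identical(endothelial_bc$type, "velocity")) {
    v_in <- rep(endothelial_bc$value, length.out = nz)
    rhs[cid(seq_len(nz), 1L)] <- rhs[cid(seq_len(nz), 1L)] + v_in * A_endo
  } else if (identical(endothelial_bc$type, "pressure")) {
    Tb <- k * 2 * pi * dz / log(r_cell[, 1] / r_face[, 1])
    a <- cid(seq_len(nz), 1L)
    add(a, a, Tb)
    rhs[a] <- rhs[a] + Tb * endothelial_bc$value
  } else {
    stop("endothelial_bc$type must be \"velocity\" or \"pressure\"")
  }
  # adventitia boundary (outer face of j = nr)
  sealed <- is.null(adventitia_pressure_pa)
  if (!sealed) {
    Tb <- k * 2 * pi * dz / log(r_face[, nr + 1L] / r_cell[, nr])
    a <- cid(seq_len(nz), nr)
    add(a, a, Tb)
    rhs[a] <- rhs[a] + Tb * adventitia_pressure_pa
  } else if (identical(endothelial_bc$type, "velocity")) {
    net <- sum(rep(endothelial_bc$value, length.out = nz) * A_endo)
    if (abs(net) > 1e-14 * max(A_endo)) {
      stop("inconsistent boundary data: net endothelial inflow ",
           format(net), " m^3/s with a sealed adventitia and sealed wall ends")
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ncell, ncell))
  if (sealed && identical(endothelial_bc$type, "velocity")) {
    # pure Neumann problem: pin one cell to zero pressure
    A[1, ] <- 0; A[1, 1] <- 1; rhs[1] <- 0
  }
  p <- as.numeric(Matrix::solve(A, rhs))
  pm <- matrix(p, nz, nr)

  # radial face velocities, positive outward (+r)
  u_r_face <- matrix(0, nz, nr + 1L)
  for (j in seq_len(nr - 1L)) {
    Tr <- k * 2 * pi * dz / log(r_cell[, j + 1L] / r_cell[, j])
    q <- Tr * (pm[, j] - pm[, j + 1L])
    u_r_face[, j + 1L] <- q / (2 * pi * r_face[, j + 1L] * dz)
  }
  if (identical(endothelial_bc$type, "velocity")) {
    u_r_face[, 1] <- rep(endothelial_bc$value, length.out = nz)
  } else {
    Tb <- k * 2 * pi * dz / log(r_cell[, 1] / r_face[, 1])
    q <- Tb * (endothelial_bc$value - pm[, 1])
    u_r_face[, 1] <- q / A_endo
  }
  if (!sealed) {
    Tb <- k * 2 * pi * dz / log(r_face[, nr + 1L] / r_cell[, nr])
    q <- Tb * (pm[, nr] - adventitia_pressure_pa)
    u_r_face[, nr + 1L] <- q / (2 * pi * r_face[, nr + 1L] * dz)
  }
  # axial face velocities (nz+1) x nr, positive +z; zero at wall ends
  u_z_face <- matrix(0, nz + 1L, nr)
  for (j in seq_len(nr)) {
    i <- seq_len(nz - 1L)
    rin <- (r_face[i, j] + r_face[i + 1L, j]) / 2
    rout <- (r_face[i, j + 1L] + r_face[i + 1L, j + 1L]) / 2
    Az <- pi * (rout^2 - rin^2)
    Tz <- k * Az / ((dz[i] + dz[i + 1L]) / 2)
    u_z_face[i + 1L, j] <- Tz * (pm[i, j] - pm[i + 1L, j]) / Az
  }
  influx <- sum(u_r_face[, 1] * A_endo)
  outflux <- sum(u_r_face[, nr + 1L] * 2 * pi * r_face[, nr + 1L] * dz)
  structure(list(
    p_pa = pm, u_r_face = u_r_face, u_z_face = u_z_face,
    r_face_m = r_face, r_cell_m = r_cell, dz_m = dz,
    endothelial_influx_m3_s = influx, adventitial_outflux_m3_s = outflux,
    mass_balance_residual = abs(influx - outflux) /
      max(abs(influx), abs(outflux), .Machine$double.xmin),
    props = props
  ), class = "wall_flow_solution")
}

#' @export
print.wall_flow_solution <- function(x, ...) {
  cat("<wall_flow_solution>\n")
  cat(sprintf("  pressure %.4g..%.4g Pa, filtration velocity %.3g..%.3g m/s\n",
              min(x$p_pa), max(x$p_pa), min(x$u_r_face), max(x$u_r_face)))
  cat(sprintf("  mass balance residual %.2e\n", x$mass_balance_residual))
  invisible(x)
}
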