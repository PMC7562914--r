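#' Steady blood flow in the lumen (stream-function / vorticity solver)
#'
#' Solves steady, laminar, incompressible Newtonian flow in the axisymmetric
#' lumen on a body-fitted grid (axial coordinate z, radial fraction
#' eta = r / R(z)) using the Stokes stream function psi and azimuthal
#' vorticity omega:
#' `E^2 psi = -r omega` and the steady vorticity transport equation,
#' iterated (Picard, under-relaxed) with no-slip wall vorticity from a
#' second-order one-sided closure. Mass conservation is identical in this
#' formulation: the volumetric flux through every cross-section equals
#' `2 pi psi_wall` by construction, so the reported continuity residual is
#' the relative inlet/outlet flux imbalance of the reconstructed velocity
#' field's stream function (machine level).
#'
#' Boundary conditions: fully developed (parabolic) or flat inlet profile,
#' prescribed outlet pressure (pressure is recovered as an axial profile
#' from the viscous gradient plus a momentum-flux correction), no-slip
#' impenetrable endothelium, symmetry at the axis.
#'
#' @param mesh An `artery_mesh`.
#' @param props A [blood_properties()] object.
#' @param inlet_mean_velocity Mean inlet velocity, m/s (>= 0; 0 returns the
#'   rest state).
#' @param outlet_pressure_pa Outlet pressure, Pa.
#' @param inlet_profile `"parabolic"` (default) or `"flat"`.
#' @param relax Under-relaxation factor for the vorticity update.
#' @param tol Convergence tolerance on the relative vorticity change.
#' @param max_iter Maximum Picard iterations.
#' @param include_advection Set `FALSE` to solve the Stokes (creeping-flow)
#'   limit.
#' @return An object of class `flow_solution`: velocity components `u_z`,
#'   `u_r` (node matrices, m/s), stream function and vorticity, the axial
#'   pressure profile `p_z_pa`, residuals, and solver diagnostics.
#' @export
solve_lumen_flow <- function(mesh, props = blood_properties(),
                             inlet_mean_velocity = 0.15,
                             outlet_pressure_pa = mmhg_to_pa(100),
                             inlet_profile = c("parabolic", "flat"),
                             relax = 0.5, tol = 1e-6, max_iter = 400L,
                             include_advection = TRUE) {
  stopifnot(inherits(mesh, "artery_mesh"), inherits(props, "blood_properties"))
  inlet_profile <- match.arg(inlet_profile)
  if (inlet_mean_velocity < 0) stop("inlet_mean_velocity must be >= 0")
  z <- mm_to_m(mesh$z_mm)
  R <- mm_to_m(endothelium_radius(mesh))
  Ni <- length(z)
  Nj <- ncol(mesh$lumen_r_mm)
  eta <- mesh$eta_lumen
  mu <- props$viscosity_pa_s
  rho <- props$density_kg_m3
  nu <- mu / rho

  if (inlet_mean_velocity == 0) {
    zero <- matrix(0, Ni, Nj)
    sol <- structure(list(
      mesh = mesh, u_z = zero, u_r = zero, psi = zero, omega = zero,
      p_z_pa = rep(outlet_pressure_pa, Ni),
      mean_velocity = rep(0, Ni), flow_rate_m3_s = 0,
      continuity_residual = 0, momentum_residual = 0,
      iterations = 0L, converged = TRUE, reynolds = 0,
      props = props, outlet_pressure_pa = outlet_pressure_pa
    ), class = "flow_solution")
    return(sol)
  }

  reynolds <- rho * inlet_mean_velocity * 2 * max(R) / mu
  if (reynolds > 2000) {
    warning(sprintf("Reynolds number %.0f exceeds 2000; laminar assumption violated",
                    reynolds))
  }

  sp <- stats::splinefun(z, R, method = "natural")
  Rp <- sp(z, deriv = 1)
  Rpp <- sp(z, deriv = 2)

  dz <- z[2] - z[1]
  de <- eta[2] - eta[1]
  ops <- fd_ops(Ni, dz)
  opse <- fd_ops(Nj, de)
  I_i <- Matrix::Diagonal(Ni)
  I_j <- Matrix::Diagonal(Nj)
  DZ  <- Matrix::kronecker(I_j, ops$D1)
  DZZ <- Matrix::kronecker(I_j, ops$D2)
  DZb <- Matrix::kronecker(I_j, ops$D1b)
  DZf <- Matrix::kronecker(I_j, ops$D1f)
  DE  <- Matrix::kronecker(opse$D1, I_i)
  DEE <- Matrix::kronecker(opse$D2, I_i)
  DEb <- Matrix::kronecker(opse$D1b, I_i)
  DEf <- Matrix::kronecker(opse$D1f, I_i)

  Rv   <- rep(R, Nj)
  Rpv  <- rep(Rp, Nj)
  Rppv <- rep(Rpp, Nj)
  etav <- rep(eta, each = Ni)
  rv   <- etav * Rv
  av   <- -etav * Rpv / Rv
  bv   <- etav * (2 * Rpv^2 / Rv^2 - Rppv / Rv)
  Dg <- Matrix::Diagonal(x = av)
  GradZ <- DZ + Dg %*% DE
  GradR <- Matrix::Diagonal(x = 1 / Rv) %*% DE
  LapZZ <- DZZ + 2 * Dg %*% (DZ %*% DE) + Matrix::Diagonal(x = av^2) %*% DEE +
    Matrix::Diagonal(x = bv) %*% DE
  LapRR <- Matrix::Diagonal(x = 1 / Rv^2) %*% DEE

  idx <- function(i, j) i + (j - 1L) * Ni
  axis_k <- idx(seq_len(Ni), 1L)
  wall_k <- idx(seq_len(Ni), Nj)
  inlet_k <- setdiff(idx(1L, seq_len(Nj)), c(axis_k, wall_k))
  outlet_k <- setdiff(idx(Ni, seq_len(Nj)), c(axis_k, wall_k))
  bnd <- c(axis_k, wall_k, inlet_k, outlet_k)
  interior <- setdiff(seq_len(Ni * Nj), bnd)

  ubar_in <- inlet_mean_velocity
  Q <- ubar_in * pi * R[1]^2
  psi_w <- Q / (2 * pi)
  ubar_z <- Q / (pi * R^2)

  rinv_safe <- ifelse(rv > 0, 1 / rv, 0)
  # psi operator: E^2 psi = psi_zz + psi_rr - (1/r) psi_r
  Lpsi <- LapZZ + LapRR - Matrix::Diagonal(x = rinv_safe) %*% GradR
  Lpsi <- set_dirichlet_rows(Lpsi, c(axis_k, wall_k, inlet_k))
  # outlet: d psi / d xi = 0 (one-sided)
  Lpsi <- set_neumann_outlet_rows(Lpsi, outlet_k, Ni)
  psi_scale <- row_equilibrate(Lpsi)
  Lpsi_lu <- Matrix::lu(Matrix::Diagonal(x = psi_scale) %*% Lpsi)

  psi_inlet <- if (inlet_profile == "parabolic") {
    ubar_in * R[1]^2 * (eta^2 - eta^4 / 2)
  } else {
    # flat core with thin numerical boundary layer: psi = ubar * r^2 / 2
    ubar_in * R[1]^2 * eta^2 / 2
  }
  omega_inlet <- if (inlet_profile == "parabolic") {
    4 * ubar_in * eta / R[1]
  } else {
    rep(0, Nj)
  }

  # initial guess: locally Poiseuille vorticity
  omega <- outer(4 * ubar_z / R, eta)
  dim(omega) <- NULL
  dn <- R * de / sqrt(1 + Rp^2)

  solve_psi <- function(omega) {
    rhs <- -(rv * omega)
    rhs[axis_k] <- 0
    rhs[wall_k] <- psi_w
    rhs[inlet_k] <- psi_inlet[match(inlet_k, idx(1L, seq_len(Nj)))]
    rhs[outlet_k] <- 0
    as.numeric(Matrix::solve(Lpsi_lu, psi_scale * rhs))
  }

  velocities <- function(psi) {
    psim <- matrix(psi, Ni, Nj)
    dpsi_eta <- matrix(as.numeric(DE %*% psi), Ni, Nj)
    dpsi_z <- matrix(as.numeric(GradZ %*% psi), Ni, Nj)
    u_z <- dpsi_eta / (outer(R, eta) * R)
    # axis closure exact for psi = a r^2 + b r^4 (uniform eta spacing)
    u_z[, 1] <- (16 * psim[, 2] - psim[, 3]) / (6 * (R * eta[2])^2)
    u_r <- -dpsi_z / outer(R, eta)
    u_r[, 1] <- 0
    list(u_z = u_z, u_r = u_r)
  }

  wall_omega <- function(psi) {
    psim <- matrix(psi, Ni, Nj)
    (7 * psi_w - 8 * psim[, Nj - 1L] + psim[, Nj - 2L]) / (2 * dn^2 * R)
  }

  delta <- Inf
  prev_delta <- Inf
  grow <- 0L
  iter <- 0L
  psi <- solve_psi(omega)
  omega_scale <- max(abs(omega))
  while (iter < max_iter && delta > tol) {
    iter <- iter + 1L
    vel <- velocities(psi)
    uz <- as.vector(vel$u_z)
    ur <- as.vector(vel$u_r)
    Uxi <- uz
    Ueta <- uz * av + ur / Rv
    Adv <- if (include_advection) {
      Matrix::Diagonal(x = pmax(Uxi, 0)) %*% DZb +
        Matrix::Diagonal(x = pmin(Uxi, 0)) %*% DZf +
        Matrix::Diagonal(x = pmax(Ueta, 0)) %*% DEb +
        Matrix::Diagonal(x = pmin(Ueta, 0)) %*% DEf
    } else {
      Matrix::Diagonal(x = rep(0, Ni * Nj))
    }
    Lom <- Adv - Matrix::Diagonal(x = ur * rinv_safe) -
      nu * (LapZZ + LapRR + Matrix::Diagonal(x = rinv_safe) %*% GradR -
              Matrix::Diagonal(x = rinv_safe^2))
    Lom <- set_dirichlet_rows(Lom, c(axis_k, wall_k, inlet_k))
    Lom <- set_neumann_outlet_rows(Lom, outlet_k, Ni)
    rhs <- rep(0, Ni * Nj)
    rhs[wall_k] <- wall_omega(psi)
    rhs[inlet_k] <- omega_inlet[match(inlet_k, idx(1L, seq_len(Nj)))]
    om_scale <- row_equilibrate(Lom)
    omega_new <- as.numeric(Matrix::solve(
      Matrix::Diagonal(x = om_scale) %*% Lom, om_scale * rhs))
    delta <- max(abs(omega_new - omega)) / max(omega_scale, max(abs(omega_new)))
    # damp the iteration if the update norm keeps growing
    grow <- if (delta > prev_delta) grow + 1L else 0L
    if (grow >= 3L && relax > 0.05) {
      relax <- relax / 2
      grow <- 0L
    }
    prev_delta <- delta
    omega <- omega + relax * (omega_new - omega)
    psi <- solve_psi(omega)
  }
  if (delta > tol) {
    stop(sprintf(paste0("lumen flow solver did not converge in %d iterations: ",
                        "relative vorticity change %.3e (tol %.1e)"),
                 max_iter, delta, tol))
  }
  vel <- velocities(psi)
  # continuity: flux through every section is 2*pi*(psi_wall - psi_axis), fixed
  psim <- matrix(psi, Ni, Nj)
  flux_rel <- abs((psim[Ni, Nj] - psim[Ni, 1]) - (psim[1, Nj] - psim[1, 1])) /
    abs(psim[1, Nj] - psim[1, 1])

  # axial pressure profile: viscous Poiseuille gradient + momentum-flux term
  visc_grad <- 8 * mu * ubar_z / R^2
  cum <- rev(cumsum(rev((visc_grad[-1] + visc_grad[-Ni]) / 2 * diff(z))))
  p_z <- outlet_pressure_pa + c(cum, 0) +
    (4 / 3) * rho * (ubar_z[Ni]^2 - ubar_z^2)

  structure(list(
    mesh = mesh, u_z = vel$u_z, u_r = vel$u_r,
    psi = psim, omega = matrix(omega, Ni, Nj),
    p_z_pa = p_z, mean_velocity = ubar_z, flow_rate_m3_s = Q,
    continuity_residual = flux_rel, momentum_residual = delta,
    iterations = iter, converged = TRUE, reynolds = reynolds,
    props = props, outlet_pressure_pa = outlet_pressure_pa,
    wall_vorticity = wall_omega(psi), wall_normal_spacing = dn
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution>\n")
  cat(sprintf("  Q = %.4g m^3/s, Re = %.3g, %d Picard iterations\n",
              x$flow_rate_m3_s, x$reynolds, x$iterations))
  cat(sprintf("  continuity residual %.2e, momentum residual %.2e\n",
              x$continuity_residual, x$momentum_residual))
  invisible(x)
}

#' Endothelial shear stress field
#'
#' Magnitude of the tangential viscous traction on each endothelial face,
#' `ESS = mu * |omega_wall|` evaluated at the no-slip wall and averaged onto
#' faces.
#'
#' @param solution A converged [solve_lumen_flow()] result.
#' @param mesh The mesh the solution was computed on (defaults to the one
#'   stored in the solution).
#' @return A tibble of class `wall_shear_field` with `face_id`, `z_mm`,
#'   `ess_pa`.
#' @export
compute_ess <- function(solution, mesh = solution$mesh) {
  stopifnot(inherits(solution, "flow_solution"))
  if (!isTRUE(solution$converged)) stop("flow solution is not converged")
  mu <- solution$props$viscosity_pa_s
  z <- mesh$z_mm
  nz <- length(z) - 1L
  tau_nodes <- if (all(solution$u_z == 0)) {
    rep(0, nz + 1L)
  } else {
    mu * abs(solution$wall_vorticity)
  }
  out <- tibble::tibble(
    face_id = seq_len(nz),
    z_mm = (z[-1] + z[-length(z)]) / 2,
    ess_pa = (tau_nodes[-1] + tau_nodes[-length(tau_nodes)]) / 2
  )
  class(out) <- c("wall_shear_field", class(out))
  out
}

#' @export
glance.flow_solution <- function(x, ...) {
  tibble::tibble(
    flow_rate_m3_s = x$flow_rate_m3_s,
    reynolds = x$reynolds,
    iterations = x$iterations,
    continuity_residual = x$continuity_residual,
    momentum_residual = x$momentum_residual,
    converged = x$converged
  )
}

# --- finite-difference helpers ------------------------------------------------

# uniform-grid 1-D sparse operators: central first/second derivatives with
# one-sided ends, plus pure backward/forward first derivatives for upwinding
fd_ops <- function(n, h) {
  stopifnot(n >= 3)
  D1 <- Matrix::bandSparse(n, n, k = c(-1, 1),
                           diagonals = list(rep(-1 / (2 * h), n - 1),
                                            rep(1 / (2 * h), n - 1)))
  D1 <- as(D1, "CsparseMatrix")
  D1[1, 1:3] <- c(-3, 4, -1) / (2 * h)
  D1[n, (n - 2):n] <- c(1, -4, 3) / (2 * h)
  D2 <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                           diagonals = list(rep(1 / h^2, n - 1),
                                            rep(-2 / h^2, n),
                                            rep(1 / h^2, n - 1)))
  D2 <- as(D2, "CsparseMatrix")
  D2[1, 1:4] <- c(2, -5, 4, -1) / h^2
  D2[n, (n - 3):n] <- c(-1, 4, -5, 2) / h^2
  D1b <- Matrix::bandSparse(n, n, k = c(-1, 0),
                            diagonals = list(rep(-1 / h, n - 1), rep(1 / h, n)))
  D1b <- as(D1b, "CsparseMatrix")
  D1b[1, 1:2] <- c(-1, 1) / h
  D1f <- Matrix::bandSparse(n, n, k = c(0, 1),
                            diagonals = list(rep(-1 / h, n), rep(1 / h, n - 1)))
  D1f <- as(D1f, "CsparseMatrix")
  D1f[n, (n - 1):n] <- c(-1, 1) / h
  list(D1 = D1, D2 = D2, D1b = D1b, D1f = D1f)
}

# inverse row-max scaling for equilibration before sparse LU
row_equilibrate <- function(A) {
  1 / pmax(apply_rowmax(abs(A)), .Machine$double.xmin)
}

apply_rowmax <- function(m) {
  out <- numeric(nrow(m))
  mt <- as(m, "TsparseMatrix")
  if (length(mt@x)) {
    agg <- tapply(mt@x, mt@i, max)
    out[as.integer(names(agg)) + 1L] <- agg
  }
  out
}

# replace the given rows by identity (Dirichlet rows)
set_dirichlet_rows <- function(A, rows) {
  A <- as(A, "CsparseMatrix")
  n <- nrow(A)
  M <- Matrix::Diagonal(n, x = as.numeric(!(seq_len(n) %in% rows)))
  A <- M %*% A
  A + Matrix::sparseMatrix(i = rows, j = rows, x = 1, dims = c(n, n))
}

# replace the given rows by f(i) - f(i-1) = 0 (outlet zero-gradient in xi)
set_neumann_outlet_rows <- function(A, rows, Ni) {
  A <- as(A, "CsparseMatrix")
  n <- nrow(A)
  M <- Matrix::Diagonal(n, x = as.numeric(!(seq_len(n) %in% rows)))
  A <- M %*% A
  A + Matrix::sparseMatrix(i = c(rows, rows), j = c(rows, rows - 1L),
                           x = rep(c(1, -1), each = length(rows)),
                           dims = c(n, n))
}
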