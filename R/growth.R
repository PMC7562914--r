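#' Per-element plaque volume ratio
#'
#' Volume fraction newly occupied by plaque constituents in each wall
#' element: `dV/V = c_foam V_foam + c_sSMC V_sSMC + c_collagen v_collagen`.
#' The printed sum is unbounded (concentration x volume products can exceed
#' 1); values are capped at `cap` (config-exposed) to keep the deformation
#' geometrically valid.
#'
#' @param state A `species_state` (or matrix with `foam`, `ssmc`,
#'   `collagen` columns).
#' @param vols A [cellular_volumes()].
#' @param cap Upper clamp on dV/V; `Inf` disables.
#' @return Numeric vector, one dV/V per wall cell.
#' @export
plaque_volume_ratio <- function(state, vols = cellular_volumes(), cap = 0.95) {
  C <- unclass(state)
  if (any(C < 0)) stop("negative concentrations in plaque_volume_ratio")
  dv <- C[, "foam"] * vols$v_foam_m3 + C[, "ssmc"] * vols$v_ssmc_m3 +
    C[, "collagen"] * vols$v_collagen_m3_g
  pmin(dv, cap)
}

#' Directional strain from the volumetric ratio
#'
#' With thickening constrained to the direction of the centerline,
#' `dV/V = ((l + dl) l^2 - l^3)/l^3 = dl/l`, so the directional strain
#' equals the volumetric ratio exactly.
#'
#' @param dv_over_v Volumetric ratio (> -1).
#' @return Directional strain, same shape.
#' @export
directional_strain <- function(dv_over_v) {
  if (any(dv_over_v <= -1)) stop("dV/V must exceed -1")
  dv_over_v
}

#' Apply strain-based wall thickening
#'
#' Converts the per-element directional strain into an inward displacement
#' of the endothelium (`dl = eps * l`, `l` the local wall thickness), with
#' the adventitia and wall ends supported (zero displacement).
#'
#' `mode = "kinematic"` (default) displaces the endothelial nodes directly
#' and interpolates the interior linearly — the strain identity fully
#' determines the displacement magnitude. `mode = "elastic"` solves, per
#' axial station, the radial linear-elastostatic equilibrium of the wall
#' annulus with the growth strain as a radial eigenstrain (Young modulus
#' and Poisson ratio from `material`), traction-free at the endothelium and
#' fixed at the adventitia; elasticity redistributes, but does not set, the
#' thickening.
#'
#' @param mesh The baseline `artery_mesh`.
#' @param eps Per-wall-cell directional strain (vector of length nz*nr, or
#'   a single value).
#' @param material A [wall_material()] (elastic mode).
#' @param mode `"kinematic"` or `"elastic"`.
#' @return An object of class `growth_result`: the `deformed` mesh,
#'   `displacement_mm` of the endothelial nodes (positive inward),
#'   per-station strain, and a per-station audit tibble.
#' @export
apply_wall_thickening <- function(mesh, eps, material = wall_material(),
                                  mode = c("kinematic", "elastic")) {
  mode <- match.arg(mode)
  if (any(!is.finite(eps))) stop("strain field must be finite")
  nz <- length(mesh$z_mm) - 1L
  nr <- ncol(mesh$wall_r_mm) - 1L
  epsm <- matrix(rep(eps, length.out = nz * nr), nz, nr)
  # volume-weighted mean strain per axial station
  vol <- matrix(cell_volumes(mesh, "wall")$volume_mm3, nz, nr)
  eps_cell_z <- rowSums(epsm * vol) / rowSums(vol)
  # node strain by averaging adjacent stations
  eps_node <- c(eps_cell_z[1], (eps_cell_z[-1] + eps_cell_z[-nz]) / 2,
                eps_cell_z[nz])
  re <- endothelium_radius(mesh)
  ra <- adventitia_radius(mesh)
  thick <- ra - re
  dl <- if (mode == "kinematic") {
    eps_node * thick
  } else {
    vapply(seq_len(nz + 1L), function(i) {
      radial_eigenstrain_displacement(re[i], ra[i], eps_node[i], material)
    }, numeric(1))
  }
  re_new <- re - dl
  if (any(re_new <= 0)) {
    bad <- which(re_new <= 0)
    stop("wall thickening inverts elements at axial node(s) ",
         paste(bad, collapse = ", "), " (non-positive lumen radius)")
  }
  deformed <- mesh
  # wall: adventitia fixed, interior interpolated on the radial fraction
  eta_w <- mesh$eta_wall
  deformed$wall_r_mm <- outer(ra, rep(1, length(eta_w))) -
    outer(ra - re_new, 1 - eta_w)
  # lumen follows the new endothelial radius
  deformed$lumen_r_mm <- outer(re_new, mesh$eta_lumen)
  vol_new <- cell_volumes(deformed, "wall")$volume_mm3
  if (any(vol_new <= 0)) {
    stop("wall thickening produced non-positive cell volumes at cell(s) ",
         paste(which(vol_new <= 0), collapse = ", "))
  }
  audit <- tibble::tibble(
    z_mm = mesh$z_mm,
    strain = eps_node,
    wall_thickness_mm = thick,
    displacement_mm = dl,
    lumen_radius_mm = re_new
  )
  structure(list(
    baseline = mesh, deformed = deformed,
    dv_over_v = epsm, strain_per_station = eps_node,
    displacement_mm = dl, mode = mode, audit = audit
  ), class = "growth_result")
}

# radial elastostatic displacement of an annulus with radial eigenstrain:
# solves d(sigma_r)/dr + (sigma_r - sigma_t)/r = 0 on [re, ra] with
# sigma_r(re) = 0, u(ra) = 0; returns inward endothelial displacement (mm).
radial_eigenstrain_displacement <- function(re_mm, ra_mm, eps, material, n = 60L) {
  if (eps == 0) return(0)
  E <- material$young_modulus_pa
  nuv <- material$poisson_ratio
  lam <- E * nuv / ((1 + nuv) * (1 - 2 * nuv))
  muv <- E / (2 * (1 + nuv))
  r <- seq(re_mm, ra_mm, length.out = n)
  hr <- r[2] - r[1]
  # unknown u at nodes; sigma_r = (lam+2mu)(u' - eps) + lam u/r
  A <- matrix(0, n, n)
  b <- numeric(n)
  c1 <- lam + 2 * muv
  # interior: u'' + u'/r - u/r^2 = (2 mu eps)/(c1 r)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- 1 / hr^2 - 1 / (2 * hr * r[i])
    A[i, i] <- -2 / hr^2 - 1 / r[i]^2
    A[i, i + 1] <- 1 / hr^2 + 1 / (2 * hr * r[i])
    b[i] <- 2 * muv * eps / (c1 * r[i])
  }
  # endothelium: sigma_r = 0 -> c1 (u2 - u1)/hr + lam u1/r1 = c1 * eps
  A[1, 1] <- -c1 / hr + lam / r[1]
  A[1, 2] <- c1 / hr
  b[1] <- c1 * eps
  A[n, n] <- 1
  b[n] <- 0
  u <- solve(A, b)
  -u[1]  # inward displacement positive
}

#' @export
print.growth_result <- function(x, ...) {
  cat("<growth_result> mode:", x$mode, "\n")
  cat(sprintf("  inward displacement %.4g..%.4g mm, strain %.4g..%.4g\n",
              min(x$displacement_mm), max(x$displacement_mm),
              min(x$strain_per_station), max(x$strain_per_station)))
  invisible(x)
}

#' @export
glance.growth_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    mean_strain = mean(x$strain_per_station),
    max_displacement_mm = max(x$displacement_mm),
    min_lumen_radius_mm = min(endothelium_radius(x$deformed))
  )
}
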