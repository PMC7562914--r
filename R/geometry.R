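#' Specification of a synthetic coronary segment
#'
#' Describes an idealized axisymmetric coronary artery: a straight tube of
#' given lumen radius and wall thickness, optionally narrowed by one or more
#' Gaussian stenoses. Stands in for an image-based reconstruction as the
#' geometric substrate of the simulator.
#'
#' @param length_mm Segment length along the centerline, mm (> 0).
#' @param lumen_radius_mm Nominal lumen radius, mm (> 0).
#' @param wall_thickness_mm Wall thickness (endothelium to adventitia), mm.
#' @param stenoses A data frame / tibble with columns `position_mm`
#'   (axial centre), `depth_fraction` (0 <= d < 1, fraction of the lumen
#'   radius removed at the centre) and `width_mm` (Gaussian standard
#'   deviation). `NULL` or zero rows means an unstenosed tube.
#' @param edge_length_mm Target mesh edge length, mm; 0.15 by default.
#' @param dimensionality Only `"axisymmetric-2D"` is implemented.
#' @param seed Integer stored with the spec; mesh generation is fully
#'   deterministic, the seed is provenance.
#' @return An object of class `artery_spec`.
#' @export
artery_spec <- function(length_mm = 30,
                        lumen_radius_mm = 1.5,
                        wall_thickness_mm = 0.75,
                        stenoses = NULL,
                        edge_length_mm = 0.15,
                        dimensionality = "axisymmetric-2D",
                        seed = 1L) {
  stopifnot(length_mm > 0, lumen_radius_mm > 0, wall_thickness_mm > 0,
            edge_length_mm > 0)
  if (!identical(dimensionality, "axisymmetric-2D")) {
    stop("only dimensionality = \"axisymmetric-2D\" is implemented; ",
         "full-3D meshing is not available")
  }
  if (is.null(stenoses)) {
    stenoses <- tibble::tibble(position_mm = numeric(), depth_fraction = numeric(),
                               width_mm = numeric())
  }
  stenoses <- tibble::as_tibble(stenoses)
  need <- c("position_mm", "depth_fraction", "width_mm")
  if (!all(need %in% names(stenoses))) {
    stop("stenoses must have columns ", paste(need, collapse = ", "))
  }
  if (any(stenoses$depth_fraction >= 1)) {
    stop("stenosis depth_fraction >= 1 closes the lumen and is rejected")
  }
  if (any(stenoses$depth_fraction < 0) || any(stenoses$width_mm <= 0)) {
    stop("stenoses require 0 <= depth_fraction < 1 and width_mm > 0")
  }
  structure(list(length_mm = length_mm,
                 lumen_radius_mm = lumen_radius_mm,
                 wall_thickness_mm = wall_thickness_mm,
                 stenoses = stenoses,
                 edge_length_mm = edge_length_mm,
                 dimensionality = dimensionality,
                 seed = as.integer(seed)),
            class = "artery_spec")
}

#' Lumen radius profile of a synthetic artery
#'
#' `r(z) = R0 * (1 - sum_k d_k exp(-(z - z_k)^2 / (2 w_k^2)))`.
#'
#' @param spec An [artery_spec()].
#' @param z_mm Axial positions, mm.
#' @return Lumen radius at `z_mm`, mm.
#' @export
lumen_radius_profile <- function(spec, z_mm) {
  red <- rep(0, length(z_mm))
  st <- spec$stenoses
  if (nrow(st)) {
    for (k in seq_len(nrow(st))) {
      red <- red + st$depth_fraction[k] *
        exp(-(z_mm - st$position_mm[k])^2 / (2 * st$width_mm[k]^2))
    }
  }
  spec$lumen_radius_mm * (1 - red)
}

#' Generate a synthetic artery mesh
#'
#' Builds a structured axisymmetric (r, z) mesh of the lumen and the wall
#' annulus with tagged boundary faces (inlet, outlet, endothelium,
#' adventitia, wall ends) and an axial polyline centerline. Deterministic:
#' identical spec (including seed) yields a bit-identical mesh.
#'
#' @param spec An [artery_spec()].
#' @return An object of class `artery_mesh` with components `z_mm` (axial
#'   node positions), `lumen_r_mm` and `wall_r_mm` (node radius matrices,
#'   axial index by radial index), `eta_lumen`, `eta_wall` (radial
#'   fractions), `centerline` (tibble), and the originating `spec`.
#' @export
generate_synthetic_artery <- function(spec) {
  stopifnot(inherits(spec, "artery_spec"))
  e <- spec$edge_length_mm
  nz <- max(4L, as.integer(round(spec$length_mm / e)))
  nrl <- max(8L, as.integer(round(spec$lumen_radius_mm / e)))
  nrw <- max(3L, as.integer(round(spec$wall_thickness_mm / e)))
  z <- seq(0, spec$length_mm, length.out = nz + 1L)
  r_endo <- lumen_radius_profile(spec, z)
  if (any(r_endo <= 0)) {
    stop("combined stenoses close the lumen (non-positive radius); rejected")
  }
  eta_l <- seq(0, 1, length.out = nrl + 1L)
  eta_w <- seq(0, 1, length.out = nrw + 1L)
  lumen_r <- outer(r_endo, eta_l)
  wall_r <- outer(r_endo, rep(1, nrw + 1L)) +
    outer(rep(spec$wall_thickness_mm, nz + 1L), eta_w)
  mesh <- structure(list(
    z_mm = z,
    lumen_r_mm = lumen_r,
    wall_r_mm = wall_r,
    eta_lumen = eta_l,
    eta_wall = eta_w,
    centerline = tibble::tibble(x_mm = 0, y_mm = 0, z_mm = z),
    spec = spec
  ), class = "artery_mesh")
  mesh
}

#' @export
print.artery_mesh <- function(x, ...) {
  nz <- length(x$z_mm) - 1L
  cat("<artery_mesh> axisymmetric-2D\n")
  cat(sprintf("  length %.3g mm, %d axial x %d lumen-radial x %d wall-radial cells\n",
              max(x$z_mm) - min(x$z_mm), nz, ncol(x$lumen_r_mm) - 1L,
              ncol(x$wall_r_mm) - 1L))
  cat(sprintf("  lumen radius %.4g-%.4g mm, wall thickness %.4g mm (inlet)\n",
              min(x$lumen_r_mm[, ncol(x$lumen_r_mm)]),
              max(x$lumen_r_mm[, ncol(x$lumen_r_mm)]),
              x$wall_r_mm[1, ncol(x$wall_r_mm)] - x$wall_r_mm[1, 1]))
  invisible(x)
}

#' Endothelial and adventitial surface radii
#'
#' @param mesh An `artery_mesh`.
#' @return Numeric vectors of surface radius at each axial node, mm.
#' @name surface_radii
NULL

#' @rdname surface_radii
#' @export
endothelium_radius <- function(mesh) mesh$wall_r_mm[, 1]

#' @rdname surface_radii
#' @export
adventitia_radius <- function(mesh) mesh$wall_r_mm[, ncol(mesh$wall_r_mm)]

#' Cell volumes of a mesh domain
#'
#' Axisymmetric ring volumes, trapezoidal in z:
#' `V = pi * dz * mean over the two axial faces of (r_outer^2 - r_inner^2)`.
#' Exact for straight tubes, second-order for varying radius.
#'
#' @param mesh An `artery_mesh`.
#' @param domain `"lumen"` or `"wall"`.
#' @return A tibble with `cell_id`, axial index `i`, radial index `j`,
#'   `z_mm` (cell centre), `r_mm` (cell centre), `volume_mm3`.
#' @export
cell_volumes <- function(mesh, domain = c("lumen", "wall")) {
  domain <- match.arg(domain)
  r <- if (domain == "lumen") mesh$lumen_r_mm else mesh$wall_r_mm
  z <- mesh$z_mm
  nz <- length(z) - 1L
  nr <- ncol(r) - 1L
  dz <- diff(z)
  # ring areas at each axial node for each radial cell
  ring <- r[, -1, drop = FALSE]^2 - r[, -ncol(r), drop = FALSE]^2  # (nz+1) x nr
  vol <- pi * (ring[-nrow(ring), , drop = FALSE] + ring[-1, , drop = FALSE]) / 2 * dz
  rc <- (r[, -1, drop = FALSE] + r[, -ncol(r), drop = FALSE]) / 2
  rcent <- (rc[-nrow(rc), , drop = FALSE] + rc[-1, , drop = FALSE]) / 2
  zc <- (z[-1] + z[-length(z)]) / 2
  tibble::tibble(
    cell_id = seq_len(nz * nr),
    i = rep(seq_len(nz), times = nr),
    j = rep(seq_len(nr), each = nz),
    z_mm = rep(zc, times = nr),
    r_mm = as.vector(rcent),
    volume_mm3 = as.vector(vol)
  )
}

#' Tagged boundary faces of a mesh
#'
#' Every boundary face of the two domains carries exactly one tag:
#' `inlet` / `outlet` (lumen ends), `endothelium` (shared lumen-wall
#' interface, reported once on the wall side), `adventitia` (outer wall) and
#' `wall_end` (annular wall faces at both ends).
#'
#' @param mesh An `artery_mesh`.
#' @return A tibble with `face_id`, `tag`, `domain`, axial index `i` (for
#'   lateral faces) , `z_mm`, `r_mm` and `area_mm2`.
#' @export
boundary_faces <- function(mesh) {
  z <- mesh$z_mm
  nz <- length(z) - 1L
  re <- endothelium_radius(mesh)
  ra <- adventitia_radius(mesh)
  lat <- function(rv, tag, domain) {
    rmid <- (rv[-1] + rv[-length(rv)]) / 2
    slant <- sqrt(diff(z)^2 + diff(rv)^2)
    tibble::tibble(tag = tag, domain = domain, i = seq_len(nz),
                   z_mm = (z[-1] + z[-length(z)]) / 2, r_mm = rmid,
                   area_mm2 = 2 * pi * rmid * slant)
  }
  endf <- function(rv, idx, tag, domain, zpos) {
    tibble::tibble(tag = tag, domain = domain, i = NA_integer_,
                   z_mm = zpos, r_mm = mean(range(rv)),
                   area_mm2 = pi * (max(rv)^2 - min(rv)^2))
  }
  inlet <- tibble::tibble(tag = "inlet", domain = "lumen", i = NA_integer_,
                          z_mm = z[1], r_mm = re[1] / 2,
                          area_mm2 = pi * re[1]^2)
  outlet <- tibble::tibble(tag = "outlet", domain = "lumen", i = NA_integer_,
                           z_mm = z[nz + 1L], r_mm = re[nz + 1L] / 2,
                           area_mm2 = pi * re[nz + 1L]^2)
  out <- dplyr::bind_rows(
    inlet, outlet,
    lat(re, "endothelium", "wall"),
    lat(ra, "adventitia", "wall"),
    endf(c(re[1], ra[1]), 1L, "wall_end", "wall", z[1]),
    endf(c(re[nz + 1L], ra[nz + 1L]), nz + 1L, "wall_end", "wall", z[nz + 1L])
  )
  out$face_id <- seq_len(nrow(out))
  dplyr::relocate(out, "face_id")
}

#' Total centerline arclength, mm
#' @param mesh An `artery_mesh`.
#' @return Arclength of the centerline polyline, mm.
#' @export
centerline_length <- function(mesh) {
  cl <- mesh$centerline
  sum(sqrt(diff(cl$x_mm)^2 + diff(cl$y_mm)^2 + diff(cl$z_mm)^2))
}

#' Extract evenly spaced cross-sections
#'
#' Slices both domains perpendicular to the centerline at positions
#' `0, spacing, 2 spacing, ...` and reports lumen area and wall area (the
#' annulus between endothelium and adventitia) at each.
#'
#' @param mesh An `artery_mesh`.
#' @param spacing_mm Section spacing along the centerline, mm (> 0);
#'   0.5 by default.
#' @return A tibble (class `cross_sections`) with `section`,
#'   `z_mm`, `lumen_radius_mm`, `adventitia_radius_mm`, `lumen_area_mm2`,
#'   `wall_area_mm2`.
#' @export
extract_cross_sections <- function(mesh, spacing_mm = 0.5) {
  stopifnot(inherits(mesh, "artery_mesh"), spacing_mm > 0)
  L <- max(mesh$z_mm)
  zs <- seq(0, L, by = spacing_mm)
  miss <- zs < min(mesh$z_mm) - 1e-9 | zs > L + 1e-9
  if (any(miss)) {
    stop("cross-section plane misses the mesh at z = ",
         paste(format(zs[miss]), collapse = ", "), " mm")
  }
  re <- stats::approx(mesh$z_mm, endothelium_radius(mesh), xout = zs)$y
  ra <- stats::approx(mesh$z_mm, adventitia_radius(mesh), xout = zs)$y
  out <- tibble::tibble(
    section = seq_along(zs),
    z_mm = zs,
    lumen_radius_mm = re,
    adventitia_radius_mm = ra,
    lumen_area_mm2 = pi * re^2,
    wall_area_mm2 = pi * (ra^2 - re^2)
  )
  class(out) <- c("cross_sections", class(out))
  out
}
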