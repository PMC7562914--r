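#' Write an artery mesh to a legacy VTK unstructured-grid file
#'
#' The axisymmetric mesh is written as quadrilateral cells in the (z, r)
#' plane (x = z, y = r), one block of lumen cells followed by one block of
#' wall cells, with a `domain` cell array (0 = lumen, 1 = wall). The
#' structured description (axial nodes and surface radius matrices) is
#' embedded as a `FIELD` block so that [read_vtk()] can reconstruct the
#' mesh exactly.
#'
#' @param mesh An `artery_mesh`.
#' @param path Output file path (`.vtk`).
#' @param cell_data Optional named list of numeric vectors, each of length
#'   `n_lumen_cells + n_wall_cells` (lumen block first), written as scalar
#'   cell arrays.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = NULL) {
  stopifnot(inherits(mesh, "artery_mesh"))
  z <- mesh$z_mm
  nzp <- length(z)
  fmtv <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  pts_block <- function(r) {
    nrp <- ncol(r)
    cbind(rep(z, nrp), as.vector(r), 0)
  }
  p_l <- pts_block(mesh$lumen_r_mm)
  p_w <- pts_block(mesh$wall_r_mm)
  pts <- rbind(p_l, p_w)
  quads <- function(nrp, offset) {
    nz <- nzp - 1L
    nr <- nrp - 1L
    idx <- function(i, j) (j - 1L) * nzp + i - 1L + offset  # 0-based
    do.call(rbind, lapply(seq_len(nr), function(j) {
      i <- seq_len(nz)
      cbind(4L, idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    }))
  }
  c_l <- quads(ncol(mesh$lumen_r_mm), 0L)
  c_w <- quads(ncol(mesh$wall_r_mm), nrow(p_l))
  cells <- rbind(c_l, c_w)
  ncell <- nrow(cells)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0",
     "atherosim axisymmetric artery mesh (x = z mm, y = r mm)",
     "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("FIELD atherosim 5"))
  wl(sprintf("dims 3 1 int"))
  wl(paste(nzp, ncol(mesh$lumen_r_mm), ncol(mesh$wall_r_mm)))
  wl(sprintf("z_mm 1 %d double", nzp)); wl(paste(fmtv(z), collapse = " "))
  wl(sprintf("lumen_r_mm 1 %d double", length(mesh$lumen_r_mm)))
  wl(paste(fmtv(as.vector(mesh$lumen_r_mm)), collapse = " "))
  wl(sprintf("wall_r_mm 1 %d double", length(mesh$wall_r_mm)))
  wl(paste(fmtv(as.vector(mesh$wall_r_mm)), collapse = " "))
  wl(sprintf("seed 1 1 int")); wl(as.character(mesh$spec$seed))
  wl(sprintf("POINTS %d double", nrow(pts)))
  wl(apply(pts, 1, function(p) paste(fmtv(p), collapse = " ")))
  wl(sprintf("CELLS %d %d", ncell, ncell * 5L))
  wl(apply(cells, 1, paste, collapse = " "))
  wl(sprintf("CELL_TYPES %d", ncell))
  wl(as.character(rep(9L, ncell)))  # VTK_QUAD
  wl(sprintf("CELL_DATA %d", ncell))
  domain <- c(rep(0L, nrow(c_l)), rep(1L, nrow(c_w)))
  wl("SCALARS domain int 1", "LOOKUP_TABLE default")
  wl(as.character(domain))
  if (!is.null(cell_data)) {
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      stopifnot(length(v) == ncell)
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      wl(fmtv(v))
    }
  }
  invisible(path)
}

#' Read an artery mesh written by [write_vtk()]
#'
#' Reconstructs the structured axisymmetric mesh from the embedded `FIELD`
#' block. Only files produced by this package are supported.
#'
#' @param path Path to a `.vtk` file written by [write_vtk()].
#' @return An `artery_mesh`. Cell arrays (beyond `domain`) are attached as
#'   the `cell_data` attribute, a named list.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^FIELD atherosim", lines))) {
    stop("not an atherosim VTK file (missing FIELD metadata): ", path)
  }
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  pos <- grep("^dims ", lines)[1]
  dims <- as.integer(toks(lines[pos + 1L]))
  nzp <- dims[1]; nrl_p <- dims[2]; nrw_p <- dims[3]
  read_field <- function(name, n) {
    p <- grep(paste0("^", name, " "), lines)[1]
    vals <- numeric(0)
    k <- p + 1L
    while (length(vals) < n) {
      vals <- c(vals, as.numeric(toks(lines[k])))
      k <- k + 1L
    }
    vals
  }
  z <- read_field("z_mm", nzp)
  lum <- matrix(read_field("lumen_r_mm", nzp * nrl_p), nzp, nrl_p)
  wal <- matrix(read_field("wall_r_mm", nzp * nrw_p), nzp, nrw_p)
  seed <- as.integer(read_field("seed", 1))
  spec <- artery_spec(length_mm = max(z) - min(z),
                      lumen_radius_mm = max(lum[, nrl_p]),
                      wall_thickness_mm = wal[1, nrw_p] - wal[1, 1],
                      edge_length_mm = (max(z) - min(z)) / (nzp - 1L),
                      seed = seed)
  mesh <- structure(list(
    z_mm = z, lumen_r_mm = lum, wall_r_mm = wal,
    eta_lumen = seq(0, 1, length.out = nrl_p),
    eta_wall = seq(0, 1, length.out = nrw_p),
    centerline = tibble::tibble(x_mm = 0, y_mm = 0, z_mm = z),
    spec = spec
  ), class = "artery_mesh")
  # optional extra cell arrays
  cd <- list()
  sc <- grep("^SCALARS ", lines)
  ncell <- (nzp - 1L) * (nrl_p - 1L + nrw_p - 1L)
  for (p in sc) {
    nm <- toks(lines[p])[2]
    if (nm == "domain") next
    cd[[nm]] <- read_field_at(lines, p + 2L, ncell)
  }
  if (length(cd)) attr(mesh, "cell_data") <- cd
  mesh
}

read_field_at <- function(lines, start, n) {
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  vals <- numeric(0)
  k <- start
  while (length(vals) < n) {
    vals <- c(vals, as.numeric(toks(lines[k])))
    k <- k + 1L
  }
  vals
}

#' Export the endothelial surface as ASCII STL
#'
#' Revolves the endothelial generator curve about the centerline into a
#' triangulated surface of revolution.
#'
#' @param mesh An `artery_mesh`.
#' @param path Output `.stl` path.
#' @param n_theta Number of circumferential facets (>= 8).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, n_theta = 48L) {
  stopifnot(n_theta >= 8L)
  z <- mesh$z_mm
  r <- endothelium_radius(mesh)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid endothelium", con)
  tri <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %g %g %g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", p1[1], p1[2], p1[3]),
                 sprintf("    vertex %g %g %g", p2[1], p2[2], p2[3]),
                 sprintf("    vertex %g %g %g", p3[1], p3[2], p3[3]),
                 "  endloop", "endfacet"), con)
  }
  pt <- function(i, k) c(r[i] * cos(th[k]), r[i] * sin(th[k]), z[i])
  for (i in seq_len(length(z) - 1L)) {
    for (k in seq_len(n_theta)) {
      tri(pt(i, k), pt(i + 1L, k), pt(i + 1L, k + 1L))
      tri(pt(i, k), pt(i + 1L, k + 1L), pt(i, k + 1L))
    }
  }
  writeLines("endsolid endothelium", con)
  invisible(path)
}
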