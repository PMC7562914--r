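test_that("sub-segment aggregation drops the trailing partial segment", {
  cs <- extract_cross_sections(straight_mesh(0.5), 0.5)
  expect_equal(nrow(cs), 61)
  seg <- segment_metrics(cs)
  expect_equal(nrow(seg), 10)  # floor(61 / 6)
  # uniform tube: every segment mean equals the section value
  expect_equal(seg$lumen_area_mm2, rep(pi * 1.5^2, 10), tolerance = 0.01)
  burden_an <- 100 * (pi * (2.25^2 - 1.5^2)) / (pi * 2.25^2)
  expect_equal(seg$plaque_burden_pct, rep(burden_an, 10), tolerance = 0.01)
  expect_true(all(seg$plaque_burden_pct >= 0 & seg$plaque_burden_pct <= 100))
  expect_error(segment_metrics(cs[1:4, ]), "at least 6")
})

test_that("plaque burden limits behave at degenerate walls", {
  mk <- function(lumen, wall) {
    tibble::tibble(section = 1:6, z_mm = seq(0, 2.5, 0.5),
                   lumen_area_mm2 = lumen, wall_area_mm2 = wall)
  }
  expect_equal(segment_metrics(mk(7, 0))$plaque_burden_pct, 0)
  expect_gt(segment_metrics(mk(1e-9, 10))$plaque_burden_pct, 99.9)
})

test_that("identical geometries compare to zero change with unit correlation", {
  mesh <- straight_mesh(0.5)
  cmp <- compare_geometries(mesh, mesh)
  expect_equal(cmp$segments$lumen_area_change, rep(0, 10))
  expect_equal(cmp$summary$mean_change, rep(0, 3))
  expect_equal(cmp$summary$correlation, rep(1, 3))
})

test_that("a uniform 5% inward displacement produces the scaled-circle area change", {
  mesh <- straight_mesh(0.25)
  shrunk <- mesh
  shrunk$lumen_r_mm <- mesh$lumen_r_mm * 0.95
  shrunk$wall_r_mm <- cbind(mesh$wall_r_mm[, 1, drop = FALSE] * 0.95,
                            mesh$wall_r_mm[, -1, drop = FALSE])
  cmp <- compare_geometries(mesh, shrunk)
  expected <- -(1 - 0.95^2) * pi * 1.5^2
  expect_equal(cmp$segments$lumen_area_change, rep(expected, 10),
               tolerance = 1e-6)
})

test_that("simulated growth round-trips through the morphometrics", {
  # impose a known, axially varying strain and recover the implied
  # per-segment lumen-area change from the paired geometries
  mesh <- straight_mesh(0.25)
  nz <- length(mesh$z_mm) - 1L
  nr <- ncol(mesh$wall_r_mm) - 1L
  zc <- (mesh$z_mm[-1] + mesh$z_mm[-length(mesh$z_mm)]) / 2
  eps_cells <- rep(0.02 + 0.03 * zc / 30, nr)
  g <- apply_wall_thickening(mesh, eps_cells)
  cmp <- compare_geometries(mesh, g$deformed)
  re <- endothelium_radius(mesh)
  re_new <- endothelium_radius(g$deformed)
  cs_z <- extract_cross_sections(mesh, 0.5)$z_mm
  imposed <- pi * (stats::approx(mesh$z_mm, re_new, cs_z)$y^2 -
                     stats::approx(mesh$z_mm, re, cs_z)$y^2)
  seg_imposed <- tapply(imposed[1:60], rep(1:10, each = 6), mean)
  expect_equal(cmp$segments$lumen_area_change, as.numeric(seg_imposed),
               tolerance = 1e-6)
})

test_that("progression binarization uses a closed 20% threshold with direction", {
  expect_equal(binarize_progression(-25, "lumen"), 1L)
  expect_equal(binarize_progression(-10, "lumen"), 0L)
  expect_equal(binarize_progression(20, "wall"), 1L)   # closed boundary
  expect_equal(binarize_progression(25, "lumen"), 0L)  # wrong direction
  expect_equal(binarize_progression(c(-30, 5, -20), "lumen"), c(1L, 0L, 1L))
  expect_error(binarize_progression(NaN, "lumen"), "finite")
})
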