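test_that("plaque volume ratio is the capped linear combination", {
  p <- kinetic_parameters()
  zero <- matrix(0, 3, 10, dimnames = list(NULL, atherosim:::species_names()))
  vols <- cellular_volumes()
  expect_equal(plaque_volume_ratio(zero, vols), rep(0, 3))

  st <- zero
  st[, "foam"] <- 1e12
  expect_equal(plaque_volume_ratio(st, cellular_volumes(v_foam_m3 = 1e-15)),
               rep(1e-3, 3))
  # additivity of the three contributions
  a <- zero; a[, "foam"] <- 2e12
  b <- zero; b[, "ssmc"] <- 1e13
  d <- zero; d[, "collagen"] <- 1e4
  ab <- zero; ab[, "foam"] <- 2e12; ab[, "ssmc"] <- 1e13; ab[, "collagen"] <- 1e4
  expect_equal(plaque_volume_ratio(ab, vols),
               plaque_volume_ratio(a, vols) + plaque_volume_ratio(b, vols) +
                 plaque_volume_ratio(d, vols))
  # cap engages
  big <- zero; big[, "collagen"] <- 1e10
  expect_equal(plaque_volume_ratio(big, vols, cap = 0.95), rep(0.95, 3))
  expect_error(plaque_volume_ratio(zero - 1, vols), "negative")
})

test_that("directional strain equals the volumetric ratio and is small-strain consistent", {
  expect_equal(directional_strain(0.03), 0.03)
  expect_equal(directional_strain(0), 0)
  expect_error(directional_strain(-1.5), "exceed -1")
  # exact triaxial form vs linearized sum at 1% per axis
  exact <- (1 + 0.01)^3 - 1
  expect_equal(exact, 0.03, tolerance = 0.0102)
  expect_gt(abs(exact - 0.03) / 0.03, 0.009)  # the 1% discrepancy is real
})

test_that("kinematic thickening displaces the endothelium by eps times thickness", {
  mesh <- straight_mesh(0.5)
  idg <- apply_wall_thickening(mesh, 0)
  expect_equal(idg$deformed$wall_r_mm, mesh$wall_r_mm, tolerance = 1e-14)
  expect_equal(idg$deformed$lumen_r_mm, mesh$lumen_r_mm, tolerance = 1e-14)

  g <- apply_wall_thickening(mesh, 0.05)
  expect_equal(g$displacement_mm,
               rep(0.05 * 0.75, length(mesh$z_mm)))  # dl = eps * l, exact
  expect_equal(endothelium_radius(g$deformed),
               endothelium_radius(mesh) - 0.0375)
  # adventitia supported
  expect_equal(adventitia_radius(g$deformed), adventitia_radius(mesh))
  expect_true(all(cell_volumes(g$deformed, "wall")$volume_mm3 > 0))
})

test_that("achieved element volume change approaches the prescribed ratio in the slab limit", {
  # large radius-to-thickness ratio: the cubic-element identity dl/l = dV/V
  # holds; on coronary-calibre annuli curvature reduces the achieved change
  mesh <- generate_synthetic_artery(artery_spec(
    length_mm = 20, lumen_radius_mm = 10, wall_thickness_mm = 0.5,
    edge_length_mm = 0.5))
  eps <- 0.05
  g <- apply_wall_thickening(mesh, eps)
  v0 <- cell_volumes(mesh, "wall")$volume_mm3
  v1 <- cell_volumes(g$deformed, "wall")$volume_mm3
  achieved <- (v1 - v0) / v0
  expect_equal(achieved, rep(eps, length(v0)), tolerance = 0.05)
})

test_that("larger strain never yields larger lumen area and inversion is caught", {
  mesh <- straight_mesh(0.5)
  a1 <- extract_cross_sections(apply_wall_thickening(mesh, 0.02)$deformed,
                               1)$lumen_area_mm2
  a2 <- extract_cross_sections(apply_wall_thickening(mesh, 0.05)$deformed,
                               1)$lumen_area_mm2
  expect_true(all(a2 < a1))
  expect_error(apply_wall_thickening(mesh, 2.5), "inverts")
})

test_that("the elastic mode redistributes but does not exceed the kinematic scale", {
  mesh <- straight_mesh(0.5)
  gk <- apply_wall_thickening(mesh, 0.05, mode = "kinematic")
  ge <- apply_wall_thickening(mesh, 0.05, mode = "elastic")
  expect_true(all(ge$displacement_mm > 0))  # still inward
  expect_lt(max(ge$displacement_mm), 2 * max(gk$displacement_mm))
  expect_equal(adventitia_radius(ge$deformed), adventitia_radius(mesh))
  expect_equal(apply_wall_thickening(mesh, 0, mode = "elastic")$displacement_mm,
               rep(0, length(mesh$z_mm)))
})
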