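test_that("radius profile and generated mesh honour the Gaussian stenosis model", {
  straight <- straight_mesh()
  expect_equal(min(endothelium_radius(straight)), 1.5)

  sten <- stenosed_mesh()
  re <- endothelium_radius(sten)
  expect_equal(min(re), 0.9, tolerance = 1e-6)
  expect_equal(sten$z_mm[which.min(re)], 15, tolerance = 1e-9)
  # analytic profile at arbitrary positions
  spec <- stenosed_spec()
  expect_equal(lumen_radius_profile(spec, 15), 0.9)
  expect_equal(lumen_radius_profile(spec, c(0, 30)), c(1.5, 1.5), tolerance = 1e-9)

  expect_error(artery_spec(stenoses = tibble::tibble(
    position_mm = 10, depth_fraction = 1, width_mm = 2)), "closes the lumen")
  expect_error(artery_spec(stenoses = tibble::tibble(
    position_mm = 10, depth_fraction = 0.2, width_mm = -1)), "width_mm")
  expect_error(artery_spec(dimensionality = "full-3D"), "axisymmetric")
})

test_that("cell volumes match the analytic cylinder and converge under refinement", {
  mesh <- generate_synthetic_artery(artery_spec(edge_length_mm = 0.15))
  v_lumen <- sum(cell_volumes(mesh, "lumen")$volume_mm3)
  expect_equal(v_lumen, pi * 1.5^2 * 30, tolerance = 0.02)
  expect_true(all(cell_volumes(mesh, "lumen")$volume_mm3 > 0))
  expect_true(all(cell_volumes(mesh, "wall")$volume_mm3 > 0))

  # refinement on the stenosed geometry: halving the edge moves volume < 1%
  v1 <- sum(cell_volumes(generate_synthetic_artery(stenosed_spec(0.4)),
                         "lumen")$volume_mm3)
  v2 <- sum(cell_volumes(generate_synthetic_artery(stenosed_spec(0.2)),
                         "lumen")$volume_mm3)
  expect_lt(abs(v2 - v1) / v1, 0.01)
})

test_that("cross-sections reproduce analytic areas and counts", {
  mesh <- straight_mesh()
  cs <- extract_cross_sections(mesh, 0.5)
  expect_equal(nrow(cs), 61)
  expect_equal(cs$lumen_area_mm2, rep(pi * 1.5^2, 61), tolerance = 0.01)
  expect_equal(cs$wall_area_mm2, rep(pi * (2.25^2 - 1.5^2), 61),
               tolerance = 0.01)
  expect_lt(max(cs$lumen_area_mm2) / min(cs$lumen_area_mm2), 1.01)

  shifted <- mesh
  shifted$z_mm <- mesh$z_mm + 1  # mesh no longer starts at arclength 0
  expect_error(extract_cross_sections(shifted, 0.5), "misses the mesh at z = 0")
})

test_that("mesh generation is deterministic with fully tagged boundary faces", {
  spec <- stenosed_spec()
  expect_identical(generate_synthetic_artery(spec),
                   generate_synthetic_artery(spec))

  mesh <- stenosed_mesh()
  bf <- boundary_faces(mesh)
  expect_setequal(unique(bf$tag),
                  c("inlet", "outlet", "endothelium", "adventitia", "wall_end"))
  expect_true(all(bf$area_mm2 > 0))
  expect_equal(sum(bf$tag == "wall_end"), 2L)
  # endothelium faces are the shared lumen-wall interface
  nz <- length(mesh$z_mm) - 1L
  expect_equal(sum(bf$tag == "endothelium"), nz)
  expect_equal(centerline_length(mesh), 30, tolerance = 0.01)
})
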