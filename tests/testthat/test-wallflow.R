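test_that("area porosity tensor is gamma times the identity", {
  expect_equal(area_porosity_tensor(0.96), diag(0.96, 3))
  expect_equal(area_porosity_tensor(1), diag(3))
  expect_equal(area_porosity_tensor(0.5), diag(0.5, 3))
  expect_error(area_porosity_tensor(0), "porosity")
  expect_error(area_porosity_tensor(1.2), "porosity")
})

test_that("Darcy filtration matches the radial closed form to round-off", {
  mesh <- straight_mesh()
  props <- porous_wall_properties()
  k <- props$darcian_permeability_m2 / props$plasma_viscosity_pa_s
  p_in <- mmhg_to_pa(100); p_out <- mmhg_to_pa(17.5)
  wf <- solve_plasma_flow(mesh, props,
                          endothelial_bc = list(type = "pressure", value = p_in),
                          adventitia_pressure_pa = p_out)
  v_an <- k * (p_in - p_out) / (1.5e-3 * log(2.25 / 1.5))
  expect_equal(wf$u_r_face[, 1], rep(v_an, nrow(wf$u_r_face)),
               tolerance = 1e-10)
  expect_lt(wf$mass_balance_residual, 1e-8)
  # pressure bounded by its boundary values
  expect_true(all(wf$p_pa <= p_in & wf$p_pa >= p_out))
})

test_that("filtration is linear in the pressure drop and vanishes without one", {
  mesh <- straight_mesh(0.5)
  props <- porous_wall_properties()
  p0 <- mmhg_to_pa(17.5)
  base <- solve_plasma_flow(mesh, props,
                            endothelial_bc = list(type = "pressure",
                                                  value = p0 + 1000),
                            adventitia_pressure_pa = p0)
  dbl <- solve_plasma_flow(mesh, props,
                           endothelial_bc = list(type = "pressure",
                                                 value = p0 + 2000),
                           adventitia_pressure_pa = p0)
  expect_equal(dbl$u_r_face[, 1] / base$u_r_face[, 1],
               rep(2, nrow(base$u_r_face)), tolerance = 1e-10)

  flat <- solve_plasma_flow(mesh, props,
                            endothelial_bc = list(type = "pressure", value = p0),
                            adventitia_pressure_pa = p0)
  expect_equal(max(abs(flat$u_r_face)), 0, tolerance = 1e-20)
  # permeability -> 0 drives filtration to 0 monotonically
  v_half <- solve_plasma_flow(mesh, porous_wall_properties(
    darcian_permeability_m2 = 0.6e-18),
    endothelial_bc = list(type = "pressure", value = p0 + 1000),
    adventitia_pressure_pa = p0)$u_r_face[1, 1]
  expect_equal(v_half / base$u_r_face[1, 1], 0.5, tolerance = 1e-10)
})

test_that("velocity boundary data are conserved and inconsistencies rejected", {
  mesh <- straight_mesh(0.5)
  wf <- solve_plasma_flow(mesh, endothelial_bc = list(type = "velocity",
                                                      value = 3.5e-8),
                          adventitia_pressure_pa = mmhg_to_pa(17.5))
  expect_lt(wf$mass_balance_residual, 1e-8)
  expect_error(
    solve_plasma_flow(mesh, endothelial_bc = list(type = "velocity",
                                                  value = 3.5e-8),
                      adventitia_pressure_pa = NULL),
    "inconsistent boundary data")
})
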