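test_that("hydraulic conductivity follows the printed shear correlation", {
  expect_equal(hydraulic_conductivity(0.985), 3.1588e-12)
  expect_equal(hydraulic_conductivity(exp(1) - 0.015),
               0.2077e-12 + 3.1588e-12, tolerance = 1e-12)
  expect_gt(hydraulic_conductivity(2), hydraulic_conductivity(1))
  expect_error(hydraulic_conductivity(-0.1), "WSS")
})

test_that("eNOS and NO concentrations follow their correlations", {
  expect_equal(enos_concentration(1), 0.0322)
  expect_equal(enos_concentration(exp(1)), 0.0355, tolerance = 1e-12)
  expect_gt(enos_concentration(2), enos_concentration(1))
  expect_error(enos_concentration(0), "singularity")

  expect_equal(no_concentration(0.0322, 0, 3.5), 0)
  expect_equal(no_concentration(0.0322, 1e12, 3.5), 1.26 * 0.0322,
               tolerance = 1e-9)
  expect_equal(no_concentration(0.0322, 3.5, 3.5), 0.63 * 0.0322)
})

test_that("diffusive permeability is the floored linear NO response", {
  expect_equal(diffusive_permeability(0), 0.34)
  expect_equal(diffusive_permeability(0.34 / 6), 0)
  expect_equal(diffusive_permeability(1), 0)  # floored
  expect_lt(diffusive_permeability(0.05), diffusive_permeability(0.01))
})

test_that("Kedem-Katchalsky volume, solute and monocyte fluxes behave as defined", {
  expect_equal(volume_flux(3.1588e-12, 0), 0)
  expect_equal(volume_flux(3.1588e-12, 1), 3.1588e-12)
  expect_equal(sign(volume_flux(1e-12, c(-5, 5))), c(-1, 1))

  expect_equal(solute_flux(0.5, 0, 1, 2, 3), 0)
  expect_equal(solute_flux(0.34, 1, 1, 0, 0), 0.34)
  jv <- 2e-8
  expect_equal(solute_flux(0, 0, 0.997, jv, 1), 0.003 * jv)
  expect_error(solute_flux(0.1, 1, 1.2, 0, 0), "sigma_f")

  m_r <- 5.5e-4 / 86400
  expect_equal(monocyte_flux(1, 2, 3, m_r, 1), m_r / 2 * 2 * 3)
  expect_equal(monocyte_flux(5, 0, 1e11, m_r, 1), 0)
  f <- monocyte_flux(c(0.5, 1, 2, 4), 1e-3, 5e11, m_r, 1)
  expect_true(all(diff(f) < 0))
  expect_error(monocyte_flux(1, -1, 1), ">= 0")
})

test_that("total LDL influx decreases monotonically with shear", {
  # fixed transmural conditions spanning the physiological shear range
  ep <- endothelial_parameters()
  wss <- seq(0.1, 5, by = 0.05)
  k_m_mmhg <- ep$k_m_um / ep$o2_solubility_um_per_mmhg
  cno <- no_concentration(enos_concentration(wss), ep$po2_mmhg, k_m_mmhg)
  dp <- diffusive_permeability(cno, ep$permeability_unit_scale)
  jv <- volume_flux(hydraulic_conductivity(wss), 11000)
  c_lumen <- 2.8e-3
  j_total <- solute_flux(dp, c_lumen, ep$sigma_f, jv, c_lumen / 2)
  expect_true(all(diff(j_total) < 0))
})

test_that("the per-face state is a pure deterministic function of its inputs", {
  mesh <- straight_mesh(0.5)
  wssf <- compute_ess(straight_flow(0.5, 0.2))
  a <- endothelial_state(wssf, lumen_pressure_pa = 13332, wall_pressure_pa = 2333,
                         c_ldl_lumen = 2.8e-3, c_hdl_lumen = 3.2e-3,
                         c_mono_lumen = 5e11)
  b <- endothelial_state(wssf, lumen_pressure_pa = 13332, wall_pressure_pa = 2333,
                         c_ldl_lumen = 2.8e-3, c_hdl_lumen = 3.2e-3,
                         c_mono_lumen = 5e11)
  expect_identical(a, b)
  expect_true(all(is.finite(unlist(a[sapply(a, is.numeric)]))))
  expect_true(all(sign(a$j_v_m_s) == sign(a$dp_pa)))
})
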