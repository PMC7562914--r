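test_that("straight-tube solve reproduces Hagen-Poiseuille flow", {
  mesh <- straight_mesh(0.15)
  sol <- straight_flow(0.15)
  ess <- compute_ess(sol)
  tau_an <- 4 * 0.0035 * 0.2 / 1.5e-3
  expect_equal(mean(ess$ess_pa), tau_an, tolerance = 0.03)
  expect_true(all(ess$ess_pa >= 0))
  # developed axial profile vs the parabola, L2 error < 2%
  i <- round(nrow(sol$u_z) / 2)
  u_an <- 2 * 0.2 * (1 - mesh$eta_lumen^2)
  expect_lt(sqrt(sum((sol$u_z[i, ] - u_an)^2)) / sqrt(sum(u_an^2)), 0.02)
  # mass conservation between inlet and outlet
  expect_lt(sol$continuity_residual, 1e-6)
  expect_lt(sol$momentum_residual, 1e-6)
  # axial pressure falls at the Poiseuille gradient
  dpdz <- -diff(sol$p_z_pa[c(1, length(sol$p_z_pa))]) /
    diff(range(mm_to_m(mesh$z_mm)))
  expect_equal(dpdz, 8 * 0.0035 * 0.2 / 1.5e-3^2, tolerance = 1e-6)
})

test_that("rest state is exact and creeping flow responds linearly", {
  mesh <- straight_mesh(0.5)
  rest <- solve_lumen_flow(mesh, inlet_mean_velocity = 0)
  expect_true(all(rest$u_z == 0) && all(rest$u_r == 0))
  expect_equal(unique(rest$p_z_pa), rest$outlet_pressure_pa)
  expect_equal(compute_ess(rest)$ess_pa, rep(0, nrow(compute_ess(rest))))

  # Re << 1: doubling the inlet velocity doubles ESS within 1%
  s1 <- solve_lumen_flow(mesh, inlet_mean_velocity = 1e-6)
  s2 <- solve_lumen_flow(mesh, inlet_mean_velocity = 2e-6)
  r <- compute_ess(s2)$ess_pa / compute_ess(s1)$ess_pa
  expect_equal(r, rep(2, length(r)), tolerance = 0.01)
})

test_that("mid-tube ESS is grid-convergent", {
  e_coarse <- compute_ess(solve_lumen_flow(straight_mesh(0.5),
                                           inlet_mean_velocity = 0.2))
  e_fine <- compute_ess(straight_flow(0.25))
  mid <- function(w) w$ess_pa[which.min(abs(w$z_mm - 15))]
  expect_lt(abs(mid(e_fine) - mid(e_coarse)) / mid(e_fine), 0.02)
})

test_that("stenosed tube shows a throat shear maximum with low shear downstream", {
  sol <- solve_lumen_flow(stenosed_mesh(0.3), inlet_mean_velocity = 0.15)
  ess <- compute_ess(sol)
  z_max <- ess$z_mm[which.max(ess$ess_pa)]
  expect_lt(abs(z_max - 15), 2)  # maximum at the throat
  up <- mean(ess$ess_pa[ess$z_mm > 5 & ess$z_mm < 9])
  dn <- mean(ess$ess_pa[ess$z_mm > 21 & ess$z_mm < 25])
  expect_lt(dn, up)              # separation region downstream
  expect_lt(min(ess$ess_pa[ess$z_mm > 15]), 0.25 * up)
})

test_that("the laminar assumption is guarded by a Reynolds warning", {
  expect_warning(solve_lumen_flow(straight_mesh(0.5), inlet_mean_velocity = 3),
                 "Reynolds")
})
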