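test_that("HDL protection follows the printed quadratic", {
  expect_equal(hdl_protection(0), 1.0056)
  expect_equal(hdl_protection(25 / 3), -3e-5 * (25 / 3)^2 + 5e-4 * 25 / 3 + 1.0056)
  expect_gt(hdl_protection(0), 1)
  expect_lt(hdl_protection(200), hdl_protection(25 / 3))  # eventually decreasing
  expect_equal(hdl_protection(1000), 0)                   # floored
  expect_error(hdl_protection(-1), ">= 0")
})

test_that("reaction sources implement the printed network", {
  p <- kinetic_parameters()
  zero <- matrix(0, 1, 10, dimnames = list(NULL, atherosim:::species_names()))
  expect_true(all(reaction_rhs(zero, p) == 0))

  st <- zero; st[, "ldl"] <- 1
  r <- reaction_rhs(st, p, porosity = 0.96)
  expect_equal(unname(r[, "ldl"]), -0.96 * hdl_protection(1) * 1.4e-4)
  # OxLDL source excludes the protection factor, as printed
  expect_equal(unname(r[, "oxldl"]), 0.96 * 1.4e-4)

  st2 <- zero; st2[, "csmc"] <- 29.26e12; st2[, "cytokines"] <- 5
  r2 <- reaction_rhs(st2, p)
  expect_equal(unname(r2[, "csmc"] + r2[, "ssmc"]), 0)  # SMC transfer

  stneg <- zero; stneg[, "hdl"] <- -1
  expect_error(reaction_rhs(stneg, p), "negative")
})

test_that("sealed-domain diffusion conserves every species and nonnegativity", {
  mesh <- straight_mesh(0.5)
  p <- kinetic_parameters(r_LDL = 0, r_HDL = 0, m_d = 0, d_m = 0, d_c = 0,
                          d_g = 0, g_r = 0, base_switch_rate_per_s = 0)
  st <- species_state(mesh, p)
  nz <- attr(st, "dims")["nz"]
  # nonuniform initial fields
  st[, "ldl"] <- rep(seq(0, 2e-3, length.out = nz), 3)
  st[, "cytokines"] <- rep(c(1, 0, 0), each = nz)
  st[, "macrophages"] <- runif(nrow(st), 0, 1e9)
  V <- cell_volumes(mesh, "wall")$volume_mm3
  mass0 <- colSums(st * V)
  bc <- species_bc(adventitia = NULL, endothelium_sealed = TRUE)
  out <- st
  for (k in 1:3) {
    out <- step_species(out, mesh, NULL, NULL, p,
                        bc = bc, dt_s = months_to_seconds(1))
  }
  mass1 <- colSums(out * V)
  nz_mass <- mass0 > 0
  expect_equal(mass1[nz_mass] / mass0[nz_mass],
               rep(1, sum(nz_mass)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(out >= 0))
  # diffusion smooths: the spread of the LDL field shrinks
  expect_lt(stats::sd(out[, "ldl"]), stats::sd(st[, "ldl"]))
})

test_that("SMC switching conserves the total SMC count exactly", {
  mesh <- straight_mesh(0.5)
  p <- kinetic_parameters()
  st <- species_state(mesh, p)
  st[, "cytokines"] <- runif(nrow(st), 0, 10)
  bc <- species_bc(adventitia = NULL, endothelium_sealed = TRUE)
  out <- step_species(st, mesh, NULL, NULL, p, bc = bc,
                      dt_s = months_to_seconds(6), frozen = "cytokines")
  total0 <- st[, "csmc"] + st[, "ssmc"]
  total1 <- out[, "csmc"] + out[, "ssmc"]
  expect_equal(total1, total0, tolerance = 1e-14)
  expect_true(all(out[, "ssmc"] > 0))  # switching happened
})

test_that("the spatial reaction path matches the adaptive 0-D integrator", {
  p0 <- reaction_only_params()
  mesh <- generate_synthetic_artery(artery_spec(length_mm = 2,
                                                edge_length_mm = 0.5))
  ep <- endothelial_parameters()
  endo <- uniform_endo_state(mesh, ep = ep)
  bc <- species_bc(2.8e-3, 3.2e-3, 5e11, adventitia = NULL)
  st <- species_state(mesh, p0)
  ops <- atherosim:::build_transport_ops(mesh, NULL, p0, 0.96)
  months <- 6
  for (k in seq_len(months)) {
    st <- step_species(st, mesh, NULL, endo, p0, ep, bc,
                       dt_s = months_to_seconds(1), ops = ops)
  }
  ec <- ops$endo_cells[1]
  sfv <- ops$A_endo[1] / (0.96 * ops$V[ec])
  dp <- endo$dp_m_s[1]; jv <- endo$j_v_m_s[1]
  flux <- function(t, c) {
    jsl <- dp * (2.8e-3 - c["ldl"]) + (1 - ep$sigma_f) * jv * (2.8e-3 + c["ldl"]) / 2
    jsh <- dp * (3.2e-3 - c["hdl"]) + (1 - ep$sigma_f) * jv * (3.2e-3 + c["hdl"]) / 2
    jm <- (ep$m_r_m3_mol_day / 86400) / 2 * c["oxldl"] * 5e11
    c(ldl = unname(jsl * sfv), hdl = unname(jsh * sfv),
      monocytes = unname(jm * sfv))
  }
  ode <- simulate_wellmixed(p0, flux, duration_s = months_to_seconds(months),
                            n_out = 30)
  ref <- as.numeric(ode[nrow(ode), atherosim:::species_names()])
  got <- st[ec, ]
  rel <- abs(got - ref) / pmax(abs(ref), 1e-12 * max(abs(ref)))
  expect_lt(max(rel), 0.01)
})

test_that("frozen-input trajectories match their closed forms", {
  p0 <- reaction_only_params()
  mesh <- generate_synthetic_artery(artery_spec(length_mm = 2,
                                                edge_length_mm = 0.5))
  bc <- species_bc(adventitia = NULL, endothelium_sealed = TRUE)
  # foam cells: frozen OxLDL, initial macrophage pool decays exponentially
  st <- species_state(mesh, p0)
  st[, "oxldl"] <- 1e-2; st[, "macrophages"] <- 1e9; st[, "csmc"] <- 0
  t_end <- days_to_seconds(100)
  out <- step_species(st, mesh, NULL, NULL, p0, bc = bc, dt_s = t_end,
                      frozen = "oxldl")
  foam_an <- 1e9 * (1 - exp(-p0$k_1 * 1e-2 * t_end))
  expect_equal(out[1, "foam"], foam_an, tolerance = 0.005,
               ignore_attr = TRUE)

  # cytokine steady state with frozen OxLDL and macrophages
  sim <- simulate_wellmixed(p0, duration_s = days_to_seconds(30),
                            init = list(oxldl = 1e-3, macrophages = 1e9,
                                        csmc = 0),
                            frozen = c("oxldl", "macrophages"))
  cyt_eq <- p0$d_r * 1e-3 * 1e9 / p0$d_c
  expect_equal(tail(sim$cytokines, 1), cyt_eq, tolerance = 0.005)

  # collagen steady state with frozen synthetic SMCs
  sim2 <- simulate_wellmixed(p0, duration_s = days_to_seconds(400),
                             init = list(ssmc = 1e10, csmc = 0),
                             frozen = "ssmc")
  coll_eq <- p0$g_r * 1e10 / p0$d_g
  expect_equal(tail(sim2$collagen, 1), coll_eq, tolerance = 0.005)
})

test_that("LDL oxidation bookkeeping balances with the printed asymmetry", {
  # sealed domain, LDL only: LDL loss = protection * OxLDL gain
  p0 <- reaction_only_params(m_d = 0, d_m = 0)
  mesh <- straight_mesh(0.5)
  st <- species_state(mesh, p0)
  st[, "csmc"] <- 0
  l0 <- 1e-4
  st[, "ldl"] <- l0
  bc <- species_bc(adventitia = NULL, endothelium_sealed = TRUE)
  out <- step_species(st, mesh, NULL, NULL, p0, bc = bc,
                      dt_s = days_to_seconds(1))
  ratio <- (l0 - out[1, "ldl"]) / out[1, "oxldl"]
  expect_equal(ratio, hdl_protection(0), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("nonnegativity is preserved across random admissible step sequences", {
  set.seed(42)
  mesh <- straight_mesh(0.5)
  p <- kinetic_parameters()
  ep <- endothelial_parameters()
  endo <- uniform_endo_state(mesh, wss = 0.5, ep = ep)
  for (rep in 1:5) {
    st <- species_state(mesh, p)
    n <- nrow(st)
    st[, "ldl"] <- runif(n, 0, 5e-3); st[, "hdl"] <- runif(n, 0, 5e-3)
    st[, "oxldl"] <- runif(n, 0, 1e-2); st[, "monocytes"] <- runif(n, 0, 1e6)
    st[, "macrophages"] <- runif(n, 0, 1e9); st[, "cytokines"] <- runif(n, 0, 10)
    bc <- species_bc(runif(1, 0, 5e-3), runif(1, 0, 5e-3), 5e11,
                     adventitia = list(ldl = 1e-5, hdl = 1e-5))
    out <- step_species(st, mesh, NULL, endo, p, ep, bc,
                        dt_s = months_to_seconds(2))
    expect_true(all(out >= 0))
    expect_false(anyNA(out))
  }
})
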