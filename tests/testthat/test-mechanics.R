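test_that("the active stress law rises, plateaus and decays as specified", {
  p <- mech_parameters(sigma0 = 295, k_atp = 0.02, k_rs = 0.03)
  # zero before activation
  expect_equal(active_stress(50, t_act = 100, t_rep = 400, p), 0)
  # value on the rising interval: 295 (1 - e^-2) at 100 ms after onset
  expect_equal(active_stress(200, 100, 400, p), 295 * (1 - exp(-2)),
               tolerance = 1e-12)
  # instantaneous rise limit reaches the plateau
  pfast <- mech_parameters(sigma0 = 295, k_atp = 1e3, k_rs = 0.03)
  expect_equal(active_stress(200, 100, 400, pfast), 295, tolerance = 1e-6)
  # continuity at repolarization and exponential release after it
  eps <- 1e-6
  before <- active_stress(400 - eps, 100, 400, p)
  after <- active_stress(400 + eps, 100, 400, p)
  expect_equal(before, after, tolerance = 1e-4)
  expect_equal(active_stress(500, 100, 400, p),
               295 * (1 - exp(-0.02 * 300)) * exp(-0.03 * 100),
               tolerance = 1e-10)
  # unactivated elements never contract
  expect_equal(active_stress(200, NA, NA, p), 0)
  expect_true(all(active_stress(200, c(100, NA), c(400, NA), p) ==
                    c(295 * (1 - exp(-2)), 0)))
})

test_that("rigid motions produce no co-rotational force", {
  m <- build_biventricular_mesh(anatomy_config(edge_length = 16))
  R <- rotation_align(c(0, 0, 1), c(1, 1, 1))
  disp <- m$nodes %*% t(R) - m$nodes
  disp <- sweep(disp, 2, c(5, -3, 2), "+")  # rotation + translation
  f <- passive_force(m, disp)
  # compare against the force scale of a 1% stretch
  fs <- passive_force(m, cbind(0.01 * m$nodes[, 1], 0, 0))
  expect_lt(max(abs(f)) / max(abs(fs)), 1e-8)
})

test_that("uniaxial and hydrostatic responses match linear elasticity", {
  cube <- build_box_mesh(c(10, 10, 10), c(3, 3, 3))
  xmax <- surface_nodes(cube, "XMAX")
  # nu ~ 0: uniaxial strain stress = E * eps, reaction on the face = E eps A
  E <- 500; eps <- 0.01
  p0 <- mech_parameters(E = E, nu = 1e-4)
  f <- passive_force(cube, cbind(eps * cube$nodes[, 1], 0, 0), p0)
  Fx <- sum(f[xmax, 1])
  expect_equal(Fx, E * eps * 100, tolerance = 1e-6)

  # nu = 0.48: uniform dilatation delta gives sigma_xx = 3 K delta with
  # bulk modulus K = E / (3 (1 - 2 nu))
  nu <- 0.48; delta <- 0.005
  p1 <- mech_parameters(E = E, nu = nu)
  f2 <- passive_force(cube, delta * cube$nodes, p1)
  K <- E / (3 * (1 - 2 * nu))
  expect_equal(sum(f2[xmax, 1]), 3 * K * delta * 100, tolerance = 0.02)

  # an inverting deformation is refused with a count
  expect_error(passive_force(cube, cbind(-1.2 * cube$nodes[, 1], 0, 0), p0),
               "invert")
})

test_that("a coupled beat contracts, keeps isovolumetric phases tight and cycles phases", {
  beat <- heart_beat()
  lv <- beat$lv
  expect_gt(lv$EF, 10)
  expect_lt(lv$ESV, lv$EDV)
  expect_equal(lv$SV, lv$EDV - lv$ESV, tolerance = 1e-9)
  expect_equal(lv$EF, 100 * lv$SV / lv$EDV, tolerance = 1e-9)

  pv <- beat$pv
  # phase sequence only moves forward through the cycle
  allowed <- list(FILLING = c("FILLING", "ISO_CONTRACTION"),
                  ISO_CONTRACTION = c("ISO_CONTRACTION", "EJECTION"),
                  EJECTION = c("EJECTION", "ISO_RELAXATION"),
                  ISO_RELAXATION = c("ISO_RELAXATION", "FILLING"))
  trans <- cbind(pv$phase_lv[-nrow(pv)], pv$phase_lv[-1])
  ok <- vapply(seq_len(nrow(trans)),
               function(i) trans[i, 2] %in% allowed[[trans[i, 1]]], TRUE)
  expect_true(all(ok))
  expect_setequal(unique(pv$phase_lv),
                  c("FILLING", "ISO_CONTRACTION", "EJECTION",
                    "ISO_RELAXATION"))

  # isovolumetric drift < 1% of stroke volume within each iso segment
  iso <- pv$phase_lv %in% c("ISO_CONTRACTION", "ISO_RELAXATION")
  seg <- cumsum(c(1, diff(iso) != 0))[iso]
  drift <- max(tapply(pv$v_lv[iso], seg, function(v) diff(range(v))))
  expect_lt(drift, 0.01 * lv$SV)

  # flow-volume consistency: ejected flow integrates to the stroke volume
  ej <- pv$phase_lv == "EJECTION"
  sv_flow <- sum(pv$q_lv[ej]) * beat$dt / 1000 / 1000  # mm^3/s -> ml
  expect_equal(sv_flow, lv$SV, tolerance = 0.01)

  # near-incompressibility at peak systole. With nu = 0.48 the bulk
  # modulus is K = E/(3(1-2 nu)) ~ 4900 kPa, so the trace of the active
  # stress alone implies a volumetric strain of sigma0/(3K) ~ 2%; together
  # with cavity-pressure compression the linear-elastic wall volume change
  # is bounded by ~5%, which is what near-incompressibility can deliver at
  # these stress levels.
  m <- heart_mesh()
  vol_of <- function(disp) {
    p1 <- m$nodes + disp
    a <- p1[m$tets[, 2], ] - p1[m$tets[, 1], ]
    b <- p1[m$tets[, 3], ] - p1[m$tets[, 1], ]
    cc <- p1[m$tets[, 4], ] - p1[m$tets[, 1], ]
    sum(abs(rowSums(a * cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
                              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
                              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])))) / 6
  }
  v0 <- vol_of(0 * m$nodes)
  ves <- vol_of(beat$displacement_es)
  expect_lt(abs(ves - v0) / v0, 0.05)

  # arterial pressures stay in a physiological band
  expect_gt(max(pv$p_ao), 70)
  expect_lt(max(pv$p_ao), 200)
})

test_that("ejection fraction rises with sigma0 and falls with stiffness", {
  m <- heart_mesh()
  fib <- heart_fibers()
  et <- element_activation_times(heart_sol(), m)
  ef <- function(E, s0) {
    simulate_beat(m, fib, et, mech_parameters(E = E, sigma0 = s0),
                  hemo_parameters(), early_stop = TRUE)$lv$EF
  }
  ef_lo <- ef(590, 180)
  ef_base <- heart_beat()$lv$EF
  ef_soft <- ef(450, 295)
  expect_lt(ef_lo, ef_base)   # weaker contraction, lower EF
  expect_gt(ef_soft, ef_base) # softer tissue, higher EF
})

test_that("without active stress the damped system dissipates energy", {
  cube <- build_box_mesh(c(10, 10, 10), c(2, 2, 2))
  p <- mech_parameters(E = 100, nu = 0.3, density = 0.4, damping = 0.3)
  setup <- cardiotwin:::mech_setup_cpp(cube$nodes, cube$tets, p$E, p$nu,
                                       p$density)
  n3 <- 3 * nrow(cube$nodes)
  U <- as.vector(t(cbind(0.05 * cube$nodes[, 1], 0, 0)))
  V <- numeric(n3)
  mass3 <- rep(pmax(setup$mass, 1e-12), each = 3)
  dt <- 0.05
  nstep <- 600
  energy <- numeric(nstep)
  for (s in seq_len(nstep)) {
    fr <- cardiotwin:::mech_force_cpp(cube$nodes, cube$tets, U, setup,
                                      numeric(nrow(cube$tets)),
                                      matrix(0, nrow(cube$tets), 3))
    V <- (V + dt * (-1e-3 * fr$force / mass3)) * exp(-p$damping * dt)
    U <- U + dt * V
    energy[s] <- fr$energy + 0.5 * sum(mass3 * V^2) / 1e-3
  }
  # total mechanical energy decays: never above its running envelope by
  # more than the O(dt) integrator wiggle, and strongly dissipated overall
  expect_lt(max(energy), 1.01 * energy[1])
  expect_true(all(energy <= 1.01 * cummin(energy) + 1e-9 * energy[1]))
  expect_lt(energy[nstep], 0.1 * energy[1])
})
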