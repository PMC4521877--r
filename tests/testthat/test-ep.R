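test_that("the resting state is a fixed point and dt is validated", {
  p <- ep_parameters()
  st <- ms_cell_step(list(u = 0, h = 1), dt = 0.1, params = p)
  expect_equal(st$u, 0)
  expect_equal(st$h, 1)
  expect_error(ms_cell_step(list(u = 0, h = 1), dt = 0, params = p),
               "positive")
  expect_error(ep_parameters(tau_in = -1), "positive")
  expect_error(ep_parameters(u_gate = 2), "u_gate")
  expect_error(ep_parameters(c_lv = 100, c_myo = 400), "c_myo")
})

test_that("0D action potential matches the stiff-ODE oracle and the closed form", {
  skip_if_not_installed("deSolve")
  # asymptotic regime (tau_close >> tau_out) where the closed form
  # APD = tau_close log(tau_out / (4 tau_in)) is accurate
  p <- ep_parameters(tau_close = 300)
  tr <- ms_simulate_cell(p, duration = 700, dt = 0.02)
  oracle <- ms_ode_oracle(p, duration = 700)
  apd_sim <- measure_apd(tr, threshold = 0.5)
  apd_ode <- measure_apd(oracle, threshold = 0.5)
  expect_equal(apd_sim, apd_ode, tolerance = 0.01)
  closed <- 300 * log(p$tau_out / (4 * p$tau_in))
  expect_equal(apd_sim, closed, tolerance = 0.05)
})

test_that("APD scales linearly with tau_close at the closed-form slope", {
  taus <- c(100, 150, 200)
  apds <- sapply(taus, function(tc) {
    measure_apd(ms_simulate_cell(ep_parameters(tau_close = tc),
                                 duration = 450, dt = 0.05),
                threshold = 0.5)
  })
  slope <- coef(lm(apds ~ taus))[[2]]
  expect_equal(slope, log(6 / (4 * 0.3)), tolerance = 0.05)
})

test_that("diffusion tensors encode the anisotropy by construction", {
  slab <- build_box_mesh(c(10, 10, 10), c(2, 2, 2))
  fib <- uniform_fiber_field(slab, c(1, 0, 0))
  p <- ep_parameters(c_myo = 9, c_lv = 9, c_rv = 9, anisotropy_ratio = 9)
  D <- assemble_diffusivity(slab, fib, p)
  expect_equal(D[1, ], c(9, 0, 0, 0, 1, 0, 0, 0, 1), tolerance = 1e-12)

  # random fiber: eigenvalues (c, c/r, c/r), congruent rotation
  set.seed(1)
  v <- rnorm(3); v <- v / sqrt(sum(v^2))
  fib2 <- uniform_fiber_field(slab, v)
  p2 <- ep_parameters(c_myo = 413, c_lv = 413, c_rv = 413)
  D2 <- assemble_diffusivity(slab, fib2, p2)
  M <- matrix(D2[1, ], 3, 3, byrow = TRUE)
  ev <- sort(eigen(M, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(ev, c(413, 413 / 9, 413 / 9), tolerance = 1e-9)
  Dx <- matrix(assemble_diffusivity(slab, fib, p2)[1, ], 3, 3, byrow = TRUE)
  R <- rotation_align(c(1, 0, 0), v)
  expect_equal(M, R %*% Dx %*% t(R), tolerance = 1e-9)
})

test_that("rest is an equilibrium and the potential stays in bounds", {
  slab <- build_box_mesh(c(20, 8, 8), c(5, 2, 2))
  fib <- uniform_fiber_field(slab)
  quiet <- stimulus_protocol(list(list(nodes = 1L, onset = 1e6,
                                       duration = 1, amplitude = 1)))
  sol0 <- simulate_ep(slab, fib, ep_parameters(), quiet, duration = 50,
                      dt = 0.1)
  expect_equal(max(abs(sol0$U)), 0)
  expect_true(all(is.na(sol0$activation)))

  # short-APD parameters so one run covers depolarization + repolarization
  p60 <- ep_parameters(tau_close = 60)
  sol <- simulate_ep(slab, fib, p60, face_protocol(slab),
                     duration = 250, dt = 0.1)
  expect_gte(min(sol$U), -0.05)
  expect_lte(max(sol$U), 1.05)
  # activation earliest at the stimulated face
  stim_nodes <- surface_nodes(slab, "XMIN")
  expect_lt(max(sol$activation[stim_nodes]),
            min(sol$activation[setdiff(which(slab$nodes[, 1] > 15),
                                       stim_nodes)]))
  # activation precedes repolarization wherever both are defined
  both <- !is.na(sol$activation) & !is.na(sol$repolarization)
  expect_gt(sum(both), 0)
  expect_true(all(sol$activation[both] < sol$repolarization[both]))
})

test_that("conduction velocity scales as the square root of diffusivity", {
  bar <- build_box_mesh(c(50, 6, 6), c(50, 6, 6))
  fib <- uniform_fiber_field(bar)
  cv <- sapply(c(413, 4 * 413), function(cm) {
    p <- ep_parameters(c_myo = cm, c_lv = 4 * cm, c_rv = 4 * cm)
    sol <- simulate_ep(bar, fib, p, face_protocol(bar), duration = 90,
                       dt = 0.1)
    conduction_velocity(bar, sol$activation, 1)
  })
  expect_equal(cv[2] / cv[1], 2, tolerance = 0.1)
})

test_that("the stability guard names the maximal stable step", {
  slab <- build_box_mesh(c(10, 5, 5), c(2, 1, 1))
  fib <- uniform_fiber_field(slab)
  expect_error(simulate_ep(slab, fib, ep_parameters(), face_protocol(slab),
                           duration = 10, dt = 0.5),
               "maximal stable dt")
})

test_that("pacing protocols are well-formed and RV-only pacing widens the QRS", {
  m <- heart_mesh()
  sp <- sinus_protocol(m)
  expect_s3_class(sp, "stimulus_protocol")
  expect_true(all(vapply(sp$sites, function(s) length(s$nodes) > 0, TRUE)))
  biv <- crt_protocol(m, "BIV")
  expect_equal(biv$sites[[2]]$onset - biv$sites[[1]]$onset, 20)
  expect_error(stimulus_protocol(list(list(nodes = integer(), onset = 0,
                                           duration = 1, amplitude = 1))),
               "empty")

  # single-site RV pacing de-synchronizes the ventricles relative to sinus
  fib <- heart_fibers()
  p <- ep_parameters()
  torso <- heart_torso()
  rvp <- crt_protocol(m, "RV_ONLY")
  sol_rv <- simulate_ep(m, fib, p, rvp, duration = 250, dt = 0.1)
  f_sin <- extract_features(compute_ecg(heart_sol(), m, fib, p, torso))
  f_rv <- extract_features(compute_ecg(sol_rv, m, fib, p, torso))
  expect_gt(f_rv$qrsd, f_sin$qrsd)
})
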