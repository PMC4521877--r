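test_that("torso electrodes sit on the surface, deterministically", {
  m <- heart_mesh()
  t1 <- build_torso(m)
  t2 <- build_torso(m)
  expect_identical(t1$electrodes, t2$electrodes)
  implicit <- rowSums(sweep(t1$electrodes, 2, t1$config$semi_axes, "/")^2) - 1
  expect_lt(max(abs(implicit)), 1e-6)
  expect_equal(nrow(t1$electrodes), 10)
  # a heart larger than the torso is rejected
  expect_error(build_torso(m, torso_config(semi_axes = c(40, 40, 40))),
               "fit")
})

test_that("electrode potentials match a direct dipole-sum oracle", {
  # tiny bar with a synthetic linear potential field
  bar <- build_box_mesh(c(10, 4, 4), c(2, 1, 1))
  bar$nodes <- sweep(bar$nodes, 2, c(5, 2, 2))  # centre at origin
  fib <- uniform_fiber_field(bar)
  p <- ep_parameters(c_myo = 413, c_lv = 413, c_rv = 413)
  u <- bar$nodes[, 1] / 10 + 0.5
  sol <- structure(list(times = c(0, 1), U = cbind(0, u),
                        activation = rep(NA, nrow(bar$nodes)),
                        repolarization = rep(NA, nrow(bar$nodes)),
                        n_nodes = nrow(bar$nodes)), class = "ep_solution")
  torso <- build_torso(bar)
  trace <- compute_ecg(sol, bar, fib, p, torso)
  D <- assemble_diffusivity(bar, fib, p)
  el <- torso$electrodes_heart_frame
  oracle <- sapply(rownames(el), function(nm) {
    dipole_potential_oracle(bar, D, u, el[nm, ])
  })
  lead_I <- oracle["LA"] - oracle["RA"]
  expect_equal(unname(trace$leads[2, "I"]), unname(lead_I),
               tolerance = 1e-6)
  lead_aVF <- oracle["LL"] - (oracle["RA"] + oracle["LA"]) / 2
  expect_equal(unname(trace$leads[2, "aVF"]), unname(lead_aVF),
               tolerance = 1e-6)
})

test_that("a spatially uniform potential produces zero leads; Einthoven holds", {
  m <- heart_mesh()
  n <- nrow(m$nodes)
  solU <- structure(list(times = 0:2, U = cbind(rep(0.3, n), rep(0.8, n),
                                                rep(0.1, n)),
                         n_nodes = n), class = "ep_solution")
  tr0 <- compute_ecg(solU, m, heart_fibers(), ep_parameters(), heart_torso())
  expect_lt(max(abs(tr0$leads)), 1e-9)

  tr <- heart_trace()
  resid <- tr$leads[, "I"] + tr$leads[, "III"] - tr$leads[, "II"]
  expect_lt(max(abs(resid)), 1e-12 * max(abs(tr$leads)))
})

test_that("feature extraction recovers constructed QRS/QT/axis ground truth", {
  tt <- seq(0, 450, by = 1)
  # triangular bumps: constant-magnitude derivative, so the envelope
  # threshold crossings coincide with the support edges
  bump <- function(t0, t1) {
    mid <- (t0 + t1) / 2
    pmax(0, ifelse(tt <= mid, (tt - t0) / (mid - t0),
                   (t1 - tt) / (t1 - mid)))
  }
  qrs <- bump(50, 150)     # QRS support exactly 100 ms
  twave <- 0.3 * bump(300, 400)
  mk <- function(I, aVF) {
    L <- matrix(0, length(tt), 12,
                dimnames = list(NULL, c("I", "II", "III", "aVR", "aVL",
                                        "aVF", paste0("V", 1:6))))
    L[, "I"] <- I; L[, "aVF"] <- aVF
    ecg_trace(tt, L)
  }
  f1 <- extract_features(mk(qrs + twave, 0))
  expect_equal(f1$qrsd, 100, tolerance = 2 * 1 / 100)  # within 2 samples
  expect_equal(f1$qtd, 350, tolerance = 0.03)
  expect_equal(f1$ea, 0, tolerance = 1)

  f2 <- extract_features(mk(qrs, qrs))
  expect_equal(f2$ea, 45, tolerance = 1)
  f3 <- extract_features(mk(qrs, -qrs))
  expect_equal(f3$ea, -45, tolerance = 1)

  # amplitude scaling and time shift leave features unchanged
  tr <- mk(qrs + twave, 0.5 * qrs)
  fa <- extract_features(tr)
  trs <- ecg_trace(tt, 7.3 * tr$leads)
  expect_equal(extract_features(trs)[c("qrsd", "qtd", "ea")],
               fa[c("qrsd", "qtd", "ea")])
  tsh <- ecg_trace(tt + 40, tr$leads)
  fsh <- extract_features(tsh)
  expect_equal(fsh$qrsd, fa$qrsd)
  expect_equal(fsh$ea, fa$ea)

  expect_error(extract_features(mk(0 * qrs, 0 * qrs)), "no QRS")
})

test_that("far-field torso scaling preserves QRS duration and the axis converges", {
  m <- heart_mesh()
  scaled_features <- function(s) {
    to <- build_torso(m, torso_config(semi_axes = s * c(180, 320, 120),
                                      heart_center = s * c(35, -20, 55)))
    tr <- compute_ecg(heart_sol(), m, heart_fibers(), ep_parameters(), to)
    list(f = extract_features(tr), amp = max(abs(tr$leads)))
  }
  s2 <- scaled_features(2)
  s4 <- scaled_features(4)
  # in the far field the signals become pure dipole projections: global
  # durations are scale-invariant and the axis converges
  expect_equal(s4$f$qrsd, s2$f$qrsd, tolerance = 1e-6)
  expect_lt(abs(s4$f$ea - s2$f$ea), 5)
  # amplitudes fall off with distance while features hold
  expect_lt(s4$amp, 0.3 * s2$amp)
})

test_that("longer tau_close prolongs the extracted QT interval", {
  m <- heart_mesh()
  fib <- heart_fibers()
  torso <- heart_torso()
  qts <- sapply(c(140, 185), function(tc) {
    p <- ep_parameters(tau_close = tc)
    sol <- simulate_ep(m, fib, p, sinus_protocol(m), duration = 480,
                       dt = 0.1)
    extract_features(compute_ecg(sol, m, fib, p, torso))$qtd
  })
  expect_gt(qts[2], qts[1] + 40)
})
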