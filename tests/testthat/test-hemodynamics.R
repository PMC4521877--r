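test_that("Windkessel equilibrium, steady state and periodic response", {
  wk <- wk3_parameters()
  # no flow, distal pressure at the remote pressure: stays there
  st <- wk3_step(p_distal = wk$Pr, Q = 0, dt = 1e-3, wk = wk)
  expect_equal(st$p_distal, wk$Pr)
  expect_equal(st$p_prox, wk$Pr)
  expect_error(wk3_step(50, 0, dt = 0, wk), "positive")
  expect_error(wk3_parameters(Rc = 1e-3, Rp = 1e-4), "smaller")

  # constant inflow: closed-form steady state p = Pr + (Rc + Rp) Q
  Q0 <- 8e4  # mm^3/s
  df <- wk3_simulate(function(t) Q0, wk, period = 1, n_cycles = 10)
  expect_equal(tail(df$p_prox, 1), wk$Pr + (wk$Rc + wk$Rp) * Q0,
               tolerance = 0.001)

  # population-mean aortic parameters, half-sinusoid systolic pulse:
  # periodic regime with mean p = Pr + (Rc + Rp) mean Q and a
  # systolic > diastolic > Pr ordering
  period <- 0.857
  stroke <- 70 * 1000  # mm^3 per beat
  tej <- 0.3
  qmax <- stroke * pi / (2 * tej)
  pulse <- function(t) ifelse(t < tej, qmax * sin(pi * t / tej), 0)
  df2 <- wk3_simulate(pulse, wk, period = period, n_cycles = 12,
                      dt = 5e-4)
  hist <- attr(df2, "history")
  last <- df2$p_prox
  prev <- hist$p_prox[hist$t >= period * 10 & hist$t < period * 11]
  expect_lt(max(abs(last - prev)) / mean(last), 0.01)  # periodic
  qbar <- stroke / period
  expect_equal(mean(df2$p_distal), wk$Pr + wk$Rp * qbar, tolerance = 0.02)
  expect_gt(max(df2$p_prox), mean(df2$p_prox))
  expect_gt(min(df2$p_distal), wk$Pr)
})

test_that("the Windkessel update matches a stiff-ODE oracle", {
  skip_if_not_installed("deSolve")
  wk <- wk3_parameters(C = 1500, Rp = 4e-4, Rc = 5e-5, Pr = 40)
  pulse <- function(t) ifelse(t < 0.25, 3e5 * sin(pi * t / 0.25), 0)
  rhs <- function(t, y, p) {
    list((pulse(t %% 0.8) - (y - wk$Pr) / wk$Rp) / wk$C)
  }
  tt <- seq(0, 8, by = 1e-3)
  ode <- deSolve::lsoda(wk$Pr, tt, rhs, NULL, rtol = 1e-8, atol = 1e-8)
  df <- wk3_simulate(pulse, wk, period = 0.8, n_cycles = 10, dt = 1e-3)
  hist <- attr(df, "history")
  sel <- hist$t > 6
  oracle <- approx(ode[, 1], ode[, 2], xout = hist$t[sel])$y
  rmse <- sqrt(mean((hist$p_distal[sel] - oracle)^2))
  expect_lt(rmse, 0.5)  # mmHg
})

test_that("the valve state machine follows the four-phase rules", {
  expect_equal(phase_machine(9, 8, 80, -1, "FILLING"), "ISO_CONTRACTION")
  expect_equal(phase_machine(5, 8, 80, -1, "FILLING"), "FILLING")
  expect_equal(phase_machine(81, 8, 80, -1, "ISO_CONTRACTION"), "EJECTION")
  expect_equal(phase_machine(60, 8, 80, -1, "ISO_CONTRACTION"),
               "ISO_CONTRACTION")
  expect_equal(phase_machine(90, 8, 85, 0.1, "EJECTION"), "ISO_RELAXATION")
  expect_equal(phase_machine(90, 8, 85, -5, "EJECTION"), "EJECTION")
  expect_equal(phase_machine(5, 8, 80, 0, "ISO_RELAXATION"), "FILLING")
  expect_equal(phase_machine(20, 8, 80, 0, "ISO_RELAXATION"),
               "ISO_RELAXATION")
})

test_that("isovolumetric pressure solves the volume constraint", {
  # synthetic monotone compliance curve
  vfn <- function(p) 100 + 0.8 * p + 0.002 * p^2
  p_star <- 42
  p <- isovolumetric_pressure(vfn, target = vfn(p_star), bracket = c(0, 200))
  expect_equal(p, p_star, tolerance = 1e-4)
  expect_lt(abs(vfn(p) - vfn(p_star)) / vfn(p_star), 0.01)
  # fixed point: target equal to the current volume returns current pressure
  expect_equal(isovolumetric_pressure(vfn, vfn(10), c(0, 200)), 10,
               tolerance = 1e-4)
  expect_error(isovolumetric_pressure(vfn, 1e6, c(0, 200)), "bracket")

  # a stiffer wall needs more pressure for the same volume excursion
  m <- heart_mesh(); fib <- heart_fibers()
  dp <- sapply(c(400, 800), function(E) {
    ctx <- cardiotwin:::mech_context(m, fib, mech_parameters(E = E))
    n3 <- 3 * nrow(m$nodes)
    ld <- cardiotwin:::cavity_state(ctx, "LV", numeric(n3), TRUE)
    # quasi-static volume response to a static pressure (fixed relaxation)
    vfn_E <- function(p_mmHg) {
      U <- numeric(n3); V <- numeric(n3)
      mass3 <- ctx$mass3
      for (s in 1:400) {
        fr <- cardiotwin:::mech_force_cpp(m$nodes, m$tets, U, ctx$setup,
                                          numeric(nrow(m$tets)),
                                          fib$vectors)
        ld2 <- cardiotwin:::cavity_state(ctx, "LV", U, TRUE)
        Fb <- cardiotwin:::constraint_force(ctx, U) - fr$force +
          p_mmHg * 0.1333224 * ld2$load
        V <- (V + 0.25 * (1e-3 * Fb / mass3)) * exp(-0.5 * 0.25)
        U <- U + 0.25 * V
      }
      cardiotwin:::cavity_state(ctx, "LV", U)$volume
    }
    v0 <- cardiotwin:::cavity_state(ctx, "LV", numeric(n3))$volume
    vfn_E(10) - v0
  })
  expect_lt(dp[2], dp[1])  # stiffer -> smaller volume gain at equal pressure
})
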