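# Independent oracles used to freeze expected values: a stiff-ODE
# integration of the cell model (deSolve), the closed-form truncated-normal
# mean, and a direct dipole-sum pseudo-ECG evaluation.

# Mitchell-Schaeffer cell trajectory by piecewise lsoda integration
# (segments split at the stimulus edges to keep the RHS smooth)
ms_ode_oracle <- function(params, duration, stim_onset = 5, stim_dur = 1,
                          amp = 1, dt_out = 0.1) {
  rhs <- function(t, y, stim) {
    du <- y[2] * y[1]^2 * (1 - y[1]) / params$tau_in -
      y[1] / params$tau_out + stim
    dh <- if (y[1] < params$u_gate) (1 - y[2]) / params$tau_open else
      -y[2] / params$tau_close
    list(c(du, dh))
  }
  segs <- list(c(0, stim_onset, 0), c(stim_onset, stim_onset + stim_dur, amp),
               c(stim_onset + stim_dur, duration, 0))
  y <- c(u = 0, h = 1)
  out <- NULL
  for (sg in segs) {
    if (sg[2] <= sg[1]) next
    tt <- seq(sg[1], sg[2], by = dt_out)
    if (tail(tt, 1) < sg[2]) tt <- c(tt, sg[2])
    sol <- deSolve::lsoda(y, tt, function(t, y, p) rhs(t, y, sg[3]),
                          parms = NULL, rtol = 1e-9, atol = 1e-9)
    y <- sol[nrow(sol), 2:3]
    names(y) <- c("u", "h")
    out <- rbind(out, sol[-1, , drop = FALSE])
  }
  data.frame(t = out[, 1], u = out[, 2], h = out[, 3])
}

# mean of a truncated normal (closed form)
truncnorm_mean_oracle <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# direct dipole-sum pseudo-ECG for one electrode: least-squares per-element
# gradient of u (QR, independent of the package's shape-function algebra)
dipole_potential_oracle <- function(mesh, D_rowmajor, u, electrode) {
  phi <- 0
  for (e in seq_len(nrow(mesh$tets))) {
    vid <- mesh$tets[e, ]
    X <- mesh$nodes[vid, ]
    A <- cbind(1, X)
    g <- qr.solve(A, u[vid])[2:4]
    vol <- abs(det(cbind(X[2, ] - X[1, ], X[3, ] - X[1, ],
                         X[4, ] - X[1, ]))) / 6
    D <- matrix(D_rowmajor[e, ], 3, 3, byrow = TRUE)
    cc <- colMeans(X)
    r <- electrode - cc
    gr <- r / sum(r^2)^1.5
    phi <- phi - vol * sum((D %*% g) * gr)
  }
  phi
}
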