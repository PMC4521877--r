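# Monodomain Mitchell-Schaeffer electrophysiology. The two-variable cell
# model (normalized potential u, recovery gate h) is operator-split against
# P1 finite-element diffusion with mass lumping: reaction explicit, diffusion
# implicit (one cached Cholesky factorization per parameter set), no-flux
# boundaries.

#' Mitchell-Schaeffer / monodomain parameters
#'
#' Cell-model time constants in ms; conductivities (along-fiber diffusivities
#' of the normalized monodomain equation) in mm^2/s. Note the loose clinical
#' use of "conductivity": these values scale the diffusion tensor, and the
#' conduction velocity scales as their square root. The action potential
#' duration is controlled by `tau_close` (related to the QT interval);
#' `tau_in`, `tau_out`, `tau_open` keep their standard defaults.
#'
#' @param tau_in,tau_out,tau_open,tau_close ms.
#' @param u_gate dimensionless gate threshold in (0, 1).
#' @param c_myo bulk myocardial diffusivity (mm^2/s).
#' @param c_lv,c_rv fast sub-endocardial layer diffusivities (mm^2/s); must
#'   be >= `c_myo`.
#' @param anisotropy_ratio along-fiber / cross-fiber diffusivity ratio
#'   (default 9, i.e. a fiber speed three times the cross-fiber speed).
#' @return object of class `ep_parameters`.
#' @export
ep_parameters <- function(tau_in = 0.3, tau_out = 6, tau_open = 120,
                          tau_close = 150, u_gate = 0.13,
                          c_myo = 413, c_lv = 1600, c_rv = 2200,
                          anisotropy_ratio = 9) {
  if (any(c(tau_in, tau_out, tau_open, tau_close) <= 0)) {
    stop("all time constants must be positive")
  }
  if (u_gate <= 0 || u_gate >= 1) stop("u_gate must lie in (0, 1)")
  if (any(c(c_myo, c_lv, c_rv) <= 0)) stop("conductivities must be positive")
  if (c_lv < c_myo || c_rv < c_myo) {
    stop("fast-layer conductivities must be >= c_myo")
  }
  if (anisotropy_ratio < 1) stop("anisotropy_ratio must be >= 1")
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, u_gate = u_gate,
                 c_myo = c_myo, c_lv = c_lv, c_rv = c_rv,
                 anisotropy_ratio = anisotropy_ratio),
            class = "ep_parameters")
}

#' One explicit step of the Mitchell-Schaeffer cell model
#'
#' Vectorized over state entries. Dynamics: du/dt = h u^2 (1-u)/tau_in -
#' u/tau_out + stim; dh/dt = (1-h)/tau_open below the gate threshold,
#' -h/tau_close above it.
#'
#' @param state list with numeric `u` and `h` (same length).
#' @param dt time step (ms), must be positive.
#' @param params an [ep_parameters()].
#' @param stim stimulus current (1/ms), scalar or vector.
#' @return updated list(u, h).
#' @export
ms_cell_step <- function(state, dt, params, stim = 0) {
  if (dt <= 0) stop("dt must be positive")
  u <- state$u; h <- state$h
  du <- h * u * u * (1 - u) / params$tau_in - u / params$tau_out + stim
  dh <- ifelse(u < params$u_gate,
               (1 - h) / params$tau_open,
               -h / params$tau_close)
  list(u = u + dt * du, h = h + dt * dh)
}

#' Integrate the 0D Mitchell-Schaeffer cell model
#'
#' @param params an [ep_parameters()].
#' @param duration total time (ms).
#' @param dt step (ms); must satisfy the explicit stability bound
#'   `dt <= tau_in / 3`.
#' @param stim_onset,stim_duration,stim_amplitude square stimulus pulse.
#' @return data.frame with columns t, u, h.
#' @export
ms_simulate_cell <- function(params = ep_parameters(), duration = 500,
                             dt = 0.05, stim_onset = 5, stim_duration = 1,
                             stim_amplitude = 1) {
  nstep <- ceiling(duration / dt)
  u <- numeric(nstep + 1); hh <- numeric(nstep + 1)
  state <- list(u = 0, h = 1)
  hh[1] <- 1
  for (s in seq_len(nstep)) {
    t <- (s - 1) * dt
    stim <- if (t >= stim_onset && t < stim_onset + stim_duration)
      stim_amplitude else 0
    state <- ms_cell_step(state, dt, params, stim)
    u[s + 1] <- state$u; hh[s + 1] <- state$h
  }
  data.frame(t = (0:nstep) * dt, u = u, h = hh)
}

#' Action potential duration of a 0D trace
#'
#' Duration for which u exceeds the threshold (with linear interpolation of
#' the crossings). The closed-form value for a stimulated resting cell is
#' approximately `tau_close * log(tau_out / (4 * tau_in))`.
#'
#' @param trace data.frame from [ms_simulate_cell()].
#' @param threshold potential threshold (default: the gate value 0.13).
#' @return APD in ms (NA if never above threshold).
#' @export
measure_apd <- function(trace, threshold = 0.13) {
  above <- trace$u > threshold
  if (!any(above)) return(NA_real_)
  i_on <- which(diff(c(FALSE, above)) == 1)[1]
  i_off <- max(which(above))
  interp <- function(i0, i1) {
    if (i0 < 1 || i1 > nrow(trace)) return(trace$t[max(1, min(i0, nrow(trace)))])
    u0 <- trace$u[i0]; u1 <- trace$u[i1]
    trace$t[i0] + (threshold - u0) / (u1 - u0) * (trace$t[i1] - trace$t[i0])
  }
  t_on <- interp(i_on - 1, i_on)
  t_off <- if (i_off < nrow(trace)) interp(i_off, i_off + 1) else trace$t[i_off]
  t_off - t_on
}

#' Per-element anisotropic diffusion tensors
#'
#' D = c_tag (f f' + (1/r)(I - f f')) with c_tag selected by the element tag
#' (bulk myocardium or LV/RV fast layer), r the anisotropy ratio and f the
#' unit fiber direction; c_tag is the along-fiber diffusivity, in mm^2/s.
#'
#' @param mesh a `bv_mesh` with element tags.
#' @param fibers a `fiber_field`.
#' @param params an [ep_parameters()].
#' @return M x 9 matrix of row-major 3x3 tensors (mm^2/s).
#' @export
assemble_diffusivity <- function(mesh, fibers, params) {
  f <- fibers$vectors
  if (nrow(f) != nrow(mesh$tets)) stop("fiber field does not match mesh")
  if (any(!is.finite(f))) stop("non-finite fiber directions")
  ctag <- c(MYO = params$c_myo, LV_FAST_LAYER = params$c_lv,
            RV_FAST_LAYER = params$c_rv)[as.character(mesh$element_tag)]
  r <- params$anisotropy_ratio
  # D_ij = c * ((1 - 1/r) f_i f_j + (1/r) delta_ij)
  ff <- cbind(f[, 1] * f[, 1], f[, 1] * f[, 2], f[, 1] * f[, 3],
              f[, 2] * f[, 1], f[, 2] * f[, 2], f[, 2] * f[, 3],
              f[, 3] * f[, 1], f[, 3] * f[, 2], f[, 3] * f[, 3])
  eye <- rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = nrow(f))
  dim(eye) <- c(nrow(f), 9)
  ctag * ((1 - 1 / r) * ff + (1 / r) * eye)
}

#' Stimulus protocol
#'
#' A list of stimulation sites: node sets with onset, duration and amplitude.
#'
#' @param sites list of lists with fields `nodes` (integer indices), `onset`
#'   (ms), `duration` (ms), `amplitude` (1/ms).
#' @param name protocol label.
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(sites, name = "CUSTOM") {
  for (s in sites) {
    if (length(s$nodes) == 0) stop("empty stimulation node set")
    if (s$onset < 0) stop("stimulus onsets must be >= 0")
  }
  structure(list(sites = sites, name = name), class = "stimulus_protocol")
}

# nodes on the upper (basal) third of a labeled surface
upper_third_nodes <- function(mesh, labels) {
  ns <- surface_nodes(mesh, labels)
  if (length(ns) == 0) return(integer())
  z <- mesh$nodes[ns, 3]
  ns[z >= quantile(z, 2 / 3)]
}

#' Sinus-rhythm (His bundle) stimulation protocol
#'
#' The activation starts simultaneously on the LV and RV faces of the upper
#' third of the septum, standing in for the His bundle entry of the normal
#' conduction system.
#'
#' @param mesh a `bv_mesh`.
#' @param onset stimulus time (ms).
#' @param amplitude stimulus current (1/ms).
#' @return a [stimulus_protocol()].
#' @export
sinus_protocol <- function(mesh, onset = 0, amplitude = 2) {
  lv <- upper_third_nodes(mesh, "LV_SEPTUM")
  rv <- upper_third_nodes(mesh, "RV_SEPTUM")
  if (length(lv) == 0 || length(rv) == 0) {
    stop("mesh lacks labeled septal surfaces for His-bundle initiation")
  }
  stimulus_protocol(list(
    list(nodes = lv, onset = onset, duration = 1, amplitude = amplitude),
    list(nodes = rv, onset = onset, duration = 1, amplitude = amplitude)),
    name = "SINUS")
}

# k nearest mesh nodes to a coordinate
nearest_nodes <- function(mesh, xyz, k = 4) {
  d2 <- colSums((t(mesh$nodes) - xyz)^2)
  order(d2)[seq_len(k)]
}

#' Default CRT lead positions on the mesh
#'
#' LV lead on the lateral LV epicardium (opposite the RV sector, mid
#' base-apex height), RV lead at the RV endocardial apex.
#'
#' @param mesh a `bv_mesh` with an RV.
#' @return list with `lv_lead` and `rv_lead` coordinates.
#' @export
default_crt_leads <- function(mesh) {
  cfg <- mesh$config
  phi_lat <- (cfg$rv_center + 180) * pi / 180
  epi <- surface_nodes(mesh, "EPI")
  zmid <- mean(range(mesh$nodes[epi, 3]))
  target <- c(cos(phi_lat), sin(phi_lat), 0) * max(cfg$lv_radii) + c(0, 0, zmid)
  lv_lead <- mesh$nodes[epi[which.min(colSums((t(mesh$nodes[epi, ]) - target)^2))], ]
  rvn <- surface_nodes(mesh, "RV_ENDO")
  rv_lead <- mesh$nodes[rvn[which.min(mesh$nodes[rvn, 3])], ]
  list(lv_lead = lv_lead, rv_lead = rv_lead)
}

#' Cardiac resynchronization pacing protocols
#'
#' Three stimulation modes: `BIV` (biventricular pacing, LV lead first, RV
#' lead after `lv_rv_delay` ms, default 20), `RV_ONLY` (RV lead alone) and
#' `LV_TRIGGERED` (native His activation plus an LV lead fired after
#' `sense_delay` ms, a DDT-like triggered mode). Lead node sets are chosen as
#' the nearest mesh nodes to the supplied coordinates.
#'
#' @param mesh a `bv_mesh`.
#' @param mode pacing mode.
#' @param lv_lead,rv_lead xyz coordinates (mm); defaults from
#'   [default_crt_leads()].
#' @param lv_rv_delay LV-to-RV delay (ms) for BIV.
#' @param sense_delay trigger delay (ms) for LV_TRIGGERED.
#' @param amplitude stimulus current (1/ms).
#' @return a [stimulus_protocol()].
#' @export
crt_protocol <- function(mesh, mode = c("BIV", "RV_ONLY", "LV_TRIGGERED"),
                         lv_lead = NULL, rv_lead = NULL, lv_rv_delay = 20,
                         sense_delay = 40, amplitude = 2) {
  mode <- match.arg(mode)
  leads <- default_crt_leads(mesh)
  lv_lead <- lv_lead %||% leads$lv_lead
  rv_lead <- rv_lead %||% leads$rv_lead
  lv_nodes <- nearest_nodes(mesh, lv_lead)
  rv_nodes <- nearest_nodes(mesh, rv_lead)
  sites <- switch(mode,
    BIV = list(
      list(nodes = lv_nodes, onset = 0, duration = 1, amplitude = amplitude),
      list(nodes = rv_nodes, onset = lv_rv_delay, duration = 1,
           amplitude = amplitude)),
    RV_ONLY = list(
      list(nodes = rv_nodes, onset = 0, duration = 1, amplitude = amplitude)),
    LV_TRIGGERED = c(
      sinus_protocol(mesh, amplitude = amplitude)$sites,
      list(list(nodes = lv_nodes, onset = sense_delay, duration = 1,
                amplitude = amplitude))))
  stimulus_protocol(sites, name = paste0("CRT_", mode))
}

#' Solve the monodomain equation on a mesh
#'
#' Operator-split integration: explicit Mitchell-Schaeffer reaction, implicit
#' lumped-mass P1 diffusion with no-flux boundaries. The activation map is
#' the first upward crossing of u = 0.5, the repolarization map the last
#' downward crossing (linear interpolation in time).
#'
#' @param mesh a `bv_mesh`.
#' @param fibers a `fiber_field` on the same mesh.
#' @param params an [ep_parameters()].
#' @param protocol a [stimulus_protocol()].
#' @param duration total simulated time (ms); must cover depolarization plus
#'   repolarization when QT-type features are needed.
#' @param dt time step (ms). The explicit reaction bound requires
#'   `dt <= tau_in / 3`; violating it is an error naming the maximal stable
#'   step.
#' @param store_stride snapshot interval (ms) for the stored potential.
#' @return object of class `ep_solution`: `times`, `U` (nodes x snapshots),
#'   `activation`, `repolarization` (ms, NA where undefined), plus the
#'   inputs.
#' @export
simulate_ep <- function(mesh, fibers, params = ep_parameters(),
                        protocol, duration = 500, dt = 0.1,
                        store_stride = 1) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (dt <= 0) stop("dt must be positive")
  dt_max <- params$tau_in / 3
  if (dt > dt_max + 1e-12) {
    stop("dt = ", dt, " ms violates the reaction stability bound; ",
         "maximal stable dt = ", signif(dt_max, 3), " ms")
  }
  n <- nrow(mesh$nodes)
  D <- assemble_diffusivity(mesh, fibers, params)
  K <- fem_stiffness(mesh$nodes, mesh$tets, D * 1e-3)  # mm^2/ms
  Mv <- fem_lumped_mass(mesh$nodes, mesh$tets)
  A <- Matrix::Diagonal(x = Mv) + dt * K
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)

  nstep <- ceiling(duration / dt)
  stride_steps <- max(1L, round(store_stride / dt))
  keep <- seq(0L, nstep, by = stride_steps)
  store_at <- rep(FALSE, nstep)
  store_at[keep[-1]] <- TRUE
  U <- matrix(0, n, length(keep))
  times <- keep * dt
  u <- numeric(n); h <- rep(1, n)
  act <- rep(NA_real_, n); rep_ <- rep(NA_real_, n)
  kcol <- 1L
  thr <- 0.5
  for (s in seq_len(nstep)) {
    t <- (s - 1) * dt
    stim <- numeric(n)
    for (site in protocol$sites) {
      if (t >= site$onset && t < site$onset + site$duration) {
        # depolarizing current; gated off once the cell is fully excited
        stim[site$nodes] <- stim[site$nodes] +
          site$amplitude * (u[site$nodes] < 1)
      }
    }
    du <- h * u * u * (1 - u) / params$tau_in - u / params$tau_out + stim
    h <- h + dt * ifelse(u < params$u_gate,
                         (1 - h) / params$tau_open, -h / params$tau_close)
    ustar <- u + dt * du
    unew <- as.numeric(Matrix::solve(ch, Mv * ustar, system = "A"))
    up <- unew >= thr & u < thr
    if (any(up)) {
      tc <- t + dt * (thr - u[up]) / (unew[up] - u[up])
      act[up] <- ifelse(is.na(act[up]), tc, act[up])
    }
    dn <- unew < thr & u >= thr
    if (any(dn)) {
      rep_[dn] <- t + dt * (u[dn] - thr) / (u[dn] - unew[dn])
    }
    u <- unew
    if (store_at[s]) {
      kcol <- kcol + 1L
      U[, kcol] <- u
    }
  }
  structure(list(times = times, U = U, activation = act,
                 repolarization = rep_, duration = duration, dt = dt,
                 params = params, protocol_name = protocol$name,
                 n_nodes = n),
            class = "ep_solution")
}

#' @export
print.ep_solution <- function(x, ...) {
  cat("ep_solution:", x$n_nodes, "nodes,", length(x$times), "snapshots,",
      "protocol", x$protocol_name, "\n")
  cat("  activation span:",
      round(diff(range(x$activation, na.rm = TRUE)), 1), "ms;",
      sum(is.na(x$activation)), "nodes never activated\n")
  invisible(x)
}

#' Per-element activation and repolarization times
#'
#' Mean of the nodal maps over each element's vertices; used to time the
#' active-stress law in the mechanics module.
#'
#' @param sol an `ep_solution`.
#' @param mesh the mesh it was computed on.
#' @return list with `t_act` and `t_rep` (ms per element).
#' @export
element_activation_times <- function(sol, mesh) {
  list(t_act = rowMeans(matrix(sol$activation[mesh$tets], ncol = 4)),
       t_rep = rowMeans(matrix(sol$repolarization[mesh$tets], ncol = 4)))
}

#' Conduction velocity along an axis from an activation map
#'
#' Linear fit of activation time against the coordinate over the central
#' portion of the range (avoids stimulus and boundary effects).
#'
#' @param mesh a `bv_mesh`.
#' @param activation nodal activation times (ms).
#' @param axis 1, 2 or 3.
#' @param window fraction range used for the fit.
#' @return velocity in mm/ms.
#' @export
conduction_velocity <- function(mesh, activation, axis = 1,
                                window = c(0.25, 0.75)) {
  x <- mesh$nodes[, axis]
  sel <- !is.na(activation) &
    x >= min(x) + window[1] * diff(range(x)) &
    x <= min(x) + window[2] * diff(range(x))
  if (sum(sel) < 10) stop("too few activated nodes for a velocity fit")
  fit <- lm(activation[sel] ~ x[sel])
  1 / coef(fit)[[2]]
}
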