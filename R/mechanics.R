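# Biomechanics: two-element Hill rheology (isotropic linear-elastic passive
# tissue in a co-rotational frame, in parallel with a phenomenological
# fiber-aligned active stress), integrated explicitly with mass scaling and
# Rayleigh (mass-proportional) damping, coupled to the lumped hemodynamics
# through the four-phase valve logic.

#' Mechanics parameters
#'
#' @param E Young's modulus of the passive tissue (kPa). Population mean of
#'   the estimated LV stiffness is 590 kPa.
#' @param nu Poisson ratio; 0.48 enforces near-incompressibility.
#' @param sigma0 maximum active stress (kPa); population mean 295 kPa.
#' @param k_atp active-force rise rate (1/ms), ATP-binding-like.
#' @param k_rs active-force release rate (1/ms), myosin-release-like.
#' @param density numerical mass density (g/mm^3). The default is inflated
#'   roughly 100x above the physical myocardial density: a standard explicit
#'   mass-scaling device that lifts the stable time step while leaving the
#'   quasi-static pressure-volume behaviour unchanged at cardiac time
#'   scales.
#' @param damping mass-proportional damping rate (1/ms).
#' @param valve_spring_stiffness basal anchoring spring stiffness
#'   (kPa*mm^2/mm per node) applied to the valve-annulus node rings.
#' @param pericardium_stiffness one-sided penalty stiffness against outward
#'   motion beyond the end-diastolic epicardial bag (kPa*mm^2/mm per node).
#' @return object of class `mech_parameters`.
#' @export
mech_parameters <- function(E = 590, nu = 0.48, sigma0 = 295,
                            k_atp = 0.02, k_rs = 0.03,
                            density = 0.4, damping = 0.25,
                            valve_spring_stiffness = 60,
                            pericardium_stiffness = 60) {
  if (E <= 0) stop("E must be positive")
  if (nu <= 0 || nu >= 0.5) stop("nu must lie in (0, 0.5)")
  if (sigma0 < 0) stop("sigma0 must be >= 0")
  if (k_atp <= 0 || k_rs <= 0) stop("rates must be positive")
  structure(list(E = E, nu = nu, sigma0 = sigma0, k_atp = k_atp, k_rs = k_rs,
                 density = density, damping = damping,
                 valve_spring_stiffness = valve_spring_stiffness,
                 pericardium_stiffness = pericardium_stiffness),
            class = "mech_parameters")
}

#' Active stress law
#'
#' Zero before local activation; exponential rise toward `sigma0` with rate
#' `k_atp` on the activated interval; value-continuous exponential decay
#' with rate `k_rs` after local repolarization. Applied along the element
#' fiber direction.
#'
#' @param t time (ms), scalar.
#' @param t_act,t_rep per-element activation/repolarization times (ms); NA
#'   activation means the element never contracts, NA repolarization means
#'   the rise is never released.
#' @param params a [mech_parameters()].
#' @return active stress (kPa), vectorized over elements.
#' @export
active_stress <- function(t, t_act, t_rep, params) {
  s0 <- params$sigma0
  ta <- ifelse(is.na(t_act), Inf, t_act)
  tr <- ifelse(is.na(t_rep), Inf, t_rep)
  rise <- s0 * (1 - exp(-params$k_atp * pmax(t - ta, 0)))
  at_rep <- s0 * (1 - exp(-params$k_atp * pmax(tr - ta, 0)))
  dec <- at_rep * exp(-params$k_rs * pmax(t - tr, 0))
  out <- ifelse(t < ta, 0, ifelse(t <= tr, rise, dec))
  out[!is.finite(out)] <- 0
  out
}

# Precomputed mechanics context (C++ element data + cavity topology).
mech_context <- function(mesh, fibers, params) {
  setup <- mech_setup_cpp(mesh$nodes, mesh$tets, params$E, params$nu,
                          params$density)
  ctx <- list(mesh = mesh, fibers = fibers, params = params, setup = setup,
              mass3 = rep(pmax(setup$mass, 1e-12), each = 3))
  for (ch in c("LV", "RV")) {
    labels <- if (ch == "LV") c("LV_ENDO", "LV_SEPTUM") else
      c("RV_ENDO", "RV_SEPTUM")
    sel <- mesh$facet_label %in% labels
    if (!any(sel)) { ctx[[ch]] <- NULL; next }
    facets <- mesh$facets[sel, , drop = FALSE]
    tris_f <- facets[, c(1, 3, 2), drop = FALSE]
    edges <- rbind(tris_f[, 1:2], tris_f[, 2:3], tris_f[, c(3, 1)])
    key <- pmin(edges[, 1], edges[, 2]) * (max(edges) + 1) +
      pmax(edges[, 1], edges[, 2])
    cap <- edges[!duplicated(key) & !duplicated(key, fromLast = TRUE), ,
                 drop = FALSE]
    ctx[[ch]] <- list(facets = facets, cap_edges = cap,
                      ring_nodes = unique(as.vector(cap)))
  }
  # basal springs and pericardial bag
  ctx$anchor_nodes <- unique(unlist(mesh$annuli))
  ctx$anchor_idx <- rep(3 * (ctx$anchor_nodes - 1), each = 3) + 1:3
  epi_sel <- mesh$facet_label == "EPI"
  epi_f <- mesh$facets[epi_sel, , drop = FALSE]
  a <- mesh$nodes[epi_f[, 1], , drop = FALSE]
  b <- mesh$nodes[epi_f[, 2], , drop = FALSE]
  c_ <- mesh$nodes[epi_f[, 3], , drop = FALSE]
  fn <- cross3(b - a, c_ - a)  # outward (area-weighted)
  nrm <- matrix(0, nrow(mesh$nodes), 3)
  for (k in 1:3) {
    for (c2 in 1:3) {
      acc <- tapply(fn[, c2], epi_f[, k], sum)
      idx <- as.integer(names(acc))
      nrm[idx, c2] <- nrm[idx, c2] + as.numeric(acc)
    }
  }
  epi_nodes <- which(vnorm(nrm) > 0)
  ctx$epi_nodes <- epi_nodes
  ctx$epi_normals <- normalize_rows(nrm[epi_nodes, , drop = FALSE])
  ctx$epi_ix <- 3 * (epi_nodes - 1) + 1
  ctx$epi_iy <- 3 * (epi_nodes - 1) + 2
  ctx$epi_iz <- 3 * (epi_nodes - 1) + 3
  ctx
}

cavity_state <- function(ctx, chamber, U, want_load = FALSE) {
  cc <- ctx[[chamber]]
  if (is.null(cc)) return(NULL)
  cavity_cpp(ctx$mesh$nodes, U, cc$facets, cc$cap_edges,
             as.integer(cc$ring_nodes), want_load)
}

# constraint forces (stress units): basal springs + one-sided pericardium
constraint_force <- function(ctx, U) {
  F <- numeric(length(U))
  ii <- ctx$anchor_idx
  if (length(ii)) {
    F[ii] <- -ctx$params$valve_spring_stiffness * U[ii]
  }
  if (length(ctx$epi_nodes)) {
    nn <- ctx$epi_normals
    out <- U[ctx$epi_ix] * nn[, 1] + U[ctx$epi_iy] * nn[, 2] +
      U[ctx$epi_iz] * nn[, 3]
    pen <- pmax(out, 0) * ctx$params$pericardium_stiffness
    F[ctx$epi_ix] <- F[ctx$epi_ix] - pen * nn[, 1]
    F[ctx$epi_iy] <- F[ctx$epi_iy] - pen * nn[, 2]
    F[ctx$epi_iz] <- F[ctx$epi_iz] - pen * nn[, 3]
  }
  F
}

#' Passive co-rotational nodal forces
#'
#' Per-element rotations are extracted by polar decomposition of the
#' deformation gradient; the linear isotropic stiffness acts in the rotated
#' frame. A rigid motion of the whole mesh therefore produces zero force.
#'
#' @param mesh a `bv_mesh`.
#' @param displacements N x 3 nodal displacements (mm).
#' @param params a [mech_parameters()].
#' @return N x 3 matrix of internal nodal forces (kPa*mm^2), with the
#'   elastic energy as attribute `"energy"` (kPa*mm^3).
#' @export
passive_force <- function(mesh, displacements, params = mech_parameters()) {
  stopifnot(nrow(displacements) == nrow(mesh$nodes))
  setup <- mech_setup_cpp(mesh$nodes, mesh$tets, params$E, params$nu,
                          params$density)
  U <- as.vector(t(displacements))
  r <- mech_force_cpp(mesh$nodes, mesh$tets, U, setup,
                      numeric(nrow(mesh$tets)),
                      matrix(0, nrow(mesh$tets), 3))
  if (r$n_degenerate > 0) {
    stop("deformation inverts ", r$n_degenerate, " element(s)")
  }
  out <- matrix(r$force, ncol = 3, byrow = TRUE)
  attr(out, "energy") <- r$energy
  out
}

MMHG_TO_KPA <- 0.1333224

#' Simulate a coupled heart beat
#'
#' Explicit co-rotational elastodynamics driven by the EP activation and
#' repolarization maps through the active-stress law, loaded by cavity
#' pressures resolved per phase: atrial pressure during filling, the
#' isovolumetric prediction-correction pressure during the isovolumetric
#' phases, and the implicitly coupled 3-element Windkessel pressure during
#' ejection. The two ventricles are coupled mechanically through the septum
#' but not hemodynamically.
#'
#' @param mesh a `bv_mesh`.
#' @param fibers a `fiber_field`.
#' @param ep_sol an `ep_solution` on the same mesh, or a list with `t_act`
#'   and `t_rep` per element (ms).
#' @param mech a [mech_parameters()].
#' @param hemo list with `aorta`, `pulmonary` ([wk3_parameters()]),
#'   `atrial_lv`, `atrial_rv` ([atrial_model()]), `period` (ms); see
#'   [hemo_parameters()].
#' @param dt time step (ms).
#' @param n_cycles number of cardiac cycles.
#' @param ep_onset delay (ms) of the EP activation within the cycle,
#'   leaving room for the preload ramp.
#' @param ramp_ms pressure ramp-in at the start of the simulation.
#' @return object of class `beat_result`: `pv` (per-step data.frame),
#'   `lv`, `rv` (metric lists from [pv_metrics()]), `displacement` (final),
#'   plus inputs.
#' @export
simulate_beat <- function(mesh, fibers, ep_sol, mech = mech_parameters(),
                          hemo = hemo_parameters(), dt = 0.25, n_cycles = 1,
                          ep_onset = 60, ramp_ms = 50, early_stop = FALSE) {
  if (inherits(ep_sol, "ep_solution")) {
    et <- element_activation_times(ep_sol, mesh)
  } else {
    et <- ep_sol
  }
  stopifnot(length(et$t_act) == nrow(mesh$tets))
  bad <- !is.na(et$t_act) & !is.na(et$t_rep) & et$t_act >= et$t_rep
  if (any(bad)) stop("activation must precede repolarization")
  ctx <- mech_context(mesh, fibers, mech)
  period <- hemo$period
  nstep <- ceiling(n_cycles * period / dt)
  n3 <- 3 * nrow(mesh$nodes)
  U <- numeric(n3); Vel <- numeric(n3)
  dampf <- exp(-mech$damping * dt)
  t_act <- et$t_act + ep_onset
  t_rep <- et$t_rep + ep_onset

  vent <- list()
  for (ch in c("LV", "RV")) {
    if (is.null(ctx[[ch]])) next
    v0 <- cavity_state(ctx, ch, U)$volume
    vent[[ch]] <- list(phase = "FILLING", V = v0, V_target = v0,
                       wk = if (ch == "LV") hemo$aorta else hemo$pulmonary,
                       atr = if (ch == "LV") hemo$atrial_lv else hemo$atrial_rv,
                       pd = if (ch == "LV") hemo$init_distal_aorta else
                         hemo$init_distal_pulmonary,
                       p = 0)
  }
  chambers <- names(vent)
  rec <- matrix(NA_real_, nstep, 11)
  dt_s <- dt / 1000
  nrec <- 0L
  U_es <- NULL

  for (s in seq_len(nstep)) {
    t <- (s - 1) * dt
    tc <- t %% period
    ramp <- min(1, t / ramp_ms)
    sa <- active_stress(tc, t_act, t_rep, mech)
    fr <- mech_force_cpp(mesh$nodes, mesh$tets, U, ctx$setup, sa,
                         ctx$fibers$vectors)
    if (fr$n_degenerate > 0) {
      stop("mechanics diverged at t = ", round(t, 2), " ms: ",
           fr$n_degenerate, " inverted element(s); step diagnostics: |U|max = ",
           signif(max(abs(U)), 3), " mm")
    }
    F_base <- constraint_force(ctx, U) - fr$force
    # trial update operator: U'(p...) = U0' + sum_ch p_ch * S_ch
    Vp <- (Vel + dt * (1e-3 * F_base / ctx$mass3)) * dampf
    U0p <- U + dt * Vp
    Sfac <- dt * dampf * dt * 1e-3 * MMHG_TO_KPA * ramp / ctx$mass3
    S <- list(); Vol0 <- list(); dVdp <- list(); dVdo <- list()
    for (ch in chambers) {
      ld <- cavity_state(ctx, ch, U, TRUE)
      S[[ch]] <- Sfac * ld$load
    }
    for (ch in chambers) {
      Vol0[[ch]] <- cavity_state(ctx, ch, U0p)$volume
      dVdp[[ch]] <- max(cavity_state(ctx, ch, U0p + S[[ch]])$volume -
                          Vol0[[ch]], 1e-9)
    }
    # cross-compliance (other chamber's pressure changes this volume)
    if (length(chambers) == 2) {
      dVdo$LV <- cavity_state(ctx, "LV", U0p + S$RV)$volume - Vol0$LV
      dVdo$RV <- cavity_state(ctx, "RV", U0p + S$LV)$volume - Vol0$RV
    } else {
      for (ch in chambers) dVdo[[ch]] <- 0
    }
    p_new <- list()
    for (ch in chambers) {
      st <- vent[[ch]]
      other <- setdiff(chambers, ch)
      p_oth <- if (length(other)) vent[[other]]$p else 0
      Vb <- Vol0[[ch]] + dVdo[[ch]] * p_oth
      p_atr <- atrial_pressure(st$atr, tc, period)
      wk <- st$wk
      a1 <- (dt_s / wk$C) / (1 + dt_s / (wk$Rp * wk$C))
      a0 <- (st$pd + dt_s * wk$Pr / (wk$Rp * wk$C)) /
        (1 + dt_s / (wk$Rp * wk$C))
      p_hold <- (st$V - Vb) / dVdp[[ch]]
      phase <- st$phase
      if (phase == "FILLING") {
        nxt <- phase_machine(p_hold, p_atr, a0, -1, "FILLING")
        if (nxt == "ISO_CONTRACTION") {
          st$phase <- "ISO_CONTRACTION"; st$V_target <- st$V
          p_app <- p_hold
        } else p_app <- p_atr
        Q <- 0
      } else if (phase == "ISO_CONTRACTION") {
        p_app <- (st$V_target - Vb) / dVdp[[ch]]
        nxt <- phase_machine(p_app, p_atr, a0, -1, "ISO_CONTRACTION")
        if (nxt == "EJECTION") st$phase <- "EJECTION"
        Q <- 0
      } else if (phase == "EJECTION") {
        kq <- 1e6 / dt
        beta <- a1 + wk$Rc
        p_app <- (a0 - beta * kq * (Vb - st$V)) /
          (1 + beta * kq * dVdp[[ch]])
        Q <- -(Vb + dVdp[[ch]] * p_app - st$V) * kq
        if (Q < 0) {
          st$phase <- "ISO_RELAXATION"; st$V_target <- st$V
          if (ch == "LV" && is.null(U_es)) U_es <- U
          p_app <- (st$V_target - Vb) / dVdp[[ch]]
          Q <- 0
        }
      } else { # ISO_RELAXATION
        p_app <- (st$V_target - Vb) / dVdp[[ch]]
        nxt <- phase_machine(p_app, p_atr, a0, 0, "ISO_RELAXATION")
        if (nxt == "FILLING") { st$phase <- "FILLING"; p_app <- p_atr }
        Q <- 0
      }
      stq <- wk3_step(st$pd, Q, dt_s, wk)
      st$pd <- stq$p_distal
      st$p_art <- stq$p_prox
      st$p <- p_app
      st$Q <- Q
      vent[[ch]] <- st
      p_new[[ch]] <- p_app
    }
    # final state: affine combination of trials
    U <- U0p
    Vel <- Vp
    for (ch in chambers) {
      U <- U + p_new[[ch]] * S[[ch]]
      Vel <- Vel + p_new[[ch]] * S[[ch]] / dt
    }
    for (ch in chambers) {
      vent[[ch]]$V <- cavity_state(ctx, ch, U)$volume
    }
    nrec <- nrec + 1L
    rec[nrec, ] <- c(t,
                     vent$LV$p, vent$LV$V, vent$LV$p_art, vent$LV$Q,
                     if (!is.null(vent$RV)) c(vent$RV$p, vent$RV$V,
                                              vent$RV$p_art, vent$RV$Q)
                     else rep(NA_real_, 4),
                     match(vent$LV$phase, PHASES),
                     if (!is.null(vent$RV)) match(vent$RV$phase, PHASES)
                     else NA_real_)
    if (early_stop && n_cycles == 1 && tc > 0.55 * period &&
        vent$LV$phase == "FILLING" &&
        (is.null(vent$RV) || vent$RV$phase == "FILLING" ||
           tc > 0.8 * period)) {
      break
    }
  }
  pv <- as.data.frame(rec[seq_len(nrec), , drop = FALSE])
  names(pv) <- c("t", "p_lv", "v_lv", "p_ao", "q_lv",
                 "p_rv", "v_rv", "p_pa", "q_rv", "phase_lv", "phase_rv")
  pv$phase_lv <- PHASES[pv$phase_lv]
  if (!all(is.na(pv$phase_rv))) pv$phase_rv <- PHASES[pv$phase_rv]
  lvm <- pv_metrics(data.frame(t = pv$t, p = pv$p_lv, v = pv$v_lv,
                               phase = pv$phase_lv))
  rvm <- if (!is.null(vent$RV))
    pv_metrics(data.frame(t = pv$t, p = pv$p_rv, v = pv$v_rv,
                          phase = pv$phase_rv)) else NULL
  structure(list(pv = pv, lv = lvm, rv = rvm,
                 displacement = matrix(U, ncol = 3, byrow = TRUE),
                 displacement_es = if (!is.null(U_es))
                   matrix(U_es, ncol = 3, byrow = TRUE) else NULL,
                 mech = mech, hemo = hemo, dt = dt, n_cycles = n_cycles,
                 ep_onset = ep_onset),
            class = "beat_result")
}

PHASES <- c("FILLING", "ISO_CONTRACTION", "EJECTION", "ISO_RELAXATION")

#' Hemodynamics configuration for the coupled beat
#'
#' @param aorta,pulmonary [wk3_parameters()] per artery.
#' @param atrial_lv,atrial_rv [atrial_model()] preloads.
#' @param period cycle length (ms); default 857 ms (70 bpm).
#' @param init_distal_aorta,init_distal_pulmonary initial distal Windkessel
#'   pressures (mmHg).
#' @return list used by [simulate_beat()].
#' @export
hemo_parameters <- function(aorta = wk3_parameters(),
                            pulmonary = wk3_pulmonary(),
                            atrial_lv = atrial_model(baseline = 8, amplitude = 4),
                            atrial_rv = atrial_model(baseline = 4, amplitude = 2),
                            period = 857,
                            init_distal_aorta = 75,
                            init_distal_pulmonary = 18) {
  list(aorta = aorta, pulmonary = pulmonary, atrial_lv = atrial_lv,
       atrial_rv = atrial_rv, period = period,
       init_distal_aorta = init_distal_aorta,
       init_distal_pulmonary = init_distal_pulmonary)
}

#' @export
print.beat_result <- function(x, ...) {
  cat("beat_result:", nrow(x$pv), "steps\n")
  cat(sprintf("  LV: EDV %.1f  ESV %.1f  SV %.1f ml  EF %.1f%%  EDP %.1f  ESP %.1f mmHg\n",
              x$lv$EDV, x$lv$ESV, x$lv$SV, x$lv$EF, x$lv$EDP, x$lv$ESP))
  if (!is.null(x$rv)) {
    cat(sprintf("  RV: EDV %.1f  ESV %.1f  SV %.1f ml  EF %.1f%%\n",
                x$rv$EDV, x$rv$ESV, x$rv$SV, x$rv$EF))
  }
  invisible(x)
}

#' Write a PV loop to CSV (units in the header line)
#' @param beat a `beat_result`.
#' @param path output file.
#' @export
write_pv_csv <- function(beat, path) {
  con <- file(path, "w")
  writeLines("# t: ms; p_*: mmHg; v_*: ml; q_*: mm^3/s", con)
  write.csv(beat$pv, con, row.names = FALSE)
  close(con)
}
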