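# Inverse-problem loops: three-step electrophysiology fitting (bulk
# conductivity from QRS duration, endocardial conductivities from the
# electrical axis, tau_close from the QT interval), Windkessel estimation
# from pressure/flow curves, and (E, sigma0) estimation from global
# function (EF/SV/EDV/ESV/EDP/ESP). All optimizers are derivative-free
# (Brent / Nelder-Mead).

#' Clinical target container
#'
#' Any field may be NULL (missing targets are dropped from the objectives
#' and flagged in results). Present volume fields must be self-consistent.
#'
#' @param m_qrsd measured QRS duration (ms).
#' @param m_ea measured electrical axis (degrees).
#' @param m_qt measured QT duration (ms).
#' @param ef,sv,edv,esv ejection fraction (percent), stroke volume and
#'   volumes (ml).
#' @param edp,esp end-diastolic / end-systolic pressure (mmHg).
#' @param pressure data.frame(t, p): arterial pressure samples (s, mmHg).
#' @param flow data.frame(t, q): arterial flow samples (s, mm^3/s).
#' @return object of class `clinical_targets`.
#' @export
clinical_targets <- function(m_qrsd = NULL, m_ea = NULL, m_qt = NULL,
                             ef = NULL, sv = NULL, edv = NULL, esv = NULL,
                             edp = NULL, esp = NULL,
                             pressure = NULL, flow = NULL) {
  if (!is.null(ef) && !is.null(sv) && !is.null(edv)) {
    if (abs(ef - 100 * sv / edv) > 0.05 * ef + 1) {
      stop("inconsistent targets: ef = ", ef, " but 100*sv/edv = ",
           round(100 * sv / edv, 1))
    }
  }
  if (!is.null(edv) && !is.null(esv) && !is.null(sv)) {
    if (abs(edv - esv - sv) > 0.05 * sv + 1) {
      stop("inconsistent targets: edv - esv != sv")
    }
  }
  structure(list(m_qrsd = m_qrsd, m_ea = m_ea, m_qt = m_qt, ef = ef,
                 sv = sv, edv = edv, esv = esv, edp = edp, esp = esp,
                 pressure = pressure, flow = flow),
            class = "clinical_targets")
}

# signed angular difference in (-180, 180]
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Forward EP + ECG pipeline closure
#'
#' Packages mesh, fibers and torso into a function of [ep_parameters()]
#' returning [extract_features()] output; `full = FALSE` simulates only the
#' depolarization window (enough for QRSd and EA), `full = TRUE` covers
#' repolarization (QT).
#'
#' @param mesh,fibers,torso the anatomical stage.
#' @param duration_qrs,duration_full simulated windows (ms).
#' @param dt EP time step (ms).
#' @return function(params, full = FALSE) -> `ecg_features`.
#' @export
ep_forward_pipeline <- function(mesh, fibers, torso = build_torso(mesh),
                                duration_qrs = 250, duration_full = 520,
                                dt = 0.1) {
  force(mesh); force(fibers); force(torso)
  function(params, full = FALSE) {
    sol <- simulate_ep(mesh, fibers, params, sinus_protocol(mesh),
                       duration = if (full) duration_full else duration_qrs,
                       dt = dt)
    extract_features(compute_ecg(sol, mesh, fibers, params, torso))
  }
}

#' Three-step electrophysiology personalization
#'
#' Step 1 estimates the bulk myocardial conductivity by scalar
#' derivative-free minimization of |computed - measured| QRS duration
#' (QRSd decreases monotonically with conductivity). Step 2 estimates the
#' LV/RV fast-layer conductivities by Nelder-Mead on the absolute electrical
#' axis error. Step 3 updates tau_close directly from the QT residual using
#' the closed-form APD slope log(tau_out/(4 tau_in)). The three steps are
#' iterated until the QRSd and EA tolerances are met (typically two or three
#' outer iterations).
#'
#' @param targets a [clinical_targets()] with `m_qrsd`, `m_ea`, `m_qt`.
#' @param forward a closure from [ep_forward_pipeline()].
#' @param init initial [ep_parameters()].
#' @param tol_qrs,tol_ea convergence tolerances (ms, degrees).
#' @param max_iter maximal outer iterations.
#' @param cmyo_bounds,clayer_bounds search bounds (mm^2/s).
#' @param tau_close_bounds clamp for the QT update (ms).
#' @return list with `params` (fitted [ep_parameters()]), `iterations`,
#'   `converged`, `residuals` (qrsd, ea, qt) and `features` of the final
#'   full forward run.
#' @export
personalize_ep <- function(targets, forward, init = ep_parameters(),
                           tol_qrs = 5, tol_ea = 10, max_iter = 5,
                           cmyo_bounds = c(100, 1500),
                           clayer_bounds = c(400, 5000),
                           tau_close_bounds = c(50, 350)) {
  stopifnot(inherits(targets, "clinical_targets"))
  if (is.null(targets$m_qrsd) || is.null(targets$m_ea) ||
      is.null(targets$m_qt)) {
    stop("EP personalization needs m_qrsd, m_ea and m_qt targets")
  }
  p <- init
  iterations <- 0L
  converged <- FALSE
  feats <- NULL
  slope <- log(p$tau_out / (4 * p$tau_in))
  for (it in seq_len(max_iter)) {
    iterations <- it
    # step 1: c_myo from QRSd
    o1 <- optimize(function(lc) {
      pp <- p; pp$c_myo <- exp(lc)
      pp$c_lv <- max(pp$c_lv, pp$c_myo); pp$c_rv <- max(pp$c_rv, pp$c_myo)
      abs(forward(pp)$qrsd - targets$m_qrsd)
    }, interval = log(cmyo_bounds), tol = 0.03)
    p$c_myo <- exp(o1$minimum)
    p$c_lv <- max(p$c_lv, p$c_myo); p$c_rv <- max(p$c_rv, p$c_myo)
    # step 2: (c_lv, c_rv) from the electrical axis
    lo <- log(pmax(clayer_bounds[1], p$c_myo)); hi <- log(clayer_bounds[2])
    o2 <- optim(log(c(p$c_lv, p$c_rv)), function(lc) {
      lc <- pmin(pmax(lc, lo), hi)
      pp <- p; pp$c_lv <- exp(lc[1]); pp$c_rv <- exp(lc[2])
      abs(angle_diff(forward(pp)$ea, targets$m_ea))
    }, method = "Nelder-Mead",
    control = list(maxit = 20, reltol = 0.05))
    l2 <- pmin(pmax(o2$par, lo), hi)
    p$c_lv <- exp(l2[1]); p$c_rv <- exp(l2[2])
    # step 3: tau_close directly from the QT residual
    feats <- forward(p, full = TRUE)
    if (!is.na(feats$qtd)) {
      p$tau_close <- min(max(p$tau_close +
                               (targets$m_qt - feats$qtd) / slope,
                             tau_close_bounds[1]), tau_close_bounds[2])
      feats <- forward(p, full = TRUE)
    }
    if (abs(feats$qrsd - targets$m_qrsd) <= tol_qrs &&
        abs(angle_diff(feats$ea, targets$m_ea)) <= tol_ea) {
      converged <- TRUE
      break
    }
  }
  list(params = p, iterations = iterations, converged = converged,
       residuals = list(qrsd = feats$qrsd - targets$m_qrsd,
                        ea = angle_diff(feats$ea, targets$m_ea),
                        qt = if (is.na(feats$qtd)) NA else
                          feats$qtd - targets$m_qt),
       features = feats)
}

#' Windkessel parameter estimation from pressure and flow curves
#'
#' Least-squares fit (derivative-free Nelder-Mead on log-parameters) of the
#' simulated proximal pressure to measured samples over the cycle,
#' initialized from the mean-pressure identity Rp + Rc = (mean p - Pr) /
#' mean Q.
#'
#' @param pressure data.frame(t, p): measured arterial pressure (s, mmHg),
#'   one cycle.
#' @param flow data.frame(t, q): measured flow (s, mm^3/s), one cycle.
#' @param wk0 optional initial [wk3_parameters()].
#' @param n_cycles settling cycles per objective evaluation.
#' @param maxit Nelder-Mead iteration budget.
#' @return fitted [wk3_parameters()] with attributes `rmse` (mmHg) and
#'   `fit` (optim result).
#' @export
personalize_windkessel <- function(pressure, flow, wk0 = NULL,
                                   n_cycles = 8, maxit = 200) {
  stopifnot(all(c("t", "p") %in% names(pressure)),
            all(c("t", "q") %in% names(flow)))
  if (all(abs(flow$q) < 1e-12)) stop("degenerate flow: all samples are zero")
  period <- max(flow$t)
  flow_fn <- function(t) {
    approx(flow$t, flow$q, xout = t %% period, rule = 2)$y
  }
  qbar <- mean(flow_fn(seq(0, period, length.out = 200)))
  pr0 <- wk0$Pr %||% (0.8 * min(pressure$p))
  rtot <- max((mean(pressure$p) - pr0) / max(qbar, 1e-9), 1e-6)
  x0 <- log(c(C = wk0$C %||% 2000, Rp = wk0$Rp %||% (0.9 * rtot),
              Rc = wk0$Rc %||% (0.1 * rtot), Pr = pr0))
  sim_p <- function(wk) {
    df <- wk3_simulate(flow_fn, wk, period = period, n_cycles = n_cycles,
                       dt = period / 200)
    approx(df$t, df$p_prox, xout = pressure$t %% period, rule = 2)$y
  }
  obj <- function(x) {
    x <- exp(x)
    if (x[3] >= x[2]) return(1e6)
    wk <- try(wk3_parameters(C = x[1], Rp = x[2], Rc = x[3], Pr = x[4]),
              silent = TRUE)
    if (inherits(wk, "try-error")) return(1e6)
    sqrt(mean((sim_p(wk) - pressure$p)^2))
  }
  fit <- optim(x0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
  x <- unname(exp(fit$par))
  wk <- wk3_parameters(C = x[1], Rp = x[2], Rc = x[3], Pr = x[4],
                       artery = wk0$artery %||% "aorta")
  attr(wk, "rmse") <- fit$value
  attr(wk, "fit") <- fit
  wk
}

#' Forward mechanics pipeline closure
#'
#' Packages the anatomical and electrical stages into a function of
#' (E, sigma0) returning the global function metrics of a simulated beat.
#'
#' @param mesh,fibers anatomical stage.
#' @param ep_sol `ep_solution` or activation-time list for the beat.
#' @param hemo [hemo_parameters()].
#' @param mech_template [mech_parameters()] whose non-fitted fields are kept.
#' @param dt mechanics step (ms).
#' @return function(E, sigma0) -> list(EF, SV, EDV, ESV, EDP, ESP).
#' @export
mech_forward_pipeline <- function(mesh, fibers, ep_sol,
                                  hemo = hemo_parameters(),
                                  mech_template = mech_parameters(),
                                  dt = 0.25) {
  if (inherits(ep_sol, "ep_solution")) {
    ep_sol <- element_activation_times(ep_sol, mesh)
  }
  force(mesh); force(fibers); force(hemo); force(mech_template)
  function(E, sigma0) {
    mp <- mech_template
    mp$E <- E; mp$sigma0 <- sigma0
    b <- simulate_beat(mesh, fibers, ep_sol, mp, hemo, dt = dt,
                       early_stop = TRUE)
    list(EF = b$lv$EF, SV = b$lv$SV, EDV = b$lv$EDV, ESV = b$lv$ESV,
         EDP = b$lv$EDP, ESP = b$lv$ESP)
  }
}

#' Mechanics personalization: (E, sigma0) from global function
#'
#' Derivative-free (Nelder-Mead, log-parameters) minimization of the sum of
#' squared normalized residuals between computed and measured EF, SV, EDV,
#' ESV, EDP and ESP (each term divided by its measured value; missing
#' targets are dropped and flagged). Forward-model failures (diverged
#' beats) are penalized, which keeps the search inside the feasible region.
#'
#' @param targets a [clinical_targets()].
#' @param forward closure from [mech_forward_pipeline()].
#' @param init c(E, sigma0) initial guess (kPa).
#' @param bounds list(E = c(lo, hi), sigma0 = c(lo, hi)) (kPa).
#' @param maxit Nelder-Mead iteration budget.
#' @param weights named weights for the residual terms (default 1).
#' @return list with `E`, `sigma0`, `objective`, `residuals` (per target),
#'   `computed`, `dropped` (missing target names), `converged`, `fit`.
#' @export
personalize_mechanics <- function(targets, forward, init = c(590, 295),
                                  bounds = list(E = c(150, 2000),
                                                sigma0 = c(40, 900)),
                                  maxit = 40, weights = NULL) {
  stopifnot(inherits(targets, "clinical_targets"))
  fields <- c("ef", "sv", "edv", "esv", "edp", "esp")
  keys <- c(ef = "EF", sv = "SV", edv = "EDV", esv = "ESV",
            edp = "EDP", esp = "ESP")
  present <- fields[!vapply(targets[fields], is.null, TRUE)]
  if (length(present) == 0) stop("no mechanics targets present")
  dropped <- setdiff(fields, present)
  w <- rep(1, length(present)); names(w) <- present
  if (!is.null(weights)) w[names(weights)] <- weights
  lo <- log(c(bounds$E[1], bounds$sigma0[1]))
  hi <- log(c(bounds$E[2], bounds$sigma0[2]))
  best <- list(val = Inf, par = log(init))
  obj <- function(x) {
    if (any(x < lo) || any(x > hi)) return(1e4 + sum(pmax(x - hi, 0)^2 +
                                                       pmax(lo - x, 0)^2))
    cmp <- try(forward(exp(x[1]), exp(x[2])), silent = TRUE)
    if (inherits(cmp, "try-error")) return(1e4)
    v <- sum(vapply(present, function(f) {
      w[f] * ((cmp[[keys[f]]] - targets[[f]]) / targets[[f]])^2
    }, 0))
    if (v < best$val) best <<- list(val = v, par = x, computed = cmp)
    v
  }
  fit <- optim(log(init), obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-4))
  par <- if (best$val <= fit$value) best$par else fit$par
  cmp <- best$computed %||% forward(exp(par[1]), exp(par[2]))
  res <- lapply(present, function(f) cmp[[keys[f]]] - targets[[f]])
  names(res) <- present
  list(E = exp(par[1]), sigma0 = exp(par[2]), objective = best$val,
       residuals = res, computed = cmp, dropped = dropped,
       converged = fit$convergence == 0, fit = fit)
}
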