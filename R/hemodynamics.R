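# Lumped hemodynamics: 3-element Windkessel afterload per artery, a simple
# atrial pressure model for preload, the four-phase valve state machine, and
# the isovolumetric pressure solver used by the coupled beat simulation.

#' 3-element Windkessel parameters
#'
#' Units follow the clinical convention: compliance C in mm^3/mmHg,
#' resistances in mmHg*s/mm^3 (flows in mm^3/s; the printed clinical values
#' omit the time unit, which is seconds under this convention - the only one
#' that closes the ODE dimensionally), remote pressure Pr in mmHg. Defaults
#' are the systemic (aortic) population means; use [wk3_pulmonary()] for the
#' pulmonary side.
#'
#' @param C compliance (mm^3/mmHg).
#' @param Rp peripheral resistance (mmHg*s/mm^3).
#' @param Rc characteristic resistance (mmHg*s/mm^3); physiologically
#'   `Rc < Rp`.
#' @param Pr remote pressure (mmHg).
#' @param artery label ("aorta" or "pulmonary").
#' @return object of class `wk3_parameters`.
#' @export
wk3_parameters <- function(C = 2269, Rp = 3.64e-4, Rc = 4.72e-5, Pr = 52,
                           artery = "aorta") {
  if (any(c(C, Rp, Rc, Pr) <= 0)) stop("all Windkessel parameters must be positive")
  if (Rc >= Rp) stop("characteristic resistance must be smaller than peripheral")
  structure(list(C = C, Rp = Rp, Rc = Rc, Pr = Pr, artery = artery),
            class = "wk3_parameters")
}

#' Pulmonary-artery Windkessel defaults
#' @return a [wk3_parameters()] with pulmonary population means.
#' @export
wk3_pulmonary <- function() {
  wk3_parameters(C = 2757, Rp = 1.51e-4, Rc = 2.91e-5, Pr = 15,
                 artery = "pulmonary")
}

#' One semi-implicit step of the 3-element Windkessel
#'
#' C dp_distal/dt = Q - (p_distal - Pr)/Rp; p_prox = p_distal + Rc Q.
#' The distal update is implicit in p_distal (unconditionally stable).
#'
#' @param p_distal current distal (compliance) pressure, mmHg.
#' @param Q inflow, mm^3/s.
#' @param dt step in seconds.
#' @param wk a [wk3_parameters()].
#' @return list(p_prox, p_distal).
#' @export
wk3_step <- function(p_distal, Q, dt, wk) {
  if (dt <= 0) stop("dt must be positive")
  pd <- (p_distal + dt * (Q / wk$C + wk$Pr / (wk$Rp * wk$C))) /
    (1 + dt / (wk$Rp * wk$C))
  list(p_prox = pd + wk$Rc * Q, p_distal = pd)
}

#' Simulate the Windkessel response to a flow waveform
#'
#' @param flow_fn function of time (s) returning inflow (mm^3/s).
#' @param wk a [wk3_parameters()].
#' @param period cycle length (s).
#' @param n_cycles number of cycles (transients decay within a few).
#' @param dt step (s).
#' @param p0 initial distal pressure (mmHg); defaults to Pr.
#' @return data.frame(t, Q, p_prox, p_distal) for the final cycle, with the
#'   full history as attribute "history".
#' @export
wk3_simulate <- function(flow_fn, wk, period = 0.857, n_cycles = 10,
                         dt = 1e-3, p0 = NULL) {
  pd <- p0 %||% wk$Pr
  nstep <- round(period * n_cycles / dt)
  out <- matrix(0, nstep, 4)
  for (s in seq_len(nstep)) {
    t <- (s - 1) * dt
    Q <- flow_fn(t %% period)
    st <- wk3_step(pd, Q, dt, wk)
    pd <- st$p_distal
    out[s, ] <- c(t, Q, st$p_prox, pd)
  }
  df <- data.frame(t = out[, 1], Q = out[, 2], p_prox = out[, 3],
                   p_distal = out[, 4])
  last <- df[df$t >= period * (n_cycles - 1), ]
  last$t <- last$t - period * (n_cycles - 1)
  attr(last, "history") <- df
  last
}

#' Lumped atrial pressure model
#'
#' Constant baseline plus a timed half-sinusoid contraction bump - a
#' surrogate preload model preserving the role of atrial contraction in the
#' coupling (the detailed published atrial model is not reproduced here).
#'
#' @param baseline mmHg.
#' @param amplitude bump height (mmHg).
#' @param onset bump onset within the cycle (ms).
#' @param width bump duration (ms).
#' @return object of class `atrial_model`; call it via [atrial_pressure()].
#' @export
atrial_model <- function(baseline = 8, amplitude = 4, onset = 700,
                         width = 120) {
  if (baseline < 0 || amplitude < 0) stop("pressures must be >= 0")
  structure(list(baseline = baseline, amplitude = amplitude,
                 onset = onset, width = width), class = "atrial_model")
}

#' Atrial pressure at a time in the cycle
#' @param model an [atrial_model()].
#' @param t_ms time within the cycle (ms), vectorized.
#' @param period cycle length (ms).
#' @return pressure (mmHg).
#' @export
atrial_pressure <- function(model, t_ms, period = 857) {
  tt <- t_ms %% period
  rel <- (tt - model$onset) / model$width
  bump <- ifelse(rel >= 0 & rel <= 1, sin(pi * rel), 0)
  model$baseline + model$amplitude * bump
}

#' Four-phase valve state machine
#'
#' FILLING -> ISO_CONTRACTION when ventricular pressure rises above atrial;
#' ISO_CONTRACTION -> EJECTION when it reaches arterial pressure;
#' EJECTION -> ISO_RELAXATION when forward flow would reverse;
#' ISO_RELAXATION -> FILLING when pressure falls below atrial.
#'
#' @param p_v ventricular pressure (mmHg).
#' @param p_atrium atrial pressure (mmHg).
#' @param p_art arterial (proximal) pressure (mmHg).
#' @param dvdt cavity volume rate (ml/s); negative during forward ejection.
#' @param phase current phase.
#' @return next phase (character).
#' @export
phase_machine <- function(p_v, p_atrium, p_art, dvdt,
                          phase = c("FILLING", "ISO_CONTRACTION", "EJECTION",
                                    "ISO_RELAXATION")) {
  phase <- match.arg(phase)
  switch(phase,
    FILLING = if (p_v > p_atrium) "ISO_CONTRACTION" else "FILLING",
    ISO_CONTRACTION = if (p_v >= p_art) "EJECTION" else "ISO_CONTRACTION",
    EJECTION = if (dvdt >= 0) "ISO_RELAXATION" else "EJECTION",
    ISO_RELAXATION = if (p_v < p_atrium) "FILLING" else "ISO_RELAXATION")
}

#' Pressure enforcing an isovolumetric constraint
#'
#' Bracketed scalar root find of V(p) = target on a mechanics volume
#' response; the prediction-correction contract is |V(p) - target| /
#' target < `tol`.
#'
#' @param volume_fn function p (mmHg) -> cavity volume (ml), monotone
#'   increasing over the bracket.
#' @param target target volume (ml).
#' @param bracket pressure bracket (mmHg).
#' @param tol relative volume tolerance (default 1%).
#' @return pressure (mmHg).
#' @export
isovolumetric_pressure <- function(volume_fn, target, bracket = c(-20, 400),
                                   tol = 0.01) {
  f <- function(p) volume_fn(p) - target
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (flo * fhi > 0) {
    stop("bracket [", bracket[1], ", ", bracket[2],
         "] mmHg does not contain the isovolumetric pressure: V(lo)-target = ",
         signif(flo, 4), ", V(hi)-target = ", signif(fhi, 4))
  }
  r <- uniroot(f, bracket, tol = 1e-6 * diff(bracket))
  if (abs(volume_fn(r$root) - target) / target > tol) {
    stop("isovolumetric solve did not reach the volume tolerance")
  }
  r$root
}

#' Derived pressure-volume metrics
#'
#' @param pv data.frame with columns t, p, v, phase (single ventricle).
#' @return list with EDV, ESV, SV, EF (percent), EDP, ESP.
#' @export
pv_metrics <- function(pv) {
  stopifnot(all(c("t", "p", "v", "phase") %in% names(pv)))
  idx_ed <- which(pv$phase == "FILLING" &
                    c(pv$phase[-1], NA) == "ISO_CONTRACTION")
  idx_es <- which(pv$phase == "EJECTION" &
                    c(pv$phase[-1], NA) == "ISO_RELAXATION")
  if (length(idx_ed) == 0 || length(idx_es) == 0) {
    return(list(EDV = max(pv$v), ESV = min(pv$v),
                SV = max(pv$v) - min(pv$v),
                EF = 100 * (max(pv$v) - min(pv$v)) / max(pv$v),
                EDP = NA_real_, ESP = NA_real_))
  }
  i_ed <- idx_ed[length(idx_ed)]
  i_es <- idx_es[length(idx_es)]
  edv <- pv$v[i_ed]; esv <- pv$v[i_es]
  list(EDV = edv, ESV = esv, SV = edv - esv, EF = 100 * (edv - esv) / edv,
       EDP = pv$p[i_ed], ESP = pv$p[i_es])
}
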