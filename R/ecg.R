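# Pseudo-ECG synthesis: infinite-homogeneous-medium lead fields evaluated at
# electrodes placed on a parametric ellipsoidal torso, and global feature
# extraction (QRS duration, QT duration, frontal-plane electrical axis).
# Global durations and axis are only weakly sensitive to torso tissue
# heterogeneity, which is why the simple forward model is the default.

#' Torso configuration
#'
#' @param semi_axes torso ellipsoid semi-axes (mm) in the torso frame:
#'   x toward the patient's left, y inferior (toward the feet), z anterior.
#' @param heart_center position of the heart centroid in the torso frame (mm).
#' @param apex_direction direction the cardiac apex points toward
#'   (left-inferior-anterior by default).
#' @param roll additional rotation about the long axis (degrees).
#' @param gain multiplicative output scale (arbitrary mV-like units).
#' @return object of class `torso_config`.
#' @export
torso_config <- function(semi_axes = c(180, 320, 120),
                         heart_center = c(35, -20, 55),
                         apex_direction = c(0.65, 0.6, 0.45),
                         roll = 0, gain = 1) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  structure(list(semi_axes = semi_axes, heart_center = heart_center,
                 apex_direction = apex_direction, roll = roll, gain = gain),
            class = "torso_config")
}

# unit direction -> point on the ellipsoid surface
on_ellipsoid <- function(dirs, axes) {
  s <- sqrt(rowSums(sweep(dirs, 2, axes, "/")^2))
  dirs / s
}

#' Build the torso model for ECG synthesis
#'
#' Places a parametric ellipsoidal torso around the heart mesh and the ten
#' standard electrodes (RA, LA, LL, RL, V1-V6) at fixed fractional surface
#' coordinates. The heart is positioned with its apex pointing
#' left-inferior-anterior (configurable). Deterministic given (mesh, config).
#'
#' @param mesh a `bv_mesh` (its bounding box is checked against the torso).
#' @param config a [torso_config()].
#' @return object of class `torso_model` with electrode positions (torso
#'   frame), the heart placement transform, and electrode positions mapped
#'   into the heart frame (used by the lead-field computation).
#' @export
build_torso <- function(mesh, config = torso_config()) {
  ax <- config$semi_axes
  dirs <- rbind(
    RA = c(-0.80, -0.85, 0.10), LA = c(0.80, -0.85, 0.10),
    LL = c(0.60, 0.90, 0.10),  RL = c(-0.60, 0.90, 0.10),
    V1 = c(-0.15, -0.15, 1.00), V2 = c(0.10, -0.15, 1.00),
    V3 = c(0.30, -0.05, 0.95), V4 = c(0.50, 0.00, 0.80),
    V5 = c(0.75, 0.00, 0.55),  V6 = c(0.95, 0.00, 0.15))
  electrodes <- on_ellipsoid(dirs, ax)
  R <- rotation_align(c(0, 0, -1), config$apex_direction)
  if (config$roll != 0) {
    a <- config$roll * pi / 180
    axis <- config$apex_direction / sqrt(sum(config$apex_direction^2))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- (diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K) %*% R
  }
  hc <- colMeans(mesh$nodes)
  # torso-frame position of a heart point p: R (p - hc) + heart_center
  pos <- sweep(mesh$nodes, 2, hc) %*% t(R)
  pos <- sweep(pos, 2, config$heart_center, "+")
  if (any(rowSums(sweep(pos, 2, ax, "/")^2) >= 1)) {
    stop("heart mesh does not fit inside the torso ellipsoid")
  }
  # electrodes mapped into the heart frame for the lead-field integrals
  e_heart <- sweep(electrodes, 2, config$heart_center) %*% R
  e_heart <- sweep(e_heart, 2, hc, "+")
  structure(list(electrodes = electrodes, electrode_names = rownames(dirs),
                 rotation = R, heart_centroid = hc, config = config,
                 electrodes_heart_frame = e_heart),
            class = "torso_model")
}

lead_names <- c("I", "II", "III", "aVR", "aVL", "aVF",
                "V1", "V2", "V3", "V4", "V5", "V6")

#' Compute the 12-lead pseudo-ECG from an EP solution
#'
#' Electrode potentials are volume integrals of the diffusion-current dipole
#' density against the infinite-medium lead field: phi(e, t) =
#' -sum_elements vol * (D grad u) . grad(1 / |x_e - x|). Limb leads follow
#' Einthoven/Goldberger, precordial leads are referenced to the Wilson
#' central terminal. The Einthoven identity I + III = II holds exactly.
#'
#' @param sol an `ep_solution` (snapshot stride <= 2 ms recommended).
#' @param mesh,fibers,params the EP inputs that produced `sol`.
#' @param torso a `torso_model`.
#' @return object of class `ecg_trace`: `time` (ms), `leads` (T x 12 matrix).
#' @export
compute_ecg <- function(sol, mesh, fibers, params, torso) {
  stopifnot(inherits(sol, "ep_solution"), inherits(torso, "torso_model"))
  el <- torso$electrodes_heart_frame
  cent <- element_centroids(mesh)
  # electrodes must lie well outside the myocardium
  for (k in seq_len(nrow(el))) {
    if (min(colSums((t(mesh$nodes) - el[k, ])^2)) < 4) {
      stop("electrode ", torso$electrode_names[k], " lies inside the myocardium")
    }
  }
  D <- assemble_diffusivity(mesh, fibers, params)
  pg <- p1_gradients(mesh$nodes, mesh$tets)
  vol <- pg$vol
  M <- nrow(mesh$tets); n <- nrow(mesh$nodes)
  A <- matrix(0, nrow(el), n)
  for (k in seq_len(nrow(el))) {
    r <- sweep(cent, 2, el[k, ], "-")   # x - x_e
    rn <- pmax(vnorm(r), 1e-6)
    gr <- -r / rn^3                      # grad_x 1/|x_e - x|
    w <- cbind(D[, 1] * gr[, 1] + D[, 2] * gr[, 2] + D[, 3] * gr[, 3],
               D[, 4] * gr[, 1] + D[, 5] * gr[, 2] + D[, 6] * gr[, 3],
               D[, 7] * gr[, 1] + D[, 8] * gr[, 2] + D[, 9] * gr[, 3]) * vol
    rowA <- numeric(n)
    for (a in 1:4) {
      contrib <- rowSums(w * pg$g[[a]])
      acc <- tapply(contrib, mesh$tets[, a], sum)
      idx <- as.integer(names(acc))
      rowA[idx] <- rowA[idx] + as.numeric(acc)
    }
    A[k, ] <- rowA
  }
  # the source dipole density is the diffusion current -D grad(u)
  phi <- -A %*% sol$U * torso$config$gain  # electrodes x time
  rownames(phi) <- torso$electrode_names
  RA <- phi["RA", ]; LA <- phi["LA", ]; LL <- phi["LL", ]
  wct <- (RA + LA + LL) / 3
  leads <- cbind(I = LA - RA, II = LL - RA, III = LL - LA,
                 aVR = RA - (LA + LL) / 2, aVL = LA - (RA + LL) / 2,
                 aVF = LL - (RA + LA) / 2,
                 V1 = phi["V1", ] - wct, V2 = phi["V2", ] - wct,
                 V3 = phi["V3", ] - wct, V4 = phi["V4", ] - wct,
                 V5 = phi["V5", ] - wct, V6 = phi["V6", ] - wct)
  structure(list(time = sol$times, leads = leads,
                 sample_ms = diff(sol$times[1:2])),
            class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat("ecg_trace:", nrow(x$leads), "samples at", x$sample_ms, "ms,",
      "12 leads\n")
  invisible(x)
}

#' Construct an ECG trace from raw lead samples
#'
#' Mainly for tests and file import: wraps a time vector and a 12-column (or
#' fewer) lead matrix into the `ecg_trace` container.
#'
#' @param time sample times (ms).
#' @param leads matrix with named columns among the 12 standard leads.
#' @return an `ecg_trace`.
#' @export
ecg_trace <- function(time, leads) {
  stopifnot(length(time) == nrow(leads))
  structure(list(time = time, leads = as.matrix(leads),
                 sample_ms = if (length(time) > 1) diff(time[1:2]) else NA),
            class = "ecg_trace")
}

#' Extract global ECG features
#'
#' QRS onset/offset from threshold crossings of the RMS temporal-derivative
#' envelope across leads (threshold `thr_frac` of its peak; the offset
#' requires a sustained quiet gap). The QT interval runs from QRS onset to
#' the end of the last deflection (T-wave end). The electrical axis is
#' atan2(net aVF area, net I area) over the QRS window, in degrees
#' (0 = lead I axis, positive toward aVF, clinical convention).
#'
#' Features are invariant to overall amplitude scaling and time shifts.
#'
#' @param trace an `ecg_trace` containing one beat.
#' @param thr_frac detection threshold as a fraction of the peak RMS
#'   derivative (default 0.05).
#' @param quiet_gap minimal quiet interval (ms) separating QRS from T.
#' @return object of class `ecg_features`: list(qrsd, qtd, ea).
#' @export
extract_features <- function(trace, thr_frac = 0.05, quiet_gap = 40) {
  stopifnot(inherits(trace, "ecg_trace"))
  L <- trace$leads
  tt <- trace$time
  if (nrow(L) < 5) stop("trace too short")
  dL <- apply(L, 2, diff) / diff(tt)[1]
  v <- sqrt(rowMeans(dL^2))
  tv <- (tt[-1] + tt[-length(tt)]) / 2
  peak <- max(v)
  if (!is.finite(peak) || peak <= 1e-12 * max(abs(L), 1e-300)) {
    stop("no QRS detected (flat trace)")
  }
  thr <- thr_frac * peak
  active <- v >= thr
  if (!any(active)) stop("no QRS detected")
  i_on <- which(active)[1]
  t_on <- tv[i_on]
  # QRS offset: first sustained quiet gap after onset
  gap_n <- max(1L, round(quiet_gap / diff(tt)[1]))
  i_off <- NA_integer_
  i <- i_on
  while (i <= length(active)) {
    if (!active[i]) {
      j <- min(length(active), i + gap_n - 1L)
      if (!any(active[i:j])) { i_off <- i - 1L; break }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.na(i_off)) i_off <- max(which(active))
  t_qrs_off <- tv[i_off]
  t_end <- tv[max(which(active))]
  qrsd <- t_qrs_off - t_on
  qtd <- if (t_end > t_qrs_off + quiet_gap / 2) t_end - t_on else NA_real_
  # electrical axis over the QRS window
  win <- tt >= t_on & tt <= t_qrs_off
  dtv <- diff(tt)[1]
  area <- function(lead) sum(L[win, lead]) * dtv
  ea <- atan2(area("aVF"), area("I")) * 180 / pi
  structure(list(qrsd = qrsd, qtd = qtd, ea = ea,
                 qrs_onset = t_on, qrs_offset = t_qrs_off, t_end = t_end),
            class = "ecg_features")
}

#' @export
print.ecg_features <- function(x, ...) {
  cat("QRSd:", round(x$qrsd, 1), "ms  QTd:",
      if (is.na(x$qtd)) "NA" else round(x$qtd, 1), "ms  EA:",
      round(x$ea, 1), "deg\n")
  invisible(x)
}

#' Write an ECG trace to CSV
#'
#' One time column (ms) and one column per lead; a comment header line
#' declares the units.
#'
#' @param trace an `ecg_trace`.
#' @param path output file.
#' @export
write_ecg_csv <- function(trace, path) {
  con <- file(path, "w")
  writeLines("# time: ms; leads: arbitrary mV-scaled units", con)
  df <- data.frame(time_ms = trace$time, trace$leads, check.names = FALSE)
  write.csv(df, con, row.names = FALSE)
  close(con)
}
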