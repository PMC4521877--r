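# Virtual-cohort generation and the statistics pipeline. Model parameters
# are drawn from truncated-normal priors centred on the population means of
# the estimated parameters (conductivities, stiffness, active force,
# Windkessel constants); clinical-style covariates (an NT-proBNP-like
# biomarker, vitals, an outcome score) are statistical surrogates drawn with
# a configurable correlation to the active force through a one-factor
# Gaussian copula, so the statistics layer can be tested against known
# ground truth.

#' Cohort prior distributions and effect sizes
#'
#' Each model-parameter prior is (mean, sd, lower, upper) of a truncated
#' normal. Covariate effect sizes are the target correlations with the
#' maximum active stress sigma0. Observation noise SDs apply to the
#' simulated measurements.
#'
#' @param params named list of c(mean, sd, lower, upper) priors.
#' @param covariates named list of marginal specs; `dist` is "normal",
#'   "lognormal" or "truncnorm".
#' @param effects named numeric: correlation of each covariate with sigma0
#'   (absolute value < 1).
#' @param noise_sd named numeric: observation noise SDs.
#' @return object of class `cohort_priors`.
#' @export
cohort_priors <- function(params = NULL, covariates = NULL, effects = NULL,
                          noise_sd = NULL) {
  def_params <- list(
    # lower bound 150: below it the depolarization front is not resolvable
    # on desk-scale meshes (discrete conduction block); see the vignette
    c_myo = c(413, 232, 150, 1400),
    c_lv = c(1600, 600, 500, 4500),
    c_rv = c(2200, 800, 500, 5000),
    tau_close = c(175, 30, 80, 320),
    E = c(590, 135, 250, 1100),
    sigma0 = c(295, 100, 100, 520),
    ao_C = c(2269, 1375, 300, 8000),
    ao_Rp = c(3.64e-4, 2.27e-4, 6e-5, 1.5e-3),
    ao_Rc = c(4.72e-5, 2.46e-5, 8e-6, 2e-4),
    ao_Pr = c(52, 23, 10, 120),
    pa_C = c(2757, 1869, 300, 9000),
    pa_Rp = c(1.51e-4, 1.51e-4, 2e-5, 8e-4),
    pa_Rc = c(2.91e-5, 2.26e-5, 4e-6, 1.5e-4),
    pa_Pr = c(15, 9, 3, 50),
    anatomy_scale = c(1, 0.07, 0.8, 1.25))
  def_cov <- list(
    nt_probnp = list(dist = "lognormal", meanlog = 7.295, sdlog = 1.130),
    heart_rate = list(dist = "truncnorm", mean = 70, sd = 17,
                      lower = 40, upper = 140),
    sbp_rest = list(dist = "truncnorm", mean = 121, sd = 18,
                    lower = 70, upper = 200),
    sbp_exercise = list(dist = "truncnorm", mean = 165, sd = 25,
                        lower = 90, upper = 260),
    outcome_score = list(dist = "truncnorm", mean = 0.70, sd = 0.15,
                         lower = 0, upper = 1))
  def_eff <- c(nt_probnp = -0.5, heart_rate = -0.5, sbp_rest = 0.5,
               sbp_exercise = 0.5, outcome_score = 0.77)
  def_noise <- c(qrsd = 5, ea = 8, qt = 10, ef = 2, sv = 5, edv = 8,
                 esv = 8, edp = 1, esp = 5)
  pr <- structure(list(
    params = modifyList(def_params, params %||% list()),
    covariates = modifyList(def_cov, covariates %||% list()),
    effects = def_eff, noise_sd = def_noise), class = "cohort_priors")
  if (!is.null(effects)) pr$effects[names(effects)] <- effects
  if (!is.null(noise_sd)) pr$noise_sd[names(noise_sd)] <- noise_sd
  if (any(abs(pr$effects) >= 1)) stop("|effect correlations| must be < 1")
  for (nm in names(pr$params)) {
    sp <- pr$params[[nm]]
    if (sp[2] <= 0) stop("prior SD must be positive: ", nm)
    if (sp[3] >= sp[4]) stop("empty truncation support: ", nm)
  }
  pr
}

# truncated-normal draws by inverse-CDF (exact, vectorized)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf, u = NULL) {
  plo <- pnorm(lower, mean, sd); phi <- pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) stop("infeasible truncation: empty support")
  if (is.null(u)) u <- runif(n)
  qnorm(plo + u * (phi - plo), mean, sd)
}

qtrunc_from_z <- function(z, mean, sd, lower, upper) {
  rtruncnorm(length(z), mean, sd, lower, upper, u = pnorm(z))
}

#' Sample a virtual heart-failure cohort
#'
#' Draws model parameters from the truncated-normal priors; sigma0 also
#' anchors a one-factor Gaussian copula from which the covariates inherit
#' their configured correlations. With `simulate = "ep"` or `"full"` each
#' patient's forward model is run on a scaled anatomy to produce noiseless
#' observations, to which seeded noise is added. Deterministic for fixed
#' (priors, n, seed).
#'
#' @param priors a [cohort_priors()].
#' @param n number of patients (>= 1).
#' @param seed integer seed.
#' @param simulate `"none"` (parameters + covariates only), `"ep"` (adds
#'   QRSd/EA/QT observations) or `"full"` (adds EF/SV/EDV/ESV/EDP/ESP).
#' @param edge_length mesh resolution (mm) for the forward runs.
#' @return object of class `virtual_cohort`: list of patients, each with
#'   `params`, `covariates`, `targets` (a [clinical_targets()] or NULL),
#'   `truth` (noiseless observations).
#' @export
sample_cohort <- function(priors = cohort_priors(), n, seed = 1,
                          simulate = c("none", "ep", "full"),
                          edge_length = 12) {
  simulate <- match.arg(simulate)
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  eff <- priors$effects
  ncv <- length(eff)
  # one-factor copula: z_sigma is the factor; cov_i = r_i z_sigma +
  # sqrt(1 - r_i^2) e_i gives corr(cov_i, sigma-latent) = r_i exactly
  z_sig <- rnorm(n)
  zc <- vapply(seq_len(ncv), function(k) {
    eff[k] * z_sig + sqrt(1 - eff[k]^2) * rnorm(n)
  }, numeric(n))
  zc <- matrix(zc, nrow = n)
  colnames(zc) <- names(eff)
  draw <- function(nm) {
    sp <- priors$params[[nm]]
    rtruncnorm(n, sp[1], sp[2], sp[3], sp[4])
  }
  sp <- priors$params$sigma0
  sigma0 <- qtrunc_from_z(z_sig, sp[1], sp[2], sp[3], sp[4])
  par_df <- data.frame(
    c_myo = draw("c_myo"), c_lv = draw("c_lv"), c_rv = draw("c_rv"),
    tau_close = draw("tau_close"), E = draw("E"), sigma0 = sigma0,
    ao_C = draw("ao_C"), ao_Rp = draw("ao_Rp"), ao_Rc = draw("ao_Rc"),
    ao_Pr = draw("ao_Pr"), pa_C = draw("pa_C"), pa_Rp = draw("pa_Rp"),
    pa_Rc = draw("pa_Rc"), pa_Pr = draw("pa_Pr"),
    anatomy_scale = draw("anatomy_scale"))
  par_df$c_lv <- pmax(par_df$c_lv, par_df$c_myo)
  par_df$c_rv <- pmax(par_df$c_rv, par_df$c_myo)
  cov_df <- data.frame(row.names = seq_len(n))
  for (nm in names(priors$covariates)) {
    spc <- priors$covariates[[nm]]
    z <- zc[, nm]
    cov_df[[nm]] <- switch(spc$dist,
      normal = spc$mean + spc$sd * z,
      lognormal = exp(spc$meanlog + spc$sdlog * z),
      truncnorm = qtrunc_from_z(z, spc$mean, spc$sd, spc$lower, spc$upper),
      stop("unknown covariate distribution: ", spc$dist))
  }
  noise_seeds <- sample.int(2^31 - 1, n)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    pars <- as.list(par_df[i, ])
    pat <- list(id = i, params = pars, covariates = as.list(cov_df[i, ]),
                targets = NULL, truth = NULL)
    if (simulate != "none") {
      sim <- simulate_patient(pars, priors, simulate, edge_length,
                              noise_seeds[i])
      pat$targets <- sim$targets
      pat$truth <- sim$truth
    }
    patients[[i]] <- pat
  }
  structure(list(patients = patients, priors = priors, n = n, seed = seed,
                 simulate = simulate),
            class = "virtual_cohort")
}

# forward-simulate one patient's observations (+ seeded noise)
simulate_patient <- function(pars, priors, level, edge_length, noise_seed) {
  cfg <- anatomy_config(lv_radii = c(28, 28, 48) * pars$anatomy_scale,
                        rv_offset = 16 * pars$anatomy_scale,
                        edge_length = edge_length)
  mesh <- build_biventricular_mesh(cfg)
  fib <- generate_fibers(mesh)
  ep <- ep_parameters(c_myo = pars$c_myo, c_lv = pars$c_lv,
                      c_rv = pars$c_rv, tau_close = pars$tau_close)
  sol <- simulate_ep(mesh, fib, ep, sinus_protocol(mesh), duration = 650,
                     dt = 0.1)
  torso <- build_torso(mesh)
  fe <- extract_features(compute_ecg(sol, mesh, fib, ep, torso))
  truth <- list(qrsd = fe$qrsd, ea = fe$ea, qt = fe$qtd)
  if (level == "full") {
    hemo <- hemo_parameters(
      aorta = wk3_parameters(C = pars$ao_C, Rp = pars$ao_Rp,
                             Rc = pars$ao_Rc, Pr = pars$ao_Pr),
      pulmonary = wk3_parameters(C = pars$pa_C, Rp = pars$pa_Rp,
                                 Rc = pars$pa_Rc, Pr = pars$pa_Pr,
                                 artery = "pulmonary"))
    beat <- simulate_beat(mesh, fib, sol,
                          mech_parameters(E = pars$E, sigma0 = pars$sigma0),
                          hemo, early_stop = TRUE)
    truth <- c(truth, list(ef = beat$lv$EF, sv = beat$lv$SV,
                           edv = beat$lv$EDV, esv = beat$lv$ESV,
                           edp = beat$lv$EDP, esp = beat$lv$ESP))
  }
  ns <- priors$noise_sd
  set.seed(noise_seed)
  noisy <- function(key, val) {
    if (is.null(val) || is.na(val)) return(NULL)
    val + rnorm(1, 0, ns[[key]])
  }
  targets <- clinical_targets(
    m_qrsd = noisy("qrsd", truth$qrsd),
    m_ea = noisy("ea", truth$ea),
    m_qt = noisy("qt", truth$qt),
    ef = if (level == "full") noisy("ef", truth$ef) else NULL,
    sv = if (level == "full") noisy("sv", truth$sv) else NULL,
    edv = if (level == "full") noisy("edv", truth$edv) else NULL,
    esv = if (level == "full") noisy("esv", truth$esv) else NULL,
    edp = if (level == "full") noisy("edp", truth$edp) else NULL,
    esp = if (level == "full") noisy("esp", truth$esp) else NULL)
  list(targets = targets, truth = truth)
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat("virtual_cohort:", x$n, "patients (simulate =", x$simulate, ")\n")
  invisible(x)
}

#' Flatten a cohort to a data.frame (one row per patient)
#' @param cohort a `virtual_cohort`.
#' @return data.frame with parameters, covariates and observations.
#' @export
cohort_to_df <- function(cohort) {
  rows <- lapply(cohort$patients, function(p) {
    obs <- if (!is.null(p$targets)) {
      tl <- p$targets[!vapply(p$targets, is.null, TRUE)]
      tl <- tl[!vapply(tl, is.data.frame, TRUE)]
      if (length(tl)) as.data.frame(tl) else NULL
    } else NULL
    out <- cbind(data.frame(id = p$id), as.data.frame(p$params),
                 as.data.frame(p$covariates))
    if (!is.null(obs)) out <- cbind(out, obs)
    out
  })
  do.call(rbind, rows)
}

#' Pearson correlation with significance
#'
#' Sample Pearson r with the two-sided p-value from the exact t transform
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors (length >= 3, finite, non-constant).
#' @return list(r, p, n, t).
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  r <- min(max(r, -1), 1)
  if (1 - r^2 < .Machine$double.eps) {
    return(list(r = r, p = 0, n = n, t = sign(r) * Inf))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2), n = n, t = t)
}

#' Grubbs single-outlier test
#'
#' G = max |x_i - mean| / sd, compared with the exact critical value
#' G_crit = ((n-1)/sqrt(n)) sqrt(t^2 / (n - 2 + t^2)) where t is the upper
#' alpha/(2n) quantile of the t distribution on n-2 degrees of freedom. At
#' most one observation is flagged per call.
#'
#' @param x numeric vector (length >= 3, non-constant).
#' @param alpha significance level.
#' @return list(outlier = index or NA, G, critical, value).
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  s <- sd(x)
  if (s == 0) stop("zero variance")
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  G <- dev[i] / s
  tq <- qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  list(outlier = if (G > crit) i else NA_integer_, G = G, critical = crit,
       value = if (G > crit) x[i] else NA_real_)
}

#' Cohort summary table
#'
#' Mean (SD) for numeric columns (sample SD, n-1 denominator), count
#' (percent) for categorical columns.
#'
#' @param records data.frame, one row per patient.
#' @return data.frame with columns variable, level, mean, sd, n, pct.
#' @export
cohort_summary <- function(records) {
  stopifnot(nrow(records) >= 1)
  rows <- list()
  for (nm in names(records)) {
    col <- records[[nm]]
    if (is.numeric(col)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = nm, level = NA, mean = mean(col, na.rm = TRUE),
        sd = sd(col[!is.na(col)]), n = sum(!is.na(col)), pct = NA)
    } else {
      tab <- table(col)
      for (lv in names(tab)) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = nm, level = lv, mean = NA, sd = NA,
          n = as.integer(tab[[lv]]),
          pct = 100 * tab[[lv]] / sum(tab))
      }
    }
  }
  do.call(rbind, rows)
}
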