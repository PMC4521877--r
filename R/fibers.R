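# Rule-based myocardial fiber architecture: the elevation angle of the fiber
# above the local circumferential direction varies linearly with transmural
# depth, from the epicardial to the endocardial endpoint angle of the
# ventricle owning the element.

#' Fiber angle rule
#'
#' Endpoint elevation angles (degrees) of the linear transmural angle law.
#' Defaults: LV from -60 deg (epicardium) through 0 deg (mid-wall) to
#' +60 deg (endocardium); RV from -80 deg to +80 deg.
#'
#' @param lv_endo_angle,lv_epi_angle,rv_endo_angle,rv_epi_angle degrees,
#'   each in (-90, 90).
#' @return object of class `fiber_rule`.
#' @export
fiber_rule <- function(lv_endo_angle = 60, lv_epi_angle = -60,
                       rv_endo_angle = 80, rv_epi_angle = -80) {
  ang <- c(lv_endo_angle, lv_epi_angle, rv_endo_angle, rv_epi_angle)
  if (any(ang <= -90 | ang >= 90)) stop("angles must lie in (-90, 90) degrees")
  structure(list(lv_endo_angle = lv_endo_angle, lv_epi_angle = lv_epi_angle,
                 rv_endo_angle = rv_endo_angle, rv_epi_angle = rv_epi_angle),
            class = "fiber_rule")
}

#' Elevation angle of the rule at a given transmural depth
#'
#' @param depth transmural depth in `[0, 1]` (0 = epicardium,
#'   1 = endocardium).
#' @param rule a [fiber_rule()].
#' @param ventricle `"LV"` or `"RV"`.
#' @return elevation angle in degrees.
#' @export
fiber_elevation_angle <- function(depth, rule = fiber_rule(),
                                  ventricle = c("LV", "RV")) {
  ventricle <- match.arg(ventricle)
  if (ventricle == "LV") {
    rule$lv_epi_angle + depth * (rule$lv_endo_angle - rule$lv_epi_angle)
  } else {
    rule$rv_epi_angle + depth * (rule$rv_endo_angle - rule$rv_epi_angle)
  }
}

#' Generate rule-based fibers on a bi-ventricular mesh
#'
#' For each element the local frame is built from the transmural direction
#' (gradient of the Laplace depth field) and the long axis: circumferential
#' = long_axis x transmural, longitudinal completes the triad. The fiber is
#' the circumferential direction rotated by the elevation angle within the
#' wall tangent plane. Elements whose tangent frame is degenerate (apex,
#' where the transmural gradient aligns with the long axis) fall back to a
#' projection frame and are counted in `n_degenerate`.
#'
#' @param mesh a `bv_mesh` with `node_depth`.
#' @param rule a [fiber_rule()].
#' @return object of class `fiber_field`: list with `vectors` (M x 3 unit
#'   fiber directions), `angle` (degrees), `rule`, `n_degenerate`.
#' @export
generate_fibers <- function(mesh, rule = fiber_rule()) {
  stopifnot(inherits(mesh, "bv_mesh"))
  pg <- p1_gradients(mesh$nodes, mesh$tets)
  # element-wise gradient of depth (points from epi toward endo)
  d <- mesh$node_depth
  g <- pg$g[[1]] * d[mesh$tets[, 1]] + pg$g[[2]] * d[mesh$tets[, 2]] +
    pg$g[[3]] * d[mesh$tets[, 3]] + pg$g[[4]] * d[mesh$tets[, 4]]
  gn <- vnorm(g)
  flat <- gn < 1e-10
  g[flat, ] <- matrix(rep(c(1, 0, 0), sum(flat)), ncol = 3, byrow = TRUE)
  g <- normalize_rows(g)
  la <- matrix(rep(mesh$long_axis, nrow(g)), ncol = 3, byrow = TRUE)
  ec <- cross3(la, g)
  ecn <- vnorm(ec)
  degen <- ecn < 1e-6 | flat
  if (any(degen)) {
    # transmural direction parallel to the long axis (apex): use any
    # horizontal direction orthogonal to g as "circumferential"
    alt <- cbind(-g[degen, 2], g[degen, 1], 0)
    bad <- vnorm(alt) < 1e-9
    alt[bad, ] <- matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3, byrow = TRUE)
    ec[degen, ] <- alt
  }
  ec <- normalize_rows(ec)
  el <- normalize_rows(cross3(g, ec))
  depth <- mesh$element_depth
  is_lv <- mesh$element_region == "LV"
  ang <- ifelse(is_lv,
                fiber_elevation_angle(depth, rule, "LV"),
                fiber_elevation_angle(depth, rule, "RV"))
  a <- ang * pi / 180
  f <- cos(a) * ec + sin(a) * el
  f <- normalize_rows(f)
  structure(list(vectors = f, angle = ang, rule = rule,
                 transmural = g, n_degenerate = sum(degen)),
            class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  cat("fiber_field:", nrow(x$vectors), "elements, angle range [",
      round(min(x$angle), 1), ",", round(max(x$angle), 1), "] deg,",
      x$n_degenerate, "degenerate frames\n")
  invisible(x)
}
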