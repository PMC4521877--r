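# Synthetic bi-ventricular anatomy: truncated-ellipsoid LV fused with a
# crescent-shaped RV free wall of constant (3 mm by default) thickness.
# Stands in for image-derived anatomies while preserving the surface labels,
# element tags and transmural coordinate the downstream solvers rely on.

#' Anatomy configuration for the synthetic bi-ventricular mesh
#'
#' All lengths in mm. The left ventricle is a truncated ellipsoidal shell;
#' the right ventricle is a crescent-shaped shell of constant wall thickness
#' attached to the LV epicardium over an angular sector. Defaults describe a
#' moderately dilated failing heart.
#'
#' @param lv_radii length-3 endocardial semi-axes (a, b, c) in mm; c is the
#'   long axis.
#' @param lv_wall_thickness LV wall thickness (mm), added to each semi-axis.
#' @param rv_offset maximal distance of the RV endocardial sheet from the LV
#'   epicardium (mm); 0 suppresses the RV entirely.
#' @param rv_extent angular extent of the RV sector (degrees).
#' @param rv_center azimuth of the RV sector centre (degrees). The default
#'   keeps the sector away from the periodic seam.
#' @param rv_apex_frac fraction of the base-to-apex extent covered by the RV.
#' @param rv_wall_thickness RV free-wall thickness (mm); default 3.
#' @param base_truncation fraction of the full long-axis height truncated at
#'   the base; 0 yields a closed ellipsoid (no base plane, no RV).
#' @param fast_layer_thickness thickness (mm) of the sub-endocardial
#'   fast-conduction layer mimicking the Purkinje system; default 1.
#' @param edge_length target element edge length (mm); sets grid resolution.
#' @param n_phi,n_theta,n_wall optional explicit grid dimensions overriding
#'   `edge_length` (`n_phi` must be even).
#' @param jitter relative amplitude (fraction of `edge_length`) of seeded
#'   random perturbation applied to interior (cell-centroid) nodes; 0 keeps
#'   the mesh fully structured.
#' @return object of class `anatomy_config`.
#' @export
anatomy_config <- function(lv_radii = c(28, 28, 48),
                           lv_wall_thickness = 10,
                           rv_offset = 16,
                           rv_extent = 150,
                           rv_center = 180,
                           rv_apex_frac = 0.65,
                           rv_wall_thickness = 3,
                           base_truncation = 0.25,
                           fast_layer_thickness = 1,
                           edge_length = 8,
                           n_phi = NULL, n_theta = NULL, n_wall = NULL,
                           jitter = 0) {
  stopifnot(length(lv_radii) == 3)
  if (any(lv_radii <= 0) || lv_wall_thickness <= 0 || rv_wall_thickness <= 0 ||
      edge_length <= 0) {
    stop("all lengths must be positive")
  }
  if (base_truncation < 0 || base_truncation >= 0.5) {
    stop("base_truncation must lie in [0, 0.5)")
  }
  if (fast_layer_thickness < 0 ||
      fast_layer_thickness >= min(lv_wall_thickness, rv_wall_thickness)) {
    stop("fast_layer_thickness must be >= 0 (0 disables the layer) and ",
         "smaller than the thinnest wall")
  }
  if (rv_offset < 0) stop("rv_offset must be >= 0")
  if (rv_offset > 0 && base_truncation == 0) {
    stop("a closed ellipsoid (base_truncation = 0) cannot carry an RV")
  }
  cfg <- list(lv_radii = as.numeric(lv_radii),
              lv_wall_thickness = lv_wall_thickness,
              rv_offset = rv_offset, rv_extent = rv_extent,
              rv_center = rv_center, rv_apex_frac = rv_apex_frac,
              rv_wall_thickness = rv_wall_thickness,
              base_truncation = base_truncation,
              fast_layer_thickness = fast_layer_thickness,
              edge_length = edge_length,
              n_phi = n_phi, n_theta = n_theta, n_wall = n_wall,
              jitter = jitter)
  class(cfg) <- "anatomy_config"
  cfg
}

# --- conforming hex/prism -> tet splitting ---------------------------------
# Each quad face is split along the diagonal through its minimum global node
# index (shared faces therefore split identically in both cells); every cell
# receives a centroid node and is tetrahedralised as a fan over its face
# triangles. Conforming by construction: 12 tets per hex, 8 per prism.

# vectorized quad splitting: rows of `q` are quads (cyclic); returns the
# 2R triangle rows, interleaved per quad, with the diagonal through each
# quad's minimum global index
split_quads_rows <- function(q) {
  use13 <- max.col(-q, ties.method = "first") %in% c(1, 3)
  t1 <- ifelse(use13, q[, 1], q[, 2])
  t2 <- ifelse(use13, q[, 2], q[, 3])
  t3 <- ifelse(use13, q[, 3], q[, 4])
  s1 <- ifelse(use13, q[, 1], q[, 2])
  s2 <- ifelse(use13, q[, 3], q[, 4])
  s3 <- ifelse(use13, q[, 4], q[, 1])
  out <- matrix(0L, 2 * nrow(q), 3)
  out[seq(1, 2 * nrow(q), 2), ] <- cbind(t1, t2, t3)
  out[seq(2, 2 * nrow(q), 2), ] <- cbind(s1, s2, s3)
  out
}

# nodes: N x 3. hexes: H x 8 (corner order: bottom quad then top quad,
# matching). prisms: P x 6. Returns augmented nodes, tets, owner cell id.
cells_to_tets <- function(nodes, hexes, prisms = NULL) {
  n0 <- nrow(nodes)
  nh <- if (is.null(hexes)) 0L else nrow(hexes)
  np <- if (is.null(prisms)) 0L else nrow(prisms)
  cents <- NULL; tets <- NULL; owner <- NULL
  hex_face_idx <- list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                       c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  if (nh > 0) {
    hc <- matrix(0, nh, 3)
    for (k in 1:8) hc <- hc + nodes[hexes[, k], , drop = FALSE] / 8
    cid <- n0 + seq_len(nh)
    tri_all <- vector("list", 6)
    for (f in 1:6) {
      tris <- split_quads_rows(hexes[, hex_face_idx[[f]], drop = FALSE])
      tri_all[[f]] <- cbind(tris, rep(cid, each = 2))
    }
    tets <- do.call(rbind, tri_all)
    owner <- rep(rep(seq_len(nh), each = 2), 6)
    cents <- hc
  }
  if (np > 0) {
    pc <- matrix(0, np, 3)
    for (k in 1:6) pc <- pc + nodes[prisms[, k], , drop = FALSE] / 6
    cid <- n0 + nh + seq_len(np)
    quads <- list(c(1, 2, 5, 4), c(2, 3, 6, 5), c(3, 1, 4, 6))
    tl <- list(cbind(prisms[, c(1, 2, 3), drop = FALSE], cid),
               cbind(prisms[, c(4, 5, 6), drop = FALSE], cid))
    ol <- list(seq_len(np), seq_len(np))
    for (f in 1:3) {
      tris <- split_quads_rows(prisms[, quads[[f]], drop = FALSE])
      tl[[f + 2]] <- cbind(tris, rep(cid, each = 2))
      ol[[f + 2]] <- rep(seq_len(np), each = 2)
    }
    tets <- rbind(tets, do.call(rbind, tl))
    owner <- c(owner, nh + unlist(ol))
    cents <- rbind(cents, pc)
  }
  nodes2 <- rbind(nodes, cents)
  # enforce positive volume
  p1 <- nodes2[tets[, 1], ]; p2 <- nodes2[tets[, 2], ]
  p3 <- nodes2[tets[, 3], ]; p4 <- nodes2[tets[, 4], ]
  det <- rowSums((p2 - p1) * cross3(p3 - p1, p4 - p1))
  flip <- det < 0
  tmp <- tets[flip, 1]
  tets[flip, 1] <- tets[flip, 2]
  tets[flip, 2] <- tmp
  list(nodes = nodes2, tets = tets, owner = owner,
       n_grid_nodes = n0, n_cells = nh + np)
}

# Boundary facets (faces belonging to exactly one tet), oriented outward.
# Faces appear at most twice; a numeric sorted-triple key keeps this O(n log n).
boundary_facets_of <- function(tets) {
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  opp <- c(tets[, 4], tets[, 3], tets[, 2], tets[, 1])
  n <- max(faces) + 1
  if (n^3 >= 2^53) stop("mesh too large for facet keys")
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  key <- (lo * n + mid) * n + hi
  bnd <- !duplicated(key) & !duplicated(key, fromLast = TRUE)
  list(facets = faces[bnd, , drop = FALSE], opposite = opp[bnd],
       owner_tet = rep(seq_len(nrow(tets)), 4)[bnd])
}

orient_outward <- function(nodes, facets, opposite) {
  a <- nodes[facets[, 1], , drop = FALSE]
  b <- nodes[facets[, 2], , drop = FALSE]
  c_ <- nodes[facets[, 3], , drop = FALSE]
  d <- nodes[opposite, , drop = FALSE]
  s <- rowSums(cross3(b - a, c_ - a) * (d - a))
  flip <- s > 0  # normal points toward the opposite (interior) node
  tmp <- facets[flip, 2]
  facets[flip, 2] <- facets[flip, 3]
  facets[flip, 3] <- tmp
  facets
}

# --- the generator ----------------------------------------------------------

#' Build a synthetic bi-ventricular tetrahedral mesh
#'
#' Constructs a truncated-ellipsoid LV shell fused with a crescent RV free
#' wall, labels the boundary (LV/RV endocardium, LV/RV septum, epicardium,
#' base), computes the transmural depth by solving a Laplace problem
#' (0 at the epicardium, 1 at the endocardium), tags the sub-endocardial
#' fast-conduction layer and collects valve-annulus node rings on the base
#' plane. Deterministic for fixed (config, seed).
#'
#' @param config an [anatomy_config()].
#' @param seed integer seed; only used when `config$jitter > 0`.
#' @return object of class `bv_mesh` with fields `nodes`, `tets`, `facets`,
#'   `facet_label`, `element_tag`, `element_region`, `node_depth`,
#'   `element_depth`, `long_axis`, `annuli`, `config`.
#' @export
build_biventricular_mesh <- function(config = anatomy_config(), seed = 1L) {
  stopifnot(inherits(config, "anatomy_config"))
  ax_en <- config$lv_radii
  tw <- config$lv_wall_thickness
  h <- config$edge_length
  tf <- config$base_truncation
  n_phi <- config$n_phi %||% max(8L, 2L * ceiling(pi * mean(ax_en[1:2]) / h))
  if (n_phi %% 2 == 1) n_phi <- n_phi + 1L
  z_base <- (1 - 2 * tf) * ax_en[3]
  th_b_en <- acos(min(1, z_base / ax_en[3]))
  arc <- (pi - th_b_en) * (ax_en[3] + tw / 2)
  n_t <- config$n_theta %||% max(4L, ceiling(arc / h))
  n_w <- config$n_wall %||% max(2L, round(tw / h))
  closed <- tf == 0

  layer_axes <- function(l) ax_en + (l / n_w) * tw
  ell_pt <- function(ax, th, ph) {
    cbind(ax[1] * sin(th) * cos(ph), ax[2] * sin(th) * sin(ph),
          ax[3] * cos(th))
  }

  phi <- 2 * pi * (0:(n_phi - 1)) / n_phi

  nodes <- list(); nn <- 0L
  add_nodes <- function(xyz) {
    nodes[[length(nodes) + 1]] <<- xyz
    idx <- nn + seq_len(nrow(xyz))
    nn <<- nn + nrow(xyz)
    idx
  }

  # LV sheets ---------------------------------------------------------------
  # rings: for truncated meshes ring 1 sits on the base plane; the south pole
  # is a single node per layer. Closed meshes get both poles.
  n_rings <- if (closed) n_t - 1L else n_t
  ring_idx <- array(NA_integer_, dim = c(n_w + 1L, n_rings, n_phi))
  pole_s <- integer(n_w + 1L)
  pole_n <- rep(NA_integer_, n_w + 1L)
  for (l in 0:n_w) {
    ax <- layer_axes(l)
    if (closed) {
      th <- pi * (1:(n_t - 1)) / n_t
    } else {
      thb <- acos(min(1, z_base / ax[3]))
      th <- thb + (pi - thb) * (0:(n_t - 1)) / n_t
    }
    for (i in seq_along(th)) {
      ring_idx[l + 1L, i, ] <- add_nodes(ell_pt(ax, th[i], phi))
    }
    pole_s[l + 1L] <- add_nodes(matrix(c(0, 0, -ax[3]), 1))
    if (closed) pole_n[l + 1L] <- add_nodes(matrix(c(0, 0, ax[3]), 1))
  }

  # RV sheets ---------------------------------------------------------------
  has_rv <- config$rv_offset > 0
  if (has_rv) {
    ax_ep <- layer_axes(n_w)
    phic <- config$rv_center * pi / 180
    half <- config$rv_extent * pi / 180 / 2
    angdiff <- function(a, b) {
      d <- (a - b) %% (2 * pi)
      pmin(d, 2 * pi - d)
    }
    jset <- which(angdiff(phi, phic) <= half + 1e-9)
    jset <- sort(jset)
    if (any(diff(jset) > 1)) stop("RV sector must not cross the phi seam; adjust rv_center")
    if (length(jset) < 4) stop("RV sector too narrow for grid resolution")
    n_rv_rows <- max(3L, min(n_rings, round(config$rv_apex_frac * n_rings)))
    nj <- length(jset)
    d_amp <- matrix(0, n_rv_rows, nj)
    for (r in seq_len(n_rv_rows)) {
      for (jj in seq_len(nj)) {
        d_amp[r, jj] <- config$rv_offset *
          sin(pi * (jj - 1) / (nj - 1)) *
          cos(pi / 2 * (r - 1) / (n_rv_rows - 1))
      }
    }
    d_amp[abs(d_amp) < 1e-9] <- 0
    # start from the LV epicardial sheet; nodes with positive bulge are
    # replaced by new offset nodes, the rest (sector rim) are shared
    rv_endo_idx <- ring_idx[n_w + 1L, seq_len(n_rv_rows), jset, drop = FALSE]
    dim(rv_endo_idx) <- c(n_rv_rows, nj)
    rv_epi_idx <- matrix(NA_integer_, n_rv_rows, nj)
    coords <- do.call(rbind, nodes)
    ell_normal <- function(p, ax, horizontal = FALSE) {
      g <- cbind(p[, 1] / ax[1]^2, p[, 2] / ax[2]^2,
                 if (horizontal) 0 else p[, 3] / ax[3]^2)
      normalize_rows(g)
    }
    for (r in seq_len(n_rv_rows)) {
      p <- coords[ring_idx[n_w + 1L, r, jset], , drop = FALSE]
      nrm <- ell_normal(p, ax_ep, horizontal = (r == 1))
      d <- d_amp[r, ]
      new_endo <- d > 0
      if (any(new_endo)) {
        idx <- add_nodes(p[new_endo, , drop = FALSE] + d[new_endo] * nrm[new_endo, , drop = FALSE])
        rv_endo_idx[r, new_endo] <- idx
      }
      rv_epi_idx[r, ] <- add_nodes(p + (d + config$rv_wall_thickness) * nrm)
    }
  }

  coords <- do.call(rbind, nodes)
  n_sheet_nodes <- nrow(coords)

  # node provenance flags ----------------------------------------------------
  lv_endo_sheet <- rep(FALSE, n_sheet_nodes)
  lv_epi_sheet <- rep(FALSE, n_sheet_nodes)
  rv_endo_sheet <- rep(FALSE, n_sheet_nodes)
  rv_epi_sheet <- rep(FALSE, n_sheet_nodes)
  under_rv <- rep(FALSE, n_sheet_nodes)
  drop_na <- function(x) x[!is.na(x)]
  lv_endo_sheet[drop_na(c(ring_idx[1, , ], pole_s[1], pole_n[1]))] <- TRUE
  lv_epi_sheet[drop_na(c(ring_idx[n_w + 1, , ], pole_s[n_w + 1],
                         pole_n[n_w + 1]))] <- TRUE
  if (has_rv) {
    rv_endo_sheet[rv_endo_idx] <- TRUE
    rv_epi_sheet[rv_epi_idx] <- TRUE
    under_rv[rv_endo_idx[d_amp > 0]] <- TRUE
    # the septal patch of the LV epicardium lies under the RV cavity
    under_rv[ring_idx[n_w + 1L, seq_len(n_rv_rows), jset][d_amp > 0]] <- TRUE
  }
  on_base <- abs(coords[, 3] - z_base) < 1e-6 & !closed

  # cells ---------------------------------------------------------------------
  hexes <- list(); prisms <- list(); regions_h <- list(); regions_p <- list()
  jp <- c(2:n_phi, 1)  # periodic next index
  for (l in 0:(n_w - 1)) {
    for (i in seq_len(n_rings - 1L)) {
      a <- ring_idx[l + 1L, i, ]; a2 <- ring_idx[l + 1L, i, jp]
      b <- ring_idx[l + 1L, i + 1L, ]; b2 <- ring_idx[l + 1L, i + 1L, jp]
      A <- ring_idx[l + 2L, i, ]; A2 <- ring_idx[l + 2L, i, jp]
      B <- ring_idx[l + 2L, i + 1L, ]; B2 <- ring_idx[l + 2L, i + 1L, jp]
      hexes[[length(hexes) + 1]] <- cbind(a, a2, b2, b, A, A2, B2, B)
      regions_h[[length(regions_h) + 1]] <- rep("LV", n_phi)
    }
    # south-pole prisms
    i <- n_rings
    a <- ring_idx[l + 1L, i, ]; a2 <- ring_idx[l + 1L, i, jp]
    A <- ring_idx[l + 2L, i, ]; A2 <- ring_idx[l + 2L, i, jp]
    prisms[[length(prisms) + 1]] <- cbind(a, a2, pole_s[l + 1L], A, A2, pole_s[l + 2L])
    regions_p[[length(regions_p) + 1]] <- rep("LV", n_phi)
    if (closed) {
      a <- ring_idx[l + 1L, 1, ]; a2 <- ring_idx[l + 1L, 1, jp]
      A <- ring_idx[l + 2L, 1, ]; A2 <- ring_idx[l + 2L, 1, jp]
      prisms[[length(prisms) + 1]] <- cbind(a2, a, pole_n[l + 1L], A2, A, pole_n[l + 2L])
      regions_p[[length(regions_p) + 1]] <- rep("LV", n_phi)
    }
  }
  if (has_rv) {
    for (r in seq_len(n_rv_rows - 1L)) {
      for (jj in seq_len(nj - 1L)) {
        hexes[[length(hexes) + 1]] <- matrix(c(
          rv_endo_idx[r, jj], rv_endo_idx[r, jj + 1],
          rv_endo_idx[r + 1, jj + 1], rv_endo_idx[r + 1, jj],
          rv_epi_idx[r, jj], rv_epi_idx[r, jj + 1],
          rv_epi_idx[r + 1, jj + 1], rv_epi_idx[r + 1, jj]), 1)
        regions_h[[length(regions_h) + 1]] <- "RV"
      }
    }
  }
  hexes <- do.call(rbind, hexes)
  prisms <- do.call(rbind, prisms)
  cell_region <- c(unlist(regions_h), unlist(regions_p))

  ct <- cells_to_tets(coords, hexes, prisms)
  nodes_all <- ct$nodes
  tets <- ct$tets
  element_region <- factor(cell_region[ct$owner], levels = c("LV", "RV"))
  # pad provenance flags to cover appended centroid nodes
  pad <- function(v) c(v, rep(FALSE, nrow(nodes_all) - length(v)))
  lv_endo_sheet <- pad(lv_endo_sheet); lv_epi_sheet <- pad(lv_epi_sheet)
  rv_endo_sheet <- pad(rv_endo_sheet); rv_epi_sheet <- pad(rv_epi_sheet)
  under_rv <- pad(under_rv); on_base <- pad(on_base)

  # seeded interior jitter ----------------------------------------------------
  if (config$jitter > 0) {
    set.seed(as.integer(seed))
    cent <- (n_sheet_nodes + 1):nrow(nodes_all)
    amp <- config$jitter * h / 2
    pert <- matrix(runif(3 * length(cent), -amp, amp), ncol = 3)
    trial <- nodes_all
    trial[cent, ] <- trial[cent, ] + pert
    p1 <- trial[tets[, 1], ]; p2 <- trial[tets[, 2], ]
    p3 <- trial[tets[, 3], ]; p4 <- trial[tets[, 4], ]
    det <- rowSums((p2 - p1) * cross3(p3 - p1, p4 - p1))
    bad_cells <- unique(ct$owner[det <= 1e-9])
    if (length(bad_cells)) {
      bad_nodes <- n_sheet_nodes + bad_cells
      trial[bad_nodes, ] <- nodes_all[bad_nodes, ]
    }
    nodes_all <- trial
  }

  # boundary facets + labels --------------------------------------------------
  bf <- boundary_facets_of(tets)
  facets <- orient_outward(nodes_all, bf$facets, bf$opposite)
  nlab <- nrow(facets)
  lab <- character(nlab)
  phic_sector <- function(p) {
    if (!has_rv) return(rep(FALSE, nrow(p)))
    ph <- atan2(p[, 2], p[, 1]) %% (2 * pi)
    d <- (ph - config$rv_center * pi / 180) %% (2 * pi)
    d <- pmin(d, 2 * pi - d)
    d <= config$rv_extent * pi / 180 / 2
  }
  f1 <- facets[, 1]; f2 <- facets[, 2]; f3 <- facets[, 3]
  all3 <- function(flag) flag[f1] & flag[f2] & flag[f3]
  any3 <- function(flag) flag[f1] | flag[f2] | flag[f3]
  cent <- (nodes_all[f1, ] + nodes_all[f2, ] + nodes_all[f3, ]) / 3
  in_sector <- phic_sector(cent)
  lab[] <- "EPI"
  m <- all3(lv_epi_sheet)
  lab[m & any3(under_rv)] <- "RV_SEPTUM"
  m <- all3(rv_endo_sheet) & any3(under_rv)
  lab[m] <- "RV_ENDO"
  m <- all3(lv_endo_sheet)
  lab[m] <- ifelse(in_sector[m], "LV_SEPTUM", "LV_ENDO")
  lab[all3(on_base)] <- "BASE"
  facet_label <- factor(lab, levels = c("LV_ENDO", "RV_ENDO", "LV_SEPTUM",
                                        "RV_SEPTUM", "EPI", "BASE"))

  # transmural depth (Laplace: endo = 1, epi = 0; the RV-facing septal
  # surface counts as epi so the septum carries a full LV-rule gradient) ----
  fixed <- rep(NA_real_, nrow(nodes_all))
  fixed[lv_endo_sheet] <- 1
  fixed[rv_endo_sheet & !lv_epi_sheet] <- 1
  fixed[lv_epi_sheet] <- 0
  fixed[rv_epi_sheet & is.na(fixed)] <- 0
  node_depth <- fem_laplace(nodes_all, tets, fixed)
  node_depth <- pmin(pmax(node_depth, 0), 1)
  element_depth <- rowMeans(matrix(node_depth[tets], ncol = 4))

  mesh <- structure(list(
    nodes = nodes_all, tets = tets,
    facets = facets, facet_label = facet_label,
    element_region = element_region,
    element_tag = factor(rep("MYO", nrow(tets)),
                         levels = c("MYO", "LV_FAST_LAYER", "RV_FAST_LAYER")),
    node_depth = node_depth, element_depth = element_depth,
    long_axis = c(0, 0, 1),
    z_base = if (closed) NA_real_ else z_base,
    annuli = list(), config = config, seed = as.integer(seed)),
    class = "bv_mesh")

  mesh$annuli <- make_annuli(mesh)
  mesh <- tag_fast_layer(mesh, config$fast_layer_thickness)
  mesh
}

# Valve-annulus node sets: rings on the base plane (synthetic surrogate for
# the four valve attachments; springs anchor these in the mechanics model).
make_annuli <- function(mesh) {
  if (is.na(mesh$z_base)) return(list())
  onb <- abs(mesh$nodes[, 3] - mesh$z_base) < 1e-6
  fl <- mesh$facet_label
  node_of <- function(labels) {
    f <- mesh$facets[fl %in% labels, , drop = FALSE]
    intersect(unique(as.vector(f)), which(onb))
  }
  lv_ring <- node_of(c("LV_ENDO", "LV_SEPTUM"))
  rv_ring <- node_of(c("RV_ENDO", "RV_SEPTUM"))
  split_ring <- function(ring, frac = 0.25) {
    if (length(ring) < 4) return(list(main = ring, side = ring))
    ph <- atan2(mesh$nodes[ring, 2], mesh$nodes[ring, 1])
    o <- order(ph)
    k <- max(1, round(frac * length(ring)))
    list(side = ring[o][seq_len(k)], main = ring[o][-seq_len(k)])
  }
  lv <- split_ring(lv_ring)
  rv <- split_ring(rv_ring)
  list(mitral = lv$main, aortic = lv$side,
       tricuspid = rv$main, pulmonary = rv$side)
}

#' Tag the sub-endocardial fast-conduction layer
#'
#' Elements whose centroid lies within `thickness` of the LV endocardium
#' (including the LV septal surface) are tagged `LV_FAST_LAYER`; likewise for
#' the RV endocardium and RV-facing septal surface (`RV_FAST_LAYER`). All
#' other elements are `MYO`. The layer mimics the Purkinje system; its
#' default thickness is 1 mm.
#'
#' @param mesh a `bv_mesh`.
#' @param thickness layer thickness in mm; must be smaller than the thinnest
#'   wall. A value of (numerically) zero clears all tags.
#' @return the mesh with updated `element_tag`.
#' @export
tag_fast_layer <- function(mesh, thickness) {
  stopifnot(inherits(mesh, "bv_mesh"))
  if (thickness < 0) stop("thickness must be >= 0")
  cfg <- mesh$config
  if (!is.null(cfg$lv_wall_thickness)) {
    wmin <- min(cfg$lv_wall_thickness,
                if (cfg$rv_offset > 0) cfg$rv_wall_thickness else Inf)
    if (thickness >= wmin) {
      stop("fast layer thickness (", thickness,
           " mm) would span the thinnest wall (", wmin, " mm)")
    }
  }
  tag <- rep("MYO", nrow(mesh$tets))
  if (thickness > 0) {
    cent <- element_centroids(mesh)
    d_lv <- surface_distance(cent, mesh, c("LV_ENDO", "LV_SEPTUM"),
                             limit = thickness)
    d_rv <- surface_distance(cent, mesh, c("RV_ENDO", "RV_SEPTUM"),
                             limit = thickness)
    tag[d_lv <= thickness] <- "LV_FAST_LAYER"
    tag[d_rv <= thickness & d_rv < d_lv] <- "RV_FAST_LAYER"
  }
  mesh$element_tag <- factor(tag, levels = c("MYO", "LV_FAST_LAYER",
                                             "RV_FAST_LAYER"))
  mesh
}

#' @export
print.bv_mesh <- function(x, ...) {
  cat("bv_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets,",
      nrow(x$facets), "boundary facets\n")
  print(table(x$facet_label))
  print(table(x$element_tag))
  invisible(x)
}

element_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
     mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
}

# chunked BLAS nearest-facet-centroid distance (upper bound of the true
# surface distance; lower bound after subtracting the facet circumradius)
min_centroid_distance <- function(P, C, chunk = 4000) {
  out <- numeric(nrow(P))
  c2 <- rowSums(C * C)
  for (i0 in seq(1, nrow(P), chunk)) {
    idx <- i0:min(i0 + chunk - 1, nrow(P))
    Pi <- P[idx, , drop = FALSE]
    d2 <- outer(rowSums(Pi * Pi), c2, "+") - 2 * Pi %*% t(C)
    out[idx] <- sqrt(pmax(0, d2[cbind(seq_along(idx), max.col(-d2))]))
  }
  out
}

#' Distance from points to a labeled surface
#'
#' Minimum unsigned distance from each point to the union of boundary facets
#' carrying any of the given labels.
#'
#' @param points n x 3 matrix (mm).
#' @param mesh a `bv_mesh`.
#' @param labels character vector of facet labels.
#' @param limit optional cut-off (mm): exact distances are only guaranteed
#'   up to `limit`; beyond it an upper bound is returned (cheap screening).
#' @return numeric vector of distances (mm).
#' @export
surface_distance <- function(points, mesh, labels, limit = NULL) {
  sel <- mesh$facet_label %in% labels
  if (!any(sel)) return(rep(Inf, nrow(points)))
  f <- mesh$facets[sel, , drop = FALSE]
  V1 <- mesh$nodes[f[, 1], , drop = FALSE]
  V2 <- mesh$nodes[f[, 2], , drop = FALSE]
  V3 <- mesh$nodes[f[, 3], , drop = FALSE]
  if (is.null(limit)) {
    return(dist_points_to_triangles(points, V1, V2, V3))
  }
  fc <- (V1 + V2 + V3) / 3
  r_max <- sqrt(max(rowSums((V1 - fc)^2), rowSums((V2 - fc)^2),
                    rowSums((V3 - fc)^2)))
  ub <- min_centroid_distance(points, fc)
  out <- ub
  cand <- which(ub <= limit + r_max)
  if (length(cand)) {
    out[cand] <- dist_points_to_triangles(points[cand, , drop = FALSE],
                                          V1, V2, V3)
  }
  out
}

# signed volume contribution of oriented triangles
tri_signed_volume <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 2], , drop = FALSE]
  c_ <- nodes[tris[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c_))) / 6
}

# cap an open oriented surface: boundary edges traversed once get fanned
# from their centroid (reversed orientation closes the surface).
cap_triangles <- function(nodes, tris) {
  edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  key <- pmin(edges[, 1], edges[, 2]) * (max(edges) + 1) +
    pmax(edges[, 1], edges[, 2])
  bnd <- edges[!duplicated(key) & !duplicated(key, fromLast = TRUE), ,
               drop = FALSE]
  if (nrow(bnd) == 0) return(NULL)
  ring_nodes <- unique(as.vector(bnd))
  centroid <- colMeans(nodes[ring_nodes, , drop = FALSE])
  list(centroid = centroid, edges = bnd)
}

#' Chamber blood-pool volume
#'
#' Divergence-theorem volume of the chamber's endocardial surface, capped by
#' a planar fan at the base. Invariant to rigid motion and node ordering.
#'
#' @param mesh a `bv_mesh`.
#' @param chamber `"LV"` or `"RV"`.
#' @param cap_base close the open base with a planar fan (default TRUE). With
#'   `FALSE` the endocardial surface must already be closed.
#' @param displacement optional N x 3 nodal displacement added to the mesh
#'   nodes before measuring (used by the mechanics module).
#' @return volume in ml.
#' @export
chamber_volume <- function(mesh, chamber = c("LV", "RV"), cap_base = TRUE,
                           displacement = NULL) {
  chamber <- match.arg(chamber)
  labels <- if (chamber == "LV") c("LV_ENDO", "LV_SEPTUM") else
    c("RV_ENDO", "RV_SEPTUM")
  sel <- mesh$facet_label %in% labels
  if (!any(sel)) stop("no endocardial facets for chamber ", chamber)
  nodes <- mesh$nodes
  if (!is.null(displacement)) nodes <- nodes + displacement
  # outward-from-solid orientation points into the cavity; flip so the
  # cavity surface is oriented outward from the blood pool
  tris <- mesh$facets[sel, c(1, 3, 2), drop = FALSE]
  v <- tri_signed_volume(nodes, tris)
  cap <- cap_triangles(nodes, tris)
  if (is.null(cap)) {
    if (cap_base) return(abs(v) / 1000)
    return(abs(v) / 1000)
  }
  if (!cap_base) stop("endocardial surface of ", chamber,
                      " is open at the base; use cap_base = TRUE")
  nodes2 <- rbind(nodes, cap$centroid)
  ci <- nrow(nodes2)
  fan <- cbind(ci, cap$edges[, 2], cap$edges[, 1])
  v <- tri_signed_volume(nodes2, rbind(tris, fan))
  abs(v) / 1000
}

#' Mean RV free-wall thickness
#'
#' Mean distance from RV endocardial facet centroids to the epicardial
#' surface; a geometric check of the constant-thickness RV construction.
#'
#' @param mesh a `bv_mesh` with an RV.
#' @return mean distance in mm.
#' @export
rv_wall_distance <- function(mesh) {
  sel <- mesh$facet_label == "RV_ENDO"
  if (!any(sel)) stop("mesh has no RV")
  f <- mesh$facets[sel, , drop = FALSE]
  cent <- (mesh$nodes[f[, 1], ] + mesh$nodes[f[, 2], ] +
             mesh$nodes[f[, 3], ]) / 3
  mean(surface_distance(cent, mesh, "EPI"))
}
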