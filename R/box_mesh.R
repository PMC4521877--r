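# Structured box meshes for convergence, conduction-velocity and elasticity
# oracle tests. Same splitting rule as the anatomical generator, so the box
# behaves exactly like the heart mesh in the solvers.

#' Build a structured tetrahedral box mesh
#'
#' A rectangular slab meshed with the same conforming hex-to-tet splitting as
#' the bi-ventricular generator. Boundary facets are labeled XMIN, XMAX,
#' YMIN, YMAX, ZMIN, ZMAX. Useful as a test bed for plane-wave conduction
#' and uniaxial elasticity experiments.
#'
#' @param lengths c(Lx, Ly, Lz) in mm.
#' @param n c(nx, ny, nz) number of hex cells per direction.
#' @return a `bv_mesh`-classed object (no chambers; `element_region` = LV,
#'   `element_tag` = MYO, depth = normalized x).
#' @export
build_box_mesh <- function(lengths = c(60, 10, 10), n = c(30, 5, 5)) {
  stopifnot(length(lengths) == 3, length(n) == 3, all(lengths > 0), all(n >= 1))
  n <- as.integer(n)
  xs <- seq(0, lengths[1], length.out = n[1] + 1)
  ys <- seq(0, lengths[2], length.out = n[2] + 1)
  zs <- seq(0, lengths[3], length.out = n[3] + 1)
  idx <- function(i, j, k) i + (n[1] + 1L) * ((j - 1L) + (n[2] + 1L) * (k - 1L))
  grid <- expand.grid(x = xs, y = ys, z = zs)
  nodes <- as.matrix(grid)
  hexes <- matrix(0L, prod(n), 8)
  r <- 0L
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    r <- r + 1L
    hexes[r, ] <- c(idx(i, j, k), idx(i + 1L, j, k),
                    idx(i + 1L, j + 1L, k), idx(i, j + 1L, k),
                    idx(i, j, k + 1L), idx(i + 1L, j, k + 1L),
                    idx(i + 1L, j + 1L, k + 1L), idx(i, j + 1L, k + 1L))
  }
  ct <- cells_to_tets(nodes, hexes)
  nodes_all <- ct$nodes
  tets <- ct$tets
  bf <- boundary_facets_of(tets)
  facets <- orient_outward(nodes_all, bf$facets, bf$opposite)
  cent <- (nodes_all[facets[, 1], ] + nodes_all[facets[, 2], ] +
             nodes_all[facets[, 3], ]) / 3
  tol <- 1e-9 + 1e-9 * max(lengths)
  lab <- rep("EPI", nrow(facets))
  lab[abs(cent[, 1]) < tol] <- "XMIN"
  lab[abs(cent[, 1] - lengths[1]) < tol] <- "XMAX"
  lab[abs(cent[, 2]) < tol] <- "YMIN"
  lab[abs(cent[, 2] - lengths[2]) < tol] <- "YMAX"
  lab[abs(cent[, 3]) < tol] <- "ZMIN"
  lab[abs(cent[, 3] - lengths[3]) < tol] <- "ZMAX"
  nd <- nodes_all[, 1] / lengths[1]
  structure(list(
    nodes = nodes_all, tets = tets, facets = facets,
    facet_label = factor(lab, levels = c("XMIN", "XMAX", "YMIN", "YMAX",
                                         "ZMIN", "ZMAX", "EPI")),
    element_region = factor(rep("LV", nrow(tets)), levels = c("LV", "RV")),
    element_tag = factor(rep("MYO", nrow(tets)),
                         levels = c("MYO", "LV_FAST_LAYER", "RV_FAST_LAYER")),
    node_depth = nd,
    element_depth = rowMeans(matrix(nd[tets], ncol = 4)),
    long_axis = c(0, 0, 1), z_base = NA_real_,
    annuli = list(), config = list(lengths = lengths, n = n),
    seed = NA_integer_), class = "bv_mesh")
}

#' Nodes of a mesh lying on/near a labeled surface
#'
#' @param mesh a `bv_mesh`.
#' @param labels facet labels.
#' @return integer vector of node indices.
#' @export
surface_nodes <- function(mesh, labels) {
  sel <- mesh$facet_label %in% labels
  sort(unique(as.vector(mesh$facets[sel, , drop = FALSE])))
}
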