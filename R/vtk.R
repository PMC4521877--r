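# Minimal legacy-ASCII VTK unstructured-grid writer/reader covering what the
# package emits: tetrahedral cells, scalar/vector cell data (tags, fibers,
# depth) and scalar point data (potentials, activation maps). No installed R
# package reads/writes VTK, hence the small hand-rolled dialect.

#' Write a mesh (with optional data arrays) to a legacy VTK file
#'
#' @param mesh a `bv_mesh`.
#' @param path output file (conventionally `.vtk`).
#' @param cell_data named list of per-element vectors (numeric or factor) or
#'   M x 3 matrices (written as VECTORS).
#' @param point_data named list of per-node numeric vectors.
#' @export
write_vtk_mesh <- function(mesh, path, cell_data = NULL, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0",
               "cardiotwin mesh (units: mm)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  write(t(mesh$nodes), con, ncolumns = 3)
  writeLines(paste("CELLS", m, 5 * m), con)
  write(t(cbind(4L, mesh$tets - 1L)), con, ncolumns = 5)
  writeLines(paste("CELL_TYPES", m), con)
  write(rep(10L, m), con, ncolumns = 20)
  cd <- cell_data %||% list()
  if (is.null(cd$tag) && !is.null(mesh$element_tag)) {
    cd$tag <- as.integer(mesh$element_tag)
  }
  if (length(cd)) {
    writeLines(paste("CELL_DATA", m), con)
    write_vtk_arrays(con, cd, m)
  }
  pd <- point_data %||% list()
  if (is.null(pd$transmural_depth) && !is.null(mesh$node_depth)) {
    pd$transmural_depth <- mesh$node_depth
  }
  if (length(pd)) {
    writeLines(paste("POINT_DATA", n), con)
    write_vtk_arrays(con, pd, n)
  }
  invisible(path)
}

write_vtk_arrays <- function(con, arrays, n_expected) {
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    if (is.factor(a)) a <- as.integer(a)
    if (is.matrix(a)) {
      stopifnot(nrow(a) == n_expected, ncol(a) == 3)
      writeLines(paste("VECTORS", nm, "double"), con)
      write(t(a), con, ncolumns = 3)
    } else {
      stopifnot(length(a) == n_expected)
      writeLines(c(paste("SCALARS", nm, "double", 1),
                   "LOOKUP_TABLE default"), con)
      write(a, con, ncolumns = 9)
    }
  }
}

#' Read a legacy VTK unstructured grid written by [write_vtk_mesh()]
#'
#' @param path VTK file.
#' @return list with `nodes`, `tets`, `cell_data`, `point_data`.
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  toks <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  i_pts <- grep("^POINTS", lines)[1]
  n <- as.integer(toks(i_pts)[2])
  num <- function(from, count) {
    vals <- numeric(0)
    i <- from
    while (length(vals) < count) {
      vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      i <- i + 1
    }
    list(values = vals[seq_len(count)], next_line = i)
  }
  pts <- num(i_pts + 1, 3 * n)
  nodes <- matrix(pts$values, ncol = 3, byrow = TRUE)
  i_cells <- grep("^CELLS", lines)[1]
  m <- as.integer(toks(i_cells)[2])
  cl <- num(i_cells + 1, 5 * m)
  cells <- matrix(as.integer(cl$values), ncol = 5, byrow = TRUE)
  stopifnot(all(cells[, 1] == 4))
  tets <- cells[, 2:5, drop = FALSE] + 1L
  read_arrays <- function(start_idx, count) {
    out <- list()
    i <- start_idx
    while (i <= length(lines)) {
      tk <- toks(i)
      if (length(tk) == 0) { i <- i + 1; next }
      if (tk[1] %in% c("CELL_DATA", "POINT_DATA")) break
      if (tk[1] == "SCALARS") {
        r <- num(i + 2, count)
        out[[tk[2]]] <- r$values
        i <- r$next_line
      } else if (tk[1] == "VECTORS") {
        r <- num(i + 1, 3 * count)
        out[[tk[2]]] <- matrix(r$values, ncol = 3, byrow = TRUE)
        i <- r$next_line
      } else i <- i + 1
    }
    out
  }
  cd <- list(); pd <- list()
  i_cd <- grep("^CELL_DATA", lines)
  if (length(i_cd)) cd <- read_arrays(i_cd[1] + 1, m)
  i_pd <- grep("^POINT_DATA", lines)
  if (length(i_pd)) pd <- read_arrays(i_pd[1] + 1, n)
  list(nodes = nodes, tets = tets, cell_data = cd, point_data = pd)
}
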