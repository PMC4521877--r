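# Linear (P1) tetrahedral finite-element helpers shared by the transmural
# Laplace problem and the monodomain solver.

# Shape-function gradients and volumes for all tets at once.
# Returns list(vol = M vector, g = list of four M x 3 gradient matrices).
p1_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c_ <- nodes[tets[, 4], , drop = FALSE] - p1
  bxc <- cross3(b, c_)
  det <- rowSums(a * bxc)
  if (any(det <= 0)) {
    stop("degenerate or inverted tetrahedra: ", sum(det <= 0), " elements")
  }
  g2 <- bxc / det
  g3 <- cross3(c_, a) / det
  g4 <- cross3(a, b) / det
  g1 <- -(g2 + g3 + g4)
  list(vol = det / 6, g = list(g1, g2, g3, g4))
}

# Stiffness matrix for scalar diffusion. `tensors`: NULL for isotropic unit
# diffusivity, or an M x 9 matrix of row-major 3x3 symmetric tensors.
fem_stiffness <- function(nodes, tets, tensors = NULL) {
  pg <- p1_gradients(nodes, tets)
  vol <- pg$vol; g <- pg$g
  n <- nrow(nodes)
  ii <- jj <- xx <- vector("list", 16)
  k <- 1
  for (i in 1:4) {
    gi <- g[[i]]
    Dgi <- if (is.null(tensors)) gi else
      cbind(tensors[, 1] * gi[, 1] + tensors[, 2] * gi[, 2] + tensors[, 3] * gi[, 3],
            tensors[, 4] * gi[, 1] + tensors[, 5] * gi[, 2] + tensors[, 6] * gi[, 3],
            tensors[, 7] * gi[, 1] + tensors[, 8] * gi[, 2] + tensors[, 9] * gi[, 3])
    for (j in 1:4) {
      ii[[k]] <- tets[, i]
      jj[[k]] <- tets[, j]
      xx[[k]] <- vol * rowSums(Dgi * g[[j]])
      k <- k + 1
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# Lumped mass vector (row-sum lumping of the P1 mass matrix).
fem_lumped_mass <- function(nodes, tets) {
  pg <- p1_gradients(nodes, tets)
  m <- numeric(nrow(nodes))
  for (i in 1:4) {
    acc <- tapply(pg$vol / 4, tets[, i], sum)
    m[as.integer(names(acc))] <- m[as.integer(names(acc))] + as.numeric(acc)
  }
  m
}

# Solve Laplace's equation with Dirichlet data: values fixed where
# `fixed` is not NA. Returns the full solution vector.
fem_laplace <- function(nodes, tets, fixed) {
  K <- fem_stiffness(nodes, tets)
  free <- which(is.na(fixed))
  u <- fixed
  if (length(free) == 0) return(u)
  ub <- fixed
  ub[is.na(ub)] <- 0
  rhs <- -(K %*% ub)[free]
  u[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE], rhs))
  u
}
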