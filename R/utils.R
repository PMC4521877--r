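#' @keywords internal
"_PACKAGE"

#' @useDynLib cardiotwin, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim optimize pt qt runif rnorm qnorm pnorm sd uniroot
#'   complete.cases cor lm coef approx quantile
#' @importFrom utils write.csv read.csv modifyList head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(x) sqrt(rowSums(x * x))

normalize_rows <- function(x) {
  n <- vnorm(x)
  n[n < .Machine$double.eps] <- 1
  x / n
}

cross3 <- function(a, b) {
  # row-wise cross product of n x 3 matrices
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Rotation matrix aligning one vector with another
#'
#' Returns the rotation that maps unit vector `a` onto unit vector `b`
#' (Rodrigues construction), used to place the heart inside the torso.
#'
#' @param a,b numeric length-3 vectors (need not be unit length).
#' @return 3x3 rotation matrix `R` with `R %*% a` parallel to `b`.
#' @export
rotation_align <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {
    # opposite vectors: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- axis - sum(axis * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# unsigned distance from points P (n x 3) to a set of triangles
# (Ericson's closest-point-on-triangle, vectorised over points per triangle)
dist_points_to_triangles <- function(P, V1, V2, V3) {
  n <- nrow(P)
  best <- rep(Inf, n)
  for (t in seq_len(nrow(V1))) {
    A <- V1[t, ]; B <- V2[t, ]; C <- V3[t, ]
    ab <- B - A; ac <- C - A; bc <- C - B
    ap <- sweep(P, 2, A)
    d1 <- ap %*% ab; d2 <- ap %*% ac
    bp <- sweep(P, 2, B)
    d3 <- bp %*% ab; d4 <- bp %*% ac
    cp <- sweep(P, 2, C)
    d5 <- cp %*% ab; d6 <- cp %*% ac
    va <- d3 * d6 - d5 * d4
    vb <- d5 * d2 - d1 * d6
    vc <- d1 * d4 - d3 * d2
    # interior projection by default
    denom <- va + vb + vc
    denom[abs(denom) < .Machine$double.eps] <- .Machine$double.eps
    v <- vb / denom; w <- vc / denom
    CXx <- A[1] + ab[1] * v + ac[1] * w
    CXy <- A[2] + ab[2] * v + ac[2] * w
    CXz <- A[3] + ab[3] * v + ac[3] * w
    set_pt <- function(mask, px, py, pz) {
      CXx[mask] <<- px[mask]; CXy[mask] <<- py[mask]; CXz[mask] <<- pz[mask]
    }
    # edge BC
    tBC <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), .Machine$double.eps)
    tBC <- pmin(pmax(tBC, 0), 1)
    m <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
    set_pt(m, B[1] + bc[1] * tBC, B[2] + bc[2] * tBC, B[3] + bc[3] * tBC)
    # edge AC
    tAC <- d2 / pmax(d2 - d6, .Machine$double.eps)
    tAC <- pmin(pmax(tAC, 0), 1)
    m <- vb <= 0 & d2 >= 0 & d6 <= 0
    set_pt(m, A[1] + ac[1] * tAC, A[2] + ac[2] * tAC, A[3] + ac[3] * tAC)
    # edge AB
    tAB <- d1 / pmax(d1 - d3, .Machine$double.eps)
    tAB <- pmin(pmax(tAB, 0), 1)
    m <- vc <= 0 & d1 >= 0 & d3 <= 0
    set_pt(m, A[1] + ab[1] * tAB, A[2] + ab[2] * tAB, A[3] + ab[3] * tAB)
    # vertices
    m <- d1 <= 0 & d2 <= 0
    set_pt(m, rep(A[1], n), rep(A[2], n), rep(A[3], n))
    m <- d3 >= 0 & d4 <= d3
    set_pt(m, rep(B[1], n), rep(B[2], n), rep(B[3], n))
    m <- d6 >= 0 & d5 <= d6
    set_pt(m, rep(C[1], n), rep(C[2], n), rep(C[3], n))
    d <- sqrt((P[, 1] - CXx)^2 + (P[, 2] - CXy)^2 + (P[, 3] - CXz)^2)
    best <- pmin(best, d)
  }
  best
}
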