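# Rotation-matrix utilities used by the strapdown orientation integration and
# the gait simulator. Batch forms operate on 3x3xN arrays so that per-sample
# work stays vectorised; only the sequential orientation product is a loop.

#' Standard gravity used throughout the package (m/s^2)
#' @export
GRAVITY <- 9.81

#' Skew-symmetric (cross-product) matrix of a 3-vector
#'
#' Returns the matrix form of the angular-velocity cross product, i.e.
#' `skew_matrix(w) %*% v == cross(w, v)`.
#'
#' @param v numeric 3-vector
#' @return 3x3 skew-symmetric matrix
#' @export
skew_matrix <- function(v) {
  stopifnot(length(v) == 3)
  rbind(
    c(0, -v[3], v[2]),
    c(v[3], 0, -v[1]),
    c(-v[2], v[1], 0)
  )
}

#' Rotation matrix from a rotation vector (axis * angle), Rodrigues form
#' @param v numeric 3-vector, radians
#' @return 3x3 rotation matrix
#' @export
rotvec_to_rot <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-14) return(diag(3))
  k <- v / th
  K <- skew_matrix(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation vector (axis * angle) from a rotation matrix
#' @param R 3x3 rotation matrix
#' @return numeric 3-vector, radians, angle in [0, pi]
#' @export
rot_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (th < 1e-7) return(v / 2)
  if (th > pi - 1e-6) {
    # near half-turn: axis from the symmetric part
    A <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(A), 0))
    i <- which.max(ax)
    axis <- A[, i] / ax[i]
    axis <- axis / sqrt(sum(axis^2))
    # fix sign using the skew part where it is informative
    if (sum(abs(v)) > 1e-12 && sum(axis * v) < 0) axis <- -axis
    return(axis * th)
  }
  v / (2 * sin(th)) * th
}

#' Batch Rodrigues: rotation matrices from N rotation vectors
#' @param V N x 3 matrix of rotation vectors (radians)
#' @return 3 x 3 x N array of rotation matrices
#' @export
rotvec_to_rot_batch <- function(V) {
  V <- rbind(V)
  n <- nrow(V)
  th <- sqrt(rowSums(V^2))
  small <- th < 1e-14
  thsafe <- ifelse(small, 1, th)
  kx <- V[, 1] / thsafe
  ky <- V[, 2] / thsafe
  kz <- V[, 3] / thsafe
  s <- sin(th)
  c1 <- 1 - cos(th)
  out <- array(0, dim = c(3, 3, n))
  out[1, 1, ] <- 1 + c1 * (kx * kx - 1)
  out[1, 2, ] <- c1 * kx * ky - s * kz
  out[1, 3, ] <- c1 * kx * kz + s * ky
  out[2, 1, ] <- c1 * kx * ky + s * kz
  out[2, 2, ] <- 1 + c1 * (ky * ky - 1)
  out[2, 3, ] <- c1 * ky * kz - s * kx
  out[3, 1, ] <- c1 * kx * kz - s * ky
  out[3, 2, ] <- c1 * ky * kz + s * kx
  out[3, 3, ] <- 1 + c1 * (kz * kz - 1)
  if (any(small)) out[, , small] <- diag(3)
  out
}

#' Batch rotation-vector extraction (inverse of [rotvec_to_rot_batch()])
#'
#' Vectorised for angles away from pi; the rare near-pi samples fall back to
#' the scalar routine.
#'
#' @param Rarr 3 x 3 x N array of rotation matrices
#' @return N x 3 matrix of rotation vectors
#' @export
rot_to_rotvec_batch <- function(Rarr) {
  n <- dim(Rarr)[3]
  tr <- Rarr[1, 1, ] + Rarr[2, 2, ] + Rarr[3, 3, ]
  ct <- pmin(1, pmax(-1, (tr - 1) / 2))
  th <- acos(ct)
  vx <- Rarr[3, 2, ] - Rarr[2, 3, ]
  vy <- Rarr[1, 3, ] - Rarr[3, 1, ]
  vz <- Rarr[2, 1, ] - Rarr[1, 2, ]
  fac <- ifelse(th < 1e-7, 0.5, th / (2 * sin(th)))
  out <- cbind(vx * fac, vy * fac, vz * fac)
  near_pi <- which(th > pi - 1e-6)
  for (i in near_pi) out[i, ] <- rot_to_rotvec(Rarr[, , i])
  out
}

#' Batch matrix product of rotation arrays
#'
#' Either argument may be a single 3x3 matrix, which is recycled.
#'
#' @param A,B 3 x 3 x N arrays (or 3x3 matrices)
#' @return 3 x 3 x N array with `C[,,k] = A[,,k] %*% B[,,k]`
#' @export
rot_batch_multiply <- function(A, B) {
  if (length(dim(A)) == 2 && length(dim(B)) == 2) {
    return(array(A %*% B, dim = c(3, 3, 1)))
  }
  n <- if (length(dim(A)) == 3) dim(A)[3] else dim(B)[3]
  if (length(dim(A)) == 2) A <- array(A, dim = c(3, 3, n))
  if (length(dim(B)) == 2) B <- array(B, dim = c(3, 3, n))
  out <- array(0, dim = c(3, 3, n))
  for (i in 1:3) {
    for (j in 1:3) {
      out[i, j, ] <- A[i, 1, ] * B[1, j, ] + A[i, 2, ] * B[2, j, ] +
        A[i, 3, ] * B[3, j, ]
    }
  }
  out
}

#' Transpose every rotation in a batch
#' @param A 3 x 3 x N array
#' @return 3 x 3 x N array of transposes
#' @export
rot_batch_transpose <- function(A) aperm(A, c(2, 1, 3))

#' Apply per-sample rotations to per-sample vectors
#' @param Rarr 3 x 3 x N array (or single 3x3 matrix)
#' @param V N x 3 matrix of vectors
#' @param transpose logical; apply `t(R)` instead of `R`
#' @return N x 3 matrix with row k equal to `R[,,k] %*% V[k,]`
#' @export
rot_batch_apply <- function(Rarr, V, transpose = FALSE) {
  V <- rbind(V)
  n <- nrow(V)
  if (length(dim(Rarr)) == 2) {
    R <- if (transpose) t(Rarr) else Rarr
    return(V %*% t(R))
  }
  if (transpose) Rarr <- rot_batch_transpose(Rarr)
  out <- matrix(0, n, 3)
  for (i in 1:3) {
    out[, i] <- Rarr[i, 1, ] * V[, 1] + Rarr[i, 2, ] * V[, 2] +
      Rarr[i, 3, ] * V[, 3]
  }
  out
}

#' Shortest-arc rotation taking vector `a` onto the direction of `b`
#'
#' @param a,b numeric 3-vectors (non-zero)
#' @return 3x3 rotation matrix R with `R %*% a` parallel to `b`
#' @export
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    # opposite vectors: rotate pi about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- c(a[2] * ref[3] - a[3] * ref[2],
              a[3] * ref[1] - a[1] * ref[3],
              a[1] * ref[2] - a[2] * ref[1])
    axis <- axis / sqrt(sum(axis^2))
    return(rotvec_to_rot(axis * pi))
  }
  axis <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(axis^2))
  rotvec_to_rot(axis / s * atan2(s, d))
}

#' Rotation about the vertical (z) axis
#' @param theta angle, radians; positive rotates x towards y
#' @return 3x3 rotation matrix
#' @export
rot_z <- function(theta) {
  ct <- cos(theta)
  st <- sin(theta)
  rbind(c(ct, -st, 0), c(st, ct, 0), c(0, 0, 1))
}

#' Check orthonormality of a rotation matrix
#' @param R 3x3 matrix
#' @param tol tolerance on `max|R'R - I|` and `det(R) - 1`
#' @return logical
#' @export
is_rotation <- function(R, tol = 1e-9) {
  all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

#' Re-orthonormalise a nearly-orthonormal matrix (polar projection via SVD)
#' @param R 3x3 matrix close to a rotation
#' @return nearest 3x3 rotation matrix
#' @export
orthonormalize <- function(R) {
  s <- svd(R)
  U <- s$u %*% t(s$v)
  if (det(U) < 0) {
    s$v[, 3] <- -s$v[, 3]
    U <- s$u %*% t(s$v)
  }
  U
}

#' Uniformly distributed random rotation matrix
#'
#' Draws a unit quaternion from an isotropic Gaussian (uniform on SO(3)).
#' Uses the current RNG state.
#'
#' @return 3x3 rotation matrix
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
}

# circular median of angles (radians): minimises summed angular distance;
# evaluated at the sample angles themselves
circular_median <- function(theta) {
  if (length(theta) == 1) return(theta)
  cost <- vapply(theta, function(t0) {
    d <- atan2(sin(theta - t0), cos(theta - t0))
    sum(abs(d))
  }, numeric(1))
  theta[which.min(cost)]
}
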