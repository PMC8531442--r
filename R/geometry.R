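## Small 3D geometry kernel shared by all modules.  Everything works on plain
## numeric vectors/matrices in SI units (m, rad); no external dependencies.

#' Cross product of two 3-vectors
#' @param a,b numeric 3-vectors
#' @return numeric 3-vector
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

norm3 <- function(a) sqrt(sum(a * a))

unit3 <- function(a) {
  n <- norm3(a)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  a / n
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @param a numeric 3-vector
#' @keywords internal
skew3 <- function(a) {
  matrix(c(0, a[3L], -a[2L],
           -a[3L], 0, a[1L],
           a[2L], -a[1L], 0), 3L, 3L)
}

unskew3 <- function(S) c(S[3L, 2L], S[1L, 3L], S[2L, 1L])

## Elementary rotations (right-handed, about fixed axis of the current frame).
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L, 3L)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3L, 3L)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L)
}

#' Rodrigues rotation about a unit axis
#' @param axis unit 3-vector
#' @param angle rotation angle [rad]
#' @keywords internal
rot_axis <- function(axis, angle) {
  axis <- unit3(axis)
  K <- skew3(axis)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Intrinsic Euler rotation for a letter sequence such as "zyx"
#' @param seq character scalar, letters from x/y/z
#' @param angles numeric vector of the same length [rad]
#' @keywords internal
rot_seq <- function(seq, angles) {
  letters_ <- strsplit(seq, "")[[1L]]
  stopifnot(length(letters_) == length(angles))
  R <- diag(3L)
  for (i in seq_along(letters_)) {
    R <- R %*% switch(letters_[i],
                      x = rot_x(angles[i]),
                      y = rot_y(angles[i]),
                      z = rot_z(angles[i]),
                      stop("unknown axis letter: ", letters_[i]))
  }
  R
}

#' Extract intrinsic Euler angles from a rotation matrix
#'
#' Supports the three-letter sequences with distinct consecutive axes that the
#' joint parameterization allows ("zyx", "xyz", "yzx", ...).  Returns the
#' solution with middle angle in (-pi/2, pi/2).
#' @param R 3x3 rotation matrix
#' @param seq character scalar such as "zyx"
#' @keywords internal
euler_from_R <- function(R, seq = "zyx") {
  ## generic Tait-Bryan extraction via axis indices
  idx <- match(strsplit(seq, "")[[1L]], c("x", "y", "z"))
  i <- idx[1L]; j <- idx[2L]; k <- idx[3L]
  ## parity of the permutation (i,j,k)
  eps <- if (identical(sort(idx), 1:3) &&
             ((i == 1 && j == 2) || (i == 2 && j == 3) || (i == 3 && j == 1)))
    1 else -1
  if (anyDuplicated(idx)) stop("only Tait-Bryan (distinct-axis) sequences supported")
  s2 <- eps * R[i, k]
  s2 <- max(-1, min(1, s2))
  a2 <- asin(s2)
  if (abs(s2) > 1 - 1e-10) {
    ## gimbal: split arbitrarily, keep third angle zero
    a1 <- atan2(eps * R[j, (6L - i - k)], R[j, j])
    a3 <- 0
  } else {
    a1 <- atan2(-eps * R[j, k], R[k, k])
    a3 <- atan2(-eps * R[i, j], R[i, i])
  }
  c(a1, a2, a3)
}

#' Check that a matrix is a proper rotation
#' @param R 3x3 matrix
#' @param tol tolerance on orthonormality and determinant
#' @keywords internal
is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3L))) < tol && abs(det(R) - 1) < tol
}

## Minimum-jerk scalar profile on [0, 1]: position, velocity, acceleration.
minimum_jerk <- function(s) {
  list(x = 10 * s^3 - 15 * s^4 + 6 * s^5,
       v = 30 * s^2 - 60 * s^3 + 30 * s^4,
       a = 60 * s - 180 * s^2 + 120 * s^3)
}
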