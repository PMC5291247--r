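#' Rigid-body transforms
#'
#' A `spindock_transform` is a proper rigid motion: a 3x3 rotation matrix
#' `R` (orthonormal, det +1) and a translation 3-vector `t` in Angstrom.
#' Applied to a point `p` it yields `R %*% p + t`.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric 3-vector, Angstrom.
#' @param tol orthonormality tolerance.
#' @return An object of class `spindock_transform`.
#' @export
new_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                          tol = 1e-8) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (!is_rotation(rotation, tol = tol))
    stop("rotation matrix is not orthonormal with determinant +1")
  structure(list(R = rotation, t = translation), class = "spindock_transform")
}

#' @export
print.spindock_transform <- function(x, ...) {
  cat("<rigid transform>\n")
  cat("rotation:\n"); print(round(x$R, 6))
  cat("translation (A):", paste(signif(x$t, 6), collapse = " "), "\n")
  invisible(x)
}

#' Test a matrix for being a proper rotation
#' @param R matrix.
#' @param tol tolerance on orthonormality and determinant.
#' @return logical.
#' @export
is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Identity transform
#' @return identity `spindock_transform`.
#' @export
identity_transform <- function() new_transform()

#' Compose two transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#' @param a,b `spindock_transform` objects.
#' @return `spindock_transform`.
#' @export
compose_transforms <- function(a, b) {
  new_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)
}

#' Invert a transform
#' @param x `spindock_transform`.
#' @return the inverse `spindock_transform`.
#' @export
invert_transform <- function(x) {
  Rt <- t(x$R)
  new_transform(Rt, -as.vector(Rt %*% x$t))
}

#' Apply a transform to a coordinate matrix
#' @param x `spindock_transform`.
#' @param xyz n x 3 numeric matrix of positions (Angstrom).
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(x, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  sweep(xyz %*% t(x$R), 2L, x$t, "+")
}

#' Rotation about a coordinate axis
#' @param axis "x", "y" or "z".
#' @param angle radians.
#' @return `spindock_transform` (pure rotation).
#' @export
axis_rotation <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  R <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, c1, -s1), c(0, s1, c1)),
    y = rbind(c(c1, 0, s1), c(0, 1, 0), c(-s1, 0, c1)),
    z = rbind(c(c1, -s1, 0), c(s1, c1, 0), c(0, 0, 1)))
  new_transform(R)
}

#' Exponential map: rotation vector to rotation matrix
#'
#' Rodrigues formula; `w` is an axis-angle vector whose norm is the rotation
#' angle in radians. Singularity-free near zero (series expansion).
#' @param w numeric 3-vector.
#' @return 3x3 rotation matrix.
#' @export
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  K <- rbind(c(0, -w[3], w[2]), c(w[3], 0, -w[1]), c(-w[2], w[1], 0))
  if (th < 1e-8) {
    # second-order series keeps orthonormality to ~1e-16 at small angles
    R <- diag(3) + K + 0.5 * (K %*% K)
  } else {
    R <- diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * (K %*% K)
  }
  # project to the closest rotation to cancel accumulated round-off
  s <- svd(R)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Sample a rotation uniformly on SO(3)
#'
#' Draws a random unit quaternion (4 i.i.d. standard normals, normalized) and
#' converts it to a rotation matrix; this is exactly uniform with respect to
#' Haar measure. Uses R's global RNG stream, so `set.seed()` makes the draw
#' reproducible.
#' @return `spindock_transform` with zero translation.
#' @export
sample_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  new_transform(quaternion_to_matrix(q))
}

quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Rotation angle of a transform
#' @param x `spindock_transform` or rotation matrix.
#' @return angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(x) {
  R <- if (inherits(x, "spindock_transform")) x$R else x
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rigid transform minimizing the RMSD between paired point
#' sets. Reflections are excluded by the usual sign correction on the
#' smallest singular value.
#'
#' @param mobile,reference n x 3 matrices of paired coordinates (n >= 3).
#' @return list with `transform` (maps mobile onto reference) and `rmsd`
#'   (Angstrom, after the fit).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have identical dimensions")
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 points are required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2L, cm); Y <- sweep(reference, 2L, cr)
  # collinearity check: rank of the centred mobile set
  sv <- svd(X)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    warning("degenerate (collinear) point configuration; rotation about the line is undetermined")
  H <- crossprod(X, Y)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- cr - as.vector(R %*% cm)
  tr <- new_transform(R, tvec)
  fitted <- apply_transform(tr, mobile)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(transform = tr, rmsd = rmsd)
}

#' RMSD between paired coordinate sets (no fitting)
#' @param a,b n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}
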