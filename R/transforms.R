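#' Rigid-body transforms
#'
#' A `dr_transform` is a proper rigid-body motion `y = R x + t` with a 3x3
#' rotation matrix `R` (det = +1) and a translation 3-vector `t` in Angstrom.
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @param translation numeric 3-vector, Angstrom.
#' @return An object of class `dr_transform`.
#' @export
transform_new <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation matrix must be proper (det = +1)")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation matrix must be orthonormal")
  structure(list(rotation = rotation, translation = translation),
            class = "dr_transform")
}

#' Identity transform
#' @return A `dr_transform` leaving coordinates unchanged.
#' @export
transform_identity <- function() transform_new()

#' Apply a rigid transform to coordinates
#'
#' @param tr A `dr_transform`.
#' @param xyz Numeric n x 3 matrix of coordinates (or length-3 vector).
#' @return Transformed coordinates, same shape as input.
#' @export
transform_apply <- function(tr, xyz) {
  vec <- is.null(dim(xyz))
  if (vec) xyz <- matrix(xyz, 1, 3)
  out <- xyz %*% t(tr$rotation)
  out[, 1] <- out[, 1] + tr$translation[1]
  out[, 2] <- out[, 2] + tr$translation[2]
  out[, 3] <- out[, 3] + tr$translation[3]
  if (vec) out[1, ] else out
}

#' Compose two transforms
#'
#' `transform_apply(transform_compose(t2, t1), x)` equals
#' `transform_apply(t2, transform_apply(t1, x))`.
#'
#' @param t2,t1 `dr_transform` objects; `t1` is applied first.
#' @return The composed `dr_transform`.
#' @export
transform_compose <- function(t2, t1) {
  transform_new(t2$rotation %*% t1$rotation,
                as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a transform
#' @param tr A `dr_transform`.
#' @return The inverse `dr_transform`.
#' @export
transform_invert <- function(tr) {
  rt <- t(tr$rotation)
  transform_new(rt, -as.numeric(rt %*% tr$translation))
}

#' Rotation matrix from axis and angle
#' @param axis numeric 3-vector (need not be unit length).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rigid transform rotating about a fixed center
#'
#' Rotation about `center` by `angle` around `axis`, then translation.
#' @param axis,angle axis (3-vector) and angle (radians) of rotation.
#' @param center point the rotation pivots about, Angstrom.
#' @param translation additional translation applied after the rotation.
#' @return A `dr_transform`.
#' @export
transform_about_center <- function(axis, angle, center, translation = c(0, 0, 0)) {
  R <- rotation_axis_angle(axis, angle)
  transform_new(R, as.numeric(center - R %*% center) + translation)
}

#' @export
print.dr_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<dr_transform> rotation %.2f deg, translation (%.2f, %.2f, %.2f) A\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# r.m.s. coordinate difference between two transforms applied to a CA set
transform_rms_difference <- function(t1, t2, xyz) {
  d <- transform_apply(t1, xyz) - transform_apply(t2, xyz)
  sqrt(mean(rowSums(d^2)))
}
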