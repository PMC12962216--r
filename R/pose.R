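#' Reduced gyromagnetic ratio of the proton
#'
#' Single authoritative constant used by every field-to-phase conversion in
#' the package, in Hz/T.
#'
#' @format Numeric scalar, 42.5774e6 Hz/T.
#' @export
GAMMA_BAR <- 42.5774e6

#' Rigid-body pose
#'
#' A 6-DoF rigid-body state of the object relative to the reference frame:
#' three rotation angles in degrees about the fixed device axes X, Y, Z and
#' three translations in mm along X, Y, Z. Rotations are extrinsic, applied
#' in the order X, then Y, then Z, about the iso-center (the phantom and
#' trajectory origin). At the sub-2-degree scale relevant here the ordering
#' is a second-order effect, but the convention is fixed throughout.
#'
#' @param rx,ry,rz Rotation angles in degrees about device X, Y, Z.
#' @param tx,ty,tz Translations in mm along device X, Y, Z.
#' @return An object of class `"pose"`: a named numeric vector of length 6.
#' @examples
#' p <- pose(rx = 1, tz = -2.3)
#' compose_pose(p, inverse_pose(p))  # identity
#' @export
pose <- function(rx = 0, ry = 0, rz = 0, tx = 0, ty = 0, tz = 0) {
  p <- c(rx = rx, ry = ry, rz = rz, tx = tx, ty = ty, tz = tz)
  if (!all(is.finite(p))) stop("pose entries must be finite")
  structure(p, class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose: rot (deg) [%.4g %.4g %.4g]  trans (mm) [%.4g %.4g %.4g]\n",
              x[1], x[2], x[3], x[4], x[5], x[6]))
  invisible(x)
}

as_pose <- function(x) {
  if (inherits(x, "pose")) return(x)
  stopifnot(length(x) == 6)
  pose(x[1], x[2], x[3], x[4], x[5], x[6])
}

rot_axis <- function(angle_deg, axis) {
  a <- angle_deg * pi / 180
  c1 <- cos(a); s1 <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3),
    y = matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3),
    z = matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3))
}

#' Rotation matrix of a pose
#'
#' Extrinsic X-Y-Z convention: `R = Rz %*% Ry %*% Rx` so that the X rotation
#' is applied first about the fixed device frame.
#'
#' @param p A [pose()].
#' @return A 3x3 rotation matrix.
#' @export
pose_rotation <- function(p) {
  p <- as_pose(p)
  rot_axis(p[3], "z") %*% rot_axis(p[2], "y") %*% rot_axis(p[1], "x")
}

# Extract extrinsic X-Y-Z angles (deg) from a rotation matrix.
# R = Rz(rz) Ry(ry) Rx(rx); R[3,1] = -sin(ry).
angles_from_rotation <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(sy) < 1 - 1e-12) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal degenerate (|ry| = 90 deg) - not reachable in the servo regime
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Compose two poses
#'
#' Returns the pose equivalent to applying `b` first, then `a`: rotation
#' matrices are multiplied (`Ra Rb`) and translations composed as
#' `Ra tb + ta` (poses act on points as `x -> R x + t`).
#'
#' @param a,b [pose()] objects.
#' @return A [pose()].
#' @export
compose_pose <- function(a, b) {
  a <- as_pose(a); b <- as_pose(b)
  R <- pose_rotation(a) %*% pose_rotation(b)
  t <- pose_rotation(a) %*% b[4:6] + a[4:6]
  ang <- angles_from_rotation(R)
  pose(ang[1], ang[2], ang[3], t[1], t[2], t[3])
}

#' Invert a pose
#'
#' @param p A [pose()].
#' @return The pose `q` with `compose_pose(p, q)` equal to the identity.
#' @export
inverse_pose <- function(p) {
  p <- as_pose(p)
  R <- t(pose_rotation(p))
  t <- -R %*% p[4:6]
  ang <- angles_from_rotation(R)
  pose(ang[1], ang[2], ang[3], t[1], t[2], t[3])
}

#' Zeroth- and first-order field state
#'
#' @param phi0 Phase offset in radians.
#' @param f0 Frequency offset in Hz.
#' @param gx,gy,gz Gradient (linear shim) offsets in uT/m, device XYZ.
#' @return An object of class `"field_state"`: named numeric vector, length 5.
#' @export
field_state <- function(phi0 = 0, f0 = 0, gx = 0, gy = 0, gz = 0) {
  f <- c(phi0 = phi0, f0 = f0, gx = gx, gy = gy, gz = gz)
  if (!all(is.finite(f))) stop("field state entries must be finite")
  structure(f, class = "field_state")
}

as_field_state <- function(x) {
  if (inherits(x, "field_state")) return(x)
  stopifnot(length(x) == 5)
  field_state(x[1], x[2], x[3], x[4], x[5])
}

#' The 11-parameter servo vector
#'
#' Ordered as `[rx, ry, rz, tx, ty, tz, phi0, f0, gx, gy, gz]` with units
#' (deg, deg, deg, mm, mm, mm, rad, Hz, uT/m, uT/m, uT/m). Splits losslessly
#' into a [pose()] and a [field_state()].
#'
#' @param p A [pose()] (or 6 numbers).
#' @param f A [field_state()] (or 5 numbers).
#' @return Named numeric vector of length 11, class `"param_vector"`.
#' @export
param_vector <- function(p = pose(), f = field_state()) {
  p <- as_pose(p); f <- as_field_state(f)
  structure(c(unclass(p), unclass(f)), class = "param_vector")
}

#' @rdname param_vector
#' @param x Numeric vector of length 11 in parameter order.
#' @export
as_param_vector <- function(x) {
  if (inherits(x, "param_vector")) return(x)
  stopifnot(length(x) == 11)
  structure(stats::setNames(as.numeric(x), param_names()),
            class = "param_vector")
}

#' @rdname param_vector
#' @export
param_names <- function() {
  c("rx", "ry", "rz", "tx", "ty", "tz", "phi0", "f0", "gx", "gy", "gz")
}

#' @rdname param_vector
#' @param v A `param_vector`.
#' @export
param_pose <- function(v) {
  v <- as_param_vector(v)
  pose(v[1], v[2], v[3], v[4], v[5], v[6])
}

#' @rdname param_vector
#' @export
param_field <- function(v) {
  v <- as_param_vector(v)
  field_state(v[7], v[8], v[9], v[10], v[11])
}

#' Transform servo parameters from gradient (PRS) to device (XYZ) coordinates
#'
#' Maps the rotation, translation, and gradient-offset 3-vectors of a
#' parameter vector through an orthonormal direction-cosine matrix; the
#' zeroth-order terms phi0 and f0 are frame-independent and pass through
#' unchanged. Rotation angles are mapped via conjugation of the rotation
#' matrix (`M R Mᵀ`), which for orthonormal `M` preserves the rotation angle.
#'
#' @param v A [param_vector()].
#' @param orientation 3x3 orthonormal direction-cosine matrix (PRS -> XYZ).
#' @return A [param_vector()] in device coordinates.
#' @export
prs_to_xyz <- function(v, orientation) {
  v <- as_param_vector(v)
  M <- orientation
  stopifnot(is.matrix(M), all(dim(M) == c(3, 3)))
  dev <- max(abs(t(M) %*% M - diag(3)))
  if (dev > 1e-6) {
    stop(sprintf("orientation matrix is not orthonormal: max |M'M - I| = %.3g",
                 dev))
  }
  Rp <- pose_rotation(param_pose(v))
  ang <- angles_from_rotation(M %*% Rp %*% t(M))
  tr <- as.numeric(M %*% v[4:6])
  g <- as.numeric(M %*% v[9:11])
  as_param_vector(c(ang, tr, v[7], v[8], g))
}

#' Quantize shim offsets onto the hardware increment lattice
#'
#' Linear shim updates can only be applied in discrete hardware increments
#' (about 0.14 uT/m on the target system). Each component is replaced by
#' the nearest integer multiple of the increment; exact half-increment ties
#' round away from zero so the rule is symmetric and sign-stable.
#'
#' @param g Numeric 3-vector of gradient offsets, uT/m.
#' @param increment Positive quantization step, uT/m (default 0.14).
#' @return Numeric 3-vector on the increment lattice.
#' @examples
#' quantize_shim(c(0.30, 0.07, -0.07), 0.14)  # 0.28, 0.14, -0.14
#' @export
quantize_shim <- function(g, increment = 0.14) {
  if (!is.numeric(increment) || length(increment) != 1 || increment <= 0) {
    stop("increment must be a positive scalar")
  }
  n <- abs(g) / increment
  # floor(n + 0.5) rounds half-way cases up, i.e. away from zero after the
  # sign is restored; the small epsilon keeps exact ties stable against
  # floating-point representation of the ratio
  sign(g) * floor(n + 0.5 + 1e-9) * increment
}
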