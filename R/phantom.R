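#' Uniform ellipsoid with complex amplitude
#'
#' Building block of the analytic phantom. Geometry is given in mm in the
#' device frame; the amplitude is a complex signal density in arbitrary
#' units. The k-space signal of a uniform ellipsoid is available in closed
#' form at any sample point, which is what makes exact navigator simulation
#' possible without gridding.
#'
#' @param center mm 3-vector.
#' @param semi_axes mm 3-vector, strictly positive.
#' @param rotation [pose()] whose rotation part orients the ellipsoid
#'   (translation part ignored).
#' @param amplitude Complex (or real) scalar signal density.
#' @return Object of class `"ellipsoid"`.
#' @export
ellipsoid <- function(center = c(0, 0, 0), semi_axes = c(10, 10, 10),
                      rotation = pose(), amplitude = 1 + 0i) {
  stopifnot(length(center) == 3, length(semi_axes) == 3)
  if (any(semi_axes <= 0)) stop("semi-axes must be strictly positive")
  if (!is.finite(Mod(amplitude))) stop("amplitude must be finite")
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = as_pose(rotation),
                 amplitude = as.complex(amplitude)),
            class = "ellipsoid")
}

#' Analytic ellipsoid phantom
#'
#' A non-empty list of [ellipsoid()]s plus a bounding radius (mm). All
#' ellipsoids must fit inside the bounding sphere, which is also the support
#' over which coil sensitivities are defined.
#'
#' @param ellipsoids List of [ellipsoid()]s.
#' @param bounding_radius mm.
#' @return Object of class `"ellipsoid_phantom"`.
#' @export
ellipsoid_phantom <- function(ellipsoids, bounding_radius = 120) {
  stopifnot(is.list(ellipsoids), length(ellipsoids) >= 1)
  for (e in ellipsoids) {
    if (!inherits(e, "ellipsoid")) stop("all components must be ellipsoids")
    if (sqrt(sum(e$center^2)) + max(e$semi_axes) > bounding_radius + 1e-9) {
      stop("ellipsoid extends outside the bounding radius")
    }
  }
  structure(list(ellipsoids = ellipsoids,
                 bounding_radius = bounding_radius),
            class = "ellipsoid_phantom")
}

#' Default asymmetric head-like phantom
#'
#' One large envelope plus four off-center internal features with distinct
#' amplitudes, orientations, and positions. The asymmetry is essential:
#' a symmetric phantom makes rotations unobservable from the navigator and
#' the calibration matrix rank-deficient.
#'
#' @return An [ellipsoid_phantom()].
#' @export
head_phantom <- function() {
  ellipsoid_phantom(list(
    ellipsoid(center = c(0, 0, 0), semi_axes = c(85, 105, 80),
              amplitude = 1),
    ellipsoid(center = c(28, 22, 18), semi_axes = c(24, 30, 20),
              rotation = pose(rz = 25), amplitude = -0.55 + 0.1i),
    ellipsoid(center = c(-32, -14, 24), semi_axes = c(18, 14, 26),
              rotation = pose(rx = 15), amplitude = 0.7i),
    ellipsoid(center = c(10, -45, -22), semi_axes = c(14, 20, 12),
              rotation = pose(ry = -30), amplitude = 0.8),
    ellipsoid(center = c(-15, 38, -30), semi_axes = c(10, 12, 16),
              amplitude = -0.4 - 0.3i)
  ), bounding_radius = 120)
}

#' Closed-form k-space signal of a uniform ellipsoid
#'
#' Evaluates `s(k) = integral rho(r) exp(-i k.r) dr` (k in rad/m, r in m)
#' for a uniform ellipsoid: amplitude x volume x 3(sin k - k cos k)/k^3
#' at `k = |diag(semi_axes) R' k|`, times the center-offset phase
#' `exp(-i k.center)`. The k -> 0 limit is handled by series expansion.
#'
#' @param e An [ellipsoid()].
#' @param k n x 3 matrix (or length-3 vector) of sample points, rad/m.
#' @return Complex vector of length n.
#' @export
ellipsoid_ft <- function(e, k) {
  if (is.null(dim(k))) k <- matrix(k, ncol = 3)
  stopifnot(ncol(k) == 3, all(is.finite(k)))
  a <- e$semi_axes * 1e-3             # m
  ctr <- e$center * 1e-3              # m
  R <- pose_rotation(e$rotation)
  ke <- k %*% R                       # rows are R' k
  kap <- sqrt((ke[, 1] * a[1])^2 + (ke[, 2] * a[2])^2 + (ke[, 3] * a[3])^2)
  vol <- 4 / 3 * pi * prod(a)
  shape <- ifelse(kap < 1e-4,
                  1 - kap^2 / 10 + kap^4 / 280,
                  3 * (sin(kap) - kap * cos(kap)) / pmax(kap, 1e-300)^3)
  e$amplitude * vol * shape * exp(-1i * as.numeric(k %*% ctr))
}

#' Synthetic multi-channel coil model
#'
#' Per-channel complex sensitivities modeled as a low-order (quadratic)
#' spatial polynomial over the phantom bounding sphere, emulating the
#' distinct spatial weightings of a receive array at configurable channel
#' count. Coefficients are drawn reproducibly from `seed`; the constant
#' term is kept dominant so sensitivities are bounded and nonzero over the
#' support.
#'
#' @param n_channels Number of receive channels (>= 1).
#' @param bounding_radius mm; the normalization radius for the polynomial.
#' @param seed Integer seed for the coefficient draw.
#' @return Object of class `"coil_model"` with a `sensitivity()`-style
#'   evaluator available through [coil_sensitivity()].
#' @export
coil_model <- function(n_channels = 8, bounding_radius = 120, seed = 42) {
  stopifnot(n_channels >= 1)
  coef <- with_seed(seed, {
    # columns: 1, x, y, z, x^2, y^2, z^2, xy, xz, yz (normalized coords)
    matrix(complex(real = stats::rnorm(n_channels * 10, sd = 0.4),
                   imaginary = stats::rnorm(n_channels * 10, sd = 0.4)),
           nrow = n_channels, ncol = 10)
  })
  coef[, 1] <- coef[, 1] + 1          # dominant constant term
  structure(list(n_channels = n_channels, coef = coef,
                 bounding_radius = bounding_radius),
            class = "coil_model")
}

#' Evaluate coil sensitivities at spatial points
#'
#' @param coil A [coil_model()].
#' @param points n x 3 matrix of positions, mm.
#' @return Complex matrix, channels x n.
#' @export
coil_sensitivity <- function(coil, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  u <- points / coil$bounding_radius
  basis <- rbind(1, t(u), t(u^2), u[, 1] * u[, 2], u[, 1] * u[, 3],
                 u[, 2] * u[, 3])
  coil$coef %*% basis
}

# channels x n_ellipsoids complex weights: sensitivity at ellipsoid centers
# (piecewise-constant approximation keeping the forward model closed-form)
coil_weights <- function(coil, ph) {
  centers <- t(vapply(ph$ellipsoids, function(e) e$center, numeric(3)))
  coil_sensitivity(coil, centers)
}

#' Multi-channel phantom signal at arbitrary k-space points
#'
#' Sum of [ellipsoid_ft()] over phantom components with the coil
#' sensitivity folded in as a per-ellipsoid complex weight evaluated at the
#' ellipsoid center. This piecewise-constant sensitivity approximation
#' keeps the forward model closed-form while giving channels the distinct
#' spatial weightings that condition rotation and translation estimates.
#'
#' @param ph An [ellipsoid_phantom()].
#' @param coil A [coil_model()] (or `NULL` for unit sensitivity).
#' @param channel Channel index (1-based), ignored when `coil` is `NULL`.
#' @param k n x 3 matrix of sample points, rad/m.
#' @return Complex vector of length n.
#' @export
phantom_signal_at_k <- function(ph, coil, channel, k) {
  if (is.null(dim(k))) k <- matrix(k, ncol = 3)
  if (is.null(coil)) {
    w <- rep(1 + 0i, length(ph$ellipsoids))
  } else {
    if (channel < 1 || channel > coil$n_channels) {
      stop(sprintf("channel %d out of range [1, %d]", channel,
                   coil$n_channels))
    }
    w <- coil_weights(coil, ph)[channel, ]
  }
  s <- complex(length.out = nrow(k))
  for (j in seq_along(ph$ellipsoids)) {
    s <- s + w[j] * ellipsoid_ft(ph$ellipsoids[[j]], k)
  }
  s
}

# all channels at once: channels x n complex matrix
phantom_signal_all <- function(ph, coil, k) {
  if (is.null(dim(k))) k <- matrix(k, ncol = 3)
  w <- coil_weights(coil, ph)                 # channels x E
  Fe <- vapply(ph$ellipsoids, function(e) ellipsoid_ft(e, k),
               complex(nrow(k)))              # n x E
  w %*% t(Fe)
}

#' Rasterize the phantom to a voxel volume
#'
#' Samples the (sensitivity-free) phantom density on a regular grid for
#' visual inspection; with the optional RNifti package installed the result
#' can be written as a NIfTI volume with an RAS+ mm affine.
#'
#' @param ph An [ellipsoid_phantom()].
#' @param n Grid size per dimension.
#' @param file Optional path of a NIfTI file to write (requires RNifti).
#' @return A 3D array (magnitude of the complex density), invisibly when
#'   `file` is given.
#' @export
rasterize_phantom <- function(ph, n = 64, file = NULL) {
  r <- ph$bounding_radius
  x <- seq(-r, r, length.out = n)
  vol <- array(0 + 0i, dim = c(n, n, n))
  grid <- as.matrix(expand.grid(x = x, y = x, z = x))
  dens <- complex(length.out = nrow(grid))
  for (e in ph$ellipsoids) {
    R <- pose_rotation(e$rotation)
    u <- sweep(grid, 2, e$center) %*% R
    inside <- (u[, 1] / e$semi_axes[1])^2 + (u[, 2] / e$semi_axes[2])^2 +
      (u[, 3] / e$semi_axes[3])^2 <= 1
    dens[inside] <- dens[inside] + e$amplitude
  }
  vol[] <- dens
  mag <- Mod(vol)
  if (!is.null(file)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("NIfTI export requires the RNifti package")
    }
    vox <- 2 * r / (n - 1)
    img <- RNifti::asNifti(mag, pixdim = c(vox, vox, vox))
    RNifti::writeNifti(img, file)
    return(invisible(mag))
  }
  mag
}
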