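#' Acquire the eight-shot calibration set
#'
#' Simulates the calibration block of servo navigation: two reference
#' navigators, three shots with rotated trajectories (default 0.5 degrees
#' about X, Y, Z, one each), and three shots with gradient offsets
#' (default 5 uT/m on Gx, Gy, Gz, one each). Rotation shots are produced
#' by counter-rotating the trajectory, which in this forward model is
#' exactly the signal of the object rotated by `+delta`; gradient shots
#' are produced through the field state.
#'
#' @param ph An [ellipsoid_phantom()].
#' @param coil A [coil_model()].
#' @param tr A navigator trajectory.
#' @param noise_sd Per-component complex noise sd for every shot.
#' @param seeds Eight integer seeds (ref1, ref2, 3 rotation, 3 gradient),
#'   or a single master seed from which eight are derived.
#' @param rot_delta Rotation perturbation, degrees (nonzero).
#' @param grad_delta Gradient perturbation, uT/m (nonzero).
#' @return Object of class `"calibration_set"`.
#' @export
acquire_calibration <- function(ph, coil, tr, noise_sd = 0, seeds = 1L,
                                rot_delta = 0.5, grad_delta = 5) {
  if (rot_delta == 0 || grad_delta == 0) {
    stop("calibration deltas must be nonzero")
  }
  if (length(seeds) == 1) seeds <- derive_seeds(seeds, 8)
  stopifnot(length(seeds) == 8)
  refs <- reference_pair(ph, coil, tr, noise_sd, seeds[1:2])
  axes <- c("x", "y", "z")
  rot_shots <- lapply(1:3, function(j) {
    dp <- do.call(pose, stats::setNames(list(rot_delta), paste0("r", axes[j])))
    # trajectory rotated by the inverse pose samples the static phantom at
    # R(delta)' k: identical to the object rotated by +delta
    simulate_navigator(ph, coil, rotate_trajectory(tr, inverse_pose(dp)),
                       noise_sd = noise_sd, seed = seeds[2 + j])
  })
  grad_shots <- lapply(1:3, function(j) {
    fs <- do.call(field_state,
                  stats::setNames(list(grad_delta), paste0("g", axes[j])))
    simulate_navigator(ph, coil, tr, field = fs, noise_sd = noise_sd,
                       seed = seeds[5 + j])
  })
  structure(list(ref1 = refs[[1]], ref2 = refs[[2]], rot_shots = rot_shots,
                 grad_shots = grad_shots, rot_delta = rot_delta,
                 grad_delta = grad_delta, noise_sd = noise_sd,
                 trajectory = tr, coil = coil),
            class = "calibration_set")
}

#' Build the linear perturbation model from a calibration set
#'
#' Fills the 11 columns of the model matrix: rotation and gradient columns
#' by single-sided finite differences of the perturbed shots against the
#' first reference (per degree and per uT/m); translation columns
#' analytically as `-i k_j s_ref1` per mm; the phase column as `i s_ref1`
#' per rad; the frequency column as `i 2 pi t s_ref1` per Hz. Complex rows
#' are split into stacked real and imaginary parts and the pseudo-inverse
#' is computed by SVD with a relative singular-value cutoff of 1e-10.
#' Estimation is later performed against the second reference.
#'
#' @param cal A [acquire_calibration()] result.
#' @param tr The shared navigator trajectory (defaults to the one stored
#'   in `cal`).
#' @return Object of class `"servo_model"`; see [servo_calibrate()].
#' @export
build_model <- function(cal, tr = cal$trajectory) {
  v1 <- as.vector(cal$ref1$data)            # channels fastest
  nc <- nrow(cal$ref1$data); ns <- ncol(cal$ref1$data)
  if (ns != nrow(tr$k)) stop("trajectory and calibration dimensions differ")
  t_s <- rep(tr$t * 1e-3, each = nc)
  C <- matrix(0 + 0i, nrow = nc * ns, ncol = 11,
              dimnames = list(NULL, param_names()))
  for (j in 1:3) {
    C[, j] <- (as.vector(cal$rot_shots[[j]]$data) - v1) / cal$rot_delta
  }
  for (j in 1:3) {                          # translations, per mm
    kj <- rep(tr$k[, j], each = nc)
    C[, 3 + j] <- -1i * kj * 1e-3 * v1
  }
  C[, 7] <- 1i * v1                         # phi0, per rad
  C[, 8] <- 1i * 2 * pi * t_s * v1          # f0, per Hz
  for (j in 1:3) {
    C[, 8 + j] <- (as.vector(cal$grad_shots[[j]]$data) - v1) / cal$grad_delta
  }
  A <- rbind(Re(C), Im(C))
  sv <- svd(A)
  keep <- sv$d > 1e-10 * sv$d[1]
  if (sum(keep) < 11) {
    bad <- which(!keep)
    # name the parameters loading most on the deficient directions
    load <- abs(sv$v[, bad, drop = FALSE])
    names <- unique(param_names()[apply(load, 2, which.max)])
    stop(sprintf(
      "model matrix rank %d < 11; unobservable direction(s) involve: %s ",
      sum(keep), paste(names, collapse = ", ")),
      "(is the phantom asymmetric and the coil multi-channel?)")
  }
  Ainv <- sv$v %*% (t(sv$u) / sv$d)
  structure(list(A = A, Ainv = Ainv, s_ref2 = cal$ref2$data,
                 singular_values = sv$d, trajectory = tr,
                 n_channels = nc, n_samples = ns,
                 noise_sd = cal$noise_sd,
                 rot_delta = cal$rot_delta, grad_delta = cal$grad_delta),
            class = "servo_model")
}

#' Calibrate the servo navigation linear model
#'
#' The fitting entry point: acquires the eight calibration shots
#' ([acquire_calibration()]) and builds the linear perturbation model
#' ([build_model()]) mapping complex navigator signal changes to the 11
#' servo parameters (3 rotations in deg, 3 translations in mm, phase
#' offset in rad, frequency offset in Hz, 3 gradient offsets in uT/m).
#'
#' @inheritParams acquire_calibration
#' @return An object of class `"servo_model"` with components `A` (real
#'   model matrix, stacked real/imaginary rows x 11 columns), `Ainv`
#'   (pseudo-inverse), `s_ref2` (second reference signal),
#'   `singular_values`, and the calibration geometry. Methods:
#'   [predict.servo_model()] estimates parameters from a navigator signal,
#'   [simulate.servo_model()] draws noise-only estimates,
#'   `print` and `summary` report conditioning.
#' @examples
#' ph <- head_phantom(); coil <- coil_model(4, seed = 7)
#' tr <- make_orbital(n_samples = 60)
#' m <- servo_calibrate(ph, coil, tr)
#' sig <- simulate_navigator(ph, coil, tr, pose = pose(rx = 0.1))
#' round(predict(m, sig), 4)
#' @export
servo_calibrate <- function(ph, coil, tr, noise_sd = 0, seeds = 1L,
                            rot_delta = 0.5, grad_delta = 5) {
  cal <- acquire_calibration(ph, coil, tr, noise_sd, seeds,
                             rot_delta, grad_delta)
  build_model(cal, tr)
}

stack_real_imag <- function(x) c(Re(as.vector(x)), Im(as.vector(x)))

#' Estimate servo parameters from a navigator signal
#'
#' Multiplies the signal change with respect to the second reference
#' navigator by the model pseudo-inverse:
#' `theta = A^+ stack(Re, Im)(s - s_ref2)`.
#'
#' @param m A `"servo_model"`.
#' @param s A `"nav_signal"` (or complex matrix of matching dimensions).
#' @return A [param_vector()].
#' @export
estimate <- function(m, s) {
  data <- if (inherits(s, "nav_signal")) s$data else s
  if (!all(dim(data) == dim(m$s_ref2))) {
    stop("signal dimensions do not match the model")
  }
  as_param_vector(as.numeric(m$Ainv %*% stack_real_imag(data - m$s_ref2)))
}

#' @rdname estimate
#' @param object A `"servo_model"`.
#' @param newdata A `"nav_signal"` to estimate from.
#' @param ... Unused.
#' @export
predict.servo_model <- function(object, newdata, ...) {
  estimate(object, newdata)
}

#' Predicted per-parameter noise standard deviations
#'
#' Propagates i.i.d. complex input noise through the pseudo-inverse: the
#' predicted standard deviation of parameter `j` is `noise_sd` times the
#' Euclidean norm of row `j` of `A^+`. This is the analytic counterpart of
#' the empirical precision measured by [precision_report()].
#'
#' @param m A full-rank `"servo_model"`.
#' @param noise_sd Per-component complex noise sd (default: the
#'   calibration noise level stored in the model).
#' @return A [param_vector()] of predicted standard deviations, in
#'   (deg, mm, rad, Hz, uT/m).
#' @export
conditioning_report <- function(m, noise_sd = m$noise_sd) {
  stopifnot(noise_sd >= 0)
  as_param_vector(noise_sd * sqrt(rowSums(m$Ainv^2)))
}

#' Draw noise-only parameter estimates from a calibrated model
#'
#' Simulates `nsim` navigator shots at the reference state with fresh
#' noise and returns their parameter estimates; the empirical spread
#' should match [conditioning_report()].
#'
#' @param object A `"servo_model"`.
#' @param nsim Number of draws.
#' @param seed Integer seed.
#' @param noise_sd Noise level (default: model calibration level).
#' @param ... Unused.
#' @return Matrix `nsim` x 11 of estimates.
#' @export
simulate.servo_model <- function(object, nsim = 1, seed = NULL,
                                 noise_sd = object$noise_sd, ...) {
  n2 <- 2 * length(object$s_ref2)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(n2 * nsim, sd = noise_sd), nrow = n2)
    out <- t(object$Ainv %*% noise)
    colnames(out) <- param_names()
    out
  })
}

#' @export
print.servo_model <- function(x, ...) {
  cat("Servo navigation linear perturbation model\n")
  cat(sprintf("  channels: %d, samples: %d, rows: %d, parameters: 11\n",
              x$n_channels, x$n_samples, nrow(x$A)))
  cat(sprintf("  calibration deltas: %.3g deg rotation, %.3g uT/m gradient\n",
              x$rot_delta, x$grad_delta))
  cat(sprintf("  condition number: %.3g\n",
              x$singular_values[1] / x$singular_values[11]))
  invisible(x)
}

#' @export
summary.servo_model <- function(object, ...) {
  cr <- conditioning_report(object,
                            noise_sd = if (object$noise_sd > 0)
                              object$noise_sd else 1)
  structure(list(model = object, noise_prop = cr,
                 per_unit = object$noise_sd == 0), class = "summary.servo_model")
}

#' @export
print.summary.servo_model <- function(x, ...) {
  print(x$model)
  cat("  singular values (first/last):",
      sprintf("%.3g", x$model$singular_values[1]),
      sprintf("%.3g", x$model$singular_values[11]), "\n")
  lab <- if (x$per_unit) "per unit noise sd" else "at calibration noise"
  cat(sprintf("  predicted parameter noise (%s):\n", lab))
  print(round(unclass(x$noise_prop), 6))
  invisible(x)
}

#' Save / load a servo model as plain text
#'
#' Serializes the model matrix, pseudo-inverse, second reference, and
#' metadata to a JSON file (real/imaginary parts stored as flat arrays).
#'
#' @param m A `"servo_model"`.
#' @param file Path to a JSON file.
#' @export
write_servo_model <- function(m, file) {
  obj <- list(A = as.vector(m$A), dimA = dim(m$A),
              Ainv = as.vector(m$Ainv), dimAinv = dim(m$Ainv),
              ref2_re = as.vector(Re(m$s_ref2)),
              ref2_im = as.vector(Im(m$s_ref2)),
              n_channels = m$n_channels, n_samples = m$n_samples,
              singular_values = m$singular_values,
              noise_sd = m$noise_sd, rot_delta = m$rot_delta,
              grad_delta = m$grad_delta,
              traj_k = as.vector(m$trajectory$k), traj_t = m$trajectory$t,
              traj_radius = m$trajectory$radius,
              traj_duration = m$trajectory$duration)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_servo_model
#' @export
read_servo_model <- function(file) {
  o <- jsonlite::read_json(file, simplifyVector = TRUE)
  tr <- structure(list(k = matrix(o$traj_k, ncol = 3), t = o$traj_t,
                       dwell = if (length(o$traj_t) > 1)
                         diff(o$traj_t)[1] else 0,
                       radius = o$traj_radius, duration = o$traj_duration),
                  class = "nav_trajectory")
  structure(list(A = matrix(o$A, o$dimA[1], o$dimA[2]),
                 Ainv = matrix(o$Ainv, o$dimAinv[1], o$dimAinv[2]),
                 s_ref2 = matrix(complex(real = o$ref2_re,
                                         imaginary = o$ref2_im),
                                 o$n_channels, o$n_samples),
                 singular_values = o$singular_values, trajectory = tr,
                 n_channels = o$n_channels, n_samples = o$n_samples,
                 noise_sd = o$noise_sd, rot_delta = o$rot_delta,
                 grad_delta = o$grad_delta),
            class = "servo_model")
}
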