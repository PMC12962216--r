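#' Single-shot 3D orbital navigator trajectory
#'
#' Three sequential orthogonal great circles (XY, YZ, ZX planes) on the
#' k-space sphere of the given radius, with equal time per circle and
#' uniform angular sampling; every device axis is probed by two circles.
#' This probes all three rotation axes and both transverse k-components
#' per axis, which is what gives the navigator its angular sensitivity.
#' Defaults follow the target protocol: 400 rad/m radius, 2.3 ms duration.
#'
#' @param radius k-space radius, rad/m.
#' @param duration Total readout duration, ms.
#' @param n_samples Total number of samples (>= 30; fewer would leave the
#'   11-column perturbation model rank-deficient).
#' @return Object of class `"nav_trajectory"`: list with `k` (n x 3 matrix,
#'   rad/m), `t` (ms from readout start), `dwell` (ms), `radius`, `duration`.
#' @export
make_orbital <- function(radius = 400, duration = 2.3, n_samples = 126) {
  stopifnot(radius > 0, duration > 0)
  if (n_samples < 30) {
    stop("n_samples must be >= 30: the 11-parameter model matrix would be ",
         "rank-deficient")
  }
  per <- c(rep(n_samples %/% 3, 3))
  per[seq_len(n_samples %% 3)] <- per[seq_len(n_samples %% 3)] + 1
  arc <- function(n, plane) {
    th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    u <- radius * cos(th); v <- radius * sin(th)
    switch(plane,
      xy = cbind(u, v, 0),
      yz = cbind(0, u, v),
      zx = cbind(v, 0, u))
  }
  k <- rbind(arc(per[1], "xy"), arc(per[2], "yz"), arc(per[3], "zx"))
  t <- seq(0, duration, length.out = n_samples)
  structure(list(k = unname(k), t = t, dwell = duration / (n_samples - 1),
                 radius = radius, duration = duration),
            class = "nav_trajectory")
}

#' Rotate a navigator trajectory
#'
#' Maps every sample through the rotation matrix of `dp` (translation part
#' ignored); timestamps and radius are unchanged. Used for the rotated
#' calibration shots and for the servo's run-time geometry updates.
#'
#' @param tr A [make_orbital()] trajectory.
#' @param dp A [pose()]; only its rotation part is used.
#' @return A `"nav_trajectory"`.
#' @export
rotate_trajectory <- function(tr, dp) {
  R <- pose_rotation(as_pose(dp))
  tr$k <- tr$k %*% t(R)
  tr
}

#' Write / read a trajectory as CSV
#'
#' Columns `t_ms, kx, ky, kz`. The radius is recovered as the maximum
#' sample norm on read.
#'
#' @param tr A trajectory.
#' @param file Path.
#' @return `read_trajectory_csv` returns a `"nav_trajectory"`.
#' @export
write_trajectory_csv <- function(tr, file) {
  utils::write.csv(data.frame(t_ms = tr$t, kx = tr$k[, 1], ky = tr$k[, 2],
                              kz = tr$k[, 3]),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  d <- utils::read.csv(file)
  k <- as.matrix(d[, c("kx", "ky", "kz")])
  structure(list(k = unname(k), t = d$t_ms,
                 dwell = if (nrow(d) > 1) diff(d$t_ms)[1] else 0,
                 radius = max(sqrt(rowSums(k^2))),
                 duration = max(d$t_ms) - min(d$t_ms)),
            class = "nav_trajectory")
}

#' Trapezoidal gradient waveform
#'
#' @param amplitude mT/m.
#' @param ramp Single ramp duration, ms (>= 0).
#' @param flat Flat-top duration, ms (>= 0); `ramp + flat > 0`.
#' @return Object of class `"trapezoid_gradient"`.
#' @export
trapezoid_gradient <- function(amplitude, ramp, flat) {
  stopifnot(ramp >= 0, flat >= 0)
  if (ramp + flat <= 0) stop("ramp + flat must be positive")
  structure(list(amplitude = amplitude, ramp = ramp, flat = flat),
            class = "trapezoid_gradient")
}

sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))

#' Frequency response of a trapezoidal gradient
#'
#' The symmetric trapezoid is the convolution of a rect of width
#' `flat + ramp` with a normalized rect of width `ramp`, so its spectrum is
#' `amplitude (flat+ramp) sinc(f (flat+ramp)) sinc(f ramp)` with
#' `sinc(x) = sin(pi x)/(pi x)`. At `f = 0` this is the waveform area
#' (the gradient moment); the first zero sits at `1/(flat+ramp)`. A zero
#' ramp reduces to the rect spectrum. Used to place the spectral main lobe
#' of the slice-encoding rewinder away from gradient-system acoustic
#' resonances.
#'
#' @param g A [trapezoid_gradient()].
#' @param f Frequency (kHz), vectorized.
#' @return Complex vector (zero phase for this symmetric waveform).
#' @export
trapezoid_spectrum <- function(g, f) {
  stopifnot(all(is.finite(f)))
  as.complex(g$amplitude * (g$flat + g$ramp) * sinc(f * (g$flat + g$ramp)) *
               sinc(f * g$ramp))
}

#' Reshape a trapezoid so its first spectral zero hits a target frequency
#'
#' Returns the trapezoid with `flat + ramp = 1/f_res` (placing the first
#' zero crossing of the frequency response at `f_res`, e.g. the lowest
#' acoustic resonance of the gradient system) and `ramp/flat = rolloff`
#' (side-lobe suppression; default 2/3). The amplitude is rescaled so the
#' waveform area, i.e. the gradient moment, is preserved. The roll-off
#' factor is defined here as the ratio of one ramp to the flat-top.
#'
#' @param g A [trapezoid_gradient()].
#' @param f_res Target first-zero frequency, kHz (> 0).
#' @param rolloff Ramp-to-flat ratio in (0, 1]; default 2/3.
#' @return A [trapezoid_gradient()].
#' @examples
#' g <- align_first_zero(trapezoid_gradient(10, 0.2, 0.5), f_res = 1)
#' c(g$flat, g$ramp)  # 0.6, 0.4
#' @export
align_first_zero <- function(g, f_res, rolloff = 2 / 3) {
  stopifnot(f_res > 0, rolloff > 0, rolloff <= 1)
  total <- 1 / f_res
  flat <- total / (1 + rolloff)
  ramp <- total - flat
  if (flat <= 0 || ramp < 0) stop("infeasible trapezoid durations")
  area_old <- g$amplitude * (g$flat + g$ramp)
  trapezoid_gradient(area_old / total, ramp, flat)
}
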