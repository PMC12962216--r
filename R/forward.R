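#' Shot schedule of a segmented 3D-EPI acquisition
#'
#' Maps the linear shot index to the in-plane segment index `s` (cycling
#' with period `S`, the segmentation factor) and the partition index `p`
#' (slice-direction phase-encode plane). The repeating echo-time-shifting
#' bias pattern follows `s`.
#'
#' @param S Segmentation factor (in-plane segments per partition).
#' @param P Number of partitions.
#' @param TR Repetition time per shot, ms.
#' @return data.frame with columns `shot` (1-based), `s` (0-based in-plane
#'   index), `p` (0-based partition index), `time_ms`.
#' @export
shot_schedule <- function(S, P, TR) {
  stopifnot(S >= 1, P >= 1, TR > 0)
  shot <- seq_len(S * P)
  data.frame(shot = shot,
             s = (shot - 1) %% S,
             p = (shot - 1) %/% S,
             time_ms = (shot - 1) * TR)
}

new_nav_signal <- function(data, t, meta = list()) {
  structure(list(data = data, t = t, meta = meta), class = "nav_signal")
}

#' Simulate one multi-channel navigator shot
#'
#' Synthesizes the complex navigator signal of the analytic phantom at a
#' given rigid-body pose and field state. For channel `c` and sample `i`:
#'
#' `s = S_c(R' k_eff) exp(-i k_eff . T) exp(i (phi0 + 2 pi f0 t_i))`
#'
#' where `S_c` is the channel's phantom k-space signal, `R` and `T` the
#' pose rotation and translation, and
#' `k_eff = k_i + 2 pi gamma_bar g t_i` the nominal sample shifted by the
#' k-space accrued from a constant gradient offset `g` (exact for a
#' constant offset). Independent complex Gaussian noise of per-component
#' standard deviation `noise_sd` is added, reproducible from `seed`.
#' No relaxation or intra-object off-resonance is modeled during the short
#' (~2.3 ms) readout: the navigator is an encoding-only probe.
#'
#' @param ph An [ellipsoid_phantom()].
#' @param coil A [coil_model()].
#' @param tr A [make_orbital()] trajectory.
#' @param pose Object [pose()] relative to the navigator frame.
#' @param field A [field_state()].
#' @param noise_sd Per-component noise standard deviation (signal units).
#' @param seed Integer seed for the noise draw (`NULL` for unseeded).
#' @return Object of class `"nav_signal"`: complex `data` matrix
#'   (channels x samples), timestamps `t` (ms), and metadata.
#' @export
simulate_navigator <- function(ph, coil, tr, pose = servo_pose_id(),
                               field = field_state(), noise_sd = 0,
                               seed = NULL) {
  pose <- as_pose(pose); field <- as_field_state(field)
  stopifnot(noise_sd >= 0)
  t_s <- tr$t * 1e-3
  g_Tm <- field[3:5] * 1e-6
  # time-proportional k shift from the constant gradient offset, rad/m
  k_eff <- tr$k + 2 * pi * GAMMA_BAR * outer(t_s, g_Tm)
  R <- pose_rotation(pose)
  data <- phantom_signal_all(ph, coil, k_eff %*% R)   # channels x n
  T_m <- pose[4:6] * 1e-3
  phase <- exp(-1i * as.numeric(k_eff %*% T_m)) *
    exp(1i * (field[1] + 2 * pi * field[2] * t_s))
  data <- sweep(data, 2, phase, "*")
  if (noise_sd > 0) {
    n <- length(data)
    noise <- with_seed(seed, complex(real = stats::rnorm(n, sd = noise_sd),
                                     imaginary = stats::rnorm(n, sd = noise_sd)))
    data <- data + matrix(noise, nrow = nrow(data))
  }
  new_nav_signal(data, tr$t,
                 meta = list(pose = pose, field = field,
                             noise_sd = noise_sd, seed = seed))
}

servo_pose_id <- function() pose()

#' Two independent reference navigators
#'
#' The perturbation model is calibrated against one reference and applied
#' against a second, independently acquired one, so that reference noise
#' does not correlate into the model columns and bias the estimates. This
#' returns two noise realizations of the identical reference state.
#'
#' @inheritParams simulate_navigator
#' @param seeds Two distinct integer seeds.
#' @return List of two `"nav_signal"` objects.
#' @export
reference_pair <- function(ph, coil, tr, noise_sd = 0, seeds = c(1L, 2L)) {
  stopifnot(length(seeds) == 2)
  if (seeds[1] == seeds[2]) {
    stop("reference seeds must differ: identical noise would defeat the ",
         "two-reference design")
  }
  list(simulate_navigator(ph, coil, tr, noise_sd = noise_sd, seed = seeds[1]),
       simulate_navigator(ph, coil, tr, noise_sd = noise_sd, seed = seeds[2]))
}

#' Write / read a navigator signal as CSV
#'
#' One row per (channel, sample) with real and imaginary parts; a plain-text
#' stand-in for binary signal containers.
#'
#' @param sig A `"nav_signal"`.
#' @param file Path.
#' @export
write_signal_csv <- function(sig, file) {
  nc <- nrow(sig$data); ns <- ncol(sig$data)
  d <- data.frame(channel = rep(seq_len(nc), times = ns),
                  sample = rep(seq_len(ns), each = nc),
                  t_ms = rep(sig$t, each = nc),
                  re = as.vector(Re(sig$data)),
                  im = as.vector(Im(sig$data)))
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(file) {
  d <- utils::read.csv(file)
  nc <- max(d$channel); ns <- max(d$sample)
  data <- matrix(complex(real = d$re, imaginary = d$im), nrow = nc, ncol = ns)
  new_nav_signal(data, unique(d$t_ms))
}
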