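# Shared small fixtures: a coarse navigator and a calibrated model reused
# across test files. Sizes are kept small (4 channels, 60 samples) so the
# full calibration runs in well under a second.

fix_phantom <- head_phantom()
fix_coil <- coil_model(n_channels = 4, seed = 11)
fix_traj <- make_orbital(radius = 400, duration = 2.3, n_samples = 60)
fix_model <- servo_calibrate(fix_phantom, fix_coil, fix_traj)

# midpoint-rule quadrature oracle for the ellipsoid Fourier transform,
# independent of the closed form under test
quadrature_ft <- function(e, k, n = 144) {
  a <- e$semi_axes
  g <- seq(-1 + 1 / n, 1 - 1 / n, length.out = n)
  pts <- as.matrix(expand.grid(g, g, g))
  pts <- pts[rowSums(pts^2) <= 1, , drop = FALSE]
  pts <- sweep(pts, 2, a, "*") %*% t(pose_rotation(e$rotation))
  pts <- sweep(pts, 2, e$center, "+") * 1e-3
  dV <- prod(2 * a * 1e-3 / n)
  vapply(seq_len(nrow(k)), function(i) {
    e$amplitude * sum(exp(-1i * as.numeric(pts %*% k[i, ]))) * dV
  }, complex(1))
}

random_small_pose <- function() {
  pose(stats::runif(1, -2, 2), stats::runif(1, -2, 2), stats::runif(1, -2, 2),
       stats::runif(1, -2, 2), stats::runif(1, -2, 2), stats::runif(1, -2, 2))
}
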