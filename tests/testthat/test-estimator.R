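test_that("calibration set has the published structure and deltas", {
  cal <- acquire_calibration(fix_phantom, fix_coil, fix_traj)
  expect_equal(cal$rot_delta, 0.5)
  expect_equal(cal$grad_delta, 5)
  expect_equal(cal$ref1$data, cal$ref2$data)  # noise-free references agree
  for (shot in c(cal$rot_shots, cal$grad_shots)) {
    expect_gt(sum(Mod(shot$data - cal$ref1$data)), 0)
  }
  expect_error(acquire_calibration(fix_phantom, fix_coil, fix_traj,
                                   rot_delta = 0), "nonzero")
})

test_that("analytic model columns match their closed forms", {
  cal <- acquire_calibration(fix_phantom, fix_coil, fix_traj)
  m <- build_model(cal)
  v1 <- as.vector(cal$ref1$data)
  nc <- nrow(cal$ref1$data)
  # translation column: -i k (per mm); for s = 1+0i at kx = 400 rad/m this
  # is (re, im) = (0, -0.4), the value checked here through the general form
  kx <- rep(fix_traj$k[, 1], each = nc)
  expected_tx <- -1i * kx * 1e-3 * v1
  expect_equal(m$A[, 4], c(Re(expected_tx), Im(expected_tx)),
               tolerance = 1e-12)
  expect_equal((-1i * 400 * 1e-3) * (1 + 0i), 0 - 0.4i)  # toy anchor
  # phase and frequency columns
  expected_phi <- 1i * v1
  expect_equal(m$A[, 7], c(Re(expected_phi), Im(expected_phi)),
               tolerance = 1e-12)
  t_s <- rep(fix_traj$t * 1e-3, each = nc)
  expected_f0 <- 1i * 2 * pi * t_s * v1
  expect_equal(m$A[, 8], c(Re(expected_f0), Im(expected_f0)),
               tolerance = 1e-12)
})

test_that("pseudo-inverse is a left inverse of the model matrix", {
  expect_lt(max(abs(fix_model$Ainv %*% fix_model$A - diag(11))), 1e-6)
})

test_that("noise-free estimates recover each injected parameter within 5%", {
  inject <- c(rx = 0.1, ry = 0.1, rz = 0.1, tx = 0.1, ty = 0.1, tz = 0.1,
              phi0 = 0.01, f0 = 1, gx = 1, gy = 1, gz = 1)
  for (nm in names(inject)) {
    v <- inject[[nm]]
    if (nm %in% names(unclass(pose()))) {
      sig <- simulate_navigator(fix_phantom, fix_coil, fix_traj,
                                pose = do.call(pose, stats::setNames(list(v), nm)))
    } else {
      sig <- simulate_navigator(fix_phantom, fix_coil, fix_traj,
                                field = do.call(field_state,
                                                stats::setNames(list(v), nm)))
    }
    est <- estimate(fix_model, sig)
    expect_equal(est[[nm]], v, tolerance = 0.05)
  }
  # tighter anchors from the calibration geometry
  sig <- simulate_navigator(fix_phantom, fix_coil, fix_traj,
                            pose = pose(rx = 0.1))
  expect_equal(estimate(fix_model, sig)[["rx"]], 0.1, tolerance = 0.02)
  sig <- new_sig <- simulate_navigator(fix_phantom, fix_coil, fix_traj,
                                       field = field_state(phi0 = 0.01))
  expect_equal(estimate(fix_model, sig)[["phi0"]], 0.01, tolerance = 0.01)
})

test_that("recovery stays within 5% at 20% of the 2 deg / 2 mm linear range", {
  for (nm in c("rx", "ry", "rz")) {
    sig <- simulate_navigator(fix_phantom, fix_coil, fix_traj,
                              pose = do.call(pose, stats::setNames(list(0.4), nm)))
    expect_equal(estimate(fix_model, sig)[[nm]], 0.4, tolerance = 0.05)
  }
  for (nm in c("tx", "ty", "tz")) {
    sig <- simulate_navigator(fix_phantom, fix_coil, fix_traj,
                              pose = do.call(pose, stats::setNames(list(0.4), nm)))
    expect_equal(estimate(fix_model, sig)[[nm]], 0.4, tolerance = 0.05)
  }
})

test_that("the estimator is an exactly linear map of the signal difference", {
  ref2 <- fix_model$s_ref2
  set.seed(12)
  delta <- matrix(complex(real = rnorm(length(ref2), sd = 1e-7),
                          imaginary = rnorm(length(ref2), sd = 1e-7)),
                  nrow = nrow(ref2))
  e1 <- estimate(fix_model, ref2 + delta)
  e3 <- estimate(fix_model, ref2 + 3 * delta)
  expect_equal(unclass(e3), 3 * unclass(e1), tolerance = 1e-9)
  expect_true(all(estimate(fix_model, ref2) == 0))
  expect_error(estimate(fix_model, ref2[, 1:10]), "dimensions")
})

test_that("conditioning report predicts the Monte-Carlo estimate spread", {
  sd0 <- 1e-7
  pred <- conditioning_report(fix_model, sd0)
  expect_true(all(conditioning_report(fix_model, 0) == 0))
  expect_equal(unclass(conditioning_report(fix_model, 2 * sd0)),
               2 * unclass(pred), tolerance = 1e-12)
  draws <- simulate(fix_model, nsim = 500, seed = 77L, noise_sd = sd0)
  emp <- apply(draws, 2, sd)
  expect_true(all(abs(emp - unclass(pred)) / unclass(pred) < 0.15))
})

test_that("estimates from a noisy two-reference calibration stay unbiased to the noise floor", {
  sd0 <- 5e-8
  m <- servo_calibrate(fix_phantom, fix_coil, fix_traj, noise_sd = sd0,
                       seeds = 31L)
  clean <- simulate_navigator(fix_phantom, fix_coil, fix_traj)
  ests <- vapply(1:80, function(i) {
    sig <- simulate_navigator(fix_phantom, fix_coil, fix_traj,
                              noise_sd = sd0, seed = 1000L + i)
    unclass(estimate(m, sig))
  }, numeric(11))
  bias <- rowMeans(ests)
  floor <- unclass(conditioning_report(m, sd0))
  # the residual offset is set by the second reference's noise realization
  # and stays on the order of the single-shot noise floor
  expect_true(all(abs(bias) < 3 * floor))
})

test_that("a symmetric phantom is rejected as rank-deficient with named directions", {
  sym <- ellipsoid_phantom(list(ellipsoid(semi_axes = c(50, 50, 50),
                                          amplitude = 1)),
                           bounding_radius = 60)
  coil1 <- coil_model(1, bounding_radius = 60, seed = 2)
  coil1$coef[1, ] <- c(1, rep(0, 9))  # flat sensitivity: rotations unseen
  expect_error(servo_calibrate(sym, coil1, fix_traj), "rank|unobservable")
})

test_that("model serialization round-trips estimates exactly", {
  f <- tempfile(fileext = ".json")
  write_servo_model(fix_model, f)
  m2 <- read_servo_model(f)
  sig <- simulate_navigator(fix_phantom, fix_coil, fix_traj,
                            pose = pose(ry = 0.2), field = field_state(f0 = 2))
  expect_equal(unclass(estimate(m2, sig)), unclass(estimate(fix_model, sig)),
               tolerance = 1e-9)
  unlink(f)
})
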