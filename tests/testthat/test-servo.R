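# loop tests share a slightly finer model so linearization effects at the
# ~2 deg scale behave as on the validated system
servo_fix <- local({
  coil <- coil_model(n_channels = 6, seed = 3)
  tr <- make_orbital(n_samples = 90)
  list(coil = coil, tr = tr,
       model = servo_calibrate(head_phantom(), coil, tr))
})

null_scenario <- function(P = 2, noise_sd = 0, seed = 1L) {
  disturbance_script(S = 36, P = P, TR = 58, coil = servo_fix$coil,
                     noise_sd = noise_sd, seed = seed)
}

test_that("controller steps accumulate corrections and skip non-finite estimates", {
  st <- controller_init()
  st2 <- controller_step(st, as_param_vector(rep(0, 11)))
  expect_equal(st2$pose_corr, st$pose_corr)
  expect_equal(st2$g_applied, c(0, 0, 0))

  v <- param_vector(pose(rx = 0.5), field_state(f0 = 5, gx = 0.20))
  st3 <- controller_step(st, v)
  expect_equal(st3$f0_corr, 5)
  expect_equal(st3$pose_corr[["rx"]], 0.5)
  # shim applied on the lattice, sub-increment remainder retained exactly
  expect_equal(st3$g_applied[1], 0.14)
  expect_equal(st3$g_corr[1], 0.20)

  bad <- as_param_vector(c(NaN, rep(0, 10)))
  st4 <- controller_step(st3, bad)
  expect_equal(st4$skipped, 1L)
  expect_equal(st4$pose_corr, st3$pose_corr)
})

test_that("null scenario stays quiet: no corrections, no divergence", {
  cfg <- servo_config(servo_fix$model, noise_sd = 0, seed = 2L)
  run <- run_closed_loop(null_scenario(P = 2), cfg)
  r <- residuals(run)
  expect_lt(max(abs(as.matrix(r))), 1e-8)
  expect_lt(max(abs(run$traces$applied_rx)), 1e-8)
  open <- run_open_loop(null_scenario(P = 2), cfg)
  expect_equal(as.matrix(residuals(open)), as.matrix(r), tolerance = 1e-8)
})

test_that("frequency-offset step is corrected with geometric residual decay", {
  sc <- bottle_scenario(f0_step = 40, onset = 10, S = 36, P = 2, TR = 58,
                        coil = servo_fix$coil)
  run <- run_closed_loop(sc, servo_config(servo_fix$model, seed = 3L))
  res <- abs(run$traces$resid_f0[10:18])
  expect_equal(res[1], 40, tolerance = 1e-6)   # step lands, latency 1
  expect_true(all(diff(res[1:5]) < 0))
  ratios <- res[2:5] / res[1:4]
  expect_true(all(ratios < 0.2))               # fast geometric convergence
  expect_lt(res[9], 1e-3)
  # applied f0 correction converges onto the disturbance
  expect_equal(tail(run$traces$applied_f0, 1), 40, tolerance = 1e-3)
})

test_that("abrupt pose step is corrected to the published residual level", {
  sc <- step_motion_scenario(onset = 30, S = 36, P = 3, TR = 58,
                             coil = servo_fix$coil, noise_sd = 1e-8, seed = 4L)
  cfg <- servo_config(servo_fix$model, noise_sd = 1e-8, seed = 5L)
  run <- run_closed_loop(sc, cfg)
  tr <- run$traces
  post <- tr$shot >= 50                        # 20 shots after the event
  rot <- sqrt(tr$resid_rx^2 + tr$resid_ry^2 + tr$resid_rz^2)[post]
  trn <- sqrt(tr$resid_tx^2 + tr$resid_ty^2 + tr$resid_tz^2)[post]
  expect_lt(mean(rot), 0.03)
  expect_lt(mean(trn), 0.04)
})

test_that("closed loop restores accuracy beyond the open-loop linear range", {
  sc <- disturbance_script(S = 36, P = 3, TR = 58, coil = servo_fix$coil,
                           events = list(list(param = "rz", magnitude = 3,
                                              onset = 20, duration = 0)))
  cfg <- servo_config(servo_fix$model, seed = 6L)
  open <- run_open_loop(sc, cfg)
  closed <- run_closed_loop(sc, cfg)
  open_err <- abs(tail(open$traces$raw_rz, 1) - 3) / 3
  expect_gt(open_err, 0.05)                    # outside the linear range
  expect_lt(abs(tail(closed$traces$resid_rz, 1)), 0.01)
})

test_that("single-parameter steps within the linear range converge within 10 shots", {
  floor0 <- 1e-6                               # effective noise-free floor
  for (nm in c("rx", "tz", "gy")) {
    mag <- switch(nm, rx = 1.5, tz = 1.5, gy = 3)
    sc <- disturbance_script(S = 36, P = 2, TR = 58, coil = servo_fix$coil,
                             events = list(list(param = nm, magnitude = mag,
                                                onset = 10, duration = 0)))
    run <- run_closed_loop(sc, servo_config(servo_fix$model, seed = 7L))
    res <- abs(run$traces[[paste0("resid_", nm)]])
    post <- res[12:21]
    if (nm == "gy") {
      # shim residual settles within half a quantization step (plus the
      # estimation error on the remainder)
      expect_lt(res[21], 0.14 / 2 + 0.01)
    } else {
      expect_true(all(diff(post) < 1e-9))      # non-increasing after latency
      expect_lt(res[21], 10 * floor0)
    }
  }
})

test_that("applied shim corrections always sit on the quantization lattice", {
  sc <- disturbance_script(S = 36, P = 2, TR = 58, coil = servo_fix$coil,
                           drift_rates = c(gx = 0.5, f0 = 2),
                           noise_sd = 1e-8, seed = 8L)
  run <- run_closed_loop(sc, servo_config(servo_fix$model, noise_sd = 1e-8,
                                          seed = 9L))
  gx <- run$traces$applied_gx
  expect_true(all(abs(gx / 0.14 - round(gx / 0.14)) < 1e-9))
})

test_that("update latency delays the first applied correction", {
  sc <- bottle_scenario(f0_step = 20, onset = 5, S = 36, P = 1, TR = 58,
                        coil = servo_fix$coil)
  run2 <- run_closed_loop(sc, servo_config(servo_fix$model, latency = 3L,
                                           seed = 10L))
  ap <- run2$traces$applied_f0
  # estimate from shot 5 (first seeing the step) acts from shot 8 on
  expect_true(all(ap[1:7] == 0))
  expect_gt(ap[8], 19)
})

test_that("long noisy null run stays bounded near the noise floor", {
  sd0 <- 1e-8
  sc <- disturbance_script(S = 36, P = 28, TR = 58, coil = servo_fix$coil,
                           noise_sd = sd0, seed = 11L)   # 1008 shots
  run <- run_closed_loop(sc, servo_config(servo_fix$model, noise_sd = sd0,
                                          seed = 12L))
  floor <- unclass(conditioning_report(servo_fix$model, sd0))
  r <- as.matrix(residuals(run))
  for (j in 1:11) {
    # gain-1 feedback holds residuals within a few noise floors throughout
    expect_lt(stats::quantile(abs(r[, j]), 0.999), 5 * max(floor[j], 1e-12))
  }
})

test_that("trace and manifest export round-trip the run", {
  sc <- null_scenario(P = 1)
  run <- run_closed_loop(sc, servo_config(servo_fix$model, seed = 13L))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_traces(run, csv, js)
  long <- utils::read.csv(csv)
  expect_equal(nrow(long), 36 * 11 * 6)
  man <- jsonlite::read_json(js)
  expect_equal(man$n_shots, 36)
  expect_equal(man$S, 36)
  unlink(c(csv, js))
})
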