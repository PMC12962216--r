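embed_tz <- function(x) {
  m <- matrix(0, length(x), 11, dimnames = list(NULL, param_names()))
  m[, "tz"] <- x
  m
}

test_that("bias table averages the first four partitions per in-plane index", {
  S <- 6
  # constant input: every table entry equals the constant
  tb <- init_bias(matrix(2.5, 4 * S, 11), S)
  expect_true(all(tb$table == 2.5))

  # a pure period-S pattern is reproduced exactly
  pat <- make_ets_pattern(S, c(tz = 0.3), seed = 4L)
  preds <- embed_tz(rep(pat[, "tz"], 4))
  tb2 <- init_bias(preds, S)
  expect_equal(tb2$table[, "tz"], pat[, "tz"], tolerance = 1e-12)

  # with iid noise the table error std shrinks to sigma / 2 (mean of 4)
  set.seed(9)
  sigma <- 0.2
  errs <- replicate(300, {
    noisy <- preds
    noisy[, "tz"] <- noisy[, "tz"] + rnorm(4 * S, sd = sigma)
    init_bias(noisy, S)$table[, "tz"] - pat[, "tz"]
  })
  expect_equal(sd(as.vector(errs)), sigma / 2, tolerance = 0.1)

  expect_error(init_bias(matrix(0, 3 * S, 11), S), "4 x S")
})

test_that("sliding the window tracks bias changes over exactly four partitions", {
  S <- 5
  pat <- make_ets_pattern(S, c(tz = 1), seed = 2L)[, "tz"]
  tb <- init_bias(embed_tz(rep(pat, 4)), S)
  # stationary pattern: unchanged after sliding
  tb1 <- slide_bias(tb, embed_tz(pat))
  expect_equal(tb1$table, tb$table, tolerance = 1e-12)
  expect_equal(length(tb1$buffer), 4)

  # pattern amplitude doubles: table reaches the new level after 4 slides
  for (i in 1:4) tb <- slide_bias(tb, embed_tz(2 * pat))
  expect_equal(tb$table[, "tz"], 2 * pat, tolerance = 1e-12)
  expect_equal(length(tb$buffer), 4)
  expect_error(slide_bias(tb, embed_tz(pat[1:3])), "5 x 11")
})

test_that("bias subtraction cancels stationary patterns and respects de-meaning", {
  S <- 8
  pat <- make_ets_pattern(S, c(tz = 0.4), seed = 3L)
  tb <- init_bias(embed_tz(rep(pat[, "tz"], 4)), S)
  for (s in 0:(S - 1)) {
    corrected <- apply_bias_correction(as_param_vector(pat[s + 1, ]), tb, s)
    expect_lt(abs(corrected[["tz"]]), 1e-12)
  }
  # zero bias table is the identity
  tb0 <- init_bias(matrix(0, 4 * S, 11), S)
  v <- param_vector(pose(tx = 1), field_state(f0 = 3))
  expect_equal(unclass(apply_bias_correction(v, tb0, 2)), unclass(v))
  # a common-mode (DC) component is not subtracted under de-meaning
  tbc <- init_bias(matrix(1, 4 * S, 11), S)
  expect_equal(unclass(apply_bias_correction(v, tbc, 0)), unclass(v))
  # ... but is subtracted when de-meaning is turned off
  expect_equal(apply_bias_correction(v, tbc, 0, demean = FALSE)[["tx"]], 0)
  expect_error(apply_bias_correction(v, tb, S), "out of range")
})

test_that("moving average reduces white noise by sqrt(window) and ramps over steps", {
  x <- rep(3.2, 50)
  expect_equal(moving_average(x, 10), x)
  set.seed(21)
  w <- rnorm(20000)
  r <- sd(w[200:20000]) / sd(moving_average(w, 10)[200:20000])
  expect_equal(r, sqrt(10), tolerance = 0.05)
  # unit step ramps over exactly `window` samples
  st <- c(rep(0, 10), rep(1, 20))
  ma <- moving_average(st, 5)
  expect_equal(ma[10], 0)
  expect_equal(ma[11:15], (1:5) / 5)
  expect_equal(ma[15:30], rep(1, 16))
  # commutes with affine scaling
  expect_equal(moving_average(2 * w[1:100] + 3, 7),
               2 * moving_average(w[1:100], 7) + 3, tolerance = 1e-12)
  expect_error(moving_average(w, 0), "window")
})

test_that("high-pass std removes drifts but keeps white-noise power", {
  fs <- 1000 / 43                     # protocol II shot rate
  f_thr <- ets_threshold_freq(protocol("II"))
  expect_equal(f_thr, 0.77, tolerance = 0.01)
  n <- 3000
  drift <- 5 + 0.8 * seq_len(n) / fs  # constant plus linear drift
  expect_lt(highpass_std(drift, f_thr, fs), 0.01 * sd(drift))
  set.seed(31)
  w <- rnorm(n)
  expect_equal(highpass_std(w, f_thr, fs), sd(w), tolerance = 0.1)
  # invariant to adding any linear trend
  expect_equal(highpass_std(w + drift, f_thr, fs),
               highpass_std(w, f_thr, fs), tolerance = 0.01)
  expect_error(highpass_std(w, fs, fs), "Nyquist")
})

test_that("apparent phase-encode shift is the offset over the bandwidth", {
  expect_equal(apparent_shift(0, 93), 0)
  expect_equal(apparent_shift(93, protocol("I")$pe_bandwidth), 1.0)
  expect_error(apparent_shift(10, 0), "positive")
})

test_that("precision report separates the three processing stages", {
  S <- 30; TR <- 43
  # pattern-dominated, noise-free run built in the parameter domain
  pat <- make_ets_pattern(S, c(tz = 0.1), seed = 5L)
  sched <- shot_schedule(S, 10, TR)
  set.seed(41)
  raw <- embed_tz(pat[sched$s + 1, "tz"] +
                    rnorm(nrow(sched), sd = 0.01))
  run <- structure(list(traces = cbind(sched,
                                       stats::setNames(as.data.frame(raw),
                                                       paste0("raw_", param_names()))),
                        scenario = list(S = S, TR = TR)),
                   class = "servo_run")
  rep_ <- precision_report(run)
  # bias correction removes the period-S pattern: >= 5x std reduction
  expect_gt(rep_$improvement["raw_to_bias", "tz"], 5)
  expect_equal(rep_$f_threshold, 1000 / (S * TR), tolerance = 1e-12)
  # silent input: every stage reports (numerically) zero spread
  run0 <- run
  run0$traces[paste0("raw_", param_names())] <- 0
  expect_lt(max(precision_report(run0)$std), 1e-12)
  expect_error(precision_report(structure(list(
    traces = run$traces[1:60, ], scenario = list(S = S, TR = TR)),
    class = "servo_run")), "8 partitions")
})
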