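#' Trailing moving-average filter
#'
#' Causal (prospective) moving average: `out[n]` is the mean of the last
#' `window` samples up to and including `n`; the first `window - 1`
#' outputs use the available prefix mean. The validated run-time windows
#' are 10 shots for motion parameters and 14 for field parameters.
#'
#' @param series Numeric vector.
#' @param window Window length in shots (>= 1).
#' @return Filtered vector of the same length.
#' @export
moving_average <- function(series, window) {
  if (window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  n <- length(series)
  cs <- cumsum(series)
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - window + 1L)
    (cs[i] - if (j > 1) cs[j - 1] else 0) / (i - j + 1)
  }, numeric(1))
}

#' High-pass-filtered standard deviation
#'
#' Tracking precision metric: the series is high-passed with a
#' second-order zero-phase (forward-backward) Butterworth filter at the
#' threshold frequency, removing drifts and slow motion, and the sample
#' standard deviation of the result is returned. To retain the
#' echo-time-shifting periodicity band, the threshold is set to
#' `1/(TR x S)` of the protocol in use (see [ets_threshold_freq()]).
#'
#' @param series Numeric vector.
#' @param f_threshold High-pass threshold, Hz.
#' @param fs Sampling rate (shot rate `1/TR`), Hz.
#' @return Standard deviation of the high-passed series.
#' @export
highpass_std <- function(series, f_threshold, fs) {
  if (f_threshold >= fs / 2) stop("threshold must be below the Nyquist rate")
  if (f_threshold <= 0) stop("threshold must be positive")
  # remove the linear trend first: filtfilt has no edge padding and a large
  # drift would otherwise leak in through boundary transients
  n <- length(series)
  series <- stats::residuals(stats::lm(series ~ seq_len(n)))
  bf <- signal::butter(2, f_threshold / (fs / 2), type = "high")
  stats::sd(signal::filtfilt(bf, series))
}

#' Stage-wise precision report for a servo run
#'
#' Retrospectively recomputes the three processing stages from the raw
#' per-shot predictions of a run — raw, bias-corrected (sliding-window
#' pipeline), and moving-average filtered — and reports per-parameter
#' high-pass-filtered standard deviations plus stage-to-stage improvement
#' factors. The high-pass threshold is `1/(TR x S)`; the filtered-stage
#' figure is therefore confined to the band between that threshold and
#' the moving-average cutoff.
#'
#' @param run A `"servo_run"` covering at least 8 partitions.
#' @param windows Moving-average windows `c(motion, field)` in shots.
#' @param demean Passed to [apply_bias_correction()].
#' @return Object of class `"precision_report"`: list with `std` (3 x 11
#'   matrix of stds by stage), `improvement` (stage ratios), and the
#'   threshold frequency in Hz.
#' @export
precision_report <- function(run, windows = c(10, 14), demean = TRUE) {
  tr <- run$traces
  S <- run$scenario$S
  TR <- run$scenario$TR
  n <- nrow(tr)
  if (n < 8 * S) stop("traces must cover at least 8 partitions")
  raw <- as.matrix(tr[, paste0("raw_", param_names())])
  colnames(raw) <- param_names()

  corr <- retrospective_bias_correct(raw, S, demean = demean)
  wvec <- filter_window_vec(windows)
  filt <- vapply(1:11, function(j) moving_average(corr[, j], wvec[j]),
                 numeric(n))

  fs <- 1000 / TR
  f_thr <- 1000 / (S * TR)
  # exclude the first four partitions (bias-estimator warm-up) from every
  # stage so the stages are compared over the same steady-state region
  keep <- (4 * S + 1):n
  stages <- list(raw = raw[keep, ], bias_corrected = corr[keep, ],
                 filtered = filt[keep, ])
  std <- t(vapply(stages, function(m)
    vapply(1:11, function(j) highpass_std(m[, j], f_thr, fs), numeric(1)),
    numeric(11)))
  colnames(std) <- param_names()
  improvement <- rbind(raw_to_bias = std[1, ] / std[2, ],
                       bias_to_filtered = std[2, ] / std[3, ],
                       raw_to_filtered = std[1, ] / std[3, ])
  structure(list(std = std, improvement = improvement,
                 f_threshold = f_thr, windows = windows),
            class = "precision_report")
}

# run the init/slide/apply pipeline over a recorded raw prediction matrix
retrospective_bias_correct <- function(raw, S, demean = TRUE) {
  n <- nrow(raw)
  corr <- raw
  bias <- NULL
  p_max <- n %/% S
  for (p in seq_len(p_max + 1) - 1) {
    rows <- p * S + seq_len(S)
    rows <- rows[rows <= n]
    if (!length(rows)) break
    if (!is.null(bias)) {
      for (i in rows) {
        corr[i, ] <- unclass(apply_bias_correction(raw[i, ], bias,
                                                   (i - 1) %% S, demean))
      }
    }
    if (length(rows) == S) {
      if (p == 3) {
        bias <- init_bias(raw[seq_len(4 * S), , drop = FALSE], S)
      } else if (p > 3) {
        bias <- slide_bias(bias, raw[rows, , drop = FALSE])
      }
    }
  }
  corr
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("precision report (high-pass %.3g Hz, windows %d/%d shots)\n",
              x$f_threshold, x$windows[1], x$windows[2]))
  cat("high-pass-filtered standard deviations by stage:\n")
  print(signif(x$std, 3))
  cat("improvement factors:\n")
  print(signif(x$improvement, 3))
  invisible(x)
}

#' Write a precision report as JSON and/or CSV
#'
#' @param report A `"precision_report"`.
#' @param json_file,csv_file Output paths (`NULL` to skip).
#' @export
write_precision_report <- function(report, json_file = NULL, csv_file = NULL) {
  if (!is.null(json_file)) {
    jsonlite::write_json(list(f_threshold_hz = report$f_threshold,
                              windows = report$windows,
                              std = as.data.frame(report$std),
                              improvement = as.data.frame(report$improvement)),
                         json_file, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_file)) {
    d <- data.frame(stage = rep(rownames(report$std), each = 11),
                    parameter = rep(param_names(), 3),
                    hp_std = as.vector(t(report$std)))
    utils::write.csv(d, csv_file, row.names = FALSE)
  }
  invisible(report)
}

#' Apparent image shift from a frequency offset
#'
#' In EPI, a frequency offset displaces the image along the low-bandwidth
#' phase-encoding direction by `f0 / pe_bandwidth` (e.g. a 93 Hz offset at
#' the 93 Hz/mm phase-encode bandwidth of the 7 T protocol shifts the
#' image by 1 mm).
#'
#' @param f0_offset Frequency offset, Hz.
#' @param pe_bandwidth Phase-encoding bandwidth, Hz/mm (> 0).
#' @return Shift in mm.
#' @export
apparent_shift <- function(f0_offset, pe_bandwidth) {
  if (pe_bandwidth <= 0) stop("pe_bandwidth must be positive")
  f0_offset / pe_bandwidth
}
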