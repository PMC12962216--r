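#' Servo loop configuration
#'
#' Bundles the calibrated model, protocol constants, and controller
#' settings for [run_closed_loop()] / [run_open_loop()].
#'
#' The loop gain is fixed at 1 (full correction each update); damping, when
#' wanted, comes from the run-time moving-average filters. The default
#' latency of one shot reflects a total system latency well below one TR:
#' a correction computed from shot `n` is in force for shot `n + 1`.
#' The phase offset phi0 is estimated and logged but never fed back (no
#' actuator exists for it); shim corrections are applied on the hardware
#' quantization lattice while the unquantized accumulator is retained, so
#' sub-increment remainders stay visible to subsequent estimates.
#'
#' @param model A `"servo_model"` from [servo_calibrate()].
#' @param latency Update latency in shots (>= 1).
#' @param shim_increment Shim quantization step, uT/m.
#' @param bias_correct Logical: run the sliding-window echo-time-shifting
#'   bias correction at run time.
#' @param filter_windows `NULL` for no run-time filtering, or a length-2
#'   vector `c(motion, field)` of trailing moving-average windows in shots
#'   (the validated values are 10 and 14).
#' @param noise_sd Per-shot complex noise sd (signal units).
#' @param seed Master seed for per-shot noise.
#' @return Object of class `"servo_config"`.
#' @export
servo_config <- function(model, latency = 1L, shim_increment = 0.14,
                         bias_correct = FALSE, filter_windows = NULL,
                         noise_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "servo_model"), latency >= 1,
            shim_increment > 0, noise_sd >= 0)
  if (!is.null(filter_windows)) {
    stopifnot(length(filter_windows) == 2, all(filter_windows >= 1))
  }
  structure(list(model = model, latency = as.integer(latency),
                 shim_increment = shim_increment,
                 bias_correct = bias_correct,
                 filter_windows = filter_windows,
                 noise_sd = noise_sd, seed = seed),
            class = "servo_config")
}

# per-parameter filter window vector (length 11) from c(motion, field)
filter_window_vec <- function(filter_windows) {
  if (is.null(filter_windows)) return(rep(1L, 11))
  w <- rep(filter_windows[2], 11)
  w[1:6] <- filter_windows[1]
  as.integer(w)
}

#' Advance the controller state by one filtered estimate
#'
#' Gain-1 negative feedback: the pose correction is composed with the
#' estimated residual pose increment (so the navigator frame follows the
#' object), frequency corrections accumulate, and shim corrections
#' accumulate exactly but are applied quantized. Non-finite estimates are
#' skipped with the state unchanged and the event logged.
#'
#' @param state List with `pose_corr` ([pose()]), `f0_corr`, `phi0_log`,
#'   `g_corr` (exact accumulator, uT/m), `skipped` (count); as returned by
#'   [controller_init()].
#' @param filtered_estimate A [param_vector()].
#' @param shim_increment Quantization step, uT/m.
#' @return Updated state; `state$g_applied` holds the quantized shim.
#' @export
controller_step <- function(state, filtered_estimate, shim_increment = 0.14) {
  v <- as_param_vector(filtered_estimate)
  if (!all(is.finite(v))) {
    state$skipped <- state$skipped + 1L
    return(state)
  }
  state$pose_corr <- compose_pose(state$pose_corr, param_pose(v))
  state$f0_corr <- unname(state$f0_corr + v["f0"])
  state$phi0_log <- unname(state$phi0_log + v["phi0"])
  # accumulate on top of the last applied (quantized) value: the estimate
  # already measures the residual left by quantization, so sub-increment
  # remainders stay visible without the exact accumulator drifting
  state$g_corr <- unname(state$g_applied + v[9:11])
  state$g_applied <- quantize_shim(state$g_corr, shim_increment)
  state
}

#' @rdname controller_step
#' @export
controller_init <- function() {
  list(pose_corr = pose(), f0_corr = 0, phi0_log = 0,
       g_corr = c(0, 0, 0), g_applied = c(0, 0, 0), skipped = 0L)
}

# shared loop engine; closed = FALSE logs estimates without applying them
servo_loop <- function(scenario, config, closed = TRUE) {
  stopifnot(inherits(scenario, "disturbance_script"),
            inherits(config, "servo_config"))
  model <- config$model
  tr <- model$trajectory
  ph <- scenario$phantom
  coil <- scenario$coil
  n_shots <- nrow(scenario$schedule)
  S <- scenario$S
  seeds <- derive_seeds(config$seed, n_shots)
  wvec <- filter_window_vec(config$filter_windows)

  state <- controller_init()
  pending <- vector("list", config$latency)  # updates awaiting application
  bias <- NULL
  part_buf <- list()                          # raw predictions, current partition

  cols <- c("true", "raw", "corr", "filt", "applied", "resid")
  traces <- lapply(cols, function(x)
    matrix(NA_real_, n_shots, 11, dimnames = list(NULL, param_names())))
  names(traces) <- cols
  filt_hist <- matrix(0, 0, 11)

  for (n in seq_len(n_shots)) {
    # apply the update whose latency has elapsed
    if (closed && length(pending) && !is.null(pending[[1]])) {
      state <- controller_step(state, pending[[1]], config$shim_increment)
    }
    pending <- c(pending[-1], list(NULL))

    truth <- scenario$truth[n, ]
    true_pose <- pose(truth[1], truth[2], truth[3], truth[4], truth[5],
                      truth[6])
    # state actually seen by the navigator, relative to the corrected frame
    eff_pose <- if (closed) {
      compose_pose(inverse_pose(state$pose_corr), true_pose)
    } else true_pose
    eff_field <- field_state(truth[7],
                             truth[8] - if (closed) state$f0_corr else 0,
                             truth[9] - if (closed) state$g_applied[1] else 0,
                             truth[10] - if (closed) state$g_applied[2] else 0,
                             truth[11] - if (closed) state$g_applied[3] else 0)
    sig <- simulate_navigator(ph, coil, tr, pose = eff_pose,
                              field = eff_field,
                              noise_sd = config$noise_sd, seed = seeds[n])
    raw <- estimate(model, sig) + scenario$pattern[scenario$schedule$s[n] + 1, ]
    raw <- as_param_vector(raw)
    traces$raw[n, ] <- unclass(raw)

    # sliding-window bias correction on the raw (uncorrected) predictions
    s_idx <- scenario$schedule$s[n]
    corr <- raw
    if (config$bias_correct) {
      if (!is.null(bias)) corr <- apply_bias_correction(raw, bias, s_idx)
      part_buf[[length(part_buf) + 1]] <- unclass(raw)
      if (length(part_buf) == S) {           # partition complete
        part <- do.call(rbind, part_buf)
        bias <- if (is.null(bias)) {
          if (scenario$schedule$p[n] >= 3) {
            init_bias(utils::tail(traces$raw[1:n, , drop = FALSE], 4 * S), S)
          } else NULL
        } else slide_bias(bias, part)
        part_buf <- list()
      }
    }

    # run-time trailing moving average (per-parameter windows)
    filt <- corr
    if (!is.null(config$filter_windows)) {
      filt_hist <- rbind(filt_hist, unclass(corr))
      filt <- as_param_vector(vapply(1:11, function(j) {
        w <- min(wvec[j], nrow(filt_hist))
        mean(filt_hist[(nrow(filt_hist) - w + 1):nrow(filt_hist), j])
      }, numeric(1)))
    }

    if (closed) pending[[config$latency]] <- filt

    applied <- c(unclass(state$pose_corr), state$phi0_log, state$f0_corr,
                 state$g_applied)
    resid_pose <- compose_pose(inverse_pose(state$pose_corr), true_pose)
    resid <- c(unclass(resid_pose), truth[7] - 0,
               truth[8] - state$f0_corr, truth[9:11] - state$g_applied)

    traces$corr[n, ] <- unclass(corr)
    traces$filt[n, ] <- unclass(filt)
    traces$applied[n, ] <- applied
    traces$resid[n, ] <- resid
    traces$true[n, ] <- truth
  }

  out <- data.frame(scenario$schedule)
  for (cn in cols) {
    m <- traces[[cn]]
    colnames(m) <- paste(cn, param_names(), sep = "_")
    out <- cbind(out, m)
  }
  structure(list(traces = out, config = config, scenario = scenario,
                 closed = closed, skipped = state$skipped),
            class = "servo_run")
}

#' Run the closed-loop servo simulation
#'
#' Per shot: compose the scripted true state with the current correction,
#' simulate the navigator, estimate the 11 parameters, optionally
#' bias-correct and filter them, and feed the result back with gain 1
#' after the configured latency. Open-loop mode runs the identical
#' pipeline with corrections never applied (estimate-only), as used for
#' the uncorrected comparison scans.
#'
#' @param scenario A [disturbance_script()].
#' @param config A [servo_config()].
#' @return Object of class `"servo_run"` whose `traces` data.frame holds,
#'   per shot and parameter: the scripted truth (`true_*`), raw estimate
#'   (`raw_*`), bias-corrected estimate (`corr_*`), filtered estimate
#'   (`filt_*`), applied correction (`applied_*`), and residual
#'   (`resid_*`, truth relative to the applied correction).
#' @export
run_closed_loop <- function(scenario, config) servo_loop(scenario, config, TRUE)

#' @rdname run_closed_loop
#' @export
run_open_loop <- function(scenario, config) servo_loop(scenario, config, FALSE)

#' @export
print.servo_run <- function(x, ...) {
  cat(sprintf("servo_run (%s loop): %d shots, S = %d, TR = %.3g ms\n",
              if (x$closed) "closed" else "open", nrow(x$traces),
              x$scenario$S, x$scenario$TR))
  if (x$skipped > 0) cat(sprintf("  skipped shots: %d\n", x$skipped))
  invisible(x)
}

#' @export
summary.servo_run <- function(object, ...) {
  tr <- object$traces
  rot <- sqrt(tr$resid_rx^2 + tr$resid_ry^2 + tr$resid_rz^2)
  trn <- sqrt(tr$resid_tx^2 + tr$resid_ty^2 + tr$resid_tz^2)
  res <- list(run = object,
              final_rot_resid = mean(utils::tail(rot, 10)),
              final_trans_resid = mean(utils::tail(trn, 10)),
              max_rot_resid = max(rot), max_trans_resid = max(trn))
  class(res) <- "summary.servo_run"
  res
}

#' @export
print.summary.servo_run <- function(x, ...) {
  print(x$run)
  cat(sprintf("  residual rotation  (last 10 shots): %.4g deg (max %.4g)\n",
              x$final_rot_resid, x$max_rot_resid))
  cat(sprintf("  residual translation (last 10 shots): %.4g mm (max %.4g)\n",
              x$final_trans_resid, x$max_trans_resid))
  invisible(x)
}

#' @export
residuals.servo_run <- function(object, ...) {
  r <- object$traces[, paste0("resid_", param_names())]
  names(r) <- param_names()
  r
}

#' @param x A `"servo_run"`.
#' @param params Parameters to plot (default: the six pose parameters).
#' @param ... Passed to [graphics::matplot()].
#' @rdname run_closed_loop
#' @export
plot.servo_run <- function(x, params = c("rx", "ry", "rz", "tx", "ty", "tz"),
                           ...) {
  tr <- x$traces
  old <- graphics::par(mfrow = c(length(params), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in params) {
    graphics::matplot(tr$shot,
                      cbind(tr[[paste0("true_", p)]],
                            tr[[paste0("raw_", p)]],
                            tr[[paste0("resid_", p)]]),
                      type = "l", lty = c(1, 3, 1),
                      col = c("black", "grey50", "red"),
                      xlab = "shot", ylab = p, ...)
  }
  invisible(x)
}

#' Write loop traces as tidy CSV and a JSON run manifest
#'
#' One row per shot per parameter per series; the manifest records the
#' configuration and seeds for bit-reproducibility.
#'
#' @param run A `"servo_run"`.
#' @param csv_file,json_file Output paths (`NULL` to skip either).
#' @export
write_traces <- function(run, csv_file = NULL, json_file = NULL) {
  if (!is.null(csv_file)) {
    tr <- run$traces
    long <- do.call(rbind, lapply(param_names(), function(p) {
      do.call(rbind, lapply(c("true", "raw", "corr", "filt", "applied",
                              "resid"), function(st) {
        data.frame(shot = tr$shot, s = tr$s, p = tr$p,
                   parameter = p, series = st,
                   value = tr[[paste(st, p, sep = "_")]])
      }))
    }))
    utils::write.csv(long, csv_file, row.names = FALSE)
  }
  if (!is.null(json_file)) {
    cfg <- run$config
    manifest <- list(closed = run$closed,
                     n_shots = nrow(run$traces),
                     S = run$scenario$S, TR = run$scenario$TR,
                     latency = cfg$latency,
                     shim_increment = cfg$shim_increment,
                     bias_correct = cfg$bias_correct,
                     filter_windows = cfg$filter_windows,
                     noise_sd = cfg$noise_sd, seed = cfg$seed,
                     scenario_seed = run$scenario$seed,
                     package_version = as.character(
                       utils::packageVersion("servonav")))
    jsonlite::write_json(manifest, json_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(run)
}
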