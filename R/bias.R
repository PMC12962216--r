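#' Initialize the echo-time-shifting bias table
#'
#' Echo time shifting makes the eddy-current state at the navigator vary
#' shot-to-shot with a pattern that repeats every `S` shots (the
#' segmentation factor). The per-in-plane-shot biases are estimated by
#' averaging the uncorrected predictions of the first four partitions per
#' in-plane index, which suppresses motion and field fluctuations.
#'
#' @param predictions Matrix `(4 S) x 11` of uncorrected per-shot
#'   parameter predictions, rows ordered by shot (partition-major, in-plane
#'   index `0 .. S-1` within each partition).
#' @param S Segmentation factor.
#' @return Object of class `"bias_table"`: the `S x 11` table of raw
#'   per-index means plus the ring buffer of the last 4 partitions.
#' @export
init_bias <- function(predictions, S) {
  predictions <- as.matrix(predictions)
  if (nrow(predictions) != 4 * S) {
    stop(sprintf("need exactly 4 x S = %d predictions, got %d", 4 * S,
                 nrow(predictions)))
  }
  if (ncol(predictions) != 11) stop("predictions must have 11 columns")
  if (!all(is.finite(predictions))) stop("predictions must be finite")
  buffer <- lapply(0:3, function(p)
    predictions[p * S + seq_len(S), , drop = FALSE])
  new_bias_table(buffer, S)
}

new_bias_table <- function(buffer, S) {
  table <- Reduce(`+`, buffer) / length(buffer)
  colnames(table) <- param_names()
  structure(list(table = table, buffer = buffer, S = S,
                 partitions_seen = length(buffer)),
            class = "bias_table")
}

#' Slide the bias window by one partition
#'
#' Advances the ring buffer by one full partition of uncorrected
#' predictions (the oldest partition is dropped) and recomputes the
#' per-index means, tracking the slowly varying component of the bias
#' (e.g. from the slice-encoding rewinder gradient).
#'
#' @param table A `"bias_table"`.
#' @param partition Matrix `S x 11` of uncorrected predictions for the new
#'   partition.
#' @return Updated `"bias_table"`.
#' @export
slide_bias <- function(table, partition) {
  partition <- as.matrix(partition)
  if (nrow(partition) != table$S || ncol(partition) != 11) {
    stop(sprintf("partition must be %d x 11", table$S))
  }
  buffer <- c(table$buffer[-1], list(partition))
  out <- new_bias_table(buffer, table$S)
  out$partitions_seen <- table$partitions_seen + 1L
  out
}

#' Subtract the shot-specific bias from a prediction
#'
#' Subtracts the bias-table entry for in-plane index `s`. By default the
#' table is first de-meaned across the period (each parameter's mean over
#' the `S` entries is removed): the echo-time-shifting bias is zero-mean
#' across the period by nature, while any common-mode content of the
#' window mean is true motion or field change that must not be absorbed
#' into the bias. Without de-meaning, a net pose change during the window
#' would be subtracted from all subsequent predictions.
#'
#' @param pred A [param_vector()] (uncorrected prediction).
#' @param table A `"bias_table"`.
#' @param s In-plane shot index, `0 .. S-1`.
#' @param demean Remove the across-period mean of the table first
#'   (default `TRUE`).
#' @return The bias-corrected [param_vector()].
#' @export
apply_bias_correction <- function(pred, table, s, demean = TRUE) {
  if (s < 0 || s >= table$S) {
    stop(sprintf("in-plane index %d out of range [0, %d)", s, table$S))
  }
  b <- table$table
  if (demean) b <- sweep(b, 2, colMeans(b))
  as_param_vector(unclass(as_param_vector(pred)) - b[s + 1, ])
}

#' @export
print.bias_table <- function(x, ...) {
  cat(sprintf("bias_table: S = %d, window = %d partitions (seen %d)\n",
              x$S, length(x$buffer), x$partitions_seen))
  invisible(x)
}
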