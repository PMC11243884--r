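#' Low-pass denoise a recording
#'
#' Second-order infinite-impulse-response (Butterworth) low-pass filtering of
#' each taxel's time series independently, with the pass-band edge at
#' `cutoff_fraction` of the sampling rate (default fs/7). By default the
#' filter is applied forward-backward (zero phase) so the temporal error
#' analyses are not biased by phase lag; `causal = TRUE` applies the
#' single-pass causal filter instead. The output is real-valued: no
#' re-quantization takes place.
#'
#' @param rec A `tactile_recording`.
#' @param order Filter order (the denominator polynomial degree).
#' @param cutoff_fraction Pass-band edge as a fraction of the sampling rate,
#'   in (0, 0.5).
#' @param causal Use single-pass causal filtering instead of zero-phase
#'   forward-backward filtering.
#' @return A `tactile_recording` with filtered real-valued frames and
#'   `metadata$denoised = "true"`.
#' @export
lowpass_denoise <- function(rec, order = 2L, cutoff_fraction = 1 / 7,
                            causal = FALSE) {
  validate_recording(rec)
  if (cutoff_fraction <= 0 || cutoff_fraction >= 0.5) {
    abort("cutoff_fraction must be in (0, 0.5)", class = "tactwave_error")
  }
  d <- dim(rec$frames)
  warmup <- 3L * (2L * order + 1L)
  if (d[1L] <= warmup) {
    abort(sprintf("recording shorter than the filter warm-up length (%d frames)",
                  warmup), class = "tactwave_error")
  }
  bw <- signal::butter(order, 2 * cutoff_fraction, type = "low")
  m <- matrix(rec$frames, nrow = d[1L])
  active <- rep(as.logical(rec$sensor_mask), 1L)
  out <- m
  # zero-phase: forward-backward pass over an odd-reflection padded signal so
  # the filter state has settled before the recording starts (in either
  # direction); the padding is discarded afterwards
  pad <- min(d[1L] - 1L, 12L * (2L * order + 1L))
  fn <- if (causal) {
    function(x) as.numeric(signal::filter(bw, x))
  } else {
    function(x) {
      n <- length(x)
      ext <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
      y <- as.numeric(signal::filter(bw, ext))
      y <- rev(as.numeric(signal::filter(bw, rev(y))))
      y[(pad + 1L):(pad + n)]
    }
  }
  for (j in which(active)) out[, j] <- fn(m[, j])
  rec$frames <- array(out, dim = d)
  rec$metadata$denoised <- "true"
  rec$metadata$denoise_order <- as.character(order)
  rec$metadata$denoise_cutoff_fraction <- as.character(cutoff_fraction)
  rec$metadata$denoise_causal <- if (causal) "true" else "false"
  rec
}
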