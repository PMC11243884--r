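#' Construct a tactile recording
#'
#' The unit of analysis: a time-ordered stack of 2D pressure frames from a
#' tactile sensor array, together with the boolean mask of physically present
#' taxels, the sampling rate and the ADC bit depth. Raw (pre-denoising)
#' recordings hold integer ADC counts in `[0, 2^bit_depth - 1]`; denoised
#' recordings are real-valued and flagged via `metadata$denoised`.
#'
#' @param frames 3D numeric array, time x rows x cols.
#' @param sensor_mask Logical rows x cols matrix of active taxels; defaults to
#'   all active.
#' @param sampling_rate Frames per second (Hz).
#' @param bit_depth ADC resolution in bits (10 for the tactile-glove class of
#'   arrays this package targets).
#' @param metadata Named list of strings (object label, trial id, provenance).
#' @return A `tactile_recording` object.
#' @export
tactile_recording <- function(frames, sensor_mask = NULL, sampling_rate,
                              bit_depth = 10L, metadata = list()) {
  frames <- .as_dim_array(frames)
  if (length(dim(frames)) != 3L) {
    abort("frames must be a 3D array (time x rows x cols)", class = "tactwave_error")
  }
  if (is.null(sensor_mask)) {
    sensor_mask <- matrix(TRUE, dim(frames)[2L], dim(frames)[3L])
  }
  rec <- structure(
    list(frames = frames, sensor_mask = sensor_mask,
         sampling_rate = sampling_rate, bit_depth = as.integer(bit_depth),
         metadata = metadata),
    class = "tactile_recording"
  )
  validate_recording(rec)
  rec
}

#' Validate a tactile recording
#'
#' Checks the container invariants and fails with an error naming the first
#' violated field: non-empty finite frames, mask shape equal to the frame
#' shape, positive sampling rate, and (for raw integer data) values within the
#' ADC range.
#'
#' @param rec A `tactile_recording`.
#' @param raw Enforce the integer ADC-range invariant (skipped for denoised,
#'   real-valued recordings).
#' @return `rec`, invisibly.
#' @export
validate_recording <- function(rec, raw = NULL) {
  if (!inherits(rec, "tactile_recording")) {
    abort("not a tactile_recording", class = "tactwave_error")
  }
  d <- dim(rec$frames)
  if (is.null(d) || length(d) != 3L || any(d < 1L)) {
    abort("field 'frames': must be a non-empty 3D array", class = "tactwave_error")
  }
  if (any(!is.finite(rec$frames))) {
    abort("field 'frames': contains non-finite values", class = "tactwave_error")
  }
  if (!is.logical(rec$sensor_mask) || !identical(dim(rec$sensor_mask), d[2:3])) {
    abort("field 'sensor_mask': shape must equal the spatial frame shape",
          class = "tactwave_error")
  }
  if (!is.numeric(rec$sampling_rate) || rec$sampling_rate <= 0) {
    abort("field 'sampling_rate': must be positive", class = "tactwave_error")
  }
  if (is.null(raw)) raw <- !isTRUE(rec$metadata$denoised == "true")
  if (raw) {
    top <- 2^rec$bit_depth - 1
    if (min(rec$frames) < 0 || max(rec$frames) > top) {
      abort(sprintf("field 'frames': raw values must lie in [0, %d]", top),
            class = "tactwave_error")
    }
  }
  invisible(rec)
}

#' @export
print.tactile_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<tactile_recording> %d frames of %d x %d (%d active taxels), %g Hz, %d-bit\n",
    d[1L], d[2L], d[3L], sum(x$sensor_mask), x$sampling_rate, x$bit_depth))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Recording as a tidy tibble
#'
#' One row per sample: `time` (seconds), `row`, `col`, `value`, `active`.
#' Convenient for ggplot2; the array form remains the computational container.
#'
#' @param x A `tactile_recording`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tactile_recording <- function(x, ...) {
  d <- dim(x$frames)
  tibble::tibble(
    time = rep((seq_len(d[1L]) - 1L) / x$sampling_rate, times = d[2L] * d[3L]),
    row = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    col = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    value = as.numeric(x$frames),
    active = rep(as.logical(x$sensor_mask), each = d[1L])
  )
}
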