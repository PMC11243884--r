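# Orthonormal type-II discrete cosine transform, the survey's baseline
# sparsifying transform. Computed via the even-odd FFT factorization, applied
# separably along the transform axes with the same batching semantics as the
# wavelet path (1D: along time per taxel; 2D: per frame; 3D: full volume).

.dct_mat <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(m)
  v <- m[c(seq(1L, n, 2L), rev(seq(2L, n, 2L))), , drop = FALSE]
  V <- stats::mvfft(v)
  k <- seq_len(n) - 1L
  ph <- exp(-1i * pi * k / (2 * n))
  y <- Re(ph * V) * sqrt(2 / n)
  y[1L, ] <- y[1L, ] / sqrt(2)
  y
}

.idct_mat <- function(y) {
  n <- nrow(y)
  if (n == 1L) return(y)
  cu <- y / sqrt(2 / n)
  cu[1L, ] <- cu[1L, ] * sqrt(2)
  k <- seq_len(n) - 1L
  ph <- exp(1i * pi * k / (2 * n))
  shifted <- rbind(rep(0, ncol(cu)), cu[n:2L, , drop = FALSE])
  V <- ph * (cu - 1i * shifted)
  v <- Re(stats::mvfft(V, inverse = TRUE)) / n
  x <- matrix(0, n, ncol(y))
  x[c(seq(1L, n, 2L), rev(seq(2L, n, 2L))), ] <- v
  x
}

#' Forward discrete cosine transform (orthonormal, type II)
#'
#' The conventional sparsifying baseline against which the wavelet survey is
#' compared. Applied globally per slice (no blocking): along each taxel's
#' time series (`dimensionality = 1`), per spatial frame (2), or separably
#' over the full volume (3). The orthonormal convention preserves energy, so
#' Parseval's identity holds exactly.
#'
#' @inheritParams dwt_forward
#' @return A `coefficient_set` with a single coefficient band.
#' @export
dct_forward <- function(x, dimensionality = 1L) {
  arr <- .as_dim_array(x)
  dimensionality <- as.integer(dimensionality)
  if (!dimensionality %in% 1:3) {
    abort("dimensionality must be 1, 2 or 3", class = "tactwave_error")
  }
  if (any(!is.finite(arr))) {
    abort("input contains non-finite values", class = "tactwave_error")
  }
  axes <- .transform_axes(length(dim(arr)), dimensionality)
  for (ax in axes) arr <- .along_axis(arr, ax, .dct_mat)
  structure(
    list(transform = "dct", wavelet = "dct", dimensionality = dimensionality,
         axes = axes, level = 0L, original_shape = dim(arr),
         pre_dims = list(), extension = "none", bands = list(c = arr)),
    class = "coefficient_set"
  )
}

#' Inverse discrete cosine transform
#'
#' @param coeffs A `coefficient_set` from [dct_forward()].
#' @return Numeric array of the original shape.
#' @export
dct_inverse <- function(coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (coeffs$transform != "dct") {
    abort("coefficient set is not a DCT representation; use dwt_inverse()",
          class = "tactwave_error")
  }
  arr <- coeffs$bands$c
  for (ax in rev(coeffs$axes)) arr <- .along_axis(arr, ax, .idct_mat)
  if (length(coeffs$original_shape) == 1L) as.numeric(arr) else arr
}
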