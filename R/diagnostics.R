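# Secondary analyses: compactness (phase-transition) curves, spatiotemporal
# error decomposition, grand-average interaction, filter-length trend, and
# scaling-function similarity.

#' Top-k coefficient reconstruction curve
#'
#' Keeps the `k` largest-magnitude transform coefficients (ties keep the
#' earlier position in the documented subband order), zeroes the rest,
#' inverts and scores the reconstruction — the phase-transition view of how
#' compact a representation is. Also returns the sorted coefficient
#' magnitudes.
#'
#' @param data Numeric array.
#' @param wavelet Wavelet name, `wavelet_spec` or `"dct"`.
#' @param dimensionality 1, 2 or 3.
#' @param k_values Numbers of retained coefficients (0 to the total count).
#' @param peak Peak value for the PSNR (default 10-bit).
#' @return A `compactness_curve`: list with `curve` (tibble of `k`, `nmse`,
#'   `psnr`) and `magnitudes` (sorted decreasing).
#' @export
topk_reconstruction_curve <- function(data, wavelet, dimensionality = 1L,
                                      k_values, peak = 1023) {
  data <- .as_dim_array(data)
  cs <- .forward_transform(data, wavelet, dimensionality)
  v <- coef_values(cs)
  if (!length(k_values)) {
    abort("k_values is empty", class = "tactwave_error")
  }
  if (any(k_values < 0 | k_values > length(v))) {
    abort("k_values must lie between 0 and the total coefficient count",
          class = "tactwave_error")
  }
  ord <- order(-abs(v))  # stable: ties keep the earlier position
  curve <- purrr::map_dfr(sort(unique(as.integer(k_values))), function(k) {
    keep <- numeric(length(v))
    if (k > 0) keep[ord[seq_len(k)]] <- v[ord[seq_len(k)]]
    recon <- .inverse_transform(.coef_replace(cs, keep))
    tibble::tibble(k = k, nmse = nmse(data, recon),
                   psnr = psnr(data, recon, peak))
  })
  structure(list(curve = curve, magnitudes = sort(abs(v), decreasing = TRUE),
                 wavelet = cs$wavelet, dimensionality = dimensionality),
            class = "compactness_curve")
}

#' @export
print.compactness_curve <- function(x, ...) {
  cat(sprintf("<compactness_curve> %s %dD, %d points\n", x$wavelet,
              x$dimensionality, nrow(x$curve)))
  print(x$curve)
  invisible(x)
}

.slice_nmse <- function(y, y_hat) {
  ybar <- mean(y)
  if (abs(ybar) < .Machine$double.eps) return(NA_real_)
  mean((y - y_hat)^2) / ybar
}

#' Spatiotemporal error decomposition
#'
#' Recomputes the reconstruction NMSE per slice: once per masked-in sensor
#' over its full time series (the temporal profile) and once per time point
#' over the spatial frame (the spatial profile). Slices with zero mean (no
#' signal) are excluded as degenerate and reported via the `n_degenerate`
#' counts. The per-slice normalization differs from the pooled NMSE's, so the
#' sample-weighted mean of a profile need not equal the pooled value unless
#' all slices share the same mean.
#'
#' @param original,reconstructed `tactile_recording`s (or bare 3D arrays) of
#'   the same shape.
#' @param sensor_mask Logical mask when bare arrays are given.
#' @return An `error_profile`: tibbles `temporal` (sensor, row, col, nmse) and
#'   `spatial` (t, nmse), plus `summary` with the mean and standard deviation
#'   of each profile.
#' @export
spatiotemporal_error_profile <- function(original, reconstructed,
                                         sensor_mask = NULL) {
  if (inherits(original, "tactile_recording")) {
    sensor_mask <- original$sensor_mask
    original <- original$frames
  }
  if (inherits(reconstructed, "tactile_recording")) {
    reconstructed <- reconstructed$frames
  }
  if (!identical(dim(original), dim(reconstructed))) {
    abort("original and reconstructed must have the same shape",
          class = "tactwave_error")
  }
  d <- dim(original)
  if (is.null(sensor_mask)) sensor_mask <- matrix(TRUE, d[2L], d[3L])
  om <- matrix(original, nrow = d[1L])
  rm_ <- matrix(reconstructed, nrow = d[1L])
  idx <- which(as.logical(sensor_mask))
  temporal <- tibble::tibble(
    sensor = idx,
    row = ((idx - 1L) %% d[2L]) + 1L,
    col = ((idx - 1L) %/% d[2L]) + 1L,
    nmse = purrr::map_dbl(idx, function(j) .slice_nmse(om[, j], rm_[, j]))
  )
  spatial <- tibble::tibble(
    t = seq_len(d[1L]),
    nmse = purrr::map_dbl(seq_len(d[1L]),
                          function(i) .slice_nmse(om[i, ], rm_[i, ]))
  )
  summarise_profile <- function(v) {
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v[!is.na(v)]))
  }
  st <- summarise_profile(temporal$nmse)
  ss <- summarise_profile(spatial$nmse)
  structure(
    list(temporal = temporal, spatial = spatial,
         summary = tibble::tibble(
           profile = c("temporal", "spatial"),
           mean = c(st[["mean"]], ss[["mean"]]),
           sd = c(st[["sd"]], ss[["sd"]]),
           n_degenerate = c(sum(is.na(temporal$nmse)), sum(is.na(spatial$nmse)))
         )),
    class = "error_profile"
  )
}

#' @export
print.error_profile <- function(x, ...) {
  cat("<error_profile>\n")
  print(x$summary)
  invisible(x)
}

# per-frame activity above each taxel's resting level, summed over the mask
.activity_series <- function(rec) {
  d <- dim(rec$frames)
  m <- matrix(rec$frames, nrow = d[1L])[, as.logical(rec$sensor_mask), drop = FALSE]
  rest <- apply(m, 2L, stats::median)
  rowSums(pmax(sweep(m, 2L, rest), 0))
}

#' Grand-average tactile interaction
#'
#' Reduces every recording to a scalar per-frame activity series (pressure
#' above each taxel's resting level, summed over the mask), aligns the trials
#' at onset — the first frame whose activity exceeds 10% of that trial's peak
#' — resamples to a common length and averages. Recordings with no
#' supra-threshold activity are excluded and reported.
#'
#' @param dataset List of at least two `tactile_recording`s.
#' @param n_points Length of the common time base.
#' @return A `grand_average`: tibble `template` (`frame`, `mean`, `sd`) plus
#'   the number of trials used and excluded.
#' @export
grand_average_interaction <- function(dataset, n_points = NULL) {
  if (inherits(dataset, "tactile_recording") || length(dataset) < 2L) {
    abort("grand average requires at least 2 recordings", class = "tactwave_error")
  }
  series <- lapply(dataset, .activity_series)
  peaks <- purrr::map_dbl(series, max)
  keep <- peaks > 0
  if (!all(keep)) {
    message(sprintf("grand_average_interaction: excluded %d flat recording(s)",
                    sum(!keep)))
  }
  series <- series[keep]
  if (length(series) < 2L) {
    abort("fewer than 2 recordings with supra-threshold activity",
          class = "tactwave_error")
  }
  onset <- purrr::map_int(series, function(s) {
    as.integer(which(s > 0.1 * max(s))[1L])
  })
  aligned <- purrr::map2(series, onset, function(s, o) s[o:length(s)])
  len <- min(purrr::map_int(aligned, length))
  if (is.null(n_points)) n_points <- len
  common <- purrr::map(aligned, function(s) {
    stats::approx(seq_along(s), s, xout = seq(1, length(s), length.out = n_points))$y
  })
  m <- do.call(cbind, common)
  structure(
    list(template = tibble::tibble(frame = seq_len(n_points),
                                   mean = rowMeans(m),
                                   sd = apply(m, 1L, stats::sd)),
         n_trials = length(series), n_excluded = sum(!keep)),
    class = "grand_average"
  )
}

#' @export
print.grand_average <- function(x, ...) {
  cat(sprintf("<grand_average> %d trials (%d excluded), %d points\n",
              x$n_trials, x$n_excluded, nrow(x$template)))
  invisible(x)
}

#' Trend of sparsity against wavelet filter length
#'
#' Ordinary least squares of the survey's 1D sparsity on the wavelet support
#' length, with the 95% confidence interval of the slope — the filter-size
#' trend analysis.
#'
#' @param results A `survey_table`.
#' @param dimensionality Dimensionality to analyse (1 for the survey's
#'   trend).
#' @param target NMSE target.
#' @return One-row tibble: `slope`, `intercept`, `conf_low`, `conf_high`,
#'   `r_squared`, `n`.
#' @export
filter_length_vs_sparsity <- function(results, dimensionality = 1L,
                                      target = 0.01) {
  reg <- wavelet_registry()
  tb <- dplyr::filter(tibble::as_tibble(results),
                      .data$transform == "dwt",
                      .data$dimensionality == !!dimensionality,
                      .data$target_nmse == !!target,
                      .data$status == "converged")
  tb$support_length <- reg$support_length[match(tb$wavelet, reg$name)]
  tb <- tb[!is.na(tb$support_length), ]
  if (nrow(tb) < 3L) {
    abort("need at least 3 converged entries for the trend fit",
          class = "tactwave_error")
  }
  if (length(unique(tb$support_length)) < 2L) {
    abort("degenerate design: all filter lengths equal", class = "tactwave_error")
  }
  fit <- stats::lm(sparsity ~ support_length, data = tb)
  ci <- suppressWarnings(stats::confint(fit, "support_length", level = 0.95))
  tibble::tibble(
    slope = stats::coef(fit)[["support_length"]],
    intercept = stats::coef(fit)[["(Intercept)"]],
    conf_low = ci[1L], conf_high = ci[2L],
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n = nrow(tb)
  )
}

#' Scaling function of a wavelet by the cascade algorithm
#'
#' Iterates the reconstruction low-pass refinement (upsample and convolve)
#' from the filter taps; five iterations give the conventional rendering of
#' the scaling ("father") function's shape.
#'
#' @param wavelet Wavelet name or `wavelet_spec`.
#' @param iterations Cascade iterations.
#' @return Tibble with `t` (support coordinate) and `phi`.
#' @export
scaling_function <- function(wavelet, iterations = 5L) {
  spec <- .as_wavelet_spec(wavelet)
  p <- spec$rec_lo
  for (i in seq_len(iterations - 1L)) {
    up <- numeric(2L * length(p) - 1L)
    up[seq(1L, length(up), 2L)] <- p
    p <- stats::convolve(up, rev(spec$rec_lo), type = "open") * sqrt(2)
  }
  tibble::tibble(t = (seq_along(p) - 1L) / 2^(iterations - 1L), phi = p)
}

#' Similarity of a scaling function to a temporal template
#'
#' Maximum normalized cross-correlation (over shifts, after resampling both
#' curves to a common support) between the wavelet's iterated scaling
#' function and a temporal activity template such as the grand-average
#' interaction. The signed value at the best-matching shift is reported; -1
#' means a perfectly inverted match.
#'
#' @param wavelet Wavelet name or `wavelet_spec`.
#' @param template Numeric vector (or `grand_average`) of the temporal shape.
#' @param iterations Cascade iterations for the scaling function.
#' @param n_points Common resampling length.
#' @return Correlation in `[-1, 1]`.
#' @export
scaling_similarity <- function(wavelet, template, iterations = 5L,
                               n_points = 256L) {
  if (inherits(template, "grand_average")) template <- template$template$mean
  template <- as.numeric(template)
  if (length(template) < 3L || stats::sd(template) == 0) {
    abort("template must be non-constant", class = "tactwave_error")
  }
  phi <- scaling_function(wavelet, iterations)$phi
  rs <- function(v) stats::approx(seq_along(v), v,
                                  xout = seq(1, length(v), length.out = n_points))$y
  a <- rs(phi)
  b <- rs(template)
  min_overlap <- max(8L, n_points %/% 4L)
  best <- 0
  best_abs <- -Inf
  for (lag in seq(-(n_points - min_overlap), n_points - min_overlap)) {
    ia <- max(1L, 1L - lag):min(n_points, n_points - lag)
    ib <- ia + lag
    if (stats::sd(a[ia]) == 0 || stats::sd(b[ib]) == 0) next
    r <- stats::cor(a[ia], b[ib])
    if (is.finite(r) && abs(r) > best_abs) {
      best_abs <- abs(r)
      best <- r
    }
  }
  best
}
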