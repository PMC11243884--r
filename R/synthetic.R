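# Seeded synthetic tactile-grasp generator.
#
# Emulates the statistical structure the sparsification survey relies on:
# spatiotemporally localized grasp events of roughly five seconds, a smooth
# low-frequency temporal bump shared by all active taxels, spatially compact
# Gaussian activation blobs on the sensor grid, a resting ADC level on the
# physically present taxels, additive Gaussian sensor noise, and 10-bit
# integer quantization. It makes no attempt to model per-object grasp
# signatures; it is a statistical stand-in so the whole pipeline can run with
# no external download.

#' Parameters of the synthetic grasp model
#'
#' @param grid_rows,grid_cols Sensor grid size (the tactile-glove class of
#'   arrays packs its taxels into a 32 x 32 matrix).
#' @param n_active_sensors Number of physically present taxels; the remaining
#'   grid positions read identically zero (548 for the glove layout).
#' @param sampling_rate Frames per second.
#' @param duration Recording length in seconds.
#' @param onset_time,offset_time Start and end of the grasp event (seconds);
#'   the envelope is exactly zero outside `[onset_time, offset_time]`.
#' @param peak_pressure Peak grasp amplitude above the resting level, in ADC
#'   counts.
#' @param baseline Resting ADC level of the active taxels (counts). Resistive
#'   tactile arrays rest mid-range rather than at zero, and the survey's
#'   normalized error divides by the raw-signal mean, so the resting level is
#'   part of the operating conditions being emulated.
#' @param n_blobs Number of spatial contact blobs.
#' @param blob_width Spatial Gaussian sigma of a blob, in taxels.
#' @param temporal_smoothness Rise/fall time constant of the envelope
#'   (seconds).
#' @param noise_sd Additive Gaussian sensor noise, in ADC counts.
#' @param bit_depth ADC resolution in bits.
#' @param seed Integer seed; the generated recording is a pure function of
#'   the model (including the seed).
#' @return A validated `grasp_model` object.
#' @export
grasp_model <- function(grid_rows = 32L, grid_cols = 32L,
                        n_active_sensors = 548L, sampling_rate = 16,
                        duration = 8, onset_time = 1.5, offset_time = 6.5,
                        peak_pressure = 400, baseline = 500,
                        n_blobs = 3L, blob_width = 2.5,
                        temporal_smoothness = 0.4, noise_sd = 2,
                        bit_depth = 10L, seed = 1L) {
  model <- structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         n_active_sensors = as.integer(n_active_sensors),
         sampling_rate = sampling_rate, duration = duration,
         onset_time = onset_time, offset_time = offset_time,
         peak_pressure = peak_pressure, baseline = baseline,
         n_blobs = as.integer(n_blobs), blob_width = blob_width,
         temporal_smoothness = temporal_smoothness, noise_sd = noise_sd,
         bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
    class = "grasp_model"
  )
  validate_grasp_model(model)
  model
}

#' @rdname grasp_model
#' @param model A `grasp_model` to validate.
#' @export
validate_grasp_model <- function(model) {
  with(model, {
    if (!(0 < onset_time && onset_time < offset_time && offset_time < duration)) {
      abort("invariant violated: 0 < onset_time < offset_time < duration",
            class = "tactwave_error")
    }
    if (n_active_sensors > grid_rows * grid_cols) {
      abort("invariant violated: n_active_sensors <= grid_rows * grid_cols",
            class = "tactwave_error")
    }
    if (baseline + peak_pressure >= 2^bit_depth) {
      abort("invariant violated: baseline + peak_pressure < 2^bit_depth",
            class = "tactwave_error")
    }
    if (peak_pressure < 0 || noise_sd < 0 || blob_width <= 0 ||
        temporal_smoothness <= 0 || n_blobs < 1L) {
      abort("invariant violated: nonnegative amplitudes, positive widths, n_blobs >= 1",
            class = "tactwave_error")
    }
  })
  invisible(model)
}

# difference-of-logistics bump: smooth rise/plateau/fall, exactly zero outside
# [onset, offset] (the small logistic tails at the edges are subtracted off)
.grasp_envelope <- function(t, onset, offset, tau) {
  mid1 <- onset + 3 * tau
  mid2 <- offset - 3 * tau
  if (mid2 <= mid1) {
    mid <- (onset + offset) / 2
    mid1 <- mid - tau
    mid2 <- mid + tau
  }
  env <- stats::plogis((t - mid1) / tau) - stats::plogis((t - mid2) / tau)
  edge <- max(stats::plogis((onset - mid1) / tau) - stats::plogis((onset - mid2) / tau),
              stats::plogis((offset - mid1) / tau) - stats::plogis((offset - mid2) / tau))
  env <- pmax(env - edge, 0)
  env[t < onset | t > offset] <- 0
  if (max(env) > 0) env <- env / max(env)
  env
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# seeded sensor layout: glove taxels form contiguous patches, so the mask is
# the top-n cells of a smoothed random field rather than independent draws
.layout_mask <- function(model) {
  n_cells <- model$grid_rows * model$grid_cols
  if (model$n_active_sensors == n_cells) {
    return(matrix(TRUE, model$grid_rows, model$grid_cols))
  }
  field <- matrix(stats::rnorm(n_cells), model$grid_rows, model$grid_cols)
  kern <- stats::dnorm(-6:6, sd = 3)
  smooth_axis <- function(m) {
    apply(m, 2L, function(col) {
      as.numeric(stats::filter(c(col, col, col), kern, circular = TRUE))[
        (length(col) + 1L):(2L * length(col))]
    })
  }
  field <- t(smooth_axis(t(smooth_axis(field))))
  mask <- matrix(FALSE, model$grid_rows, model$grid_cols)
  mask[order(field, decreasing = TRUE)[seq_len(model$n_active_sensors)]] <- TRUE
  mask
}

.grasp_fields <- function(model, rng_offset = 0L) {
  # everything random about one trial, drawn from the model's seeded stream
  .with_seed(model$seed + rng_offset, {
    active <- integer(0)
    mask <- .layout_mask(model)
    active <- which(mask)
    centers_idx <- sample(active, model$n_blobs, replace = TRUE)
    list(
      mask = mask,
      center_r = ((centers_idx - 1L) %% model$grid_rows) + 1L + stats::runif(model$n_blobs, -0.5, 0.5),
      center_c = ((centers_idx - 1L) %/% model$grid_rows) + 1L + stats::runif(model$n_blobs, -0.5, 0.5),
      blob_amp = stats::runif(model$n_blobs, 0.6, 1)
    )
  })
}

.spatial_field <- function(model, fields) {
  r <- matrix(seq_len(model$grid_rows), model$grid_rows, model$grid_cols)
  cc <- matrix(seq_len(model$grid_cols), model$grid_rows, model$grid_cols,
               byrow = TRUE)
  s <- matrix(0, model$grid_rows, model$grid_cols)
  for (b in seq_len(model$n_blobs)) {
    s <- s + fields$blob_amp[b] *
      exp(-((r - fields$center_r[b])^2 + (cc - fields$center_c[b])^2) /
            (2 * model$blob_width^2))
  }
  s[!fields$mask] <- 0
  if (max(s) > 0) s <- s / max(s)
  s
}

#' Generate one synthetic grasp recording
#'
#' Per-taxel signal = resting level + smooth unimodal temporal envelope
#' (exactly zero before onset and after offset) x spatial Gaussian blob
#' amplitude x peak pressure + zero-mean Gaussian noise, clipped to the ADC
#' range and rounded to integers. Masked-out grid positions are identically
#' zero. Identical model (including seed) gives a bit-identical recording.
#'
#' @param model A [grasp_model()].
#' @param trial Optional trial index recorded in the metadata (also offsets
#'   the seeded stream when called through [generate_dataset()]).
#' @return A `tactile_recording`.
#' @export
generate_grasp <- function(model, trial = NULL) {
  validate_grasp_model(model)
  fields <- .grasp_fields(model)
  .generate_from_fields(model, fields, model$onset_time, model$offset_time,
                        model$peak_pressure, trial = trial,
                        noise_seed = model$seed * 1000L + 1L)
}

.generate_from_fields <- function(model, fields, onset, offset, peak,
                                  trial = NULL, noise_seed) {
  n_t <- round(model$duration * model$sampling_rate)
  t <- (seq_len(n_t) - 1L) / model$sampling_rate
  env <- .grasp_envelope(t, onset, offset, model$temporal_smoothness)
  s <- .spatial_field(model, fields)
  frames <- model$baseline * array(rep(as.numeric(fields$mask), each = n_t),
                                   dim = c(n_t, model$grid_rows, model$grid_cols)) +
    peak * outer(env, s)
  if (model$noise_sd > 0) {
    noise <- .with_seed(noise_seed,
                        stats::rnorm(length(frames), sd = model$noise_sd))
    noise <- array(noise, dim = dim(frames))
    noise[rep(!fields$mask, each = n_t)] <- 0
    frames <- frames + noise
  }
  frames <- round(pmin(pmax(frames, 0), 2^model$bit_depth - 1))
  meta <- list(provenance = "synthetic")
  if (!is.null(trial)) meta$trial <- as.character(trial)
  tactile_recording(frames, fields$mask, model$sampling_rate,
                    model$bit_depth, meta)
}

#' Generate a seeded multi-trial synthetic dataset
#'
#' Repeats the grasp of [generate_grasp()] with per-trial jitter of the onset
#' time, the peak amplitude and the blob centers, all drawn from the model's
#' seeded stream; the sensor mask is the fixed property of the array and does
#' not vary across trials. Trial indices are recorded in the metadata.
#'
#' @param model A [grasp_model()].
#' @param n_trials Number of recordings.
#' @param jitter List with elements `onset_sd` (seconds), `amplitude_sd`
#'   (fraction of the peak) and `center_sd` (taxels); zero entries disable
#'   that jitter.
#' @return List of `tactile_recording` objects.
#' @export
generate_dataset <- function(model, n_trials,
                             jitter = list(onset_sd = 0.3, amplitude_sd = 0.1,
                                           center_sd = 1)) {
  validate_grasp_model(model)
  if (n_trials < 1L) abort("n_trials must be >= 1", class = "tactwave_error")
  jit <- utils::modifyList(list(onset_sd = 0, amplitude_sd = 0, center_sd = 0),
                           as.list(jitter))
  base_fields <- .grasp_fields(model)
  draws <- .with_seed(model$seed + 7919L, {
    lapply(seq_len(n_trials), function(i) {
      list(dt = stats::rnorm(1, 0, jit$onset_sd),
           amp = stats::rnorm(1, 0, jit$amplitude_sd),
           dr = stats::rnorm(model$n_blobs, 0, jit$center_sd),
           dc = stats::rnorm(model$n_blobs, 0, jit$center_sd))
    })
  })
  no_jitter <- jit$onset_sd == 0 && jit$amplitude_sd == 0 && jit$center_sd == 0
  lapply(seq_len(n_trials), function(i) {
    dr <- draws[[i]]
    fields <- base_fields
    fields$center_r <- pmin(pmax(fields$center_r + dr$dr, 1), model$grid_rows)
    fields$center_c <- pmin(pmax(fields$center_c + dr$dc, 1), model$grid_cols)
    dt <- min(max(dr$dt, -model$onset_time + 1e-3),
              model$duration - model$offset_time - 1e-3)
    peak <- model$peak_pressure * max(1 + dr$amp, 0)
    peak <- min(peak, 2^model$bit_depth - 1 - model$baseline)
    # zero jitter means exact replicate trials (shared noise realization)
    noise_seed <- model$seed * 1000L + if (no_jitter) 1L else i
    .generate_from_fields(model, fields,
                          model$onset_time + dt, model$offset_time + dt,
                          peak, trial = i, noise_seed = noise_seed)
  })
}
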