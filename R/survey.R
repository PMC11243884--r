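# The full wavelet x dimensionality x error-target sweep.

#' Run the sparsification survey
#'
#' For every combination of candidate wavelet, transform dimensionality and
#' target NMSE, runs the quantization-step search per recording and averages
#' the metrics (achieved NMSE, Q, sparsity, bits per pixel, energy ratio)
#' arithmetically across recordings. The discrete cosine baseline is included
#' per dimensionality when `include_dct` is on. Deterministic given the
#' dataset and settings; failures and non-convergence are recorded per cell
#' in a `status` column, never silently dropped.
#'
#' @param dataset A list of `tactile_recording`s (or a single one).
#' @param wavelets Character vector of registry names; defaults to every
#'   implemented registry wavelet.
#' @param dimensionalities Subset of `1:3`.
#' @param targets NMSE targets; the survey's four values by default.
#' @param include_dct Add the DCT baseline rows.
#' @param denoise Low-pass denoise the recordings first (the survey's
#'   preprocessing); disable if the dataset is already preprocessed.
#' @param tolerance_factor Convergence band as a fraction of each target.
#' @param max_iterations Bisection budget per cell and recording.
#' @param progress Print one line per survey cell.
#' @return A `survey_table` tibble: one row per (wavelet, dimensionality,
#'   target), with attributes recording the dataset fingerprint and settings.
#' @export
run_survey <- function(dataset, wavelets = NULL, dimensionalities = 1:3,
                       targets = c(0.01, 0.0043, 0.0015, 0.0001),
                       include_dct = TRUE, denoise = TRUE,
                       tolerance_factor = 1e-4, max_iterations = 60L,
                       progress = FALSE) {
  if (inherits(dataset, "tactile_recording")) dataset <- list(dataset)
  if (!length(dataset)) {
    abort("dataset is empty", class = "tactwave_error")
  }
  lapply(dataset, validate_recording)
  if (is.null(wavelets)) wavelets <- implemented_wavelets()
  reg <- wavelet_registry()
  if (denoise) dataset <- lapply(dataset, lowpass_denoise)
  candidates <- c(as.list(wavelets), if (include_dct) list("dct"))
  rows <- list()
  for (w in candidates) {
    fam <- if (identical(w, "dct")) "DCT" else reg$family[match(w, reg$name)]
    for (dm in dimensionalities) {
      # one forward transform per recording, shared across the targets
      css <- lapply(dataset, function(rec) {
        tryCatch(.forward_transform(rec$frames, w, dm), error = identity)
      })
      for (tg in targets) {
        per_rec <- purrr::map2(css, dataset, function(cs, rec) {
          if (inherits(cs, "error")) return(cs)
          tryCatch({
            r <- .search_q_core(cs, rec$frames, tg, tolerance_factor * tg,
                                max_iterations)
            b <- r$best
            list(achieved_nmse = b$nmse, q = b$q,
                 sparsity = sparsity_of(b$qz),
                 bits_per_pixel = bits_per_pixel(b$qz, b$q),
                 energy_ratio = energy_ratio(b$qz, cs),
                 iterations = r$iterations, converged = r$converged)
          }, error = identity)
        })
        errs <- purrr::map_lgl(per_rec, inherits, "error")
        row <- tibble::tibble(
          wavelet = if (identical(w, "dct")) "dct" else w,
          family = fam,
          transform = if (identical(w, "dct")) "dct" else "dwt",
          dimensionality = as.integer(dm),
          target_nmse = tg
        )
        if (all(errs)) {
          row$achieved_nmse <- NA_real_; row$q <- NA_real_
          row$sparsity <- NA_real_; row$bits_per_pixel <- NA_real_
          row$energy_ratio <- NA_real_; row$iterations <- NA_real_
          row$n_recordings <- 0L
          row$status <- paste0("error: ", conditionMessage(per_rec[[1]]))
        } else {
          ok <- per_rec[!errs]
          m <- function(f) mean(purrr::map_dbl(ok, f))
          row$achieved_nmse <- m("achieved_nmse")
          row$q <- m("q")
          row$sparsity <- m("sparsity")
          row$bits_per_pixel <- m("bits_per_pixel")
          row$energy_ratio <- m("energy_ratio")
          row$iterations <- m("iterations")
          row$n_recordings <- length(ok)
          all_conv <- all(purrr::map_lgl(ok, "converged"))
          row$status <- if (!all_conv) "unconverged"
                        else if (any(errs)) "partial" else "converged"
        }
        if (progress) {
          message(sprintf("survey: %s %sD target %g -> %s",
                          row$wavelet, dm, tg, row$status))
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "dataset_id") <- rlang::hash(lapply(dataset, function(r) r$frames))
  attr(out, "n_recordings") <- length(dataset)
  attr(out, "denoise") <- denoise
  class(out) <- c("survey_table", class(out))
  out
}

#' Rank survey cells by a metric
#'
#' Top candidates for one dimensionality at one target: ascending for
#' `sparsity` and `nbp` (smaller is better), descending for `energy_ratio`.
#' Only converged wavelet cells are ranked (the DCT baseline and unconverged
#' cells are excluded); ties break lexicographically by wavelet name.
#'
#' @param table A `survey_table`.
#' @param dimensionality 1, 2 or 3.
#' @param metric `"sparsity"`, `"nbp"` or `"energy_ratio"`.
#' @param top_k Number of entries to return (all converged entries if fewer).
#' @param target NMSE target to rank at (default 0.01, the coarse survey
#'   setting).
#' @return Tibble of the top rows with a `rank` column.
#' @export
rank_by <- function(table, dimensionality, metric = c("sparsity", "nbp",
                                                      "energy_ratio"),
                    top_k = 5L, target = 0.01) {
  metric <- match.arg(metric)
  col <- c(sparsity = "sparsity", nbp = "bits_per_pixel",
           energy_ratio = "energy_ratio")[[metric]]
  tb <- dplyr::filter(tibble::as_tibble(table),
                      .data$transform == "dwt",
                      .data$dimensionality == !!dimensionality,
                      .data$target_nmse == !!target,
                      .data$status == "converged")
  tb <- if (metric == "energy_ratio") {
    dplyr::arrange(tb, dplyr::desc(.data[[col]]), .data$wavelet)
  } else {
    dplyr::arrange(tb, .data[[col]], .data$wavelet)
  }
  tb <- utils::head(tb, top_k)
  dplyr::mutate(tb, rank = dplyr::row_number(), .before = 1L)
}

#' Sparsity ratio of the DCT baseline to the best wavelet
#'
#' How many times sparser the best discrete wavelet transform is than the
#' conventional sparsifying DCT for a given dimensionality and error target:
#' `(DCT sparsity) / (best DWT sparsity)`.
#'
#' @param table A `survey_table` containing both the DCT row and at least one
#'   converged DWT row for the requested cell.
#' @param dimensionality 1, 2 or 3.
#' @param target NMSE target.
#' @return A single ratio (`> 1` means the wavelet is sparser).
#' @export
dct_sparsity_ratio <- function(table, dimensionality, target = 0.01) {
  tb <- tibble::as_tibble(table)
  dct <- dplyr::filter(tb, .data$transform == "dct",
                       .data$dimensionality == !!dimensionality,
                       .data$target_nmse == !!target)
  dwt <- dplyr::filter(tb, .data$transform == "dwt",
                       .data$dimensionality == !!dimensionality,
                       .data$target_nmse == !!target,
                       .data$status == "converged")
  if (nrow(dct) != 1L || !nrow(dwt)) {
    abort("table lacks the DCT baseline or a converged DWT entry for this cell",
          class = "tactwave_error")
  }
  dct$sparsity / min(dwt$sparsity)
}

#' @rdname run_survey
#' @param x A `survey_table`.
#' @param ... Unused.
#' @export
glance.survey_table <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  tibble::tibble(
    n_cells = nrow(tb),
    n_converged = sum(tb$status == "converged"),
    n_unconverged = sum(tb$status == "unconverged"),
    n_error = sum(startsWith(tb$status, "error")),
    n_wavelets = length(unique(tb$wavelet[tb$transform == "dwt"])),
    n_recordings = attr(x, "n_recordings") %||% NA_integer_,
    dataset_id = attr(x, "dataset_id") %||% NA_character_
  )
}

#' @rdname run_survey
#' @export
tidy.survey_table <- function(x, ...) {
  tibble::as_tibble(x)
}
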