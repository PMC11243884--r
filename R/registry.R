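#' @useDynLib tactwave, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data abort
#' @importFrom tibble tibble as_tibble
NULL

.tw_env <- new.env(parent = emptyenv())

.load_filter_table <- function() {
  if (!is.null(.tw_env$filters)) {
    return(.tw_env$filters)
  }
  path <- system.file("extdata", "wavelet_filters.csv", package = "tactwave")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "integer",
                                        "character", "integer", "character",
                                        "character"))
  raw$support <- suppressWarnings(as.integer(raw$support))
  .tw_env$filters <- raw
  raw
}

.parse_taps <- function(s) as.numeric(strsplit(s, " ", fixed = TRUE)[[1]])

#' The wavelet registry
#'
#' Enumerates the 75 candidate wavelets of the sparsification survey, grouped
#' into 12 families spanning orthogonal (Daubechies including Haar, Symlets,
#' Coiflets, Fejér-Korovkin, best-localized Daubechies, Morris
#' minimum-bandwidth, Beylkin, Vaidyanathan, Han linear-phase moments,
#' discrete Meyer) and biorthogonal spline (BiorSplines and their reversed
#' duals) constructions. A registry entry is `implemented` when its published
#' filter taps could be sourced from a standard filter-coefficient reference;
#' the MATLAB-only families (Fejér-Korovkin, best-localized Daubechies, Morris
#' minimum-bandwidth, Han) are listed but flagged unimplemented, and
#' [wavelet_filter()] refuses to build them.
#'
#' @return A tibble with one row per wavelet: `name`, `family`, `orthogonal`,
#'   `support_length` (number of filter taps, `NA` where unknown) and
#'   `implemented`.
#' @seealso [wavelet_filter()] for the filter quadruple of a single wavelet.
#' @export
#' @examples
#' reg <- wavelet_registry()
#' nrow(reg)                      # 75 candidates
#' length(unique(reg$family))     # 12 families
wavelet_registry <- function() {
  raw <- .load_filter_table()
  tibble::tibble(
    name = raw$name,
    family = raw$family,
    orthogonal = raw$orthogonal == 1L,
    support_length = raw$support,
    implemented = raw$implemented == 1L
  )
}

#' Look up one wavelet's analysis/synthesis filter quadruple
#'
#' Builds the four filters of the two-channel filter bank: decomposition
#' low/high-pass (`dec_lo`, `dec_hi`) and reconstruction low/high-pass
#' (`rec_lo`, `rec_hi`). Only the two low-pass prototypes are stored on disk;
#' the high-pass filters follow from the standard alternating-sign (quadrature
#' mirror) relations, so every quadruple satisfies the perfect-reconstruction
#' conditions by construction. For orthogonal wavelets the reconstruction
#' filters are the time-reversed decomposition filters.
#'
#' @param name Wavelet name as listed by [wavelet_registry()], e.g. `"sym4"`.
#' @return A `wavelet_spec` object: a list with `name`, `family`,
#'   `orthogonal`, `support_length` and the four numeric tap vectors.
#' @export
#' @examples
#' w <- wavelet_filter("haar")
#' w$support_length  # 2
wavelet_filter <- function(name) {
  raw <- .load_filter_table()
  i <- match(name, raw$name)
  if (is.na(i)) {
    abort(paste0("unknown wavelet '", name, "'"), class = "tactwave_error")
  }
  if (raw$implemented[i] != 1L) {
    abort(paste0("wavelet '", name, "' (family ", raw$family[i],
                 ") is registered but its filter taps are not available"),
          class = "tactwave_error")
  }
  key <- paste0("spec_", name)
  if (!is.null(.tw_env[[key]])) {
    return(.tw_env[[key]])
  }
  dec_lo <- .parse_taps(raw$dec_lo[i])
  rec_lo <- .parse_taps(raw$rec_lo[i])
  m <- seq_along(rec_lo)
  dec_hi <- (-1)^m * rec_lo
  rec_hi <- (-1)^(m + 1) * dec_lo
  spec <- structure(
    list(name = raw$name[i], family = raw$family[i],
         orthogonal = raw$orthogonal[i] == 1L,
         support_length = length(dec_lo),
         dec_lo = dec_lo, dec_hi = dec_hi,
         rec_lo = rec_lo, rec_hi = rec_hi),
    class = "wavelet_spec"
  )
  .tw_env[[key]] <- spec
  spec
}

.as_wavelet_spec <- function(wavelet) {
  if (inherits(wavelet, "wavelet_spec")) {
    return(wavelet)
  }
  if (is.character(wavelet) && length(wavelet) == 1L) {
    return(wavelet_filter(wavelet))
  }
  abort("`wavelet` must be a wavelet name or a wavelet_spec", class = "tactwave_error")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> %s (%s), %s, %d taps\n", x$name, x$family,
              if (x$orthogonal) "orthogonal" else "biorthogonal",
              x$support_length))
  invisible(x)
}

#' Names of the implemented registry wavelets
#'
#' Convenience accessor: registry names with available filter taps, optionally
#' restricted to orthogonal wavelets.
#'
#' @param orthogonal_only Keep only orthogonal wavelets.
#' @return Character vector of wavelet names.
#' @export
implemented_wavelets <- function(orthogonal_only = FALSE) {
  reg <- wavelet_registry()
  reg <- reg[reg$implemented & (!orthogonal_only | reg$orthogonal), ]
  reg$name
}
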