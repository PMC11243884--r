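# Plain-text container for tactile recordings ("csv-stack") plus an R-native
# RDS convenience format, and the survey-table CSV writer.
#
# csv-stack layout: '#'-prefixed header lines carry sampling_rate, bit_depth,
# the row-major 0/1 sensor mask and a JSON metadata map; the body stacks the
# frames in time order, one frame = `rows` lines of `cols` comma-separated
# values. Indices are 0-based in the header documentation; time is the first
# axis throughout.

.supported_formats <- c("csv", "rds")

.infer_format <- function(path, format) {
  if (!is.null(format)) {
    format <- match.arg(format, c(.supported_formats, "hdf5", "mat", "npz"))
    if (!format %in% .supported_formats) {
      abort(paste0("format '", format, "' is not supported by this build; ",
                   "use one of: ", paste(.supported_formats, collapse = ", ")),
            class = "tactwave_error")
    }
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% .supported_formats) ext else "csv"
}

#' Write a tactile recording to disk
#'
#' @param rec A `tactile_recording`.
#' @param path Output file path.
#' @param format `"csv"` (the plain-text csv-stack container, default) or
#'   `"rds"`. Inferred from the file extension when omitted.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path, format = NULL) {
  validate_recording(rec)
  format <- .infer_format(path, format)
  if (format == "rds") {
    saveRDS(rec, path)
    return(invisible(path))
  }
  d <- dim(rec$frames)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# tactwave csv-stack v1"),
    sprintf("# shape: %d %d %d", d[1L], d[2L], d[3L]),
    sprintf("# sampling_rate: %.17g", rec$sampling_rate),
    sprintf("# bit_depth: %d", rec$bit_depth),
    sprintf("# mask: %s", paste(as.integer(t(rec$sensor_mask)), collapse = "")),
    sprintf("# metadata: %s", jsonlite::toJSON(rec$metadata, auto_unbox = TRUE))
  ), con)
  for (i in seq_len(d[1L])) {
    frame <- rec$frames[i, , , drop = TRUE]
    writeLines(apply(matrix(sprintf("%.17g", frame), d[2L], d[3L]), 1L,
                     paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read a tactile recording from disk
#'
#' @param path Input file path.
#' @param format See [write_recording()].
#' @return A validated `tactile_recording`.
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tactwave_io_error")
  }
  format <- .infer_format(path, format)
  if (format == "rds") {
    rec <- readRDS(path)
    validate_recording(rec)
    return(rec)
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (length(ln) != 1L) {
      abort(paste0("corrupt csv-stack file: missing header field '", key, "'"),
            class = "tactwave_io_error")
    }
    trimws(sub(paste0("# ", key, ":"), "", ln, fixed = TRUE))
  }
  shape <- as.integer(strsplit(get_field("shape"), " ")[[1]])
  if (length(shape) != 3L || any(is.na(shape))) {
    abort("corrupt csv-stack file: bad shape header", class = "tactwave_io_error")
  }
  mask_bits <- strsplit(get_field("mask"), "")[[1]] == "1"
  if (length(mask_bits) != shape[2L] * shape[3L]) {
    abort("field 'sensor_mask': shape must equal the spatial frame shape",
          class = "tactwave_error")
  }
  mask <- matrix(mask_bits, shape[2L], shape[3L], byrow = TRUE)
  meta_json <- get_field("metadata")
  metadata <- if (nzchar(meta_json)) {
    lapply(jsonlite::fromJSON(meta_json), as.character)
  } else {
    list()
  }
  body <- body[nzchar(body)]
  if (length(body) != shape[1L] * shape[2L]) {
    abort("corrupt csv-stack file: frame line count does not match shape",
          class = "tactwave_io_error")
  }
  vals <- as.numeric(unlist(strsplit(body, ",", fixed = TRUE), use.names = FALSE))
  if (length(vals) != prod(shape) || anyNA(vals)) {
    abort("corrupt csv-stack file: value count does not match shape",
          class = "tactwave_io_error")
  }
  # body order: frame-major, row within frame, col within row
  frames <- aperm(array(vals, dim = c(shape[3L], shape[2L], shape[1L])),
                  c(3L, 2L, 1L))
  tactile_recording(frames, mask, as.numeric(get_field("sampling_rate")),
                    as.integer(get_field("bit_depth")), metadata)
}

#' Write a survey table to CSV
#'
#' One row per survey cell, stable column order, full float precision, header
#' row; an empty table yields a header-only CSV.
#'
#' @param table A `survey_table` (or plain data frame of results).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  cols <- c("wavelet", "family", "transform", "dimensionality", "target_nmse",
            "achieved_nmse", "q", "sparsity", "bits_per_pixel", "energy_ratio",
            "iterations", "n_recordings", "status")
  tb <- tibble::as_tibble(table)
  for (mc in setdiff(cols, names(tb))) tb[[mc]] <- rep(NA, nrow(tb))
  readr::write_csv(tb[, cols], path)
  invisible(path)
}
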