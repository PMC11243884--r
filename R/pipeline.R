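# Config-driven pipeline commands. One declarative YAML file is the single
# source of truth for a run; each command logs the config hash and seed so
# results can be reproduced byte for byte. A thin command-line wrapper around
# these functions is installed under inst/scripts/tactwave.

.read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "tactwave_io_error")
  }
  cfg <- yaml::read_yaml(path)
  attr(cfg, "hash") <- rlang::hash(cfg)
  cfg
}

.cfg <- function(cfg, key, default = NULL) {
  val <- cfg
  for (k in strsplit(key, ".", fixed = TRUE)[[1]]) {
    val <- val[[k]]
    if (is.null(val)) return(default)
  }
  val
}

.log_run <- function(cmd, cfg, extra = character()) {
  message(sprintf("[tactwave %s] config_hash=%s seed=%s %s", cmd,
                  attr(cfg, "hash") %||% "none",
                  .cfg(cfg, "seed", "default"),
                  paste(extra, collapse = " ")))
}

.model_from_config <- function(cfg) {
  sim <- .cfg(cfg, "simulate", list())
  defaults <- formals(grasp_model)
  args <- lapply(names(defaults), function(nm) {
    v <- sim[[nm]]
    if (is.null(v)) eval(defaults[[nm]]) else v
  })
  names(args) <- names(defaults)
  if (is.null(sim$seed) && !is.null(cfg$seed)) args$seed <- cfg$seed
  if (is.null(sim$seed) && is.null(cfg$seed)) {
    message("[tactwave simulate] no seed in config; using default seed ", args$seed)
  }
  do.call(grasp_model, args)
}

#' Pipeline commands
#'
#' Config-driven entry points tying the modules together: `pipeline_simulate`
#' writes a seeded synthetic dataset, `pipeline_preprocess` denoises stored
#' recordings, `pipeline_survey` runs the sweep and writes the survey CSV
#' (with `#` metadata header lines carrying the config hash),
#' `pipeline_diagnose` writes the diagnostic CSVs, and `pipeline_report`
#' writes the ranked top-k summary. All accept the same YAML config; every
#' run logs its config hash and seed.
#'
#' @param config Path to the YAML config file.
#' @param out_dir,dataset_dir,out_csv,table_csv,out_md Input/output locations.
#' @return The written paths, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config, out_dir) {
  cfg <- .read_config(config)
  model <- .model_from_config(cfg)
  n_trials <- .cfg(cfg, "simulate.n_trials", 1L)
  jitter <- .cfg(cfg, "simulate.jitter",
                 list(onset_sd = 0.3, amplitude_sd = 0.1, center_sd = 1))
  .log_run("simulate", cfg, sprintf("n_trials=%d", n_trials))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- generate_dataset(model, n_trials, jitter)
  paths <- purrr::imap_chr(dataset, function(rec, i) {
    p <- file.path(out_dir, sprintf("trial_%03d.csv", i))
    write_recording(rec, p)
    p
  })
  invisible(paths)
}

.read_dataset_dir <- function(dataset_dir) {
  files <- sort(list.files(dataset_dir, pattern = "\\.(csv|rds)$",
                           full.names = TRUE))
  if (!length(files)) {
    abort(paste0("no recordings found under ", dataset_dir),
          class = "tactwave_io_error")
  }
  lapply(files, read_recording)
}

#' @rdname pipeline
#' @export
pipeline_preprocess <- function(config, dataset_dir, out_dir) {
  cfg <- .read_config(config)
  .log_run("preprocess", cfg)
  dataset <- .read_dataset_dir(dataset_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- purrr::imap_chr(dataset, function(rec, i) {
    den <- lowpass_denoise(rec,
                           order = .cfg(cfg, "denoise.order", 2L),
                           cutoff_fraction = .cfg(cfg, "denoise.cutoff_fraction", 1 / 7),
                           causal = .cfg(cfg, "denoise.causal", FALSE))
    p <- file.path(out_dir, sprintf("denoised_%03d.rds", i))
    write_recording(den, p, format = "rds")
    p
  })
  invisible(out)
}

#' @rdname pipeline
#' @export
pipeline_survey <- function(config, dataset_dir, out_csv) {
  cfg <- .read_config(config)
  dataset <- .read_dataset_dir(dataset_dir)
  already_denoised <- all(purrr::map_lgl(dataset, function(r) {
    isTRUE(r$metadata$denoised == "true")
  }))
  table <- run_survey(
    dataset,
    wavelets = .cfg(cfg, "transform.wavelets", implemented_wavelets()),
    dimensionalities = .cfg(cfg, "transform.dimensionalities", 1:3),
    targets = .cfg(cfg, "sparsify.targets", c(0.01, 0.0043, 0.0015, 0.0001)),
    include_dct = .cfg(cfg, "survey.include_dct", TRUE),
    denoise = !already_denoised,
    tolerance_factor = .cfg(cfg, "sparsify.tolerance", 1e-4),
    max_iterations = .cfg(cfg, "sparsify.max_iterations", 60L),
    progress = .cfg(cfg, "survey.progress", FALSE)
  )
  g <- glance(table)
  .log_run("survey", cfg, sprintf("cells=%d converged=%d", g$n_cells,
                                  g$n_converged))
  dir.create(dirname(out_csv), recursive = TRUE, showWarnings = FALSE)
  hdr <- c(
    sprintf("# tactwave survey v%s", as.character(utils::packageVersion("tactwave"))),
    sprintf("# config_hash: %s", attr(cfg, "hash")),
    sprintf("# dataset_id: %s", attr(table, "dataset_id")),
    sprintf("# seed: %s", .cfg(cfg, "seed", "default"))
  )
  writeLines(hdr, out_csv)
  tmp <- tempfile(fileext = ".csv")
  write_table(table, tmp)
  file.append(out_csv, tmp)
  unlink(tmp)
  invisible(out_csv)
}

#' @rdname pipeline
#' @export
pipeline_diagnose <- function(config, dataset_dir, table_csv, out_dir) {
  cfg <- .read_config(config)
  .log_run("diagnose", cfg)
  if (!file.exists(table_csv)) {
    abort(paste0("survey table not found: ", table_csv),
          class = "tactwave_io_error")
  }
  dataset <- .read_dataset_dir(dataset_dir)
  table <- readr::read_csv(table_csv, comment = "#", show_col_types = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  idx <- .cfg(cfg, "diagnose.recording_index", 1L)
  rec <- lowpass_denoise(dataset[[min(idx, length(dataset))]])
  wavelet <- .cfg(cfg, "diagnose.wavelet", "sym4")
  k_values <- .cfg(cfg, "diagnose.k_values",
                   round(seq(0, length(rec$frames), length.out = 12L)))
  if (!length(k_values)) {
    abort("diagnose.k_values is empty", class = "tactwave_error")
  }
  curve <- topk_reconstruction_curve(rec$frames, wavelet, 1L, k_values)
  readr::write_csv(curve$curve, file.path(out_dir, "compactness_curve.csv"))
  sr <- search_q(rec$frames, wavelet, 1L,
                 target_nmse = .cfg(cfg, "diagnose.target", 0.01),
                 keep_recon = TRUE)
  prof <- spatiotemporal_error_profile(rec$frames, sr$recon, rec$sensor_mask)
  readr::write_csv(prof$temporal, file.path(out_dir, "temporal_error.csv"))
  readr::write_csv(prof$spatial, file.path(out_dir, "spatial_error.csv"))
  readr::write_csv(prof$summary, file.path(out_dir, "error_summary.csv"))
  if (length(dataset) >= 2L) {
    ga <- grand_average_interaction(dataset)
    readr::write_csv(ga$template, file.path(out_dir, "grand_average.csv"))
  }
  trend <- tryCatch(filter_length_vs_sparsity(table, 1L,
                                              .cfg(cfg, "diagnose.target", 0.01)),
                    error = function(e) NULL)
  if (!is.null(trend)) {
    readr::write_csv(trend, file.path(out_dir, "filter_length_trend.csv"))
  }
  invisible(out_dir)
}

#' @rdname pipeline
#' @export
pipeline_report <- function(table_csv, out_md) {
  if (!file.exists(table_csv)) {
    abort(paste0("survey table not found: ", table_csv),
          class = "tactwave_io_error")
  }
  table <- readr::read_csv(table_csv, comment = "#", show_col_types = FALSE)
  lines <- c("# Sparsification survey report", "")
  for (dm in sort(unique(table$dimensionality))) {
    for (metric in c("sparsity", "nbp", "energy_ratio")) {
      top <- tryCatch(rank_by(table, dm, metric), error = function(e) NULL)
      if (is.null(top) || !nrow(top)) next
      lines <- c(lines, sprintf("## %dD, ranked by %s", dm, metric), "")
      col <- c(sparsity = "sparsity", nbp = "bits_per_pixel",
               energy_ratio = "energy_ratio")[[metric]]
      lines <- c(lines, sprintf("%d. %s = %.6g (%s)", top$rank,
                                top$wavelet, top[[col]], top$family), "")
    }
  }
  writeLines(lines, out_md)
  invisible(out_md)
}
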