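#' Read a run configuration file
#'
#' YAML (JSON-compatible) configuration for the full pipeline. Missing fields
#' fall back to the standard defaults: 1536 format, 5-point regression window,
#' median window 5 / Gaussian sigma 1.5 smoothing, 2 px safety margin,
#' surface bandwidth 4 grid units, alpha 0.05, seed 1.
#'
#' @param path Config file, or \code{NULL} for pure defaults.
#' @return Named list of class \code{run_config}.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(format = 1536L, window = 5L, median_window = 5L,
                   gaussian_sigma = 1.5, margin = 2L, bandwidth = 4,
                   alpha = 0.05, seed = 1L, contrast_guard = 5,
                   opacity_calibration = NULL, cell_calibration = NULL,
                   output_dir = ".")
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  }
  if (!cfg$format %in% c(96L, 384L, 1536L)) {
    stop("config error: format must be 96, 384 or 1536", call. = FALSE)
  }
  for (nm in c("opacity_calibration", "cell_calibration")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]])) {
      stop("config error: ", nm, " file not found: ", cfg[[nm]],
           call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration snapshot
#'
#' @param config A \code{run_config}.
#' @param path Output path (YAML).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write / read a growth-curve series table
#'
#' @param series Data frame from \code{\link{analyze_series}}.
#' @param path CSV path.
#' @name series_csv
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname series_csv
#' @export
read_series_csv <- function(path) {
  utils::read.csv(path)
}

#' Run the full analysis pipeline on a plate
#'
#' From either an image series or a pre-extracted curve table: (1) extract raw
#' growth curves (grid detection on the last image, reverse-chronological
#' measurement), (2) smooth curves and extract minimum doubling times with
#' quality flags, (3) filter control outliers, build the normalization
#' surface and compute relative phenotypes, (4) run the adjacency bias
#' diagnostics before and after normalization. All outputs are written under
#' \code{config$output_dir}.
#'
#' @param config A \code{run_config} (see \code{\link{read_run_config}}).
#' @param images Optional list of \code{\link{opacity_image}}.
#' @param series Optional curve table (used when \code{images} is NULL).
#' @param cell_cal A \code{cell_cal}; defaults to the config's serialized
#'   calibration, or an identity-slope linear calibration.
#' @return List: \code{series}, \code{features}, \code{phenotypes},
#'   \code{surface}, \code{report_raw}, \code{report_norm}, \code{paths}.
#' @export
run_pipeline <- function(config, images = NULL, series = NULL,
                         cell_cal = NULL) {
  stopifnot(inherits(config, "run_config"))
  layout <- plate_layout(config$format)
  if (is.null(cell_cal)) {
    cell_cal <- if (!is.null(config$cell_calibration)) {
      read_calibration(config$cell_calibration)
    } else {
      structure(list(coefficients = c(0, 1), degree = 1L,
                     constrained_zero = TRUE, fit_range = c(0, 1e9), rmse = 0),
                class = "cell_cal")
    }
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$output_dir, f)
  if (is.null(series)) {
    if (is.null(images)) stop("supply images or a curve series", call. = FALSE)
    series <- analyze_series(images, layout, cell_cal,
                             margin = config$margin,
                             contrast_guard = config$contrast_guard)
  }
  write_series_csv(series, out_path("curves.csv"))
  curves <- series_to_curves(series)
  features <- extract_features_all(curves,
                                   median_window = config$median_window,
                                   gaussian_sigma = config$gaussian_sigma,
                                   window = config$window)
  features <- flag_curves(features)
  utils::write.csv(features, out_path("features.csv"), row.names = FALSE)
  ctrl <- control_positions(layout)
  ctrl_feat <- merge(ctrl, features, by = c("row", "col"))
  retained <- filter_control_outliers(ctrl_feat[, c("row", "col", "dt_min_hr")])
  surface <- build_surface(layout, retained, bandwidth = config$bandwidth)
  phenotypes <- normalize_plate(features, surface)
  utils::write.csv(phenotypes, out_path("phenotypes.csv"), row.names = FALSE)
  to_matrix <- function(v, rw, cl) {
    m <- matrix(NA_real_, layout$rows, layout$cols)
    m[cbind(rw + 1L, cl + 1L)] <- v
    m
  }
  dt_mat <- to_matrix(features$dt_min_hr, features$row, features$col)
  ph_mat <- to_matrix(phenotypes$rel_phenotype_log2, phenotypes$row,
                      phenotypes$col)
  # the adjacency test needs >= 100 experimental positions (not met on 96)
  try_report <- function(m) {
    tryCatch(adjacency_fp_rate(layout, m, alpha = config$alpha),
             error = function(e) NULL)
  }
  report_raw <- try_report(dt_mat)
  report_norm <- try_report(ph_mat)
  rep_entry <- function(r) {
    if (is.null(r)) list(fp_rate = NA, n_tested = 0L)
    else list(fp_rate = r$fp_rate, n_tested = r$n_tested)
  }
  rep_json <- list(
    raw = rep_entry(report_raw),
    normalized = rep_entry(report_norm),
    alpha = config$alpha,
    flagged_fraction = attr(features, "flagged_fraction"),
    controls_removed_fraction = attr(retained, "removed_fraction"))
  jsonlite::write_json(rep_json, out_path("bias_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_config(config, out_path("config_snapshot.yaml"))
  list(series = series, features = features, phenotypes = phenotypes,
       surface = surface, report_raw = report_raw, report_norm = report_norm,
       paths = vapply(c("curves.csv", "features.csv", "phenotypes.csv",
                        "bias_report.json", "config_snapshot.yaml"),
                      out_path, character(1L)))
}
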