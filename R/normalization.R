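#' Remove control colonies with extreme doubling times
#'
#' Controls outside median +/- 3 scaled-MAD of log2(doubling time) are removed
#' before the normalization surface is interpolated; a surface built on
#' outlier controls would imprint their error on every neighbor.
#'
#' @param controls Data frame with columns \code{row}, \code{col},
#'   \code{dt_min_hr}.
#' @param n_mad Removal threshold in scaled-MAD units (default 3).
#' @return The retained rows; removed rows are attached as attribute
#'   \code{removed}, the removed fraction as \code{removed_fraction}. Aborts
#'   when more than half of the controls would be removed.
#' @export
filter_control_outliers <- function(controls, n_mad = 3) {
  stopifnot(all(c("row", "col", "dt_min_hr") %in% names(controls)))
  ok <- is.finite(controls$dt_min_hr) & controls$dt_min_hr > 0
  controls <- controls[ok, , drop = FALSE]
  if (nrow(controls) < 8L) {
    stop("need at least 8 controls with finite doubling times", call. = FALSE)
  }
  ld <- log2(controls$dt_min_hr)
  med <- stats::median(ld)
  s <- stats::mad(ld)                      # scaled MAD (x1.4826)
  keep <- abs(ld - med) <= n_mad * s
  frac <- mean(!keep)
  if (frac > 0.5) {
    stop(sprintf(
      "control filtering removed %.0f%% of controls; surface untrustworthy",
      100 * frac), call. = FALSE)
  }
  out <- controls[keep, , drop = FALSE]
  attr(out, "removed") <- controls[!keep, , drop = FALSE]
  attr(out, "removed_fraction") <- frac
  out
}

#' Interpolate the spatial normalization surface from control colonies
#'
#' The retained controls' log2 doubling times are interpolated into a smooth
#' per-position expectation, evaluated at every plate position including the
#' control-free edges (row 0, col 0), where the surface is a mild
#' extrapolation and the correction is necessarily weaker. Working in log2
#' space makes multiplicative spatial bias additive; the result is
#' exponentiated back to hours.
#'
#' Two smoothers are available. The default, \code{"tps"}, fits a thin-plate
#' regression spline over (row, col) with REML smoothness selection: it tracks
#' smooth bias fields essentially exactly while shrinking independent control
#' noise toward a flat surface. \code{"kernel"} is a Gaussian-kernel weighted
#' mean with fixed bandwidth (grid units; default 4 = two tetrad spacings);
#' it is simpler but attenuates even very smooth fields appreciably, leaving
#' part of the bias in place, and is kept for comparison.
#'
#' @param layout A \code{\link{plate_layout}}.
#' @param controls Retained controls (data frame \code{row}, \code{col},
#'   \code{dt_min_hr}), e.g. from \code{\link{filter_control_outliers}}.
#' @param method \code{"tps"} (default) or \code{"kernel"}.
#' @param bandwidth Gaussian kernel standard deviation in grid-position units
#'   (kernel method only).
#' @param k Thin-plate spline basis dimension (tps method). Default scales
#'   with the reference grid: half the number of retained controls, between 12
#'   and 60 — flexible enough for softly undulating bias fields, small enough
#'   to keep noise-fitting low.
#' @return Object of class \code{norm_surface}: list with \code{expected_dt}
#'   (rows x cols matrix, hours; finite everywhere), \code{method},
#'   \code{bandwidth}, \code{controls}.
#' @export
build_surface <- function(layout, controls, method = c("tps", "kernel"),
                          bandwidth = 4, k = NULL) {
  stopifnot(inherits(layout, "plate_layout"),
            all(c("row", "col", "dt_min_hr") %in% names(controls)))
  method <- match.arg(method)
  ok <- is.finite(controls$dt_min_hr) & controls$dt_min_hr > 0
  controls <- controls[ok, , drop = FALSE]
  if (nrow(controls) < 8L ||
      length(unique(controls$row)) < 4L || length(unique(controls$col)) < 4L) {
    stop("degenerate control geometry: need >= 8 controls spread over >= 4 control rows and columns",
         call. = FALSE)
  }
  ld <- log2(controls$dt_min_hr)
  grid <- plate_positions(layout)
  if (stats::sd(ld) < 1e-10) {        # flat control field: constant surface
    surf <- matrix(2^mean(ld), layout$rows, layout$cols)
  } else if (method == "tps") {
    dat <- data.frame(ld = ld, row = controls$row, col = controls$col)
    if (is.null(k)) k <- max(12L, min(60L, nrow(dat) %/% 2L))
    kk <- min(k, nrow(dat) - 2L)
    fit <- mgcv::gam(ld ~ s(row, col, k = kk), data = dat, method = "REML")
    pred <- as.numeric(mgcv::predict.gam(fit, newdata = grid))
    surf <- matrix(NA_real_, layout$rows, layout$cols)
    surf[cbind(grid$row + 1L, grid$col + 1L)] <- 2^pred
  } else {
    rows <- seq_len(layout$rows) - 1L
    cols <- seq_len(layout$cols) - 1L
    # separable Gaussian weights: rows x n_ctrl and cols x n_ctrl
    wr <- exp(-outer(rows, controls$row, `-`)^2 / (2 * bandwidth^2))
    wc <- exp(-outer(cols, controls$col, `-`)^2 / (2 * bandwidth^2))
    W <- wr %*% t(wc)               # total kernel weight per position
    S <- wr %*% (ld * t(wc))        # weight * control log2(dt)
    surf <- 2^(S / W)
  }
  structure(list(expected_dt = surf, method = method, bandwidth = bandwidth,
                 controls = controls),
            class = "norm_surface")
}

#' @export
print.norm_surface <- function(x, ...) {
  cat(sprintf("norm_surface (%s): %d x %d, expected dt %.2f-%.2f hr, %d controls\n",
              x$method,
              nrow(x$expected_dt), ncol(x$expected_dt),
              min(x$expected_dt), max(x$expected_dt),
              nrow(x$controls)))
  invisible(x)
}

#' Spatially normalize a plate of growth features
#'
#' Each colony's doubling time is compared with the normalization surface at
#' its position: relative phenotype = log2(surface / observed), so a colony
#' growing exactly as its local controls predict scores 0 and a colony with a
#' longer-than-expected doubling time (growth defect) scores negative.
#'
#' @param features Data frame with \code{row}, \code{col}, \code{dt_min_hr}
#'   (and optionally \code{flags}).
#' @param surface A \code{\link{build_surface}} result for the same plate.
#' @param plate Plate identifier carried into the output.
#' @return Phenotype table: \code{plate, row, col, dt_min_hr,
#'   rel_phenotype_log2, flags}.
#' @export
normalize_plate <- function(features, surface, plate = "plate1") {
  stopifnot(inherits(surface, "norm_surface"),
            all(c("row", "col", "dt_min_hr") %in% names(features)))
  exp_dt <- surface$expected_dt[cbind(features$row + 1L, features$col + 1L)]
  flags <- if ("flags" %in% names(features)) features$flags else ""
  flags[is.na(flags)] <- ""
  ok <- is.finite(features$dt_min_hr) & features$dt_min_hr > 0
  rel <- ifelse(ok, log2(exp_dt / features$dt_min_hr), NA_real_)
  flags <- ifelse(ok, flags,
                  ifelse(nzchar(flags), paste0(flags, ";undefined_dt"),
                         "undefined_dt"))
  data.frame(plate = plate, row = features$row, col = features$col,
             dt_min_hr = features$dt_min_hr, rel_phenotype_log2 = rel,
             flags = flags, stringsAsFactors = FALSE)
}

#' Align plates of a shared condition on their control means
#'
#' Each plate's phenotypes are shifted additively (log2 units) by the amount
#' that moves the mean of its raw (not spatially normalized) control log2
#' doubling times onto the grand control mean over all plates. Because the
#' spatial normalization has already referenced every colony to its local
#' controls, these shifts are expected to be very small.
#'
#' @param tables Named list of phenotype tables (\code{\link{normalize_plate}}
#'   output).
#' @param control_dts Named list (same names) of numeric vectors: each plate's
#'   retained control doubling times (hours).
#' @return The tables with shifted \code{rel_phenotype_log2}; applied shifts
#'   attached as attribute \code{shifts}. Plates without controls are dropped
#'   with a warning.
#' @export
normalize_between_plates <- function(tables, control_dts) {
  stopifnot(is.list(tables), is.list(control_dts),
            length(tables) >= 2L, !is.null(names(tables)),
            all(names(tables) %in% names(control_dts)))
  has_ctrl <- vapply(names(tables), function(nm) {
    v <- control_dts[[nm]]
    sum(is.finite(v) & v > 0) > 0L
  }, logical(1L))
  if (any(!has_ctrl)) {
    warning("plate(s) without controls excluded: ",
            paste(names(tables)[!has_ctrl], collapse = ", "), call. = FALSE)
    tables <- tables[has_ctrl]
  }
  ctrl_log <- lapply(names(tables), function(nm) {
    v <- control_dts[[nm]]
    log2(v[is.finite(v) & v > 0])
  })
  grand <- mean(unlist(ctrl_log))
  shifts <- grand - vapply(ctrl_log, mean, numeric(1L))
  names(shifts) <- names(tables)
  out <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    tb$rel_phenotype_log2 <- tb$rel_phenotype_log2 + shifts[[nm]]
    tb
  })
  names(out) <- names(tables)
  attr(out, "shifts") <- shifts
  out
}

#' Condition-specific phenotype by subtracting the basal phenotype
#'
#' Gene-by-environment effects are isolated by subtracting each strain's
#' phenotype in the basal environment from its phenotype under the stress
#' condition, removing general growth defects from the condition call.
#'
#' @param stress,basal Phenotype tables. Rows are matched on \code{strain}
#'   when both tables carry that column, otherwise on (\code{row},
#'   \code{col}).
#' @return Data frame with the match keys and \code{condition_effect_log2} =
#'   stress - basal; the number of unmatched rows dropped is attached as
#'   attribute \code{n_unmatched}.
#' @export
condition_difference <- function(stress, basal) {
  by <- if ("strain" %in% names(stress) && "strain" %in% names(basal)) {
    "strain"
  } else {
    c("row", "col")
  }
  m <- merge(stress[, c(by, "rel_phenotype_log2")],
             basal[, c(by, "rel_phenotype_log2")],
             by = by, suffixes = c("_stress", "_basal"))
  m$condition_effect_log2 <-
    m$rel_phenotype_log2_stress - m$rel_phenotype_log2_basal
  n_unmatched <- (nrow(stress) - nrow(m)) + (nrow(basal) - nrow(m))
  if (n_unmatched > 0L) {
    message(n_unmatched, " unmatched rows dropped in condition comparison")
  }
  attr(m, "n_unmatched") <- n_unmatched
  m
}
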