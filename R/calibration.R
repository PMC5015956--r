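# Evaluate a polynomial with coefficients in ascending order (c0 + c1 x + ...)
poly_eval <- function(coef, x) {
  y <- numeric(length(x)) + coef[length(coef)]
  if (length(coef) > 1L) {
    for (i in (length(coef) - 1L):1L) y <- y * x + coef[i]
  }
  y
}

poly_deriv <- function(coef) {
  if (length(coef) <= 1L) return(0)
  coef[-1L] * seq_len(length(coef) - 1L)
}

#' Fit the gray-scale (pixel intensity to opacity) calibration polynomial
#'
#' Transmissive scans are standardized across instruments by relating the mean
#' pixel intensity of each segment of a gray-scale calibration strip to the
#' manufacturer's opacity value for that segment, through a least-squares
#' polynomial. Applying the polynomial turns raw scanner intensities into
#' scanner-independent pixel opacity values.
#'
#' The fit is rejected unless it is strictly monotone over the data range:
#' calibration must preserve the ordering of pixel intensities.
#'
#' @param intensity Mean raw pixel intensity per calibration segment.
#' @param opacity Manufacturer opacity value per segment (same length).
#' @param degree Polynomial degree (default 3).
#' @return An object of class \code{opacity_cal}: list with \code{coefficients}
#'   (ascending order), \code{degree}, \code{valid_range} (range of the fitted
#'   intensities) and \code{rmse} of the fit residuals.
#' @export
fit_opacity_calibration <- function(intensity, opacity, degree = 3L) {
  stopifnot(is.numeric(intensity), is.numeric(opacity), degree >= 1L)
  if (length(intensity) != length(opacity)) {
    stop("intensity and opacity must have equal length", call. = FALSE)
  }
  need <- 2L * (degree + 1L)
  if (length(intensity) < need) {
    stop("need at least ", need, " calibration segments for degree ", degree,
         " (got ", length(intensity), ")", call. = FALSE)
  }
  o <- order(intensity)
  intensity <- intensity[o]; opacity <- opacity[o]
  if (any(diff(intensity) <= 0)) {
    stop("segment intensities must be distinct", call. = FALSE)
  }
  fit <- stats::lm(opacity ~ stats::poly(intensity, degree, raw = TRUE))
  coef <- unname(stats::coef(fit))
  coef[is.na(coef)] <- 0
  rng <- range(intensity)
  # monotonicity over the data range, checked on the derivative
  grid <- seq(rng[1L], rng[2L], length.out = 512L)
  dv <- poly_eval(poly_deriv(coef), grid)
  if (!(all(dv > 0) || all(dv < 0))) {
    stop("fitted calibration polynomial is not monotone over [",
         signif(rng[1L], 4L), ", ", signif(rng[2L], 4L),
         "]; use a lower degree or check the segment table", call. = FALSE)
  }
  structure(list(coefficients = coef, degree = as.integer(degree),
                 valid_range = rng,
                 rmse = sqrt(mean(stats::residuals(fit)^2))),
            class = "opacity_cal")
}

#' Convert a raw grayscale image to pixel opacity
#'
#' Applies the calibration polynomial elementwise. Pixels outside the
#' calibration's valid intensity range are clamped to it (plates can contain
#' specular artifacts); the number of clamped pixels is attached as attribute
#' \code{clamped} and reported in a warning when nonzero.
#'
#' @param cal An \code{opacity_cal}.
#' @param image Numeric matrix of raw intensities.
#' @param time Acquisition time in hours, carried on the output.
#' @return An \code{\link{opacity_image}}.
#' @export
apply_opacity_calibration <- function(cal, image, time = NA_real_) {
  stopifnot(inherits(cal, "opacity_cal"), is.matrix(image))
  rng <- cal$valid_range
  n_clamped <- sum(image < rng[1L] | image > rng[2L])
  x <- pmin(pmax(image, rng[1L]), rng[2L])
  out <- poly_eval(cal$coefficients, x)
  dim(out) <- dim(image)
  if (n_clamped > 0L) {
    warning(n_clamped, " pixel(s) outside calibration range were clamped",
            call. = FALSE)
  }
  img <- opacity_image(out, time = time)
  attr(img, "clamped") <- n_clamped
  img
}

#' Fit the cell-count calibration polynomial
#'
#' Relates background-subtracted pixel opacity to cells per pixel through a
#' least-squares polynomial. By default the intercept is constrained to zero
#' (zero opacity above background means zero cells). Predictions are clipped
#' at zero on evaluation.
#'
#' @param opacity Background-subtracted pixel opacity values.
#' @param cells Matched cell counts per pixel (non-negative).
#' @param degree Polynomial degree (default 5).
#' @param constrained_zero Force a zero intercept (default \code{TRUE}).
#' @return An object of class \code{cell_cal}: list with \code{coefficients}
#'   (ascending, length degree + 1; intercept 0 when constrained),
#'   \code{degree}, \code{constrained_zero}, \code{fit_range} and \code{rmse}.
#' @export
fit_cell_calibration <- function(opacity, cells, degree = 5L,
                                 constrained_zero = TRUE) {
  stopifnot(is.numeric(opacity), is.numeric(cells), degree >= 1L)
  if (length(opacity) != length(cells)) {
    stop("opacity and cells must have equal length", call. = FALSE)
  }
  if (length(opacity) < degree + 2L) {
    stop("need at least ", degree + 2L, " calibration pairs for degree ",
         degree, " (got ", length(opacity), ")", call. = FALSE)
  }
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (all(opacity == 0)) stop("all opacity values are zero", call. = FALSE)
  X <- outer(opacity, seq_len(degree), `^`)
  if (constrained_zero) {
    fit <- stats::lm.fit(X, cells)
    coef <- c(0, unname(fit$coefficients))
  } else {
    fit <- stats::lm.fit(cbind(1, X), cells)
    coef <- unname(fit$coefficients)
  }
  coef[is.na(coef)] <- 0
  structure(list(coefficients = coef, degree = as.integer(degree),
                 constrained_zero = isTRUE(constrained_zero),
                 fit_range = range(opacity),
                 rmse = sqrt(mean(fit$residuals^2))),
            class = "cell_cal")
}

#' Convert background-subtracted opacity to cells per pixel
#'
#' Elementwise evaluation of the cell calibration polynomial, clipped at zero
#' (a pixel can never hold a negative number of cells).
#'
#' @param cal A \code{cell_cal}.
#' @param bg_subtracted Numeric vector/matrix of background-subtracted opacity.
#' @return Cells per pixel, same shape as the input, all values >= 0.
#' @export
cells_from_opacity <- function(cal, bg_subtracted) {
  stopifnot(inherits(cal, "cell_cal"))
  out <- poly_eval(cal$coefficients, bg_subtracted)
  out <- pmax(out, 0)
  dim(out) <- dim(bg_subtracted)
  out
}

#' Invert a cell calibration for a total population
#'
#' Finds the total integrated opacity that the calibration maps to a given
#' population, used by the plate renderer to decide how much opacity a colony
#' of known population must carry.
#'
#' @param cal A \code{cell_cal}.
#' @param population Total cell count (scalar or vector).
#' @param n_pixels Number of pixels the opacity is spread over (per colony);
#'   used for non-linear calibrations where cells/pixel matters. For linear
#'   calibrations the answer is independent of \code{n_pixels}.
#' @return Total opacity (same length as \code{population}).
#' @keywords internal
#' @export
opacity_from_cells <- function(cal, population, n_pixels = 1) {
  stopifnot(inherits(cal, "cell_cal"))
  co <- cal$coefficients
  if (all(co[-2L] == 0)) {           # pure linear: cells = a * opacity
    return(population / co[2L])
  }
  n_pixels <- rep_len(n_pixels, length(population))
  vapply(seq_along(population), function(i) {
    target <- population[i] / n_pixels[i]   # cells per pixel
    f <- function(x) poly_eval(co, x) - target
    hi <- max(1, cal$fit_range[2L])
    while (f(hi) < 0 && hi < 1e12) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-9)$root * n_pixels[i]
  }, numeric(1L))
}

#' Serialize a calibration to JSON
#'
#' @param cal An \code{opacity_cal} or \code{cell_cal}.
#' @param path Output file path.
#' @export
write_calibration <- function(cal, path) {
  rec <- unclass(cal)
  rec$type <- class(cal)[1L]
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration from JSON
#'
#' @param path File written by \code{\link{write_calibration}}.
#' @return The calibration object.
#' @export
read_calibration <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- rec$type
  rec$type <- NULL
  structure(rec, class = type)
}
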