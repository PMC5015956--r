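#' Colony population growth curve
#'
#' @param times Time in hours, strictly increasing.
#' @param raw Population size (cells) per timepoint.
#' @param row,col 0-based plate position (optional).
#' @param smoothed Optional smoothed population values (same length).
#' @return Object of class \code{growth_curve}.
#' @export
growth_curve <- function(times, raw, row = NA_integer_, col = NA_integer_,
                         smoothed = NULL) {
  stopifnot(is.numeric(times), is.numeric(raw), length(times) == length(raw))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("curve times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times), raw = as.numeric(raw),
                 smoothed = smoothed, row = row, col = col),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("growth_curve (%s,%s): %d points over %.1f hr, %s\n",
              format(x$row), format(x$col), length(x$times),
              diff(range(x$times)),
              if (is.null(x$smoothed)) "raw only" else "smoothed"))
  invisible(x)
}

# Gaussian filter with antisymmetric (trend-preserving) boundary reflection:
# the series is extended by mirroring around its endpoint values, so a linear
# trend passes through the filter unchanged right up to the edges.
gaussian_filter_reflect <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  if (n >= r + 1L) {
    left <- 2 * x[1L] - x[(r + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - r)]
  } else {                                # very short series: clamp-pad
    left <- rep(x[1L], r)
    right <- rep(x[n], r)
  }
  pad <- c(left, x, right)
  as.numeric(stats::filter(pad, k, sides = 2L))[r + seq_len(n)]
}

#' Smooth a raw growth curve
#'
#' Two-stage smoothing: a running-median filter removes local spikes, then a
#' Gaussian filter reduces the remaining noise. The Gaussian stage operates on
#' log2 population whenever the median-filtered curve is strictly positive:
#' measurement noise on populations is multiplicative, and in log space the
#' smoother does not distort exponential growth. Curves containing zeros fall
#' back to linear-space smoothing. Edges are handled by reflection; the raw
#' values are preserved alongside.
#'
#' @param curve A \code{\link{growth_curve}}.
#' @param median_window Odd window width for the median stage (default 5).
#' @param gaussian_sigma Gaussian standard deviation in samples (default 1.5).
#' @return The curve with \code{smoothed} filled in. Curves shorter than
#'   \code{median_window} are flagged \code{"too_short"} and passed through
#'   unsmoothed.
#' @export
smooth_curve <- function(curve, median_window = 5L, gaussian_sigma = 1.5) {
  stopifnot(inherits(curve, "growth_curve"))
  if (median_window %% 2L != 1L || median_window < 3L) {
    stop("median_window must be an odd integer >= 3", call. = FALSE)
  }
  if (length(curve$raw) < median_window) {
    curve$smoothed <- curve$raw
    attr(curve, "flags") <- union(attr(curve, "flags"), "too_short")
    return(curve)
  }
  med <- as.numeric(stats::runmed(curve$raw, median_window,
                                  endrule = "median"))
  curve$smoothed <- if (all(med > 0)) {
    2^gaussian_filter_reflect(log2(med), gaussian_sigma)
  } else {
    gaussian_filter_reflect(med, gaussian_sigma)
  }
  curve
}

#' Minimum population doubling time by sliding-window log-linear regression
#'
#' For every run of \code{window} consecutive timepoints with strictly
#' positive smoothed population, an ordinary least-squares line is fitted to
#' log2(population) against time. The maximum slope over all windows is the
#' peak growth rate; its reciprocal is the minimum population doubling time in
#' hours per doubling. Ties are broken by the earliest window.
#'
#' @param curve A smoothed \code{\link{growth_curve}}.
#' @param window Number of points per regression window (default 5).
#' @return List: \code{dt_min} (hours), \code{t_at_dt_min} (center time of the
#'   winning window, hours), \code{regression_se} (standard error of the slope
#'   refitted on the raw log2 values of the winning window, log2-cells/hr;
#'   smoothing hides local scatter, so the raw points carry the honest error),
#'   \code{slope_max}, and \code{flags} (character; \code{"non_growing"} when
#'   no window has positive slope, \code{"boundary"} when the winning window
#'   touches either end of the series, \code{"nonpositive_values"} when the
#'   curve contains values <= 0).
#' @export
min_doubling_time <- function(curve, window = 5L) {
  stopifnot(inherits(curve, "growth_curve"))
  y_pop <- curve$smoothed
  if (is.null(y_pop)) stop("curve must be smoothed first", call. = FALSE)
  t <- curve$times
  n <- length(t)
  flags <- character(0L)
  if (any(!is.finite(y_pop) | y_pop <= 0)) flags <- c(flags, "nonpositive_values")
  none <- list(dt_min = NA_real_, t_at_dt_min = NA_real_,
               regression_se = NA_real_, slope_max = NA_real_,
               flags = union(flags, "non_growing"))
  if (n < window) return(none)
  y <- ifelse(is.finite(y_pop) & y_pop > 0, log2(y_pop), NA_real_)
  best <- NULL
  for (i in seq_len(n - window + 1L)) {
    j <- i:(i + window - 1L)
    yi <- y[j]
    if (anyNA(yi)) next
    ti <- t[j]
    tc <- ti - mean(ti)
    sxx <- sum(tc^2)
    slope <- sum(tc * yi) / sxx
    # relative tolerance so floating-point jitter cannot steal an exact tie
    if (is.null(best) || slope > best$slope + 1e-9 * max(abs(best$slope), 1e-12)) {
      best <- list(slope = slope, i = i, j = j, sxx = sxx,
                   t_center = ti[(window + 1L) %/% 2L])
    }
  }
  if (is.null(best) || best$slope <= 1e-9) return(none)
  # slope SE measured against the raw observations of the winning window
  yr <- curve$raw[best$j]
  se <- NA_real_
  src <- if (all(is.finite(yr) & yr > 0)) log2(yr) else y[best$j]
  if (!anyNA(src)) {
    tc <- t[best$j] - mean(t[best$j])
    s_raw <- sum(tc * src) / best$sxx
    res <- src - mean(src) - s_raw * tc
    se <- sqrt(max(sum(res^2), 0) / (window - 2L) / best$sxx)
  }
  if (best$i == 1L || best$i == n - window + 1L) flags <- c(flags, "boundary")
  list(dt_min = 1 / best$slope, t_at_dt_min = best$t_center,
       regression_se = se, slope_max = best$slope, flags = flags)
}

# Chapman-Richards curve with an initial-value term, on the log2 scale:
# y(t) = y0 + (K - y0) * (1 - b * exp(-r * t))^nu
chapman_richards <- function(t, y0, K, b, r, nu) {
  base <- pmax(1 - b * exp(-r * t), 0)
  y0 + (K - y0) * base^nu
}

#' Fit the initial-value Chapman-Richards growth model
#'
#' Fits y(t) = y0 + (K - y0) (1 - b e^(-r t))^nu to log2(population) by
#' bounded least squares (Levenberg-Marquardt) from a fixed grid of starting
#' values. The fit serves purely as a curve-quality index: its RMSE in log2
#' units flags ill-behaved curves; no growth feature is extracted from it.
#'
#' @param curve A smoothed \code{\link{growth_curve}} with positive values.
#' @param n_starts Number of starting points taken from the fixed grid.
#' @return List: \code{params} (named y0, K, b, r, nu), \code{rmse} in log2
#'   units (\code{Inf} when no start converges), \code{converged}.
#' @export
chapman_richards_fit <- function(curve, n_starts = 8L) {
  stopifnot(inherits(curve, "growth_curve"))
  if (is.null(curve$smoothed)) stop("curve must be smoothed first", call. = FALSE)
  ok <- is.finite(curve$smoothed) & curve$smoothed > 0
  t <- curve$times[ok]
  y <- log2(curve$smoothed[ok])
  if (length(y) < 6L) {
    return(list(params = NULL, rmse = Inf, converged = FALSE))
  }
  ylo <- min(y); yhi <- max(y)
  if (yhi - ylo < 1e-8) {      # flat curve: model degenerates to K = y0
    return(list(params = c(y0 = mean(y), K = mean(y), b = 1, r = 1, nu = 1),
                rmse = sqrt(mean((y - mean(y))^2)), converged = TRUE))
  }
  span <- max(diff(range(t)), 1e-6)
  # fixed multi-start grid (deterministic)
  starts <- expand.grid(r = c(1, 3, 8, 20) / span, nu = c(1.5, 4))
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
  lower <- c(y0 = ylo - abs(ylo) - 10, K = ylo, b = 1e-6, r = 1e-6, nu = 1e-2)
  upper <- c(y0 = yhi, K = yhi + abs(yhi) + 10, b = 1, r = 1e3, nu = 50)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    st <- c(y0 = ylo, K = yhi, b = 0.99, r = starts$r[s], nu = starts$nu[s])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ chapman_richards(t, y0, K, b, r, nu),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200L)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(stats::residuals(fit)^2))
    if (is.null(best) || rmse < best$rmse) {
      best <- list(params = stats::coef(fit), rmse = rmse)
    }
  }
  if (is.null(best)) return(list(params = NULL, rmse = Inf, converged = FALSE))
  list(params = best$params, rmse = best$rmse, converged = TRUE)
}

#' Extract growth features and quality indices from a curve
#'
#' Assembles the minimum population doubling time with its extraction time and
#' regression standard error, the Chapman-Richards fit RMSE, the initial
#' population (first smoothed point, a diagnostic output) and the total number
#' of doublings log2(final/initial). Failures surface as flags, never errors.
#'
#' @param curve A \code{\link{growth_curve}} (smoothed; if not, it is smoothed
#'   with defaults first).
#' @param window Regression window for \code{\link{min_doubling_time}}.
#' @param fit_cr Compute the Chapman-Richards quality index (default TRUE;
#'   the fit is the slow step).
#' @return One-row data frame: \code{row, col, dt_min_hr, t_at_dt_min_hr,
#'   regression_se, cr_rmse, initial_cells, doublings, flags} (flags as a
#'   single ";"-separated string).
#' @export
extract_features <- function(curve, window = 5L, fit_cr = TRUE) {
  stopifnot(inherits(curve, "growth_curve"))
  if (is.null(curve$smoothed)) curve <- smooth_curve(curve)
  flags <- attr(curve, "flags")
  dt <- min_doubling_time(curve, window = window)
  flags <- union(flags, dt$flags)
  cr_rmse <- NA_real_
  if (fit_cr) {
    cr <- chapman_richards_fit(curve)
    cr_rmse <- cr$rmse
    if (!cr$converged) flags <- union(flags, "cr_fit_failed")
  }
  s <- curve$smoothed
  init <- s[1L]
  if (is.finite(init) && init > 0 && is.finite(s[length(s)]) &&
      s[length(s)] > 0) {
    doublings <- log2(s[length(s)] / init)
  } else {
    doublings <- NA_real_
    flags <- union(flags, "undefined_initial")
  }
  data.frame(row = curve$row, col = curve$col,
             dt_min_hr = dt$dt_min, t_at_dt_min_hr = dt$t_at_dt_min,
             regression_se = dt$regression_se, cr_rmse = cr_rmse,
             initial_cells = init, doublings = doublings,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Extract features for a whole set of curves
#'
#' @param curves List of \code{\link{growth_curve}} (e.g. from
#'   \code{\link{series_to_curves}}).
#' @param median_window,gaussian_sigma Smoothing parameters.
#' @param window Regression window.
#' @param fit_cr Compute Chapman-Richards quality indices.
#' @return Data frame, one row per curve (see \code{\link{extract_features}}).
#' @export
extract_features_all <- function(curves, median_window = 5L,
                                 gaussian_sigma = 1.5, window = 5L,
                                 fit_cr = TRUE) {
  rows <- lapply(curves, function(cv) {
    cv <- smooth_curve(cv, median_window = median_window,
                       gaussian_sigma = gaussian_sigma)
    extract_features(cv, window = window, fit_cr = fit_cr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply quality thresholds to extracted features
#'
#' Raises threshold flags on top of the structural flags from extraction:
#' regression standard error or Chapman-Richards RMSE above their configured
#' maxima, a growth span too small to be signal, or an extraction time at the
#' curve boundary. The flagged fraction is attached as attribute
#' \code{flagged_fraction}.
#'
#' @param features Data frame from \code{\link{extract_features_all}}.
#' @param max_regression_se Threshold on the raw-scatter slope standard error
#'   (log2-cells/hr; default 0.1).
#' @param max_cr_rmse Threshold on the Chapman-Richards RMSE (log2 units;
#'   default 0.5).
#' @param min_doublings Minimum total growth span (log2 units) below which a
#'   curve is flagged as having no usable signal (default 1).
#' @return The features with an added logical column \code{flagged} and
#'   updated \code{flags}.
#' @export
flag_curves <- function(features, max_regression_se = 0.1,
                        max_cr_rmse = 0.5, min_doublings = 1) {
  fl <- strsplit(ifelse(is.na(features$flags), "", features$flags), ";",
                 fixed = TRUE)
  add <- function(i, f) fl[[i]] <<- union(setdiff(fl[[i]], ""), f)
  for (i in seq_len(nrow(features))) {
    if (is.na(features$dt_min_hr[i])) add(i, "non_growing")
    if (is.finite(features$regression_se[i]) &&
        features$regression_se[i] > max_regression_se) add(i, "high_regression_se")
    if (is.finite(features$cr_rmse[i]) &&
        features$cr_rmse[i] > max_cr_rmse) add(i, "high_cr_rmse")
    if (!is.finite(features$doublings[i]) ||
        features$doublings[i] < min_doublings) add(i, "low_doublings")
  }
  features$flags <- vapply(fl, function(f) paste(setdiff(f, ""), collapse = ";"),
                           character(1L))
  features$flagged <- nzchar(features$flags)
  attr(features, "flagged_fraction") <- mean(features$flagged)
  features
}
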