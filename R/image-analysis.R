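#' Calibrated pixel-opacity image
#'
#' A 2-D numeric array of pixel opacity values (rows = image y, origin at the
#' top-left) carrying its acquisition time in hours.
#'
#' @param opacity Numeric matrix of pixel opacity.
#' @param time Acquisition time, hours.
#' @return Object of class \code{opacity_image}.
#' @export
opacity_image <- function(opacity, time = NA_real_) {
  stopifnot(is.matrix(opacity), is.numeric(opacity))
  structure(list(opacity = opacity, time = as.numeric(time)),
            class = "opacity_image")
}

#' @export
print.opacity_image <- function(x, ...) {
  cat(sprintf("opacity_image: %d x %d px, t = %s hr, opacity range [%.3g, %.3g]\n",
              nrow(x$opacity), ncol(x$opacity),
              format(x$time), min(x$opacity), max(x$opacity)))
  invisible(x)
}

# Otsu threshold on a 256-bin histogram of arbitrary-ranged values.
otsu_threshold <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(r[1L])
  h <- tabulate(pmin(as.integer((x - r[1L]) / diff(r) * 256) + 1L, 256L), 256L)
  p <- h / sum(h)
  mids <- r[1L] + (seq_len(256L) - 0.5) / 256 * diff(r)
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256L]
  between <- (mu_t * w - mu)^2 / (w * (1 - w))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Robust fit of a 1-D lattice (n points, approximate pitch s0) to observed
# center coordinates. Phase by circular mean, index assignment by rounding,
# pitch/offset refined with a Huber M-estimator. Returns the n lattice
# coordinates, anchored so the lattice midpoint matches extent/2 (plate
# regions are pre-cropped, so the array is centered in the image).
fit_lattice_1d <- function(cent, n, s0, extent) {
  ang <- 2 * pi * cent / s0
  off <- Arg(mean(exp(1i * ang))) / (2 * pi) * s0
  off <- off %% s0
  k <- round((cent - off) / s0)
  for (it in 1:2) {
    fit <- stats::lm(cent ~ k)
    if (stats::median(abs(stats::residuals(fit))) > 1e-6) {
      rfit <- tryCatch(suppressWarnings(MASS::rlm(cent ~ k, maxit = 50)),
                       error = function(e) NULL)
      if (!is.null(rfit)) fit <- rfit
    }
    off <- unname(stats::coef(fit)[1L])
    s <- unname(stats::coef(fit)[2L])
    if (!is.finite(s) || s <= 0) {
      stop("gridding failure: degenerate lattice fit", call. = FALSE)
    }
    k <- round((cent - off) / s)
  }
  if (abs(s - s0) > 0.2 * s0) {
    stop(sprintf(
      "gridding failure: fitted pitch %.2f px deviates more than 20%% from expected %.2f px",
      s, s0), call. = FALSE)
  }
  start <- round((extent / 2 - off) / s - (n - 1) / 2)
  centers <- off + s * (start + 0:(n - 1))
  resid <- abs(cent - (off + s * k))
  list(centers = centers, pitch = s,
       inlier_frac = mean(resid < 0.3 * s),
       med_resid = stats::median(resid) / s)
}

#' Detect the colony grid on a plate image
#'
#' Places a virtual rows x cols lattice over the plate with intersections at
#' the predicted colony centers. Bright blobs are found by Otsu thresholding
#' and connected-component labelling; their centroids are collapsed per axis
#' and a robust 1-D lattice (pitch + phase) is fitted on each axis, so the
#' returned grid is complete even at positions where no colony is visible.
#'
#' @param img An \code{\link{opacity_image}} covering exactly one plate region.
#' @param layout A \code{\link{plate_layout}}.
#' @param min_blob_px Components smaller than this many pixels are ignored as
#'   specks (default 4).
#' @param contrast_guard Minimum opacity range required to attempt detection.
#' @return Object of class \code{plate_grid}: list with \code{centers_y},
#'   \code{centers_x} (lattice coordinates per axis, px), \code{pitch}
#'   (c(dy, dx)), \code{window} (c(h, w), px) and the layout dimensions.
#' @export
detect_grid <- function(img, layout, min_blob_px = 4L, contrast_guard = 5) {
  stopifnot(inherits(img, "opacity_image"), inherits(layout, "plate_layout"))
  mat <- img$opacity
  if (diff(range(mat)) < contrast_guard) {
    stop("gridding failure: image contrast below guard (blank image?)",
         call. = FALSE)
  }
  thr <- otsu_threshold(mat)
  lab <- EBImage::bwlabel(EBImage::Image((mat > thr) * 1))
  lab <- EBImage::imageData(lab)
  nlab <- max(lab)
  if (nlab < 1L) stop("gridding failure: no colony blobs detected", call. = FALSE)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  ys <- (idx - 1L) %% nrow(mat) + 1L
  xs <- (idx - 1L) %/% nrow(mat) + 1L
  size <- tabulate(comp, nlab)
  keep <- which(size >= min_blob_px)
  if (length(keep) < max(4L, layout$rows * layout$cols * 0.1)) {
    stop("gridding failure: too few colony blobs detected (",
         length(keep), ")", call. = FALSE)
  }
  cy <- (rowsum(ys, comp)[, 1L] / size)[keep]
  cx <- (rowsum(xs, comp)[, 1L] / size)[keep]
  fy <- fit_lattice_1d(cy, layout$rows, nrow(mat) / layout$rows, nrow(mat))
  fx <- fit_lattice_1d(cx, layout$cols, ncol(mat) / layout$cols, ncol(mat))
  if (fy$inlier_frac < 0.5 || fx$inlier_frac < 0.5 ||
      fy$med_resid > 0.15 || fx$med_resid > 0.15) {
    stop("gridding failure: blob centroids are not periodic on the expected lattice",
         call. = FALSE)
  }
  structure(list(centers_y = fy$centers, centers_x = fx$centers,
                 pitch = c(fy$pitch, fx$pitch),
                 window = c(round(fy$pitch), round(fx$pitch)),
                 rows = layout$rows, cols = layout$cols,
                 image_dim = dim(mat)),
            class = "plate_grid")
}

#' @export
print.plate_grid <- function(x, ...) {
  cat(sprintf("plate_grid: %d x %d lattice, pitch (%.2f, %.2f) px, window %d x %d px\n",
              x$rows, x$cols, x$pitch[1L], x$pitch[2L],
              x$window[1L], x$window[2L]))
  invisible(x)
}

# Half-open pixel window of a grid cell, clipped to the image.
grid_window <- function(grid, row, col) {
  h <- grid$window[1L]; w <- grid$window[2L]
  y0 <- floor(grid$centers_y[row + 1L] - h / 2) + 1L
  x0 <- floor(grid$centers_x[col + 1L] - w / 2) + 1L
  ys <- max(1L, y0):min(grid$image_dim[1L], y0 + h - 1L)
  xs <- max(1L, x0):min(grid$image_dim[2L], x0 + w - 1L)
  list(ys = ys, xs = xs,
       cy = grid$centers_y[row + 1L] - ys[1L] + 1,
       cx = grid$centers_x[col + 1L] - xs[1L] + 1)
}

#' Segment one colony window into colony / background / trash pixels
#'
#' Within the local window around a grid intersection, pixels are partitioned
#' into the focal colony, trash (pixels that cannot confidently be assigned to
#' colony or background) and local background. Colony candidates are found by
#' hysteresis thresholding: an Otsu threshold on the window histogram seeds
#' the bright cores, and each core grows to its connected component above a
#' low threshold (estimated background + contrast guard), so that dim colony
#' rims are not clipped. The component nearest the window center is the focal
#' colony; other components, and a safety-margin ring dilated around the
#' colony, are trash. A window whose opacity range is below the contrast
#' guard is declared colony-free.
#'
#' @param img An \code{\link{opacity_image}}.
#' @param grid A \code{\link{detect_grid}} result.
#' @param row,col 0-based plate position.
#' @param margin Safety-margin width in pixels dilated around the colony
#'   (default 2).
#' @param contrast_guard Minimum window opacity range to accept a colony.
#' @return Object of class \code{colony_seg}: logical matrices \code{colony},
#'   \code{background}, \code{trash} (pairwise disjoint, union = window) plus
#'   the window pixel indices.
#' @export
segment_colony <- function(img, grid, row, col, margin = 2L,
                           contrast_guard = 5) {
  stopifnot(inherits(img, "opacity_image"), inherits(grid, "plate_grid"))
  win <- grid_window(grid, row, col)
  w <- img$opacity[win$ys, win$xs, drop = FALSE]
  empty <- function() {
    structure(list(colony = matrix(FALSE, nrow(w), ncol(w)),
                   background = matrix(TRUE, nrow(w), ncol(w)),
                   trash = matrix(FALSE, nrow(w), ncol(w)),
                   ys = win$ys, xs = win$xs),
              class = "colony_seg")
  }
  if (diff(range(w)) < contrast_guard) return(empty())
  thr <- otsu_threshold(w)
  seed <- w > thr
  if (!any(seed)) return(empty())
  bg_est <- stats::median(w[w <= thr])
  bin <- w > min(thr, bg_est + contrast_guard)   # hysteresis: grown support
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
  keep_comp <- unique(lab[seed])                 # components containing a seed
  lab[!(lab %in% keep_comp)] <- 0L
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((lab > 0L) * 1)))
  nlab <- max(lab)
  # component whose pixels come closest to the window center is the colony
  d2 <- outer((seq_len(nrow(w)) - win$cy)^2, (seq_len(ncol(w)) - win$cx)^2, `+`)
  mind <- vapply(seq_len(nlab), function(k) min(d2[lab == k]), numeric(1L))
  focal <- which.min(mind)
  colony <- lab == focal
  trash <- bin & !colony
  if (margin > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(margin) + 1L, shape = "box")
    dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(colony * 1), brush)) > 0
    trash <- trash | (dil & !colony)
  }
  background <- !colony & !trash
  structure(list(colony = colony, background = background, trash = trash,
                 ys = win$ys, xs = win$xs),
            class = "colony_seg")
}

#' Measure a segmented colony
#'
#' The local background level is the median opacity of the window's background
#' pixels. It is subtracted from every colony pixel; the background-subtracted
#' opacities are converted to cells per pixel by the cell calibration
#' (negative values clip to zero) and summed into the colony population size.
#'
#' @param seg A \code{colony_seg}.
#' @param img The \code{\link{opacity_image}} it was segmented from.
#' @param cal A \code{cell_cal}.
#' @return List: \code{population} (cells), \code{area_px}, \code{background}
#'   (opacity), \code{time} (hours), \code{valid}.
#' @export
measure_colony <- function(seg, img, cal) {
  stopifnot(inherits(seg, "colony_seg"), inherits(img, "opacity_image"))
  w <- img$opacity[seg$ys, seg$xs, drop = FALSE]
  if (!any(seg$background)) {
    return(list(population = NA_real_, area_px = sum(seg$colony),
                background = NA_real_, time = img$time, valid = FALSE))
  }
  bg <- stats::median(w[seg$background])
  area <- sum(seg$colony)
  pop <- if (area == 0L) 0 else sum(cells_from_opacity(cal, w[seg$colony] - bg))
  list(population = pop, area_px = area, background = bg,
       time = img$time, valid = TRUE)
}

#' Analyze a plate image time series into growth curves
#'
#' The virtual grid is detected on the \emph{last} image of the series, where
#' colonies are largest and easiest to localize, and reused verbatim for all
#' earlier images (reverse-chronological analysis). Every position is then
#' segmented and measured on every image.
#'
#' @param images List of \code{\link{opacity_image}} with strictly increasing
#'   timestamps.
#' @param layout A \code{\link{plate_layout}}.
#' @param cal A \code{cell_cal}.
#' @param margin Safety margin in pixels (see \code{\link{segment_colony}}).
#' @param contrast_guard Minimum window contrast for colony detection.
#' @return Data frame with one row per (row, col, time_hr):
#'   \code{row, col, time_hr, population_cells, area_px, background_opacity,
#'   valid}, ordered by position then time.
#' @export
analyze_series <- function(images, layout, cal, margin = 2L,
                           contrast_guard = 5) {
  stopifnot(length(images) >= 1L,
            all(vapply(images, inherits, logical(1L), "opacity_image")))
  times <- vapply(images, `[[`, numeric(1L), "time")
  if (anyNA(times) || (length(times) > 1L && any(diff(times) <= 0))) {
    stop("image timestamps must be strictly increasing", call. = FALSE)
  }
  grid <- detect_grid(images[[length(images)]], layout,
                      contrast_guard = contrast_guard)
  pos <- plate_positions(layout)
  n_pos <- nrow(pos); n_t <- length(images)
  out <- data.frame(
    row = rep(pos$row, each = n_t), col = rep(pos$col, each = n_t),
    time_hr = rep(times, times = n_pos),
    population_cells = NA_real_, area_px = NA_integer_,
    background_opacity = NA_real_, valid = FALSE)
  # reverse chronological pass per image, filling all positions
  for (ti in rev(seq_len(n_t))) {
    img <- images[[ti]]
    for (pi in seq_len(n_pos)) {
      m <- tryCatch({
        seg <- segment_colony(img, grid, pos$row[pi], pos$col[pi],
                              margin = margin, contrast_guard = contrast_guard)
        measure_colony(seg, img, cal)
      }, error = function(e) NULL)
      if (is.null(m)) next
      k <- (pi - 1L) * n_t + ti
      out$population_cells[k] <- m$population
      out$area_px[k] <- m$area_px
      out$background_opacity[k] <- m$background
      out$valid[k] <- m$valid
    }
  }
  attr(out, "grid") <- grid
  out
}

#' Split a plate time-series table into growth-curve objects
#'
#' @param series Data frame from \code{\link{analyze_series}} (or a curves CSV
#'   with the same columns).
#' @return Named list (\code{"row,col"}) of \code{\link{growth_curve}}.
#' @export
series_to_curves <- function(series) {
  stopifnot(all(c("row", "col", "time_hr", "population_cells") %in%
                  names(series)))
  key <- paste(series$row, series$col, sep = ",")
  lapply(split(series, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$time_hr), ]
    growth_curve(d$time_hr, d$population_cells,
                 row = d$row[1L], col = d$col[1L])
  })
}

#' Read a plate image file as an opacity image
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG. Values are rescaled from
#' the [0, 1] range used by the image reader back to native integer units.
#'
#' @param path Image file path.
#' @param time Acquisition time in hours.
#' @param cal Optional \code{opacity_cal}; when supplied, raw intensities are
#'   calibrated to opacity, otherwise raw values are used as-is.
#' @return An \code{\link{opacity_image}}.
#' @export
read_plate_image <- function(path, time = NA_real_, cal = NULL) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) dat <- dat[, , 1L]
  # EBImage stores x in dim 1: transpose so rows = image y
  mat <- t(dat) * 255
  if (!is.null(cal)) {
    apply_opacity_calibration(cal, mat, time = time)
  } else {
    opacity_image(mat, time = time)
  }
}

#' Write an opacity image to file
#'
#' Opacity values are linearly rescaled to [0, 1] over \code{max_opacity} and
#' written as 16-bit grayscale.
#'
#' @param img An \code{\link{opacity_image}}.
#' @param path Output path (.tif or .png).
#' @param max_opacity Opacity mapped to full scale.
#' @export
write_plate_image <- function(img, path, max_opacity = max(img$opacity)) {
  stopifnot(inherits(img, "opacity_image"))
  m <- pmin(pmax(img$opacity / max_opacity, 0), 1)
  EBImage::writeImage(EBImage::Image(t(m)), path, bits.per.sample = 16L)
  invisible(path)
}
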