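# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Smooth standardized random field over the plate: a few low-frequency cosine
# waves with random orientation and phase, rescaled to mean 0, sd 1.
smooth_field <- function(rows, cols, n_waves = 3L) {
  r <- (seq_len(rows) - 1) / max(rows - 1, 1)
  c <- (seq_len(cols) - 1) / max(cols - 1, 1)
  g <- matrix(0, rows, cols)
  for (i in seq_len(n_waves)) {
    fr <- stats::runif(1, 0.3, 1.2); fc <- stats::runif(1, 0.3, 1.2)
    ph <- stats::runif(1, 0, 2 * pi); a <- stats::rnorm(1)
    g <- g + a * cos(2 * pi * outer(fr * r, fc * c, `+`) + ph)
  }
  (g - mean(g)) / stats::sd(g)
}

# Lognormal multipliers with mean 1 and the given coefficient of variation.
lognormal_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate ground-truth colony growth curves for a plate
#'
#' Every colony follows a Chapman-Richards sigmoid in log2 cell count,
#' y(t) = y0 + A (1 - e^(-r t))^nu, whose rate constant is solved in closed
#' form from the colony's target minimum doubling time (the model's maximal
#' log2 slope is A r (1 - 1/nu)^(nu - 1)). Per-colony doubling times combine
#' the plate mean, per-position strain effects (log2 scale), and a smooth
#' multiplicative spatial bias field acting on growth rate. Pinning noise
#' perturbs initial population sizes (lognormal); measurement noise multiplies
#' each observed population (lognormal). Timepoints run from 0 to \code{t_end}
#' at \code{interval_min}-minute steps (a 72-hr series at the default 20-min
#' interval has 217 points); intervals below the 7-minute scan floor are
#' rejected.
#'
#' @param layout A \code{\link{plate_layout}}.
#' @param mean_dt Plate mean minimum doubling time, hours (default 2.0).
#' @param dt_effects_log2 rows x cols matrix of per-position log2 doubling
#'   time effects (e.g. +1 = 2-fold slower strain); default all zero.
#' @param bias_amplitude Standard deviation of the spatial bias field on the
#'   log growth-rate scale (default 0.15; 0 disables).
#' @param pinning_cv CV of initial population sizes (default 0.10).
#' @param noise_cv CV of multiplicative measurement noise per observation
#'   (default 0.025).
#' @param t_end Series length, hours (default 72).
#' @param interval_min Scan interval, minutes (default 20; minimum 7).
#' @param initial_cells Mean initial population (default 5e4 cells).
#' @param doublings Total log2 growth span A (default 5, matching carbon-
#'   limited colonies reaching 4.5-5.5 doublings).
#' @param nu Chapman-Richards shape (default 3).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return Object of class \code{sim_plate}: \code{truth} (data frame: row,
#'   col, is_control, true_dt_hr, effect_log2, bias_log_rate, init_cells,
#'   final_cells), \code{times}, \code{curves} (list of noisy
#'   \code{\link{growth_curve}}), \code{true_pop} (positions x times matrix of
#'   noiseless populations), \code{bias_field}, \code{params}, \code{seed}.
#' @export
simulate_growth_curves <- function(layout, mean_dt = 2.0,
                                   dt_effects_log2 = NULL,
                                   bias_amplitude = 0.15, pinning_cv = 0.10,
                                   noise_cv = 0.025, t_end = 72,
                                   interval_min = 20, initial_cells = 5e4,
                                   doublings = 5, nu = 3, seed = 1L) {
  stopifnot(inherits(layout, "plate_layout"), mean_dt > 0, t_end > 0,
            initial_cells > 0, doublings > 0, nu > 1)
  if (interval_min < 7) {
    stop("scan interval below the 7-minute hardware floor", call. = FALSE)
  }
  if (is.null(dt_effects_log2)) {
    dt_effects_log2 <- matrix(0, layout$rows, layout$cols)
  }
  stopifnot(all(dim(dt_effects_log2) == c(layout$rows, layout$cols)))
  n_t <- floor(t_end * 60 / interval_min + 1e-9) + 1L
  times <- (seq_len(n_t) - 1L) * interval_min / 60
  pos <- plate_positions(layout)
  n <- nrow(pos)
  with_seed(seed, {
    bias <- if (bias_amplitude > 0) {
      bias_amplitude * smooth_field(layout$rows, layout$cols)
    } else {
      matrix(0, layout$rows, layout$cols)
    }
    init <- initial_cells * lognormal_cv(n, pinning_cv)
    idx <- cbind(pos$row + 1L, pos$col + 1L)
    true_dt <- mean_dt * 2^dt_effects_log2[idx] / exp(bias[idx])
    # closed-form rate from target minimum doubling time
    r <- 1 / (true_dt * doublings * (1 - 1 / nu)^(nu - 1))
    y0 <- log2(init)
    true_pop <- matrix(NA_real_, n, n_t)
    for (i in seq_len(n)) {
      true_pop[i, ] <- 2^(y0[i] + doublings * (1 - exp(-r[i] * times))^nu)
    }
    noise <- matrix(lognormal_cv(n * n_t, noise_cv), n, n_t)
    obs <- true_pop * noise
    curves <- lapply(seq_len(n), function(i) {
      growth_curve(times, obs[i, ], row = pos$row[i], col = pos$col[i])
    })
    names(curves) <- paste(pos$row, pos$col, sep = ",")
    truth <- data.frame(row = pos$row, col = pos$col,
                        is_control = layout$is_control[idx],
                        true_dt_hr = true_dt,
                        effect_log2 = dt_effects_log2[idx],
                        bias_log_rate = bias[idx],
                        init_cells = init,
                        final_cells = true_pop[, n_t])
    structure(list(truth = truth, times = times, curves = curves,
                   true_pop = true_pop, bias_field = bias,
                   params = list(mean_dt = mean_dt,
                                 bias_amplitude = bias_amplitude,
                                 pinning_cv = pinning_cv, noise_cv = noise_cv,
                                 t_end = t_end, interval_min = interval_min,
                                 initial_cells = initial_cells,
                                 doublings = doublings, nu = nu),
                   seed = seed),
              class = "sim_plate")
  })
}

#' Assign growth handicaps to random experimental positions
#'
#' Builds a per-position log2 doubling-time effect matrix with a fixed effect
#' at a random subset of experimental positions; control positions always stay
#' at 0 (they carry the isogenic reference strain).
#'
#' @param layout A \code{\link{plate_layout}}.
#' @param fraction Fraction of experimental positions to handicap.
#' @param effect_log2 Effect size in log2 doubling time (+1 = 2-fold slower).
#' @param seed Integer seed.
#' @return rows x cols effect matrix.
#' @export
assign_handicaps <- function(layout, fraction = 0.1, effect_log2 = 1,
                             seed = 1L) {
  stopifnot(inherits(layout, "plate_layout"), fraction >= 0, fraction <= 1)
  eff <- matrix(0, layout$rows, layout$cols)
  ep <- experimental_positions(layout)
  with_seed(seed, {
    pick <- sample(nrow(ep), round(fraction * nrow(ep)))
    eff[cbind(ep$row[pick] + 1L, ep$col[pick] + 1L)] <- effect_log2
  })
  eff
}

#' Render a simulated plate as an opacity-image time series
#'
#' Each colony is drawn as a radially symmetric truncated-paraboloid opacity
#' dome on top of the background level: pixel opacity falls from the center as
#' 1 - trunc (d/radius)^2 inside the colony radius and steps to background
#' outside it, and the dome is scaled so its integrated opacity equals the
#' cell-calibration inverse of the colony's observed population (the
#' simulated trajectory including its multiplicative measurement noise, so
#' the simulator's noise model propagates through the image path; with
#' \code{noise_cv = 0} this is the exact true population). The radius grows
#' with the cube root of population (volume-like scaling), so colony area
#' grows far slower than population. Gaussian pixel noise is added
#' independently per image.
#'
#' @param sim A \code{\link{simulate_growth_curves}} result.
#' @param cal A \code{cell_cal} defining the opacity-to-cells map the images
#'   should be consistent with (default: identity-slope linear calibration).
#' @param px_per_colony Pixels per lattice cell (default 24, minimum 8).
#' @param radius_frac Colony radius at the reference (final mean) population,
#'   as a fraction of the cell pitch (default 0.35).
#' @param trunc Dome truncation depth in (0, 1); the colony edge keeps
#'   opacity (1 - trunc) x center (default 0.7).
#' @param background Background opacity level (scalar; default 5).
#' @param pixel_noise_sd Gaussian pixel noise standard deviation (default 0.5
#'   opacity units; 0 disables).
#' @param seed Integer seed for the pixel noise.
#' @return List of \code{\link{opacity_image}}, one per timepoint.
#' @export
render_plate_series <- function(sim, cal = NULL, px_per_colony = 24L,
                                radius_frac = 0.35, trunc = 0.7,
                                background = 5, pixel_noise_sd = 0.5,
                                seed = 1L) {
  stopifnot(inherits(sim, "sim_plate"))
  if (px_per_colony < 8L) stop("px_per_colony must be >= 8", call. = FALSE)
  if (is.null(cal)) {
    cal <- structure(list(coefficients = c(0, 1), degree = 1L,
                          constrained_zero = TRUE, fit_range = c(0, 1e9),
                          rmse = 0),
                     class = "cell_cal")
  }
  rows <- max(sim$truth$row) + 1L; cols <- max(sim$truth$col) + 1L
  H <- rows * px_per_colony; Wd <- cols * px_per_colony
  obs_pop <- do.call(rbind, lapply(sim$curves, `[[`, "raw"))
  pop_ref <- mean(sim$truth$final_cells)
  r_ref <- radius_frac * px_per_colony
  rad <- r_ref * (obs_pop / pop_ref)^(1 / 3)
  margin_guard <- px_per_colony / 2 - 1
  if (any(rad > margin_guard)) {
    stop("colony domes would overlap at this density; reduce radius_frac or increase px_per_colony",
         call. = FALSE)
  }
  cy <- (sim$truth$row + 0.5) * px_per_colony   # image y of colony centers
  cx <- (sim$truth$col + 0.5) * px_per_colony
  n_t <- length(sim$times)
  with_seed(seed, {
    lapply(seq_len(n_t), function(ti) {
      img <- matrix(background, H, Wd)
      for (i in seq_len(nrow(sim$truth))) {
        rho <- rad[i, ti]
        pop <- obs_pop[i, ti]
        ys <- max(1L, floor(cy[i] - rho)):min(H, ceiling(cy[i] + rho))
        xs <- max(1L, floor(cx[i] - rho)):min(Wd, ceiling(cx[i] + rho))
        d2 <- outer((ys - 0.5 - cy[i])^2, (xs - 0.5 - cx[i])^2, `+`)
        inside <- d2 <= rho^2
        if (!any(inside)) {      # sub-pixel colony: all opacity on one pixel
          yy <- pmin(pmax(round(cy[i] + 0.5), 1L), H)
          xx <- pmin(pmax(round(cx[i] + 0.5), 1L), Wd)
          img[yy, xx] <- img[yy, xx] + opacity_from_cells(cal, pop, 1)
          next
        }
        shape <- (1 - trunc * d2 / rho^2) * inside
        total <- opacity_from_cells(cal, pop, sum(inside))
        img[ys, xs] <- img[ys, xs] + shape * (total / sum(shape))
      }
      if (pixel_noise_sd > 0) {
        img <- img + matrix(stats::rnorm(H * Wd, 0, pixel_noise_sd), H, Wd)
      }
      opacity_image(img, time = sim$times[ti])
    })
  })
}

#' Simulate a null plate of iid per-position values
#'
#' Ground truth for the adjacency false-positive calibration: every position
#' receives an independent draw, so any detected "bias" is a false positive.
#'
#' @param layout A \code{\link{plate_layout}}.
#' @param mu Mean (or log-mean when \code{lognormal}).
#' @param sigma Standard deviation (>= 0).
#' @param seed Integer seed.
#' @param lognormal Draw lognormal instead of normal values.
#' @return rows x cols numeric matrix.
#' @export
simulate_null_plate <- function(layout, mu = 2, sigma = 0.1, seed = 1L,
                                lognormal = FALSE) {
  stopifnot(inherits(layout, "plate_layout"), sigma >= 0)
  with_seed(seed, {
    n <- layout$rows * layout$cols
    v <- if (lognormal) stats::rlnorm(n, mu, sigma) else stats::rnorm(n, mu, sigma)
    matrix(v, layout$rows, layout$cols)
  })
}
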