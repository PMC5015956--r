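test_that("median+Gaussian smoothing preserves constants, kills spikes, reduces noise", {
  t <- seq(0, 10, by = 0.5)
  const <- smooth_curve(growth_curve(t, rep(400, length(t))))
  expect_equal(const$smoothed, rep(400, length(t)))
  spiked <- rep(100, length(t)); spiked[10] <- 1000
  sm <- smooth_curve(growth_curve(t, spiked))
  expect_equal(sm$smoothed, rep(100, length(t)))   # single spike fully removed
  # iid noise: smoothed closer to truth than raw
  set.seed(11)
  truth <- 100 * 2^(t / 2)
  noisy <- truth * exp(rnorm(length(t), 0, 0.05))
  smn <- smooth_curve(growth_curve(t, noisy))
  expect_lt(var(smn$smoothed - truth), var(noisy - truth))
  # too-short curves pass through flagged
  short <- smooth_curve(growth_curve(t[1:3], truth[1:3]))
  expect_true("too_short" %in% attr(short, "flags"))
  expect_equal(short$smoothed, short$raw)
})

test_that("an exact exponential with 2-hr doubling yields dt_min = 2.000 and zero slope SE", {
  t <- seq(0, 12, by = 1 / 3)
  cv <- growth_curve(t, 100 * 2^(t / 2))
  cv$smoothed <- cv$raw
  res <- min_doubling_time(cv)
  expect_equal(res$dt_min, 2, tolerance = 1e-10)
  expect_lt(res$regression_se, 1e-10)
  # ties among identical slopes break to the earliest window center
  expect_equal(res$t_at_dt_min, t[3])
})

test_that("dt_min equals the brute-force minimum over all 5-point windows", {
  brute <- function(times, pop, window = 5) {
    best <- -Inf
    for (i in seq_len(length(times) - window + 1)) {
      j <- i:(i + window - 1)
      if (any(pop[j] <= 0)) next
      s <- unname(coef(lm(log2(pop[j]) ~ times[j]))[2])
      if (s > best) best <- s
    }
    if (best <= 0) NA_real_ else 1 / best
  }
  t <- seq(0, 12, by = 1 / 3)
  # piecewise growth: 4-hr doubling then 1.5-hr doubling
  pw <- ifelse(t < 6, 100 * 2^(t / 4), 100 * 2^(6 / 4) * 2^((t - 6) / 1.5))
  set.seed(21)
  cases <- list(
    piecewise = pw,
    exponential = 100 * 2^(t / 2),
    noisy = 100 * 2^(t / 2) * exp(rnorm(length(t), 0, 0.1)),
    sigmoid = 2^(10 + 5 * (1 - exp(-0.25 * t))^3),
    rough = 50 + 100 * abs(sin(t)))
  for (nm in names(cases)) {
    cv <- growth_curve(t, cases[[nm]])
    cv$smoothed <- cv$raw
    res <- min_doubling_time(cv)
    expect_equal(res$dt_min, brute(t, cases[[nm]]), tolerance = 1e-9,
                 label = paste("case", nm))
  }
  expect_equal(min_doubling_time({
    cv <- growth_curve(t, pw); cv$smoothed <- cv$raw; cv
  })$dt_min, 1.5, tolerance = 0.01)
})

test_that("dt_min is invariant under uniform population scaling", {
  t <- seq(0, 12, by = 1 / 3)
  set.seed(3)
  pop <- 2^(8 + 5 * (1 - exp(-0.3 * t))^3) * exp(rnorm(length(t), 0, 0.03))
  r1 <- min_doubling_time({cv <- growth_curve(t, pop); cv$smoothed <- pop; cv})
  r2 <- min_doubling_time({cv <- growth_curve(t, 7 * pop); cv$smoothed <- 7 * pop; cv})
  expect_equal(r1$dt_min, r2$dt_min, tolerance = 1e-12)
  expect_equal(r1$t_at_dt_min, r2$t_at_dt_min)
})

test_that("constant and declining curves are flagged non-growing", {
  t <- seq(0, 12, by = 1 / 3)
  for (pop in list(rep(500, length(t)), 500 * 2^(-t / 3))) {
    cv <- growth_curve(t, pop); cv$smoothed <- cv$raw
    res <- min_doubling_time(cv)
    expect_true("non_growing" %in% res$flags)
    expect_true(is.na(res$dt_min))
  }
})

test_that("discretized sigmoid dt_min overshoots truth by less than 2% at 20-min sampling", {
  lay <- plate_layout(96)
  sim <- simulate_growth_curves(lay, mean_dt = 2, bias_amplitude = 0,
                                pinning_cv = 0, noise_cv = 0, t_end = 24,
                                seed = 2)
  cv <- smooth_curve(sim$curves[[1]])
  res <- min_doubling_time(cv)
  expect_gte(res$dt_min, 2 * (1 - 1e-9))   # secant slopes cannot beat the max
  expect_lt(res$dt_min / 2 - 1, 0.02)
})

test_that("Chapman-Richards fit is self-consistent and reports noise as RMSE", {
  t <- seq(0, 24, by = 1 / 3)
  y <- 15 + (22 - 15) * (1 - 0.9 * exp(-0.3 * t))^2.5
  cv <- growth_curve(t, 2^y); cv$smoothed <- cv$raw
  fit <- chapman_richards_fit(cv)
  expect_lt(fit$rmse, 1e-6)
  expect_equal(unname(fit$params[c("y0", "K", "b", "r", "nu")]),
               c(15, 22, 0.9, 0.3, 2.5), tolerance = 0.01)
  # flat curve: K collapses onto y0 with ~zero RMSE
  cc <- growth_curve(t, rep(500, length(t))); cc$smoothed <- cc$raw
  fc <- chapman_richards_fit(cc)
  expect_equal(unname(fc$params["K"] - fc$params["y0"]), 0, tolerance = 1e-9)
  expect_lt(fc$rmse, 1e-9)
  # heavy noise: RMSE tracks the injected noise scale
  set.seed(13)
  yn <- y + rnorm(length(y), 0, 0.2)
  cn <- growth_curve(t, 2^yn); cn$smoothed <- cn$raw
  fn <- chapman_richards_fit(cn)
  expect_gt(fn$rmse, 0.1); expect_lt(fn$rmse, 0.35)
})

test_that("feature extraction assembles doublings, initial size and flags", {
  t <- seq(0, 10, by = 1 / 3)
  cv <- growth_curve(t, 100 * 2^(t / 2), row = 4, col = 7)
  cv$smoothed <- cv$raw
  f <- extract_features(cv, fit_cr = FALSE)
  expect_equal(f$doublings, 5)                     # 100 -> 3200 cells
  expect_equal(f$initial_cells, 100)
  expect_equal(c(f$row, f$col), c(4, 7))
  # zero initial population: doublings undefined and flagged
  z <- growth_curve(t, c(0, 100 * 2^(t[-1] / 2)))
  z$smoothed <- z$raw
  fz <- extract_features(z, fit_cr = FALSE)
  expect_true(is.na(fz$doublings))
  expect_match(fz$flags, "undefined_initial")
})

test_that("quality flagging passes clean plates and rejects pure-noise curves", {
  lay <- plate_layout(96)
  sim <- simulate_growth_curves(lay, bias_amplitude = 0, t_end = 16, seed = 17)
  feat <- extract_features_all(sim$curves, fit_cr = FALSE)
  feat <- flag_curves(feat)
  expect_lt(attr(feat, "flagged_fraction"), 0.01)
  # no-signal curves: lognormal noise around a constant
  set.seed(19)
  t <- seq(0, 16, by = 1 / 3)
  noise_curves <- lapply(1:30, function(i) {
    growth_curve(t, 500 * exp(rnorm(length(t), 0, 0.3)))
  })
  nf <- flag_curves(extract_features_all(noise_curves, fit_cr = FALSE))
  expect_equal(attr(nf, "flagged_fraction"), 1)
  # a curve whose steepest window touches the series end gets a boundary flag
  up <- growth_curve(t, 2^(5 + t))   # slope never peaks inside
  up$smoothed <- up$raw
  expect_true("boundary" %in% min_doubling_time(up)$flags)
})
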