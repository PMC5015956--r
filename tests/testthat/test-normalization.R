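make_controls <- function(layout, dt) {
  cp <- control_positions(layout)
  data.frame(row = cp$row, col = cp$col, dt_min_hr = dt)
}

test_that("control outlier filtering removes extremes by the 3-MAD rule", {
  lay <- plate_layout(96)
  equal <- make_controls(lay, rep(2, 24))
  kept <- filter_control_outliers(equal)
  expect_equal(nrow(kept), 24L)
  expect_equal(attr(kept, "removed_fraction"), 0)
  # a single 10x control is exactly the one removed
  one_out <- make_controls(lay, c(rep(2, 23), 20))
  kept2 <- filter_control_outliers(one_out)
  expect_equal(nrow(kept2), 23L)
  expect_equal(attr(kept2, "removed")$dt_min_hr, 20)
  # iid lognormal controls: mean removal fraction under 2%
  lay2 <- plate_layout(1536)
  fr <- vapply(1:20, function(s) {
    set.seed(s)
    ctrl <- make_controls(lay2, rlnorm(384, log(2), 0.1))
    attr(filter_control_outliers(ctrl), "removed_fraction")
  }, numeric(1))
  expect_lt(mean(fr), 0.02)
  expect_error(filter_control_outliers(make_controls(lay, rep(NA_real_, 24))),
               "at least 8")
})

test_that("the normalization surface reproduces constant and gradient control fields", {
  lay <- plate_layout(384)
  flat <- build_surface(lay, make_controls(lay, rep(2, 96)))
  expect_true(all(is.finite(flat$expected_dt)))
  expect_equal(dim(flat$expected_dt), c(16L, 24L))
  expect_equal(max(abs(flat$expected_dt - 2)), 0, tolerance = 1e-6)
  # linear gradient in column: recovered within 2% at every position
  cp <- control_positions(lay)
  grad <- data.frame(row = cp$row, col = cp$col,
                     dt_min_hr = 2 + 0.01 * cp$col)
  surf <- build_surface(lay, grad)
  truth <- outer(rep(1, lay$rows), 2 + 0.01 * (seq_len(lay$cols) - 1))
  expect_lt(max(abs(surf$expected_dt / truth - 1)), 0.02)
  # kernel variant also available and finite everywhere
  surfk <- build_surface(lay, grad, method = "kernel")
  expect_true(all(is.finite(surfk$expected_dt)))
})

test_that("the surface shrinks checkerboard control noise rather than tracking it", {
  lay <- plate_layout(384)
  cp <- control_positions(lay)
  checker <- 2 * 2^(0.2 * (-1)^((cp$row + cp$col) / 2))
  surf <- build_surface(lay, data.frame(row = cp$row, col = cp$col,
                                        dt_min_hr = checker))
  at_ctrl <- log2(surf$expected_dt[cbind(cp$row + 1, cp$col + 1)])
  expect_lt(var(at_ctrl), 0.05 * var(log2(checker)))
})

test_that("surface construction rejects degenerate control geometry", {
  lay <- plate_layout(384)
  cp <- control_positions(lay)
  few <- cp[cp$row == 1, ][1:8, ]       # all in one control row
  expect_error(build_surface(lay, data.frame(row = few$row, col = few$col,
                                             dt_min_hr = rep(2, 8))),
               "degenerate")
})

test_that("plate normalization is zero on-surface, signed by the defect convention, idempotent", {
  lay <- plate_layout(96)
  pos <- plate_positions(lay)
  feats <- data.frame(row = pos$row, col = pos$col, dt_min_hr = 2)
  surf <- build_surface(lay, make_controls(lay, rep(2, 24)))
  ph <- normalize_plate(feats, surf)
  expect_equal(ph$rel_phenotype_log2, rep(0, 96), tolerance = 1e-6)
  # observed doubling time twice the expectation: phenotype -1 (growth defect)
  slow <- feats; slow$dt_min_hr <- 4
  expect_equal(normalize_plate(slow, surf)$rel_phenotype_log2,
               rep(-1, 96), tolerance = 1e-6)
  # non-positive doubling times flagged undefined
  bad <- feats; bad$dt_min_hr[5] <- NA
  phb <- normalize_plate(bad, surf)
  expect_true(is.na(phb$rel_phenotype_log2[5]))
  expect_match(phb$flags[5], "undefined_dt")
})

test_that("between-plate alignment recovers a constructed offset and preserves the grand mean", {
  lay <- plate_layout(96)
  pos <- plate_positions(lay)
  surf <- build_surface(lay, make_controls(lay, rep(2, 24)))
  base_feats <- data.frame(row = pos$row, col = pos$col, dt_min_hr = 2)
  tabA <- normalize_plate(base_feats, surf, plate = "A")
  offs_feats <- base_feats; offs_feats$dt_min_hr <- 2 * 2^0.3
  surfB <- build_surface(lay, make_controls(lay, rep(2 * 2^0.3, 24)))
  tabB <- normalize_plate(offs_feats, surfB, plate = "B")
  ctrls <- list(A = rep(2, 24), B = rep(2 * 2^0.3, 24))
  out <- normalize_between_plates(list(A = tabA, B = tabB), ctrls)
  shifts <- attr(out, "shifts")
  # plate B is shifted 0.3 log2 down relative to plate A
  expect_equal(unname(shifts["B"] - shifts["A"]), -0.3, tolerance = 1e-9)
  # the grand control mean is invariant: shifted control means coincide
  expect_equal(mean(log2(ctrls$A)) + shifts[["A"]],
               mean(log2(ctrls$B)) + shifts[["B"]])
  # identical plates need no shift
  out2 <- normalize_between_plates(list(A = tabA, B = tabA),
                                   list(A = ctrls$A, B = ctrls$A))
  expect_equal(unname(attr(out2, "shifts")), c(0, 0))
})

test_that("condition differencing isolates condition-specific effects", {
  basal <- data.frame(strain = paste0("s", 1:5),
                      rel_phenotype_log2 = c(-0.2, 0, 0.1, -0.5, 0.3))
  stress <- data.frame(strain = paste0("s", 1:5),
                       rel_phenotype_log2 = c(-0.5, 0, 0.1, -0.5, 0.1))
  d <- condition_difference(stress, basal)
  expect_equal(d$condition_effect_log2[d$strain == "s1"], -0.3)
  expect_equal(d$condition_effect_log2[d$strain == "s3"], 0)
  # stress == basal: all zeros
  d0 <- condition_difference(basal, basal)
  expect_true(all(d0$condition_effect_log2 == 0))
  # independent basal and condition effects decorrelate (n = 1000)
  set.seed(31)
  n <- 1000
  basal_eff <- rnorm(n, 0, 0.3)
  cond_eff <- rnorm(n, 0, 0.3)
  b <- data.frame(strain = paste0("g", 1:n), rel_phenotype_log2 = basal_eff)
  s <- data.frame(strain = paste0("g", 1:n),
                  rel_phenotype_log2 = basal_eff + cond_eff)
  dd <- condition_difference(s, b)
  m <- merge(dd, b, by = "strain")
  expect_lt(abs(cor(m$condition_effect_log2, m$rel_phenotype_log2)), 0.1)
  # unmatched strains dropped with a count
  s2 <- s[1:900, ]
  expect_message(d2 <- condition_difference(s2, b), "unmatched")
  expect_equal(nrow(d2), 900L)
})
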