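# Shared fixtures: identity calibration, matrix helpers, small rendered plates.

identity_cell_cal <- function() {
  structure(list(coefficients = c(0, 1), degree = 1L, constrained_zero = TRUE,
                 fit_range = c(0, 1e9), rmse = 0),
            class = "cell_cal")
}

to_matrix <- function(layout, v, row, col) {
  m <- matrix(NA_real_, layout$rows, layout$cols)
  m[cbind(row + 1L, col + 1L)] <- v
  m
}

# A free-standing 1-cell grid for window-level segmentation tests.
single_window_grid <- function(size = 41L) {
  structure(list(centers_y = (size + 1) / 2, centers_x = (size + 1) / 2,
                 pitch = c(size, size), window = c(size, size),
                 rows = 1L, cols = 1L, image_dim = c(size, size)),
            class = "plate_grid")
}

# Draw filled discs (uniform opacity) on a background; centers in (y, x).
draw_discs <- function(dim_yx, centers, radii, heights, background = 0) {
  img <- matrix(background, dim_yx[1L], dim_yx[2L])
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(dim_yx[1L]) - 0.5 - centers[i, 1L])^2,
                (seq_len(dim_yx[2L]) - 0.5 - centers[i, 2L])^2, `+`)
    img[d2 <= radii[i]^2] <- heights[i]
  }
  img
}

# Gaussian-spot lattice image for grid-detection tests.
spot_lattice <- function(layout, px = 20, sigma = 2.5, height = 100,
                         drop = integer(0)) {
  H <- layout$rows * px; W <- layout$cols * px
  img <- matrix(0, H, W)
  pos <- plate_positions(layout)
  keep <- setdiff(seq_len(nrow(pos)), drop)
  for (i in keep) {
    cy <- (pos$row[i] + 0.5) * px; cx <- (pos$col[i] + 0.5) * px
    ys <- max(1, floor(cy - 4 * sigma)):min(H, ceiling(cy + 4 * sigma))
    xs <- max(1, floor(cx - 4 * sigma)):min(W, ceiling(cx + 4 * sigma))
    g <- height * exp(-outer((ys - 0.5 - cy)^2, (xs - 0.5 - cx)^2, `+`) /
                        (2 * sigma^2))
    img[ys, xs] <- img[ys, xs] + g
  }
  list(img = opacity_image(img, time = 1),
       centers_y = (seq_len(layout$rows) - 0.5) * px,
       centers_x = (seq_len(layout$cols) - 0.5) * px)
}

# Evaluate a fitted calibration polynomial at given raw values.
poly_at <- function(cal, x) phenoplate:::poly_eval(cal$coefficients, x)
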