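#' Plate layout for a pinned colony array
#'
#' Builds the geometry of a standard SBS pinned-array plate: 96 = 8 x 12,
#' 384 = 16 x 24, 1536 = 32 x 48 (rows x columns). Every fourth position is
#' reserved for an isogenic control colony: when a lower-density array is
#' replicated four-fold onto the next density, each source position becomes a
#' 2 x 2 "tetrad" of positions, and the control occupies the lower-right
#' position of every tetrad. With 0-based indices, row 0 at the image top and
#' column 0 at the left, the controls are exactly the positions with odd row
#' and odd column index, so no control lies on row 0 or column 0.
#'
#' @param format Plate density: one of 96, 384 or 1536.
#' @return An object of class \code{plate_layout} with elements \code{format},
#'   \code{rows}, \code{cols} and \code{is_control} (a rows x cols logical
#'   matrix, \code{TRUE} at control positions).
#' @examples
#' lay <- plate_layout(1536)
#' sum(lay$is_control)   # 384 control positions
#' @export
plate_layout <- function(format) {
  shapes <- list(`96` = c(8L, 12L), `384` = c(16L, 24L), `1536` = c(32L, 48L))
  key <- as.character(format)
  if (length(format) != 1L || !key %in% names(shapes)) {
    stop("unsupported plate format '", format,
         "'; allowed formats are 96, 384 and 1536", call. = FALSE)
  }
  rc <- shapes[[key]]
  rows <- rc[1L]; cols <- rc[2L]
  # control rule: odd row AND odd col (0-based) = lower right of each tetrad
  ctrl <- outer(seq_len(rows) - 1L, seq_len(cols) - 1L,
                function(r, c) (r %% 2L == 1L) & (c %% 2L == 1L))
  structure(list(format = as.integer(format), rows = rows, cols = cols,
                 is_control = ctrl),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("plate_layout: %d-format (%d x %d), %d control / %d experimental positions\n",
              x$format, x$rows, x$cols, sum(x$is_control), sum(!x$is_control)))
  invisible(x)
}

#' All positions of a plate layout
#'
#' @param layout A \code{plate_layout}.
#' @return Data frame with 0-based integer columns \code{row}, \code{col} in
#'   row-major order.
#' @export
plate_positions <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  data.frame(row = rep(seq_len(layout$rows) - 1L, each = layout$cols),
             col = rep(seq_len(layout$cols) - 1L, times = layout$rows))
}

#' Control positions of a plate layout
#'
#' The reference-grid positions (odd row, odd col; 0-based), in row-major
#' order. These hold the isogenic wild-type controls from which the
#' normalization surface is interpolated.
#'
#' @param layout A \code{plate_layout}.
#' @return Data frame with columns \code{row}, \code{col}; exactly
#'   \code{rows * cols / 4} positions.
#' @export
control_positions <- function(layout) {
  pos <- plate_positions(layout)
  pos[layout$is_control[cbind(pos$row + 1L, pos$col + 1L)], , drop = FALSE]
}

#' Experimental (non-control) positions of a plate layout
#'
#' @param layout A \code{plate_layout}.
#' @return Data frame with columns \code{row}, \code{col}.
#' @export
experimental_positions <- function(layout) {
  pos <- plate_positions(layout)
  pos[!layout$is_control[cbind(pos$row + 1L, pos$col + 1L)], , drop = FALSE]
}

#' Moore (8-connected) neighborhood of a position
#'
#' In-bounds positions at Chebyshev distance 1 from \code{(row, col)}; used by
#' the adjacency bias diagnostics ("immediately adjacent colonies").
#'
#' @param layout A \code{plate_layout}.
#' @param row,col 0-based position indices.
#' @param scheme Neighborhood scheme; only \code{"moore8"} is supported.
#' @return Data frame with columns \code{row}, \code{col} (3 to 8 rows).
#' @export
neighbors <- function(layout, row, col, scheme = "moore8") {
  stopifnot(inherits(layout, "plate_layout"))
  scheme <- match.arg(scheme, "moore8")
  if (length(row) != 1L || length(col) != 1L ||
      row < 0L || row >= layout$rows || col < 0L || col >= layout$cols) {
    stop("position (", row, ",", col, ") is outside the ",
         layout$rows, " x ", layout$cols, " plate", call. = FALSE)
  }
  d <- expand.grid(dr = -1:1, dc = -1:1)
  d <- d[!(d$dr == 0L & d$dc == 0L), ]
  nb <- data.frame(row = row + d$dr, col = col + d$dc)
  nb <- nb[nb$row >= 0L & nb$row < layout$rows &
           nb$col >= 0L & nb$col < layout$cols, , drop = FALSE]
  rownames(nb) <- NULL
  nb
}
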