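# Shift a matrix by (dy, dx), padding with `fill`.
shift_matrix <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  yok <- ys >= 1L & ys <= nr; xok <- xs >= 1L & xs <= nc
  out[yok, xok] <- m[ys[yok], xs[xok]]
  out
}

moore_offsets <- expand.grid(dr = -1:1, dc = -1:1)
moore_offsets <- moore_offsets[!(moore_offsets$dr == 0 & moore_offsets$dc == 0), ]

#' Adjacency false-positive test for residual spatial bias
#'
#' For every experimental focal colony, the doubling times of its immediately
#' adjacent experimental colonies (Moore 8-neighborhood; control positions
#' excluded from focal, adjacent, and nonadjacent sets) are compared with the
#' mean of all nonadjacent experimental values by a one-sample Student's
#' t-test (H0: no difference). On a plate of genetically identical colonies
#' with no spatial bias, the expected rejection fraction equals the
#' significance level; any systematic excess measures spatial bias.
#'
#' @param layout A \code{\link{plate_layout}}.
#' @param values rows x cols numeric matrix of per-position doubling times (or
#'   any per-position statistic; use normalized phenotypes to test residual
#'   bias after normalization).
#' @param alpha Significance level (default 0.05).
#' @return Object of class \code{bias_report}: \code{fp_rate}, \code{alpha},
#'   \code{n_tested}, \code{n_skipped} (focal colonies with < 2 valid
#'   neighbors or zero neighbor variance), \code{cv_plate} (percent CV over
#'   experimental values, when defined), \code{neighbor_cv} (summary of
#'   \code{\link{neighbor_cv}}), and the per-focal p-value matrix.
#' @export
adjacency_fp_rate <- function(layout, values, alpha = 0.05) {
  stopifnot(inherits(layout, "plate_layout"), is.matrix(values),
            nrow(values) == layout$rows, ncol(values) == layout$cols)
  expm <- !layout$is_control
  valid <- expm & is.finite(values)
  if (sum(valid) < 100L) {
    stop("need >= 100 experimental positions with finite values", call. = FALSE)
  }
  X <- ifelse(valid, values, 0)
  V <- valid * 1
  nsum <- nss <- ncnt <- matrix(0, layout$rows, layout$cols)
  for (i in seq_len(nrow(moore_offsets))) {
    dy <- moore_offsets$dr[i]; dx <- moore_offsets$dc[i]
    nsum <- nsum + shift_matrix(X, dy, dx)
    nss <- nss + shift_matrix(X^2, dy, dx)
    ncnt <- ncnt + shift_matrix(V, dy, dx)
  }
  S <- sum(X); N <- sum(V)
  focal <- valid & ncnt >= 2L
  n <- ncnt[focal]
  m <- nsum[focal] / n
  v <- pmax((nss[focal] - nsum[focal]^2 / n) / (n - 1), 0)
  mu0 <- (S - X[focal] - nsum[focal]) / (N - 1 - n)
  eps <- 1e-12 * pmax(abs(m), 1)^2
  zerovar <- v <= eps
  tt <- (m - mu0) / sqrt(v / n)
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  p[zerovar] <- NA_real_
  n_tested <- sum(!zerovar)
  n_skipped <- sum(valid & ncnt < 2L) + sum(zerovar)
  fp <- if (n_tested > 0L) sum(p < alpha, na.rm = TRUE) / n_tested else 0
  pmat <- matrix(NA_real_, layout$rows, layout$cols)
  pmat[focal] <- p
  ev <- values[valid]
  cv <- if (mean(ev) > 0) 100 * stats::sd(ev) / mean(ev) else NA_real_
  ncv <- tryCatch(neighbor_cv(layout, values), error = function(e) NULL)
  structure(list(fp_rate = fp, alpha = alpha, n_tested = n_tested,
                 n_skipped = n_skipped, cv_plate = cv,
                 neighbor_cv = if (is.null(ncv)) NULL else attr(ncv, "summary"),
                 p_values = pmat),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf(
    "bias_report: fp_rate %.3f (alpha %.2f, %d tested, %d skipped), plate CV %s%%\n",
    x$fp_rate, x$alpha, x$n_tested, x$n_skipped,
    if (is.na(x$cv_plate)) "NA" else sprintf("%.1f", x$cv_plate)))
  if (!is.null(x$neighbor_cv)) {
    cat(sprintf("  neighbor CV%%: median %.2f, IQR [%.2f, %.2f], range [%.2f, %.2f]\n",
                x$neighbor_cv[["median"]], x$neighbor_cv[["q25"]],
                x$neighbor_cv[["q75"]], x$neighbor_cv[["min"]],
                x$neighbor_cv[["max"]]))
  }
  invisible(x)
}

#' Plate coefficient of variation
#'
#' 100 * sd / mean over the supplied values (sample standard deviation).
#'
#' @param values Numeric vector (non-finite values dropped).
#' @return CV in percent.
#' @export
plate_cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need >= 2 finite values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("CV undefined for non-positive mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Coefficient of variation between adjacent colonies
#'
#' For each experimental focal position, the CV (percent) over the values of
#' its experimental Moore neighbors; neighborhoods with fewer than 2 valid
#' values are skipped.
#'
#' @param layout A \code{\link{plate_layout}}.
#' @param values rows x cols numeric matrix.
#' @return Numeric vector of per-focal CVs with a \code{summary} attribute
#'   (median, q25, q75, min, max).
#' @export
neighbor_cv <- function(layout, values) {
  stopifnot(inherits(layout, "plate_layout"), is.matrix(values),
            nrow(values) == layout$rows, ncol(values) == layout$cols)
  expm <- !layout$is_control
  valid <- expm & is.finite(values)
  X <- ifelse(valid, values, 0)
  V <- valid * 1
  nsum <- nss <- ncnt <- matrix(0, layout$rows, layout$cols)
  for (i in seq_len(nrow(moore_offsets))) {
    dy <- moore_offsets$dr[i]; dx <- moore_offsets$dc[i]
    nsum <- nsum + shift_matrix(X, dy, dx)
    nss <- nss + shift_matrix(X^2, dy, dx)
    ncnt <- ncnt + shift_matrix(V, dy, dx)
  }
  focal <- valid & ncnt >= 2L
  n <- ncnt[focal]
  m <- nsum[focal] / n
  v <- pmax((nss[focal] - nsum[focal]^2 / n) / (n - 1), 0)
  cv <- ifelse(m > 0, 100 * sqrt(v) / m, NA_real_)
  cv <- cv[is.finite(cv)]
  if (length(cv) == 0L) stop("no neighborhoods with >= 2 valid values", call. = FALSE)
  attr(cv, "summary") <- c(median = stats::median(cv),
                           q25 = unname(stats::quantile(cv, 0.25)),
                           q75 = unname(stats::quantile(cv, 0.75)),
                           min = min(cv), max = max(cv))
  cv
}
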