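#' Break point of a curve by maximum perpendicular distance to the chord
#'
#' Draws the chord from the first to the last data point and returns the
#' interior index with the largest unsigned perpendicular distance to it,
#' computed in raw data units (no axis normalization: display scaling
#' would distort the perpendicular). Ties break toward the smallest index,
#' i.e. the earliest detectable transition.
#'
#' @param xs Strictly increasing abscissae (length >= 3).
#' @param ys Ordinates, same length.
#' @param normalize Optionally min-max scale both axes to \[0, 1\] before
#'   measuring distances (default `FALSE`).
#' @return The 1-based index of the break point (always interior).
#' @export
find_break_point <- function(xs, ys, normalize = FALSE) {
  n <- length(xs)
  if (n < 3) stop("need at least 3 points to locate a break point")
  if (length(ys) != n) stop("xs and ys must have the same length")
  if (any(diff(xs) <= 0)) stop("xs must be strictly increasing")
  if (normalize) {
    xs <- (xs - xs[1]) / (xs[n] - xs[1])
    if (max(ys) > min(ys)) ys <- (ys - min(ys)) / (max(ys) - min(ys))
  }
  dx <- xs[n] - xs[1]; dy <- ys[n] - ys[1]
  d <- abs(dx * (ys[1] - ys) - (xs[1] - xs) * dy) / sqrt(dx^2 + dy^2)
  interior <- 2:(n - 1)
  interior[which.max(d[interior])]
}

#' Estimate the onset of rapid cell elongation
#'
#' Locates the transition-zone landmark on the cell-length series as the
#' break point (maximum perpendicular distance to the first-to-last
#' chord). In the default `cell_number` mode the abscissa is the cell
#' index 1..n; the `cumulative_length` variant uses each cell's start
#' position instead, but forms less well-defined curves (elongated cells
#' stretch the axis) and is provided for comparison only.
#'
#' For a meaningful estimate the profile should reach well into the
#' elongation zone: a warning (not an error) is emitted unless at least
#' two cells are ~4x the typical meristem cell length (the median of the
#' first quarter of the series).
#'
#' @param cellfile A [cell_file] with >= 3 cells.
#' @param mode `"cell_number"` (default) or `"cumulative_length"`.
#' @param normalize Passed to [find_break_point()].
#' @return An object of class `tsz_estimate`: `cell_index` (1-based),
#'   `distance_um` (arc distance from the profile start to the proximal
#'   boundary of that cell) and `mode`.
#' @export
estimate_tsz <- function(cellfile, mode = c("cell_number",
                                            "cumulative_length"),
                         normalize = FALSE) {
  stopifnot(inherits(cellfile, "cell_file"))
  mode <- match.arg(mode)
  L <- cellfile$lengths_um
  n <- cellfile$n_cells
  if (n < 3) stop("need at least 3 cells to estimate the transition zone")
  meristem_len <- stats::median(L[seq_len(ceiling(n / 4))])
  if (sum(L >= 4 * meristem_len) < 2)
    warning(paste("profile may not extend far enough into the elongation",
                  "zone: fewer than 2 cells reach ~4x the meristem cell",
                  "length"), call. = FALSE)
  xs <- switch(mode, cell_number = seq_len(n),
               cumulative_length = cellfile$starts_um)
  idx <- find_break_point(xs, L, normalize = normalize)
  structure(list(cell_index = idx,
                 distance_um = cellfile$starts_um[idx],
                 mode = mode),
            class = "tsz_estimate")
}

#' @export
print.tsz_estimate <- function(x, ...) {
  cat(sprintf(
    "<tsz_estimate> cell %d, %.2f um from profile start (mode: %s)\n",
    x$cell_index, x$distance_um, x$mode))
  invisible(x)
}

#' Plot the cell-length series with chord and break point
#'
#' Cell number against cell length, with the first-to-last chord and the
#' transition-zone break point marked.
#'
#' @param cellfile A [cell_file].
#' @param tsz Optional [tsz_estimate] to mark.
#' @param path Optional PNG output path; when `NULL`, plots to the active
#'   device.
#' @export
plot_length_series <- function(cellfile, tsz = NULL, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  L <- cellfile$lengths_um; n <- cellfile$n_cells
  graphics::plot(seq_len(n), L, type = "b", pch = 16,
                 xlab = "cell number", ylab = "cell length (um)",
                 main = "Cell length along the file")
  graphics::segments(1, L[1], n, L[n], col = "grey50", lty = 2)
  if (!is.null(tsz)) {
    graphics::points(tsz$cell_index, L[tsz$cell_index], col = "red",
                     pch = 17, cex = 1.6)
    graphics::abline(v = tsz$cell_index, col = "red", lty = 3)
  }
  invisible(NULL)
}
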