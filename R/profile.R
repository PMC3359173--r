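#' Fit a spline through a polyline and resample at uniform arc length
#'
#' Fits an interpolating cubic spline through the polyline anchors
#' (chord-length parameterized, natural end conditions; two anchors give a
#' straight segment) and resamples it at uniform arc-length steps by
#' numeric inversion of the cumulative arc length, measured on a dense
#' evaluation of the spline. The first sample lies on the first anchor and
#' the last sample within one step of the last anchor.
#'
#' @param poly A [polyline].
#' @param step_px Arc-length sample spacing in pixels (default 1, matching
#'   a per-pixel scan of the profile).
#' @return An object of class `sampled_path` with elements `points`
#'   (n x 2 matrix of x, y), `step_px`, and `arc_length_px` (cumulative
#'   arc length per sample, starting at 0).
#' @export
fit_spline <- function(poly, step_px = 1.0) {
  stopifnot(inherits(poly, "polyline"))
  if (!is.numeric(step_px) || step_px <= 0) stop("step_px must be > 0")
  a <- poly$anchors
  seg <- sqrt(rowSums(diff(a)^2))
  if (any(seg == 0)) stop("consecutive anchors must not be identical")
  tk <- c(0, cumsum(seg))
  if (nrow(a) == 2) {
    fx <- stats::approxfun(tk, a[, 1])
    fy <- stats::approxfun(tk, a[, 2])
  } else {
    fx <- stats::splinefun(tk, a[, 1], method = "natural")
    fy <- stats::splinefun(tk, a[, 2], method = "natural")
  }
  # dense polyline for arc-length inversion: ~0.05 px parameter resolution
  tt <- seq(0, tk[length(tk)],
            length.out = max(1000L, ceiling(tk[length(tk)] / 0.05)))
  dx <- fx(tt); dy <- fy(tt)
  cum <- c(0, cumsum(sqrt(diff(dx)^2 + diff(dy)^2)))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step_px)
  t_at_s <- stats::approx(cum, tt, xout = s, ties = "ordered")$y
  structure(
    list(points = cbind(x = fx(t_at_s), y = fy(t_at_s)),
         step_px = step_px, arc_length_px = s, total_length_px = total),
    class = "sampled_path")
}

#' @export
print.sampled_path <- function(x, ...) {
  cat(sprintf("<sampled_path> %d samples, step %.3g px, length %.2f px\n",
              nrow(x$points), x$step_px,
              x$arc_length_px[length(x$arc_length_px)]))
  invisible(x)
}

# Bilinear interpolation of image intensity at continuous pixel-center
# coordinates. Vectorized over points.
bilinear_at <- function(pixels, x, y) {
  w <- ncol(pixels); h <- nrow(pixels)
  x0 <- pmin(pmax(floor(x), 0), w - 2)
  y0 <- pmin(pmax(floor(y), 0), h - 2)
  dx <- x - x0; dy <- y - y0
  i00 <- pixels[cbind(y0 + 1, x0 + 1)]
  i01 <- pixels[cbind(y0 + 1, x0 + 2)]
  i10 <- pixels[cbind(y0 + 2, x0 + 1)]
  i11 <- pixels[cbind(y0 + 2, x0 + 2)]
  (1 - dy) * ((1 - dx) * i00 + dx * i01) + dy * ((1 - dx) * i10 + dx * i11)
}

#' Sample image intensity along a path
#'
#' Bilinearly interpolates the image at every point of the sampled path,
#' producing an intensity profile in calibrated arc-length coordinates
#' (`s_um = arc_length_px * pixel_size_um`).
#'
#' @param image A [calibrated_image].
#' @param path A [sampled_path].
#' @return An object of class `intensity_profile` with elements `s_um`,
#'   `intensity`, `pixel_size_um`, `step_px` and `points` (the path
#'   coordinates, carried along for wall localization).
#' @export
sample_intensity <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(path, "sampled_path"))
  pts <- path$points
  w <- ncol(image$pixels); h <- nrow(image$pixels)
  out <- which(pts[, 1] < 0 | pts[, 1] > w - 1 |
               pts[, 2] < 0 | pts[, 2] > h - 1)
  if (length(out) > 0)
    stop(sprintf(
      "path sample %d at (%.2f, %.2f) lies outside the image bounds",
      out[1], pts[out[1], 1], pts[out[1], 2]))
  intensity <- bilinear_at(image$pixels, pts[, 1], pts[, 2])
  structure(
    list(s_um = path$arc_length_px * image$pixel_size_um,
         intensity = intensity,
         pixel_size_um = image$pixel_size_um,
         step_px = path$step_px,
         points = pts),
    class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf(
    "<intensity_profile> %d samples over %.2f um (%.4g um/px)\n",
    length(x$intensity), x$s_um[length(x$s_um)], x$pixel_size_um))
  invisible(x)
}
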