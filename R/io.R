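#' Calibrated grayscale image
#'
#' Container for a single-channel image together with its spatial
#' calibration. Pixel values are kept in raw units (integer counts for 8-
#' and 16-bit data). Coordinates used throughout the package are 0-based
#' continuous pixel-center coordinates: x increases rightward (columns),
#' y downward (rows), and the center of the top-left pixel is (0, 0).
#'
#' @param pixels Numeric matrix of intensities, rows = y, columns = x.
#' @param pixel_size_um Microns per pixel (scalar > 0, square pixels).
#' @param bit_depth Either 8 or 16.
#' @param source_path Optional origin of the data, for provenance.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, bit_depth = 16L,
                             source_path = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    stop("intensities outside [0, 2^bit_depth - 1]")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         bit_depth = as.integer(bit_depth), source_path = source_path),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %d-bit, %.4g um/px\n",
              ncol(x$pixels), nrow(x$pixels), x$bit_depth,
              x$pixel_size_um))
  invisible(x)
}

#' Polyline region of interest
#'
#' An ordered list of at least two anchor points, in 0-based pixel-center
#' coordinates, tracing the cell file to be measured.
#'
#' @param anchors Two-column numeric matrix (x, y) or a list of length-2
#'   vectors.
#' @return An object of class `polyline`.
#' @export
polyline <- function(anchors) {
  if (is.list(anchors)) anchors <- do.call(rbind, anchors)
  anchors <- as.matrix(anchors)
  if (ncol(anchors) != 2 || !is.numeric(anchors))
    stop("`anchors` must be an n x 2 numeric matrix of (x, y)")
  if (nrow(anchors) < 2) stop("a polyline needs at least 2 anchors")
  seg <- sqrt(rowSums(diff(anchors)^2))
  if (any(seg == 0)) stop("consecutive anchors must not be identical")
  colnames(anchors) <- c("x", "y")
  structure(list(anchors = unname(anchors)), class = "polyline")
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("<polyline> %d anchors, chord length %.2f px\n",
              nrow(x$anchors), sum(sqrt(rowSums(diff(x$anchors)^2)))))
  invisible(x)
}

# Bit depth of a PNG file from its IHDR chunk (byte 25 of the file).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26)
  as.integer(hdr[25])
}

# Convert TIFF resolution tags to a pixel size in microns. XResolution is
# pixels per resolution unit; with no absolute unit it is taken as px/um.
tiff_pixel_size <- function(info) {
  xres <- info[["x.resolution"]]
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  yres <- info[["y.resolution"]]
  if (!is.null(yres) && is.finite(yres) && abs(yres - xres) > 1e-6 * xres)
    stop("anisotropic pixel calibration (x != y resolution) is not supported")
  unit <- info[["resolution.unit"]]
  if (is.null(unit)) unit <- "none"
  switch(unit,
         none = , unknown = 1 / xres,      # px per micron
         cm = 1e4 / xres,
         inch = 25400 / xres,
         stop("unsupported TIFF resolution unit: ", unit))
}

#' Read a calibrated grayscale image
#'
#' Reads an 8- or 16-bit TIFF or PNG as a [calibrated_image]. The pixel
#' size is taken, in order of precedence, from the `pixel_size_um`
#' argument, then from TIFF resolution metadata, and otherwise defaults to
#' 1 micron/pixel with a warning. Multi-channel images require an explicit
#' `channel`; no automatic projection is performed.
#'
#' @param path Path to a TIFF or PNG file.
#' @param pixel_size_um Optional calibration override (um per pixel).
#' @param channel 1-based channel index for multi-channel images.
#' @return A [calibrated_image].
#' @export
read_image <- function(path, pixel_size_um = NULL, channel = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  magic <- readBin(path, "raw", n = 4)
  is_png <- identical(as.integer(magic[1:4]), c(137L, 80L, 78L, 71L))
  meta_px <- NULL
  if (is_png) {
    arr <- png::readPNG(path)
    bit <- png_bit_depth(path)
    if (!bit %in% c(8L, 16L))
      stop("unsupported PNG bit depth: ", bit)
    if (length(dim(arr)) == 3) {
      if (is.null(channel)) stop("multi-channel image: `channel` required")
      if (channel < 1 || channel > dim(arr)[3])
        stop("channel index out of range: ", channel)
      arr <- arr[, , channel]
    }
    pix <- round(arr * (2^bit - 1))
  } else {
    arr <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                    error = function(e) stop("unreadable image: ", path,
                                             " (", conditionMessage(e), ")"))
    info <- attributes(arr)
    bit <- info[["bits.per.sample"]]
    if (is.null(bit) || !bit %in% c(8L, 16L))
      stop("unsupported TIFF bit depth")
    if (length(dim(arr)) == 3) {
      if (is.null(channel)) stop("multi-channel image: `channel` required")
      if (channel < 1 || channel > dim(arr)[3])
        stop("channel index out of range: ", channel)
      arr <- arr[, , channel]
    }
    pix <- arr
    meta_px <- tiff_pixel_size(info)
  }
  if (!is.null(pixel_size_um)) {
    if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
    px <- pixel_size_um
  } else if (!is.null(meta_px)) {
    px <- meta_px
    message(sprintf("calibration from image metadata: %.6g um/px", px))
  } else {
    px <- 1.0
    warning("no calibration available; defaulting to 1.0 um/px",
            call. = FALSE)
  }
  calibrated_image(matrix(as.numeric(pix), nrow = nrow(pix)),
                   pixel_size_um = px, bit_depth = bit,
                   source_path = normalizePath(path))
}

# ImageJ .roi binary reader (polyline subtypes only). Layout after the
# "Iout" magic: version short at 4, type byte at 6, bounding box shorts at
# 8..15 (top, left, bottom, right), n at 16, line endpoints as floats at
# 18..33, options short at 50 (bit 7 = sub-pixel resolution), coordinate
# block from byte 64: n shorts of x then n shorts of y relative to
# (left, top); with sub-pixel resolution, 4-byte absolute floats follow.
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ .roi file: ", path)
  rd_short <- function(off, n = 1)  # big-endian, byte offset is 0-based
    readBin(raw[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
            endian = "big")
  rd_float <- function(off, n = 1)
    readBin(raw[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "big")
  type <- as.integer(raw[7])
  top <- rd_short(8); left <- rd_short(10)
  n <- rd_short(16)
  options <- rd_short(50)
  subpixel <- bitwAnd(options, 128L) != 0L
  if (type == 3L) {                       # straight line: float endpoints
    xy <- rd_float(18, 4)
    anchors <- cbind(c(xy[1], xy[3]), c(xy[2], xy[4]))
  } else if (type %in% c(4L, 5L)) {       # freeline / polyline
    if (n < 2) stop("ROI has fewer than 2 anchors")
    if (subpixel) {
      xs <- rd_float(64 + 4 * n, n)
      ys <- rd_float(64 + 4 * n + 4 * n, n)
      anchors <- cbind(xs, ys)
    } else {
      xs <- rd_short(64, n) + left
      ys <- rd_short(64 + 2 * n, n) + top
      anchors <- cbind(xs, ys)
    }
  } else {
    stop("unsupported ROI type ", type,
         ": only line/polyline/freeline ROIs are accepted")
  }
  # ImageJ integer line coordinates sit on pixel corners; shift to the
  # pixel-center convention used throughout this package.
  polyline(anchors - 0.5)
}

#' Read a polyline region of interest
#'
#' Accepts either the package's JSON dialect
#' `{"anchors": [[x, y], ...]}` (pixel-center coordinates) or a binary
#' ImageJ `.roi` file of line/polyline/freeline type, whose corner-origin
#' coordinates are shifted by -0.5 to pixel-center coordinates.
#'
#' @param path Path to a `.json` or `.roi` file.
#' @return A [polyline].
#' @export
read_polyline <- function(path) {
  if (!file.exists(path)) stop("polyline file not found: ", path)
  magic <- readBin(path, "raw", n = 4)
  if (length(magic) == 4 && rawToChar(magic) == "Iout")
    return(read_imagej_roi(path))
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$anchors)) stop("JSON polyline must have an 'anchors' field")
  polyline(obj$anchors)
}

#' Write a polyline to JSON
#'
#' @param poly A [polyline].
#' @param path Output path.
#' @export
write_polyline <- function(poly, path) {
  jsonlite::write_json(list(anchors = poly$anchors), path, digits = NA)
  invisible(path)
}

#' Write cell measurements to CSV
#'
#' Writes one row per cell with columns `cell_index` (1-based),
#' `start_um`, `end_um` and `length_um`. When a transition-zone estimate
#' is supplied, a JSON sidecar `<path>.tsz.json` records the landmark both
#' as a cell count and as a distance from the profile start.
#'
#' @param cellfile A [cell_file].
#' @param path Output CSV path.
#' @param tsz Optional [tsz_estimate].
#' @export
write_measurements <- function(cellfile, path, tsz = NULL) {
  n <- cellfile$n_cells
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("cell_index,start_um,end_um,length_um", con)
  if (n > 0) {
    rows <- sprintf("%d,%.6f,%.6f,%.6f", seq_len(n), cellfile$starts_um,
                    cellfile$starts_um + cellfile$lengths_um,
                    cellfile$lengths_um)
    writeLines(rows, con)
  }
  if (!is.null(tsz)) {
    jsonlite::write_json(
      list(cell_index = tsz$cell_index, distance_um = tsz$distance_um,
           mode = tsz$mode),
      paste0(path, ".tsz.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a measurements CSV back into a cell file
#'
#' @param path Path to a CSV written by [write_measurements()].
#' @return A [cell_file].
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) return(cell_file(numeric(0)))
  cell_file(df$length_um, start_um = df$start_um[1])
}

# Stamp a filled square marker centred at pixel-center coords (x, y).
stamp_marker <- function(rgb, x, y, half, col) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  rs <- max(1, round(y) + 1 - half):min(h, round(y) + 1 + half)
  cs <- max(1, round(x) + 1 - half):min(w, round(x) + 1 + half)
  for (k in 1:3) rgb[rs, cs, k] <- col[k]
  rgb
}

#' Write an annotated overlay image
#'
#' Renders the grayscale image as RGB, draws the sampled profile line in
#' blue, a red square marker at every detected wall, and a green marker at
#' the wall nearest the transition-zone landmark when one is supplied.
#'
#' @param image A [calibrated_image].
#' @param path_samples A [sampled_path] from [fit_spline()].
#' @param walls A [wall_set] (may be empty).
#' @param path Output PNG path.
#' @param tsz Optional [tsz_estimate].
#' @export
write_overlay <- function(image, path_samples, walls, path, tsz = NULL) {
  g <- image$pixels / (2^image$bit_depth - 1)
  rgb <- array(c(g, g, g), dim = c(nrow(g), ncol(g), 3))
  pts <- path_samples$points
  rr <- pmin(pmax(round(pts[, 2]) + 1, 1), nrow(g))
  cc <- pmin(pmax(round(pts[, 1]) + 1, 1), ncol(g))
  for (i in seq_along(rr)) rgb[rr[i], cc[i], ] <- c(0, 0, 1)
  tsz_i <- 0L
  if (!is.null(tsz) && nrow(walls$walls) > 0)
    tsz_i <- which.min(abs(walls$walls$s_um - tsz$distance_um))
  if (nrow(walls$walls) > 0) {
    for (i in seq_len(nrow(walls$walls))) {
      col <- if (i == tsz_i) c(0, 1, 0) else c(1, 0, 0)
      rgb <- stamp_marker(rgb, walls$walls$x[i], walls$walls$y[i], 1, col)
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
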