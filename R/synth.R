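#' Specification for a synthetic cell-file image
#'
#' Parameters of the ground-truthed generator that emulates a confocal
#' image of a single file of cells: bright Gaussian wall ridges
#' perpendicular to the file axis on a dark noisy background, with cell
#' lengths roughly constant in a meristem region and then ramping up
#' geometrically to `elongation_factor` times the meristem length, as
#' cells do on entering the elongation zone.
#'
#' @param n_meristem Cells before the elongation ramp (default 30).
#' @param L_m Mean meristem cell length, um (default 8).
#' @param elongation_factor Final/initial length ratio (default 15, the
#'   typical expansion of an elongating root cell).
#' @param ramp_cells Cells over which elongation completes (default 6).
#' @param n_post Fully elongated cells after the ramp (default 3).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   length noise (default 0.1).
#' @param wall_sigma_px Gaussian ridge half-width in pixels (default 1.5).
#' @param wall_amp Ridge peak intensity, raw 16-bit units (default 4000).
#' @param bg_noise_sd Additive background noise sd (default 80).
#' @param pixel_size_um Calibration (default 0.5 um/px).
#' @param seed RNG seed (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_meristem = 30L, L_m = 8, elongation_factor = 15,
                           ramp_cells = 6L, n_post = 3L, noise_cv = 0.1,
                           wall_sigma_px = 1.5, wall_amp = 4000,
                           bg_noise_sd = 80, pixel_size_um = 0.5, seed = 1L) {
  spec <- list(n_meristem = as.integer(n_meristem), L_m = L_m,
               elongation_factor = elongation_factor,
               ramp_cells = as.integer(ramp_cells),
               n_post = as.integer(n_post), noise_cv = noise_cv,
               wall_sigma_px = wall_sigma_px, wall_amp = wall_amp,
               bg_noise_sd = bg_noise_sd, pixel_size_um = pixel_size_um,
               seed = as.integer(seed))
  pos <- c("n_meristem", "L_m", "elongation_factor", "ramp_cells",
           "wall_sigma_px", "wall_amp", "pixel_size_um")
  for (f in pos) if (spec[[f]] <= 0) stop("`", f, "` must be positive")
  if (spec$n_post < 0) stop("`n_post` must be >= 0")
  if (spec$elongation_factor <= 1) stop("`elongation_factor` must be > 1")
  if (spec$noise_cv < 0 || spec$bg_noise_sd < 0)
    stop("noise parameters must be >= 0")
  structure(spec, class = "synthetic_spec")
}

#' Generate a ground-truthed cell-length series
#'
#' The noise-free template holds `n_meristem` cells at `L_m`, then a
#' geometric ramp reaching `L_m * elongation_factor` over `ramp_cells`
#' cells, then `n_post` cells at the final length. Multiplicative
#' lognormal noise with the requested coefficient of variation (unit mean)
#' is applied to every cell. The true transition index is `n_meristem`,
#' the last meristem-length cell: the change point just before elongation
#' begins, which is what the break-point rule locates.
#'
#' @param spec A [synthetic_spec].
#' @return List with `lengths_um` and `true_tsz_index`.
#' @export
generate_length_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  base <- c(rep(spec$L_m, spec$n_meristem),
            spec$L_m * spec$elongation_factor^
              (seq_len(spec$ramp_cells) / spec$ramp_cells),
            rep(spec$L_m * spec$elongation_factor, spec$n_post))
  if (spec$noise_cv > 0) {
    set.seed(spec$seed)
    s2 <- log(1 + spec$noise_cv^2)   # lognormal with unit mean, given CV
    base <- base * stats::rlnorm(length(base), -s2 / 2, sqrt(s2))
  }
  list(lengths_um = base, true_tsz_index = spec$n_meristem)
}

# Nearest-wall distance (in px) for a vector of arc positions.
nearest_wall_dist <- function(s_px, walls_px) {
  apply(abs(outer(s_px, walls_px, "-")), 1, min)
}

#' Render a synthetic cell-file image
#'
#' Draws bright Gaussian ridges (in arc-length distance to the nearest
#' wall plane, constant across the file's width) at the cumulative wall
#' positions of the given lengths, on a zero-mean background with additive
#' Gaussian noise, as a 16-bit calibrated image. The returned polyline
#' runs along the file axis and starts exactly at wall 0.
#'
#' @param lengths_um Per-cell lengths (um).
#' @param spec A [synthetic_spec] (rendering and noise parameters).
#' @param orientation `"straight"` (axis along x) or `"arc"` (gently
#'   curved circular file axis).
#' @return List with `image` ([calibrated_image]), `true_wall_s_um`
#'   (arc-length wall positions from the polyline start, wall 0 first) and
#'   `polyline` ([polyline]).
#' @export
render_cell_file_image <- function(lengths_um, spec,
                                   orientation = c("straight", "arc")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  orientation <- match.arg(orientation)
  if (any(lengths_um <= 0)) stop("lengths must be positive")
  walls_um <- c(0, cumsum(lengths_um))
  walls_px <- walls_um / spec$pixel_size_um
  total_px <- walls_px[length(walls_px)]
  margin <- 12
  if (orientation == "straight") {
    w <- ceiling(total_px) + 2 * margin + 1
    h <- 41
    sx <- (0:(w - 1)) - margin           # arc position of each column
    ridge <- spec$wall_amp *
      exp(-nearest_wall_dist(sx, walls_px)^2 / (2 * spec$wall_sigma_px^2))
    pix <- matrix(ridge, nrow = h, ncol = w, byrow = TRUE)
    axis_y <- (h - 1) / 2
    anchors <- cbind(c(margin, margin + total_px), c(axis_y, axis_y))
  } else {
    R <- max(400, 2 * total_px)          # gentle curvature
    th_tot <- total_px / R
    th0 <- -th_tot / 2
    halfwidth <- 15
    # arc points: (cx + R sin th, cy - R cos th); bulges toward small y
    xs_ext <- R * sin(c(th0, -th0))
    cx <- margin + halfwidth - xs_ext[1]
    top_y <- margin + halfwidth          # y of arc apex (theta = 0)
    cy <- top_y + R
    w <- ceiling(cx + xs_ext[2] + halfwidth + margin) + 1
    h <- ceiling(top_y + R * (1 - cos(th0)) + halfwidth + margin) + 1
    X <- matrix(0:(w - 1), h, w, byrow = TRUE)
    Y <- matrix(0:(h - 1), h, w)
    r <- sqrt((X - cx)^2 + (Y - cy)^2)
    th <- atan2(X - cx, cy - Y)
    inband <- abs(r - R) <= halfwidth & th >= th0 & th <= th0 + th_tot
    pix <- matrix(0, h, w)
    s_arc <- R * (th[inband] - th0)
    pix[inband] <- spec$wall_amp *
      exp(-nearest_wall_dist(s_arc, walls_px)^2 /
            (2 * spec$wall_sigma_px^2))
    n_anch <- max(5, ceiling(total_px / 25) + 1)
    th_a <- th0 + seq(0, th_tot, length.out = n_anch)
    anchors <- cbind(cx + R * sin(th_a), cy - R * cos(th_a))
  }
  if (spec$bg_noise_sd > 0) {
    set.seed(spec$seed + 1L)
    pix <- pix + matrix(stats::rnorm(length(pix), 0, spec$bg_noise_sd),
                        nrow = nrow(pix))
  }
  pix <- round(pmin(pmax(pix, 0), 65535))
  list(image = calibrated_image(pix, spec$pixel_size_um, bit_depth = 16L,
                                source_path = "synthetic"),
       true_wall_s_um = walls_um,
       polyline = polyline(anchors))
}

#' Write a calibrated image as TIFF
#'
#' Uncompressed 8- or 16-bit grayscale TIFF; integer intensities
#' round-trip exactly through [read_image()]. Resolution tags are not
#' written, so carry the calibration alongside (the fixture manifests do).
#'
#' @param image A [calibrated_image].
#' @param path Output `.tif` path.
#' @export
write_image <- function(image, path) {
  tiff::writeTIFF(image$pixels / (2^image$bit_depth - 1), path,
                  bits.per.sample = image$bit_depth, compression = "none")
  invisible(path)
}

# One fixture case: generate series (with optional truncation), render,
# and write image + polyline + ground truth JSON.
write_fixture_case <- function(name, spec, orientation, out_dir,
                               drop_last = 0L, parent = NULL) {
  series <- generate_length_series(spec)
  lengths <- series$lengths_um
  if (drop_last > 0) lengths <- lengths[seq_len(length(lengths) - drop_last)]
  rendered <- render_cell_file_image(lengths, spec, orientation)
  img_path <- file.path(out_dir, paste0(name, ".tif"))
  poly_path <- file.path(out_dir, paste0(name, "_polyline.json"))
  truth_path <- file.path(out_dir, paste0(name, "_truth.json"))
  write_image(rendered$image, img_path)
  write_polyline(rendered$polyline, poly_path)
  jsonlite::write_json(
    list(name = name, lengths_um = lengths,
         wall_s_um = rendered$true_wall_s_um,
         true_tsz_index = series$true_tsz_index,
         pixel_size_um = spec$pixel_size_um,
         orientation = orientation, seed = spec$seed,
         parent = if (is.null(parent)) NA else parent,
         dropped_cells = drop_last),
    truth_path, auto_unbox = TRUE, digits = NA)
  list(name = name, image = basename(img_path),
       polyline = basename(poly_path), truth = basename(truth_path),
       pixel_size_um = spec$pixel_size_um, orientation = orientation,
       clean = spec$noise_cv == 0 && spec$bg_noise_sd == 0,
       parent = if (is.null(parent)) NA else parent)
}

#' Write the standard synthetic fixture suite
#'
#' Generates a fixed set of ground-truthed cases — clean and noisy,
#' straight and curved, a truncated-profile variant missing the final two
#' elongated cells of its parent, and a finer-calibration clean case —
#' each as a 16-bit TIFF with a polyline and ground-truth JSON, plus a
#' `manifest.json` indexing them. Deterministic for a fixed seed. The
#' fixture cases use a shorter meristem (12 cells) than the generator
#' default to keep images compact.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Base RNG seed; case seeds are derived from it.
#' @param base Optional named list of [synthetic_spec()] arguments
#'   overriding the fixture defaults (case-defining parameters such as
#'   noise levels and per-case seeds are kept).
#' @return The manifest, invisibly (a list with one entry per case).
#' @export
make_fixture_suite <- function(out_dir, seed = 1L, base = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  fx <- function(i, ...) {
    d <- list(n_meristem = 12L, ramp_cells = 5L, n_post = 3L)
    if (!is.null(base)) d <- utils::modifyList(d, as.list(base))
    d <- utils::modifyList(d, list(...))
    d$seed <- seed + i
    do.call(synthetic_spec, d)
  }
  cases <- list(
    write_fixture_case("clean_straight",
                       fx(1, noise_cv = 0, bg_noise_sd = 0),
                       "straight", out_dir),
    write_fixture_case("clean_arc",
                       fx(2, noise_cv = 0, bg_noise_sd = 0),
                       "arc", out_dir),
    write_fixture_case("noisy_straight", fx(3), "straight", out_dir),
    write_fixture_case("noisy_arc", fx(4), "arc", out_dir),
    write_fixture_case("truncated_straight",
                       fx(1, noise_cv = 0, bg_noise_sd = 0),
                       "straight", out_dir, drop_last = 2L,
                       parent = "clean_straight"),
    write_fixture_case("clean_straight_fine",
                       fx(6, noise_cv = 0, bg_noise_sd = 0,
                          pixel_size_um = 0.25),
                       "straight", out_dir))
  names(cases) <- vapply(cases, `[[`, "", "name")
  jsonlite::write_json(cases, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cases)
}
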