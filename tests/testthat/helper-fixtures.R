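# Shared synthetic fixture suite, generated once per test session.
fixture_suite <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "cellfile-fixtures")
      manifest <- make_fixture_suite(dir, seed = 42L)
      attr(manifest, "dir") <- dir
      cache <<- manifest
    }
    cache
  }
})

fixture_dir <- function() attr(fixture_suite(), "dir")

# Run the image pipeline on one fixture case and pair it with its truth.
measure_case <- function(case, params = detector_params(9, 1.5,
                                                        min_intensity = 400)) {
  dir <- fixture_dir()
  img <- read_image(file.path(dir, case$image),
                    pixel_size_um = case$pixel_size_um)
  poly <- read_polyline(file.path(dir, case$polyline))
  path <- fit_spline(poly, step_px = 1)
  prof <- sample_intensity(img, path)
  walls <- detect_walls(prof, params)
  truth <- jsonlite::fromJSON(file.path(dir, case$truth))
  list(img = img, path = path, prof = prof, walls = walls, truth = truth)
}

# Recall/precision of detected against true wall positions, matched within
# a tolerance in microns.
match_walls <- function(detected_s_um, true_s_um, tol_um) {
  hit_true <- vapply(true_s_um,
                     function(t) any(abs(detected_s_um - t) <= tol_um),
                     logical(1))
  hit_det <- vapply(detected_s_um,
                    function(d) any(abs(true_s_um - d) <= tol_um),
                    logical(1))
  list(recall = mean(hit_true), precision = mean(hit_det),
       errors_um = vapply(true_s_um,
                          function(t) min(abs(detected_s_um - t)),
                          numeric(1)))
}

# Wrap a bare intensity vector as an intensity_profile on a straight path.
profile_from <- function(intensity, pixel_size_um = 1, step_px = 1) {
  n <- length(intensity)
  structure(list(s_um = (seq_len(n) - 1) * step_px * pixel_size_um,
                 intensity = intensity, pixel_size_um = pixel_size_um,
                 step_px = step_px,
                 points = cbind(x = (seq_len(n) - 1) * step_px, y = 0)),
            class = "intensity_profile")
}

# Straight-line profile over a constant-width image built in memory.
flat_image <- function(value, w = 64, h = 16, pixel_size_um = 1) {
  calibrated_image(matrix(value, h, w), pixel_size_um, bit_depth = 16L)
}
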