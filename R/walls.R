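#' Wall detector parameters
#'
#' Parameters of the windowed peak rule that flags cell-wall locations on
#' an intensity profile. A sample is a raw candidate when its intensity is
#' at least the maximum of the surrounding window (excluding the sample
#' itself), at least `stringency` times the window minimum, and at least
#' the absolute floor `min_intensity`. The floor guards against false
#' positives in noisy regions of very low signal, where the in-window
#' minimum can be near zero and the stringency ratio becomes vacuous.
#'
#' @param window Window size in samples, odd and >= 3 (default 9; spans a
#'   typical wall-ridge width at ~0.5 um/px imagery).
#' @param stringency Unitless multiplier >= 1 applied to the in-window
#'   minimum.
#' @param min_intensity Absolute intensity floor, raw units.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(window = 9L, stringency = 1.5,
                            min_intensity = 0) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3")
  if (!is.numeric(stringency) || stringency < 1)
    stop("`stringency` must be >= 1")
  if (!is.numeric(min_intensity) || min_intensity < 0)
    stop("`min_intensity` must be >= 0")
  structure(list(window = window, stringency = stringency,
                 min_intensity = min_intensity),
            class = "detector_params")
}

#' Raw wall candidates (pre-merge)
#'
#' Applies the windowed peak rule sample-by-sample and returns the logical
#' candidate mask, before any run merging or separation filtering. The
#' window is truncated at the profile ends rather than padded, so
#' candidates in the first and last half-window are judged against the
#' samples actually present.
#'
#' @param intensity Numeric vector of profile intensities.
#' @param params A [detector_params].
#' @return Logical vector, `TRUE` where the sample is a raw candidate.
#' @export
wall_candidates <- function(intensity, params) {
  n <- length(intensity)
  if (n <= params$window)
    stop("profile must be longer than the detector window")
  half <- (params$window - 1L) %/% 2L
  shifted <- lapply(setdiff(-half:half, 0L), function(k) {
    if (k > 0) c(intensity[-seq_len(k)], rep(NA_real_, k))
    else c(rep(NA_real_, -k), intensity[seq_len(n + k)])
  })
  i_max <- do.call(pmax, c(shifted, list(na.rm = TRUE)))
  i_min <- do.call(pmin, c(shifted, list(na.rm = TRUE)))
  intensity >= i_max & intensity >= i_min * params$stringency &
    intensity >= params$min_intensity
}

# Merge maximal runs of consecutive candidates into one wall at the run's
# intensity-weighted centroid (fractional 1-based sample index); the run's
# peak intensity is kept for later tie-breaking.
merge_candidate_runs <- function(candidates, intensity) {
  r <- rle(candidates)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  idx <- vapply(keep, function(k) {
    i <- starts[k]:ends[k]
    sum(i * intensity[i]) / sum(intensity[i])
  }, numeric(1))
  peak <- vapply(keep, function(k) max(intensity[starts[k]:ends[k]]),
                 numeric(1))
  list(index = idx, peak = peak)
}

# Enforce a minimum wall separation (in samples): while any adjacent pair
# is closer than `minsep`, drop the lower-intensity wall of the closest
# pair (ties keep the earlier wall).
enforce_separation <- function(index, peak, minsep) {
  repeat {
    if (length(index) < 2) break
    gaps <- diff(index)
    if (all(gaps >= minsep)) break
    j <- which.min(gaps)
    drop <- if (peak[j + 1] > peak[j]) j else j + 1L
    index <- index[-drop]; peak <- peak[-drop]
  }
  list(index = index, peak = peak)
}

#' Detect cell walls on an intensity profile
#'
#' Runs the windowed peak rule (see [detector_params()]), merges maximal
#' runs of consecutive candidates into a single wall at the run's
#' intensity-weighted centroid (flat-topped ridges produce runs because
#' the peak rule uses >=), and merges walls closer than half a window
#' apart, keeping the higher-intensity one: two peaks within half a window
#' belong to the same wall ridge.
#'
#' @param profile An [intensity_profile].
#' @param params A [detector_params].
#' @return An object of class `wall_set` whose `walls` data frame has one
#'   row per wall: `sample_index` (fractional, 1-based), `s_um`, `x`, `y`,
#'   `intensity` and `source` (`"auto"` or `"manual"`).
#' @export
detect_walls <- function(profile, params = detector_params()) {
  stopifnot(inherits(profile, "intensity_profile"))
  cand <- wall_candidates(profile$intensity, params)
  runs <- merge_candidate_runs(cand, profile$intensity)
  minsep <- ceiling(params$window / 2)
  merged <- enforce_separation(runs$index, runs$peak, minsep)
  wall_set_at(merged$index, merged$peak, profile, source = "auto")
}

# Build a wall_set from fractional sample indices on a profile.
wall_set_at <- function(index, peak, profile, source) {
  n <- length(profile$s_um)
  if (length(index) > 0) {
    s_um <- stats::approx(seq_len(n), profile$s_um, xout = index)$y
    x <- stats::approx(seq_len(n), profile$points[, 1], xout = index)$y
    y <- stats::approx(seq_len(n), profile$points[, 2], xout = index)$y
  } else {
    s_um <- x <- y <- numeric(0)
  }
  walls <- data.frame(sample_index = index, s_um = s_um, x = x, y = y,
                      intensity = peak,
                      source = rep_len(source, length(index)))
  walls <- walls[order(walls$s_um), , drop = FALSE]
  rownames(walls) <- NULL
  structure(list(walls = walls,
                 step_um = profile$step_px * profile$pixel_size_um,
                 extent_um = profile$s_um[n]),
            class = "wall_set")
}

#' @export
print.wall_set <- function(x, ...) {
  cat(sprintf("<wall_set> %d walls over %.2f um (%d manual)\n",
              nrow(x$walls), x$extent_um, sum(x$walls$source == "manual")))
  invisible(x)
}

#' Insert manually placed walls
#'
#' Surrogate for interactive wall enhancement on low-contrast data: walls
#' are inserted at the given arc-length positions with
#' `source = "manual"`. Positions within one sample step of an existing
#' wall are rejected with a warning.
#'
#' @param wallset A [wall_set].
#' @param positions_um Arc-length positions (um from the profile start).
#' @param path The [sampled_path] the walls lie on.
#' @return The augmented, re-sorted [wall_set].
#' @export
add_manual_walls <- function(wallset, positions_um, path) {
  stopifnot(inherits(wallset, "wall_set"), inherits(path, "sampled_path"))
  step_um <- wallset$step_um
  px_size <- step_um / path$step_px
  for (pos in positions_um) {
    if (pos < 0 || pos > wallset$extent_um)
      stop(sprintf("manual wall at %.2f um lies outside [0, %.2f]",
                   pos, wallset$extent_um))
    if (any(abs(wallset$walls$s_um - pos) < step_um)) {
      warning(sprintf(
        "manual wall at %.2f um duplicates an existing wall; skipped", pos),
        call. = FALSE)
      next
    }
    s_px <- pos / px_size
    idx <- stats::approx(path$arc_length_px, seq_len(nrow(path$points)),
                         xout = s_px)$y
    x <- stats::approx(path$arc_length_px, path$points[, 1], xout = s_px)$y
    y <- stats::approx(path$arc_length_px, path$points[, 2], xout = s_px)$y
    wallset$walls <- rbind(wallset$walls,
                           data.frame(sample_index = idx, s_um = pos,
                                      x = x, y = y, intensity = NA_real_,
                                      source = "manual"))
  }
  ord <- order(wallset$walls$s_um)
  wallset$walls <- wallset$walls[ord, , drop = FALSE]
  rownames(wallset$walls) <- NULL
  wallset
}

#' Ordered cell lengths along a file
#'
#' @param lengths_um Per-cell lengths in microns, ordered from the profile
#'   start; all positive.
#' @param start_um Arc-length position of the first cell's proximal
#'   boundary (default 0).
#' @return An object of class `cell_file` with elements `lengths_um`,
#'   `starts_um` (cumulative proximal-boundary positions) and `n_cells`.
#' @export
cell_file <- function(lengths_um, start_um = 0) {
  lengths_um <- as.numeric(lengths_um)
  if (any(lengths_um <= 0)) stop("all cell lengths must be positive")
  starts <- start_um + c(0, cumsum(lengths_um))[seq_along(lengths_um)]
  structure(list(lengths_um = lengths_um, starts_um = starts,
                 n_cells = length(lengths_um)),
            class = "cell_file")
}

#' @export
print.cell_file <- function(x, ...) {
  cat(sprintf("<cell_file> %d cells, total %.2f um\n", x$n_cells,
              sum(x$lengths_um)))
  invisible(x)
}

#' Segment a wall set into cells
#'
#' Consecutive boundaries delimit cells; each cell's length is the
#' arc-length difference between its walls. By default the profile start
#' (conventionally placed by the user at the cortex/endodermis initial) is
#' boundary 0, so distances are reported from it; a wall detected within
#' half a sample step of the start is not duplicated.
#'
#' @param wallset A [wall_set].
#' @param include_start_as_wall Treat the profile start as boundary 0
#'   (default `TRUE`).
#' @return A [cell_file].
#' @export
segment_cells <- function(wallset, include_start_as_wall = TRUE) {
  stopifnot(inherits(wallset, "wall_set"))
  b <- wallset$walls$s_um
  if (include_start_as_wall && (length(b) == 0 || b[1] > wallset$step_um / 2))
    b <- c(0, b)
  if (length(b) < 2)
    stop("fewer than 2 boundaries: cannot segment cells")
  cell_file(diff(b), start_um = b[1])
}
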