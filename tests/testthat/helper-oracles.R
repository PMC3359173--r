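# Independent oracles, written as literal transcriptions of the rules the
# package implements, kept deliberately naive and loop-based.

# Sample-by-sample transcription of the windowed wall-candidate rule:
# for each sample p_t, examine the window centred on it (truncated at the
# profile ends), store the min and max intensity ignoring p_t, and mark
# p_t iff  i(p_t) >= i_max  and  i(p_t) >= i_min * stringency  and
# i(p_t) >= min_intensity.
oracle_candidates <- function(intensity, window, stringency,
                              min_intensity = 0) {
  n <- length(intensity)
  half <- (window - 1) %/% 2
  out <- logical(n)
  for (t in seq_len(n)) {
    w <- setdiff(max(1, t - half):min(n, t + half), t)
    i_min <- min(intensity[w])
    i_max <- max(intensity[w])
    out[t] <- intensity[t] >= i_max &&
      intensity[t] >= i_min * stringency &&
      intensity[t] >= min_intensity
  }
  out
}

# Exhaustive break-point search: perpendicular distance of every interior
# point to the first-to-last chord, via the triangle-area formula; strict
# improvement keeps the smallest index on ties.
oracle_break_point <- function(xs, ys) {
  n <- length(xs)
  ax <- xs[n] - xs[1]; ay <- ys[n] - ys[1]
  best <- -1; best_i <- NA_integer_
  for (i in 2:(n - 1)) {
    d <- abs(ax * (ys[i] - ys[1]) - ay * (xs[i] - xs[1])) / sqrt(ax^2 + ay^2)
    if (d > best + 1e-12) { best <- d; best_i <- i }
  }
  best_i
}

# Element-wise mean-absolute-difference disagreement, computed directly.
oracle_disagreement <- function(m) {
  k <- ncol(m)
  D <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    D[i, j] <- mean(abs(m[, i] - m[, j]))
  D
}

# Minimal ImageJ .roi polyline writer following the documented byte
# layout: "Iout", version short, type byte (5 = polyline), bounding-box
# shorts, n, zero padding to byte 64, then n shorts of x and n shorts of
# y relative to (left, top). Integer corner coordinates.
write_roi_polyline <- function(anchors, path) {
  anchors <- round(anchors)
  left <- min(anchors[, 1]); top <- min(anchors[, 2])
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, nchars = 4, eos = NULL)
  writeBin(227L, con, size = 2, endian = "big")        # version
  writeBin(as.raw(c(5, 0)), con)                       # type, unused
  writeBin(as.integer(c(top, left, max(anchors[, 2]), max(anchors[, 1]),
                        nrow(anchors))), con, size = 2, endian = "big")
  writeBin(raw(64 - 18), con)                          # pad to coords
  writeBin(as.integer(anchors[, 1] - left), con, size = 2, endian = "big")
  writeBin(as.integer(anchors[, 2] - top), con, size = 2, endian = "big")
  invisible(path)
}

# Seeded random profile for detector equivalence checks.
random_profile <- function(n, seed) {
  set.seed(seed)
  stats::runif(n)
}
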