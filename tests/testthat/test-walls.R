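test_that("a constant profile yields no walls under stringency > 1", {
  prof <- profile_from(rep(10, 50))
  w <- detect_walls(prof, detector_params(9, 1.1, 0))
  expect_equal(nrow(w$walls), 0L)
})

test_that("an isolated spike above the floor is a single wall", {
  x <- rep(0, 101); x[51] <- 100
  prof <- profile_from(x)
  w <- detect_walls(prof, detector_params(9, 2, min_intensity = 10))
  expect_equal(nrow(w$walls), 1L)
  expect_equal(w$walls$sample_index, 51)
  expect_equal(w$walls$s_um, 50)
  expect_equal(w$walls$source, "auto")
})

test_that("pre-merge candidates equal the sample-by-sample transcription", {
  for (k in 1:25) {
    stringency <- c(1.1, 1.5, 2.0)[(k %% 3) + 1]
    x <- random_profile(500, seed = 100 + k)
    got <- wall_candidates(x, detector_params(9, stringency,
                                              min_intensity = 0.2))
    want <- oracle_candidates(x, 9, stringency, 0.2)
    expect_identical(got, want)
  }
  # other window sizes too
  x <- random_profile(400, seed = 999)
  for (win in c(3, 5, 13)) {
    expect_identical(wall_candidates(x, detector_params(win, 1.3, 0.1)),
                     oracle_candidates(x, win, 1.3, 0.1))
  }
})

test_that("full detection matches transcription plus the stated merge rules", {
  naive_detect <- function(x, window, stringency, min_intensity) {
    cand <- oracle_candidates(x, window, stringency, min_intensity)
    idx <- numeric(0); peak <- numeric(0)
    i <- 1
    while (i <= length(x)) {          # runs -> intensity-weighted centroid
      if (cand[i]) {
        j <- i
        while (j < length(x) && cand[j + 1]) j <- j + 1
        idx <- c(idx, sum((i:j) * x[i:j]) / sum(x[i:j]))
        peak <- c(peak, max(x[i:j]))
        i <- j + 1
      } else i <- i + 1
    }
    minsep <- ceiling(window / 2)     # drop lower peak of closest pair
    repeat {
      if (length(idx) < 2 || all(diff(idx) >= minsep)) break
      g <- which.min(diff(idx))
      drop <- if (peak[g + 1] > peak[g]) g else g + 1
      idx <- idx[-drop]; peak <- peak[-drop]
    }
    idx
  }
  for (k in 1:10) {
    x <- random_profile(1000, seed = 500 + k)
    prof <- profile_from(x)
    got <- detect_walls(prof, detector_params(9, 1.5, 0.2))
    expect_equal(got$walls$sample_index, naive_detect(x, 9, 1.5, 0.2),
                 tolerance = 1e-12)
  }
})

test_that("plateau peaks merge at the intensity-weighted centroid", {
  x <- rep(0, 60); x[30:32] <- c(50, 50, 50)
  w <- detect_walls(profile_from(x), detector_params(9, 2, 5))
  expect_equal(nrow(w$walls), 1L)
  expect_equal(w$walls$sample_index, 31)
  # even-length plateau lands midway between the two samples
  x2 <- rep(0, 60); x2[30:31] <- c(50, 50)
  w2 <- detect_walls(profile_from(x2), detector_params(9, 2, 5))
  expect_equal(w2$walls$sample_index, 30.5)
})

test_that("detection is invariant to intensity scaling", {
  x <- random_profile(600, seed = 11)
  p1 <- detect_walls(profile_from(x), detector_params(9, 1.4, 0.3))
  for (c_scale in c(0.01, 7, 1000)) {
    p2 <- detect_walls(profile_from(c_scale * x),
                       detector_params(9, 1.4, 0.3 * c_scale))
    expect_equal(p2$walls$sample_index, p1$walls$sample_index,
                 tolerance = 1e-12)
  }
})

test_that("raising stringency never adds a wall", {
  for (k in 1:8) {
    x <- random_profile(500, seed = 40 + k)
    counts <- vapply(c(1, 1.2, 1.5, 2, 3), function(s)
      nrow(detect_walls(profile_from(x),
                        detector_params(9, s, 0.1))$walls), numeric(1))
    expect_true(all(diff(counts) <= 0))
    # candidate sets shrink monotonically too
    c1 <- wall_candidates(x, detector_params(9, 1.2, 0.1))
    c2 <- wall_candidates(x, detector_params(9, 1.8, 0.1))
    expect_true(all(c1 | !c2))
  }
})

test_that("manual walls insert sorted, reject duplicates and out-of-range", {
  case <- fixture_suite()$clean_straight
  m <- measure_case(case)
  w0 <- m$walls
  n0 <- nrow(w0$walls)
  pos <- mean(w0$walls$s_um[1:2])   # between the first two walls
  w1 <- add_manual_walls(w0, pos, m$path)
  expect_equal(nrow(w1$walls), n0 + 1L)
  expect_true(!is.unsorted(w1$walls$s_um))
  expect_equal(w1$walls$source[2], "manual")
  # duplicate within one sample step -> unchanged plus a warning
  expect_warning(w2 <- add_manual_walls(w1, w1$walls$s_um[3], m$path),
                 "duplicates")
  expect_equal(nrow(w2$walls), nrow(w1$walls))
  expect_error(add_manual_walls(w0, w0$extent_um + 5, m$path), "outside")
  # inserting before the first wall makes it wall 1
  far <- w0; far$walls <- far$walls[-1, ]
  w3 <- add_manual_walls(far, 0, m$path)
  expect_equal(w3$walls$source[1], "manual")
  expect_equal(w3$walls$s_um[1], 0)
})

test_that("segmentation turns boundaries into positive cell lengths", {
  ws <- structure(list(walls = data.frame(sample_index = c(1, 11, 26),
                                          s_um = c(0, 10, 25),
                                          x = c(0, 10, 25), y = 0,
                                          intensity = 1, source = "auto"),
                       step_um = 1, extent_um = 30),
                  class = "wall_set")
  cf <- segment_cells(ws)
  expect_equal(cf$lengths_um, c(10, 15))
  expect_equal(cf$starts_um, c(0, 10))
  expect_equal(cf$n_cells, 2L)
  # a single interior wall plus the conventional start boundary
  ws1 <- ws; ws1$walls <- ws$walls[2, ]
  cf1 <- segment_cells(ws1)
  expect_equal(cf1$lengths_um, 10)
  expect_error(segment_cells(ws1, include_start_as_wall = FALSE),
               "fewer than 2 boundaries")
  # conservation: lengths sum to the first-to-last boundary distance
  expect_equal(sum(cf$lengths_um),
               max(ws$walls$s_um) - min(c(0, ws$walls$s_um)))
})

test_that("walls on synthetic images sit within one sampling step of truth", {
  suite <- fixture_suite()
  for (name in c("clean_straight", "clean_arc", "clean_straight_fine")) {
    m <- measure_case(suite[[name]])
    step_um <- m$prof$step_px * m$prof$pixel_size_um
    res <- match_walls(m$walls$walls$s_um, m$truth$wall_s_um, step_um)
    expect_equal(res$recall, 1.0)
    expect_equal(res$precision, 1.0)
    cf <- segment_cells(m$walls)
    expect_equal(cf$n_cells, length(m$truth$lengths_um))
    expect_lt(max(abs(cf$lengths_um - m$truth$lengths_um)), 2 * step_um)
  }
})
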