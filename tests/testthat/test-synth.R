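test_that("noise-free series follow the declared construction", {
  spec <- synthetic_spec(n_meristem = 5L, L_m = 8, elongation_factor = 15,
                         ramp_cells = 4L, n_post = 2L, noise_cv = 0)
  s <- generate_length_series(spec)
  expect_equal(s$lengths_um[1:5], rep(8, 5))
  expect_equal(s$lengths_um[9], 120)           # last ramp cell: L_m * factor
  expect_equal(s$lengths_um[10:11], c(120, 120))
  expect_equal(s$true_tsz_index, 5L)
  # geometric ramp: constant ratio between consecutive ramp cells
  ratios <- s$lengths_um[6:9] / s$lengths_um[5:8]
  expect_equal(ratios, rep(15^(1 / 4), 4))
  # ground-truth conservation: lengths sum to the last wall position
  r <- render_cell_file_image(s$lengths_um, spec)
  expect_equal(sum(s$lengths_um), max(r$true_wall_s_um))
  expect_equal(length(r$true_wall_s_um), length(s$lengths_um) + 1L)
})

test_that("series are deterministic for a fixed seed", {
  a <- generate_length_series(synthetic_spec(seed = 99))
  b <- generate_length_series(synthetic_spec(seed = 99))
  expect_identical(a, b)
  c <- generate_length_series(synthetic_spec(seed = 100))
  expect_false(identical(a$lengths_um, c$lengths_um))
})

test_that("multiplicative length noise has the requested CV", {
  cvs <- vapply(1:1000, function(i) {
    s <- generate_length_series(synthetic_spec(noise_cv = 0.1,
                                               seed = 5000 + i))
    mer <- s$lengths_um[1:30]
    sd(mer) / mean(mer)
  }, numeric(1))
  expect_gt(mean(cvs), 0.08)
  expect_lt(mean(cvs), 0.12)
  # unit mean: meristem lengths average to L_m
  expect_equal(mean(vapply(1:1000, function(i)
    mean(generate_length_series(
      synthetic_spec(seed = 5000 + i))$lengths_um[1:30]),
    numeric(1))), 8, tolerance = 0.01)
})

test_that("rendered ridges peak at the true wall positions", {
  spec <- synthetic_spec(n_meristem = 3L, L_m = 10, ramp_cells = 1L,
                         n_post = 0L, noise_cv = 0, bg_noise_sd = 0,
                         pixel_size_um = 1)
  # 3 cells of 10 um (ramp_cells=1, n_post=0 gives 4 cells; take first 3)
  r <- render_cell_file_image(c(10, 10, 10), spec)
  expect_equal(r$true_wall_s_um, c(0, 10, 20, 30))
  path <- fit_spline(r$polyline, step_px = 1)
  prof <- sample_intensity(r$image, path)
  peaks <- which(diff(sign(diff(prof$intensity))) == -2) + 1
  expect_equal(prof$s_um[peaks], c(10, 20))   # interior maxima
  expect_equal(prof$intensity[c(1, length(prof$intensity))],
               rep(spec$wall_amp, 2), tolerance = 1e-6)  # end walls
  # off-ridge samples beyond 4 sigma decay below 1% of the amplitude
  d <- vapply(prof$s_um, function(s) min(abs(s - r$true_wall_s_um)),
              numeric(1))
  far <- d > 4 * spec$wall_sigma_px * spec$pixel_size_um
  expect_true(all(prof$intensity[far] < 0.01 * spec$wall_amp))
})

test_that("the noise-free pipeline recovers every true wall", {
  spec <- synthetic_spec(n_meristem = 8L, ramp_cells = 4L, n_post = 2L,
                         noise_cv = 0, bg_noise_sd = 0, seed = 21)
  s <- generate_length_series(spec)
  for (orient in c("straight", "arc")) {
    r <- render_cell_file_image(s$lengths_um, spec, orient)
    prof <- sample_intensity(r$image, fit_spline(r$polyline))
    w <- detect_walls(prof, detector_params(9, 1.5, min_intensity = 400))
    res <- match_walls(w$walls$s_um, r$true_wall_s_um,
                       prof$step_px * prof$pixel_size_um)
    expect_equal(res$recall, 1.0)
    expect_equal(res$precision, 1.0)
  }
})

test_that("the fixture suite is complete, grounded and reproducible", {
  dir1 <- file.path(tempdir(), "suiteA")
  dir2 <- file.path(tempdir(), "suiteB")
  m1 <- make_fixture_suite(dir1, seed = 7)
  m2 <- make_fixture_suite(dir2, seed = 7)
  expect_gte(length(m1), 6L)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  for (case in m1) {
    expect_true(file.exists(file.path(dir1, case$image)))
    expect_true(file.exists(file.path(dir1, case$polyline)))
    # identical seeds give byte-identical ground truth
    t1 <- readBin(file.path(dir1, case$truth), "raw",
                  file.size(file.path(dir1, case$truth)))
    t2 <- readBin(file.path(dir2, case$truth), "raw",
                  file.size(file.path(dir2, case$truth)))
    expect_identical(t1, t2)
  }
  # the truncated variant omits the final two cells of its parent
  parent <- jsonlite::fromJSON(file.path(dir1, m1$clean_straight$truth))
  trunc <- jsonlite::fromJSON(file.path(dir1, m1$truncated_straight$truth))
  expect_equal(trunc$parent, "clean_straight")
  expect_equal(trunc$lengths_um,
               parent$lengths_um[seq_len(length(parent$lengths_um) - 2)])
})
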