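test_that("all motion directions in a display stay 20 deg apart", {
  set.seed(201)
  spec <- stimulus_spec(n_disks = 3)
  d <- sample_direction_set(spec, n_sets = 300)
  min_sep <- vapply(split(d, d$set), function(s) {
    dirs <- c(s$pre_direction_deg, s$post_direction_deg)
    pairs <- utils::combn(dirs, 2)
    min(circular_separation(pairs[1, ], pairs[2, ]))
  }, numeric(1))
  expect_true(all(min_sep >= 20))
})

test_that("post direction follows the active deviation convention", {
  set.seed(202)
  dc <- sample_direction_set(stimulus_spec(n_disks = 2), n_sets = 50)
  expect_equal(wrap_angle(dc$post_direction_deg - dc$pre_direction_deg),
               wrap_angle(dc$deviation_deg))
  ia <- sample_direction_set(
    stimulus_spec(n_disks = 2, deviation_convention = "interior_angle"),
    n_sets = 50)
  expect_equal(
    wrap_angle(ia$post_direction_deg - ia$pre_direction_deg),
    wrap_angle(sign(ia$deviation_deg) * (180 - abs(ia$deviation_deg))))
})

test_that("deviation magnitudes stay uniform on 30-180 with mean near 105", {
  set.seed(203)
  d <- sample_direction_set(stimulus_spec(n_disks = 3), n_sets = 2000)
  m <- abs(d$deviation_deg)
  expect_equal(mean(m), 105, tolerance = 2 / 105)
  expect_true(all(m >= 30 & m <= 180))
})

test_that("identical seeds reproduce identical stimulus sets", {
  spec <- stimulus_spec(n_disks = 3)
  set.seed(204)
  a <- sample_stimulus_set(spec, n_sets = 5)
  set.seed(204)
  b <- sample_stimulus_set(spec, n_sets = 5)
  expect_equal(a, b)
})

test_that("trajectory geometry: equal half-segments joined at the vertex", {
  set.seed(205)
  stim <- sample_stimulus_set(stimulus_spec(n_disks = 3, speed_deg_per_s = 5,
                                            duration_ms = 800), n_sets = 20)
  half <- sqrt((stim$vertex_x_deg - stim$start_x_deg)^2 +
                 (stim$vertex_y_deg - stim$start_y_deg)^2)
  expect_equal(half, rep(2, nrow(stim)), tolerance = 1e-9)
  half2 <- sqrt((stim$end_x_deg - stim$vertex_x_deg)^2 +
                  (stim$end_y_deg - stim$vertex_y_deg)^2)
  expect_equal(half2, rep(2, nrow(stim)), tolerance = 1e-9)
})

test_that("no frame of any disk leaves the display minus the disk radius", {
  set.seed(206)
  disp <- display_spec()
  for (spec in list(stimulus_spec(n_disks = 4, speed_deg_per_s = 5,
                                  duration_ms = 800),
                    stimulus_spec(n_disks = 3, speed_deg_per_s = 5,
                                  duration_ms = 1200))) {
    stim <- sample_stimulus_set(spec, disp, n_sets = 100)
    fr <- trajectory_frames(stim, frame_rate_hz = disp$frame_rate_hz)
    r <- spec$disk_diameter_deg / 2
    expect_true(all(fr$x_deg >= r - 1e-9 & fr$x_deg <= disp$width_deg - r + 1e-9))
    expect_true(all(fr$y_deg >= r - 1e-9 & fr$y_deg <= disp$height_deg - r + 1e-9))
  }
})

test_that("start points never overlap", {
  set.seed(207)
  stim <- sample_stimulus_set(stimulus_spec(n_disks = 4), n_sets = 100)
  mind <- vapply(split(stim, stim$set), function(s) {
    min(dist(cbind(s$start_x_deg, s$start_y_deg)))
  }, numeric(1))
  expect_true(all(mind > 1))
})

test_that("geometrically impossible displays raise explicit errors", {
  tiny <- display_spec(width_deg = 3, height_deg = 3)
  expect_error(
    sample_stimulus_set(stimulus_spec(speed_deg_per_s = 5,
                                      duration_ms = 800), tiny),
    "infeasible|diagonal")
})

test_that("positions interpolate piecewise-linearly between start, vertex, end", {
  traj <- tibble::tibble(
    start_x_deg = 0, start_y_deg = 0, vertex_x_deg = 2, vertex_y_deg = 0,
    pre_direction_deg = 0, post_direction_deg = 90,
    speed_deg_per_s = 5, duration_ms = 800)
  expect_equal(position_at(traj, 0), tibble::tibble(x_deg = 0, y_deg = 0))
  expect_equal(position_at(traj, 400), tibble::tibble(x_deg = 2, y_deg = 0))
  expect_equal(position_at(traj, 800), tibble::tibble(x_deg = 2, y_deg = 2))
  expect_equal(position_at(traj, 600), tibble::tibble(x_deg = 2, y_deg = 1))
  expect_error(position_at(traj, 900), "duration")
  expect_error(position_at(traj, -1), "duration")
})

test_that("pixel subtense matches the small-angle oracle and the 1.694 mean", {
  ps <- pixel_subtense(display_spec())
  # small-angle approximation as an independent check (sizes ~0.05 cm at 1 m)
  sa_h <- (39.5 / 800) / 100 * 180 / pi * 60
  sa_v <- (29.5 / 600) / 100 * 180 / pi * 60
  expect_equal(ps$horizontal_arcmin, sa_h, tolerance = 1e-6)
  expect_equal(ps$vertical_arcmin, sa_v, tolerance = 1e-6)
  expect_equal(round(ps$horizontal_arcmin, 3), 1.697)
  expect_equal(round(ps$vertical_arcmin, 3), 1.690)
  expect_equal(round(ps$mean_arcmin, 3), 1.694)
  expect_error(pixel_subtense(display_spec(viewing_distance_cm = 0)),
               "positive")
})
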