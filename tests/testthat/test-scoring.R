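test_that("condition means average TP arithmetically", {
  log <- log_with_errors(c(0, -90))
  s <- summarize_conditions(log)
  pooled <- s[is.na(s$report_order), ]
  expect_equal(pooled$mean_tp, 0.75)
  expect_equal(pooled$n_reports, 2L)
})

test_that("pooled full-report mean equals the mean over report orders", {
  set.seed(501)
  tr <- build_experiment(tiny_config("exp1a", blocks = 2, tpb = 5))
  log <- simulate_responses(tr, observer_params("shared"))
  s <- summarize_conditions(log)
  fr <- s[s$scope == "FR", ]
  pooled <- fr[is.na(fr$report_order), ]
  orders <- fr[!is.na(fr$report_order), ]
  per_cell <- tapply(orders$mean_tp,
                     paste(orders$stimulus_condition, orders$segment), mean)
  pooled_cell <- setNames(pooled$mean_tp,
                          paste(pooled$stimulus_condition, pooled$segment))
  expect_equal(unname(pooled_cell[names(per_cell)]), as.numeric(per_cell),
               tolerance = 1e-9)
})

test_that("aggregation is invariant to record order", {
  set.seed(502)
  tr <- build_experiment(tiny_config("exp3", blocks = 1, tpb = 3))
  log <- simulate_responses(tr, observer_params("exclusive"))
  shuffled <- log[sample.int(nrow(log)), ]
  expect_equal(summarize_conditions(log), summarize_conditions(shuffled))
})

test_that("cells in the design crossing with no reports are flagged, not zeroed", {
  log <- dplyr::bind_rows(
    log_with_errors(c(0, 10), segment = "pre", scope = "SR"),
    log_with_errors(c(0, 10), segment = "post", scope = "FR"))
  expect_warning(s <- summarize_conditions(log), "no reports")
  missing_cell <- s[s$segment == "pre" & s$scope == "FR" &
                      is.na(s$report_order), ]
  expect_true(is.na(missing_cell$mean_tp))
  expect_identical(missing_cell$n_reports, 0L)
})

test_that("balanced designs yield equal per-cell report counts", {
  set.seed(503)
  tr <- build_experiment(tiny_config("exp1a", blocks = 2, tpb = 5))
  log <- simulate_responses(tr, observer_params("exclusive"))
  s <- summarize_conditions(log)
  sr <- s[s$scope == "SR", ]
  # blocks x trials-per-condition single reports per duration and segment
  expect_true(all(sr$n_reports == 10))
})

test_that("mean TP of mildly noisy reports follows the half-normal limit", {
  # E[TP] = 1 - sigma * sqrt(2/pi) / 180 for wrapped-Gaussian errors with
  # sigma well below the wrap point
  set.seed(504)
  for (sigma in c(5, 12, 20)) {
    log <- log_with_errors(circular_error(rnorm(5000, 0, sigma) %% 360, 0))
    expect_equal(mean(log$tp), 1 - sigma * sqrt(2 / pi) / 180,
                 tolerance = 0.002 / 0.9)
  }
})

test_that("mean TP is almost perfectly linear in nominal RMS error", {
  set.seed(505)
  r <- rms_tp_equivalence()
  expect_lte(r$pearson_r, -0.999)
  expect_equal(nrow(r$levels), 21L)
  expect_equal(r$levels$mean_tp[1], 0.995, tolerance = 0.002 / 0.995)
  # sigma -> 0: no error, perfect TP
  r0 <- rms_tp_equivalence(rms_levels_deg = c(0.001, 1), n_trials = 500)
  expect_equal(r0$levels$mean_tp[1], 1, tolerance = 1e-4)
  expect_error(rms_tp_equivalence(rms_levels_deg = c(-1, 10)), "0, 180")
  expect_error(rms_tp_equivalence(n_trials = 1), ">= 2")
})

test_that("tidy and glance expose the equivalence table and correlation", {
  set.seed(506)
  r <- rms_tp_equivalence(n_trials = 100)
  expect_named(tidy(r), c("rms_deg", "mean_tp"))
  g <- glance(r)
  expect_equal(g$pearson_r, r$pearson_r)
  expect_equal(g$n_levels, 21L)
})
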