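test_that("an exclusive cohort shows sensory-memory signatures post-deviation only", {
  set.seed(701)
  trials <- build_experiment(tiny_config("exp1b", blocks = 5, tpb = 5))
  log <- simulate_cohort(trials, make_cohort(4, observer_params("exclusive")))
  sig <- signature_battery(log)
  post <- sig[sig$segment == "post", ]
  pre <- sig[sig$segment == "pre", ]
  expect_true(post$decay && post$sr_gt_fr)
  expect_false(pre$decay)
  # pre-deviation retrieval is STM-limited: SR is reliably worse than the
  # first (STM-held) full report, so the comparability signature fails
  expect_false(pre$sr_eq_fr1)
  expect_lt(pre$sr_fr1_diff, 0)
  v <- classify_model(sig)
  expect_identical(v$verdict, "exclusive")
  expect_identical(sig$decay_variable, c("cue_delay_ms", "report_order"))
})

test_that("a shared cohort shows the signatures in both segments", {
  set.seed(702)
  trials <- build_experiment(tiny_config("exp1b", blocks = 5, tpb = 5))
  log <- simulate_cohort(trials, make_cohort(4, observer_params("shared")))
  sig <- signature_battery(log)
  expect_true(all(sig$decay))
  expect_true(all(sig$sr_gt_fr))
  expect_identical(classify_model(sig)$verdict, "shared")
})

test_that("a guessing cohort yields chance TP and no model evidence", {
  set.seed(703)
  trials <- build_experiment(tiny_config("exp1b", blocks = 5, tpb = 5))
  log <- simulate_cohort(trials, make_cohort(4, observer_params("guessing")))
  expect_equal(mean(log$tp), 0.5, tolerance = 0.02 / 0.5)
  sig <- signature_battery(log)
  expect_false(any(sig$decay & sig$sr_gt_fr))
  expect_identical(classify_model(sig)$verdict, "indeterminate")
})

test_that("cue delay drives decay in the delay experiment, both segments resolvable", {
  set.seed(704)
  trials <- build_experiment(tiny_config("exp2", blocks = 5, tpb = 5))
  log <- simulate_cohort(trials, make_cohort(4, observer_params("exclusive")))
  sig <- signature_battery(log)
  post <- sig[sig$segment == "post", ]
  expect_identical(post$decay_variable, "cue_delay_ms")
  expect_true(post$decay)
  expect_lt(post$decay_slope, 0)
})

test_that("the verdict rule maps signature matrices to architectures", {
  fake <- function(pre, post) {
    s <- tibble::tibble(
      segment = c("pre", "post"),
      decay = c(pre[1], post[1]),
      sr_gt_fr = c(pre[2], post[2]),
      sr_eq_fr1 = c(pre[3], post[3]),
      decay_p = 0.5, decay_slope = 0, decay_variable = "cue_delay_ms",
      sr_fr_p = 0.5, sr_fr_diff = 0, sr_fr1_p = 0.5, sr_fr1_diff = 0)
    class(s) <- c("segmot_signatures", class(s))
    attr(s, "alpha") <- 0.05
    s
  }
  expect_identical(
    classify_model(fake(c(FALSE, FALSE, FALSE), c(TRUE, TRUE, TRUE)))$verdict,
    "exclusive")
  expect_identical(
    classify_model(fake(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, TRUE)))$verdict,
    "shared")
  expect_identical(
    classify_model(fake(c(FALSE, FALSE, FALSE), c(FALSE, FALSE, FALSE)))$verdict,
    "indeterminate")
  v <- classify_model(fake(c(FALSE, FALSE, FALSE), c(TRUE, TRUE, TRUE)))
  expect_true(all(v$agreement$agrees_exclusive))
  expect_false(all(v$agreement$agrees_shared))
})

test_that("the battery refuses logs with missing reporting cells", {
  set.seed(705)
  trials <- build_experiment(tiny_config("exp1b", blocks = 1, tpb = 2))
  log <- simulate_responses(trials, observer_params("exclusive"))
  expect_error(signature_battery(log[log$segment == "post", ]),
               "missing segment/scope")
  expect_error(signature_battery(log[!(log$segment == "pre" &
                                         log$scope == "FR"), ]),
               "pre FR")
})
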