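test_that("a guessing observer performs at chance TP 0.5", {
  set.seed(401)
  tr <- build_experiment(tiny_config("exp1a", blocks = 8, tpb = 10))
  log <- simulate_responses(tr, observer_params("guessing"))
  expect_gt(nrow(log), 2000)
  expect_equal(mean(log$tp), 0.5, tolerance = 0.015 / 0.5)
})

test_that("a noiseless high-capacity observer is perfect everywhere", {
  set.seed(402)
  tr <- build_experiment(tiny_config("exp3", blocks = 1, tpb = 3))
  p <- observer_params("exclusive", sm_sigma_deg = 0, stm_sigma_deg = 0,
                       stm_capacity = 4, lapse_rate = 0, sm_tau_ms = Inf)
  log <- simulate_responses(tr, p)
  expect_true(all(log$tp == 1))
  expect_true(all(log$report_order[log$scope == "SR"] == 1))
  expect_true(all(abs(log$error_deg) <= 180))
})

test_that("a noiseless overwriting observer is capped near TP 0.583", {
  # unconstrained deviations, interior-angle convention: the reported
  # post-deviation direction differs from the queried pre-deviation one by
  # 180 - |deviation|, mean 75 deg, so mean TP ~ 1 - 75/180
  set.seed(403)
  cfg <- tiny_config("exp1a", blocks = 10, tpb = 10,
                     min_direction_sep_deg = 0,
                     deviation_convention = "interior_angle")
  # a single 400-report schedule carries ~0.012 SD of Monte-Carlo noise;
  # average a few independent schedules to test the expectation
  means <- replicate(5, {
    tr <- build_experiment(cfg)
    log <- simulate_responses(
      tr, observer_params("overwriting", sm_sigma_deg = 0, lapse_rate = 0))
    pre_sr <- log[log$segment == "pre" & log$scope == "SR", ]
    expect_gt(nrow(pre_sr), 350)
    mean(pre_sr$tp)
  })
  expect_equal(mean(means), 0.583, tolerance = 0.02 / 0.583)
})

test_that("uniform report-order policy gives exchangeable full-report orders", {
  set.seed(404)
  tr <- build_experiment(tiny_config("exp1a", blocks = 5, tpb = 10))
  log <- simulate_responses(
    tr, observer_params("exclusive", report_order_policy = "uniform"))
  fr1 <- log[log$scope == "FR" & log$report_order == 1, ]
  expect_gt(nrow(fr1), 350)
  expect_gt(stats::chisq.test(table(fr1$disk_id))$p.value, 0.001)
})

test_that("strength ordering reports STM-held items first when SM is absent", {
  set.seed(405)
  tr <- build_experiment(tiny_config("exp1a", blocks = 5, tpb = 10))
  log <- simulate_responses(tr, observer_params("exclusive"))
  pre_fr <- log[log$scope == "FR" & log$segment == "pre", ]
  stm_rate <- tapply(pre_fr$source == "stm", pre_fr$report_order, mean)
  # K = 2 of 3 disks stored: first two reports retrieved from STM (minus
  # lapses), the last report is the unstored item
  expect_gt(stm_rate[["1"]], 0.9)
  expect_gt(stm_rate[["2"]], 0.9)
  expect_lt(stm_rate[["3"]], 0.05)
  # post-deviation, everything is in SM at zero delay: order uninformative
  post_fr1 <- log[log$scope == "FR" & log$segment == "post" &
                    log$report_order == 1, ]
  expect_gt(stats::chisq.test(table(post_fr1$disk_id))$p.value, 0.001)
})

test_that("cohort jitter individuates observers; zero jitter clones them", {
  set.seed(406)
  same <- make_cohort(4, observer_params("shared"), jitter = 0)
  expect_length(same, 4)
  expect_equal(same[[1]]$sm_sigma_deg, same[[4]]$sm_sigma_deg)
  expect_setequal(vapply(same, `[[`, character(1), "observer"),
                  paste0("obs", 1:4))
  jit <- make_cohort(4, observer_params("shared"), jitter = 0.1)
  expect_gt(length(unique(vapply(jit, `[[`, numeric(1), "sm_sigma_deg"))), 1)
})

test_that("simulation is deterministic given the seed", {
  cfg <- tiny_config("exp1b", blocks = 1, tpb = 2)
  run <- function() {
    set.seed(407)
    simulate_cohort(build_experiment(cfg),
                    make_cohort(3, observer_params("exclusive")))
  }
  expect_equal(run(), run())
})

test_that("observer parameter validation rejects impossible values", {
  expect_error(observer_params(sm_sigma_deg = -1), ">= 0")
  expect_error(observer_params(sm_tau_ms = 0), "positive")
  expect_error(observer_params(lapse_rate = 1.5), "0, 1")
  expect_error(observer_params(stm_capacity = 1.5), "whole")
  expect_error(make_cohort(1), ">= 2")
})
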