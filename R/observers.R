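#' Observer model parameters
#'
#' A generative observer retrieves a queried motion direction from one of
#' three sources and reports it with source-specific wrapped-Gaussian noise:
#'
#' 1. **Sensory memory (SM)** — high capacity, rapidly decaying. An item is
#'    available with probability `exp(-t_eff / sm_tau_ms)` where
#'    `t_eff = cue_delay + (report_order - 1) * inter_report_latency_ms`.
#'    Which segments SM may serve depends on the architecture: under
#'    `"exclusive"` only the current (post-deviation) segment; under
#'    `"shared"` both segments.
#' 2. **Short-term memory (STM)** — durable but limited to `stm_capacity`
#'    items, sampled without replacement per trial; no within-trial decay.
#' 3. **Guessing** — uniform on the circle, also reached with probability
#'    `lapse_rate` regardless of memory state.
#'
#' Two degenerate controls are included: `"overwriting"` always reports the
#' post-deviation direction (plus SM noise), even when queried about the
#' pre-deviation segment; `"guessing"` always reports uniformly.
#'
#' `report_order_policy` controls the order in which full-report items are
#' given: `"strength"` (default) reports stronger memories first — when the
#' queried segment is not held in SM, STM-stored items come before unknown
#' ones (ties broken at random); `"uniform"` is a uniform random permutation.
#'
#' @param architecture `"exclusive"`, `"shared"`, `"overwriting"` or
#'   `"guessing"`.
#' @param sm_sigma_deg Report noise SD (degrees) for SM retrievals.
#' @param sm_tau_ms Exponential decay constant of SM availability, ms.
#' @param stm_capacity Number of items STM can hold (K).
#' @param stm_sigma_deg Report noise SD (degrees) for STM retrievals.
#' @param inter_report_latency_ms Extra delay accrued by each successive
#'   full-report response, ms.
#' @param lapse_rate Probability of a uniform guess irrespective of memory.
#' @param report_order_policy `"strength"` or `"uniform"`.
#' @param observer Observer label carried into response records.
#' @return An object of class `segmot_observer`.
#' @examples
#' observer_params("exclusive")
#' @export
observer_params <- function(architecture = c("exclusive", "shared",
                                             "overwriting", "guessing"),
                            sm_sigma_deg = 15, sm_tau_ms = 700,
                            stm_capacity = 2, stm_sigma_deg = 35,
                            inter_report_latency_ms = 1500,
                            lapse_rate = 0.02,
                            report_order_policy = c("strength", "uniform"),
                            observer = "obs1") {
  architecture <- match.arg(architecture)
  report_order_policy <- match.arg(report_order_policy)
  if (sm_sigma_deg < 0 || stm_sigma_deg < 0) abort("noise SDs must be >= 0.")
  if (!(sm_tau_ms > 0)) abort("`sm_tau_ms` must be positive.")
  if (stm_capacity < 0 || stm_capacity != round(stm_capacity)) {
    abort("`stm_capacity` must be a non-negative whole number.")
  }
  if (lapse_rate < 0 || lapse_rate > 1) abort("`lapse_rate` must be in [0, 1].")
  if (inter_report_latency_ms < 0) abort("`inter_report_latency_ms` must be >= 0.")
  structure(
    list(architecture = architecture, sm_sigma_deg = sm_sigma_deg,
         sm_tau_ms = sm_tau_ms, stm_capacity = as.integer(stm_capacity),
         stm_sigma_deg = stm_sigma_deg,
         inter_report_latency_ms = inter_report_latency_ms,
         lapse_rate = lapse_rate, report_order_policy = report_order_policy,
         observer = observer),
    class = "segmot_observer"
  )
}

#' @export
print.segmot_observer <- function(x, ...) {
  cat(sprintf("<segmot observer> %s (%s): sm sigma %g deg, tau %g ms, K = %d, stm sigma %g deg, latency %g ms, lapse %g (%s order)\n",
              x$observer, x$architecture, x$sm_sigma_deg, x$sm_tau_ms,
              x$stm_capacity, x$stm_sigma_deg, x$inter_report_latency_ms,
              x$lapse_rate, x$report_order_policy))
  invisible(x)
}

#' Build a cohort of synthetic observers
#'
#' Replicates a parameter template with multiplicative log-normal jitter on
#' the noise SDs and the SM decay constant, inducing between-subject
#' variance for repeated-measures analyses.
#'
#' @param n_observers Number of observers (>= 2 for RM-ANOVA downstream).
#' @param params Template [observer_params()].
#' @param jitter SD of the log-normal multiplicative jitter (0.1 = ~10%).
#' @return A list of `segmot_observer` objects, class `segmot_cohort`.
#' @examples
#' set.seed(1)
#' cohort <- make_cohort(4, observer_params("exclusive"))
#' @export
make_cohort <- function(n_observers = 4, params = observer_params(),
                        jitter = 0.1) {
  stopifnot(inherits(params, "segmot_observer"))
  if (n_observers < 2) abort("`n_observers` must be >= 2.")
  if (jitter < 0) abort("`jitter` must be >= 0.")
  out <- lapply(seq_len(n_observers), function(i) {
    p <- params
    p$observer <- sprintf("obs%d", i)
    if (jitter > 0) {
      p$sm_sigma_deg <- p$sm_sigma_deg * exp(rnorm(1, 0, jitter))
      p$stm_sigma_deg <- p$stm_sigma_deg * exp(rnorm(1, 0, jitter))
      if (is.finite(p$sm_tau_ms)) {
        p$sm_tau_ms <- p$sm_tau_ms * exp(rnorm(1, 0, jitter))
      }
    }
    p
  })
  structure(out, class = "segmot_cohort")
}

#' Simulate direction reports for a trial schedule
#'
#' Runs one synthetic observer through every queried report of a trial
#' schedule. For each report the retrieval source (SM, STM, guess) is drawn
#' as described in [observer_params()], a report-order permutation is chosen
#' for full-report trials, and the reported direction is the true direction
#' of the queried segment plus wrapped-Gaussian noise (or a uniform guess).
#'
#' @param trials A `segmot_trials` tibble from [build_experiment()].
#' @param params An [observer_params()] object.
#' @return A tibble of response records, one row per report: `observer`,
#'   schedule columns, `disk_id`, `report_order`, `true_dir_deg`,
#'   `reported_dir_deg`, `error_deg` (signed, in `(-180, 180]`), `tp`,
#'   `direction_change_deg` (signed inter-segment direction change of the
#'   queried trajectory) and the diagnostic `source`.
#' @examples
#' set.seed(1)
#' trials <- build_experiment(
#'   experiment_config("exp1b", blocks_per_condition = 1,
#'                     trials_per_condition_per_block = 2))
#' log <- simulate_responses(trials, observer_params("exclusive"))
#' @export
simulate_responses <- function(trials, params) {
  if (!inherits(params, "segmot_observer")) {
    abort("`params` must come from `observer_params()`.")
  }
  need <- c("experiment", "stimulus_condition", "set_size", "duration_ms",
            "cue_delay_ms", "block", "trial", "segment", "scope", "disk",
            "pre_direction_deg", "post_direction_deg", "queried")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    abort(paste0("`trials` is missing columns: ", toString(miss)))
  }
  q <- dplyr::filter(trials, .data$queried)
  if (nrow(q) == 0) abort("no queried reports in `trials`.")
  arch <- params$architecture
  K <- params$stm_capacity

  q$true_dir_deg <- ifelse(q$segment == "pre", q$pre_direction_deg,
                           q$post_direction_deg)
  q$direction_change_deg <- wrap_angle(q$post_direction_deg -
                                         q$pre_direction_deg)
  sm_held <- q$segment == "post" | arch == "shared"

  n <- nrow(q)
  is_fr <- q$scope == "FR"
  within_trial_rank <- function(key) {
    o <- order(q$trial, key)
    runs <- rle(q$trial[o])$lengths
    pos <- integer(n)
    pos[o] <- sequence(runs)
    pos
  }

  # STM membership: K items per trial, sampled without replacement; on
  # single-report trials the queried disk is stored with probability K / N
  u_stm <- runif(n)
  stm_rank <- within_trial_rank(u_stm)
  q$in_stm <- ifelse(is_fr, stm_rank <= K,
                     u_stm < pmin(K, q$set_size) / q$set_size)

  order_key <- if (params$report_order_policy == "uniform") {
    runif(n)
  } else {
    # strength ordering: when SM does not hold the queried segment,
    # STM-stored items are reported first; ties broken at random
    ifelse(sm_held, 0, -as.numeric(q$in_stm)) + runif(n) * 0.5
  }
  q$report_order <- within_trial_rank(order_key)
  t_eff <- q$cue_delay_ms + (q$report_order - 1) * params$inter_report_latency_ms
  p_sm <- ifelse(sm_held, exp(-t_eff / params$sm_tau_ms), 0)

  src <- rep("guess", n)
  u1 <- runif(n)
  src[u1 < p_sm] <- "sm"
  src[u1 >= p_sm & q$in_stm] <- "stm"
  src[runif(n) < params$lapse_rate] <- "guess"

  if (arch == "guessing") {
    reported <- runif(n, 0, 360)
    src <- rep("guess", n)
  } else if (arch == "overwriting") {
    reported <- q$post_direction_deg + rnorm(n, 0, params$sm_sigma_deg)
    lapse <- runif(n) < params$lapse_rate
    reported[lapse] <- runif(sum(lapse), 0, 360)
    src <- ifelse(lapse, "guess", "sm")
  } else {
    reported <- rep(NA_real_, n)
    i_sm <- src == "sm"
    i_stm <- src == "stm"
    i_g <- src == "guess"
    reported[i_sm] <- q$true_dir_deg[i_sm] + rnorm(sum(i_sm), 0, params$sm_sigma_deg)
    reported[i_stm] <- q$true_dir_deg[i_stm] + rnorm(sum(i_stm), 0, params$stm_sigma_deg)
    reported[i_g] <- runif(sum(i_g), 0, 360)
  }
  reported <- reported %% 360
  err <- wrap_angle(reported - q$true_dir_deg)

  tibble::tibble(
    observer = params$observer,
    experiment = q$experiment,
    stimulus_condition = q$stimulus_condition,
    block = q$block,
    trial = q$trial,
    segment = q$segment,
    scope = q$scope,
    set_size = q$set_size,
    duration_ms = q$duration_ms,
    cue_delay_ms = q$cue_delay_ms,
    disk_id = q$disk,
    report_order = q$report_order,
    true_dir_deg = q$true_dir_deg,
    reported_dir_deg = reported,
    error_deg = err,
    tp = tp(err),
    direction_change_deg = q$direction_change_deg,
    source = src
  ) |>
    dplyr::arrange(.data$trial, .data$report_order)
}

#' Simulate a whole cohort
#'
#' Convenience wrapper running every observer of a cohort through the same
#' trial schedule and binding the response logs.
#'
#' @param trials A `segmot_trials` tibble.
#' @param cohort A `segmot_cohort` list from [make_cohort()].
#' @return A bound tibble of response records.
#' @export
simulate_cohort <- function(trials, cohort) {
  if (inherits(cohort, "segmot_observer")) cohort <- list(cohort)
  purrr::list_rbind(lapply(cohort, function(p) simulate_responses(trials, p)))
}
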