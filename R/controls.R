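#' Theoretical TP ceiling for an overwriting reporter
#'
#' If pre-deviation queries were systematically answered with the
#' post-deviation direction, the expected report error equals the expected
#' difference between the two segment directions, and passing that through
#' `TP = 1 - |delta| / 180` bounds the attainable transformed performance.
#' Under the interior-angle reading of the deviation (direction difference
#' `180 - |deviation|`) a uniform 30-180 deg deviation gives a mean
#' deviation of 105 deg, a mean direction difference of 75 deg, and a TP
#' ceiling of 0.583; under the direction-change reading the difference is
#' the deviation itself (mean 105 deg, ceiling ~0.417).
#'
#' @param deviation_range_deg Length-2 magnitude range of the deviation.
#' @param convention `"interior_angle"` (used for the printed control
#'   numbers) or `"direction_change"`.
#' @return A one-row tibble: `mean_deviation_deg`, `mean_direction_diff_deg`,
#'   `tp_bound`, `convention`.
#' @examples
#' overwriting_bound(c(30, 180), "interior_angle")
#' @export
overwriting_bound <- function(deviation_range_deg = c(30, 180),
                              convention = c("interior_angle",
                                             "direction_change")) {
  convention <- match.arg(convention)
  rng <- sort(deviation_range_deg)
  if (rng[1] < 0 || rng[2] > 180) {
    abort("`deviation_range_deg` magnitudes must lie in [0, 180].")
  }
  mean_dev <- mean(rng)
  diff <- switch(convention,
                 interior_angle = 180 - mean_dev,
                 direction_change = mean_dev)
  tibble::tibble(
    mean_deviation_deg = mean_dev,
    mean_direction_diff_deg = diff,
    tp_bound = 1 - diff / 180,
    convention = convention
  )
}

#' Monte-Carlo TP of the overwriting reporter across conditions
#'
#' Simulates, for every stimulus-condition level of an experiment
#' configuration, an observer who answers pre-deviation queries with the
#' post-deviation direction (plus optional report noise). Direction sets are
#' drawn under each condition's own constraints, so the pairwise-separation
#' rule truncates the deviation distribution exactly as it would in the
#' experiment; with the interior-angle convention the truncation pulls the
#' per-condition means below the analytic ceiling of [overwriting_bound()].
#'
#' @param config An [experiment_config()].
#' @param n_trials Simulated pre-deviation queries per condition level.
#' @param sm_sigma_deg Report noise SD in degrees (0 = noiseless).
#' @param deviation_convention Convention used when sampling the constrained
#'   direction sets.
#' @param min_direction_sep_deg Pairwise separation constraint; set to 0 for
#'   unconstrained deviations.
#' @return A tibble with one row per condition: `stimulus_condition`,
#'   `set_size`, `mean_tp`, `n_trials`.
#' @examples
#' set.seed(1)
#' overwriting_simulation(experiment_config("exp3"), n_trials = 200)
#' @export
overwriting_simulation <- function(config, n_trials = 1000, sm_sigma_deg = 0,
                                   deviation_convention = "interior_angle",
                                   min_direction_sep_deg = 20) {
  if (!inherits(config, "segmot_config")) {
    abort("`config` must come from `experiment_config()`.")
  }
  lv <- config$levels
  rows <- lapply(seq_len(nrow(lv)), function(i) {
    base <- lv$spec[[i]]
    spec <- stimulus_spec(
      n_disks = base$n_disks,
      disk_diameter_deg = base$disk_diameter_deg,
      speed_deg_per_s = base$speed_deg_per_s,
      duration_ms = base$duration_ms,
      regime = "constant_speed",
      deviation_range_deg = base$deviation_range_deg,
      min_direction_sep_deg = min_direction_sep_deg,
      deviation_convention = deviation_convention)
    dirs <- sample_direction_set(spec, n_sets = n_trials)
    one <- dirs[dirs$disk == 1, ] # disks are exchangeable
    reported <- one$post_direction_deg + rnorm(n_trials, 0, sm_sigma_deg)
    err <- wrap_angle(reported - one$pre_direction_deg)
    tibble::tibble(
      stimulus_condition = lv$stimulus_condition[i],
      set_size = lv$set_size[i],
      mean_tp = mean(tp(err)),
      n_trials = n_trials
    )
  })
  dplyr::bind_rows(rows)
}

#' Pre/post segment integration correlation
#'
#' If the two motion segments were integrated rather than stored as separate
#' event segments, the magnitude of the post-deviation report error should
#' grow with the angle between the segments. For each observer this computes
#' the Pearson correlation and least-squares slope of `|error|` on the
#' absolute inter-segment direction change, over post-deviation single
#' reports of the selected condition; the summary is the mean of the squared
#' correlations. An observer reporting the midpoint of the two segment
#' directions would show a slope near 0.5; independent report noise gives
#' correlations near 0.
#'
#' @param records A response-record tibble containing post-deviation single
#'   reports with a `direction_change_deg` column.
#' @param duration_ms Stimulus duration to select, or `NULL` to keep all.
#' @param min_reports Minimal qualifying reports per observer.
#' @return An object of class `segmot_integration`: list with `by_observer`
#'   (tibble of `observer`, `n`, `r`, `slope`) and `mean_r_squared`.
#' @export
integration_correlation <- function(records, duration_ms = 200,
                                    min_reports = 10) {
  need <- c("observer", "segment", "scope", "error_deg",
            "direction_change_deg")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) abort(paste0("missing columns: ", toString(miss)))
  sub <- records[records$segment == "post" & records$scope == "SR", ]
  if (!is.null(duration_ms)) {
    sub <- sub[sub$duration_ms == duration_ms, ]
  }
  if (nrow(sub) == 0) abort("no qualifying post-deviation single reports.")
  counts <- table(sub$observer)
  if (any(counts < min_reports)) {
    short <- names(counts)[counts < min_reports]
    abort(sprintf("fewer than %d qualifying reports for observer(s): %s",
                  min_reports, toString(short)))
  }
  by_obs <- sub |>
    dplyr::group_by(.data$observer) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = cor(abs(.data$direction_change_deg), abs(.data$error_deg)),
      slope = unname(coef(lm(abs(error_deg) ~ abs(direction_change_deg),
                             data = dplyr::pick(dplyr::everything())))[2]),
      .groups = "drop")
  structure(list(by_observer = by_obs,
                 mean_r_squared = mean_r_squared(by_obs$r)),
            class = "segmot_integration")
}

#' @export
print.segmot_integration <- function(x, ...) {
  cat(sprintf("<segmot integration correlation> mean r^2 = %.3f\n",
              x$mean_r_squared))
  print(x$by_observer, ...)
  invisible(x)
}

#' @export
tidy.segmot_integration <- function(x, ...) x$by_observer

#' @export
glance.segmot_integration <- function(x, ...) {
  tibble::tibble(mean_r_squared = x$mean_r_squared,
                 n_observers = nrow(x$by_observer))
}

#' Mean squared correlation
#'
#' Arithmetic helper: the mean of the squared correlation coefficients,
#' i.e. the average proportion of variance explained across observers.
#'
#' @param r Numeric vector of correlation coefficients in `[-1, 1]`.
#' @return A single number in `[0, 1]`.
#' @examples
#' mean_r_squared(c(0.23, 0.09, 0.36, 0.24))
#' @export
mean_r_squared <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    abort("`r` must be finite correlations in [-1, 1].")
  }
  mean(r^2)
}
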