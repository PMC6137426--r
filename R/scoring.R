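#' Aggregate transformed performance per condition cell
#'
#' Averages TP within each grouping cell (by default observer x experiment x
#' stimulus condition x segment x scope) and, for full-report cells, also per
#' report order (FR1, FR2, ...). Pooled cells carry `report_order = NA`; the
#' pooled full-report mean equals the equally-weighted mean over the defined
#' FR orders in a balanced design. Grouping cells that exist in the crossing
#' of the observed key levels but received no reports are flagged with a
#' warning and returned with `mean_tp = NA` rather than silently dropped.
#'
#' @param records A response-record tibble (needs a `tp` column, or
#'   `error_deg` from which TP is computed).
#' @param by Character vector of grouping columns.
#' @param fr_orders Also produce per-report-order rows for full-report cells?
#' @return A tibble of class `segmot_summary` with columns `by`,
#'   `report_order`, `mean_tp`, `n_reports`.
#' @examples
#' set.seed(1)
#' trials <- build_experiment(
#'   experiment_config("exp3", blocks_per_condition = 1,
#'                     trials_per_condition_per_block = 2))
#' log <- simulate_responses(trials, observer_params("shared"))
#' summarize_conditions(log)
#' @export
summarize_conditions <- function(records,
                                 by = c("observer", "experiment",
                                        "stimulus_condition", "segment",
                                        "scope"),
                                 fr_orders = TRUE) {
  records <- ensure_tp(records)
  miss <- setdiff(by, names(records))
  if (length(miss) > 0) abort(paste0("missing grouping columns: ", toString(miss)))
  pooled <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(mean_tp = mean(.data$tp),
                     n_reports = dplyr::n(), .groups = "drop") |>
    tidyr::complete(!!!syms(by))
  if (anyNA(pooled$mean_tp)) {
    bad <- pooled[is.na(pooled$mean_tp), by, drop = FALSE]
    warn(sprintf("%d condition cell(s) received no reports; returned as NA.",
                 nrow(bad)))
    pooled$n_reports[is.na(pooled$n_reports)] <- 0L
  }
  pooled$report_order <- NA_integer_
  out <- pooled
  if (fr_orders && "scope" %in% names(records)) {
    fr <- records |>
      dplyr::filter(.data$scope == "FR") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "report_order")))) |>
      dplyr::summarise(mean_tp = mean(.data$tp),
                       n_reports = dplyr::n(), .groups = "drop")
    out <- dplyr::bind_rows(pooled, fr)
  }
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(by)),
                        .data$report_order)
  class(out) <- c("segmot_summary", class(out))
  attr(out, "by") <- by
  out
}

ensure_tp <- function(records) {
  if (!"tp" %in% names(records)) {
    if (!"error_deg" %in% names(records)) {
      abort("`records` needs a `tp` or `error_deg` column.")
    }
    records$tp <- tp(records$error_deg)
  }
  records
}

#' RMS-error versus TP equivalence simulation
#'
#' For each nominal RMS error level, simulates `n_trials` zero-mean Gaussian
#' angular errors with that RMS, applies the transformed-performance map
#' `1 - |delta| / 180` to each error, and averages; then reports the Pearson
#' correlation between the RMS levels and their mean TP values. Over levels
#' spanning 1-90 deg the relation is almost perfectly linear (r practically
#' -1), which is why statistical conclusions are insensitive to the choice
#' between the two error measures.
#'
#' Two simulation-design details keep the comparison clean. First, one
#' standard-Gaussian error sample is drawn and rescaled to every RMS level
#' (common random numbers), so the level-to-level comparison is not diluted
#' by independent sampling noise. Second, the transform is applied to the
#' raw Gaussian errors rather than to circularly wrapped ones: wrapping
#' would bend the upper end of the curve and break the affine relation
#' `E[TP] = 1 - RMS * sqrt(2/pi) / 180` that the near-perfect correlation
#' reflects. At 90 deg RMS about 4.6% of raw errors exceed the half-circle
#' and contribute TP below 0; they are retained.
#'
#' @param rms_levels_deg Numeric vector of RMS error levels in `(0, 180)`
#'   degrees; default 21 arithmetically spaced levels from 1 to 90.
#' @param n_trials Simulated trials per level (>= 2).
#' @return An object of class `segmot_rms_tp`: a list with `levels` (tibble
#'   of `rms_deg`, `mean_tp`), `pearson_r` and `n_trials`. [tidy()] returns
#'   the per-level table, [glance()] the correlation.
#' @examples
#' set.seed(1)
#' rms_tp_equivalence(n_trials = 200)
#' @export
rms_tp_equivalence <- function(rms_levels_deg = seq(1, 90, length.out = 21),
                               n_trials = 1000) {
  if (any(rms_levels_deg <= 0 | rms_levels_deg >= 180)) {
    abort("`rms_levels_deg` must lie in (0, 180).")
  }
  if (n_trials < 2) abort("`n_trials` must be >= 2.")
  z <- rnorm(n_trials)
  mean_tp <- vapply(rms_levels_deg, function(s) {
    mean(1 - abs(s * z) / 180)
  }, numeric(1))
  structure(
    list(levels = tibble::tibble(rms_deg = rms_levels_deg, mean_tp = mean_tp),
         pearson_r = cor(rms_levels_deg, mean_tp),
         n_trials = n_trials),
    class = "segmot_rms_tp"
  )
}

#' @export
print.segmot_rms_tp <- function(x, ...) {
  cat(sprintf("<segmot RMS-TP equivalence> %d levels x %d trials, Pearson r = %.4f\n",
              nrow(x$levels), x$n_trials, x$pearson_r))
  cat(sprintf("  mean TP from %.3f (RMS %.1f deg) to %.3f (RMS %.1f deg)\n",
              x$levels$mean_tp[1], x$levels$rms_deg[1],
              x$levels$mean_tp[nrow(x$levels)],
              x$levels$rms_deg[nrow(x$levels)]))
  invisible(x)
}

#' @export
tidy.segmot_rms_tp <- function(x, ...) x$levels

#' @export
glance.segmot_rms_tp <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, n_levels = nrow(x$levels),
                 n_trials = x$n_trials)
}
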