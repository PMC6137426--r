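#' Plot a condition summary
#'
#' Mean TP (averaged over observers, error bars = SEM across observers) as a
#' function of stimulus condition, one line per report type (SR, FR pooled
#' and, optionally, FR1..FR4), facetted by event segment — the conventional
#' way these partial-report results are displayed.
#'
#' @param object A `segmot_summary` from [summarize_conditions()].
#' @param fr_orders Include the per-report-order full-report lines?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segmot_summary <- function(object, fr_orders = TRUE, ...) {
  d <- tibble::as_tibble(object)
  d$report <- ifelse(d$scope == "SR", "SR",
                     ifelse(is.na(d$report_order), "FR",
                            paste0("FR", d$report_order)))
  if (!fr_orders) d <- d[d$report %in% c("SR", "FR"), ]
  d <- d[!is.na(d$mean_tp), ]
  if ("observer" %in% names(d)) {
    d <- d |>
      dplyr::group_by(.data$stimulus_condition, .data$segment, .data$report) |>
      dplyr::summarise(
        sem = sd(.data$mean_tp) / sqrt(dplyr::n()),
        mean_tp = mean(.data$mean_tp),
        .groups = "drop")
  } else {
    d$sem <- NA_real_
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stimulus_condition,
                                  y = .data$mean_tp,
                                  colour = .data$report,
                                  group = .data$report)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_tp - .data$sem,
      ymax = .data$mean_tp + .data$sem), fatten = 2, na.rm = TRUE) +
    ggplot2::facet_wrap(~segment,
                        labeller = ggplot2::as_labeller(
                          c(pre = "pre-deviation", post = "post-deviation"))) +
    ggplot2::labs(x = "stimulus condition", y = "mean TP",
                  colour = "report") +
    ggplot2::theme_bw()
}

#' Plot the RMS-TP equivalence simulation
#'
#' @param object A `segmot_rms_tp` from [rms_tp_equivalence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segmot_rms_tp <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(x = .data$rms_deg, y = .data$mean_tp)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "nominal RMS error (deg)", y = "mean TP",
      subtitle = sprintf("Pearson r = %.4f", object$pearson_r)) +
    ggplot2::theme_bw()
}

#' Plot a signature matrix
#'
#' Tile display of the three sensory-memory signatures per event segment,
#' mirroring the prediction tables used to compare the two architectures.
#'
#' @param object A `segmot_signatures` from [signature_battery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segmot_signatures <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("segment", "decay", "sr_gt_fr",
                                  "sr_eq_fr1")],
    cols = c("decay", "sr_gt_fr", "sr_eq_fr1"),
    names_to = "signature", values_to = "present")
  d$segment <- factor(d$segment, levels = c("pre", "post"),
                      labels = c("pre-deviation", "post-deviation"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signature, y = .data$segment,
                                  fill = .data$present)) +
    ggplot2::geom_tile(colour = "white", linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$present, "YES", "NO")), colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e7d32",
                                          `FALSE` = "#c62828")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "signature present") +
    ggplot2::theme_minimal()
}
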