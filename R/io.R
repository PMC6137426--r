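trial_log_columns <- c(
  "observer", "experiment", "stimulus_condition", "block", "trial",
  "segment", "scope", "set_size", "duration_ms", "cue_delay_ms", "disk_id",
  "report_order", "true_dir_deg", "reported_dir_deg", "error_deg", "tp"
)

trial_log_version <- "segmot-trial-log v1"

#' Write a tidy trial log
#'
#' Serializes response records to comma-separated UTF-8 text with a
#' `#`-prefixed schema-version header line. Numeric angle/score columns are
#' rounded to 6 decimals, which is the precision guaranteed by the
#' write-read round trip. Extra columns beyond the core schema (e.g.
#' `direction_change_deg`, `source`) are preserved.
#'
#' @param records A response-record tibble (see [simulate_responses()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(records, path) {
  miss <- setdiff(trial_log_columns, names(records))
  if (length(miss) > 0) {
    abort(paste0("records are missing schema columns: ", toString(miss)))
  }
  out <- dplyr::relocate(tibble::as_tibble(records),
                         dplyr::all_of(trial_log_columns))
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, 6))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", trial_log_version), con)
  writeLines(readr::format_csv(out), con, sep = "")
  invisible(path)
}

#' Read a tidy trial log
#'
#' Reads a CSV trial log written by [write_trial_log()] (or assembled by
#' hand in the same schema), skipping `#` metadata lines, and validates the
#' core invariants: all schema columns present, `error_deg` in
#' `(-180, 180]`, `tp` in `[0, 1]`, `report_order >= 1`. Violations raise an
#' error naming the offending column and (first) row.
#'
#' @param path Input file path.
#' @return A tibble of response records.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 50L, warn = FALSE)
  if (all(grepl("^\\s*(#|$)", first))) {
    warn("empty trial log; returning zero records.")
    out <- tibble::as_tibble(setNames(
      rep(list(logical(0)), length(trial_log_columns)), trial_log_columns))
    return(out)
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  miss <- setdiff(trial_log_columns, names(out))
  if (length(miss) > 0) {
    abort(paste0("trial log is missing schema columns: ", toString(miss)))
  }
  check <- function(col, bad_idx, rule) {
    if (length(bad_idx) > 0) {
      abort(sprintf("column `%s` violates %s at row %d (%d offending row(s)).",
                    col, rule, bad_idx[1], length(bad_idx)))
    }
  }
  check("error_deg",
        which(!is.finite(out$error_deg) | out$error_deg <= -180 |
                out$error_deg > 180),
        "error_deg in (-180, 180]")
  check("tp", which(!is.finite(out$tp) | out$tp < 0 | out$tp > 1),
        "tp in [0, 1]")
  check("report_order",
        which(!is.finite(out$report_order) | out$report_order < 1),
        "report_order >= 1")
  out
}

#' Write a model verdict as JSON
#'
#' @param verdict A `segmot_verdict` from [classify_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_verdict_json <- function(verdict, path) {
  stopifnot(inherits(verdict, "segmot_verdict"))
  payload <- list(
    verdict = verdict$verdict,
    signatures = as.data.frame(tibble::as_tibble(verdict$signatures)),
    agreement = as.data.frame(verdict$agreement)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
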