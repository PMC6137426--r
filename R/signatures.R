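#' Sensory-memory signature battery
#'
#' Runs, separately for the pre- and post-deviation segments of one
#' experiment's response log, the three classical tests for the involvement
#' of a rapidly decaying, high-capacity sensory store:
#'
#' 1. **Decay with delay** — performance on single reports declines as the
#'    report is delayed. The delay variable is the cue delay when it varies
#'    across stimulus conditions for that segment (post-deviation cue delay
#'    in the delay experiment; the pre-deviation cue delay equals half the
#'    motion duration, so duration serves as the delay in the
#'    constant-length design). When the segment's cue delay is fixed, decay
#'    is instead tested across full-report order at the largest set size,
#'    with the inter-report interval as the delay proxy. The signature
#'    requires a significant repeated-measures main effect *and* a negative
#'    trend.
#' 2. **Single-report advantage** — `TP_SR > TP_FR`: a significant
#'    report-type main effect (RM-ANOVA with report type and, where present,
#'    stimulus condition as within factors) with the single-report mean
#'    above the full-report mean.
#' 3. **SR = FR1** — single-report performance comparable to the first
#'    full-report response, operationalised (as is conventional for this
#'    battery) as *non-rejection* of the report-type effect at `alpha`.
#'    Non-rejection is weak evidence, so the raw mean difference and p value
#'    are always reported alongside the boolean, and [classify_model()] does
#'    not let this signature drive the verdict.
#'
#' @param records A response-record tibble covering both segments and both
#'   report scopes (e.g. from [simulate_cohort()]).
#' @param alpha Significance threshold for every test.
#' @return A tibble of class `segmot_signatures` with one row per segment:
#'   booleans `decay`, `sr_gt_fr`, `sr_eq_fr1` plus the supporting
#'   statistics (`decay_p`, `decay_slope`, `decay_variable`, `sr_fr_p`,
#'   `sr_fr_diff`, `sr_fr1_p`, `sr_fr1_diff`).
#' @examples
#' set.seed(42)
#' trials <- build_experiment(
#'   experiment_config("exp1b", blocks_per_condition = 2,
#'                     trials_per_condition_per_block = 5))
#' log <- simulate_cohort(trials, make_cohort(4, observer_params("shared")))
#' signature_battery(log)
#' @export
signature_battery <- function(records, alpha = 0.05) {
  records <- ensure_tp(records)
  need <- c("observer", "stimulus_condition", "segment", "scope",
            "report_order", "cue_delay_ms", "set_size", "tp")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) abort(paste0("missing columns: ", toString(miss)))
  segs <- c("pre", "post")
  have <- expand.grid(segment = segs, scope = c("SR", "FR"),
                      stringsAsFactors = FALSE)
  present <- unique(records[, c("segment", "scope")])
  gone <- dplyr::anti_join(have, present, by = c("segment", "scope"))
  if (nrow(gone) > 0) {
    abort(paste0("missing segment/scope cells: ",
                 paste(paste(gone$segment, gone$scope), collapse = ", ")))
  }
  rows <- lapply(segs, function(sg) {
    sub <- records[records$segment == sg, ]
    a1 <- scope_effect(sub, fr_first_only = FALSE)
    a2 <- scope_effect(sub, fr_first_only = TRUE)
    dec <- decay_test(sub)
    tibble::tibble(
      segment = sg,
      decay = dec$p < alpha && dec$slope < 0,
      sr_gt_fr = a1$p < alpha && a1$diff > 0,
      sr_eq_fr1 = a2$p >= alpha,
      decay_p = dec$p, decay_slope = dec$slope,
      decay_variable = dec$variable,
      sr_fr_p = a1$p, sr_fr_diff = a1$diff,
      sr_fr1_p = a2$p, sr_fr1_diff = a2$diff
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("segmot_signatures", class(out))
  attr(out, "alpha") <- alpha
  out
}

# report-type effect (SR vs FR, or SR vs FR1) within one segment
scope_effect <- function(sub, fr_first_only) {
  dat <- sub
  if (fr_first_only) {
    dat <- dat[dat$scope == "SR" | dat$report_order == 1, ]
  }
  dat$report_type <- factor(dat$scope, levels = c("SR", "FR"))
  within <- "report_type"
  if (length(unique(dat$stimulus_condition)) > 1) {
    within <- c("report_type", "stimulus_condition")
  }
  res <- rm_anova(dat, dv = "tp", within = within, subject = "observer")
  p <- res$p.value[res$term == "report_type"]
  means <- dat |>
    dplyr::group_by(.data$observer, .data$report_type) |>
    dplyr::summarise(tp = mean(.data$tp), .groups = "drop") |>
    dplyr::group_by(.data$report_type) |>
    dplyr::summarise(tp = mean(.data$tp))
  diff <- means$tp[means$report_type == "SR"] -
    means$tp[means$report_type == "FR"]
  list(p = p, diff = diff)
}

# delay-decay test within one segment; see signature_battery() docs for the
# choice of delay variable
decay_test <- function(sub) {
  srr <- sub[sub$scope == "SR", ]
  if (length(unique(srr$cue_delay_ms)) > 1) {
    dat <- srr
    dat$.level <- dat$cue_delay_ms
    variable <- "cue_delay_ms"
  } else {
    nmax <- max(sub$set_size)
    if (nmax < 2) {
      abort("decay is untestable: fixed cue delay and set size < 2.")
    }
    dat <- sub[sub$scope == "FR" & sub$set_size == nmax, ]
    dat$.level <- dat$report_order
    variable <- "report_order"
  }
  res <- rm_anova(dat, dv = "tp", within = ".level", subject = "observer")
  cellmeans <- dat |>
    dplyr::group_by(.data$observer, .data$.level) |>
    dplyr::summarise(tp = mean(.data$tp), .groups = "drop")
  slope <- unname(coef(lm(tp ~ .level, data = cellmeans))[2])
  list(p = res$p.value[1], slope = slope, variable = variable)
}

#' @export
print.segmot_signatures <- function(x, ...) {
  cat(sprintf("<segmot signature matrix> alpha = %g\n", attr(x, "alpha")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @export
tidy.segmot_signatures <- function(x, ...) tibble::as_tibble(x)

#' Classify the generating memory architecture
#'
#' Turns a signature matrix into a model verdict. A segment counts as
#' showing sensory-memory involvement when both positive-evidence signatures
#' hold (decay with delay *and* a single-report advantage); the SR = FR1
#' non-rejection is tabulated for comparison with each model's prediction
#' but, being a null result, does not gate the verdict. Evidence in the
#' current (post-deviation) segment only yields `"exclusive"`; evidence in
#' both segments yields `"shared"`; no post-deviation evidence leaves the
#' data `"indeterminate"`.
#'
#' @param signatures A `segmot_signatures` tibble from [signature_battery()].
#' @return An object of class `segmot_verdict`: list with `verdict`,
#'   the input `signatures`, and an `agreement` tibble comparing each
#'   observed signature with the predictions of the two architectures.
#' @export
classify_model <- function(signatures) {
  if (!inherits(signatures, "segmot_signatures")) {
    abort("`signatures` must come from `signature_battery()`.")
  }
  s <- tibble::as_tibble(signatures)
  sm <- function(seg) {
    i <- which(s$segment == seg)
    s$decay[i] && s$sr_gt_fr[i]
  }
  verdict <- if (!sm("post")) {
    "indeterminate"
  } else if (sm("pre")) {
    "shared"
  } else {
    "exclusive"
  }
  obs <- tidyr::pivot_longer(
    s[, c("segment", "decay", "sr_gt_fr", "sr_eq_fr1")],
    cols = c("decay", "sr_gt_fr", "sr_eq_fr1"),
    names_to = "signature", values_to = "observed")
  obs$shared_pred <- TRUE
  obs$exclusive_pred <- obs$segment == "post"
  obs$agrees_shared <- obs$observed == obs$shared_pred
  obs$agrees_exclusive <- obs$observed == obs$exclusive_pred
  structure(list(verdict = verdict, signatures = signatures,
                 agreement = obs),
            class = "segmot_verdict")
}

#' @export
print.segmot_verdict <- function(x, ...) {
  cat(sprintf("<segmot verdict> %s\n", x$verdict))
  print(x$agreement, ...)
  invisible(x)
}

#' @export
tidy.segmot_verdict <- function(x, ...) x$agreement

#' @export
glance.segmot_verdict <- function(x, ...) {
  tibble::tibble(verdict = x$verdict,
                 shared_agreement = mean(x$agreement$agrees_shared),
                 exclusive_agreement = mean(x$agreement$agrees_exclusive))
}

#' Model-recovery replication
#'
#' Repeatedly simulates a fresh cohort on a fresh trial schedule and records
#' the verdict of the signature battery, to estimate how reliably the
#' pipeline recovers the generating architecture.
#'
#' @param n_cohorts Number of replicate cohorts.
#' @param params Template [observer_params()] for the cohort.
#' @param config An [experiment_config()].
#' @param n_observers Observers per cohort.
#' @param jitter Between-observer parameter jitter (see [make_cohort()]).
#' @param alpha Significance threshold for the battery.
#' @return A tibble with one row per replicate: `replicate`, `verdict`, and
#'   the six signature booleans (`pre_decay`, `pre_sr_gt_fr`,
#'   `pre_sr_eq_fr1`, `post_decay`, `post_sr_gt_fr`, `post_sr_eq_fr1`).
#' @export
model_recovery <- function(n_cohorts = 100, params = observer_params(),
                           config = experiment_config("exp1b"),
                           n_observers = 4, jitter = 0.1, alpha = 0.05) {
  rows <- lapply(seq_len(n_cohorts), function(i) {
    trials <- build_experiment(config)
    cohort <- make_cohort(n_observers, params, jitter)
    log <- simulate_cohort(trials, cohort)
    sig <- signature_battery(log, alpha = alpha)
    v <- classify_model(sig)
    s <- tibble::as_tibble(sig)
    pre <- s[s$segment == "pre", ]
    post <- s[s$segment == "post", ]
    tibble::tibble(
      replicate = i, verdict = v$verdict,
      pre_decay = pre$decay, pre_sr_gt_fr = pre$sr_gt_fr,
      pre_sr_eq_fr1 = pre$sr_eq_fr1,
      post_decay = post$decay, post_sr_gt_fr = post$sr_gt_fr,
      post_sr_eq_fr1 = post$sr_eq_fr1
    )
  })
  dplyr::bind_rows(rows)
}
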