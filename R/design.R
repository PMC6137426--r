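#' Experiment presets
#'
#' Builds the configuration for one of the four study designs:
#'
#' * `exp1a` — constant speed: 3 disks at 5 deg/s for 200, 400, 800 or
#'   1200 ms (path length co-varies with duration).
#' * `exp1b` — constant trajectory length: same durations, path fixed at
#'   4 deg (speed co-varies), so the pre-deviation cue delay spans
#'   100-600 ms while signal strength is held constant.
#' * `exp2` — post-deviation cue delay of 0, 100, 200, 400, 800 or 1600 ms
#'   at a fixed 800 ms duration.
#' * `exp3` — set size 1-4 at 5 deg/s, 800 ms.
#'
#' Every stimulus-condition level is run in `blocks_per_condition` blocks of
#' `4 * trials_per_condition_per_block` trials (the four reporting conditions
#' randomly interleaved within a block), giving 1600 trials for exp1a/1b/3
#' and 2400 for exp2 at the defaults.
#'
#' @param preset One of `"exp1a"`, `"exp1b"`, `"exp2"`, `"exp3"`.
#' @param blocks_per_condition Blocks per stimulus-condition level.
#' @param trials_per_condition_per_block Trials per reporting condition per
#'   block.
#' @param display A [display_spec()].
#' @param ... Further arguments passed to [stimulus_spec()] for every level
#'   (e.g. `deviation_convention`, `min_direction_sep_deg`).
#' @return An object of class `segmot_config`.
#' @examples
#' experiment_config("exp1b")
#' @export
experiment_config <- function(preset = c("exp1a", "exp1b", "exp2", "exp3"),
                              blocks_per_condition = 10,
                              trials_per_condition_per_block = 10,
                              display = display_spec(), ...) {
  preset <- match.arg(preset)
  durations <- c(200, 400, 800, 1200)
  levels <- switch(
    preset,
    exp1a = tibble::tibble(
      stimulus_condition = paste0("dur", durations),
      set_size = 3L, duration_ms = durations, cue_delay_post_ms = 0,
      spec = lapply(durations, function(d) {
        stimulus_spec(n_disks = 3, speed_deg_per_s = 5, duration_ms = d,
                      regime = "constant_speed", ...)
      })),
    exp1b = tibble::tibble(
      stimulus_condition = paste0("dur", durations),
      set_size = 3L, duration_ms = durations, cue_delay_post_ms = 0,
      spec = lapply(durations, function(d) {
        stimulus_spec(n_disks = 3, duration_ms = d,
                      regime = "constant_length",
                      trajectory_length_deg = 4, ...)
      })),
    exp2 = {
      delays <- c(0, 100, 200, 400, 800, 1600)
      tibble::tibble(
        stimulus_condition = paste0("delay", delays),
        set_size = 3L, duration_ms = 800, cue_delay_post_ms = delays,
        spec = lapply(delays, function(d) {
          stimulus_spec(n_disks = 3, speed_deg_per_s = 5, duration_ms = 800,
                        regime = "constant_speed", ...)
        }))
    },
    exp3 = tibble::tibble(
      stimulus_condition = paste0("set", 1:4),
      set_size = 1:4, duration_ms = 800, cue_delay_post_ms = 0,
      spec = lapply(1:4, function(n) {
        stimulus_spec(n_disks = n, speed_deg_per_s = 5, duration_ms = 800,
                      regime = "constant_speed", ...)
      }))
  )
  levels$speed_deg_per_s <- vapply(levels$spec, `[[`, numeric(1),
                                   "speed_deg_per_s")
  structure(
    list(preset = preset, levels = levels,
         blocks_per_condition = blocks_per_condition,
         trials_per_condition_per_block = trials_per_condition_per_block,
         display = display),
    class = "segmot_config"
  )
}

#' @export
print.segmot_config <- function(x, ...) {
  n <- nrow(x$levels) * x$blocks_per_condition * 4 *
    x$trials_per_condition_per_block
  cat(sprintf("<segmot config> preset %s: %d condition level(s) x %d block(s) x 4 reporting conditions x %d trials = %d trials\n",
              x$preset, nrow(x$levels), x$blocks_per_condition,
              x$trials_per_condition_per_block, n))
  invisible(x)
}

#' Build a full trial schedule
#'
#' Expands an [experiment_config()] into per-trial, per-disk rows with
#' freshly sampled stimuli. Stimulus-condition levels are blocked and block
#' order is randomised; within a block the four reporting conditions
#' (pre/post-deviation x single/full report) are equally frequent and
#' randomly interleaved. Single-report trials query one disk chosen
#' uniformly; full-report trials query all. The pre-deviation cue delay is
#' half the motion duration (the cue appears at motion offset, the segment
#' ended mid-trajectory); post-deviation cue delay is 0 except in `exp2`.
#'
#' @param config An [experiment_config()].
#' @param display Optional [display_spec()] overriding the one in `config`.
#' @return A tibble of class `segmot_trials` with one row per (trial, disk):
#'   schedule columns (`experiment`, `stimulus_condition`, `set_size`,
#'   `duration_ms`, `speed_deg_per_s`, `cue_delay_ms`, `block`, `trial`,
#'   `segment`, `scope`), trajectory geometry columns from
#'   [sample_stimulus_set()], and the logical `queried`.
#' @examples
#' set.seed(1)
#' trials <- build_experiment(
#'   experiment_config("exp3", blocks_per_condition = 1,
#'                     trials_per_condition_per_block = 2))
#' @export
build_experiment <- function(config, display = NULL) {
  if (!inherits(config, "segmot_config")) {
    abort("`config` must come from `experiment_config()`.")
  }
  display <- display %||% config$display
  lv <- config$levels
  nb <- config$blocks_per_condition
  tpb <- config$trials_per_condition_per_block

  block_cond <- rep(lv$stimulus_condition, each = nb)
  block_cond <- block_cond[sample.int(length(block_cond))]
  n_blocks <- length(block_cond)
  per_block <- 4L * tpb
  base <- rep(c("pre.SR", "pre.FR", "post.SR", "post.FR"), each = tpb)
  cond <- as.vector(vapply(seq_len(n_blocks),
                           function(b) sample(base), character(per_block)))
  trials <- tibble::tibble(
    block = rep(seq_len(n_blocks), each = per_block),
    stimulus_condition = rep(block_cond, each = per_block),
    segment = sub("\\..*$", "", cond),
    scope = sub("^.*\\.", "", cond)
  )
  trials$trial <- seq_len(nrow(trials))
  trials <- dplyr::left_join(
    trials,
    dplyr::select(lv, "stimulus_condition", "set_size", "duration_ms",
                  "speed_deg_per_s", "cue_delay_post_ms"),
    by = "stimulus_condition")
  trials$cue_delay_ms <- ifelse(trials$segment == "pre",
                                trials$duration_ms / 2,
                                trials$cue_delay_post_ms)
  trials$cue_delay_post_ms <- NULL
  trials$sr_disk <- vapply(trials$set_size, function(n) sample.int(n, 1L),
                           integer(1))

  geom_cols <- c("pre_direction_deg", "deviation_deg", "post_direction_deg",
                 "start_x_deg", "start_y_deg", "vertex_x_deg", "vertex_y_deg",
                 "end_x_deg", "end_y_deg")
  disk_rows <- purrr::map(seq_len(nrow(lv)), function(i) {
    tri <- trials$trial[trials$stimulus_condition == lv$stimulus_condition[i]]
    stim <- sample_stimulus_set(lv$spec[[i]], display, n_sets = length(tri))
    stim$trial <- tri[stim$set]
    stim[, c("trial", "disk", geom_cols)]
  })
  disk_rows <- purrr::list_rbind(disk_rows)

  out <- dplyr::inner_join(trials, disk_rows, by = "trial")
  out$queried <- out$scope == "FR" | out$disk == out$sr_disk
  out$sr_disk <- NULL
  out$experiment <- config$preset
  out <- dplyr::relocate(out, "experiment") |>
    dplyr::arrange(.data$trial, .data$disk)
  class(out) <- c("segmot_trials", class(out))
  attr(out, "config") <- config
  attr(out, "display") <- display
  out
}

#' Report-cue description for scheduled trials
#'
#' For every disk of every trial, gives the cue the observer would see at
#' report time: pre-deviation cues redraw each disk at its deviation vertex
#' and mark the queried disk(s) blue; post-deviation cues leave disks at
#' their final positions and mark the queried disk(s) red. Unmarked disks
#' stay gray.
#'
#' @param trials A `segmot_trials` tibble from [build_experiment()].
#' @return A tibble with columns `trial`, `disk`, `x_deg`, `y_deg`,
#'   `marked`, `color`.
#' @export
cue_for <- function(trials) {
  need <- c("trial", "disk", "segment", "queried", "vertex_x_deg",
            "vertex_y_deg", "end_x_deg", "end_y_deg")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) abort(paste0("missing columns: ", toString(miss)))
  pre <- trials$segment == "pre"
  tibble::tibble(
    trial = trials$trial,
    disk = trials$disk,
    x_deg = ifelse(pre, trials$vertex_x_deg, trials$end_x_deg),
    y_deg = ifelse(pre, trials$vertex_y_deg, trials$end_y_deg),
    marked = trials$queried,
    color = ifelse(trials$queried, ifelse(pre, "blue", "red"), "gray")
  )
}
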