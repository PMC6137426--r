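# Vectorised rejection sampler for direction sets. Returns matrices
# (n_sets x n_disks) of pre directions, signed deviations and post
# directions. The whole direction set of a failing display is resampled, so
# accepted sets keep the unconditioned per-disk distributions exactly
# (under the direction-change convention the separation rule is
# independent of the deviation magnitude; see the methods vignette).
sample_direction_matrices <- function(spec, n_sets, max_attempts = 10000) {
  N <- spec$n_disks
  lo <- spec$deviation_range_deg[1]
  hi <- spec$deviation_range_deg[2]
  min_sep <- spec$min_direction_sep_deg
  pre <- dev <- post <- matrix(NA_real_, n_sets, N)
  active <- seq_len(n_sets)
  attempt <- 0L
  while (length(active) > 0) {
    attempt <- attempt + 1L
    if (attempt > max_attempts) {
      abort(sprintf(
        "direction-set constraints unsatisfied after %d attempts; the separation rule may be infeasible.",
        max_attempts))
    }
    m <- length(active)
    p <- matrix(runif(m * N, 0, 360), m, N)
    mag <- matrix(runif(m * N, lo, hi), m, N)
    sgn <- matrix(sample(c(-1, 1), m * N, replace = TRUE), m, N)
    d <- sgn * mag
    po <- switch(spec$deviation_convention,
                 direction_change = p + d,
                 interior_angle = p + sgn * (180 - mag))
    po <- po %% 360
    dirs <- cbind(p, po)
    ok <- rep(TRUE, m)
    k <- 2L * N
    if (k > 1 && min_sep > 0) {
      for (i in seq_len(k - 1L)) {
        for (j in seq.int(i + 1L, k)) {
          df <- abs(dirs[, i] - dirs[, j]) %% 360
          sep <- 180 - abs(180 - df)
          ok <- ok & sep >= min_sep
        }
      }
    }
    if (any(ok)) {
      rows <- active[ok]
      pre[rows, ] <- p[ok, , drop = FALSE]
      dev[rows, ] <- d[ok, , drop = FALSE]
      post[rows, ] <- po[ok, , drop = FALSE]
      active <- active[!ok]
    }
  }
  list(pre = pre, deviation = dev, post = post)
}

#' Sample constrained direction sets
#'
#' Draws, for each display, `n_disks` pre-deviation directions uniformly on
#' the circle and deviation magnitudes uniformly on the configured range with
#' random sign, derives post-deviation directions under the active deviation
#' convention, and rejection-samples whole sets until all `2 * n_disks`
#' directions are pairwise at least `min_direction_sep_deg` apart.
#'
#' @param spec A [stimulus_spec()].
#' @param n_sets Number of independent direction sets to draw.
#' @param max_attempts Maximal number of resampling rounds before an
#'   infeasible-constraint error is raised.
#' @return A tibble with one row per (set, disk): columns `set`, `disk`,
#'   `pre_direction_deg`, `deviation_deg` (signed), `post_direction_deg`.
#' @examples
#' set.seed(1)
#' sample_direction_set(stimulus_spec(n_disks = 3))
#' @export
sample_direction_set <- function(spec, n_sets = 1, max_attempts = 10000) {
  stopifnot(inherits(spec, "segmot_stimulus_spec"))
  m <- sample_direction_matrices(spec, n_sets, max_attempts)
  N <- spec$n_disks
  tibble::tibble(
    set = rep(seq_len(n_sets), times = N),
    disk = rep(seq_len(N), each = n_sets),
    pre_direction_deg = as.vector(m$pre),
    deviation_deg = as.vector(m$deviation),
    post_direction_deg = as.vector(m$post)
  ) |>
    dplyr::arrange(.data$set, .data$disk)
}

#' Sample complete bilinear-trajectory stimulus sets
#'
#' Combines constrained direction sampling with start-point placement. Every
#' trajectory is two straight segments of equal length joined at the
#' deviation vertex; the start point is drawn uniformly from the (closed-form)
#' feasible rectangle that keeps start, vertex and end — plus the disk
#' radius — inside the display, so no frame of the motion leaves the screen.
#' Sets whose start points come closer than one disk diameter are rejected
#' and their start points resampled.
#'
#' @inheritParams sample_direction_set
#' @param display A [display_spec()] giving the bounds, in degrees, with the
#'   origin at the lower-left corner of the visible area.
#' @return A tibble with one row per (set, disk): directions plus
#'   `start_x_deg`, `start_y_deg`, `vertex_x_deg`, `vertex_y_deg`,
#'   `end_x_deg`, `end_y_deg`, `speed_deg_per_s`, `duration_ms`.
#' @examples
#' set.seed(1)
#' stim <- sample_stimulus_set(stimulus_spec(), display_spec())
#' @export
sample_stimulus_set <- function(spec, display = display_spec(), n_sets = 1,
                                max_attempts = 10000) {
  stopifnot(inherits(spec, "segmot_stimulus_spec"),
            inherits(display, "segmot_display"))
  N <- spec$n_disks
  L <- spec$trajectory_length_deg
  r <- spec$disk_diameter_deg / 2
  W <- display$width_deg
  H <- display$height_deg
  if (L + 2 * r > sqrt(W^2 + H^2)) {
    abort("infeasible geometry: trajectory length exceeds the display diagonal.")
  }
  h <- L / 2
  dirs <- sample_direction_matrices(spec, n_sets, max_attempts)
  sx <- sy <- matrix(NA_real_, n_sets, N)
  active <- seq_len(n_sets)
  attempt <- 0L
  while (length(active) > 0) {
    attempt <- attempt + 1L
    if (attempt > max_attempts) {
      abort(sprintf(
        "could not place trajectories after %d attempts; display too small for the path length.",
        max_attempts))
    }
    rows <- active
    m <- length(rows)
    dx1 <- h * cos(dirs$pre[rows, , drop = FALSE] * pi / 180)
    dy1 <- h * sin(dirs$pre[rows, , drop = FALSE] * pi / 180)
    dx2 <- h * cos(dirs$post[rows, , drop = FALSE] * pi / 180)
    dy2 <- h * sin(dirs$post[rows, , drop = FALSE] * pi / 180)
    # pmax takes dims from its first argument, so the matrix must come first
    xlo <- r + pmax(-dx1, -(dx1 + dx2), 0)
    xhi <- W - r - pmax(dx1, dx1 + dx2, 0)
    ylo <- r + pmax(-dy1, -(dy1 + dy2), 0)
    yhi <- H - r - pmax(dy1, dy1 + dy2, 0)
    bad <- matrix(xlo > xhi | ylo > yhi, m, N)
    bad_set <- rowSums(bad) > 0
    if (any(bad_set)) {
      # no feasible start for some disk: redraw that display's directions
      redo <- sample_direction_matrices(spec, sum(bad_set), max_attempts)
      idx <- rows[bad_set]
      dirs$pre[idx, ] <- redo$pre
      dirs$deviation[idx, ] <- redo$deviation
      dirs$post[idx, ] <- redo$post
    }
    good <- which(!bad_set)
    if (length(good) > 0) {
      g <- rows[good]
      gx <- matrix(runif(length(good) * N, xlo[good, ], xhi[good, ]),
                   length(good), N)
      gy <- matrix(runif(length(good) * N, ylo[good, ], yhi[good, ]),
                   length(good), N)
      sx[g, ] <- gx
      sy[g, ] <- gy
      overlap <- rep(FALSE, length(good))
      if (N > 1) {
        for (i in seq_len(N - 1L)) {
          for (j in seq.int(i + 1L, N)) {
            dd <- sqrt((gx[, i] - gx[, j])^2 + (gy[, i] - gy[, j])^2)
            overlap <- overlap | dd <= spec$disk_diameter_deg
          }
        }
      }
      placed <- g[!overlap]
      active <- setdiff(active, placed)
    }
  }
  pre_r <- dirs$pre * pi / 180
  post_r <- dirs$post * pi / 180
  vx <- sx + h * cos(pre_r)
  vy <- sy + h * sin(pre_r)
  ex <- vx + h * cos(post_r)
  ey <- vy + h * sin(post_r)
  out <- tibble::tibble(
    set = rep(seq_len(n_sets), times = N),
    disk = rep(seq_len(N), each = n_sets),
    pre_direction_deg = as.vector(dirs$pre),
    deviation_deg = as.vector(dirs$deviation),
    post_direction_deg = as.vector(dirs$post),
    start_x_deg = as.vector(sx),
    start_y_deg = as.vector(sy),
    vertex_x_deg = as.vector(vx),
    vertex_y_deg = as.vector(vy),
    end_x_deg = as.vector(ex),
    end_y_deg = as.vector(ey),
    speed_deg_per_s = spec$speed_deg_per_s,
    duration_ms = spec$duration_ms
  ) |>
    dplyr::arrange(.data$set, .data$disk)
  attr(out, "spec") <- spec
  attr(out, "display") <- display
  out
}

#' Disk position along a bilinear trajectory
#'
#' Piecewise-linear position at time `t_ms`: along the pre-deviation segment
#' for `t <= duration/2`, along the post-deviation segment afterwards,
#' continuous at the vertex.
#'
#' @param traj A tibble of trajectories as returned by
#'   [sample_stimulus_set()] (columns `start_x_deg`, `start_y_deg`,
#'   `vertex_x_deg`, `vertex_y_deg`, `pre_direction_deg`,
#'   `post_direction_deg`, `speed_deg_per_s`, `duration_ms`).
#' @param t_ms Time since motion onset in ms, scalar or one value per row;
#'   must lie in `[0, duration_ms]`.
#' @return A tibble with columns `x_deg`, `y_deg`.
#' @export
position_at <- function(traj, t_ms) {
  need <- c("start_x_deg", "start_y_deg", "vertex_x_deg", "vertex_y_deg",
            "pre_direction_deg", "post_direction_deg", "speed_deg_per_s",
            "duration_ms")
  miss <- setdiff(need, names(traj))
  if (length(miss) > 0) abort(paste0("missing columns: ", toString(miss)))
  t_ms <- rep_len(t_ms, nrow(traj))
  if (any(t_ms < 0 | t_ms > traj$duration_ms)) {
    abort("`t_ms` must lie within [0, duration_ms].")
  }
  v <- traj$speed_deg_per_s / 1000 # deg per ms
  half <- traj$duration_ms / 2
  t1 <- pmin(t_ms, half)
  t2 <- pmax(t_ms - half, 0)
  x <- traj$start_x_deg + v * t1 * cos(traj$pre_direction_deg * pi / 180) +
    v * t2 * cos(traj$post_direction_deg * pi / 180)
  y <- traj$start_y_deg + v * t1 * sin(traj$pre_direction_deg * pi / 180) +
    v * t2 * sin(traj$post_direction_deg * pi / 180)
  tibble::tibble(x_deg = x, y_deg = y)
}

#' Frame-by-frame disk positions
#'
#' Expands trajectories into per-frame positions at the display refresh rate,
#' suitable for containment checks or CSV export.
#'
#' @inheritParams position_at
#' @param frame_rate_hz Sampling rate in Hz.
#' @return A tibble with columns `set`, `disk`, `frame`, `t_ms`, `x_deg`,
#'   `y_deg`.
#' @export
trajectory_frames <- function(traj, frame_rate_hz = 100) {
  step <- 1000 / frame_rate_hz
  idx <- rep(seq_len(nrow(traj)), times = floor(traj$duration_ms / step) + 1)
  expanded <- traj[idx, , drop = FALSE]
  frame <- unlist(lapply(floor(traj$duration_ms / step), function(k) 0:k))
  t_ms <- frame * step
  pos <- position_at(expanded, t_ms)
  tibble::tibble(
    set = if ("set" %in% names(expanded)) expanded$set else 1L,
    disk = if ("disk" %in% names(expanded)) expanded$disk else 1L,
    frame = frame,
    t_ms = t_ms,
    x_deg = pos$x_deg,
    y_deg = pos$y_deg
  )
}

#' Serialize a stimulus set to JSON
#'
#' Writes trajectories (all geometric fields) plus the generating stimulus
#' parameters to a JSON file.
#'
#' @param stim A tibble from [sample_stimulus_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_json <- function(stim, path) {
  spec <- attr(stim, "spec")
  payload <- list(
    spec = if (is.null(spec)) NULL else unclass(spec),
    trajectories = as.data.frame(stim)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
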