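#' Display geometry
#'
#' Physical and angular geometry of the stimulus display. Defaults describe a
#' CRT viewed from 1 m: 22.5 x 17 degrees of visual angle, 800 x 600 pixels on
#' a 39.5 x 29.5 cm visible area, refreshed at 100 Hz.
#'
#' @param width_deg,height_deg Display extent in degrees of visual angle.
#' @param width_px,height_px Display extent in pixels.
#' @param width_cm,height_cm Physical extent of the visible area in cm.
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#' @param frame_rate_hz Refresh rate in Hz.
#' @return An object of class `segmot_display`.
#' @examples
#' display_spec()
#' @export
display_spec <- function(width_deg = 22.5, height_deg = 17,
                         width_px = 800L, height_px = 600L,
                         width_cm = 39.5, height_cm = 29.5,
                         viewing_distance_cm = 100,
                         frame_rate_hz = 100) {
  vals <- c(width_deg, height_deg, width_px, height_px, width_cm, height_cm,
            viewing_distance_cm, frame_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all display dimensions must be positive and finite.")
  }
  if (width_px != round(width_px) || height_px != round(height_px)) {
    abort("pixel counts must be whole numbers.")
  }
  structure(
    list(width_deg = width_deg, height_deg = height_deg,
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         width_cm = width_cm, height_cm = height_cm,
         viewing_distance_cm = viewing_distance_cm,
         frame_rate_hz = frame_rate_hz),
    class = "segmot_display"
  )
}

#' @export
print.segmot_display <- function(x, ...) {
  cat(sprintf("<segmot display> %.1f x %.1f deg, %d x %d px, %g Hz, %g cm viewing distance\n",
              x$width_deg, x$height_deg, x$width_px, x$height_px,
              x$frame_rate_hz, x$viewing_distance_cm))
  invisible(x)
}

#' Stimulus parameters for bilinear-trajectory displays
#'
#' Describes one stimulus condition: `n_disks` gray disks of diameter
#' `disk_diameter_deg` move along bilinear trajectories (two straight
#' segments joined at a mid-course deviation). The deviation magnitude is
#' drawn uniformly from `deviation_range_deg`, clockwise or counter-clockwise
#' with equal probability, and none of the `2 * n_disks` motion directions in
#' a display may come within `min_direction_sep_deg` of one another.
#'
#' Two speed regimes are supported: `"constant_speed"` fixes
#' `speed_deg_per_s` and lets the path length follow the duration;
#' `"constant_length"` fixes `trajectory_length_deg` and derives the speed.
#'
#' Two readings of "deviated by x degrees" are exposed.
#' `"direction_change"` (the default) treats the sampled deviation as the
#' change in direction (`post = pre + deviation`); `"interior_angle"` treats
#' it as the angle subtended at the vertex, so the direction change is
#' `180 - |deviation|` with the sampled sign.
#'
#' @param n_disks Number of disks (1 to 4).
#' @param disk_diameter_deg Disk diameter in degrees.
#' @param speed_deg_per_s Motion speed in deg/s (constant-speed regime).
#' @param duration_ms Total motion duration in ms.
#' @param regime `"constant_speed"` or `"constant_length"`.
#' @param trajectory_length_deg Total path length in degrees
#'   (constant-length regime).
#' @param deviation_range_deg Length-2 numeric, the magnitude range of the
#'   mid-course deviation in degrees; must lie within `(0, 180]`.
#' @param min_direction_sep_deg Minimal pairwise circular separation among
#'   all motion directions in one display, degrees.
#' @param deviation_convention `"direction_change"` or `"interior_angle"`.
#' @return An object of class `segmot_stimulus_spec`.
#' @examples
#' stimulus_spec(n_disks = 3, duration_ms = 800)
#' @export
stimulus_spec <- function(n_disks = 3, disk_diameter_deg = 1,
                          speed_deg_per_s = 5, duration_ms = 800,
                          regime = c("constant_speed", "constant_length"),
                          trajectory_length_deg = 4,
                          deviation_range_deg = c(30, 180),
                          min_direction_sep_deg = 20,
                          deviation_convention = c("direction_change",
                                                   "interior_angle")) {
  regime <- match.arg(regime)
  deviation_convention <- match.arg(deviation_convention)
  if (n_disks < 1 || n_disks > 4 || n_disks != round(n_disks)) {
    abort("`n_disks` must be a whole number between 1 and 4.")
  }
  if (duration_ms <= 0) abort("`duration_ms` must be positive.")
  if (min_direction_sep_deg < 0) abort("`min_direction_sep_deg` must be >= 0.")
  rng <- sort(deviation_range_deg)
  if (length(rng) != 2 || rng[2] > 180 || rng[2] <= 0 || rng[1] < 0) {
    abort("`deviation_range_deg` must be two magnitudes within (0, 180].")
  }
  if (regime == "constant_length") {
    speed_deg_per_s <- trajectory_length_deg / (duration_ms / 1000)
  } else {
    trajectory_length_deg <- speed_deg_per_s * duration_ms / 1000
  }
  if (speed_deg_per_s <= 0) abort("`speed_deg_per_s` must be positive.")
  structure(
    list(n_disks = as.integer(n_disks),
         disk_diameter_deg = disk_diameter_deg,
         speed_deg_per_s = speed_deg_per_s,
         duration_ms = duration_ms,
         regime = regime,
         trajectory_length_deg = trajectory_length_deg,
         deviation_range_deg = rng,
         min_direction_sep_deg = min_direction_sep_deg,
         deviation_convention = deviation_convention),
    class = "segmot_stimulus_spec"
  )
}

#' @export
print.segmot_stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<segmot stimulus spec> %d disk(s), %g deg/s, %g ms, path %g deg, deviations %g-%g deg (%s)\n",
    x$n_disks, x$speed_deg_per_s, x$duration_ms, x$trajectory_length_deg,
    x$deviation_range_deg[1], x$deviation_range_deg[2],
    x$deviation_convention))
  invisible(x)
}

#' Angular subtense of one screen pixel
#'
#' Converts the physical pixel pitch and viewing distance into the exact
#' (arctangent) angular size of one pixel, in minutes of arc, horizontally
#' and vertically, together with their mean.
#'
#' @param display A [display_spec()].
#' @return A one-row tibble with columns `horizontal_arcmin`,
#'   `vertical_arcmin`, `mean_arcmin`.
#' @examples
#' pixel_subtense(display_spec())
#' @export
pixel_subtense <- function(display = display_spec()) {
  stopifnot(inherits(display, "segmot_display"))
  if (display$viewing_distance_cm <= 0) abort("viewing distance must be positive.")
  to_arcmin <- function(size_cm) {
    atan(size_cm / display$viewing_distance_cm) * 180 / pi * 60
  }
  h <- to_arcmin(display$width_cm / display$width_px)
  v <- to_arcmin(display$height_cm / display$height_px)
  tibble::tibble(horizontal_arcmin = h, vertical_arcmin = v,
                 mean_arcmin = (h + v) / 2)
}
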