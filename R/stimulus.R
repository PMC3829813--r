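#' Virtual-cylinder grating stimulus geometry
#'
#' Gratings live on a virtual cylinder centered on the animal's head; the
#' four monitors show the intersection of that cylinder with their planes
#' so the perceived spatial frequency stays constant wherever the animal
#' stands. This module computes the geometry and photometry offline:
#' spatial-frequency bookkeeping, rotation protocols, luminance
#' linearization against a measured calibration curve, and per-monitor
#' rendering.
#'
#' @name stimulus
NULL

#' Spatial frequency to pattern repetitions per cylinder
#'
#' A grating of `sf` cycles per degree of visual angle wraps to
#' `sf * 360` pattern repetitions around the full cylinder.
#'
#' @param sf spatial frequency, cyc/deg (>= 0).
#' @return repetitions per 360 degrees.
#' @examples
#' sf_to_repetitions(0.2)   # 72
#' repetitions_to_sf(216)   # 0.6
#' @export
sf_to_repetitions <- function(sf) {
  if (any(sf < 0)) stop("spatial frequency must be >= 0")
  sf * 360
}

#' @rdname sf_to_repetitions
#' @param n_rep repetitions per 360 degrees.
#' @export
repetitions_to_sf <- function(n_rep) {
  if (any(n_rep < 0)) stop("repetitions must be >= 0")
  n_rep / 360
}

#' Build a linear rotation protocol with direction reversals
#'
#' Triangle-wave cylinder angle: constant speed, direction flipping every
#' `reversal_period_s`. The standard protocol (12 deg/s, reversal every
#' 6 s, 60 s presentation) offers at most ten unidirectional tracking
#' movements of 72 degrees each. `velocity_deg_s = 0` gives the static
#' (null-condition) protocol.
#'
#' @param velocity_deg_s rotation speed (>= 0).
#' @param reversal_period_s time between direction reversals (> 0).
#' @param duration_s total protocol duration (> 0).
#' @param dt_s sample interval (> 0, <= reversal period).
#' @return object of class `rotation_protocol`: data frame with `time_s`,
#'   `stim_angle_deg`, and attributes `velocity_deg_s`,
#'   `reversal_period_s`, `duration_s`, `n_epochs`, `kind`.
#' @export
make_rotation_protocol <- function(velocity_deg_s = 12, reversal_period_s = 6,
                                   duration_s = 60, dt_s = 0.04) {
  if (velocity_deg_s < 0) stop("velocity must be >= 0")
  if (!(reversal_period_s > 0 && duration_s > 0 && dt_s > 0))
    stop("reversal period, duration and dt must be > 0")
  if (dt_s > reversal_period_s) stop("dt must not exceed the reversal period")
  t <- seq(0, duration_s, by = dt_s)
  k <- pmin(floor(t / reversal_period_s), ceiling(duration_s / reversal_period_s) - 1)
  dir <- (-1)^k                       # +1 on the first epoch
  t0 <- k * reversal_period_s
  # angle at the start of epoch k: alternating partial sums
  ang0 <- velocity_deg_s * reversal_period_s * (k %% 2)  # 0, vT, 0, vT, ...
  ang <- ang0 + dir * velocity_deg_s * (t - t0)
  n_ep <- if (velocity_deg_s == 0) 1L else
    as.integer(ceiling(duration_s / reversal_period_s))
  structure(data.frame(time_s = t, stim_angle_deg = ang),
            velocity_deg_s = velocity_deg_s,
            reversal_period_s = reversal_period_s,
            duration_s = duration_s, n_epochs = n_ep,
            kind = "linear-with-reversals",
            class = c("rotation_protocol", "data.frame"))
}

#' Count unidirectional epochs of a protocol
#'
#' @param protocol a rotation protocol data frame.
#' @return number of maximal unidirectional segments (1 for a static
#'   protocol).
#' @export
protocol_epochs <- function(protocol) {
  v <- diff(protocol$stim_angle_deg) / diff(protocol$time_s)
  max(.epoch_ids(v))
}

#' Grating specification
#'
#' @param spatial_freq_cyc_deg spatial frequency in cyc/deg.
#' @param contrast Michelson contrast in [0, 1].
#' @param mean_level mean relative luminance in [0, 1].
#' @param profile `"sinusoidal"` or `"square"`.
#' @return object of class `grating_spec` with the derived
#'   `n_repetitions = spatial_freq_cyc_deg * 360`.
#' @export
grating_spec <- function(spatial_freq_cyc_deg, contrast = 1,
                         mean_level = 0.5,
                         profile = c("sinusoidal", "square")) {
  profile <- match.arg(profile)
  if (spatial_freq_cyc_deg < 0) stop("spatial frequency must be >= 0")
  if (!(contrast >= 0 && contrast <= 1)) stop("contrast must be in [0, 1]")
  if (!(mean_level >= 0 && mean_level <= 1)) stop("mean_level must be in [0, 1]")
  structure(list(spatial_freq_cyc_deg = spatial_freq_cyc_deg,
                 n_repetitions = sf_to_repetitions(spatial_freq_cyc_deg),
                 contrast = contrast, mean_level = mean_level,
                 profile = profile),
            class = "grating_spec")
}

#' Grating luminance at an azimuth
#'
#' Relative luminance of the cylinder texture at a given azimuth about
#' the cylinder axis:
#' `mean + mean * contrast * sin(2 * pi * n_rep * (azimuth + phase) / 360)`,
#' clipped to [0, 1]. The square profile thresholds the sinusoid. With
#' `mean_level = 0.5` the grating spans black to white at contrast 1 and
#' its Michelson contrast equals the `contrast` parameter.
#'
#' @param spec a [grating_spec()].
#' @param azimuth_deg azimuth(s) in degrees.
#' @param phase_deg pattern phase in degrees of azimuth; positive phase
#'   rotates the pattern counterclockwise seen from above.
#' @return relative luminance in [0, 1] (vectorized).
#' @export
grating_luminance <- function(spec, azimuth_deg, phase_deg = 0) {
  stopifnot(inherits(spec, "grating_spec"))
  s <- sin(2 * pi * spec$n_repetitions * (azimuth_deg + phase_deg) / 360)
  if (spec$profile == "square") s <- ifelse(s >= 0, 1, -1)
  pmin(1, pmax(0, spec$mean_level + spec$mean_level * spec$contrast * s))
}

#' Invert a display calibration: relative luminance to command level
#'
#' Finds, for each target relative luminance, the command level whose
#' measured luminance is nearest to
#' `black + target * (white - black)` (monotone interpolation, then
#' rounding to the nearer measured level). Driving the display through
#' this inverse yields a linear luminance staircase from linearly spaced
#' targets.
#'
#' @param curve a calibration curve (data frame `level`, `luminance`,
#'   strictly increasing luminance).
#' @param target_rel_luminance target(s) in [0, 1].
#' @return integer command level(s).
#' @export
linearize <- function(curve, target_rel_luminance) {
  if (!all(c("level", "luminance") %in% names(curve)))
    stop("curve must have columns `level` and `luminance`")
  if (any(diff(curve$luminance) <= 0))
    stop("calibration curve must be strictly increasing")
  if (any(target_rel_luminance < 0 | target_rel_luminance > 1))
    stop("target relative luminance must be in [0, 1]")
  black <- curve$luminance[1]
  white <- curve$luminance[nrow(curve)]
  lum_t <- black + target_rel_luminance * (white - black)
  lo <- findInterval(lum_t, curve$luminance, all.inside = TRUE)
  hi <- lo + 1L
  pick_hi <- abs(curve$luminance[hi] - lum_t) < abs(curve$luminance[lo] - lum_t)
  as.integer(curve$level[ifelse(pick_hi, hi, lo)])
}

#' Render the grating on the four monitors about a head position
#'
#' For every monitor pixel column at world position q, the azimuth about
#' the animal's head is the angle of (q - head), and the pixel takes the
#' grating luminance at that azimuth. Re-centering the cylinder on the
#' head in this way keeps the pattern's angular frequency about the head
#' equal to the specified frequency wherever the animal stands.
#'
#' @param layout a [monitor_layout()].
#' @param head_pos_mm head position (x, y) in mm, origin at box center;
#'   must lie inside the box.
#' @param spec a [grating_spec()].
#' @param phase_deg pattern phase.
#' @param curve optional calibration curve; when given, pixel values are
#'   integer command levels via [linearize()], otherwise relative
#'   luminances in [0, 1].
#' @return list of four matrices (`px_height` x `px_width`), one per
#'   monitor, named as in `layout$walls`.
#' @export
render_stimulus_frame <- function(layout, head_pos_mm = c(0, 0), spec,
                                  phase_deg = 0, curve = NULL) {
  stopifnot(inherits(layout, "monitor_layout"), inherits(spec, "grating_spec"))
  h <- layout$side_mm / 2
  if (any(abs(head_pos_mm) >= h))
    stop("head position lies outside the monitor box")
  lapply(layout$walls, function(wall) {
    az <- atan2(wall[, 2] - head_pos_mm[2],
                wall[, 1] - head_pos_mm[1]) * 180 / pi
    lum <- grating_luminance(spec, az, phase_deg)
    if (!is.null(curve)) lum <- linearize(curve, lum)
    matrix(rep(lum, each = layout$px_height),
           layout$px_height, layout$px_width)
  })
}

#' Count azimuthal grating cycles of a rendered panorama
#'
#' Collects all monitor pixel columns, orders them by azimuth about a
#' head position, and counts upward zero crossings of the luminance
#' about the grating mean (including the wrap-around), i.e. full cycles
#' seen from that head position.
#'
#' @param layout a [monitor_layout()].
#' @param head_pos_mm head position (x, y) in mm.
#' @param spec a [grating_spec()].
#' @param phase_deg pattern phase.
#' @return integer cycle count.
#' @export
panorama_cycles <- function(layout, head_pos_mm = c(0, 0), spec,
                            phase_deg = 0) {
  stopifnot(inherits(layout, "monitor_layout"))
  pts <- do.call(rbind, layout$walls)
  az <- atan2(pts[, 2] - head_pos_mm[2], pts[, 1] - head_pos_mm[1]) * 180 / pi
  ord <- order(az %% 360)
  lum <- grating_luminance(spec, az[ord], phase_deg)
  s <- lum - spec$mean_level
  s <- s[s != 0]
  up <- s <= 0 & c(s[-1], s[1]) > 0
  sum(up)
}

#' Low-pass filter for the cylinder center feedback
#'
#' Trailing moving average over the last `window` samples of the head
#' position (shorter prefixes average what is available). Smoothing the
#' correction movement of the cylinder avoids the looming-like stimulus
#' jumps that startle the animal when the feedback reacts too fast.
#'
#' @param positions numeric vector, matrix or data frame of head
#'   positions over time (rows = samples).
#' @param window window length in frames (default 20).
#' @return smoothed positions, same shape as the input.
#' @export
smooth_center <- function(positions, window = 20) {
  if (window < 1) stop("window must be >= 1")
  vec <- is.null(dim(positions))
  m <- if (vec) matrix(as.numeric(positions), ncol = 1) else as.matrix(positions)
  if (!nrow(m)) stop("empty position series")
  n <- nrow(m)
  out <- m
  for (j in seq_len(ncol(m))) {
    cs <- cumsum(m[, j])
    i <- seq_len(n)
    lag <- pmin(i, window)
    out[, j] <- (cs - c(rep(0, min(window, n)),
                        cs[seq_len(max(0, n - window))])) / lag
  }
  if (vec) out[, 1] else out
}
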