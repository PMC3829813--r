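#' Synthetic data: rendered mouse frames and simulated gaze traces
#'
#' The synthetic module stands in for recordings: it renders overhead
#' frames of a mouse-like silhouette with exactly known pose, and
#' simulates head-angle traces with exactly known tracking epochs, so the
#' tracker and the behavioral analysis can be validated end to end.
#'
#' @name synth
NULL

# Silhouette proportions as fractions of the pose scale (body length unit).
# Chosen so that the nose-to-centroid distance exceeds half the body
# length (keeps the farthest-from-cog nose heuristic in its intended
# regime) and the head mass fits inside the default head disc used by the
# tracker's head-center step.
.SIL <- list(
  body_a     = 14.5 / 60,  # body ellipse semi-major, along heading
  body_b     = 6.0  / 60,  # body ellipse semi-minor
  head_off   = 17.5 / 60,  # head ellipse center offset from body center
  head_a     = 3.5  / 60,
  head_b     = 2.8  / 60,
  snout_base = 20.0 / 60,  # snout triangle base offset
  snout_hw   = 2.5  / 60,  # snout half width at its base
  nose_off   = 24.0 / 60   # snout tip (nose) offset
)

# Gray values of the rendered scene (dark-animal-on-light polarity).
# Fur is two-tone: a dark base plus sparse lighter diagonal speckle, so
# the calibration mean falls strictly between the two tones and a strict
# below-threshold binarization recovers the (8-connected) body.
.TONES <- list(platform = 240, background = 200, fur = 30, speckle = 80,
               speckle_mod = 5L)

#' Mouse pose ground truth
#'
#' @param x_mm,y_mm body-center position in mm relative to the platform
#'   center (x toward +x of the image, y upward as seen from above).
#' @param heading_deg gaze direction in degrees, 0 = +x, counterclockwise
#'   positive, reduced to [0, 360).
#' @param scale_mm body length scale in mm (nose sits 0.4 * scale ahead of
#'   the body center).
#' @return object of class `mouse_pose`.
#' @export
mouse_pose <- function(x_mm = 0, y_mm = 0, heading_deg = 0, scale_mm = 60) {
  stopifnot(is.finite(x_mm), is.finite(y_mm), is.finite(heading_deg),
            scale_mm > 0)
  structure(list(x_mm = x_mm, y_mm = y_mm,
                 heading_deg = heading_deg %% 360,
                 scale_mm = scale_mm),
            class = "mouse_pose")
}

#' Stochastic behavior model for simulated traces
#'
#' @param p_track probability, per unidirectional stimulus epoch, that the
#'   animal tracks the stimulus during that epoch.
#' @param tracking_noise_sd sd (deg/s) of the velocity noise around the
#'   stimulus velocity while tracking.
#' @param idle_velocity_sd scale (deg/s) of the random-walk head velocity
#'   outside tracking epochs; 0 gives a motionless head.
#' @param seed integer seed; all randomness of [simulate_trace()] flows
#'   through it.
#' @return object of class `behavior_model`.
#' @export
behavior_model <- function(p_track = 0.5, tracking_noise_sd = 4,
                           idle_velocity_sd = 6, seed = 1L) {
  if (!(p_track >= 0 && p_track <= 1)) stop("p_track must be in [0, 1]")
  if (tracking_noise_sd < 0 || idle_velocity_sd < 0)
    stop("noise parameters must be >= 0")
  structure(list(p_track = p_track,
                 tracking_noise_sd = tracking_noise_sd,
                 idle_velocity_sd = idle_velocity_sd,
                 seed = as.integer(seed)),
            class = "behavior_model")
}

# silhouette membership test in world mm coordinates (platform origin,
# y up); p is an n x 2 matrix
.in_silhouette <- function(p, pose) {
  L <- pose$scale_mm
  th <- pose$heading_deg * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  dx <- p[, 1] - pose$x_mm; dy <- p[, 2] - pose$y_mm
  a <- dx * u[1] + dy * u[2]   # along heading
  b <- dx * v[1] + dy * v[2]   # across
  s <- .SIL
  body <- (a / (s$body_a * L))^2 + (b / (s$body_b * L))^2 <= 1
  head <- ((a - s$head_off * L) / (s$head_a * L))^2 +
          (b / (s$head_b * L))^2 <= 1
  base <- s$snout_base * L; tip <- s$nose_off * L
  snout <- a >= base & a <= tip &
    abs(b) <= s$snout_hw * L * (tip - a) / (tip - base)
  body | head | snout
}

#' Ground-truth landmarks of a pose, in pixel coordinates
#'
#' Returns where the renderer puts the nose tip and the head-ellipse
#' center, for use as tracking ground truth.
#'
#' @param pose a [mouse_pose()].
#' @param geometry an [arena_geometry()].
#' @return list with `nose_px`, `head_center_px`, `position_px` (x, y in
#'   pixels) and `heading_deg`.
#' @export
pose_landmarks <- function(pose, geometry) {
  stopifnot(inherits(pose, "mouse_pose"), inherits(geometry, "arena_geometry"))
  th <- pose$heading_deg * pi / 180
  u <- c(cos(th), sin(th))
  mm2px <- function(q) c(
    geometry$platform_center[1] + q[1] / geometry$mm_per_px,
    geometry$platform_center[2] - q[2] / geometry$mm_per_px)
  pos <- c(pose$x_mm, pose$y_mm)
  list(nose_px = mm2px(pos + .SIL$nose_off * pose$scale_mm * u),
       head_center_px = mm2px(pos + .SIL$head_off * pose$scale_mm * u),
       position_px = mm2px(pos),
       heading_deg = pose$heading_deg)
}

#' Render an overhead frame of a mouse silhouette
#'
#' Draws the platform disc and a connected silhouette (body ellipse,
#' smaller head ellipse, snout taper) oriented along the pose heading,
#' with the snout tip at the gaze end. The silhouette is the largest dark
#' (or light, for inverted polarity) connected component of the frame and
#' is segmentable by the tracker's calibrate-then-binarize path.
#'
#' @param pose a [mouse_pose()]; its position must lie inside the
#'   reachable region.
#' @param geometry an [arena_geometry()].
#' @param dark_on_light logical; `FALSE` renders the inverted-polarity
#'   scene (light animal on dark platform, for albino animals).
#' @param time_s timestamp stored on the frame.
#' @param rgb logical; return a 3-channel array instead of a matrix.
#' @return an `omr_frame`: list with `px` (numeric array, values 0..255,
#'   indexed `[row, col]`) and `time_s`.
#' @export
render_mouse_frame <- function(pose, geometry, dark_on_light = TRUE,
                               time_s = 0, rgb = FALSE) {
  stopifnot(inherits(pose, "mouse_pose"), inherits(geometry, "arena_geometry"))
  reach_mm <- geometry$reach_radius_px * geometry$mm_per_px
  if (sqrt(pose$x_mm^2 + pose$y_mm^2) > reach_mm)
    stop("pose position lies outside the reachable region")
  H <- geometry$height_px; W <- geometry$width_px
  cx <- geometry$platform_center[1]; cy <- geometry$platform_center[2]
  col <- matrix(rep(seq_len(W), each = H), H, W)
  row <- matrix(rep(seq_len(H), W), H, W)
  # world mm coordinates of pixel centers (y up)
  wx <- (col - cx) * geometry$mm_per_px
  wy <- (cy - row) * geometry$mm_per_px
  r2 <- wx^2 + wy^2
  plat_mm <- geometry$platform_radius_px * geometry$mm_per_px
  img <- matrix(.TONES$background, H, W)
  img[r2 <= plat_mm^2] <- .TONES$platform
  inside <- .in_silhouette(cbind(as.vector(wx), as.vector(wy)), pose)
  fur <- matrix(.TONES$fur, H, W)
  fur[(col + row) %% .TONES$speckle_mod == 0L] <- .TONES$speckle
  img[inside] <- fur[inside]
  if (!dark_on_light) img <- 255 - img
  if (rgb) img <- array(rep(img, 3), dim = c(H, W, 3))
  structure(list(px = img, time_s = time_s), class = "omr_frame")
}

#' @export
print.omr_frame <- function(x, ...) {
  d <- dim(x$px)
  cat(sprintf("omr_frame %d x %d px (%s), t = %.3f s\n", d[1], d[2],
              if (length(d) == 3) "RGB" else "gray", x$time_s))
  invisible(x)
}

#' Write / read numbered PNG frame sequences
#'
#' Frames are written as `frame_000001.png` etc.; timestamps are
#' reconstructed from `fps` on reading.
#'
#' @param frames list of `omr_frame` objects (or plain 0..255 arrays).
#' @param dir directory (created if needed).
#' @param fps nominal frame rate used to reconstruct timestamps.
#' @return `write_frames` returns the file paths invisibly; `read_frames`
#'   returns a list of `omr_frame`s.
#' @export
write_frames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    px <- if (inherits(frames[[i]], "omr_frame")) frames[[i]]$px else frames[[i]]
    paths[i] <- file.path(dir, sprintf("frame_%06d.png", i))
    png::writePNG(px / 255, paths[i])
  }
  invisible(paths)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir, fps = 25) {
  paths <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(paths)) stop("no PNG frames found in ", dir)
  lapply(seq_along(paths), function(i) {
    px <- png::readPNG(paths[i]) * 255
    if (length(dim(px)) == 3 && dim(px)[3] == 4)
      px <- px[, , 1:3]  # drop alpha
    structure(list(px = px, time_s = (i - 1) / fps), class = "omr_frame")
  })
}

#' Simulate a head-angle trace with known tracking epochs
#'
#' The rotation protocol is split into unidirectional epochs (between
#' direction reversals). Each epoch is independently a tracking epoch with
#' probability `p_track`; during tracking epochs the head's angular
#' velocity equals the stimulus velocity plus zero-mean Gaussian noise,
#' elsewhere the head velocity performs a zero-mean Gaussian random walk.
#' All randomness derives from `model$seed`.
#'
#' @param protocol a rotation protocol from [make_rotation_protocol()]
#'   (data frame with `time_s`, `stim_angle_deg`).
#' @param model a [behavior_model()].
#' @param start_angle_deg initial head angle.
#' @return data frame with columns `time_s`, `head_angle_deg`,
#'   `stim_angle_deg`, `srb_truth` (logical, TRUE inside tracking epochs).
#' @export
simulate_trace <- function(protocol, model, start_angle_deg = 0) {
  stopifnot(inherits(model, "behavior_model"))
  if (!is.data.frame(protocol) || nrow(protocol) < 2)
    stop("protocol must have at least 2 samples")
  t <- protocol$time_s; ang <- protocol$stim_angle_deg
  dt <- diff(t)
  v_stim <- diff(ang) / dt                       # velocity on intervals
  epoch <- .epoch_ids(v_stim)
  n_int <- length(v_stim)
  with_seed(model$seed, {
    tracking_epoch <- stats::runif(max(epoch)) < model$p_track
    is_track <- tracking_epoch[epoch]
    # the idle velocity is one continuous random walk over the whole
    # trial (overridden inside tracking epochs), so idle statistics do
    # not depend on how tracking epochs slice the trial
    v_idle <- cumsum(stats::rnorm(n_int, 0,
                                  model$idle_velocity_sd * sqrt(dt)))
    v_head <- ifelse(is_track,
                     v_stim + stats::rnorm(n_int, 0, model$tracking_noise_sd),
                     v_idle)
  })
  head_ang <- (start_angle_deg + cumsum(c(0, v_head * dt))) %% 360
  data.frame(time_s = t,
             head_angle_deg = head_ang,
             stim_angle_deg = ang,
             srb_truth = c(is_track[1], is_track))
}

# epoch ids from interval velocities: a new epoch starts at each sign
# change; zero-velocity protocols form a single epoch
.epoch_ids <- function(v) {
  s <- sign(round(v, 10))
  if (all(s == 0)) return(rep(1L, length(v)))
  chg <- c(FALSE, s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0)
  cumsum(c(TRUE, chg[-1]))
}

#' Synthetic monitor calibration curve
#'
#' Gamma-law luminance table emulating a measured display response:
#' `luminance(level) = black + (white - black) * (level / (n_levels - 1)) ^ gamma`.
#'
#' @param gamma display gamma (> 0).
#' @param black_cdm2,white_cdm2 luminance at the lowest/highest command
#'   level, cd/m2; `white > black >= 0`.
#' @param n_levels number of command levels (>= 2; default 256 for 8-bit).
#' @return object of class `calibration_curve`: data frame with columns
#'   `level` (0-based) and `luminance`, strictly increasing.
#' @export
synth_calibration <- function(gamma = 2.2, black_cdm2 = 0.22,
                              white_cdm2 = 152.13, n_levels = 256L) {
  if (!(gamma > 0)) stop("gamma must be > 0")
  if (!(white_cdm2 > black_cdm2 && black_cdm2 >= 0))
    stop("need white > black >= 0")
  if (n_levels < 2) stop("n_levels must be >= 2")
  lev <- seq_len(n_levels) - 1L
  lum <- black_cdm2 + (white_cdm2 - black_cdm2) *
    (lev / (n_levels - 1))^gamma
  structure(data.frame(level = lev, luminance = lum),
            class = c("calibration_curve", "data.frame"))
}
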