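#' Markerless head-gaze tracking
#'
#' Five-step pipeline per frame: binarize against a calibrated color
#' threshold within the reachable disc, keep the largest 8-connected
#' component, weight its coordinates radially, take the weighted center
#' of gravity, find the nose as the weighted coordinate farthest from it,
#' average the mask inside a disc around the nose to get the head center,
#' and read the gaze off the head-center-to-nose vector.
#'
#' @name tracker
NULL

# frame -> numeric array H x W x C with values 0..255
.frame_px <- function(frame) {
  px <- if (inherits(frame, "omr_frame")) frame$px else frame
  if (is.matrix(px)) px <- array(px, dim = c(dim(px), 1L))
  if (length(dim(px)) != 3) stop("frame must be a matrix or H x W x C array")
  px
}

#' Color threshold for fur segmentation
#'
#' @param value per-channel threshold, each component in [0, 255]
#'   (3 values for RGB, 1 for grayscale).
#' @param polarity `"dark_on_light"` (dark fur, light platform) or
#'   `"light_on_dark"` (albino animals on a dark platform).
#' @return object of class `color_threshold`.
#' @export
color_threshold <- function(value, polarity = c("dark_on_light",
                                                "light_on_dark")) {
  polarity <- match.arg(polarity)
  if (any(value < 0 | value > 255)) stop("threshold components must be in [0, 255]")
  structure(list(value = as.numeric(value), polarity = polarity),
            class = "color_threshold")
}

#' Calibrate the segmentation threshold from the first frames
#'
#' Pools the platform-region pixels of the given frames (normally the
#' first ten of a recording), keeps those whose every channel is below
#' `cutoff` (above `255 - cutoff` for inverted polarity) -- in a lit
#' arena these are the animal's fur pixels -- and returns their
#' per-channel mean as the threshold.
#'
#' @param frames list of frames (the first ten of the recording).
#' @param geometry an [arena_geometry()].
#' @param cutoff channel cutoff selecting candidate fur pixels
#'   (default 100).
#' @param polarity see [color_threshold()].
#' @return a [color_threshold()]. If no platform pixel qualifies, the
#'   threshold falls back to `cutoff` with a warning.
#' @export
calibrate_threshold <- function(frames, geometry, cutoff = 100,
                                polarity = c("dark_on_light",
                                             "light_on_dark")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(geometry, "arena_geometry"))
  if (!length(frames)) stop("need at least one frame")
  if (inherits(frames, "omr_frame") || is.numeric(frames)) frames <- list(frames)
  acc <- NULL
  for (f in frames) {
    px <- .frame_px(f)
    H <- dim(px)[1]; W <- dim(px)[2]; C <- dim(px)[3]
    col <- rep(seq_len(W), each = H); row <- rep(seq_len(H), W)
    on_platform <- (col - geometry$platform_center[1])^2 +
      (row - geometry$platform_center[2])^2 <= geometry$platform_radius_px^2
    if (!any(on_platform)) stop("platform region is empty in the frame")
    chan <- matrix(px, H * W, C)[on_platform, , drop = FALSE]
    keep <- if (polarity == "dark_on_light")
      rowSums(chan < cutoff) == C else rowSums(chan > 255 - cutoff) == C
    acc <- rbind(acc, chan[keep, , drop = FALSE])
  }
  if (is.null(acc) || nrow(acc) == 0) {
    warning("no platform pixel passed the calibration cutoff; ",
            "falling back to threshold = cutoff")
    val <- rep(if (polarity == "dark_on_light") cutoff else 255 - cutoff,
               dim(.frame_px(frames[[1]]))[3])
  } else {
    val <- colMeans(acc)
  }
  color_threshold(val, polarity)
}

# 8-connected component labels of a logical matrix, via vectorized
# frontier expansion; returns an integer matrix (0 = background)
.label_components <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  todo <- which(bin)
  if (!length(todo)) return(lab)
  remaining <- bin
  next_lab <- 0L
  offs <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
  row_of <- function(idx) ((idx - 1L) %% H) + 1L
  repeat {
    seeds <- which(remaining)
    if (!length(seeds)) break
    next_lab <- next_lab + 1L
    frontier <- seeds[1]
    remaining[frontier] <- FALSE
    lab[frontier] <- next_lab
    while (length(frontier)) {
      r <- row_of(frontier)
      nb <- c(frontier[r > 1L] - 1L, frontier[r < H] + 1L,
              frontier - H, frontier + H,
              frontier[r > 1L] - H - 1L, frontier[r > 1L] + H - 1L,
              frontier[r < H] - H + 1L, frontier[r < H] + H + 1L)
      nb <- unique(nb[nb >= 1L & nb <= H * W])
      nb <- nb[remaining[nb]]
      remaining[nb] <- FALSE
      lab[nb] <- next_lab
      frontier <- nb
    }
  }
  lab
}

#' Segment the animal's body from a frame
#'
#' Discards everything outside the reachable disc, binarizes against the
#' calibrated threshold (strictly below every channel threshold for
#' dark-on-light polarity, strictly above for the inverse), labels
#' 8-connected components and keeps only the largest.
#'
#' @param frame a frame (matrix, array, or `omr_frame`).
#' @param threshold a [color_threshold()].
#' @param geometry an [arena_geometry()].
#' @return object of class `body_mask`: list with `coords` (n x 2 matrix
#'   of pixel x, y), `dim` (frame H, W) and `valid`. An empty mask has
#'   `valid = FALSE`.
#' @export
segment_body <- function(frame, threshold, geometry) {
  stopifnot(inherits(threshold, "color_threshold"),
            inherits(geometry, "arena_geometry"))
  px <- .frame_px(frame)
  H <- dim(px)[1]; W <- dim(px)[2]; C <- dim(px)[3]
  if (length(threshold$value) == 1 && C > 1)
    threshold$value <- rep(threshold$value, C)
  if (length(threshold$value) != C)
    stop("threshold has ", length(threshold$value),
         " components but frame has ", C, " channels")
  fg <- matrix(TRUE, H, W)
  for (k in seq_len(C)) {
    fg <- fg & (if (threshold$polarity == "dark_on_light")
      px[, , k] < threshold$value[k] else px[, , k] > threshold$value[k])
  }
  col <- matrix(rep(seq_len(W), each = H), H, W)
  row <- matrix(rep(seq_len(H), W), H, W)
  inside <- (col - geometry$platform_center[1])^2 +
    (row - geometry$platform_center[2])^2 <= geometry$reach_radius_px^2
  fg <- fg & inside
  if (!any(fg))
    return(structure(list(coords = matrix(numeric(0), 0, 2),
                          dim = c(H, W), valid = FALSE),
                     class = "body_mask"))
  lab <- .label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))[1]  # tie -> first label (determinism)
  idx <- which(lab == best)
  structure(list(coords = cbind(x = col[idx], y = row[idx]),
                 dim = c(H, W), valid = TRUE),
            class = "body_mask")
}

#' Radial coordinate weighting
#'
#' Weights each body pixel with a linear radial ramp: 1 at the platform
#' center, falling to 0 at the border of the reachable disc. The weighting
#' biases the center of gravity toward the platform center (in practice
#' the animal's hindquarters) so that the farthest-weighted-coordinate
#' nose heuristic works over the whole platform.
#'
#' @param mask a [segment_body()] result.
#' @param geometry an [arena_geometry()].
#' @return list with `coords` (n x 2) and `w` (weights in [0, 1]).
#' @export
weight_coordinates <- function(mask, geometry) {
  stopifnot(inherits(mask, "body_mask"), inherits(geometry, "arena_geometry"))
  if (!mask$valid || nrow(mask$coords) == 0) stop("mask is empty")
  d <- sqrt((mask$coords[, 1] - geometry$platform_center[1])^2 +
            (mask$coords[, 2] - geometry$platform_center[2])^2)
  list(coords = mask$coords,
       w = pmax(0, 1 - d / geometry$reach_radius_px))
}

#' Weighted body center of gravity
#'
#' @param weighted result of [weight_coordinates()].
#' @return numeric length-2 point (x, y) in pixels.
#' @export
body_cog <- function(weighted) {
  tw <- sum(weighted$w)
  if (tw <= 0) stop("total weight is zero; cannot compute center of gravity")
  c(sum(weighted$w * weighted$coords[, 1]),
    sum(weighted$w * weighted$coords[, 2])) / tw
}

#' Locate the nose as the coordinate farthest from the weighted cog
#'
#' Maximizes `||p - cog||` over the weighted coordinate set. Because the
#' radial weighting pulls the center of gravity toward the platform
#' center (and into the hindquarters), the farthest coordinate is the
#' nose for any body orientation: a pixel is the more likely nose
#' candidate the farther it lies from the platform center. Ties are
#' broken by lexicographic (x, y) order, so the result is deterministic.
#'
#' @param weighted result of [weight_coordinates()].
#' @param cog the weighted center of gravity from [body_cog()].
#' @return numeric length-2 point (x, y) in pixels.
#' @export
locate_nose <- function(weighted, cog) {
  p <- weighted$coords
  if (!nrow(p)) stop("empty coordinate set")
  d <- sqrt((p[, 1] - cog[1])^2 + (p[, 2] - cog[2])^2)
  best <- which(d == max(d))
  if (length(best) > 1)
    best <- best[order(p[best, 1], p[best, 2])[1]]
  as.numeric(p[best[1], ])
}

#' Head center as the mask centroid near the nose
#'
#' Unweighted centroid of the body-mask pixels inside a disc around the
#' nose; by the head's bilateral symmetry this lands on the sagittal axis
#' of the skull, between the ears.
#'
#' @param mask a [segment_body()] result.
#' @param nose the nose point from [locate_nose()].
#' @param head_radius_px disc radius in pixels (default: 10 mm at the
#'   geometry's scale, set by the caller).
#' @return numeric length-2 point (x, y) in pixels.
#' @export
locate_head_center <- function(mask, nose, head_radius_px) {
  stopifnot(inherits(mask, "body_mask"))
  p <- mask$coords
  keep <- (p[, 1] - nose[1])^2 + (p[, 2] - nose[2])^2 <= head_radius_px^2
  if (!any(keep)) stop("no mask pixel within the head disc around the nose")
  c(mean(p[keep, 1]), mean(p[keep, 2]))
}

#' Gaze angle from head center and nose
#'
#' Angle of the vector from the head center to the nose, in degrees in
#' [0, 360), 0 along +x and counterclockwise positive as seen from above
#' (image rows increase downward, which the sign convention accounts
#' for).
#'
#' @param head_center,nose points (x, y) in pixels.
#' @return gaze angle in degrees.
#' @export
compute_gaze <- function(head_center, nose) {
  dx <- nose[1] - head_center[1]
  dy <- nose[2] - head_center[2]
  if (dx == 0 && dy == 0) stop("nose and head center coincide")
  (atan2(-dy, dx) * 180 / pi) %% 360
}

#' Track a frame sequence
#'
#' Calibrates the threshold on the first ten frames (unless one is
#' supplied), then runs the per-frame gaze pipeline. Frames that fail any
#' step are flagged invalid and kept in the output.
#'
#' @param frames list of frames (`omr_frame`s or arrays) or a directory
#'   of numbered PNG files.
#' @param geometry an [arena_geometry()].
#' @param fps frame rate used for timestamps when frames carry none.
#' @param cutoff calibration cutoff (see [calibrate_threshold()]).
#' @param polarity see [color_threshold()].
#' @param head_radius_px head-disc radius; default 10 mm at the
#'   geometry's scale.
#' @param threshold optional externally calibrated [color_threshold()];
#'   when supplied, fewer than 11 frames are accepted.
#' @return object of class `gaze_trace`: a data frame with one row per
#'   frame and columns `time_s`, `cog_x`, `cog_y`, `nose_x`, `nose_y`,
#'   `head_x`, `head_y`, `gaze_deg`, `valid`.
#' @export
track_sequence <- function(frames, geometry, fps = 25, cutoff = 100,
                           polarity = c("dark_on_light", "light_on_dark"),
                           head_radius_px = 10 / geometry$mm_per_px,
                           threshold = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(geometry, "arena_geometry"))
  if (is.character(frames)) frames <- read_frames(frames, fps = fps)
  n <- length(frames)
  if (is.null(threshold)) {
    if (n < 11)
      stop("need at least 11 frames to calibrate, or supply `threshold`")
    threshold <- calibrate_threshold(frames[seq_len(min(10, n))], geometry,
                                     cutoff = cutoff, polarity = polarity)
  }
  out <- data.frame(time_s = numeric(n), cog_x = NA_real_, cog_y = NA_real_,
                    nose_x = NA_real_, nose_y = NA_real_,
                    head_x = NA_real_, head_y = NA_real_,
                    gaze_deg = NA_real_, valid = FALSE)
  for (i in seq_len(n)) {
    f <- frames[[i]]
    out$time_s[i] <- if (inherits(f, "omr_frame") && !is.null(f$time_s))
      f$time_s else (i - 1) / fps
    sample_i <- tryCatch({
      mask <- segment_body(f, threshold, geometry)
      if (!mask$valid) stop("empty mask")
      wts <- weight_coordinates(mask, geometry)
      cog <- body_cog(wts)
      nose <- locate_nose(wts, cog)
      head <- locate_head_center(mask, nose, head_radius_px)
      list(cog = cog, nose = nose, head = head,
           gaze = compute_gaze(head, nose))
    }, error = function(e) NULL)
    if (!is.null(sample_i)) {
      out[i, c("cog_x", "cog_y")] <- sample_i$cog
      out[i, c("nose_x", "nose_y")] <- sample_i$nose
      out[i, c("head_x", "head_y")] <- sample_i$head
      out$gaze_deg[i] <- sample_i$gaze
      out$valid[i] <- TRUE
    }
  }
  attr(out, "threshold") <- threshold
  attr(out, "fps") <- fps
  class(out) <- c("gaze_trace", "data.frame")
  out
}
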