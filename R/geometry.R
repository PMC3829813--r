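#' Arena geometry for overhead tracking
#'
#' Describes the overhead camera's view of the elevated circular platform:
#' where the platform sits in the image, how far the animal can reach its
#' nose beyond the platform edge, and the pixel scale. All tracking
#' operations are restricted to the reachable disc; coordinate weighting
#' ramps from 1 at the platform center to 0 at the reachable border.
#'
#' Pixel coordinates are `(x, y)` with `x` the column and `y` the row of
#' the image, `y` increasing downward. Angles returned by the tracker are
#' degrees counterclockwise (as seen from above, with the usual
#' mathematical orientation), 0 degrees pointing along +x.
#'
#' @param platform_center numeric length-2, platform center in pixels (x, y).
#' @param platform_radius_px platform radius in pixels (> 0).
#' @param reach_radius_px radius of the circular region the mouse can reach
#'   with its nose, in pixels; must exceed `platform_radius_px`.
#' @param mm_per_px physical scale of the image (> 0).
#' @param width_px,height_px frame dimensions used by the synthetic renderer.
#' @return An object of class `arena_geometry`.
#' @examples
#' geo <- arena_geometry()
#' geo$reach_radius_px * geo$mm_per_px  # reachable radius in mm
#' @export
arena_geometry <- function(platform_center = c(200, 200),
                           platform_radius_px = 53,
                           reach_radius_px = 160,
                           mm_per_px = 0.5,
                           width_px = 400,
                           height_px = 400) {
  stopifnot(length(platform_center) == 2, is.finite(platform_center))
  if (!(is.numeric(mm_per_px) && mm_per_px > 0))
    stop("mm_per_px must be > 0")
  if (!(platform_radius_px > 0))
    stop("platform_radius_px must be > 0")
  if (!(reach_radius_px > platform_radius_px))
    stop("reach_radius_px must exceed platform_radius_px")
  structure(list(
    platform_center = as.numeric(platform_center),
    platform_radius_px = as.numeric(platform_radius_px),
    reach_radius_px = as.numeric(reach_radius_px),
    mm_per_px = as.numeric(mm_per_px),
    width_px = as.integer(width_px),
    height_px = as.integer(height_px)
  ), class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("Arena geometry:\n")
  cat(sprintf("  platform center  (%.1f, %.1f) px\n",
              x$platform_center[1], x$platform_center[2]))
  cat(sprintf("  platform radius  %.1f px (%.1f mm)\n",
              x$platform_radius_px, x$platform_radius_px * x$mm_per_px))
  cat(sprintf("  reach radius     %.1f px (%.1f mm)\n",
              x$reach_radius_px, x$reach_radius_px * x$mm_per_px))
  cat(sprintf("  scale            %.3f mm/px, frame %d x %d px\n",
              x$mm_per_px, x$width_px, x$height_px))
  invisible(x)
}

#' Read/write arena geometry as YAML
#'
#' @param path file path.
#' @rdname arena_geometry_io
#' @return `read_geometry` returns an `arena_geometry`; `write_geometry`
#'   returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("platform_center", "platform_radius_px", "reach_radius_px",
            "mm_per_px")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("geometry config missing fields: ",
                         paste(miss, collapse = ", "))
  arena_geometry(platform_center = unlist(y$platform_center),
                 platform_radius_px = y$platform_radius_px,
                 reach_radius_px = y$reach_radius_px,
                 mm_per_px = y$mm_per_px,
                 width_px = y$width_px %||% 400,
                 height_px = y$height_px %||% 400)
}

#' @param geometry an `arena_geometry`.
#' @rdname arena_geometry_io
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "arena_geometry"))
  yaml::write_yaml(unclass(geometry), path)
  invisible(path)
}

#' Four-monitor box layout around the platform
#'
#' The stimulation box is a square of four vertically mounted displays
#' surrounding the platform. Only the horizontal geometry matters for a
#' cylinder with vertical gratings, so each monitor is described by the
#' world (x, y) positions of its pixel columns, in mm, with the origin at
#' the center of the box. Monitors are ordered so that walking along
#' columns 1..4*px_width sweeps the panorama counterclockwise.
#'
#' @param side_mm inner side length of the square box (default 690 mm).
#' @param height_mm monitor height in mm (kept for completeness; vertical
#'   position does not enter the azimuth of a vertical grating).
#' @param px_width number of pixel columns rendered per monitor.
#' @param px_height number of pixel rows rendered per monitor.
#' @return An object of class `monitor_layout` with a `walls` element:
#'   a list of four matrices (px_width x 2) of world coordinates in mm.
#' @export
monitor_layout <- function(side_mm = 690, height_mm = 354,
                           px_width = 480, px_height = 8) {
  stopifnot(side_mm > 0, px_width >= 2, px_height >= 1)
  h <- side_mm / 2
  s <- side_mm * (seq_len(px_width) - 0.5) / px_width - h  # pixel centers
  walls <- list(
    east  = cbind(x = rep(h, px_width),  y = s),           # x=+h, y up
    north = cbind(x = -s,                y = rep(h, px_width)),
    west  = cbind(x = rep(-h, px_width), y = -s),
    south = cbind(x = s,                 y = rep(-h, px_width))
  )
  structure(list(side_mm = side_mm, height_mm = height_mm,
                 px_width = as.integer(px_width),
                 px_height = as.integer(px_height),
                 walls = walls),
            class = "monitor_layout")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a private, restorable RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}
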