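# Shared fixtures and independent brute-force oracles.

# default rendering geometry (platform 53 px radius ~ 53 mm diameter at
# 0.5 mm/px, reach 80 mm)
test_geometry <- function() arena_geometry()

# small geometry for hand-built segmentation fixtures
tiny_geometry <- function() {
  arena_geometry(platform_center = c(25, 25), platform_radius_px = 8,
                 reach_radius_px = 20, mm_per_px = 1,
                 width_px = 50, height_px = 50)
}

# independent 8-connected labeling oracle: stack-based flood fill over
# explicit (row, col) pairs
brute_label8 <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (!bin[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            bin[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# brute-force nose search: plain loop maximizing distance from the cog,
# with the documented lexicographic tie-break
brute_nose <- function(coords, w, cog) {
  best <- NULL; best_d <- -Inf
  for (i in seq_len(nrow(coords))) {
    d <- sqrt(sum((coords[i, ] - cog)^2))
    better <- d > best_d ||
      (d == best_d &&
         (coords[i, 1] < best[1] ||
            (coords[i, 1] == best[1] && coords[i, 2] < best[2])))
    if (better) { best <- as.numeric(coords[i, ]); best_d <- d }
  }
  best
}

# brute-force per-frame SRB check
brute_srb <- function(v_head, v_stim, lambda) {
  out <- logical(length(v_head))
  for (i in seq_along(v_head)) {
    if (is.na(v_head[i]) || is.na(v_stim[i])) { out[i] <- NA; next }
    out[i] <- abs(v_head[i] - v_stim[i]) < lambda
  }
  out
}

# brute-force median-of-medians chance level
brute_chance <- function(per_animal) {
  meds <- numeric(length(per_animal))
  for (i in seq_along(per_animal)) meds[i] <- median(per_animal[[i]])
  median(meds)
}

# shortest angular distance in degrees
ang_err <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# binary silhouette mask (TRUE = fur) of a rendered dark-on-light frame
frame_fur_mask <- function(frame, base_tone = 30) {
  abs(frame$px - base_tone) < 1e-9
}
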