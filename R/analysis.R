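#' Automated quantification of optomotor tracking
#'
#' Head and stimulus angle traces are differentiated to angular
#' velocities; a frame counts as stimulus-related behavior (SRB) when the
#' signed head velocity differs from the stimulus velocity by less than a
#' discrimination parameter lambda. The fraction of SRB frames per trial
#' (T_track), corrected by a chance level estimated from null-condition
#' recordings, gives the per-frequency response; a robust logistic fit to
#' the descending branch of the response curve yields the visual-acuity
#' threshold at its inflection point.
#'
#' @name analysis
NULL

#' Angular velocity of an angle trace
#'
#' Finite differences with shortest-arc wrap handling: an angle step is
#' mapped into (-180, 180] degrees before dividing by the time step, so a
#' 359 -> 1 degree transition reads as +2 degrees, not -358. Velocities
#' are assigned to the later sample; missing (invalid) angles propagate
#' as `NA`.
#'
#' @param angle_deg angle series in degrees (NA allowed).
#' @param time_s strictly increasing sample times.
#' @return data frame with `time_s` (one shorter than the input) and
#'   `velocity_deg_s`.
#' @export
angular_velocity <- function(angle_deg, time_s) {
  if (length(angle_deg) != length(time_s)) stop("length mismatch")
  if (length(angle_deg) < 2)
    return(data.frame(time_s = numeric(0), velocity_deg_s = numeric(0)))
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  d <- diff(angle_deg)
  d <- ((d + 180) %% 360) - 180
  data.frame(time_s = time_s[-1], velocity_deg_s = d / diff(time_s))
}

#' Aligned head and stimulus velocity series
#'
#' @param head_angle_deg,stim_angle_deg angle traces on the same timebase.
#' @param time_s sample times.
#' @return object of class `velocity_series`: data frame `time_s`,
#'   `v_head`, `v_stim`.
#' @export
velocity_series <- function(head_angle_deg, stim_angle_deg, time_s) {
  vh <- angular_velocity(head_angle_deg, time_s)
  vs <- angular_velocity(stim_angle_deg, time_s)
  structure(data.frame(time_s = vh$time_s, v_head = vh$velocity_deg_s,
                       v_stim = vs$velocity_deg_s),
            class = c("velocity_series", "data.frame"))
}

#' Detect stimulus-related behavior
#'
#' A frame is SRB iff `|v_head - v_stim| < lambda` (strict), with signed
#' velocities so that only movement in the stimulus direction qualifies:
#' at the standard 12 deg/s stimulus and lambda = 9 deg/s the accepted
#' band is head velocities in (3, 21) deg/s in the stimulus direction.
#' Missing samples are excluded from both numerator and denominator of
#' the tracked fraction.
#'
#' @param v a [velocity_series()] (or data frame with `v_head`, `v_stim`).
#' @param lambda_deg_s discrimination parameter (> 0), default 9.
#' @return object of class `srb_result`: list with `srb` (logical per
#'   frame, `NA` where a velocity is missing), `lambda_deg_s`, `t_track`
#'   (SRB frames / evaluable frames) and `n` (evaluable frames).
#' @export
detect_srb <- function(v, lambda_deg_s = 9) {
  if (!(lambda_deg_s > 0)) stop("lambda must be > 0")
  if (!all(c("v_head", "v_stim") %in% names(v)))
    stop("v must have columns v_head and v_stim")
  srb <- abs(v$v_head - v$v_stim) < lambda_deg_s
  n <- sum(!is.na(srb))
  structure(list(srb = srb, lambda_deg_s = lambda_deg_s,
                 t_track = if (n > 0) sum(srb, na.rm = TRUE) / n else NA_real_,
                 n = n),
            class = "srb_result")
}

#' Tracked fraction of a trace against a stimulus profile
#'
#' Convenience wrapper: differentiate both traces and score SRB. The
#' stimulus angles may come from a different (reference) protocol than
#' the one shown, which is how null-condition recordings are scored
#' against the standard moving profile.
#'
#' @inheritParams velocity_series
#' @inheritParams detect_srb
#' @return the tracked fraction `t_track` in [0, 1].
#' @export
trace_t_track <- function(head_angle_deg, stim_angle_deg, time_s,
                          lambda_deg_s = 9) {
  detect_srb(velocity_series(head_angle_deg, stim_angle_deg, time_s),
             lambda_deg_s)$t_track
}

#' Chance level from null-condition trials
#'
#' For each animal, the median tracked fraction over its null trials
#' (head recorded under a static pattern, scored against the standard
#' moving-velocity profile); the chance level is the median of those
#' per-animal medians.
#'
#' @param null_t_track list (one element per animal) of numeric vectors
#'   of per-trial tracked fractions under the null condition.
#' @return chance level in [0, 1].
#' @export
chance_level <- function(null_t_track) {
  if (!length(null_t_track)) stop("need at least one animal with null trials")
  if (is.numeric(null_t_track)) null_t_track <- list(null_t_track)
  if (any(!vapply(null_t_track, length, 1L))) stop("empty null-trial vector")
  stats::median(vapply(null_t_track, stats::median, numeric(1)))
}

#' Chance-corrected, normalized response curve
#'
#' Subtracts the chance level from every tracked fraction, takes
#' per-animal medians for each spatial frequency, then the population
#' median of the per-animal medians, and normalizes so that the
#' population median at the optimal frequency equals one. Negative
#' chance-corrected values are preserved unless `clip` is set.
#'
#' @param trials data frame with columns `animal_id`,
#'   `spatial_freq_cyc_deg`, `t_track` (one row per trial).
#' @param chance chance level to subtract (default 0).
#' @param optimal_freq frequency whose population median anchors the
#'   normalization (default 0.2 cyc/deg; `"auto"` picks the frequency
#'   with the largest population median).
#' @param clip clip negative corrected values to 0 (default FALSE).
#' @return object of class `response_curve`: data frame with
#'   `spatial_freq_cyc_deg`, `median_corrected`, `normalized`; attributes
#'   `chance`, `optimal_freq`, `norm_value`, `per_animal` (matrix of
#'   per-animal medians, animals x frequencies).
#' @export
build_response_curve <- function(trials, chance = 0, optimal_freq = 0.2,
                                 clip = FALSE) {
  need <- c("animal_id", "spatial_freq_cyc_deg", "t_track")
  if (!all(need %in% names(trials)))
    stop("trials must have columns ", paste(need, collapse = ", "))
  x <- trials
  x$t_track <- x$t_track - chance
  if (clip) x$t_track <- pmax(0, x$t_track)
  freqs <- sort(unique(x$spatial_freq_cyc_deg))
  animals <- unique(x$animal_id)
  per_animal <- matrix(NA_real_, length(animals), length(freqs),
                       dimnames = list(as.character(animals),
                                       as.character(freqs)))
  for (a in seq_along(animals)) for (f in seq_along(freqs)) {
    v <- x$t_track[x$animal_id == animals[a] &
                   x$spatial_freq_cyc_deg == freqs[f]]
    if (length(v)) per_animal[a, f] <- stats::median(v)
  }
  if (anyNA(per_animal))
    stop("every animal needs at least one trial per frequency")
  pop <- apply(per_animal, 2, stats::median)
  if (identical(optimal_freq, "auto")) optimal_freq <- freqs[which.max(pop)]
  if (!optimal_freq %in% freqs)
    stop("optimal_freq ", optimal_freq, " not among the tested frequencies")
  norm_value <- pop[as.character(optimal_freq)]
  if (!is.finite(norm_value) || norm_value <= 0)
    stop("population median at the optimal frequency is not positive; ",
         "cannot normalize")
  structure(data.frame(spatial_freq_cyc_deg = freqs,
                       median_corrected = unname(pop),
                       normalized = unname(pop / norm_value)),
            chance = chance, optimal_freq = optimal_freq,
            norm_value = unname(norm_value), per_animal = per_animal,
            class = c("response_curve", "data.frame"))
}

# sum of absolute residuals of the logistic a / (1 + exp((f - b) / c))
.lad_objective <- function(par, freq, y) {
  c_ <- par[3]
  if (abs(c_) < 1e-8) return(.Machine$double.xmax)
  r <- y - par[1] / (1 + exp((freq - par[2]) / c_))
  sum(abs(r))
}

.logistic_pred <- function(par, f) par[1] / (1 + exp((f - par[2]) / par[3]))

#' Fit a logistic function to the descending response branch
#'
#' Fits `R(f) = a / (1 + exp((f - b) / c))` to the responses at spatial
#' frequencies above `fit_above_cyc_deg`, minimizing the sum of absolute
#' residuals (robust to outlying medians). `a` is the response maximum,
#' `b` the inflection point (half-maximum frequency), and `c > 0` the
#' steepness of the descending slope. Optimization is Nelder-Mead with
#' multiple starts of `b` spread over the fitted frequency range; 95%
#' prediction bounds come from a residual bootstrap.
#'
#' @param curve a [build_response_curve()] result, or a data frame with
#'   columns `spatial_freq_cyc_deg` and `response`.
#' @param fit_above_cyc_deg only frequencies strictly above this value
#'   enter the fit (default 0.2).
#' @param response which column of a `response_curve` to fit
#'   (`"normalized"` or `"median_corrected"`).
#' @param n_starts number of multi-start initializations over `b`.
#' @param n_boot residual-bootstrap replicates for the prediction bounds
#'   (0 disables bounds).
#' @param seed seed for the bootstrap.
#' @return object of class `acuity_fit`: coefficients `a`, `b`, `c`, the
#'   fitted data, residuals, the sum of absolute residuals, a
#'   convergence/degeneracy flag, and (if bootstrapped) a `bounds` data
#'   frame with 95% prediction bounds on a frequency grid.
#' @export
fit_logistic <- function(curve, fit_above_cyc_deg = 0.2,
                         response = c("normalized", "median_corrected"),
                         n_starts = 5, n_boot = 1000, seed = 1L) {
  response <- match.arg(response)
  if (inherits(curve, "response_curve")) {
    f <- curve$spatial_freq_cyc_deg
    y <- curve[[response]]
  } else {
    if (!all(c("spatial_freq_cyc_deg", "response") %in% names(curve)))
      stop("curve must be a response_curve or have columns ",
           "spatial_freq_cyc_deg and response")
    f <- curve$spatial_freq_cyc_deg
    y <- curve$response
  }
  keep <- f > fit_above_cyc_deg & is.finite(y)
  f <- f[keep]; y <- y[keep]
  if (length(f) < 3)
    stop("need at least 3 frequencies above the fitting cutoff")
  degenerate <- diff(range(y)) < sqrt(.Machine$double.eps)
  a0 <- max(y)
  if (a0 <= 0) a0 <- 1
  c0 <- diff(range(f)) / 10
  b_grid <- seq(min(f), max(f), length.out = n_starts)
  best <- NULL
  for (b0 in b_grid) {
    for (cc in c(c0, c0 / 4)) {
      opt <- stats::optim(c(a0, b0, cc), .lad_objective, freq = f, y = y,
                          method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12))
      # polish from the incumbent
      opt <- stats::optim(opt$par, .lad_objective, freq = f, y = y,
                          method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  par <- best$par
  fitted <- .logistic_pred(par, f)
  resid <- y - fitted
  fit <- structure(list(
    coefficients = c(a = par[1], b = par[2], c = par[3]),
    data = data.frame(spatial_freq_cyc_deg = f, response = y),
    fitted = fitted, residuals = resid,
    objective = best$value,
    # Nelder-Mead reports code 10 (simplex degeneracy) at the kinked
    # optimum of an absolute-residual objective; that is a valid solution
    converged = best$convergence %in% c(0L, 10L) && !degenerate,
    degenerate = degenerate,
    fit_above_cyc_deg = fit_above_cyc_deg,
    bounds = NULL), class = "acuity_fit")
  if (degenerate)
    warning("responses are constant over the fitted range; ",
            "fit flagged degenerate")
  if (n_boot > 0 && !degenerate) {
    grid <- seq(min(f), max(f), length.out = 60)
    with_seed(seed, {
      preds <- matrix(NA_real_, n_boot, length(grid))
      for (bidx in seq_len(n_boot)) {
        yb <- fitted + sample(resid, length(resid), replace = TRUE)
        ob <- stats::optim(par, .lad_objective, freq = f, y = yb,
                           method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-10))
        preds[bidx, ] <- .logistic_pred(ob$par, grid) +
          sample(resid, 1)  # new-measurement noise
      }
      fit$bounds <- data.frame(
        spatial_freq_cyc_deg = grid,
        lower = apply(preds, 2, stats::quantile, 0.025),
        upper = apply(preds, 2, stats::quantile, 0.975))
    })
  }
  fit
}

#' Visual acuity from a logistic fit
#'
#' Solves `R(f) = criterion_fraction * a` for the spatial frequency `f`.
#' The default criterion 0.5 gives the inflection point, i.e. exactly
#' `b`; a criterion q gives `b + c * log((1 - q) / q)` (e.g. 25% of the
#' maximum response lies at `b + c * log(3)`).
#'
#' @param fit an [fit_logistic()] result.
#' @param criterion_fraction response criterion in (0, 1).
#' @return threshold spatial frequency in cyc/deg.
#' @export
visual_acuity <- function(fit, criterion_fraction = 0.5) {
  stopifnot(inherits(fit, "acuity_fit"))
  if (!fit$converged) stop("fit did not converge (or is degenerate)")
  if (!(criterion_fraction > 0 && criterion_fraction < 1))
    stop("criterion_fraction must be in (0, 1)")
  co <- fit$coefficients
  unname(co["b"] + co["c"] * log((1 - criterion_fraction) / criterion_fraction))
}

#' @export
coef.acuity_fit <- function(object, ...) object$coefficients

#' @export
residuals.acuity_fit <- function(object, ...) object$residuals

#' @export
#' @param newdata optional data frame with `spatial_freq_cyc_deg`.
#' @rdname fit_logistic
predict.acuity_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) object$data$spatial_freq_cyc_deg
       else newdata$spatial_freq_cyc_deg
  .logistic_pred(object$coefficients, f)
}

#' @export
print.acuity_fit <- function(x, ...) {
  co <- x$coefficients
  cat("Logistic acuity fit: R(f) = a / (1 + exp((f - b) / c))\n")
  cat(sprintf("  a (max response) = %.4f\n", co["a"]))
  cat(sprintf("  b (inflection)   = %.4f cyc/deg\n", co["b"]))
  cat(sprintf("  c (steepness)    = %.4f\n", co["c"]))
  cat(sprintf("  sum |resid|      = %.4g over %d frequencies\n",
              x$objective, nrow(x$data)))
  if (x$converged)
    cat(sprintf("  visual acuity (50%% criterion) = %.3f cyc/deg\n",
                visual_acuity(x)))
  else cat("  fit flagged as not converged/degenerate\n")
  invisible(x)
}

#' @export
summary.acuity_fit <- function(object, ...) {
  print(object)
  cat("\nFitted points:\n")
  print(cbind(object$data, fitted = object$fitted,
              residual = object$residuals), digits = 4)
  invisible(object)
}

#' @export
plot.acuity_fit <- function(x, ...) {
  d <- x$data
  grid <- seq(min(d$spatial_freq_cyc_deg), max(d$spatial_freq_cyc_deg),
              length.out = 200)
  plot(d$spatial_freq_cyc_deg, d$response,
       xlab = "spatial frequency (cyc/deg)", ylab = "response",
       pch = 19, ...)
  lines(grid, .logistic_pred(x$coefficients, grid), col = "blue")
  if (!is.null(x$bounds)) {
    lines(x$bounds$spatial_freq_cyc_deg, x$bounds$lower, lty = 2, col = "blue")
    lines(x$bounds$spatial_freq_cyc_deg, x$bounds$upper, lty = 2, col = "blue")
  }
  if (x$converged)
    abline(v = visual_acuity(x), col = "red", lty = 3)
  invisible(x)
}

#' @export
plot.response_curve <- function(x, ...) {
  plot(x$spatial_freq_cyc_deg, x$normalized, type = "b", pch = 19,
       xlab = "spatial frequency (cyc/deg)",
       ylab = "normalized response", ...)
  abline(h = 0, col = "red")
  invisible(x)
}
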