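test_that("angular velocity uses shortest-arc differences", {
  t <- seq(0, 1, by = 0.1)
  expect_true(all(angular_velocity(rep(40, 11), t)$velocity_deg_s == 0))
  ramp <- angular_velocity((12 * t) %% 360, t)
  expect_equal(ramp$velocity_deg_s, rep(12, 10), tolerance = 1e-9)
  wrap <- angular_velocity(c(359, 1), c(0, 0.1))
  expect_equal(wrap$velocity_deg_s, 20)
  expect_equal(nrow(angular_velocity(5, 0)), 0)
  withna <- angular_velocity(c(0, NA, 2), c(0, 1, 2))
  expect_true(all(is.na(withna$velocity_deg_s)))
})

test_that("SRB detection reproduces the printed acceptance band", {
  mk <- function(vh, vs = 12) data.frame(v_head = vh, v_stim = vs)
  expect_true(detect_srb(mk(12), 9)$srb)
  # strict band (3, 21) deg/s in the stimulus direction
  expect_false(detect_srb(mk(3), 9)$srb)
  expect_false(detect_srb(mk(21), 9)$srb)
  expect_true(detect_srb(mk(3.001), 9)$srb)
  expect_true(detect_srb(mk(20.999), 9)$srb)
  expect_false(detect_srb(mk(-12), 9)$srb)   # wrong direction
  # lambda above the stimulus speed accepts a motionless head
  expect_true(detect_srb(mk(0), 13)$srb)
  expect_false(detect_srb(mk(0), 9)$srb)
})

test_that("SRB detection equals the brute-force per-frame check", {
  set.seed(21)
  for (rep in 1:4) {
    vh <- rnorm(300, 5, 15); vs <- sample(c(-12, 12), 300, TRUE)
    vh[sample(300, 10)] <- NA
    v <- data.frame(v_head = vh, v_stim = vs)
    for (lam in c(2, 9, 12)) {
      got <- detect_srb(v, lam)
      want <- brute_srb(vh, vs, lam)
      expect_identical(got$srb, want)
      expect_equal(got$t_track, sum(want, na.rm = TRUE) / sum(!is.na(want)))
    }
  }
})

test_that("t_track is non-decreasing in lambda for any trace", {
  proto <- make_rotation_protocol(12, 6, 60, 0.04)
  for (s in 1:6) {
    tr <- simulate_trace(proto, behavior_model(0.4, 4, 6, seed = s))
    tts <- sapply(seq(2, 12, by = 0.5), function(l)
      trace_t_track(tr$head_angle_deg, tr$stim_angle_deg, tr$time_s, l))
    expect_true(all(diff(tts) >= 0))
  }
})

test_that("perfect tracking and motionless heads score 1 and 0", {
  proto <- make_rotation_protocol(12, 6, 60, 0.04)
  perfect <- simulate_trace(proto, behavior_model(1, 0, 0, seed = 1))
  expect_equal(trace_t_track(perfect$head_angle_deg, perfect$stim_angle_deg,
                             perfect$time_s, 9), 1)
  still <- simulate_trace(proto, behavior_model(0, 0, 0, seed = 1))
  expect_equal(trace_t_track(still$head_angle_deg, still$stim_angle_deg,
                             still$time_s, 9), 0)
})

test_that("chance level is the median of per-animal medians", {
  expect_equal(chance_level(list(rep(0.05, 10))), 0.05)
  expect_equal(chance_level(list(0.02, 0.04, 0.06)), 0.04)
  set.seed(8)
  per_animal <- replicate(6, runif(10, 0, 0.2), simplify = FALSE)
  expect_equal(chance_level(per_animal), brute_chance(per_animal))
  expect_error(chance_level(list()), "at least one")
})

test_that("response curves are chance-corrected and normalized at the optimum", {
  # single animal, one trial per frequency, no chance
  d <- data.frame(animal_id = 1,
                  spatial_freq_cyc_deg = c(0.1, 0.2, 0.4),
                  t_track = c(0.2, 0.4, 0.1))
  rc <- build_response_curve(d, chance = 0, optimal_freq = 0.2)
  expect_equal(rc$normalized, c(0.5, 1, 0.25))

  # uniform responses minus chance normalize to exactly one
  d2 <- expand.grid(animal_id = 1:3, spatial_freq_cyc_deg = c(0.1, 0.2, 0.4),
                    trial = 1:2)
  d2$t_track <- 0.3
  rc2 <- build_response_curve(d2, chance = 0.1, optimal_freq = 0.2)
  expect_true(all(rc2$normalized == 1))
  expect_equal(rc2$median_corrected, rep(0.2, 3))

  # negative corrected values are preserved unless clipped
  d3 <- data.frame(animal_id = 1, spatial_freq_cyc_deg = c(0.2, 0.6),
                   t_track = c(0.5, 0.05))
  rc3 <- build_response_curve(d3, chance = 0.1, optimal_freq = 0.2)
  expect_lt(rc3$median_corrected[2], 0)
  rc3c <- build_response_curve(d3, chance = 0.1, optimal_freq = 0.2,
                               clip = TRUE)
  expect_equal(rc3c$median_corrected[2], 0)
})

test_that("response-curve pipeline matches a hand-rolled median pipeline", {
  set.seed(31)
  freqs <- c(0.1, 0.2, 0.4, 0.6)
  d <- expand.grid(animal_id = 1:6, spatial_freq_cyc_deg = freqs,
                   trial = 1:10)
  d$t_track <- runif(nrow(d), 0, 0.5)
  chance <- 0.07
  rc <- build_response_curve(d, chance = chance, optimal_freq = 0.2)
  want <- sapply(freqs, function(f) {
    median(sapply(1:6, function(a)
      median(d$t_track[d$animal_id == a & d$spatial_freq_cyc_deg == f] -
               chance)))
  })
  expect_equal(rc$median_corrected, want)
  expect_equal(rc$normalized, want / want[freqs == 0.2])
})

test_that("the logistic fit recovers noiseless parameters", {
  freqs <- c(0.3, 0.4, 0.425, 0.45, 0.475, 0.5, 0.6)
  truth <- c(a = 1, b = 0.4, c = 0.02)
  y <- truth["a"] / (1 + exp((freqs - truth["b"]) / truth["c"]))
  fit <- fit_logistic(data.frame(spatial_freq_cyc_deg = freqs, response = y),
                      n_boot = 0)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-6)
  expect_equal(visual_acuity(fit), 0.4, tolerance = 1e-6)
})

test_that("degenerate flat responses are flagged", {
  d <- data.frame(spatial_freq_cyc_deg = c(0.3, 0.4, 0.5), response = 0.2)
  expect_warning(fit <- fit_logistic(d, n_boot = 0), "degenerate")
  expect_false(fit$converged)
  expect_error(visual_acuity(fit), "converge")
})

test_that("absolute-residual fitting resists an outlier better than least squares", {
  freqs <- c(0.25, 0.3, 0.35, 0.4, 0.425, 0.45, 0.475, 0.5, 0.55, 0.6)
  y <- 1 / (1 + exp((freqs - 0.4) / 0.03))
  y_out <- y; y_out[8] <- y_out[8] + 0.8
  lad_clean <- coef(fit_logistic(
    data.frame(spatial_freq_cyc_deg = freqs, response = y),
    fit_above_cyc_deg = 0.2, n_boot = 0))["b"]
  lad_dirty <- coef(fit_logistic(
    data.frame(spatial_freq_cyc_deg = freqs, response = y_out),
    fit_above_cyc_deg = 0.2, n_boot = 0))["b"]
  ls_obj <- function(par, fr, yy) {
    if (abs(par[3]) < 1e-8) return(1e300)
    sum((yy - par[1] / (1 + exp((fr - par[2]) / par[3])))^2)
  }
  ls_fit <- function(yy) optim(c(1, 0.4, 0.03), ls_obj, fr = freqs, yy = yy,
                               control = list(maxit = 5000,
                                              reltol = 1e-12))$par[2]
  expect_lt(abs(lad_dirty - lad_clean),
            abs(ls_fit(y_out) - ls_fit(y)))
})

test_that("acuity criteria invert the logistic in closed form", {
  freqs <- c(0.3, 0.4, 0.45, 0.5, 0.6)
  y <- 0.8 / (1 + exp((freqs - 0.39) / 0.025))
  fit <- fit_logistic(data.frame(spatial_freq_cyc_deg = freqs, response = y),
                      n_boot = 0)
  co <- coef(fit)
  expect_equal(visual_acuity(fit, 0.5), unname(co["b"]), tolerance = 1e-8)
  expect_equal(visual_acuity(fit, 0.25),
               unname(co["b"] + co["c"] * log(3)), tolerance = 1e-8)
  # doubling the response scale leaves the half-max acuity unchanged
  fit2 <- fit_logistic(data.frame(spatial_freq_cyc_deg = freqs,
                                  response = 2 * y), n_boot = 0)
  expect_equal(visual_acuity(fit2), visual_acuity(fit), tolerance = 1e-5)
  expect_error(visual_acuity(fit, 1.5), "criterion")
})

test_that("prediction bounds cover the fitted data", {
  freqs <- c(0.3, 0.4, 0.425, 0.45, 0.475, 0.5, 0.6)
  set.seed(4)
  y <- 1 / (1 + exp((freqs - 0.4) / 0.03)) + rnorm(7, 0, 0.03)
  fit <- fit_logistic(data.frame(spatial_freq_cyc_deg = freqs, response = y),
                      n_boot = 300, seed = 2)
  expect_s3_class(fit$bounds, "data.frame")
  expect_true(all(fit$bounds$upper >= fit$bounds$lower))
  pred <- predict(fit)
  lo <- approx(fit$bounds$spatial_freq_cyc_deg, fit$bounds$lower, freqs)$y
  hi <- approx(fit$bounds$spatial_freq_cyc_deg, fit$bounds$upper, freqs)$y
  expect_true(mean(y >= lo & y <= hi) >= 6 / 7)
})
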