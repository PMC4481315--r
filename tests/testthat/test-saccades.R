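test_that("constant yaw and brief spikes yield no events", {
  yaw <- make_yaw(rep(20, 1000))
  expect_equal(nrow(detect_saccades(yaw)), 0)
  # 1000 deg/s sustained for only 10 ms fails the duration rule
  omega <- rep(0, 600); omega[100:119] <- 1000   # 20 samples = 10 ms
  yaw2 <- make_yaw(phi_from_omega(omega, 2000))
  expect_equal(nrow(detect_saccades(yaw2)), 0)
})

test_that("a raised-cosine saccade is detected with oracle-exact boundaries", {
  fs <- 2000
  t <- seq(0, 0.3, by = 1 / fs)
  t0 <- 0.1; dur <- 0.030; peak <- 1500
  u <- (t - t0) / dur
  omega <- ifelse(u >= 0 & u <= 1, peak * (1 - cos(2 * pi * u)) / 2, 0)
  yaw <- make_yaw(phi_from_omega(omega, fs), fs)
  ev <- detect_saccades(yaw)
  expect_equal(nrow(ev), 1)
  orc <- oracle_detect(yaw)
  expect_equal(ev$start, yaw$t[orc$start])
  expect_equal(ev$end, yaw$t[orc$end])
  expect_equal(ev$start_thresh, yaw$t[orc$start_thresh])
  expect_equal(ev$end_thresh, yaw$t[orc$end_thresh])
  # supra-threshold span of the analytic bump: 400/1500 crossing
  u_cross <- acos(1 - 2 * 400 / peak) / (2 * pi)
  expect_equal(ev$duration_ms, (1 - 2 * u_cross) * dur * 1000, tolerance = 1.5)
  expect_equal(ev$amplitude_absolute, peak * dur / 2, tolerance = 0.5)
})

test_that("detector matches the brute-force oracle on 1000 random traces", {
  set.seed(99)
  n_mismatch <- 0
  for (rep in 1:1000) {
    omega <- random_omega_trace()
    yaw <- make_yaw(phi_from_omega(omega, 2000))
    # make omega exactly the intended trace (interior central differences
    # reproduce it only approximately), so both paths see identical input
    yaw$omega <- omega
    ev <- detect_saccades(yaw)
    orc <- oracle_detect(yaw)
    same <- nrow(ev) == nrow(orc) &&
      (nrow(ev) == 0 ||
         (identical(ev$start, yaw$t[orc$start]) &&
            identical(ev$end, yaw$t[orc$end]) &&
            identical(ev$start_thresh, yaw$t[orc$start_thresh]) &&
            identical(ev$end_thresh, yaw$t[orc$end_thresh])))
    if (!same) n_mismatch <- n_mismatch + 1
  }
  expect_equal(n_mismatch, 0)
})

test_that("noise-free injected saccades are fully recovered within 2%", {
  tr <- generate_trial(synth_config(seed = 21, noise_sd = 0, drift_gain = 0))
  yaw <- compute_yaw(tr$rec)
  ev <- detect_saccades(yaw)
  inj <- tr$truth$saccades
  detectable <- inj$peak_velocity > 400 & inj$duration_ms >= 12
  expect_equal(nrow(ev), sum(detectable))   # zero false negatives
  for (k in which(detectable)) {
    j <- which.min(abs(ev$start - inj$start[k]))
    expect_lt(abs(ev$amplitude_absolute[j] - inj$amplitude[k]) /
                inj$amplitude[k], 0.02)
  }
})

test_that("with tracking noise, amplitudes >= 15 deg are recovered to ~10%", {
  errs <- c()
  for (s in 22:31) {
    tr <- generate_trial(synth_config(seed = s, drift_gain = 0))
    yaw <- compute_yaw(tr$rec)
    ev <- detect_saccades(yaw)
    inj <- tr$truth$saccades[tr$truth$saccades$amplitude >= 15, ]
    for (k in seq_len(nrow(inj))) {
      j <- which.min(abs(ev$start - inj$start[k]))
      errs <- c(errs, abs(ev$amplitude_absolute[j] - inj$amplitude[k]) /
                  inj$amplitude[k])
    }
  }
  # per-sample tracking noise leaves a Gaussian tail, so the 10% recovery
  # bound is asserted on the distribution, not on every single event
  expect_gte(mean(errs < 0.10), 0.9)
  expect_lt(median(errs), 0.05)
})

test_that("event count is monotone in threshold and minimum duration", {
  set.seed(17)
  tr <- generate_trial(synth_config(seed = 24))
  yaw <- compute_yaw(tr$rec)
  counts_thr <- vapply(seq(200, 800, by = 100), function(th) {
    nrow(detect_saccades(yaw, omega_thresh = th))
  }, 0L)
  expect_true(all(diff(counts_thr) <= 0))
  counts_dur <- vapply(seq(4, 40, by = 4), function(md) {
    nrow(detect_saccades(yaw, min_dur_ms = md))
  }, 0L)
  expect_true(all(diff(counts_dur) <= 0))
})

test_that("statistics aggregate flight to bird to cohort, never pooled", {
  ev1 <- tibble::tibble(amplitude_absolute = 20, amplitude_relative = 18,
                        duration_ms = 20, peak_velocity = 1500,
                        mean_velocity = 1000,
                        bird_id = "b1", flight_id = "f1")
  one <- saccade_statistics(ev1)
  expect_equal(one$amplitude_absolute_median, 20)
  expect_equal(one$duration_ms_mean, 20)
  # two birds with per-flight medians 20 and 40: cohort mean is 30, not the
  # pooled median of the raw events
  ev <- dplyr::bind_rows(
    tibble::tibble(amplitude_absolute = c(19, 20, 21),
                   bird_id = "b1", flight_id = "f1"),
    tibble::tibble(amplitude_absolute = c(39, 40, 41),
                   bird_id = "b2", flight_id = "f2"))
  ev$amplitude_relative <- ev$amplitude_absolute
  ev$duration_ms <- 20; ev$peak_velocity <- 1000; ev$mean_velocity <- 800
  coh <- saccade_statistics(ev)
  expect_equal(coh$amplitude_absolute_median, 30)
  expect_equal(coh$n_birds, 2L)
})

test_that("cohort amplitude median is recovered within 5% at n >= 100", {
  coh <- generate_cohort(20, synth_config(drift_gain = 0), seed = 51)
  evs <- dplyr::bind_rows(lapply(coh, function(tr) {
    detect_saccades(compute_yaw(tr$rec))
  }))
  expect_gte(nrow(evs), 100)
  inj <- dplyr::bind_rows(lapply(coh, function(tr) tr$truth$saccades))
  st <- saccade_statistics(evs)
  expect_lt(abs(st$amplitude_absolute_median - median(inj$amplitude)) /
              median(inj$amplitude), 0.05)
})

test_that("intersaccadic intervals behave as constructed", {
  yaw <- make_yaw(rep(0, 2000))
  st <- intersaccade_statistics(yaw, detect_saccades(yaw))
  expect_equal(st$n, 2000)
  # stabilized head over a rotating body: relative velocity tracks the
  # body rate while absolute stays near zero
  fs <- 2000
  body <- 300 * seq(0, 1, by = 1 / fs)
  yaw2 <- make_yaw(rep(0, length(body)), phi_body = body)
  st2 <- intersaccade_statistics(yaw2, detect_saccades(yaw2))
  expect_lt(st2$abs_omega_median, 1e-6)
  expect_equal(st2$rel_omega_median, 300, tolerance = 1e-6)
})

test_that("intersaccadic absolute velocity is below the saccadic median", {
  tr <- generate_trial(synth_config(seed = 25))
  yaw <- compute_yaw(tr$rec)
  ev <- detect_saccades(yaw)
  st <- intersaccade_statistics(yaw, ev)
  expect_lt(st$abs_omega_median, median(ev$peak_velocity))
  expect_lt(st$abs_omega_median, 400)
})

test_that("amplitude-duration regression matches hand OLS", {
  ev <- tibble::tibble(duration_ms = c(10, 20, 30, 40),
                       amplitude_absolute = 1.5 * c(10, 20, 30, 40) - 14)
  fit <- amplitude_duration_regression(ev)
  expect_equal(fit$slope_deg_per_s, 1500, tolerance = 1e-9)
  expect_equal(fit$intercept_deg, -14, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  two <- amplitude_duration_regression(
    tibble::tibble(duration_ms = c(20, 40), amplitude_absolute = c(20, 50)))
  expect_equal(two$slope_deg_per_s, 1500)
  expect_equal(two$intercept_deg, -10)
  expect_error(amplitude_duration_regression(
    tibble::tibble(duration_ms = c(20, 20, 20),
                   amplitude_absolute = c(10, 20, 30))), "degenerate")
})

test_that("regression recovers the generator's preferred head speed", {
  coh <- generate_cohort(10, synth_config(drift_gain = 0), seed = 61)
  evs <- dplyr::bind_rows(lapply(coh, function(tr) {
    detect_saccades(compute_yaw(tr$rec))
  }))
  fit <- amplitude_duration_regression(evs)
  # saccades are drawn along amplitude = 1.5 dur - 14
  expect_gt(fit$r, 0.6)
  expect_equal(fit$slope_deg_per_s, 1500, tolerance = 0.35)
})

test_that("saccadic fraction arithmetic on constructed traces", {
  fs <- 2000
  n <- 2001
  phi <- seq(0, 150, length.out = n)   # smooth 150 deg reorientation
  yaw <- make_yaw(phi, fs)
  ev0 <- detect_saccades(yaw)
  expect_equal(nrow(ev0), 0)
  none <- saccadic_fraction(yaw, ev0, c(0, 1))
  expect_equal(none$percent, 0)
  # three 40-deg saccades plus 30 deg of drift across a 150-deg turn
  ev <- tibble::tibble(start = c(0.2, 0.4, 0.6), end = c(0.25, 0.45, 0.65),
                       amplitude_absolute = c(40, 40, 40))
  frac <- saccadic_fraction(yaw, ev, c(0, 1))
  expect_equal(frac$percent, 80)
  # all reorientation inside saccades: 100 percent
  ev_all <- tibble::tibble(start = 0.1, end = 0.9,
                           amplitude_absolute = 150)
  expect_equal(saccadic_fraction(yaw, ev_all, c(0, 1))$percent, 100)
  flat <- make_yaw(rep(0, n), fs)
  expect_warning(res <- saccadic_fraction(flat, ev0, c(0, 1)), "undefined")
  expect_true(is.na(res$percent))
})

test_that("stroke phases are located and normalized correctly", {
  rec <- make_straight_rec(n_beats = 6)
  beats <- wingbeat_records(rec)
  ev <- tibble::tibble(
    start = c(beats$down_start[2], beats$down_mid[3]),
    end = c(beats$down_end[2], beats$up_mid[3]),
    bird_id = "b1", trial_id = "manual")
  sp <- stroke_phase_of_saccades(ev, beats)
  ph <- sp$phases[sp$phases$boundary == "start", ]
  expect_equal(ph$stroke, c("down", "down"))
  expect_equal(ph$percent[1], 0)
  expect_equal(ph$percent[2], 50)   # down_mid of a symmetric downstroke
  h <- sp$histogram
  for (b in unique(h$boundary)) {
    expect_equal(sum(h$height[h$boundary == b]), 1, tolerance = 1e-9)
  }
})

test_that("cohort stroke-phase histogram peaks in the injected bin", {
  coh <- generate_cohort(8, synth_config(), seed = 71)
  evs <- dplyr::bind_rows(lapply(coh, function(tr) {
    detect_saccades(compute_yaw(tr$rec))
  }))
  beats <- dplyr::bind_rows(lapply(coh, function(tr) wingbeat_records(tr$rec)))
  sp <- stroke_phase_of_saccades(evs, beats)
  hs <- sp$histogram[sp$histogram$boundary == "start" &
                       sp$histogram$stroke == "down", ]
  expect_equal(hs$bin_left[which.max(hs$height)], 70)
})
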