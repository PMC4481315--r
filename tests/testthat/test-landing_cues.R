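approach_template <- function(alpha_threshold = 25, duration = 0.7) {
  synth_config(path_type = "approach", duration = duration,
               landing = list(mode = "alpha_threshold",
                              alpha_threshold = alpha_threshold))
}

test_that("hovering at fixed distance gives constant alpha and zero RREV", {
  geo <- arena_geometry()
  cfg <- synth_config(seed = 1, path_type = "approach", duration = 0.4,
                      speeds = list(v0 = 0, v1 = 0), noise_sd = 0,
                      perch_swing = list(amp_fore = 0, amp_side = 0,
                                         period = 1.2, phase = 0),
                      landing = list(mode = "time", time = 0.35))
  tr <- generate_trial(cfg)
  s <- landing_cue_series(tr$rec, geo)
  d <- 0.75   # start distance from the perch line
  expect_equal(mean(s$alpha), 2 * atan2_deg(geo$perch_width / 2, d),
               tolerance = 0.05)
  expect_lt(diff(range(s$alpha)), 1e-6)
  expect_lt(max(abs(s$omega_exp)), 1e-3)
  expect_lt(max(abs(s$rrev), na.rm = TRUE), 1e-4)
  expect_true(all(is.na(s$tau)))
})

test_that("tau approximates distance over speed for a steady approach", {
  # narrow perch so that alpha stays small over most of the approach
  geo <- arena_geometry(perch_width = 0.08)
  cfg <- synth_config(seed = 2, path_type = "approach", duration = 1.2,
                      speeds = list(v0 = 0.5, v1 = 0.5), noise_sd = 0,
                      start_pos = c(geo$perch_x + 0.85,
                                    geo$features["perch_center", "y"]),
                      perch_swing = list(amp_fore = 0, amp_side = 0,
                                         period = 1.2, phase = 0),
                      landing = list(mode = "time", time = 1.15),
                      geometry = geo)
  tr <- generate_trial(cfg)
  s <- landing_cue_series(tr$rec, geo)
  t_abs <- s$t_rel + tr$rec$landing_init_time
  dist <- 0.85 - 0.5 * t_abs
  small <- which(s$alpha < 15 & t_abs > 0.05)
  expect_gt(length(small), 100)
  expect_equal(s$tau[small], (dist / 0.5)[small],
               tolerance = 0.02)
})

test_that("RREV rises monotonically toward contact at constant speed", {
  geo <- arena_geometry()
  cfg <- synth_config(seed = 3, path_type = "approach", duration = 1.0,
                      speeds = list(v0 = 0.6, v1 = 0.6), noise_sd = 0,
                      perch_swing = list(amp_fore = 0, amp_side = 0,
                                         period = 1.2, phase = 0),
                      landing = list(mode = "time", time = 0.95))
  tr <- generate_trial(cfg)
  s <- landing_cue_series(tr$rec, geo)
  mid <- s$rrev[s$t_rel > -0.8 & s$t_rel < -0.05]
  expect_true(all(diff(mid) > -1e-6))
})

test_that("tau times RREV is 1 wherever both are defined", {
  tr <- generate_trial(approach_template(), trial_id = "t1")
  s <- landing_cue_series(tr$rec)
  both <- !is.na(s$tau) & !is.na(s$rrev)
  expect_gt(sum(both), 10)
  expect_lt(max(abs(s$tau[both] * s$rrev[both] - 1)), 1e-12)
})

test_that("a perch swinging at the bird can raise relative speed while
           absolute speed falls", {
  geo <- arena_geometry()
  cfg <- synth_config(seed = 4, path_type = "approach", duration = 0.7,
                      speeds = list(v0 = 1.0, v1 = 0.3), noise_sd = 0,
                      perch_swing = list(amp_fore = 0.10, amp_side = 0.01,
                                         period = 1.2, phase = pi),
                      landing = list(mode = "time", time = 0.65))
  tr <- generate_trial(cfg)
  s <- landing_cue_series(tr$rec, geo)
  fs <- attr(s, "sample_rate")
  dabs <- derivative(s$speed_abs, fs)
  drel <- derivative(s$speed_rel, fs)
  expect_true(any(drel > 0 & dabs < 0))
})

test_that("identical trials have zero c.v. everywhere", {
  tr <- generate_trial(approach_template())
  s <- landing_cue_series(tr$rec)
  cv <- cv_analysis(list(s, s, s))
  vals <- unlist(cv$cv[, -1])
  expect_lt(max(vals, na.rm = TRUE), 1e-9)
})

test_that("missing landing annotation and bad factors are errors", {
  tr <- generate_trial(synth_config(seed = 5))
  expect_error(landing_cue_series(tr$rec), "landing_init_time")
  tr2 <- generate_trial(approach_template())
  expect_error(landing_cue_series(tr2$rec, downsample = 2.5), "integer")
  expect_error(cv_analysis(list()), "at least 3")
})

test_that("c.v. is invariant under rescaling a parameter across trials", {
  coh <- generate_cohort(5, approach_template(), seed = 101)
  series <- lapply(coh, function(tr) landing_cue_series(tr$rec))
  cv1 <- cv_analysis(series)
  scaled <- lapply(series, function(s) { s$alpha <- 7.3 * s$alpha; s })
  cv2 <- cv_analysis(scaled)
  expect_equal(cv2$cv$alpha, cv1$cv$alpha, tolerance = 1e-9)
})

test_that("alpha-triggered cohorts select alpha as most parsimonious", {
  coh <- generate_cohort(12, approach_template(), seed = 21)
  series <- lapply(coh, function(tr) landing_cue_series(tr$rec))
  cv <- cv_analysis(series)
  expect_equal(cv$most_parsimonious, "alpha")
  expect_true(all(cv$mean_cv["alpha"] <= cv$mean_cv))
})

test_that("the winner survives 2000 -> 50 Hz downsampling", {
  coh <- generate_cohort(8, approach_template(), seed = 22)
  recs <- lapply(coh, function(tr) tr$rec)
  dc <- downsample_check(recs, 50)
  expect_true(dc$winner_unchanged)
  expect_gte(dc$rank_correlation, 0.8)
  # downsampling by 1 is the identity
  s <- landing_cue_series(recs[[1]])
  s1 <- landing_cue_series(recs[[1]], downsample = 1L)
  expect_equal(s$alpha, s1$alpha)
  expect_error(downsample_check(recs, 4000), "exceeds")
})
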