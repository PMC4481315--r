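test_that("azimuth conventions: dead ahead is 0, left is +90", {
  geo <- arena_geometry()
  yaw <- make_yaw(rep(0, 5))          # facing +x, away from the perch
  yaw$head_x <- rep(0.5, 5); yaw$head_y <- rep(0.3, 5)
  az <- feature_azimuths(yaw, geo)
  front <- az$azimuth[az$feature_id == "corner_white_dark_front"][1]
  expect_equal(front, atan2_deg(0.6 - 0.3, 1 - 0.5), tolerance = 1e-9)
  # a feature exactly to the bird's left sits at +90
  yaw2 <- make_yaw(rep(0, 3))
  yaw2$head_x <- rep(geo$features["gray_square_left", "x"], 3)
  yaw2$head_y <- rep(0.3, 3)
  az2 <- feature_azimuths(yaw2, geo)
  expect_equal(az2$azimuth[az2$feature_id == "gray_square_left"][1], 90,
               tolerance = 1e-9)
  # facing the perch from the arena midpoint: perch center dead ahead
  yaw3 <- make_yaw(rep(180, 3))
  yaw3$head_x <- rep(0.5, 3)
  yaw3$head_y <- rep(geo$features["perch_center", "y"], 3)
  az3 <- feature_azimuths(yaw3, geo)
  expect_equal(az3$azimuth[az3$feature_id == "perch_center"][1], 0,
               tolerance = 1e-9)
})

test_that("rotating yaw by +delta shifts all azimuths by -delta", {
  geo <- arena_geometry()
  set.seed(14)
  yaw <- make_yaw(runif(20, -180, 180))
  yaw$head_x <- runif(20, 0.2, 0.8); yaw$head_y <- runif(20, 0.1, 0.5)
  az <- feature_azimuths(yaw, geo)
  for (delta in c(10, -35, 90)) {
    yaw2 <- yaw
    yaw2$phi_head <- yaw$phi_head + delta
    az2 <- feature_azimuths(yaw2, geo)
    # az2 = az - delta up to the 360-degree wrap
    resid <- (az$azimuth - az2$azimuth - delta) %% 360
    expect_true(all(pmin(resid, 360 - resid) < 1e-9))
  }
})

test_that("a dead-ahead feature stays at 0 under translation along heading", {
  geo <- arena_geometry()
  pc <- geo$features["perch_center", ]
  yaw <- make_yaw(rep(180, 4))
  yaw$head_x <- c(0.9, 0.7, 0.5, 0.3)
  yaw$head_y <- rep(pc[["y"]], 4)
  az <- feature_azimuths(yaw, geo)
  expect_true(all(abs(az$azimuth[az$feature_id == "perch_center"]) < 1e-9))
})

test_that("the tracked perch overrides the static rest position", {
  geo <- arena_geometry()
  yaw <- make_yaw(rep(180, 3))
  yaw$head_x <- rep(0.6, 3); yaw$head_y <- rep(geo$features["perch_center", "y"], 3)
  track <- tibble::tibble(t = yaw$t, x = geo$perch_x + c(0, 0.05, 0.1),
                          y = rep(geo$features["perch_center", "y"], 3))
  az <- feature_azimuths(yaw, geo, perch_track = track)
  expect_true(all(abs(az$azimuth[az$feature_id == "perch_center"]) < 1e-9))
  # edges straddle the center when the perch is ahead
  left <- az$azimuth[az$feature_id == "perch_left_edge"]
  right <- az$azimuth[az$feature_id == "perch_right_edge"]
  expect_true(all(left < 0 & right > 0 | left > 0 & right < 0))
})

test_that("low-resolution mask drops beats with large within-beat yaw SD", {
  beats <- tibble::tibble(down_start = c(0, 0.06), up_end = c(0.06, 0.12))
  t <- c(0.00, 0.015, 0.03, 0.045, 0.06, 0.075, 0.09, 0.105)
  phi <- c(10, 10, 10, 10, 0, 0, 40, 40)  # second beat jumps 40 deg
  mask <- intersaccadic_mask_lowres(t, phi, beats)
  expect_true(all(mask[1:4]))
  expect_false(any(mask[5:8]))
})

test_that("histogram normalization and peaks behave as specified", {
  s <- tibble::tibble(feature_id = rep(c("a", "b"), each = 100),
                      t = rep(1:100, 2),
                      azimuth = c(rep(2, 100), runif(100, -90, 89.9)))
  h <- azimuth_distributions(s)
  expect_lte(sum(h$prob), 1 + 1e-9)
  ha <- h[h$feature_id == "a", ]
  expect_equal(ha$prob[ha$bin_left == 0], 0.5)   # all of a's mass in [0, 10)
  expect_equal(sum(ha$prob), 0.5)
  peaks <- attr(h, "peaks")
  expect_equal(peaks$bin_left[peaks$feature_id == "a"], 0)
  # azimuths outside +/-90 are excluded from the histogram
  s2 <- tibble::tibble(feature_id = "a", t = 1:4,
                       azimuth = c(0, 120, -170, 45))
  h2 <- azimuth_distributions(s2)
  expect_equal(sum(h2$prob), 1)
  expect_equal(nrow(h2[h2$prob > 0, ]), 2)
})

test_that("per-sample masks recycle across feature blocks", {
  yaw <- make_yaw(rep(0, 10))
  yaw$head_x <- rep(0.5, 10); yaw$head_y <- rep(0.3, 10)
  az <- feature_azimuths(yaw, arena_geometry())
  mask <- c(rep(TRUE, 5), rep(FALSE, 5))
  h <- azimuth_distributions(az, mask = mask)
  expect_gt(sum(h$prob), 0)
  expect_error(azimuth_distributions(az, mask = c(TRUE, FALSE)), "mask length")
})

test_that("a frontally stabilized perch peaks near 0 with broader edges", {
  # after-turn construction: head stabilizes the perch center frontally
  # (a few degrees off-axis, well inside the +/-10 deg eye-motion band)
  geo <- arena_geometry()
  set.seed(15)
  n <- 400
  hx <- seq(0.75, 0.35, length.out = n)
  hy <- geo$features["perch_center", "y"] + rnorm(n, 0, 0.01)
  look <- atan2_deg(geo$features["perch_center", "y"] - hy,
                    geo$perch_x - hx) - 4 + rnorm(n, 0, 0.8)
  yaw <- make_yaw(look)
  yaw$head_x <- hx; yaw$head_y <- hy
  az <- feature_azimuths(yaw, geo)
  h <- azimuth_distributions(az)
  pk <- attr(h, "peaks")
  expect_lte(abs(pk$bin_mid[pk$feature_id == "perch_center"]), 10)
  expect_gt(pk$prob[pk$feature_id == "perch_center"],
            pk$prob[pk$feature_id == "perch_left_edge"])
  expect_gt(pk$prob[pk$feature_id == "perch_center"],
            pk$prob[pk$feature_id == "perch_right_edge"])
})

test_that("low-res histograms correlate > 0.9 with full-rate histograms", {
  coh <- generate_cohort(10, synth_config(), seed = 91)
  full <- list(); low <- list()
  for (tr in coh) {
    yaw <- compute_yaw(tr$rec)
    az <- feature_azimuths(yaw, arena_geometry())
    az$bird_id <- tr$rec$bird_id
    ev <- detect_saccades(yaw)
    mask <- rep(TRUE, nrow(yaw))
    for (k in seq_len(nrow(ev))) {
      mask[yaw$t >= ev$start[k] & yaw$t <= ev$end[k]] <- FALSE
    }
    beats <- wingbeat_records(tr$rec)
    idx <- match(round(tr$rec$stroke_marks$time, 6), round(tr$rec$t, 6))
    lowm <- intersaccadic_mask_lowres(tr$rec$t[idx], yaw$phi_head[idx], beats)
    azl <- az[az$t %in% tr$rec$t[idx], ]
    full[[length(full) + 1]] <- az[rep(mask, times = 7), ]
    low[[length(low) + 1]] <- azl[rep(lowm, times = 7), ]
  }
  hf <- azimuth_distributions(dplyr::bind_rows(full))
  hl <- azimuth_distributions(dplyr::bind_rows(low))
  m <- merge(as.data.frame(hf), as.data.frame(hl),
             by = c("feature_id", "bin_left"))
  cors <- vapply(split(m, m$feature_id),
                 function(mm) cor(mm$prob.x, mm$prob.y), 0)
  expect_true(all(cors > 0.9))
})
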