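# Independent oracles and hand-built fixtures used across the suite.

# Hand-built yaw trace object (bypasses compute_yaw) for detector tests.
make_yaw <- function(phi_head, fs = 2000, phi_body = 0) {
  n <- length(phi_head)
  out <- tibble::tibble(
    t = seq(0, by = 1 / fs, length.out = n),
    phi_head = phi_head,
    phi_body = rep_len(phi_body, n),
    phi_diff = phi_head - rep_len(phi_body, n),
    omega = derivative(phi_head, fs),
    speed = rep(0, n), head_x = rep(0, n), head_y = rep(0, n))
  structure(out, class = c("yaw_traces", class(out)),
            sample_rate = fs, trial_id = "manual", bird_id = "b1",
            flight_id = "f1")
}

# Brute-force saccade detector: explicit sample-by-sample run scan plus the
# same boundary-extension rule, written as plain loops.
oracle_detect <- function(yaw, omega_thresh = 400, min_dur_ms = 12,
                          floor_dps = 100, max_extend_ms = 10) {
  fs <- attr(yaw, "sample_rate")
  w <- abs(yaw$omega)
  n <- length(w)
  min_len <- round(min_dur_ms / 1000 * fs)
  max_ext <- round(max_extend_ms / 1000 * fs)
  events <- list()
  i <- 1
  while (i <= n) {
    if (w[i] > omega_thresh) {
      j <- i
      while (j < n && w[j + 1] > omega_thresh) j <- j + 1
      if (j - i + 1 >= min_len) {
        a <- i
        for (s in seq_len(max_ext)) {
          if (a - 1 < 1) break
          if (w[a - 1] < floor_dps) { a <- a - 1; break }
          if (w[a - 1] >= w[a]) break
          a <- a - 1
        }
        b <- j
        for (s in seq_len(max_ext)) {
          if (b + 1 > n) break
          if (w[b + 1] < floor_dps) { b <- b + 1; break }
          if (w[b + 1] >= w[b]) break
          b <- b + 1
        }
        events[[length(events) + 1]] <-
          c(start = a, end = b, start_thresh = i, end_thresh = j)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(events)) {
    return(data.frame(start = numeric(), end = numeric(),
                      start_thresh = numeric(), end_thresh = numeric()))
  }
  as.data.frame(do.call(rbind, events))
}

# Random smooth angular-velocity trace that crosses the saccade threshold
# irregularly: sum of a few random raised-cosine bumps plus slow drift.
random_omega_trace <- function(n = 400, fs = 2000) {
  t <- seq_len(n) / fs
  omega <- 60 * sin(2 * pi * stats::runif(1, 0.5, 2) * t)
  for (k in seq_len(sample(0:4, 1))) {
    t0 <- stats::runif(1, 0, max(t))
    dur <- stats::runif(1, 0.004, 0.040)
    peak <- stats::runif(1, 200, 2500) * sample(c(-1, 1), 1)
    u <- (t - t0) / dur
    inb <- u >= 0 & u <= 1
    omega[inb] <- omega[inb] + peak * (1 - cos(2 * pi * u[inb])) / 2
  }
  omega
}

# phi series whose derivative() equals a desired interior omega closely
phi_from_omega <- function(omega, fs) {
  cumsum(omega) / fs
}

# Explicit leave-one-out cve: refit with the point's weight zeroed.
oracle_cve <- function(y, lambda, d = 2) {
  n <- length(y)
  lam <- if (lambda == 0) 1e-9 * stats::var(y) else lambda
  res <- vapply(seq_len(n), function(i) {
    w <- rep(1, n); w[i] <- 0
    z <- whittaker_smooth(y, lam, d = d, w = w)
    y[i] - z[i]
  }, 0)
  sqrt(mean(res^2))
}

# Minimal hand-built trial: straight +x flight with annotated beats and
# wingtips; head facing `facing_deg`, flying at `v` m/s.
make_straight_rec <- function(n_beats = 8, beat_period = 0.06, fs = 2000,
                              v = 1, facing_deg = 0, z_amp = 0,
                              heading_per_beat = NULL) {
  duration <- n_beats * beat_period
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)
  if (is.null(heading_per_beat)) heading_per_beat <- rep(0, n_beats)
  # piecewise-constant path heading per beat
  beat_of <- pmin(floor(t / beat_period) + 1, n_beats)
  hd <- heading_per_beat[beat_of] * pi / 180
  px <- 0.3 + cumsum(c(0, (v * cos(hd))[-n])) / fs
  py <- 0.3 + cumsum(c(0, (v * sin(hd))[-n])) / fs
  pz <- 0.45 + z_amp * sin(pi * t / duration)
  uf <- cbind(cos(facing_deg * pi / 180), sin(facing_deg * pi / 180))
  head_a <- cbind(px, py) + 0.014 * uf[rep(1, n), ]
  head_p <- cbind(px, py) - 0.014 * uf[rep(1, n), ]
  marks <- do.call(rbind, lapply(seq_len(n_beats), function(b) {
    t0 <- (b - 1) * beat_period
    data.frame(time = t0 + beat_period * c(0, 0.15, 0.3, 0.65),
               label = c("down_start", "down_mid", "down_end", "up_mid"))
  }))
  marks <- marks[marks$time <= duration, ]
  idx <- sapply(marks$time, function(tm) which.min(abs(t - tm)))
  marks$time <- t[idx]
  samples <- tibble::tibble(
    head_a_x = head_a[, 1], head_a_y = head_a[, 2], head_a_z = pz,
    head_p_x = head_p[, 1], head_p_y = head_p[, 2], head_p_z = pz,
    shoulder_l_x = NA_real_, shoulder_l_y = NA_real_, shoulder_l_z = NA_real_,
    shoulder_r_x = NA_real_, shoulder_r_y = NA_real_, shoulder_r_z = NA_real_,
    wingtip_l_x = NA_real_, wingtip_l_y = NA_real_, wingtip_l_z = NA_real_,
    wingtip_r_x = NA_real_, wingtip_r_y = NA_real_, wingtip_r_z = NA_real_)
  hd_deg <- heading_per_beat[beat_of] # body faces along the path
  ub <- heading_vec_test(hd_deg + 90)
  samples$shoulder_l_x[idx] <- px[idx] + 0.025 * ub[idx, 1]
  samples$shoulder_l_y[idx] <- py[idx] + 0.025 * ub[idx, 2]
  samples$shoulder_l_z[idx] <- pz[idx]
  samples$shoulder_r_x[idx] <- px[idx] - 0.025 * ub[idx, 1]
  samples$shoulder_r_y[idx] <- py[idx] - 0.025 * ub[idx, 2]
  samples$shoulder_r_z[idx] <- pz[idx]
  th <- c(down_start = 0.95, down_mid = 0, down_end = -0.95, up_mid = 0)
  thv <- th[marks$label]
  samples$wingtip_l_x[idx] <- samples$shoulder_l_x[idx] + 0.135 * cos(thv) * ub[idx, 1]
  samples$wingtip_l_y[idx] <- samples$shoulder_l_y[idx] + 0.135 * cos(thv) * ub[idx, 2]
  samples$wingtip_l_z[idx] <- pz[idx] + 0.135 * sin(thv)
  samples$wingtip_r_x[idx] <- samples$shoulder_r_x[idx] - 0.135 * cos(thv) * ub[idx, 1]
  samples$wingtip_r_y[idx] <- samples$shoulder_r_y[idx] - 0.135 * cos(thv) * ub[idx, 2]
  samples$wingtip_r_z[idx] <- pz[idx] + 0.135 * sin(thv)
  trial_recording("manual", t, samples, fs, stroke_marks = marks,
                  bird_id = "b1", flight_id = "f1")
}

heading_vec_test <- function(deg) {
  cbind(cos(deg * pi / 180), sin(deg * pi / 180))
}
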