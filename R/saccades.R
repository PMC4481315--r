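#' Detect head-yaw saccades
#'
#' A saccade is a maximal run of samples where the absolute head yaw
#' velocity strictly exceeds `omega_thresh` (default 400 deg/s) lasting at
#' least `min_dur_ms` (default 12 ms, i.e. 24 samples at 2000 Hz). Event
#' boundaries are then extended outward to the nearest sample where
#' |omega| falls below the boundary floor (100 deg/s) or reaches a local
#' minimum of |omega|, whichever comes first within 10 ms of the threshold
#' crossing, so the reported amplitude captures the full head turn.
#' Two supra-threshold runs separated by any sub-threshold gap are
#' distinct events. Amplitudes are read as the difference of the mean yaw
#' over the stabilized plateaus flanking the extended boundaries (at most
#' 10 ms per side, clipped at neighbouring events); this cancels the
#' smoother's symmetric ringing, which biases single-sample boundary
#' values by its overshoot.
#'
#' @param yaw a [compute_yaw()] result (uniform rate >= 400 Hz).
#' @param omega_thresh detection threshold, deg/s (strict inequality).
#' @param min_dur_ms minimum supra-threshold duration, ms.
#' @param boundary_floor amplitude-extension floor, deg/s.
#' @param max_extend_ms extension search range beyond each crossing, ms.
#' @return tibble of saccade events: `start` / `end` (extended boundaries,
#'   s), `start_thresh` / `end_thresh` (threshold crossings, s),
#'   `duration_ms` (supra-threshold), `duration_ext_ms`, `direction`,
#'   `amplitude_absolute` and `amplitude_relative` (deg, arena and body
#'   frame), `peak_velocity` and `mean_velocity` (deg/s), plus trial ids.
#' @export
detect_saccades <- function(yaw, omega_thresh = 400, min_dur_ms = 12,
                            boundary_floor = 100, max_extend_ms = 10) {
  fs <- attr(yaw, "sample_rate")
  dt <- diff(yaw$t)
  if ((max(dt) - min(dt)) > 0.01 * stats::median(dt)) {
    stop("non-uniform sampling: saccade detection needs a constant rate")
  }
  if (fs < 400) stop("sample rate too low for saccade detection")
  omega <- yaw$omega
  n <- length(omega)
  min_len <- round(min_dur_ms / 1000 * fs)
  supra <- abs(omega) > omega_thresh
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  i0 <- starts[keep]; i1 <- ends[keep]
  max_ext <- round(max_extend_ms / 1000 * fs)

  ea_all <- vapply(i0, extend_boundary, 0L, absw = abs(omega), dir = -1L,
                   floor_dps = boundary_floor, max_ext = max_ext)
  eb_all <- vapply(i1, extend_boundary, 0L, absw = abs(omega), dir = +1L,
                   floor_dps = boundary_floor, max_ext = max_ext)
  plateau_w <- round(0.020 * fs)
  # amplitudes are read from the raw (unsmoothed) yaw when available: the
  # smoothed trace rings around each saccade, biasing boundary values by
  # its overshoot, while the raw trace is flat on the flanking plateaus
  phi_amp <- if ("phi_head_raw" %in% names(yaw)) yaw$phi_head_raw else yaw$phi_head
  diff_amp <- phi_amp - yaw$phi_body

  rows <- lapply(seq_along(i0), function(k) {
    a <- i0[k]; b <- i1[k]
    ea <- ea_all[k]; eb <- eb_all[k]
    # difference of mean yaw over the stabilized plateaus flanking the
    # event; averaging suppresses the per-sample tracking noise
    lo <- max(1L, ea - plateau_w,
              if (k > 1L) eb_all[k - 1L] + 1L else 1L)
    hi <- min(n, eb + plateau_w,
              if (k < length(i0)) ea_all[k + 1L] - 1L else n)
    amp_abs <- mean(phi_amp[eb:hi]) - mean(phi_amp[lo:ea])
    amp_rel <- mean(diff_amp[eb:hi]) - mean(diff_amp[lo:ea])
    dur_ms <- (b - a + 1L) / fs * 1000
    tibble::tibble(
      start = yaw$t[ea], end = yaw$t[eb],
      start_thresh = yaw$t[a], end_thresh = yaw$t[b],
      duration_ms = dur_ms,
      duration_ext_ms = (eb - ea) / fs * 1000,
      direction = if (mean(omega[a:b]) > 0) "left" else "right",
      amplitude_absolute = abs(amp_abs),
      amplitude_relative = abs(amp_rel),
      peak_velocity = max(abs(omega[ea:eb])),
      mean_velocity = abs(amp_abs) / ((eb - ea) / fs))
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    start = numeric(), end = numeric(), start_thresh = numeric(),
    end_thresh = numeric(), duration_ms = numeric(),
    duration_ext_ms = numeric(), direction = character(),
    amplitude_absolute = numeric(), amplitude_relative = numeric(),
    peak_velocity = numeric(), mean_velocity = numeric())
  out$trial_id <- rep(attr(yaw, "trial_id") %||% NA_character_, nrow(out))
  out$bird_id <- rep(attr(yaw, "bird_id") %||% NA_character_, nrow(out))
  out$flight_id <- rep(attr(yaw, "flight_id") %||% NA_character_, nrow(out))
  out
}

# walk outward from index i (dir = -1 backward, +1 forward) until |omega|
# drops below the floor or hits a local minimum, at most max_ext samples
extend_boundary <- function(i, absw, dir, floor_dps, max_ext) {
  n <- length(absw)
  j <- i
  for (step in seq_len(max_ext)) {
    nxt <- j + dir
    if (nxt < 1L || nxt > n) break
    if (absw[nxt] < floor_dps) { j <- nxt; break }
    if (absw[nxt] >= absw[j]) break   # local minimum of |omega| at j
    j <- nxt
  }
  j
}

#' Saccade summary statistics with flight-to-bird-to-cohort aggregation
#'
#' Metrics (amplitudes, duration, peak and mean velocity) are first
#' summarized per flight, then averaged across flights within a bird, then
#' across birds -- raw events are never pooled across birds.
#'
#' @param events tibble from [detect_saccades()], with `flight_id` and
#'   `bird_id` filled.
#' @param level "flight", "bird" or "cohort".
#' @return tibble of medians and means per metric at the requested level.
#' @export
saccade_statistics <- function(events, level = c("cohort", "bird", "flight")) {
  level <- match.arg(level)
  metrics <- c("amplitude_absolute", "amplitude_relative", "duration_ms",
               "peak_velocity", "mean_velocity")
  ev <- events[!is.na(events$flight_id), ]
  if (nrow(ev) < nrow(events)) warning("events without flight_id dropped")
  if (nrow(ev) == 0) return(tibble::tibble())
  per_flight <- dplyr::summarise(
    dplyr::group_by(ev, .data$bird_id, .data$flight_id),
    n = dplyr::n(),
    dplyr::across(dplyr::all_of(metrics),
                  list(median = stats::median, mean = mean)),
    .groups = "drop")
  if (level == "flight") return(per_flight)
  stat_cols <- setdiff(names(per_flight), c("bird_id", "flight_id", "n"))
  per_bird <- dplyr::summarise(
    dplyr::group_by(per_flight, .data$bird_id),
    n_flights = dplyr::n(), n = sum(.data$n),
    dplyr::across(dplyr::all_of(stat_cols), mean), .groups = "drop")
  if (level == "bird") return(per_bird)
  dplyr::summarise(per_bird, n_birds = dplyr::n(), n = sum(.data$n),
                   dplyr::across(dplyr::all_of(stat_cols), mean))
}

#' Intersaccadic yaw-velocity statistics
#'
#' Distribution summaries of the absolute head yaw velocity |omega| and of
#' the head-relative-to-body velocity |d(phi_diff)/dt| over the complement
#' of the detected saccades (extended boundaries).
#'
#' @param yaw a [compute_yaw()] result.
#' @param events saccades from [detect_saccades()].
#' @return tibble with medians and means of both velocities over
#'   intersaccadic samples, plus the retained sample count.
#' @export
intersaccade_statistics <- function(yaw, events) {
  fs <- attr(yaw, "sample_rate")
  inter <- rep(TRUE, nrow(yaw))
  for (k in seq_len(nrow(events))) {
    inter[yaw$t >= events$start[k] & yaw$t <= events$end[k]] <- FALSE
  }
  if (!any(inter)) {
    return(tibble::tibble(n = 0L, abs_omega_median = NA_real_,
                          abs_omega_mean = NA_real_,
                          rel_omega_median = NA_real_,
                          rel_omega_mean = NA_real_))
  }
  omega_rel <- derivative(yaw$phi_diff, fs)
  tibble::tibble(
    n = sum(inter),
    abs_omega_median = stats::median(abs(yaw$omega[inter])),
    abs_omega_mean = mean(abs(yaw$omega[inter])),
    rel_omega_median = stats::median(abs(omega_rel[inter])),
    rel_omega_mean = mean(abs(omega_rel[inter])))
}

#' Saccade amplitude-duration regression
#'
#' Ordinary least squares of amplitude (deg) on duration (ms); the slope is
#' reported in deg/s (slope per ms times 1000), approximating the preferred
#' average saccadic head speed.
#'
#' @param events saccades with `amplitude_absolute` and `duration_ms`.
#' @param amplitude which amplitude column to regress.
#' @return list(slope_deg_per_s, intercept_deg, r, r_squared, n).
#' @export
amplitude_duration_regression <- function(events,
                                          amplitude = "amplitude_absolute") {
  if (nrow(events) < 2) stop("need at least 2 saccades for the regression")
  x <- events$duration_ms
  y <- events[[amplitude]]
  if (stats::var(x) == 0) stop("degenerate regression: all durations equal")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  list(slope_deg_per_s = unname(stats::coef(fit)[2]) * 1000,
       intercept_deg = unname(stats::coef(fit)[1]),
       r = r,
       r_squared = r^2,
       n = length(x))
}

#' Saccadic fraction of the turn reorientation
#'
#' Sum of absolute saccade amplitudes inside the turn window divided by
#' the absolute net head yaw change over the window, as a percentage, plus
#' the cumulative saccadic-amplitude curve.
#'
#' @param yaw a [compute_yaw()] result.
#' @param events saccades from [detect_saccades()].
#' @param turn_window numeric length-2 (start, end), seconds, usually from
#'   [segment_turn()].
#' @return list(percent, total_turn_deg, saccadic_deg, curve) where
#'   `curve` is a tibble (t, cumulative_percent).
#' @export
saccadic_fraction <- function(yaw, events, turn_window) {
  inw <- yaw$t >= turn_window[1] & yaw$t <= turn_window[2]
  if (!any(inw)) stop("turn window outside the trial")
  total <- yaw$phi_head[max(which(inw))] - yaw$phi_head[min(which(inw))]
  if (abs(total) < 1e-9) {
    warning("zero net reorientation over the turn window; fraction undefined")
    return(list(percent = NA_real_, total_turn_deg = 0,
                saccadic_deg = NA_real_, curve = NULL))
  }
  ev <- events[events$start >= turn_window[1] & events$start <= turn_window[2], ]
  sacc_sum <- sum(ev$amplitude_absolute)
  tt <- yaw$t[inw]
  cum <- vapply(tt, function(ti) {
    sum(ev$amplitude_absolute[ev$end <= ti]) / abs(total) * 100
  }, 0)
  list(percent = sacc_sum / abs(total) * 100,
       total_turn_deg = abs(total), saccadic_deg = sacc_sum,
       curve = tibble::tibble(t = tt, cumulative_percent = cum))
}

#' Wingbeat stroke phase of saccade starts and ends
#'
#' For each saccade boundary, the stroke it falls in (down or up) and the
#' percentage elapsed within that stroke; histograms in 10 percent bins
#' are normalized per bird (each boundary type sums to 1 over its down and
#' up bins) and then averaged across birds. Boundaries are the detection
#' (threshold-crossing) instants: on the smoothed velocity trace these
#' locate the saccade onset with sub-millisecond bias, whereas the
#' amplitude-extended boundaries are systematically early by about the
#' smoothing kernel's half-width.
#'
#' @param events saccades with `bird_id` (and `trial_id` when `beats`
#'   pools several trials).
#' @param beats wingbeat records from [wingbeat_records()]; may pool
#'   multiple trials, in which case boundaries are located within the
#'   beats of their own trial.
#' @return list(phases, histogram): `phases` one row per boundary with
#'   stroke and percent; `histogram` averaged normalized bin heights with
#'   columns boundary (start/end), stroke, bin_left, height.
#' @export
stroke_phase_of_saccades <- function(events, beats) {
  locate <- function(tt, trial) {
    bt <- if ("trial_id" %in% names(beats) && !is.na(trial)) {
      beats[beats$trial_id == trial, ]
    } else {
      beats
    }
    b <- which(bt$down_start <= tt & tt < bt$up_end)
    if (!length(b)) return(c(NA, NA))
    b <- b[1]
    if (tt < bt$down_end[b]) {
      c(1, (tt - bt$down_start[b]) /
          (bt$down_end[b] - bt$down_start[b]) * 100)
    } else {
      c(2, (tt - bt$down_end[b]) /
          (bt$up_end[b] - bt$down_end[b]) * 100)
    }
  }
  rows <- list()
  for (k in seq_len(nrow(events))) {
    for (boundary in c("start", "end")) {
      col <- if (paste0(boundary, "_thresh") %in% names(events)) {
        paste0(boundary, "_thresh")
      } else {
        boundary
      }
      loc <- locate(events[[col]][k], events$trial_id[k])
      rows[[length(rows) + 1]] <- tibble::tibble(
        bird_id = events$bird_id[k], boundary = boundary,
        stroke = c("down", "up", NA)[ifelse(is.na(loc[1]), 3, loc[1])],
        percent = loc[2])
    }
  }
  phases <- dplyr::bind_rows(rows)
  if (anyNA(phases$stroke)) {
    warning(sum(is.na(phases$stroke)), " saccade boundaries outside any ",
            "annotated beat counted as unassigned")
  }
  ph <- phases[!is.na(phases$stroke), ]
  ph$percent <- pmin(ph$percent, 99.999)
  edges <- seq(0, 100, by = 10)
  grid <- expand.grid(stroke = c("down", "up"), bin_left = edges[-11],
                      stringsAsFactors = FALSE)
  per_bird <- dplyr::group_by(ph, .data$bird_id, .data$boundary)
  hist_bird <- dplyr::reframe(per_bird, {
    counts <- table(factor(paste(.data$stroke, floor(.data$percent / 10) * 10),
                           levels = paste(grid$stroke, grid$bin_left)))
    data.frame(stroke = grid$stroke, bin_left = grid$bin_left,
               height = as.numeric(counts) / sum(counts))
  })
  histogram <- dplyr::summarise(
    dplyr::group_by(hist_bird, .data$boundary, .data$stroke, .data$bin_left),
    height = mean(.data$height), .groups = "drop")
  list(phases = phases, histogram = histogram)
}
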