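#' Head and body yaw traces
#'
#' Head yaw is the planform arctangent of the vector connecting the two
#' head markers (posterior to anterior), unwrapped and Whittaker-smoothed
#' with the head penalty. Body yaw is the normal of the shoulder-connecting
#' vector, computed at the sparse wingbeat-related tracking instants,
#' unwrapped, and smoothed-and-interpolated to the full rate in one
#' penalized least-squares pass (gap weights 0). Yaw 0 deg faces away from
#' the perch along the arena's long axis; positive yaw is a left turn.
#'
#' @param rec a [trial_recording()].
#' @param settings a [smoother_settings()].
#' @param check_cve also compute the leave-one-out cross-validation error
#'   per channel and warn when a configured bound is exceeded (slower).
#' @return object of class `yaw_traces`: tibble with columns `t`,
#'   `phi_head`, `phi_body`, `phi_diff` (head minus body), `omega`
#'   (deg/s, derivative of head yaw) and `speed` (m/s, planform
#'   head-position derivative); sample rate and ids in attributes.
#' @export
compute_yaw <- function(rec, settings = smoother_settings(),
                        check_cve = FALSE) {
  stopifnot(inherits(rec, "trial_recording"))
  s <- rec$samples
  fs <- rec$sample_rate
  d <- settings$difference_order

  vx <- s$head_a_x - s$head_p_x
  vy <- s$head_a_y - s$head_p_y
  len <- sqrt(vx^2 + vy^2)
  if (any(len < 1e-12, na.rm = TRUE)) {
    stop("coincident head marker pair at frame ", which(len < 1e-12)[1])
  }
  phi_head_raw <- unwrap_deg(atan2_deg(vy, vx))
  phi_head <- smooth_checked(phi_head_raw, settings$lambda_head, d,
                             settings$cve_head, "head yaw", check_cve)

  obs <- stats::complete.cases(s$shoulder_l_x, s$shoulder_l_y,
                               s$shoulder_r_x, s$shoulder_r_y)
  if (sum(obs) < d + 1) stop("too few shoulder observations for body yaw")
  wx <- s$shoulder_l_x[obs] - s$shoulder_r_x[obs]
  wy <- s$shoulder_l_y[obs] - s$shoulder_r_y[obs]
  wlen <- sqrt(wx^2 + wy^2)
  if (any(wlen < 1e-12)) {
    stop("coincident shoulder pair at frame ", which(obs)[which(wlen < 1e-12)[1]])
  }
  phi_body_sparse <- unwrap_deg(atan2_deg(wy, wx) - 90)
  phi_body_full <- rep(NA_real_, nrow(s))
  phi_body_full[obs] <- phi_body_sparse
  phi_body <- whittaker_smooth(phi_body_full, settings$lambda_body, d = d)
  if (isTRUE(check_cve)) {
    cve_b <- cross_validation_error(phi_body_full, settings$lambda_body, d = d)
    if (cve_b > settings$cve_body) {
      warning(sprintf("cve of body yaw channel (%.3g) exceeds bound %.3g",
                      cve_b, settings$cve_body))
    }
  }
  # align the branch of the unwrapped body trace with the head trace
  offs <- round(mean(phi_head - phi_body) / 360) * 360
  phi_body <- phi_body + offs

  cx <- smooth_checked((s$head_a_x + s$head_p_x) / 2, settings$lambda_coord,
                       d, settings$cve_coord, "head x", check_cve)
  cy <- smooth_checked((s$head_a_y + s$head_p_y) / 2, settings$lambda_coord,
                       d, settings$cve_coord, "head y", check_cve)
  speed <- sqrt(derivative(cx, fs)^2 + derivative(cy, fs)^2)

  out <- tibble::tibble(t = rec$t, phi_head = phi_head, phi_body = phi_body,
                        phi_diff = phi_head - phi_body,
                        phi_head_raw = phi_head_raw,
                        omega = derivative(phi_head, fs), speed = speed,
                        head_x = cx, head_y = cy)
  structure(out, class = c("yaw_traces", class(out)),
            sample_rate = fs, trial_id = rec$trial_id,
            bird_id = rec$bird_id, flight_id = rec$flight_id)
}

#' Per-wingbeat records
#'
#' Builds one record per complete annotated wingbeat: stroke timing,
#' instantaneous frequency f = 1/(up_end - down_start), downstroke/upstroke
#' period ratio, wingbeat-averaged flight speed, stroke amplitude (angle
#' between the most dorsal and most ventral wingtip position, radians) and
#' advance ratio J = V / (2 A f R).
#'
#' @param rec a [trial_recording()] with stroke marks.
#' @param yaw optional [compute_yaw()] result used for the per-beat mean
#'   speed (NULL: speeds and J are NA).
#' @param wing_R root-to-tip wing length, meters.
#' @return tibble of wingbeat records (one row per complete beat).
#' @export
wingbeat_records <- function(rec, yaw = NULL, wing_R = 0.135) {
  sm <- rec$stroke_marks
  if (is.null(sm) || nrow(sm) < 5) stop("trial has no usable stroke marks")
  ds_idx <- which(sm$label == "down_start")
  n_beats <- length(ds_idx) - 1      # complete beats end at the next down_start
  if (n_beats < 1) stop("no complete wingbeat in stroke marks")
  get_mark <- function(b, lab) {
    i <- ds_idx[b] + match(lab, STROKE_LABELS) - 1
    sm$time[i]
  }
  beats <- tibble::tibble(
    index = seq_len(n_beats),
    down_start = vapply(seq_len(n_beats), get_mark, 0, lab = "down_start"),
    down_mid = vapply(seq_len(n_beats), get_mark, 0, lab = "down_mid"),
    down_end = vapply(seq_len(n_beats), get_mark, 0, lab = "down_end"),
    up_mid = vapply(seq_len(n_beats), get_mark, 0, lab = "up_mid"))
  beats$up_end <- sm$time[ds_idx[-1]]
  beats$frequency <- 1 / (beats$up_end - beats$down_start)
  beats$du_ratio <- (beats$down_end - beats$down_start) /
    (beats$up_end - beats$down_end)

  beats$amplitude <- stroke_amplitude(rec, beats)
  beats$mean_speed <- NA_real_
  if (!is.null(yaw)) {
    beats$mean_speed <- vapply(seq_len(n_beats), function(b) {
      inb <- yaw$t >= beats$down_start[b] & yaw$t < beats$up_end[b]
      mean(yaw$speed[inb])
    }, 0)
  }
  beats$advance_ratio <- ifelse(
    is.na(beats$mean_speed) | is.na(beats$amplitude), NA_real_,
    beats$mean_speed / (2 * beats$amplitude * beats$frequency * wing_R))
  beats$trial_id <- rec$trial_id
  beats$bird_id <- rec$bird_id
  beats$flight_id <- rec$flight_id
  beats
}

# stroke angle between dorsal (down_start) and ventral (down_end) wingtip
# positions, measured from the shoulder, averaged over available wings
stroke_amplitude <- function(rec, beats) {
  s <- rec$samples
  t <- rec$t
  ang_one <- function(t_dorsal, t_ventral, wing) {
    i1 <- which.min(abs(t - t_dorsal)); i2 <- which.min(abs(t - t_ventral))
    sh <- paste0("shoulder_", wing, "_"); wt <- paste0("wingtip_", wing, "_")
    u <- c(s[[paste0(wt, "x")]][i1] - s[[paste0(sh, "x")]][i1],
           s[[paste0(wt, "y")]][i1] - s[[paste0(sh, "y")]][i1],
           s[[paste0(wt, "z")]][i1] - s[[paste0(sh, "z")]][i1])
    v <- c(s[[paste0(wt, "x")]][i2] - s[[paste0(sh, "x")]][i2],
           s[[paste0(wt, "y")]][i2] - s[[paste0(sh, "y")]][i2],
           s[[paste0(wt, "z")]][i2] - s[[paste0(sh, "z")]][i2])
    if (anyNA(c(u, v))) return(NA_real_)
    acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1))
  }
  vapply(seq_len(nrow(beats)), function(b) {
    a <- c(ang_one(beats$down_start[b], beats$down_end[b], "l"),
           ang_one(beats$down_start[b], beats$down_end[b], "r"))
    if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE)
  }, 0)
}

#' Advance ratio of a wingbeat
#'
#' J = V / (2 A f R): wingbeat-averaged flight speed over mean wingtip
#' speed. Small J indicates hovering-like flight.
#'
#' @param V wingbeat-averaged flight speed, m/s.
#' @param A stroke amplitude, radians (> 0).
#' @param f wingbeat frequency, Hz (> 0).
#' @param R root-to-tip wing length, meters (> 0).
#' @return dimensionless advance ratio.
#' @export
advance_ratio <- function(V, A, f, R = 0.135) {
  if (any(A <= 0)) stop("stroke amplitude must be positive")
  if (any(f <= 0)) stop("wingbeat frequency must be positive")
  if (any(R <= 0)) stop("wing length must be positive")
  V / (2 * A * f * R)
}

#' Segment a flight into before / during / after turn
#'
#' Uses the planform wingtip positions at mid-downstroke: the heading of
#' the segment between consecutive mid-stroke positions is compared with
#' the pre-turn running heading (circular mean of the first three
#' segments). The turn starts at the first beat whose segment heading
#' deviates by more than `threshold` degrees and ends at the first
#' subsequent beat whose successive segment headings re-align within the
#' threshold.
#'
#' @param rec a [trial_recording()] with >= 5 annotated beats carrying
#'   mid-stroke wingtip positions.
#' @param threshold heading-deflection threshold, degrees.
#' @return list with `t_turn_start`, `t_turn_end` (NA when no turn is
#'   found), `phase` (factor per beat: before_turn / during_turn /
#'   after_turn), `n_turns` (number of disjoint deflection episodes) and
#'   the per-segment headings.
#' @export
segment_turn <- function(rec, threshold = 20) {
  beats <- wingbeat_records(rec)
  if (nrow(beats) < 5) stop("need at least 5 wingbeats to segment the turn")
  s <- rec$samples
  t <- rec$t
  mid_pos <- t(vapply(beats$down_mid, function(tm) {
    i <- which.min(abs(t - tm))
    c(mean(c(s$wingtip_l_x[i], s$wingtip_r_x[i]), na.rm = TRUE),
      mean(c(s$wingtip_l_y[i], s$wingtip_r_y[i]), na.rm = TRUE))
  }, numeric(2)))
  seg <- diff(mid_pos)
  head_deg <- atan2_deg(seg[, 2], seg[, 1])
  n_seg <- length(head_deg)
  ref <- circ_mean_deg(head_deg[1:min(3, n_seg)])
  dev_ref <- abs(wrap180(head_deg - ref))
  dev_succ <- c(0, abs(wrap180(diff(head_deg))))
  phase <- rep("before_turn", nrow(beats))
  k <- which(dev_ref > threshold)[1]
  t_start <- t_end <- NA_real_
  n_turns <- 0L
  if (is.na(k)) {
    warning("no turn deflection found; whole trial labeled before_turn")
  } else {
    m <- k + which(dev_succ[(k + 1):n_seg] <= threshold)[1]
    if (is.na(m)) m <- n_seg + 1L
    # the deviating segment leaves beat k, so the turn is underway at k
    phase[k:nrow(beats)] <- "during_turn"
    if (m <= nrow(beats)) phase[m:nrow(beats)] <- "after_turn"
    t_start <- beats$down_start[k]
    t_end <- if (m <= nrow(beats)) beats$down_start[m] else utils::tail(beats$up_end, 1)
    # count disjoint episodes of successive-heading deflection (a second
    # one violates the single-U-turn inclusion criterion)
    runs <- rle(dev_succ > threshold)
    n_turns <- sum(runs$values)
    if (n_turns > 1) {
      warning("multiple turn episodes detected; single-U-turn assumption violated")
    }
  }
  list(t_turn_start = t_start, t_turn_end = t_end,
       phase = factor(phase, levels = c("before_turn", "during_turn",
                                        "after_turn")),
       n_turns = n_turns, segment_headings = head_deg)
}

#' Flight inclusion filters
#'
#' Evaluates the kinematically implementable inclusion criteria: a single
#' U-turn, altitude change (max minus min of the vertical head coordinate)
#' below 0.21 m, and the bird facing into the initial flight direction
#' within +/- 45 deg before take-off. Camera-coverage, first-attempt
#' landing and mesh-occlusion criteria are video-level and not evaluated.
#'
#' @param rec a [trial_recording()].
#' @param max_altitude_change meters.
#' @param max_heading_dev degrees.
#' @return tibble with columns criterion, pass, detail.
#' @export
flight_filters <- function(rec, max_altitude_change = 0.21,
                           max_heading_dev = 45) {
  z <- (rec$samples$head_a_z + rec$samples$head_p_z) / 2
  alt_change <- max(z, na.rm = TRUE) - min(z, na.rm = TRUE)

  seg <- withCallingHandlers(
    segment_turn(rec), warning = function(w) invokeRestart("muffleWarning"))
  single_turn <- seg$n_turns <= 1

  vx <- rec$samples$head_a_x - rec$samples$head_p_x
  vy <- rec$samples$head_a_y - rec$samples$head_p_y
  facing0 <- atan2_deg(vy[1], vx[1])
  n0 <- min(length(rec$t), ceiling(0.1 * rec$sample_rate))
  cx <- (rec$samples$head_a_x + rec$samples$head_p_x) / 2
  cy <- (rec$samples$head_a_y + rec$samples$head_p_y) / 2
  path_dir <- atan2_deg(cy[n0] - cy[1], cx[n0] - cx[1])
  heading_dev <- abs(wrap180(facing0 - path_dir))

  tibble::tibble(
    criterion = c("single_u_turn", "altitude_change", "takeoff_heading"),
    pass = c(single_turn, alt_change < max_altitude_change,
             heading_dev <= max_heading_dev),
    detail = c(sprintf("%d turn episode(s)", seg$n_turns),
               sprintf("%.3f m (limit %.2f)", alt_change, max_altitude_change),
               sprintf("%.1f deg off flight direction (limit %.0f)",
                       heading_dev, max_heading_dev)))
}
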