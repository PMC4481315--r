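#' Synthetic trial configuration
#'
#' Fully explicit recipe for one synthetic flight: every injected event is
#' known, so each downstream stage has a parameter-recovery test surface.
#' Head yaw is built as `drift_gain * body_profile + sum of saccade steps`,
#' each saccade a raised-cosine velocity bump (zero velocity and
#' acceleration at its endpoints, amplitude = peak * duration / 2). By
#' default `drift_gain` is chosen so head and body end the turn aligned,
#' i.e. the smooth ("body-carried") drift supplies whatever reorientation
#' the saccades do not.
#'
#' @param seed integer seed consumed by [generate_trial()].
#' @param sample_rate Hz (nominal 2000).
#' @param duration trial length, seconds.
#' @param path_type "uturn" (take off, turn on a dime, return) or
#'   "approach" (straight decelerating flight towards the perch, used for
#'   landing-cue cohorts).
#' @param turn_direction "left" (positive yaw) or "right".
#' @param body_turn list(t_start, t_end, total): smooth raised-cosine body
#'   yaw ramp of `total` degrees (sign applied from `turn_direction`).
#' @param saccade_schedule data frame with columns start (s),
#'   amplitude (deg, signed), duration (s); non-overlapping. NULL for none.
#' @param wingbeat_plan data frame with columns mode ("normal" or
#'   "intermittent"), frequency (Hz), du_ratio (downstroke/upstroke period
#'   ratio); one row per beat, truncated to the trial duration.
#' @param speeds for "uturn": list(v_out, v_turn, v_in) m/s with smooth
#'   ramps at the turn boundaries; for "approach": list(v0, v1), a smooth
#'   deceleration across the trial.
#' @param start_pos planform start position c(x, y), meters.
#' @param altitude list(z0, amp): head height z0 plus a half-sine bump of
#'   `amp` meters across the trial.
#' @param perch_swing list(amp_fore, amp_side, period, phase): fore-aft
#'   (x) and sideways (y) perch oscillation, meters / seconds / radians.
#'   Defaults 0.10 m fore-aft, 0.01 m sideways.
#' @param noise_sd i.i.d. Gaussian tracking noise added to every observed
#'   marker coordinate, meters (default 0.0013).
#' @param landing list(mode = "none" | "alpha_threshold" | "time", ...):
#'   landing initiation absent, triggered at the first frame where the
#'   perch's azimuthal extent alpha exceeds `alpha_threshold` degrees, or
#'   fixed at `time` seconds.
#' @param drift_gain smooth head-drift gain; NULL (default) solves for the
#'   gain that aligns head and body at the end of the turn.
#' @param geometry an [arena_geometry()].
#' @param head_sep,shoulder_sep anterior-posterior head marker separation
#'   and shoulder separation, meters.
#' @param wing_R root-to-tip wing length, meters (0.1262-0.1403 typical).
#' @param stroke_amp wingbeat amplitude, radians (most dorsal to most
#'   ventral wingtip).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, sample_rate = 2000, duration = 1.15,
                         path_type = c("uturn", "approach"),
                         turn_direction = c("left", "right"),
                         body_turn = list(t_start = 0.35, t_end = 0.75,
                                          total = 180),
                         saccade_schedule = NULL,
                         wingbeat_plan = NULL,
                         speeds = NULL,
                         start_pos = NULL,
                         altitude = list(z0 = 0.45, amp = 0.05),
                         perch_swing = list(amp_fore = 0.10, amp_side = 0.01,
                                            period = 1.2, phase = 0),
                         noise_sd = 0.0013,
                         landing = list(mode = "none"),
                         drift_gain = NULL,
                         geometry = arena_geometry(),
                         head_sep = 0.028, shoulder_sep = 0.05,
                         wing_R = 0.135, stroke_amp = 1.9) {
  path_type <- match.arg(path_type)
  turn_direction <- match.arg(turn_direction)
  if (is.null(wingbeat_plan)) wingbeat_plan <- default_wingbeat_plan(duration)
  if (any(wingbeat_plan$frequency <= 0)) stop("wingbeat frequencies must be positive")
  if (any(wingbeat_plan$du_ratio <= 0)) stop("du_ratio must be positive")
  if (is.null(speeds)) {
    speeds <- if (path_type == "uturn") {
      list(v_out = 1.05, v_turn = 0.51, v_in = 1.03)
    } else {
      list(v0 = 1.0, v1 = 0.45)
    }
  }
  if (is.null(start_pos)) {
    pc <- geometry$features["perch_center", ]
    start_pos <- if (path_type == "uturn") {
      c(pc[["x"]] + 0.08, pc[["y"]])
    } else {
      c(pc[["x"]] + 0.75, pc[["y"]])
    }
  }
  if (path_type == "approach") body_turn$total <- 0
  if (is.null(saccade_schedule) && path_type == "uturn") {
    saccade_schedule <- default_saccade_schedule(wingbeat_plan, body_turn)
  }
  if (!is.null(saccade_schedule) && nrow(saccade_schedule) > 1) {
    ss <- saccade_schedule[order(saccade_schedule$start), ]
    if (any(ss$start[-1] < ss$start[-nrow(ss)] + ss$duration[-nrow(ss)])) {
      stop("config error: overlapping saccades in schedule")
    }
  }
  structure(list(seed = as.integer(seed), sample_rate = sample_rate,
                 duration = duration, path_type = path_type,
                 turn_direction = turn_direction, body_turn = body_turn,
                 saccade_schedule = saccade_schedule,
                 wingbeat_plan = wingbeat_plan, speeds = speeds,
                 start_pos = start_pos, altitude = altitude,
                 perch_swing = perch_swing, noise_sd = noise_sd,
                 landing = landing, drift_gain = drift_gain,
                 geometry = geometry, head_sep = head_sep,
                 shoulder_sep = shoulder_sep, wing_R = wing_R,
                 stroke_amp = stroke_amp),
            class = "synth_config")
}

#' Default wingbeat plan
#'
#' Alternating blocks of normal (17 Hz, down/up ratio 1.35) and occasional
#' intermittent (9.5 Hz, ratio 0.53) beats, enough to fill `duration`.
#'
#' @param duration seconds to fill.
#' @param f_normal,f_intermittent mode frequencies, Hz.
#' @param r_normal,r_intermittent mode down/up period ratios.
#' @param intermittent_every insert one intermittent beat after this many
#'   normal beats (0 = never).
#' @return data frame with columns mode, frequency, du_ratio.
#' @export
default_wingbeat_plan <- function(duration, f_normal = 17,
                                  f_intermittent = 9.5,
                                  r_normal = 1.35, r_intermittent = 0.53,
                                  intermittent_every = 5) {
  n_max <- ceiling(duration * f_normal) + 2
  mode <- rep("normal", n_max)
  if (intermittent_every > 0) {
    mode[seq_along(mode) %% (intermittent_every + 1) == 0] <- "intermittent"
  }
  tibble::tibble(
    mode = mode,
    frequency = ifelse(mode == "normal", f_normal, f_intermittent),
    du_ratio = ifelse(mode == "normal", r_normal, r_intermittent))
}

# beat boundary / stroke-mark times implied by a wingbeat plan
plan_stroke_marks <- function(plan, duration) {
  t0 <- 0
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    period <- 1 / plan$frequency[i]
    if (t0 + period > duration) break
    dd <- period * plan$du_ratio[i] / (1 + plan$du_ratio[i])
    rows[[i]] <- tibble::tibble(
      beat = i,
      time = t0 + c(0, dd / 2, dd, dd + (period - dd) / 2),
      label = STROKE_LABELS)
    t0 <- t0 + period
  }
  if (!length(rows)) stop("config error: no complete wingbeat fits the duration")
  dplyr::bind_rows(rows)
}

#' Default saccade schedule tied to the downstroke
#'
#' Places one leftward saccade at 75 percent of the downstroke of every
#' wingbeat whose downstroke lies inside the body-turn window, sizing the
#' saccades so that together they carry `sacc_fraction` of the total turn.
#' Durations follow the amplitude-duration main sequence
#' amplitude = 1.5 deg/ms * duration - 14 deg.
#'
#' @param wingbeat_plan,body_turn as in [synth_config()].
#' @param sacc_fraction fraction of the turn carried saccadically.
#' @param stroke_frac position within the downstroke (0-1).
#' @return data frame start / amplitude / duration.
#' @export
default_saccade_schedule <- function(wingbeat_plan, body_turn,
                                     sacc_fraction = 0.7625,
                                     stroke_frac = 0.75) {
  marks <- plan_stroke_marks(wingbeat_plan, Inf)
  starts <- numeric(0)
  for (b in unique(marks$beat)) {
    m <- marks[marks$beat == b, ]
    ds <- m$time[m$label == "down_start"]
    de <- m$time[m$label == "down_end"]
    t_sac <- ds + stroke_frac * (de - ds)
    if (t_sac >= body_turn$t_start && t_sac <= body_turn$t_end) {
      starts <- c(starts, t_sac)
    }
  }
  if (!length(starts)) stop("config error: no downstroke inside the turn window")
  amp <- sacc_fraction * abs(body_turn$total) / length(starts)
  dur <- (amp + 14) / 1.5 / 1000
  tibble::tibble(start = starts, amplitude = amp, duration = dur)
}

# raised-cosine step: displacement fraction completed at phase u in [0,1]
raised_cosine_step <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u - sin(2 * pi * u) / (2 * pi)
}

# smooth trapezoidal body turn: cosine velocity ramps into a constant-rate
# plateau, mirroring the steady body rotation seen during the maneuver
body_turn_profile <- function(t, t1, t2, total, ramp_frac = 0.1) {
  if (total == 0) return(numeric(length(t)))
  ramp <- ramp_frac * (t2 - t1)
  q <- numeric(length(t))
  up <- t >= t1 & t < t1 + ramp
  plat <- t >= t1 + ramp & t <= t2 - ramp
  down <- t > t2 - ramp & t <= t2
  q[up] <- (1 - cos(pi * (t[up] - t1) / ramp)) / 2
  q[plat] <- 1
  q[down] <- (1 - cos(pi * (t2 - t[down]) / ramp)) / 2
  b <- cumsum(q)
  after <- t > t2
  b[after] <- b[which(after)[1] - 1]
  total * b / max(b)
}

#' Generate one synthetic trial
#'
#' Deterministic given the config (the config's `seed` drives the only
#' random element, the marker noise). Marker pairs are placed so that the
#' planform arctangent of their difference reproduces the configured yaw
#' exactly before noise.
#'
#' @param cfg a [synth_config()].
#' @param trial_id,bird_id,flight_id ids stamped on the recording.
#' @return list with elements `rec` (a [trial_recording()]) and `truth`
#'   (ground truth: true yaw traces, injected saccades with peak
#'   velocities, beat table with mode labels, turn window, drift gain,
#'   speed and alpha series, landing time).
#' @export
generate_trial <- function(cfg, trial_id = "synth", bird_id = "b1",
                           flight_id = trial_id) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  fs <- cfg$sample_rate
  t <- seq(0, cfg$duration, by = 1 / fs)
  n <- length(t)
  sgn <- if (cfg$turn_direction == "left") 1 else -1

  # --- body yaw profile ---------------------------------------------------
  bt <- cfg$body_turn
  phi_body <- if (cfg$path_type == "approach") {
    rep(180, n)
  } else {
    sgn * body_turn_profile(t, bt$t_start, bt$t_end, bt$total)
  }

  # --- saccade steps and head yaw -----------------------------------------
  ss <- cfg$saccade_schedule
  sacc_sum <- numeric(n)
  if (!is.null(ss) && nrow(ss) > 0) {
    for (k in seq_len(nrow(ss))) {
      amp <- sgn * abs(ss$amplitude[k])
      sacc_sum <- sacc_sum +
        amp * raised_cosine_step((t - ss$start[k]) / ss$duration[k])
    }
  }
  drift_gain <- cfg$drift_gain
  if (is.null(drift_gain)) {
    total_body <- if (cfg$path_type == "approach") 0 else sgn * bt$total
    total_sacc <- if (is.null(ss)) 0 else sum(sgn * abs(ss$amplitude))
    drift_gain <- if (total_body == 0) 1 else {
      max(0, (total_body - total_sacc) / total_body)
    }
  }
  phi_head <- drift_gain * phi_body + sacc_sum

  # --- speed profile and planform path ------------------------------------
  v <- speed_profile(cfg, t)
  hv <- heading_vec(phi_body)
  dt <- 1 / fs
  px <- cfg$start_pos[1] + cumsum(c(0, (v * hv[, 1])[-n])) * dt
  py <- cfg$start_pos[2] + cumsum(c(0, (v * hv[, 2])[-n])) * dt
  lim_x <- c(0, cfg$geometry$length); lim_y <- c(0, cfg$geometry$width)
  if (any(px < lim_x[1] | px > lim_x[2] | py < lim_y[1] | py > lim_y[2])) {
    stop("config error: flight path leaves the arena")
  }
  pz <- cfg$altitude$z0 + cfg$altitude$amp * sin(pi * t / cfg$duration)

  # --- stroke marks, beats, sparse channels -------------------------------
  marks <- plan_stroke_marks(cfg$wingbeat_plan, cfg$duration)
  mark_idx <- pmin(pmax(round(marks$time * fs) + 1L, 1L), n)
  marks$time <- t[mark_idx]          # snap marks onto the sample grid

  u_head <- heading_vec(phi_head)
  head_a <- cbind(px, py) + cfg$head_sep / 2 * u_head
  head_p <- cbind(px, py) - cfg$head_sep / 2 * u_head
  u_left <- heading_vec(phi_body + 90)
  sh_l_full <- cbind(px, py) + cfg$shoulder_sep / 2 * u_left
  sh_r_full <- cbind(px, py) - cfg$shoulder_sep / 2 * u_left

  samples <- tibble::tibble(
    head_a_x = head_a[, 1], head_a_y = head_a[, 2], head_a_z = pz,
    head_p_x = head_p[, 1], head_p_y = head_p[, 2], head_p_z = pz,
    shoulder_l_x = NA_real_, shoulder_l_y = NA_real_, shoulder_l_z = NA_real_,
    shoulder_r_x = NA_real_, shoulder_r_y = NA_real_, shoulder_r_z = NA_real_,
    wingtip_l_x = NA_real_, wingtip_l_y = NA_real_, wingtip_l_z = NA_real_,
    wingtip_r_x = NA_real_, wingtip_r_y = NA_real_, wingtip_r_z = NA_real_)
  samples$shoulder_l_x[mark_idx] <- sh_l_full[mark_idx, 1]
  samples$shoulder_l_y[mark_idx] <- sh_l_full[mark_idx, 2]
  samples$shoulder_l_z[mark_idx] <- pz[mark_idx]
  samples$shoulder_r_x[mark_idx] <- sh_r_full[mark_idx, 1]
  samples$shoulder_r_y[mark_idx] <- sh_r_full[mark_idx, 2]
  samples$shoulder_r_z[mark_idx] <- pz[mark_idx]

  # wingtip stroke angle at the four instants: dorsal, mid, ventral, mid
  theta_at <- c(down_start = 1, down_mid = 0, down_end = -1, up_mid = 0) *
    cfg$stroke_amp / 2
  th <- theta_at[marks$label]
  wl <- sh_l_full[mark_idx, ] + cfg$wing_R * cos(th) * u_left[mark_idx, ]
  wr <- sh_r_full[mark_idx, ] - cfg$wing_R * cos(th) * u_left[mark_idx, ]
  samples$wingtip_l_x[mark_idx] <- wl[, 1]
  samples$wingtip_l_y[mark_idx] <- wl[, 2]
  samples$wingtip_l_z[mark_idx] <- pz[mark_idx] + cfg$wing_R * sin(th)
  samples$wingtip_r_x[mark_idx] <- wr[, 1]
  samples$wingtip_r_y[mark_idx] <- wr[, 2]
  samples$wingtip_r_z[mark_idx] <- pz[mark_idx] + cfg$wing_R * sin(th)

  # --- swinging perch track -----------------------------------------------
  pswing <- cfg$perch_swing
  pc <- cfg$geometry$features["perch_center", ]
  samples$perch_x <- pc[["x"]] +
    pswing$amp_fore * sin(2 * pi * t / pswing$period + pswing$phase)
  samples$perch_y <- pc[["y"]] +
    pswing$amp_side * sin(2 * pi * t / pswing$period + pswing$phase + pi / 3)

  # --- landing initiation --------------------------------------------------
  alpha_true <- perch_alpha(px, py, phi_head, samples$perch_x, samples$perch_y,
                            cfg$geometry$perch_width)
  landing_time <- NULL
  if (cfg$landing$mode == "time") {
    landing_time <- cfg$landing$time
  } else if (cfg$landing$mode == "alpha_threshold") {
    hit <- which(alpha_true >= cfg$landing$alpha_threshold)
    if (!length(hit)) stop("config error: alpha never reaches the landing threshold")
    landing_time <- t[hit[1]]
  }

  # --- tracking noise ------------------------------------------------------
  if (cfg$noise_sd > 0) {
    for (col in MARKER_COLS) {
      obs <- !is.na(samples[[col]])
      samples[[col]][obs] <- samples[[col]][obs] +
        stats::rnorm(sum(obs), 0, cfg$noise_sd)
    }
  }

  rec <- trial_recording(trial_id = trial_id, t = t, samples = samples,
                         sample_rate = fs,
                         stroke_marks = marks[, c("time", "label")],
                         landing_init_time = landing_time,
                         bird_id = bird_id, flight_id = flight_id)

  beats <- true_beat_table(marks, cfg$wingbeat_plan)
  sacc_truth <- NULL
  if (!is.null(ss) && nrow(ss) > 0) {
    sacc_truth <- tibble::tibble(
      start = ss$start, end = ss$start + ss$duration,
      amplitude = abs(ss$amplitude), duration_ms = ss$duration * 1000,
      peak_velocity = 2 * abs(ss$amplitude) / ss$duration,
      direction = if (sgn > 0) "left" else "right")
  }
  truth <- list(t = t, phi_head = phi_head, phi_body = phi_body,
                drift_gain = drift_gain, saccades = sacc_truth,
                beats = beats, speed = v,
                turn_window = if (cfg$path_type == "uturn") {
                  c(bt$t_start, bt$t_end)
                },
                alpha = alpha_true, landing_init_time = landing_time,
                position = cbind(x = px, y = py, z = pz))
  list(rec = rec, truth = truth)
}

speed_profile <- function(cfg, t) {
  s <- cfg$speeds
  if (cfg$path_type == "approach") {
    return(s$v0 + (s$v1 - s$v0) * raised_cosine_step(t / cfg$duration))
  }
  bt <- cfg$body_turn
  ramp <- 0.06
  blend <- function(v_from, v_to, t0) {
    v_from + (v_to - v_from) * raised_cosine_step((t - t0 + ramp / 2) / ramp)
  }
  v <- blend(s$v_out, s$v_turn, bt$t_start)
  v + (blend(s$v_turn, s$v_in, bt$t_end) - s$v_turn)
}

# azimuthal extent of the perch (difference of edge azimuths), degrees
perch_alpha <- function(px, py, phi_head, perch_x, perch_y, perch_width) {
  az_l <- wrap180(atan2_deg(perch_y - perch_width / 2 - py, perch_x - px) - phi_head)
  az_r <- wrap180(atan2_deg(perch_y + perch_width / 2 - py, perch_x - px) - phi_head)
  abs(wrap180(az_r - az_l))
}

true_beat_table <- function(marks, plan) {
  beats <- unique(marks$beat)
  tibble::tibble(
    index = beats,
    mode = plan$mode[beats],
    frequency = plan$frequency[beats],
    du_ratio = plan$du_ratio[beats],
    down_start = vapply(beats, function(b) {
      marks$time[marks$beat == b & marks$label == "down_start"]
    }, 0))
}

#' Generate a cohort of randomized synthetic trials
#'
#' Draws `n_trials` trials around a template config: per-beat wingbeat
#' modes from a two-mode mixture, per-beat frequencies and down/up ratios
#' from the mode distributions, saccade amplitudes and timing jittered,
#' straight/turn speeds jittered, and the perch swing phase randomized.
#' Trials are assigned round-robin to `n_birds` birds.
#'
#' @param n_trials number of trials (>= 1).
#' @param template a [synth_config()] used as the base recipe.
#' @param seed integer master seed; per-trial seeds are derived from it.
#' @param n_birds number of bird ids to cycle through.
#' @param mode_params two-mode mixture parameters:
#'   list(freq_mu, freq_sigma, ratio_mu, ratio_sigma (each length 2,
#'   intermittent first), weight_intermittent).
#' @param sacc_amp_sd jitter SD on saccade amplitudes, degrees.
#' @param speed_jitter multiplicative speed jitter SD.
#' @return list of per-trial lists (elements `rec`, `truth`) with the
#'   cohort-level ground truth in attribute `cohort_truth`.
#' @export
generate_cohort <- function(n_trials, template = synth_config(), seed = 1L,
                            n_birds = 5,
                            mode_params = list(
                              freq_mu = c(9.5, 17), freq_sigma = c(0.5, 0.9),
                              ratio_mu = c(0.53, 1.35),
                              ratio_sigma = c(0.06, 0.11),
                              weight_intermittent = 0.25),
                            sacc_amp_sd = 5, speed_jitter = 0.1) {
  stopifnot(n_trials >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cfg <- randomize_config(template, mode_params, sacc_amp_sd, speed_jitter,
                            seed = (seed %% 10000L) * 131L + i)
    trials[[i]] <- generate_trial(
      cfg, trial_id = sprintf("synth_%02d", i),
      bird_id = sprintf("b%d", (i - 1) %% n_birds + 1),
      flight_id = sprintf("f%02d", i))
  }
  attr(trials, "cohort_truth") <- list(mode_params = mode_params,
                                       template = template, seed = seed)
  trials
}

randomize_config <- function(template, mp, sacc_amp_sd, speed_jitter, seed) {
  dur <- template$duration
  # wingbeat plan: modes i.i.d. from the mixture, parameters per mode
  n_max <- ceiling(dur * max(mp$freq_mu)) + 2
  is_int <- stats::runif(n_max) < mp$weight_intermittent
  comp <- ifelse(is_int, 1L, 2L)
  freq <- pmax(stats::rnorm(n_max, mp$freq_mu[comp], mp$freq_sigma[comp]), 2)
  ratio <- pmax(stats::rnorm(n_max, mp$ratio_mu[comp], mp$ratio_sigma[comp]), 0.1)
  plan <- tibble::tibble(
    mode = ifelse(is_int, "intermittent", "normal"),
    frequency = freq, du_ratio = ratio)
  sp <- lapply(template$speeds,
               function(v) v * exp(stats::rnorm(1, 0, speed_jitter)))
  cfg <- synth_config(
    seed = seed, sample_rate = template$sample_rate, duration = dur,
    path_type = template$path_type, turn_direction = template$turn_direction,
    body_turn = template$body_turn, saccade_schedule = NULL,
    wingbeat_plan = plan, speeds = sp, start_pos = template$start_pos,
    altitude = template$altitude,
    perch_swing = utils::modifyList(template$perch_swing,
                                    list(phase = stats::runif(1, 0, 2 * pi))),
    noise_sd = template$noise_sd, landing = template$landing,
    drift_gain = template$drift_gain, geometry = template$geometry,
    head_sep = template$head_sep, shoulder_sep = template$shoulder_sep,
    wing_R = template$wing_R, stroke_amp = template$stroke_amp)
  # jitter saccade amplitudes while keeping the saccadic share of the turn
  ss <- cfg$saccade_schedule
  if (!is.null(ss) && nrow(ss) > 0) {
    amp <- pmax(ss$amplitude + stats::rnorm(nrow(ss), 0, sacc_amp_sd), 15)
    amp <- amp * sum(ss$amplitude) / sum(amp)
    ss$amplitude <- amp
    ss$duration <- (amp + 14) / 1.5 / 1000
    # re-check overlap after duration change; shrink durations if needed
    if (nrow(ss) > 1) {
      gap <- diff(ss$start)
      ss$duration[-nrow(ss)] <- pmin(ss$duration[-nrow(ss)], gap * 0.9)
    }
    cfg$saccade_schedule <- ss
  }
  cfg
}
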