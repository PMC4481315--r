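#' Optical landing-cue series for one trial
#'
#' Computes, per frame and re-indexed to time relative to landing
#' initiation (the annotated tail-pitch instant, t_rel = 0):
#' alpha, the azimuthal retinal extent of the perch (difference of the
#' left and right perch-edge azimuths, degrees); Omega = d(alpha)/dt
#' (deg/s, derivative of the Whittaker-smoothed alpha); RREV = Omega /
#' alpha (1/s); tau = alpha / Omega (s, masked where Omega is ~0);
#' absolute horizontal flight speed; and flight speed relative to the
#' (possibly swinging) perch center.
#'
#' @param rec a [trial_recording()] with `landing_init_time`.
#' @param geometry an [arena_geometry()].
#' @param settings smoother settings; alpha is smoothed with the
#'   coordinate-grade penalty before differentiation.
#' @param downsample integer decimation factor applied to alpha (and the
#'   position channels) before any derivative, emulating a lower
#'   acquisition rate; 1 = native rate.
#' @param smooth_alpha smooth alpha before differentiation (default TRUE).
#' @return tibble of class `landing_cue_series`: t_rel, alpha, omega_exp,
#'   rrev, tau, speed_abs, speed_rel, trial_id; only samples at or before
#'   landing initiation are returned.
#' @export
landing_cue_series <- function(rec, geometry = arena_geometry(),
                               settings = smoother_settings(),
                               downsample = 1L, smooth_alpha = TRUE) {
  if (is.null(rec$landing_init_time)) {
    stop("trial has no landing_init_time annotation")
  }
  if (downsample < 1 || downsample != round(downsample)) {
    stop("downsample must be a positive integer factor")
  }
  yaw <- compute_yaw(rec, settings)
  pt <- if (!is.null(rec$samples$perch_x)) {
    cbind(rec$samples$perch_x, rec$samples$perch_y)
  } else {
    matrix(geometry$features["perch_center", ], nrow(yaw), 2, byrow = TRUE)
  }
  keep <- seq(1, nrow(yaw), by = downsample)
  fs <- rec$sample_rate / downsample
  t <- yaw$t[keep]
  hx <- yaw$head_x[keep]; hy <- yaw$head_y[keep]
  phi <- yaw$phi_head[keep]
  px <- pt[keep, 1]; py <- pt[keep, 2]

  alpha_raw <- perch_alpha(hx, hy, phi, px, py, geometry$perch_width)
  alpha <- if (smooth_alpha) {
    whittaker_smooth(alpha_raw, settings$lambda_coord,
                     d = settings$difference_order)
  } else {
    alpha_raw
  }
  omega_exp <- derivative(alpha, fs)
  rrev <- ifelse(alpha > 0, omega_exp / alpha, NA_real_)
  tau <- ifelse(abs(omega_exp) > 1e-9, alpha / omega_exp, NA_real_)

  speed_abs <- sqrt(derivative(hx, fs)^2 + derivative(hy, fs)^2)
  relx <- hx - px; rely <- hy - py
  # closing speed on the perch: magnitude of the relative velocity
  speed_rel <- sqrt(derivative(relx, fs)^2 + derivative(rely, fs)^2)

  out <- tibble::tibble(
    t_rel = t - rec$landing_init_time, alpha = alpha,
    omega_exp = omega_exp, rrev = rrev, tau = tau,
    speed_abs = speed_abs, speed_rel = speed_rel,
    trial_id = rec$trial_id, bird_id = rec$bird_id)
  out <- out[out$t_rel <= 1e-12, ]
  structure(out, class = c("landing_cue_series", class(out)),
            sample_rate = fs)
}

LANDING_PARAMS <- c("alpha", "omega_exp", "rrev", "tau",
                    "speed_abs", "speed_rel")

#' Coefficient-of-variation parsimony analysis of landing cues
#'
#' For each optical parameter and each time step on a common grid before
#' landing initiation, the c.v. is the SD across trials divided by the
#' mean across trials. The parameter with the lowest window-mean c.v. is
#' the most parsimonious landing trigger. The last `viz_band_ms` before
#' initiation (visuomotor delay) are annotated, not excluded.
#'
#' @param cohort list of [landing_cue_series()] (>= 3 trials).
#' @param window_ms analysis window start before initiation, ms.
#' @param viz_band_ms visuomotor-delay annotation band, ms.
#' @param grid_hz resolution of the common t_rel grid.
#' @return list of class `cv_table`: `cv` (tibble t_rel x parameter),
#'   `mean_cv` (window-mean per parameter), `most_parsimonious`,
#'   `viz_band` (seconds).
#' @export
cv_analysis <- function(cohort, window_ms = 85, viz_band_ms = 30,
                        grid_hz = 1000) {
  if (length(cohort) < 3) stop("need at least 3 trials for the c.v. analysis")
  grid <- seq(-window_ms / 1000, 0, by = 1 / grid_hz)
  vals <- lapply(LANDING_PARAMS, function(p) {
    sapply(cohort, function(s) {
      stats::approx(s$t_rel, s[[p]], xout = grid, rule = 1)$y
    })
  })
  names(vals) <- LANDING_PARAMS
  cv <- tibble::tibble(t_rel = grid)
  for (p in LANDING_PARAMS) {
    m <- rowMeans(vals[[p]], na.rm = TRUE)
    sdev <- apply(vals[[p]], 1, stats::sd, na.rm = TRUE)
    cvp <- sdev / abs(m)
    cvp[abs(m) < 1e-9] <- NA_real_    # c.v. undefined at near-zero mean
    cv[[p]] <- cvp
  }
  mean_cv <- vapply(LANDING_PARAMS,
                    function(p) mean(cv[[p]], na.rm = TRUE), 0)
  structure(list(cv = cv, mean_cv = mean_cv,
                 most_parsimonious = names(which.min(mean_cv)),
                 viz_band = c(-viz_band_ms / 1000, 0)),
            class = "cv_table")
}

#' Robustness of the c.v. ranking to temporal downsampling
#'
#' Recomputes every trial's landing-cue series with alpha decimated to
#' `rate` Hz before differentiation, reruns the c.v. analysis, and
#' reports the rank correlation of the parameter ordering against the
#' full-rate analysis.
#'
#' @param recs list of [trial_recording()]s with landing annotations.
#' @param rate target rate, Hz; must divide the native rate.
#' @param geometry,settings,window_ms,viz_band_ms as above.
#' @return list: `cv_full`, `cv_down` (both `cv_table`), `rate`,
#'   `rank_correlation` (Spearman, parameter mean-c.v. orderings),
#'   `winner_unchanged`.
#' @export
downsample_check <- function(recs, rate, geometry = arena_geometry(),
                             settings = smoother_settings(),
                             window_ms = 85, viz_band_ms = 30) {
  fs <- recs[[1]]$sample_rate
  if (rate > fs) stop("downsample rate exceeds the native rate")
  if (fs %% rate != 0) stop("rate must divide the native sample rate")
  fac <- fs / rate
  full <- lapply(recs, landing_cue_series, geometry = geometry,
                 settings = settings)
  down <- lapply(recs, landing_cue_series, geometry = geometry,
                 settings = settings, downsample = fac)
  cv_full <- cv_analysis(full, window_ms, viz_band_ms)
  cv_down <- cv_analysis(down, window_ms, viz_band_ms,
                         grid_hz = min(1000, rate))
  rho <- stats::cor(rank(cv_full$mean_cv), rank(cv_down$mean_cv),
                    method = "spearman")
  list(cv_full = cv_full, cv_down = cv_down, rate = rate,
       rank_correlation = rho,
       winner_unchanged = identical(cv_full$most_parsimonious,
                                    cv_down$most_parsimonious))
}
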