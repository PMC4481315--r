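#' Trial recording
#'
#' Container for one flight's raw kinematic time series plus annotations.
#' Positions are in meters, time in seconds. Head markers (anterior `head_a`,
#' posterior `head_p`) are tracked at the full sample rate; shoulders and
#' wingtips may be sparse (NA except at the four wingbeat-related tracking
#' instants). `stroke_marks` lists the four annotated instants per wingbeat
#' in the legal cyclic order down_start, down_mid, down_end, up_mid.
#'
#' @param trial_id character id.
#' @param t time stamps, seconds, strictly increasing, near-uniform
#'   (sample intervals constant within 1 percent).
#' @param samples data frame with columns `<marker>_<axis>` for markers
#'   head_a, head_p, shoulder_l, shoulder_r, wingtip_l, wingtip_r and axes
#'   x, y, z; optionally `perch_x`, `perch_y` (planform track of the
#'   swinging perch center).
#' @param sample_rate nominal rate, Hz.
#' @param stroke_marks data frame with columns `time` (s) and `label`
#'   (down_start / down_mid / down_end / up_mid), or NULL.
#' @param landing_init_time tail-pitch instant, seconds, or NULL.
#' @param bird_id,flight_id optional grouping ids used by cohort summaries.
#' @return object of class `trial_recording`.
#' @export
trial_recording <- function(trial_id, t, samples, sample_rate,
                            stroke_marks = NULL, landing_init_time = NULL,
                            bird_id = NA_character_, flight_id = NA_character_) {
  rec <- structure(list(trial_id = trial_id, t = as.numeric(t),
                        samples = tibble::as_tibble(samples),
                        sample_rate = sample_rate,
                        stroke_marks = stroke_marks,
                        landing_init_time = landing_init_time,
                        bird_id = bird_id, flight_id = flight_id),
                   class = "trial_recording")
  validate_trial(rec)
}

STROKE_LABELS <- c("down_start", "down_mid", "down_end", "up_mid")

validate_trial <- function(rec) {
  t <- rec$t
  if (nrow(rec$samples) != length(t)) {
    stop("validation error: samples and t differ in length")
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("validation error: time stamps not strictly increasing (row ",
         which(dt <= 0)[1] + 1, ")")
  }
  if (length(dt) > 1 && (max(dt) - min(dt)) > 0.01 * stats::median(dt)) {
    stop("validation error: sample intervals vary by more than 1%")
  }
  num <- vapply(rec$samples, is.numeric, logical(1))
  if (!all(num)) stop("validation error: non-numeric sample column")
  bad_inf <- vapply(rec$samples, function(col) any(is.infinite(col)), logical(1))
  if (any(bad_inf)) {
    stop("validation error: non-finite position in column ",
         names(bad_inf)[bad_inf][1])
  }
  sm <- rec$stroke_marks
  if (!is.null(sm) && nrow(sm) > 0) {
    if (!all(sm$label %in% STROKE_LABELS)) {
      stop("validation error: unknown stroke label")
    }
    if (any(diff(sm$time) <= 0)) {
      stop("validation error: stroke mark times not increasing")
    }
    idx <- match(sm$label, STROKE_LABELS)
    if (length(idx) > 1 && any(diff(idx) %% 4 != 1)) {
      bad <- which(diff(idx) %% 4 != 1)[1]
      stop("validation error: illegal stroke order ", sm$label[bad],
           " -> ", sm$label[bad + 1])
    }
  }
  rec
}

MARKER_COLS <- as.vector(outer(
  c("head_a", "head_p", "shoulder_l", "shoulder_r", "wingtip_l", "wingtip_r"),
  c("x", "y", "z"), paste, sep = "_"))

#' Read / write a trial recording
#'
#' A trial is stored as a CSV of per-frame samples (column `t` plus one
#' column per marker axis, NA for untracked frames of sparse channels) and
#' a YAML sidecar `<path minus .csv>_meta.yaml` carrying trial id, sample
#' rate, stroke marks and (when present) the landing-initiation time.
#' Units (seconds, meters) are declared in the sidecar. A read of a written
#' trial reproduces it to 1e-9 on all numeric channels.
#'
#' @param path CSV file path.
#' @param rec a `trial_recording`.
#' @return `read_trial()` returns a validated `trial_recording`;
#'   `write_trial()` returns `path` invisibly.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("no such trial file: ", path)
  meta_path <- trial_meta_path(path)
  if (!file.exists(meta_path)) stop("missing trial sidecar: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$schema) || meta$schema != "trial/1") {
    stop("unrecognized trial schema: ", meta$schema)
  }
  df <- utils::read.csv(path)
  if (!"t" %in% names(df)) stop("parse error: no time column 't'")
  sm <- NULL
  if (!is.null(meta$stroke_marks)) {
    sm <- tibble::tibble(
      time = vapply(meta$stroke_marks, function(m) as.numeric(m$time), 0),
      label = vapply(meta$stroke_marks, function(m) m$label, ""))
  }
  trial_recording(trial_id = meta$trial_id, t = df$t,
                  samples = df[setdiff(names(df), "t")],
                  sample_rate = meta$sample_rate, stroke_marks = sm,
                  landing_init_time = meta$landing_init_time,
                  bird_id = meta$bird_id %||% NA_character_,
                  flight_id = meta$flight_id %||% NA_character_)
}

#' @rdname read_trial
#' @export
write_trial <- function(rec, path) {
  stopifnot(inherits(rec, "trial_recording"))
  df <- cbind(t = rec$t, as.data.frame(rec$samples))
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  meta <- list(schema = "trial/1", trial_id = rec$trial_id,
               sample_rate = rec$sample_rate,
               units = list(time = "s", position = "m"))
  if (!is.na(rec$bird_id)) meta$bird_id <- rec$bird_id
  if (!is.na(rec$flight_id)) meta$flight_id <- rec$flight_id
  if (!is.null(rec$stroke_marks) && nrow(rec$stroke_marks) > 0) {
    meta$stroke_marks <- lapply(seq_len(nrow(rec$stroke_marks)), function(i) {
      list(time = rec$stroke_marks$time[i], label = rec$stroke_marks$label[i])
    })
  }
  if (!is.null(rec$landing_init_time)) {
    meta$landing_init_time <- rec$landing_init_time
  }
  yaml::write_yaml(meta, trial_meta_path(path),
                   precision = 15L)
  invisible(path)
}

trial_meta_path <- function(path) {
  paste0(sub("\\.csv$", "", path), "_meta.yaml")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
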