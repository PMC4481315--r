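#' Azimuthal positions of arena features relative to head yaw
#'
#' For each feature point, the signed planform angle from the head-yaw
#' heading vector to the head-to-feature vector; positive azimuths lie in
#' the left visual hemisphere. Perch features use the instantaneous
#' tracked perch position when a perch track is present (columns
#' `perch_x` / `perch_y` in the recording), else the static rest position
#' from the geometry.
#'
#' @param yaw a [compute_yaw()] result (provides head position and yaw).
#' @param geometry an [arena_geometry()].
#' @param perch_track optional tibble (t, x, y) of the perch center; when
#'   NULL and `rec` carries `perch_x`/`perch_y` those are used via
#'   [trial_feature_azimuths()].
#' @return long tibble: feature_id, t, azimuth (deg, (-180, 180]);
#'   samples where the head coincides with the feature are NA.
#' @export
feature_azimuths <- function(yaw, geometry, perch_track = NULL) {
  feats <- geometry$features
  rows <- lapply(rownames(feats), function(fid) {
    fx <- rep(feats[fid, "x"], nrow(yaw))
    fy <- rep(feats[fid, "y"], nrow(yaw))
    if (!is.null(perch_track) && startsWith(fid, "perch")) {
      off_y <- feats[fid, "y"] - feats["perch_center", "y"]
      fx <- perch_track$x
      fy <- perch_track$y + off_y
    }
    dx <- fx - yaw$head_x
    dy <- fy - yaw$head_y
    az <- wrap180(atan2_deg(dy, dx) - yaw$phi_head)
    az[sqrt(dx^2 + dy^2) < 1e-9] <- NA_real_
    tibble::tibble(feature_id = fid, t = yaw$t, azimuth = az)
  })
  dplyr::bind_rows(rows)
}

#' Feature azimuths straight from a trial recording
#'
#' Convenience wrapper: computes yaw traces and uses the recording's own
#' perch track when present.
#'
#' @param rec a [trial_recording()].
#' @param geometry an [arena_geometry()].
#' @param settings smoother settings passed to [compute_yaw()].
#' @return as [feature_azimuths()].
#' @export
trial_feature_azimuths <- function(rec, geometry = arena_geometry(),
                                   settings = smoother_settings()) {
  yaw <- compute_yaw(rec, settings)
  pt <- NULL
  if (!is.null(rec$samples$perch_x)) {
    pt <- tibble::tibble(t = rec$t, x = rec$samples$perch_x,
                         y = rec$samples$perch_y)
  }
  feature_azimuths(yaw, geometry, perch_track = pt)
}

#' Intersaccadic mask for wingbeat-rate (low resolution) yaw data
#'
#' Separates saccadic from intersaccadic samples when only four yaw
#' samples per wingbeat are available: a whole wingbeat is excluded when
#' the standard deviation of its yaw samples exceeds `sd_limit` (10 deg).
#'
#' @param t sample times, seconds.
#' @param phi_head head yaw at those times, degrees.
#' @param beats wingbeat records (down_start / up_end delimit each beat).
#' @param sd_limit within-beat yaw SD limit, degrees.
#' @return logical mask aligned with `t`: TRUE for retained
#'   (intersaccadic) samples; samples outside any beat are FALSE.
#' @export
intersaccadic_mask_lowres <- function(t, phi_head, beats, sd_limit = 10) {
  keep <- rep(FALSE, length(t))
  for (b in seq_len(nrow(beats))) {
    inb <- t >= beats$down_start[b] & t < beats$up_end[b]
    nb <- sum(inb)
    if (nb < 2) {
      if (nb > 0) warning("beat ", b, " has fewer than 2 yaw samples; excluded")
      next
    }
    if (stats::sd(phi_head[inb]) <= sd_limit) keep[inb] <- TRUE
  }
  keep
}

#' Normalized azimuthal feature distributions
#'
#' Histograms of intersaccadic feature azimuths in 10-degree bins on
#' [-90, 90) (left-closed bins; azimuths outside the range are not
#' binned). Counts are normalized by the summed counts across all
#' features of the same bird (so the features of one bird share one unit
#' of probability mass), then averaged across birds.
#'
#' @param series long tibble from [feature_azimuths()], with columns
#'   feature_id, azimuth, and optionally bird_id.
#' @param mask logical vector aligned with `series` rows of one feature
#'   (recycled across features), TRUE for samples to keep -- typically an
#'   intersaccadic mask; NULL keeps everything.
#' @param bin_width degrees.
#' @return tibble feature_id, bin_left, bin_mid, prob; the per-feature
#'   peak bins in attribute `peaks`.
#' @export
azimuth_distributions <- function(series, mask = NULL, bin_width = 10) {
  if (!is.null(mask)) {
    nf <- length(unique(series$feature_id))
    if (length(mask) == nrow(series)) {
      series <- series[mask, ]
    } else if (length(mask) * nf == nrow(series)) {
      # per-sample mask recycled across the feature blocks
      series <- series[rep(mask, times = nf), ]
    } else {
      stop("mask length matches neither the series rows nor one feature block")
    }
  }
  if (!"bird_id" %in% names(series)) series$bird_id <- "all"
  edges <- seq(-90, 90, by = bin_width)
  ok <- !is.na(series$azimuth) & series$azimuth >= -90 & series$azimuth < 90
  s <- series[ok, ]
  if (nrow(s) == 0) {
    warning("no samples to bin; empty histogram")
    return(tibble::tibble(feature_id = character(), bin_left = numeric(),
                          bin_mid = numeric(), prob = numeric()))
  }
  s$bin_left <- edges[findInterval(s$azimuth, edges)]
  grid <- expand.grid(feature_id = unique(series$feature_id),
                      bin_left = edges[-length(edges)],
                      stringsAsFactors = FALSE)
  per_bird <- lapply(split(s, s$bird_id), function(sb) {
    counts <- dplyr::count(sb, .data$feature_id, .data$bin_left)
    m <- merge(grid, counts, all.x = TRUE)
    m$n[is.na(m$n)] <- 0
    m$prob <- m$n / sum(m$n)
    m
  })
  all_b <- dplyr::bind_rows(per_bird)
  out <- dplyr::summarise(
    dplyr::group_by(all_b, .data$feature_id, .data$bin_left),
    prob = mean(.data$prob), .groups = "drop")
  out$bin_mid <- out$bin_left + bin_width / 2
  out <- out[order(out$feature_id, out$bin_left),
             c("feature_id", "bin_left", "bin_mid", "prob")]
  peaks <- dplyr::slice_max(dplyr::group_by(out, .data$feature_id),
                            .data$prob, n = 1, with_ties = FALSE)
  attr(out, "peaks") <- dplyr::ungroup(peaks)
  out
}
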