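#' Angle helpers
#'
#' All public angles in the package are in degrees. `wrap180()` maps angles
#' to (-180, 180]; `unwrap_deg()` removes +/-360 jumps from a sampled angle
#' series so that it can be smoothed and differentiated; `atan2_deg()` is
#' `atan2` reported in degrees.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length.
#' @keywords internal
#' @name angle-helpers
NULL

#' @rdname angle-helpers
wrap180 <- function(x) {
  out <- (x + 180) %% 360 - 180
  # map -180 to +180 so the range is (-180, 180]
  out[out == -180] <- 180
  out
}

#' @rdname angle-helpers
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  x[1L] + c(0, cumsum(d))
}

atan2_deg <- function(y, x) atan2(y, x) * 180 / pi

#' Circular mean of angles in degrees
#' @param x angles, degrees.
#' @return mean direction in degrees, in (-180, 180].
#' @keywords internal
circ_mean_deg <- function(x) {
  wrap180(atan2_deg(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))))
}

# unit heading vector for a yaw angle in degrees (planform x-y)
heading_vec <- function(phi_deg) {
  cbind(cos(phi_deg * pi / 180), sin(phi_deg * pi / 180))
}
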