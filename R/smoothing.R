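#' Smoother settings
#'
#' Penalty weights and cross-validation bounds for the Whittaker smoother,
#' one set per signal class. The defaults are the conservative values used
#' throughout the pipeline: marker coordinates lambda = 100 (cve bound
#' 0.5 signal units), head yaw lambda = 5000 (bound 1 deg), body yaw
#' lambda = 1e6 (bound 2 deg). The difference order is 2, which makes the
#' smoother behave like a resource-efficient Savitzky-Golay filter.
#'
#' @param lambda_coord,lambda_head,lambda_body penalty weights
#'   (dimensionless, >= 0).
#' @param cve_coord,cve_head,cve_body maximum admissible leave-one-out
#'   cross-validation error, in units of the smoothed signal. Exceeding a
#'   bound triggers a warning, never an error.
#' @param difference_order integer in 1..3; order of the difference penalty.
#' @return an object of class `smoother_settings`.
#' @export
smoother_settings <- function(lambda_coord = 100, lambda_head = 5000,
                              lambda_body = 1e6,
                              cve_coord = 0.5, cve_head = 1, cve_body = 2,
                              difference_order = 2L) {
  stopifnot(lambda_coord >= 0, lambda_head >= 0, lambda_body >= 0,
            difference_order %in% 1:3)
  structure(list(lambda_coord = lambda_coord, lambda_head = lambda_head,
                 lambda_body = lambda_body, cve_coord = cve_coord,
                 cve_head = cve_head, cve_body = cve_body,
                 difference_order = as.integer(difference_order)),
            class = "smoother_settings")
}

# sparse order-d difference matrix ((n - d) x n)
diff_matrix <- function(n, d) {
  D <- Matrix::bandSparse(n - 1, n, k = 0:1,
                          diagonals = list(rep(-1, n - 1), rep(1, n - 1)))
  for (i in seq_len(d - 1)) {
    m <- nrow(D)
    D <- Matrix::bandSparse(m - 1, m, k = 0:1,
                            diagonals = list(rep(-1, m - 1), rep(1, m - 1))) %*% D
  }
  D
}

# Sparse penalized least-squares system W + lambda * D'D
whittaker_system <- function(n, lambda, d, w) {
  D <- diff_matrix(n, d)
  Matrix::Diagonal(n, w) + lambda * Matrix::crossprod(D)
}

#' Whittaker penalized least-squares smoother
#'
#' Minimizes sum(w_i (y_i - z_i)^2) + lambda * sum((diff(z, d))^2) over z.
#' Missing values (`NA`) get weight 0 and are interpolated by the penalty,
#' so sparse channels (e.g. shoulder positions tracked only at wingbeat
#' instants, placed on the full-rate grid) are smoothed and upsampled in a
#' single step.
#'
#' @param y numeric series, possibly with `NA` gaps.
#' @param lambda penalty weight, >= 0.
#' @param d difference order (default 2).
#' @param w optional non-negative weights (default: 1 at observed points,
#'   0 at `NA`).
#' @return numeric vector `z` of `length(y)` with gaps filled.
#' @export
whittaker_smooth <- function(y, lambda, d = 2L, w = NULL) {
  n <- length(y)
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(w)) w <- as.numeric(is.finite(y))
  if (length(w) != n) stop("w must have the same length as y")
  if (all(w == 0)) stop("all-missing input: no observed points to smooth")
  n_obs <- sum(w > 0)
  if (n_obs < d + 1) stop("need at least difference_order + 1 observed points")
  y0 <- ifelse(is.finite(y), y, 0)
  if (lambda == 0 && all(w > 0)) return(y0)
  A <- whittaker_system(n, lambda, d, w)
  as.numeric(Matrix::solve(A, w * y0))
}

#' Leave-one-out cross-validation error of the Whittaker smoother
#'
#' Root-mean-square leave-one-out residual, computed exactly through the
#' smoother's hat-matrix diagonal: for a linear smoother z = H y the
#' deleted residual at an observed point is (y_i - z_i) / (1 - h_ii).
#' Gap (weight-0) points are excluded from the average.
#'
#' @inheritParams whittaker_smooth
#' @return scalar cve in the units of `y`.
#' @export
cross_validation_error <- function(y, lambda, d = 2L, w = NULL) {
  n <- length(y)
  if (is.null(w)) w <- as.numeric(is.finite(y))
  if (all(w == 0)) stop("all-missing input")
  if (sum(w > 0) < d + 2) stop("too few observed points for cross-validation")
  y0 <- ifelse(is.finite(y), y, 0)
  if (lambda == 0) {
    # limit case: the unpenalized smoother reproduces the data (hat
    # diagonal 1), so the deleted residual is taken in the lambda -> 0+
    # limit, where the left-out point is predicted by minimum-roughness
    # interpolation through its neighbours
    lambda <- 1e-9 * stats::var(y0[w > 0])
  }
  A <- whittaker_system(n, lambda, d, w)
  z <- as.numeric(Matrix::solve(A, w * y0))
  h <- hat_diag(A, w)
  obs <- w > 0
  loo <- (y0[obs] - z[obs]) / (1 - h[obs])
  sqrt(mean(loo^2))
}

# diagonal of H = A^{-1} W restricted to observed points
hat_diag <- function(A, w) {
  n <- nrow(A)
  Ainv_diag <- Matrix::diag(Matrix::solve(A, Matrix::Diagonal(n)))
  Ainv_diag * w
}

#' Derivative of a uniformly sampled series
#'
#' Central differences in the interior, one-sided at the ends; the length is
#' preserved. Used for angular velocity (deg/s from deg) and flight speed
#' (m/s from m).
#'
#' @param z numeric series (usually smoothed).
#' @param sample_rate sampling rate in Hz.
#' @return numeric vector of the same length, in signal units per second.
#' @export
derivative <- function(z, sample_rate) {
  n <- length(z)
  if (n < 3) stop("need at least 3 points to differentiate")
  dt <- 1 / sample_rate
  dz <- numeric(n)
  dz[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (2 * dt)
  dz[1] <- (z[2] - z[1]) / dt
  dz[n] <- (z[n] - z[n - 1]) / dt
  dz
}

# smooth + warn if the configured cve bound is exceeded; used by compute_yaw
smooth_checked <- function(y, lambda, d, bound, label, check_cve = FALSE) {
  z <- whittaker_smooth(y, lambda, d = d)
  if (isTRUE(check_cve)) {
    cve <- cross_validation_error(y, lambda, d = d)
    if (cve > bound) {
      warning(sprintf("cve of %s channel (%.3g) exceeds bound %.3g",
                      label, cve, bound))
    }
  }
  z
}
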