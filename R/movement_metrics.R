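#' Step distance between two fixes
#'
#' Euclidean distance in metres between two planar positions.
#'
#' @param p,q Numeric length-2 vectors `c(x, y)` in metres.
#' @return Distance in metres.
#' @export
step_distance <- function(p, q) {
  sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2)
}

#' Turning angle at a fix
#'
#' Absolute angular deviation, in degrees within \[0, 180\], of the outgoing
#' step `b -> c` from the incoming step `a -> b`. 0 means straight
#' continuation, 180 a full reversal. Undefined (`NA`) if either step has
#' zero length: for coincident fixes a travel direction does not exist.
#'
#' @param a,b,c Numeric length-2 vectors `c(x, y)`, three consecutive fixes.
#' @return Angle in degrees, or `NA_real_`.
#' @export
turning_angle <- function(a, b, c) {
  turning_angles_xy(c(a[1], b[1], c[1]), c(a[2], b[2], c[2]))
}

# Vectorised turning angles along a fix sequence: element i is the angle at
# fix i+1 (between steps i and i+1); length = n_fixes - 2.
turning_angles_xy <- function(x, y) {
  dx <- diff(x); dy <- diff(y)
  n <- length(dx)
  if (n < 2) return(numeric(0))
  v1x <- dx[-n]; v1y <- dy[-n]
  v2x <- dx[-1]; v2y <- dy[-1]
  ang <- abs(atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y)) * 180 / pi
  ang[(v1x^2 + v1y^2) == 0 | (v2x^2 + v2y^2) == 0] <- NA_real_
  ang
}

#' Per-interval movement metrics
#'
#' One record per consecutive fix pair: the distance covered between the two
#' fixes and the turning angle at the first fix (which needs the preceding
#' fix, so the first interval's angle is undefined). Intervals whose duration
#' deviates from the nominal interval by more than `tolerance` (fraction) are
#' excluded; the number excluded is returned in attribute `n_irregular`.
#'
#' @param traj A [trajectory()].
#' @param tolerance Allowed relative deviation of an interval's duration
#'   from the nominal interval (default 0.1).
#' @return Data frame `t_start`, `t_end`, `distance_m`, `angle_deg`.
#' @export
interval_metrics <- function(traj, tolerance = 0.1) {
  stopifnot(inherits(traj, "trajectory"))
  f <- traj$fixes
  n <- nrow(f)
  if (n < 2) {
    warning("trajectory has fewer than 2 fixes; no intervals")
    out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      distance_m = numeric(0), angle_deg = numeric(0))
    attr(out, "n_irregular") <- 0L
    return(out)
  }
  dx <- diff(f$x); dy <- diff(f$y)
  dist <- sqrt(dx^2 + dy^2)
  ang <- c(NA_real_, turning_angles_xy(f$x, f$y))
  dt <- diff(f$t)
  regular <- abs(dt - traj$interval_s) <= tolerance * traj$interval_s
  out <- data.frame(t_start = f$t[-n], t_end = f$t[-1],
                    distance_m = dist, angle_deg = ang)[regular, ]
  rownames(out) <- NULL
  attr(out, "n_irregular") <- sum(!regular)
  out
}

#' Subsample a trajectory to a longer fix interval
#'
#' Keeps fixes at indices 1, 1+factor, 1+2*factor, ... and multiplies the
#' nominal interval by `factor`; e.g. a 2 s track subsampled by 6 yields the
#' 12 s track.
#'
#' @param traj A [trajectory()].
#' @param factor Positive integer subsampling factor.
#' @return A [trajectory()].
#' @export
subsample_trajectory <- function(traj, factor) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stop("factor must be a positive integer")
  if (factor == 1) return(traj)
  f <- traj$fixes
  idx <- seq(1, nrow(f), by = factor)
  trajectory(traj$animal_id, f$t[idx], f$x[idx], f$y[idx],
             interval_s = traj$interval_s * factor)
}
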