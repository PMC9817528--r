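## Frame-of-reference rotations.
##
## World frame: x = east, y = north, z = up. Horse frame: x = front-back
## (positive forward), y = left-right (positive left), z = vertical. Both
## right-handed. Quaternions are Hamilton, scalar-first (w,x,y,z), and
## rotate device-frame vectors into the world frame. Heading is degrees in
## [0,360), clockwise from geographic north.

#' Rotate a 3-vector by a unit quaternion
#'
#' Computes \eqn{q v q^*} (Hamilton convention, scalar-first). Rejects
#' non-unit quaternions rather than silently normalizing, since a drifting
#' norm indicates an upstream logging or interpolation defect.
#'
#' @param v numeric 3-vector, or an n x 3 matrix of row vectors.
#' @param q unit quaternion as \code{c(w, x, y, z)}, or an n x 4 matrix of
#'   per-row quaternions matching the rows of \code{v}.
#' @return rotated vector(s), same shape as \code{v}.
#' @examples
#' q <- c(cos(pi / 4), 0, 0, sin(pi / 4))  # 90 degrees about z
#' applyQuaternion(c(1, 0, 0), q)          # ~ (0, 1, 0)
#' @export
applyQuaternion <- function(v, q) {
  vec <- is.null(dim(v))
  v <- rbind(v); q <- rbind(q)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  if (ncol(v) != 3L || ncol(q) != 4L || nrow(q) != nrow(v))
    eqShapeError("v must be n x 3 and q n x 4")
  nq <- sqrt(rowSums(q^2))
  if (any(abs(nq - 1) > 1e-6))
    eqNormalizationErr("quaternion norm %.8f is not 1", nq[which(abs(nq - 1) > 1e-6)[1]])
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  ## q v q* expanded: v + 2w (u x v) + 2 u x (u x v), u = (x,y,z)
  ux <- y * v[, 3] - z * v[, 2]
  uy <- z * v[, 1] - x * v[, 3]
  uz <- x * v[, 2] - y * v[, 1]
  uux <- y * uz - z * uy
  uuy <- z * ux - x * uz
  uuz <- x * uy - y * ux
  out <- cbind(v[, 1] + 2 * (w * ux + uux),
               v[, 2] + 2 * (w * uy + uuy),
               v[, 3] + 2 * (w * uz + uuz))
  if (vec) out[1, ] else out
}

#' @rdname applyQuaternion
#' @export
quaternionConjugate <- function(q) {
  if (is.null(dim(q))) c(q[1], -q[2:4]) else cbind(q[, 1], -q[, 2:4])
}

#' Bearing between two GPS fixes
#'
#' Bearing of the displacement from fix \code{a} to fix \code{b}, clockwise
#' from geographic north, using the equirectangular local approximation
#' \eqn{\Delta x = \cos(lat)\,\Delta lon}, \eqn{\Delta y = \Delta lat},
#' \eqn{\theta = atan2(\Delta x, \Delta y)} mapped to [0, 360).
#'
#' @param a,b GPS fixes: vectors/one-row data.frames with \code{lat},
#'   \code{lon} in degrees.
#' @return bearing in degrees in [0, 360).
#' @export
gpsBearing <- function(a, b) {
  lat1 <- a[["lat"]]; lon1 <- a[["lon"]]
  lat2 <- b[["lat"]]; lon2 <- b[["lon"]]
  dx <- cos((lat1 + lat2) / 2 * pi / 180) * (lon2 - lon1)
  dy <- lat2 - lat1
  if (dx == 0 && dy == 0)
    eqUndefinedHeading("zero displacement between fixes; hold previous heading")
  (atan2(dx, dy) * 180 / pi) %% 360
}

#' Heading series from a GPS track
#'
#' Bearing of each consecutive fix pair, stamped at the later fix. Pairs
#' with zero displacement inherit the previous defined heading; leading
#' undefined headings are dropped.
#'
#' @param gps data.frame with \code{t,lat,lon}.
#' @return data.frame \code{t,theta} (degrees in [0, 360)).
#' @export
headingFromGps <- function(gps) {
  n <- nrow(gps)
  if (n < 2L) eqInsufficientData("need at least 2 GPS fixes for heading")
  theta <- rep(NA_real_, n - 1L)
  for (i in seq_len(n - 1L)) {
    th <- tryCatch(gpsBearing(gps[i, ], gps[i + 1L, ]),
                   eqUndefinedHeadingError = function(e) NA_real_)
    theta[i] <- if (is.na(th) && i > 1L) theta[i - 1L] else th
  }
  keep <- !is.na(theta)
  data.frame(t = gps$t[-1][keep], theta = theta[keep])
}

#' Unwrap a degree sequence
#'
#' Sequentially replaces elements whose absolute difference from the
#' already-corrected predecessor exceeds 180 degrees by their
#' period-complementary value (adding or subtracting multiples of 360), so
#' that successive differences are all at most 180 in magnitude. Each output
#' element is congruent to its input modulo 360. A difference of exactly 180
#' is left untouched.
#'
#' @param x numeric vector of angles in degrees.
#' @return unwrapped numeric vector.
#' @examples
#' unwrapDegrees(c(350, 10))  # 350 370
#' unwrapDegrees(c(10, 350))  # 10 -10
#' @export
unwrapDegrees <- function(x) {
  if (length(x) < 2L) return(x)
  out <- x
  for (i in 2:length(x)) {
    d <- out[i] - out[i - 1L]
    while (d > 180) { out[i] <- out[i] - 360; d <- d - 360 }
    while (d < -180) { out[i] <- out[i] + 360; d <- d + 360 }
  }
  out
}

#' Circularly smooth a heading series
#'
#' Computes a centered moving average of the heading over a time window,
#' handling the 0/360 wrap by unwrap -> average -> rewrap: the series is
#' unwrapped with \code{\link{unwrapDegrees}}, each sample is replaced by the
#' mean of all unwrapped samples within \code{window / 2} seconds, and the
#' result is wrapped back to [0, 360).
#'
#' @param h data.frame \code{t,theta}.
#' @param window averaging window in seconds (default 1).
#' @return data.frame \code{t,theta} with smoothed headings in [0, 360).
#' @export
smoothHeading <- function(h, window = 1.0) {
  if (!nrow(h)) eqInsufficientData("empty heading series")
  u <- unwrapDegrees(h$theta)
  half <- window / 2
  sm <- vapply(seq_along(u), function(i) {
    mean(u[abs(h$t - h$t[i]) <= half + 1e-12])
  }, numeric(1))
  data.frame(t = h$t, theta = sm %% 360)
}

#' Rotate a device-frame trace to the world frame
#'
#' Applies each sample's logged orientation quaternion to the acceleration
#' and angular-velocity vectors. Requires quaternion channels
#' \code{qw,qx,qy,qz} in the trace.
#'
#' @param trace device-frame \linkS4class{SensorTrace} with quaternion
#'   channels.
#' @return world-frame \linkS4class{SensorTrace} with channels
#'   \code{ax,ay,az,gx,gy,gz} (x = east, y = north, z = up).
#' @export
deviceToWorld <- function(trace) {
  if (traceFrame(trace) != "device")
    eqFrameError("expected a device-frame trace, got '%s'", traceFrame(trace))
  ch <- traceChannels(trace)
  if (!all(c("qw", "qx", "qy", "qz") %in% colnames(ch)))
    eqMissingChannel("trace has no quaternion channels; cannot rotate to world")
  q <- ch[, c("qw", "qx", "qy", "qz"), drop = FALSE]
  acc <- applyQuaternion(ch[, c("ax", "ay", "az"), drop = FALSE], q)
  gyr <- applyQuaternion(ch[, c("gx", "gy", "gz"), drop = FALSE], q)
  out <- cbind(acc, gyr)
  colnames(out) <- c("ax", "ay", "az", "gx", "gy", "gz")
  SensorTrace(traceTimes(trace), out, rate = traceRate(trace), frame = "world")
}

#' Rotate a world-frame trace to the horse frame
#'
#' Rotates the horizontal components of acceleration and angular velocity by
#' the horse's heading so that x aligns with the direction of travel and y
#' points to the horse's left; z channels pass through unchanged. The
#' heading is held piecewise-constant between heading samples (zero-order
#' hold); trace samples before the first heading sample use the first
#' heading.
#'
#' @param trace world-frame \linkS4class{SensorTrace} with channels
#'   \code{ax,ay,az,gx,gy,gz}.
#' @param heading data.frame \code{t,theta} (degrees clockwise from north),
#'   typically from \code{\link{smoothHeading}}.
#' @return horse-frame \linkS4class{SensorTrace}.
#' @export
worldToHorse <- function(trace, heading) {
  if (traceFrame(trace) != "world")
    eqFrameError("expected a world-frame trace, got '%s'", traceFrame(trace))
  if (!nrow(heading)) eqFrameError("heading undefined over the trace")
  t <- traceTimes(trace)
  idx <- findInterval(t, heading$t)
  idx[idx < 1L] <- 1L
  th <- heading$theta[idx] * pi / 180
  s <- sin(th); co <- cos(th)
  ch <- traceChannels(trace)
  rot2 <- function(e, n) cbind(front = e * s + n * co, left = -e * co + n * s)
  acc <- rot2(ch[, "ax"], ch[, "ay"])
  gyr <- rot2(ch[, "gx"], ch[, "gy"])
  out <- cbind(acc[, 1], acc[, 2], ch[, "az"], gyr[, 1], gyr[, 2], ch[, "gz"])
  colnames(out) <- c("ax", "ay", "az", "gx", "gy", "gz")
  SensorTrace(t, out, rate = traceRate(trace), frame = "horse")
}
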