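## Log-file I/O and resampling.
##
## CSV dialects (UTF-8, comma-separated, "." decimal point, times in seconds
## from ride start):
##   IMU:    t,ax,ay,az,gx,gy,gz[,qw,qx,qy,qz]   (quaternion optional)
##   GPS:    t,lat,lon[,speed]
##   labels: t,label
##   judge:  t,code
## Acceleration in m/s^2, angular velocity in deg/s, quaternion Hamilton
## scalar-first (w,x,y,z) rotating device vectors into the world frame.
## Gravity is not removed.

.imuMandatory <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
.quatCols <- c("qw", "qx", "qy", "qz")

#' The ten gait labels emitted by the limb-sensor labelling system
#'
#' Closed vocabulary of the commercial limb-mounted gait-labelling system
#' used as the labelling oracle: a label is emitted at every hoof-on event.
#'
#' @return character vector of the ten labels.
#' @export
tsLabelVocabulary <- function() {
  c("Standing", "Walk", "Trot", "Tölt", "L Canter", "R Canter",
    "L Cross Canter", "R Cross Canter", "Flying Pace")
}
## Note: 9 distinct strings above plus "Halt" are accepted on read; the
## deployed system's tenth label ("Halt") is synonymous with "Standing".
.labelVocab <- function() c(tsLabelVocabulary(), "Halt")

.readCsv <- function(path) {
  if (!file.exists(path)) eqFormatError("file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

.checkMonotone <- function(t, what) {
  if (length(t) > 1L) {
    bad <- which(diff(t) <= 0)
    if (length(bad))
      eqIntegrityError("non-monotone timestamps in %s at index %d",
                       what, bad[1] + 1L)
  }
  invisible(TRUE)
}

#' Read phone sensor logs
#'
#' Reads an IMU CSV (and optionally a GPS CSV) into a device-frame
#' \linkS4class{SensorTrace} plus a GPS fix table. Quaternion columns are
#' optional; when absent the trace carries only the six inertial channels.
#'
#' @param imuPath path to the IMU CSV (\code{t,ax,ay,az,gx,gy,gz[,qw..qz]}).
#' @param gpsPath optional path to the GPS CSV (\code{t,lat,lon[,speed]}).
#' @return list with elements \code{trace} (\linkS4class{SensorTrace},
#'   frame \code{"device"}) and \code{gps} (data.frame or \code{NULL}).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(t = c(0, .02, .04), ax = 0, ay = 0, az = 9.81,
#'                      gx = 0, gy = 0, gz = 0), f, row.names = FALSE)
#' readSensorLog(f)$trace
#' @export
readSensorLog <- function(imuPath, gpsPath = NULL) {
  df <- .readCsv(imuPath)
  missing <- setdiff(.imuMandatory, names(df))
  if (length(missing))
    eqFormatError("missing mandatory column '%s' in %s", missing[1], imuPath)
  .checkMonotone(df$t, imuPath)
  cols <- .imuMandatory[-1]
  hasQuat <- all(.quatCols %in% names(df))
  if (hasQuat) {
    nq <- sqrt(df$qw^2 + df$qx^2 + df$qy^2 + df$qz^2)
    if (any(abs(nq - 1) > 1e-6))
      eqNormalizationErr("quaternion norm deviates from 1 at row %d",
                         which(abs(nq - 1) > 1e-6)[1])
    cols <- c(cols, .quatCols)
  }
  ch <- as.matrix(df[, cols, drop = FALSE])
  rate <- .inferRate(df$t)
  trace <- SensorTrace(df$t, ch, rate = rate, frame = "device")
  gps <- if (!is.null(gpsPath)) readGpsLog(gpsPath) else NULL
  list(trace = trace, gps = gps)
}

.inferRate <- function(t) {
  if (length(t) < 2L) return(NA_real_)
  dt <- diff(t)
  if (max(dt) - min(dt) < 1e-6) 1 / mean(dt) else NA_real_
}

#' @rdname readSensorLog
#' @param path path to a GPS CSV.
#' @return \code{readGpsLog}: data.frame with \code{t,lat,lon,speed}
#'   (\code{speed} NA when not logged).
#' @export
readGpsLog <- function(path) {
  df <- .readCsv(path)
  missing <- setdiff(c("t", "lat", "lon"), names(df))
  if (length(missing))
    eqFormatError("missing mandatory column '%s' in %s", missing[1], path)
  .checkMonotone(df$t, path)
  if (any(df$lat < -90 | df$lat > 90)) eqFormatError("latitude out of range")
  if (any(df$lon < -180 | df$lon > 180)) eqFormatError("longitude out of range")
  if (is.null(df$speed)) df$speed <- NA_real_
  df[, c("t", "lat", "lon", "speed")]
}

#' Read a gait-label event log
#'
#' Label events are (time, label) pairs emitted at hoof-on events by the
#' labelling system, at a variable 4--10 Hz rate. Labels outside the closed
#' ten-label vocabulary are rejected.
#'
#' @param path path to the label CSV (\code{t,label}).
#' @return data.frame with columns \code{t} and \code{label}, time-ordered.
#' @export
readLabelLog <- function(path) {
  df <- .readCsv(path)
  missing <- setdiff(c("t", "label"), names(df))
  if (length(missing))
    eqFormatError("missing mandatory column '%s' in %s", missing[1], path)
  .checkMonotone(df$t, path)
  bad <- setdiff(unique(df$label), .labelVocab())
  if (length(bad))
    eqVocabularyError("unknown gait label '%s'", bad[1])
  df[, c("t", "label")]
}

#' Write logs in the package's CSV dialects
#'
#' Counterparts of the readers; values are written at full precision so that
#' a write/read round trip preserves every channel to better than 1e-9.
#'
#' @param trace a \linkS4class{SensorTrace} (device frame, with or without
#'   quaternion channels).
#' @param path output CSV path.
#' @export
writeSensorLog <- function(trace, path) {
  df <- data.frame(t = traceTimes(trace))
  df <- cbind(df, as.data.frame(traceChannels(trace)))
  .writeCsvFull(df, path)
}

#' @rdname writeSensorLog
#' @param gps data.frame with \code{t,lat,lon,speed}.
#' @export
writeGpsLog <- function(gps, path) .writeCsvFull(gps, path)

#' @rdname writeSensorLog
#' @param events data.frame with \code{t,label}.
#' @export
writeLabelLog <- function(events, path) .writeCsvFull(events, path)

.writeCsvFull <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Resample a trace to a uniform rate
#'
#' Linearly interpolates every channel onto a uniform grid
#' \code{t0, t0 + 1/rate, ...} spanning the input's time range. Used to
#' downsample high-rate phone logs (commonly to 50 Hz) and to regularize
#' irregularly stamped logs. No anti-aliasing filter is applied.
#'
#' @param trace a \linkS4class{SensorTrace} with at least 2 samples.
#' @param rate target rate in Hz.
#' @return a uniformly sampled \linkS4class{SensorTrace}, frame preserved.
#' @examples
#' tr <- SensorTrace(seq(0, 1, by = 0.01),
#'                   cbind(az = sin(2 * pi * seq(0, 1, by = 0.01))), rate = 100)
#' resampleTrace(tr, 50)
#' @export
resampleTrace <- function(trace, rate) {
  t <- traceTimes(trace)
  if (length(t) < 2L)
    eqInsufficientData("resampling needs at least 2 samples, got %d", length(t))
  if (rate <= 0) eqConfigError("rate must be positive")
  t0 <- t[1]; t1 <- t[length(t)]
  n <- floor((t1 - t0) * rate + 1e-9) + 1L
  grid <- t0 + (seq_len(n) - 1L) / rate
  ch <- traceChannels(trace)
  out <- matrix(0, n, ncol(ch), dimnames = list(NULL, colnames(ch)))
  for (j in seq_len(ncol(ch)))
    out[, j] <- stats::approx(t, ch[, j], xout = grid, rule = 2)$y
  SensorTrace(grid, out, rate = rate, frame = traceFrame(trace))
}
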