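## From label events and uniform traces to labelled model-ready segments.

.tsToGaitMap <- c(
  "Standing"       = "Discarded",
  "Halt"           = "Discarded",
  "Walk"           = "Walk",
  "Trot"           = "Trot",
  "Tölt"           = "Tolt",
  "L Canter"       = "Canter",
  "R Canter"       = "Canter",
  "L Cross Canter" = "Canter",
  "R Cross Canter" = "Canter",
  "Flying Pace"    = "FlyingPace")

#' Map a labelling-system gait label to one of the five model gaits
#'
#' The ten-label vocabulary of the limb-sensor labelling system collapses to
#' the five gaits used for classification: both canters and both cross
#' canters map to Canter, standing is discarded.
#'
#' @param tsLabel character vector of labelling-system labels.
#' @return character vector of \code{gaitLevels()} values or
#'   \code{"Discarded"}.
#' @examples
#' mapTsLabel(c("L Cross Canter", "Standing", "Flying Pace"))
#' @export
mapTsLabel <- function(tsLabel) {
  bad <- setdiff(unique(tsLabel), names(.tsToGaitMap))
  if (length(bad)) eqVocabularyError("unknown gait label '%s'", bad[1])
  unname(.tsToGaitMap[tsLabel])
}

#' Build a gait timeline from label events
#'
#' Each event's mapped label holds from its timestamp until the next event
#' (piecewise-constant semantics); runs of equal mapped labels are merged.
#'
#' @param events data.frame with \code{t,label} (labelling-system labels),
#'   time-ordered.
#' @return a \linkS4class{GaitTimeline}.
#' @export
buildTimeline <- function(events) {
  if (!nrow(events)) eqInsufficientData("no label events")
  lab <- mapTsLabel(events$label)
  keep <- c(TRUE, lab[-1] != lab[-length(lab)])
  GaitTimeline(events$t[keep], lab[keep])
}

#' Cut overlapping fixed-duration segments with transition exclusion
#'
#' Slides a window of \code{window} seconds along a uniformly sampled trace.
#' Candidate start times lie on the sample grid and advance by
#' \code{(1 - overlap) * window}, rounded to a whole number of samples --
#' except inside flying-pace intervals, where the step is \code{paceStep}
#' seconds (dense stepping compensates the rarity of that gait). A candidate
#' is kept only when its full extent lies inside one labelled interval and no
#' gait switch falls strictly within \code{exclusion} seconds of any part of
#' it. Discarded intervals yield nothing.
#'
#' @param trace uniformly sampled \linkS4class{SensorTrace} (any frame).
#' @param timeline a \linkS4class{GaitTimeline} for the same ride.
#' @param window window length in seconds.
#' @param overlap fractional overlap of consecutive windows (default 0.9).
#' @param exclusion half-width of the transition exclusion period in seconds
#'   (default 2).
#' @param paceStep step in seconds used inside flying-pace intervals
#'   (default 0.02).
#' @param horseId,riderId,rideId provenance attached to every segment.
#' @return a \linkS4class{SegmentSet} (possibly with 0 segments).
#' @export
generateSegments <- function(trace, timeline, window, overlap = 0.9,
                             exclusion = 2.0, paceStep = 0.020,
                             horseId = 0L, riderId = 0L, rideId = 0L) {
  if (window <= 0) eqConfigError("window must be positive")
  rate <- traceRate(trace)
  if (is.na(rate))
    eqFrameError("trace must be uniformly sampled; resample first")
  t <- traceTimes(trace)
  n <- length(t)
  wlen <- round(window * rate)
  empty <- SegmentSet(array(0, c(0, ncol(traceChannels(trace)), wlen)),
                      character(0), integer(0), integer(0), integer(0),
                      numeric(0), rate)
  if (wlen > n) return(empty)

  iv <- timelineIntervals(timeline)
  switches <- transitionTimes(timeline)
  stepReg <- max(1L, round((1 - overlap) * window * rate))
  stepPace <- max(1L, round(paceStep * rate))
  ch <- traceChannels(trace)

  starts <- integer(0); labs <- character(0)
  for (k in seq_len(nrow(iv))) {
    lab <- iv$label[k]
    if (lab == "Discarded") next
    step <- if (lab == "FlyingPace") stepPace else stepReg
    lo <- iv$start[k]; hi <- iv$end[k]          # hi may be NA (unbounded)
    ## candidate start indices on the sample grid
    i0 <- which(t >= lo - 1e-9)[1]
    if (is.na(i0) || i0 > n - wlen + 1L) next
    cand <- seq.int(i0, n - wlen + 1L, by = step)
    if (!length(cand)) next
    s <- t[cand]; e <- t[cand + wlen - 1L]
    keep <- s >= lo - 1e-9
    if (!is.na(hi)) keep <- keep & (e < hi - 1e-9)
    if (length(switches)) {
      for (sw in switches)
        keep <- keep & !(sw > s - exclusion + 1e-9 &
                         sw < e + 1 / rate + exclusion - 1e-9)
    }
    starts <- c(starts, cand[keep])
    labs <- c(labs, rep(lab, sum(keep)))
  }
  if (!length(starts)) return(empty)
  ord <- order(starts)
  starts <- starts[ord]; labs <- labs[ord]
  x <- array(0, c(length(starts), ncol(ch), wlen))
  for (i in seq_along(starts))
    x[i, , ] <- t(ch[starts[i]:(starts[i] + wlen - 1L), , drop = FALSE])
  SegmentSet(x, labs, rep(horseId, length(starts)),
             rep(riderId, length(starts)), rep(rideId, length(starts)),
             t[starts], rate)
}

#' Assemble model input channels
#'
#' Selects accelerometer and/or gyroscope channels and optionally appends
#' GPS speed, held constant between 1 Hz fixes and sampled on the trace
#' grid. The resulting channel count is 3 per inertial sensor plus 1 for
#' speed (so 3, 6 or 7).
#'
#' @param trace \linkS4class{SensorTrace} with \code{ax..gz} channels.
#' @param gps data.frame \code{t,lat,lon,speed} (required when
#'   \code{"speed"} is requested).
#' @param use character subset of \code{c("accel", "gyro", "speed")}.
#' @return \linkS4class{SensorTrace} with the selected channels.
#' @export
buildFeatureChannels <- function(trace, gps = NULL,
                                 use = c("accel", "gyro")) {
  use <- match.arg(use, c("accel", "gyro", "speed"), several.ok = TRUE)
  ch <- traceChannels(trace)
  cols <- NULL
  if ("accel" %in% use) cols <- c(cols, c("ax", "ay", "az"))
  if ("gyro" %in% use) cols <- c(cols, c("gx", "gy", "gz"))
  missing <- setdiff(cols, colnames(ch))
  if (length(missing))
    eqMissingChannel("channel '%s' not present in trace", missing[1])
  out <- ch[, cols, drop = FALSE]
  if ("speed" %in% use) {
    if (is.null(gps) || !nrow(gps) || all(is.na(gps$speed)))
      eqMissingChannel("speed requested but no GPS speed available")
    idx <- findInterval(traceTimes(trace), gps$t)
    idx[idx < 1L] <- 1L
    out <- cbind(out, speed = gps$speed[idx])
  }
  SensorTrace(traceTimes(trace), out, rate = traceRate(trace),
              frame = traceFrame(trace))
}

#' Split segments into train / validation / test by horse
#'
#' All segments of the test horses form the test set. The remaining
#' segments are shuffled with the given seed and split into training and
#' validation sets at the segment level.
#'
#' @param segments a \linkS4class{SegmentSet}.
#' @param testHorses integer ids of held-out horses
#'   (default \code{c(1, 2, 8, 9, 11)}).
#' @param valFraction fraction of non-test segments used for validation
#'   (default 0.15).
#' @param seed shuffle seed.
#' @return list with \linkS4class{SegmentSet} elements \code{train},
#'   \code{val}, \code{test}.
#' @export
splitDataset <- function(segments, testHorses = c(1L, 2L, 8L, 9L, 11L),
                         valFraction = 0.15, seed = 1L) {
  if (valFraction <= 0 || valFraction >= 1)
    eqConfigError("valFraction must lie in (0,1)")
  info <- segmentInfo(segments)
  absent <- setdiff(testHorses, unique(info$horseId))
  if (length(absent))
    warning(sprintf("test horse id(s) %s absent from data",
                    paste(absent, collapse = ", ")))
  isTest <- info$horseId %in% testHorses
  restIdx <- which(!isTest)
  ## seed-local shuffle without disturbing the caller's RNG stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  restIdx <- sample(restIdx)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  nVal <- round(valFraction * length(restIdx))
  valIdx <- restIdx[seq_len(nVal)]
  trainIdx <- restIdx[-seq_len(nVal)]
  list(train = segments[sort(trainIdx)],
       val = segments[sort(valIdx)],
       test = segments[which(isTest)])
}
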