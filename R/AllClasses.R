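#' @import methods
NULL

## ---------------------------------------------------------------------------
## Gait vocabulary
## ---------------------------------------------------------------------------

#' The five gaits of the Icelandic horse
#'
#' Class labels used throughout the package, in fixed code order. The integer
#' codes 0--4 index model outputs and break argmax ties deterministically.
#'
#' @return \code{gaitLevels()} returns the five gait names in code order;
#'   \code{gaitCodes()} returns the named integer codes 0--4.
#' @examples
#' gaitLevels()
#' gaitCodes()["Tolt"]
#' @export
gaitLevels <- function() c("Walk", "Trot", "Tolt", "Canter", "FlyingPace")

#' @rdname gaitLevels
#' @export
gaitCodes <- function() stats::setNames(0:4, gaitLevels())

#' @rdname gaitLevels
#' @param x character vector of gait names.
#' @export
gaitFactor <- function(x) factor(x, levels = gaitLevels())

## ---------------------------------------------------------------------------
## SensorTrace
## ---------------------------------------------------------------------------

#' SensorTrace: a multichannel inertial sensor recording
#'
#' Container for a time-stamped multichannel signal from a phone's inertial
#' sensors. Channels are columns of a numeric matrix sharing one timestamp
#' vector. A trace is tagged with the frame of reference its vector channels
#' are expressed in: \code{"device"} (raw phone axes), \code{"world"}
#' (x = east, y = north, z = up) or \code{"horse"} (x = front--back positive
#' forward, y = left--right positive left, z = vertical).
#'
#' @slot t numeric vector of sample times in seconds, strictly increasing.
#' @slot channels numeric matrix, one column per channel, \code{length(t)} rows.
#' @slot rate sampling rate in Hz, or \code{NA_real_} for irregular sampling.
#' @slot frame one of \code{"device"}, \code{"world"}, \code{"horse"}.
#'
#' @export
setClass("SensorTrace",
  representation(t = "numeric", channels = "matrix",
                 rate = "numeric", frame = "character"))

setValidity("SensorTrace", function(object) {
  msgs <- character()
  if (nrow(object@channels) != length(object@t))
    msgs <- c(msgs, "channel rows must equal length(t)")
  if (is.null(colnames(object@channels)))
    msgs <- c(msgs, "channels must be named")
  if (anyNA(object@t) || any(!is.finite(object@t)))
    msgs <- c(msgs, "timestamps must be finite")
  if (length(object@t) > 1L && any(diff(object@t) <= 0))
    msgs <- c(msgs, "timestamps must be strictly increasing")
  if (!object@frame %in% c("device", "world", "horse"))
    msgs <- c(msgs, "frame must be device, world or horse")
  if (!is.na(object@rate) && length(object@t) > 1L &&
      any(abs(diff(object@t) - 1 / object@rate) > 1e-6))
    msgs <- c(msgs, "timestamps inconsistent with declared rate")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SensorTrace
#'
#' @param t numeric vector of sample times (seconds).
#' @param channels numeric matrix with named columns (one per channel).
#' @param rate sampling rate in Hz, or \code{NA} if irregular.
#' @param frame frame of reference tag.
#' @return A \linkS4class{SensorTrace}.
#' @examples
#' tr <- SensorTrace(t = seq(0, 1, by = 0.02),
#'                   channels = cbind(az = rep(9.81, 51)), rate = 50)
#' traceRate(tr)
#' @export
SensorTrace <- function(t, channels, rate = NA_real_, frame = "device") {
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  new("SensorTrace", t = as.numeric(t), channels = channels,
      rate = as.numeric(rate), frame = frame)
}

## ---------------------------------------------------------------------------
## GaitTimeline
## ---------------------------------------------------------------------------

#' GaitTimeline: piecewise-constant gait label over time
#'
#' A run-length representation of the gait as a function of time, derived
#' from variable-rate label events. Interval \code{i} spans
#' \code{[start[i], start[i+1])}; the final interval is unbounded. Labels are
#' the five gaits or \code{"Discarded"} for stretches excluded from modelling
#' (e.g. standing). Adjacent intervals always carry different labels.
#'
#' @slot start numeric vector of interval start times (seconds), strictly
#'   increasing.
#' @slot label character vector of interval labels, same length as
#'   \code{start}.
#' @export
setClass("GaitTimeline", representation(start = "numeric", label = "character"))

setValidity("GaitTimeline", function(object) {
  msgs <- character()
  if (length(object@start) != length(object@label))
    msgs <- c(msgs, "start and label must have equal length")
  if (length(object@start) == 0L)
    msgs <- c(msgs, "timeline must have at least one interval")
  if (length(object@start) > 1L) {
    if (any(diff(object@start) <= 0))
      msgs <- c(msgs, "interval starts must be strictly increasing")
    if (any(object@label[-1] == object@label[-length(object@label)]))
      msgs <- c(msgs, "adjacent intervals must carry different labels")
  }
  ok <- c(gaitLevels(), "Discarded")
  if (!all(object@label %in% ok))
    msgs <- c(msgs, "labels must be gaits or 'Discarded'")
  if (length(msgs)) msgs else TRUE
})

#' @rdname GaitTimeline-class
#' @param start,label interval start times (seconds) and labels.
#' @export
GaitTimeline <- function(start, label) {
  new("GaitTimeline", start = as.numeric(start), label = as.character(label))
}

## ---------------------------------------------------------------------------
## SegmentSet
## ---------------------------------------------------------------------------

#' SegmentSet: fixed-duration labelled windows of feature channels
#'
#' Segments cut from uniformly sampled traces: a 3-D array of shape
#' (segment, channel, time) plus per-segment gait label and
#' horse/rider/ride provenance. All segments in a set share channel count
#' and window length.
#'
#' @slot x numeric array, dim = c(n segments, channels, samples per window).
#' @slot y factor of gait labels with levels \code{gaitLevels()}.
#' @slot horseId,riderId,rideId integer provenance vectors.
#' @slot tStart numeric vector of window start times (seconds within ride).
#' @slot rate sampling rate of the windows (Hz).
#' @export
setClass("SegmentSet",
  representation(x = "array", y = "factor", horseId = "integer",
                 riderId = "integer", rideId = "integer",
                 tStart = "numeric", rate = "numeric"))

setValidity("SegmentSet", function(object) {
  msgs <- character()
  n <- dim(object@x)[1]
  if (length(dim(object@x)) != 3L)
    msgs <- c(msgs, "x must be a 3-D array (segment, channel, time)")
  for (nm in c("y", "horseId", "riderId", "rideId", "tStart")) {
    if (length(slot(object, nm)) != n)
      msgs <- c(msgs, sprintf("%s length must equal number of segments", nm))
  }
  if (!identical(levels(object@y), gaitLevels()))
    msgs <- c(msgs, "y levels must be the five gaits")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SegmentSet-class
#' @param x array, labels and provenance vectors (see slots).
#' @param y,horseId,riderId,rideId,tStart,rate see slots.
#' @export
SegmentSet <- function(x, y, horseId, riderId, rideId, tStart, rate) {
  new("SegmentSet", x = x, y = gaitFactor(as.character(y)),
      horseId = as.integer(horseId), riderId = as.integer(riderId),
      rideId = as.integer(rideId), tStart = as.numeric(tStart),
      rate = as.numeric(rate))
}

## ---------------------------------------------------------------------------
## ProbSeries
## ---------------------------------------------------------------------------

#' ProbSeries: a time-ordered stream of class probabilities
#'
#' Holds the raw classifier outputs \code{h} (one probability 5-vector per
#' step), and after smoothing, the exponentially decayed vectors \code{z},
#' hard labels \code{g} (argmax of z) and majority-voted labels
#' \code{gPrime}. \code{z}, \code{g} and \code{gPrime} may be empty until
#' \code{\link{smoothProbSeries}} fills them.
#'
#' @slot t numeric step times (seconds).
#' @slot h numeric matrix, rows = steps, 5 columns, each row on the simplex.
#' @slot z numeric matrix like \code{h} (possibly 0-row before smoothing).
#' @slot g,gPrime factors with gait levels (possibly empty before smoothing).
#' @export
setClass("ProbSeries",
  representation(t = "numeric", h = "matrix", z = "matrix",
                 g = "factor", gPrime = "factor"))

setValidity("ProbSeries", function(object) {
  msgs <- character()
  if (nrow(object@h) != length(object@t))
    msgs <- c(msgs, "h rows must equal length(t)")
  if (ncol(object@h) != 5L)
    msgs <- c(msgs, "h must have 5 columns")
  if (nrow(object@h) > 0L) {
    if (any(object@h < -1e-9) || any(abs(rowSums(object@h) - 1) > 1e-6))
      msgs <- c(msgs, "h rows must lie on the probability simplex")
  }
  if (nrow(object@z) > 0L && nrow(object@z) != nrow(object@h))
    msgs <- c(msgs, "z must be empty or match h")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ProbSeries-class
#' @param t,h step times and raw probability matrix.
#' @export
ProbSeries <- function(t, h) {
  h <- as.matrix(h)
  colnames(h) <- gaitLevels()
  new("ProbSeries", t = as.numeric(t), h = h,
      z = matrix(numeric(0), 0, 5),
      g = gaitFactor(character(0)), gPrime = gaitFactor(character(0)))
}

## ---------------------------------------------------------------------------
## GaitClassifier
## ---------------------------------------------------------------------------

#' GaitClassifier: a sequence model mapping segments to gait probabilities
#'
#' Wraps an architecture tag, the parameter list of the underlying network,
#' the per-channel standardization statistics learned from the training set,
#' and (after training) the epoch history.
#'
#' @slot arch one of \code{"lstm"}, \code{"bilstm"}, \code{"gru"},
#'   \code{"cnn1d"}.
#' @slot params named list of numeric parameter matrices/vectors.
#' @slot config the \code{\link{modelConfig}} used to build the model.
#' @slot norm list with per-channel \code{mu} and \code{sd} (empty before
#'   training).
#' @slot history data.frame of training history (epoch, train/val loss,
#'   val accuracy), empty before training.
#' @export
setClass("GaitClassifier",
  representation(arch = "character", params = "list", config = "list",
                 norm = "list", history = "data.frame"))
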