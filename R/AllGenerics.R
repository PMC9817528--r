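## Accessor generics. Slot access stays internal; users go through these.

#' @rdname SensorTrace-class
#' @param x a \linkS4class{SensorTrace}.
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname SensorTrace-class
#' @export
setGeneric("traceChannels", function(x) standardGeneric("traceChannels"))
#' @rdname SensorTrace-class
#' @export
setGeneric("traceRate", function(x) standardGeneric("traceRate"))
#' @rdname SensorTrace-class
#' @export
setGeneric("traceFrame", function(x) standardGeneric("traceFrame"))

setMethod("traceTimes", "SensorTrace", function(x) x@t)
setMethod("traceChannels", "SensorTrace", function(x) x@channels)
setMethod("traceRate", "SensorTrace", function(x) x@rate)
setMethod("traceFrame", "SensorTrace", function(x) x@frame)

setMethod("show", "SensorTrace", function(object) {
  cat(sprintf("SensorTrace: %d samples x %d channels [%s frame]\n",
              length(object@t), ncol(object@channels), object@frame))
  cat(sprintf("  span %.3f..%.3f s, rate %s\n",
              if (length(object@t)) min(object@t) else NA,
              if (length(object@t)) max(object@t) else NA,
              if (is.na(object@rate)) "irregular"
              else sprintf("%g Hz", object@rate)))
  cat("  channels:", paste(colnames(object@channels), collapse = ", "), "\n")
})

#' @rdname GaitTimeline-class
#' @param x a \linkS4class{GaitTimeline}.
#' @export
setGeneric("timelineIntervals", function(x) standardGeneric("timelineIntervals"))
#' @rdname GaitTimeline-class
#' @export
setGeneric("transitionTimes", function(x) standardGeneric("transitionTimes"))

#' @describeIn GaitTimeline-class intervals as a data.frame with columns
#'   \code{start}, \code{end} (NA for the final, unbounded interval) and
#'   \code{label}.
setMethod("timelineIntervals", "GaitTimeline", function(x) {
  n <- length(x@start)
  data.frame(start = x@start,
             end = c(x@start[-1], NA_real_),
             label = x@label, stringsAsFactors = FALSE)
})

#' @describeIn GaitTimeline-class times at which the label changes (all
#'   interval starts except the first).
setMethod("transitionTimes", "GaitTimeline", function(x) x@start[-1])

#' Label of a timeline at given times
#'
#' @param timeline a \linkS4class{GaitTimeline}.
#' @param t numeric vector of query times; times before the first interval
#'   return \code{NA}.
#' @return character vector of labels.
#' @export
labelAt <- function(timeline, t) {
  idx <- findInterval(t, timeline@start)
  out <- rep(NA_character_, length(t))
  out[idx >= 1L] <- timeline@label[idx[idx >= 1L]]
  out
}

setMethod("show", "GaitTimeline", function(object) {
  cat(sprintf("GaitTimeline: %d intervals from %.3f s\n",
              length(object@start), object@start[1]))
  iv <- timelineIntervals(object)
  print(utils::head(iv, 8))
  if (nrow(iv) > 8) cat("  ...\n")
})

#' @rdname SegmentSet-class
#' @param x a \linkS4class{SegmentSet}.
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @rdname SegmentSet-class
#' @export
setGeneric("segmentArray", function(x) standardGeneric("segmentArray"))
#' @rdname SegmentSet-class
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))
#' @rdname SegmentSet-class
#' @export
setGeneric("segmentInfo", function(x) standardGeneric("segmentInfo"))

setMethod("nSegments", "SegmentSet", function(x) dim(x@x)[1])
setMethod("segmentArray", "SegmentSet", function(x) x@x)
setMethod("segmentLabels", "SegmentSet", function(x) x@y)
#' @describeIn SegmentSet-class provenance data.frame (label, horse, rider,
#'   ride, start time).
setMethod("segmentInfo", "SegmentSet", function(x) {
  data.frame(y = x@y, horseId = x@horseId, riderId = x@riderId,
             rideId = x@rideId, tStart = x@tStart)
})

setMethod("show", "SegmentSet", function(object) {
  d <- dim(object@x)
  cat(sprintf("SegmentSet: %d segments, %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@rate))
  print(table(object@y))
})

#' Subset a SegmentSet
#' @param x a \linkS4class{SegmentSet}.
#' @param i index vector of segments to keep.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SegmentSet", function(x, i, j, ..., drop = FALSE) {
  SegmentSet(x@x[i, , , drop = FALSE], as.character(x@y[i]),
             x@horseId[i], x@riderId[i], x@rideId[i], x@tStart[i], x@rate)
})

#' Combine SegmentSets (shared channel count and window length required)
#' @param x,... SegmentSets to combine.
#' @export
setMethod("rbind2", signature("SegmentSet", "SegmentSet"), function(x, y) {
  stopifnot(identical(dim(x@x)[-1], dim(y@x)[-1]), x@rate == y@rate)
  n1 <- dim(x@x)[1]; n2 <- dim(y@x)[1]
  arr <- array(0, c(n1 + n2, dim(x@x)[2], dim(x@x)[3]))
  if (n1) arr[seq_len(n1), , ] <- x@x
  if (n2) arr[n1 + seq_len(n2), , ] <- y@x
  SegmentSet(arr, c(as.character(x@y), as.character(y@y)),
             c(x@horseId, y@horseId), c(x@riderId, y@riderId),
             c(x@rideId, y@rideId), c(x@tStart, y@tStart), x@rate)
})

#' Bind a list of SegmentSets into one
#' @param sets list of \linkS4class{SegmentSet} objects (empty ones allowed).
#' @return one \linkS4class{SegmentSet}.
#' @export
bindSegmentSets <- function(sets) {
  sets <- Filter(function(s) nSegments(s) > 0, sets)
  if (!length(sets)) eqInsufficientData("no segments to bind")
  Reduce(rbind2, sets)
}

#' @rdname ProbSeries-class
#' @param x a \linkS4class{ProbSeries}.
#' @export
setGeneric("rawProbs", function(x) standardGeneric("rawProbs"))
#' @rdname ProbSeries-class
#' @export
setGeneric("smoothedProbs", function(x) standardGeneric("smoothedProbs"))
#' @rdname ProbSeries-class
#' @export
setGeneric("hardLabels", function(x) standardGeneric("hardLabels"))
#' @rdname ProbSeries-class
#' @export
setGeneric("finalLabels", function(x) standardGeneric("finalLabels"))

setMethod("rawProbs", "ProbSeries", function(x) x@h)
setMethod("smoothedProbs", "ProbSeries", function(x) x@z)
setMethod("hardLabels", "ProbSeries", function(x) x@g)
setMethod("finalLabels", "ProbSeries", function(x) x@gPrime)

setMethod("show", "ProbSeries", function(object) {
  cat(sprintf("ProbSeries: %d steps%s\n", nrow(object@h),
              if (nrow(object@z)) ", smoothed" else ""))
})

setMethod("show", "GaitClassifier", function(object) {
  cat(sprintf("GaitClassifier <%s>: ni=%d, %s\n", object@arch,
              object@config$ni,
              if (nrow(object@history)) sprintf("trained %d epochs",
                                                max(object@history$epoch))
              else "untrained"))
})

#' @rdname GaitClassifier-class
#' @param x a \linkS4class{GaitClassifier}.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
setMethod("trainingHistory", "GaitClassifier", function(x) x@history)
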