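## Validation protocol: agreement between the limb-sensor labelling system
## and a panel of judges, with exclusion periods around gait transitions.
##
## Judge label coding: NoMajority = -2, NotClassified = -1, Halt = 0,
## Walk = 1, Trot = 2, Tolt = 3, LeftCanter = 4, RightCanter = 5, Pace = 6.
## Left and right canter stay distinct throughout.

#' Judge label codes
#'
#' Integer codes of the labels judges assign while watching ride videos,
#' including the bookkeeping values for "not yet classified" (-1) and
#' "no majority / disputed" (-2).
#'
#' @return named integer vector.
#' @export
judgeLabelCodes <- function() {
  c(NoMajority = -2L, NotClassified = -1L, Halt = 0L, Walk = 1L, Trot = 2L,
    Tolt = 3L, LeftCanter = 4L, RightCanter = 5L, Pace = 6L)
}

.tsToJudge <- c("Standing" = 0L, "Halt" = 0L, "Walk" = 1L, "Trot" = 2L,
                "Tölt" = 3L, "L Canter" = 4L, "R Canter" = 5L,
                "L Cross Canter" = 4L, "R Cross Canter" = 5L,
                "Flying Pace" = 6L)

#' Map labelling-system labels to judge codes
#'
#' For the agreement protocol only: standing maps to Halt(0), the canters
#' keep their lead side, cross canters map to the canter of the same lead.
#' (Distinct from the five-gait mapping used by the classification
#' pipeline.)
#'
#' @param tsLabel character vector of labelling-system labels.
#' @return integer vector of judge codes.
#' @export
tsToJudgeCode <- function(tsLabel) {
  bad <- setdiff(unique(tsLabel), names(.tsToJudge))
  if (length(bad)) eqVocabularyError("unknown gait label '%s'", bad[1])
  unname(.tsToJudge[tsLabel])
}

.heldCodeAt <- function(stream, t) {
  ## click-and-hold: a judge's click holds until the next click; before the
  ## first click the judge has not classified (-1)
  idx <- findInterval(t, stream$t)
  out <- rep(-1L, length(t))
  out[idx >= 1L] <- stream$code[idx[idx >= 1L]]
  out
}

.mergeRuns <- function(t, code) {
  keep <- c(TRUE, code[-1] != code[-length(code)])
  data.frame(t = t[keep], code = code[keep])
}

#' Aggregate judge streams into a consensus series
#'
#' Every \code{tick} seconds the label held by each judge is sampled and the
#' most common label is taken; a tie for most common means there is no
#' majority and yields \code{-2}. Consecutive equal values are merged into
#' change points.
#'
#' @param streams list of judge streams, each a data.frame \code{t,code} of
#'   time-ordered clicks (held until the next click).
#' @param tick aggregation interval in seconds (default 0.25).
#' @param tEnd end of the observation window (default: last click time).
#' @return data.frame \code{t,code}: the aggregated series as change
#'   points, each holding until the next.
#' @export
aggregateJudges <- function(streams, tick = 0.25, tEnd = NULL) {
  if (!length(streams)) eqInsufficientData("no judge streams")
  if (is.null(tEnd)) tEnd <- max(vapply(streams, function(s) max(s$t), 0))
  ticks <- seq(0, tEnd, by = tick)
  held <- vapply(streams, function(s) .heldCodeAt(s, ticks),
                 integer(length(ticks)))
  held <- matrix(held, nrow = length(ticks))
  agg <- apply(held, 1, function(v) {
    tb <- table(v)
    mx <- max(tb)
    winners <- as.integer(names(tb)[tb == mx])
    if (length(winners) > 1L) -2L else winners
  })
  .mergeRuns(ticks, agg)
}

#' Timeline of labelling-system predictions
#'
#' Slides a window of \code{window} seconds in steps of \code{step} over the
#' label events; each window's most frequent label is paired with the
#' window's center time. The first event's timestamp is subtracted first,
#' so the timeline starts at 0 s. Windows containing no event carry the
#' previous window's label.
#'
#' @param events data.frame \code{t,label} of labelling-system events.
#' @param window window length in seconds (default 1).
#' @param step step between window centers in seconds (default 0.5).
#' @return data.frame \code{t,label,code} at \code{0, step, 2 step, ...}.
#' @export
tsTimeline <- function(events, window = 1.0, step = 0.5) {
  if (!nrow(events)) eqInsufficientData("no label events")
  t <- events$t - events$t[1]
  centers <- seq(0, max(t), by = step)
  lab <- character(length(centers))
  prev <- NA_character_
  for (i in seq_along(centers)) {
    inw <- which(t >= centers[i] - window / 2 - 1e-9 &
                 t <= centers[i] + window / 2 + 1e-9)
    if (!length(inw)) {
      lab[i] <- prev
    } else {
      tb <- table(events$label[inw])
      lab[i] <- names(tb)[which.max(tb)]
      prev <- lab[i]
    }
  }
  data.frame(t = centers, label = lab, code = tsToJudgeCode(lab))
}

#' Pair predictions with judge truth into test cases
#'
#' For each timeline point inside the span of the aggregated judge series,
#' the judge label holding at that instant becomes the truth. Cases whose
#' truth is \code{-1} (not yet classified) or \code{-2} (no majority) are
#' discarded.
#'
#' @param tsSeries data.frame \code{t,code} from \code{\link{tsTimeline}}.
#' @param judgeSeries data.frame \code{t,code} from
#'   \code{\link{aggregateJudges}}.
#' @param tEnd end of the judges' observation window (default: no upper
#'   bound beyond the prediction series).
#' @return data.frame \code{t,predicted,truth}.
#' @export
pairTestCases <- function(tsSeries, judgeSeries, tEnd = NULL) {
  lo <- judgeSeries$t[1]
  hi <- if (is.null(tEnd)) Inf else tEnd
  inSpan <- tsSeries$t >= lo & tsSeries$t <= hi
  if (!any(inSpan))
    eqCoverageError("prediction and judge series do not overlap")
  tt <- tsSeries$t[inSpan]
  truth <- .heldCodeAt(judgeSeries, tt)
  cases <- data.frame(t = tt, predicted = tsSeries$code[inSpan],
                      truth = truth)
  cases[!cases$truth %in% c(-1L, -2L), , drop = FALSE]
}

#' Drop test cases near transitions
#'
#' Removes any case within \code{tsMs} milliseconds of a prediction-series
#' transition or \code{judgeMs} milliseconds of a judge-series transition
#' (inclusive radii).
#'
#' @param cases data.frame from \code{\link{pairTestCases}}.
#' @param tsTransitions,judgeTransitions numeric vectors of transition
#'   times (seconds), i.e. the change points of each series.
#' @param tsMs,judgeMs exclusion radii in milliseconds.
#' @return the filtered cases.
#' @export
applyExclusions <- function(cases, tsTransitions, judgeTransitions,
                            tsMs, judgeMs) {
  if (tsMs < 0 || judgeMs < 0) eqConfigError("exclusion radii must be >= 0")
  keep <- rep(TRUE, nrow(cases))
  .near <- function(t, trans, radius) {
    if (!length(trans) || radius <= 0) return(rep(FALSE, length(t)))
    vapply(t, function(x) any(abs(x - trans) <= radius + 1e-9), logical(1))
  }
  keep <- keep & !.near(cases$t, tsTransitions, tsMs / 1000)
  keep <- keep & !.near(cases$t, judgeTransitions, judgeMs / 1000)
  cases[keep, , drop = FALSE]
}

#' Transition times of a label series
#'
#' Times at which the series' code differs from its predecessor. Works both
#' for dense grid series (\code{\link{tsTimeline}}) and for merged
#' change-point series (\code{\link{aggregateJudges}}).
#'
#' @param series data.frame \code{t,code}.
#' @return numeric vector of transition times.
#' @export
seriesTransitions <- function(series) {
  if (nrow(series) < 2L) return(numeric(0))
  chg <- series$code[-1] != series$code[-nrow(series)]
  series$t[-1][chg]
}

#' Accuracy for a grid of exclusion radii
#'
#' For every combination of prediction-side and judge-side exclusion radius,
#' counts the surviving test cases and the fraction of agreements.
#'
#' @param cases data.frame from \code{\link{pairTestCases}}.
#' @param tsTransitions,judgeTransitions transition times (seconds).
#' @param tsGrid,judgeGrid radii grids in milliseconds
#'   (default \code{c(0, 1000, 2000)}).
#' @return data.frame with columns \code{ts_ms, judge_ms, n_cases,
#'   accuracy} (accuracy in percent).
#' @export
agreementTable <- function(cases, tsTransitions, judgeTransitions,
                           tsGrid = c(0, 1000, 2000),
                           judgeGrid = c(0, 1000, 2000)) {
  if (!length(tsGrid) || !length(judgeGrid))
    eqConfigError("radius grids must be nonempty")
  rows <- list()
  for (a in tsGrid) for (b in judgeGrid) {
    f <- applyExclusions(cases, tsTransitions, judgeTransitions, a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      ts_ms = a, judge_ms = b, n_cases = nrow(f),
      accuracy = if (nrow(f)) 100 * mean(f$predicted == f$truth) else NA_real_)
  }
  do.call(rbind, rows)
}

#' Read / write judge click streams
#'
#' CSV dialect \code{t,code} with integer judge codes.
#'
#' @param path CSV path.
#' @return data.frame \code{t,code}.
#' @export
readJudgeLog <- function(path) {
  df <- .readCsv(path)
  missing <- setdiff(c("t", "code"), names(df))
  if (length(missing))
    eqFormatError("missing mandatory column '%s' in %s", missing[1], path)
  .checkMonotone(df$t, path)
  bad <- setdiff(unique(df$code), judgeLabelCodes())
  if (length(bad)) eqVocabularyError("unknown judge code '%s'", bad[1])
  df[, c("t", "code")]
}

#' @rdname readJudgeLog
#' @param stream data.frame \code{t,code}.
#' @export
writeJudgeLog <- function(stream, path) .writeCsvFull(stream, path)
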