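## Post-processing of sequential class probabilities: exponential weight
## decay followed by a sliding majority vote. Applied to prediction streams
## of whole rides, where consecutive overlapping segments are in temporal
## order and isolated single-step mistakes are implausible gait switches.

#' Exponential weight decay of a probability stream
#'
#' Recursively averages each probability vector with its predecessor's
#' smoothed value: \eqn{z_0 = h_0}, \eqn{z_t = (z_{t-1} + h_t) / 2}.
#' Unrolled, \eqn{z_t} is a convex combination of all vectors up to
#' \eqn{t} with weights \eqn{1/2, 1/4, \dots} backwards in time, so each
#' output row stays on the probability simplex.
#'
#' @param h numeric matrix, one probability vector per row.
#' @return matrix of the same shape with the smoothed vectors.
#' @examples
#' expDecay(rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0)))[2, ]  # 0.5 0.5 0 0 0
#' @export
expDecay <- function(h) {
  h <- as.matrix(h)
  if (!nrow(h)) eqInsufficientData("empty probability stream")
  z <- h
  for (t in seq_len(nrow(h))[-1])
    z[t, ] <- (z[t - 1, ] + h[t, ]) / 2
  z
}

#' Hard gait label from a probability vector
#'
#' Index of the maximal component; ties are broken by the lowest gait code
#' (deterministic).
#'
#' @param z numeric 5-vector, or a matrix of row vectors.
#' @return factor of gaits.
#' @export
argmaxGait <- function(z) {
  z <- rbind(z)
  gaitFactor(gaitLevels()[max.col(z, ties.method = "first")])
}

#' Sliding majority vote over a label sequence
#'
#' Replaces each label by the most common label in a centered window of
#' \code{width} steps. The window is truncated at the sequence edges; a tie
#' for the most common label keeps the center label \eqn{g_t}.
#'
#' @param g factor or character sequence of gait labels.
#' @param width odd window width (default 7).
#' @return factor of smoothed labels, same length as \code{g}.
#' @export
majoritySmooth <- function(g, width = 7L) {
  if (width %% 2L == 0L) eqConfigError("majority window width must be odd")
  lv <- if (is.factor(g)) levels(g) else gaitLevels()
  gi <- if (is.factor(g)) as.integer(g) else match(g, lv)
  n <- length(gi)
  half <- (width - 1L) %/% 2L
  out <- integer(n)
  for (t in seq_len(n)) {
    w <- gi[max(1L, t - half):min(n, t + half)]
    cnt <- tabulate(w, nbins = length(lv))
    mx <- max(cnt)
    winners <- which(cnt == mx)
    out[t] <- if (length(winners) == 1L) winners else gi[t]
  }
  factor(lv[out], levels = lv)
}

#' Apply the full smoothing pipeline to a ProbSeries
#'
#' Fills the \code{z} (exponential decay), \code{g} (argmax) and
#' \code{gPrime} (majority vote) slots of a prediction stream.
#'
#' @param ps a \linkS4class{ProbSeries} holding raw probabilities.
#' @param width odd majority-vote window (default 7).
#' @return the completed \linkS4class{ProbSeries}.
#' @export
smoothProbSeries <- function(ps, width = 7L) {
  z <- expDecay(rawProbs(ps))
  g <- argmaxGait(z)
  gp <- majoritySmooth(g, width)
  colnames(z) <- gaitLevels()
  new("ProbSeries", t = ps@t, h = ps@h, z = z, g = g, gPrime = gp)
}

#' Export a smoothed prediction stream as a data.frame
#'
#' One row per step: time, raw argmax gait, smoothed gait and the five raw
#' class probabilities.
#'
#' @param ps a smoothed \linkS4class{ProbSeries}.
#' @return data.frame with columns \code{t,raw_gait,smoothed_gait,p_walk,
#'   p_trot,p_tolt,p_canter,p_pace}.
#' @export
probSeriesFrame <- function(ps) {
  h <- rawProbs(ps)
  out <- data.frame(t = ps@t,
                    raw_gait = as.character(argmaxGait(h)),
                    smoothed_gait = as.character(finalLabels(ps)))
  p <- as.data.frame(h)
  names(p) <- c("p_walk", "p_trot", "p_tolt", "p_canter", "p_pace")
  cbind(out, p)
}
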