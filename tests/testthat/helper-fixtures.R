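# Fixtures built in code; no data files.

# Uniform trace with a single named channel computed from time.
makeTrace <- function(duration, rate, f = function(t) 0 * t,
                      channel = "az", frame = "device") {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  ch <- matrix(f(t), ncol = 1, dimnames = list(NULL, channel))
  SensorTrace(t, ch, rate = rate, frame = frame)
}

# Six-channel world-frame trace for frame tests.
makeWorldTrace <- function(n = 100, rate = 50, seed = 1) {
  set.seed(seed)
  t <- seq(0, (n - 1) / rate, by = 1 / rate)
  ch <- matrix(rnorm(6 * n), n, 6,
               dimnames = list(NULL, c("ax", "ay", "az", "gx", "gy", "gz")))
  SensorTrace(t, ch, rate = rate, frame = "world")
}

# Random unit quaternion.
randomQuat <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

# Rotation matrix from a scalar-first unit quaternion (independent oracle
# for applyQuaternion).
quatMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Independent brute-force segment enumerator mirroring the documented
# grid-snapping rule: candidates anchored at the first sample inside each
# interval, advancing by a whole number of samples; a candidate is kept when
# every sample lies in the interval and no switch falls strictly within the
# exclusion radius of the window extent [s, s + window).
bruteForceStarts <- function(t, timeline, window, rate, overlap = 0.9,
                             exclusion = 2, paceStep = 0.02) {
  iv <- timelineIntervals(timeline)
  switches <- transitionTimes(timeline)
  wlen <- round(window * rate)
  n <- length(t)
  keep <- numeric(0)
  for (k in seq_len(nrow(iv))) {
    if (iv$label[k] == "Discarded") next
    step <- if (iv$label[k] == "FlyingPace") {
      max(1, round(paceStep * rate))
    } else {
      max(1, round((1 - overlap) * window * rate))
    }
    i0 <- which(t >= iv$start[k] - 1e-9)[1]
    if (is.na(i0) || i0 > n - wlen + 1) next
    for (i in seq(i0, n - wlen + 1, by = step)) {
      s <- t[i]; eEx <- s + wlen / rate      # extent end (exclusive)
      if (!is.na(iv$end[k]) && t[i + wlen - 1] >= iv$end[k] - 1e-9) next
      bad <- FALSE
      for (sw in switches) {
        if (sw > s - exclusion + 1e-9 && sw < eEx + exclusion - 1e-9) {
          bad <- TRUE; break
        }
      }
      if (!bad) keep <- c(keep, s)
    }
  }
  sort(keep)
}

# Small separable 5-class segment set for model tests: class k is a sine at
# a class-specific frequency plus a class offset.
makeToySegments <- function(n = 64, ni = 3, Tn = 25, rate = 50, seed = 1,
                            horseId = NULL) {
  set.seed(seed)
  y <- gaitLevels()[(seq_len(n) - 1) %% 5 + 1]
  x <- array(0, c(n, ni, Tn))
  tt <- (0:(Tn - 1)) / rate
  for (i in seq_len(n)) {
    k <- match(y[i], gaitLevels())
    for (j in seq_len(ni))
      x[i, j, ] <- sin(2 * pi * (2 + 2 * k) * tt + j) + 0.3 * k +
        0.05 * rnorm(Tn)
  }
  if (is.null(horseId)) horseId <- rep(1L, n)
  SegmentSet(x, y, horseId, horseId, horseId, seq_len(n) * 0.1, rate)
}

# Brute-force majority vote (independent oracle for majoritySmooth).
bruteMajority <- function(g, width = 7) {
  n <- length(g)
  half <- (width - 1) %/% 2
  out <- g
  for (i in seq_len(n)) {
    w <- g[max(1, i - half):min(n, i + half)]
    cnt <- table(w)
    winners <- names(cnt)[cnt == max(cnt)]
    out[i] <- if (length(winners) == 1) winners else g[i]
  }
  out
}
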