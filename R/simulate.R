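## Synthetic ride generator.
##
## Forward signal model (invented for testability; the field provides no
## public phone-IMU corpus for these horses): each hoof-on contributes a
## raised-cosine force bump to the horse-frame acceleration -- vertical
## always, lateral with the sign of the limb's side, longitudinal as a
## zero-mean braking/propulsion couplet -- while the trunk's roll/pitch/yaw
## rates oscillate at the beat and stride frequencies. This preserves
## exactly what a gait classifier exploits: beat count, beat frequency,
## lateral symmetry pattern and duty factor. Device-frame output is the
## horse-frame truth rotated through the heading and a fixed random device
## orientation, with additive Gaussian noise.

#' Default gait profiles
#'
#' Footfall timing and signal amplitudes for the five gaits. Phases are
#' stride-cycle fractions in [0,1) per limb (LH, LF, RH, RF): walk and
#' toelt are even four-beat (lateral sequence), trot beats in diagonal
#' pairs, flying pace in lateral pairs, canter is three-beat. Duty is the
#' stance fraction of the stride; suspension marks gaits with a flight
#' phase. Stride-frequency ranges reach 2.5 strides/s for toelt (fast toelt
#' emits ten labels per second: four beats per stride).
#'
#' @return named list of gait profiles.
#' @export
defaultGaitProfiles <- function() {
  list(
    Walk = list(name = "Walk",
                phases = c(LH = 0, LF = 0.25, RH = 0.5, RF = 0.75),
                strideFreq = c(0.8, 1.2), duty = 0.6, suspension = FALSE,
                ampVertical = 2.0, ampLateral = 0.6, ampLongitudinal = 0.5,
                gyroAmp = 20, speed = 1.5),
    Trot = list(name = "Trot",
                phases = c(LH = 0, LF = 0.5, RH = 0.5, RF = 0),
                strideFreq = c(1.4, 1.9), duty = 0.4, suspension = TRUE,
                ampVertical = 5.0, ampLateral = 1.2, ampLongitudinal = 1.0,
                gyroAmp = 35, speed = 3.5),
    Tolt = list(name = "Tolt",
                phases = c(LH = 0, LF = 0.25, RH = 0.5, RF = 0.75),
                strideFreq = c(1.7, 2.5), duty = 0.45, suspension = FALSE,
                ampVertical = 3.5, ampLateral = 1.0, ampLongitudinal = 0.8,
                gyroAmp = 30, speed = 4.0),
    Canter = list(name = "Canter",
                  phases = c(LH = 0, LF = 0.3, RH = 0.3, RF = 0.6),
                  strideFreq = c(1.5, 2.0), duty = 0.4, suspension = TRUE,
                  ampVertical = 4.5, ampLateral = 1.5, ampLongitudinal = 1.5,
                  gyroAmp = 40, speed = 5.5),
    FlyingPace = list(name = "FlyingPace",
                      phases = c(LH = 0, LF = 0, RH = 0.5, RF = 0.5),
                      strideFreq = c(1.7, 2.2), duty = 0.35,
                      suspension = TRUE,
                      ampVertical = 5.5, ampLateral = 2.5,
                      ampLongitudinal = 1.2, gyroAmp = 45, speed = 7.0))
}

.nBeats <- function(profile) length(unique(profile$phases))

#' Footfall schedule for one bout
#'
#' Hoof-on of limb L occurs at \code{(k + phase_L) / strideFreq} for
#' \code{k = 0, 1, ...}; hoof-off follows after \code{duty / strideFreq}.
#' All events lie within \code{[0, duration]}.
#'
#' @param profile a gait profile from \code{\link{defaultGaitProfiles}}.
#' @param duration bout duration in seconds.
#' @param strideFreq strides per second.
#' @return data.frame \code{limb,on,off}, ordered by \code{on}.
#' @export
footfallSchedule <- function(profile, duration, strideFreq) {
  if (duration <= 0) eqConfigError("duration must be positive")
  rows <- lapply(names(profile$phases), function(limb) {
    ph <- profile$phases[[limb]]
    k <- 0:ceiling(duration * strideFreq)
    on <- (k + ph) / strideFreq
    on <- on[on < duration - 1e-12]
    if (!length(on)) return(NULL)
    data.frame(limb = limb, on = on,
               off = pmin(on + profile$duty / strideFreq, duration))
  })
  out <- do.call(rbind, rows)
  out[order(out$on, out$limb), , drop = FALSE]
}

.limbSide <- function(limb) ifelse(substr(limb, 1, 1) == "L", 1, -1)

## Horse-frame signal for one bout on an existing grid starting at 0.
.boutSignal <- function(profile, schedule, t, strideFreq, mirror = FALSE) {
  nb <- .nBeats(profile)
  beatFreq <- strideFreq * nb
  w <- profile$duty / beatFreq          # bump width: stance of one beat
  ax <- numeric(length(t)); ay <- ax; az <- ax
  side <- .limbSide(schedule$limb) * if (mirror) -1 else 1
  for (i in seq_len(nrow(schedule))) {
    on <- schedule$on[i]
    j <- which(t >= on & t <= on + w)
    if (!length(j)) next
    u <- (t[j] - on) / w
    bump <- 0.5 * (1 - cos(2 * pi * u))
    az[j] <- az[j] + profile$ampVertical * bump
    ay[j] <- ay[j] + side[i] * profile$ampLateral * bump
    ax[j] <- ax[j] + profile$ampLongitudinal * sin(2 * pi * u) * bump
  }
  gx <- profile$gyroAmp * sin(2 * pi * beatFreq * t)
  gy <- 0.7 * profile$gyroAmp * sin(2 * pi * strideFreq * t + 1)
  gz <- 0.3 * profile$gyroAmp * sin(2 * pi * strideFreq * t + 2)
  cbind(ax = ax, ay = ay, az = az + 9.81,
        gx = gx, gy = gy, gz = gz)
}

#' Synthesize a horse-frame IMU trace from a footfall schedule
#'
#' Deterministic signal model for a single bout: per-hoof-on raised-cosine
#' impulses on the acceleration channels plus trunk-oscillation gyro
#' channels and gravity on z. Noise-free; noise and frame rotations are
#' added by \code{\link{simulateRide}}.
#'
#' @param schedule data.frame from \code{\link{footfallSchedule}}.
#' @param profile the gait profile.
#' @param duration bout duration (seconds).
#' @param rate sample rate (Hz).
#' @param strideFreq strides per second.
#' @param mirror flip the lateral sign pattern (right-lead canter).
#' @return horse-frame \linkS4class{SensorTrace}.
#' @export
synthImu <- function(schedule, profile, duration, rate = 50,
                     strideFreq, mirror = FALSE) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  ch <- .boutSignal(profile, schedule, t, strideFreq, mirror)
  SensorTrace(t, ch, rate = rate, frame = "horse")
}

.randomUnitQuat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

.tsLabelFor <- function(gait, lead = "L") {
  switch(gait,
         Walk = "Walk", Trot = "Trot", Tolt = "Tölt",
         Canter = paste(lead, "Canter"), FlyingPace = "Flying Pace",
         Standing = "Standing",
         eqVocabularyError("unknown gait '%s'", gait))
}

.judgeCodeFor <- function(gait, lead = "L") {
  tsToJudgeCode(.tsLabelFor(gait, lead))
}

#' Plan a ride
#'
#' A ride is an ordered list of bouts; each bout has a gait, duration,
#' speed, initial heading and turn rate. Stride frequencies default to a
#' seeded draw from the profile's range. Canter bouts alternate lead by
#' default.
#'
#' @param bouts data.frame with columns \code{gait,duration} and optionally
#'   \code{speed,theta0,turnRate,strideFreq,lead}.
#' @param horseId,riderId,rideId integer provenance.
#' @param rate sample rate in Hz (default 50).
#' @param noiseAcc,noiseGyro additive Gaussian noise SD (m/s^2, deg/s).
#' @param seed ride seed; a fixed seed makes the whole bundle reproducible.
#' @param judgeLag range of judges' reaction lags in seconds.
#' @param nJudges judge panel size.
#' @param disagreeProb probability that a judge briefly registers a wrong
#'   label right after a transition.
#' @return a ride plan (named list) for \code{\link{simulateRide}}.
#' @export
ridePlan <- function(bouts, horseId = 1L, riderId = 1L, rideId = 1L,
                     rate = 50, noiseAcc = 0.3, noiseGyro = 3,
                     seed = 1L, judgeLag = c(0.2, 0.6), nJudges = 4L,
                     disagreeProb = 0) {
  stopifnot(is.data.frame(bouts), all(c("gait", "duration") %in% names(bouts)))
  if (any(bouts$duration <= 0)) eqConfigError("bout durations must be positive")
  list(bouts = bouts, horseId = as.integer(horseId),
       riderId = as.integer(riderId), rideId = as.integer(rideId),
       rate = rate, noiseAcc = noiseAcc, noiseGyro = noiseGyro,
       seed = as.integer(seed), judgeLag = judgeLag,
       nJudges = as.integer(nJudges), disagreeProb = disagreeProb)
}

#' Simulate a complete ride
#'
#' Generates, deterministically from the plan's seed: the horse-frame
#' ground-truth trace, the device-frame trace (rotated through the true
#' heading and a fixed random device orientation, with stored per-sample
#' quaternions and additive noise), a 1 Hz GPS track following the heading
#' profile, gait-label events at every hoof-on, judge click streams with
#' seeded reaction lags, and the ground-truth timeline.
#'
#' @param plan a \code{\link{ridePlan}}.
#' @return list with elements \code{deviceTrace}, \code{horseTruth},
#'   \code{headingTrue} (data.frame \code{t,theta}), \code{gps},
#'   \code{labelEvents}, \code{judgeStreams}, \code{timeline},
#'   \code{deviceQuat}, \code{plan}.
#' @export
simulateRide <- function(plan) {
  set.seed(plan$seed)
  profiles <- defaultGaitProfiles()
  bouts <- plan$bouts
  nb <- nrow(bouts)
  if (is.null(bouts$speed)) bouts$speed <- NA_real_
  if (is.null(bouts$theta0)) bouts$theta0 <- stats::runif(nb, 0, 360)
  if (is.null(bouts$turnRate)) bouts$turnRate <- 0
  if (is.null(bouts$strideFreq)) bouts$strideFreq <- NA_real_
  if (is.null(bouts$lead)) {
    bouts$lead <- rep("L", nb)
    ci <- which(bouts$gait == "Canter")
    bouts$lead[ci] <- rep(c("L", "R"), length.out = length(ci))
  }
  q <- .randomUnitQuat()
  rate <- plan$rate

  tAll <- numeric(0); horseCh <- NULL; theta <- numeric(0)
  events <- list(); startTimes <- cumsum(c(0, bouts$duration))
  for (b in seq_len(nb)) {
    g <- bouts$gait[b]
    t0 <- startTimes[b]; dur <- bouts$duration[b]
    tt <- seq(0, dur - 1 / rate, by = 1 / rate)
    if (g == "Standing") {
      ch <- cbind(ax = 0 * tt, ay = 0 * tt, az = 9.81 + 0 * tt,
                  gx = 0 * tt, gy = 0 * tt, gz = 0 * tt)
      ## standing still emits sporadic labels (no hoof-ons; one per second)
      ev <- data.frame(t = t0 + seq(0.5, dur, by = 1),
                       label = "Standing")
    } else {
      pr <- profiles[[g]]
      f <- bouts$strideFreq[b]
      if (is.na(f)) f <- stats::runif(1, pr$strideFreq[1], pr$strideFreq[2])
      if (is.na(bouts$speed[b])) bouts$speed[b] <- pr$speed
      sch <- footfallSchedule(pr, dur, f)
      ch <- .boutSignal(pr, sch, tt, f, mirror = bouts$lead[b] == "R")
      beatT <- sort(unique(round(sch$on, 9)))
      beatT <- beatT[beatT < dur - 1e-9]
      ev <- data.frame(t = t0 + beatT,
                       label = .tsLabelFor(g, bouts$lead[b]))
    }
    th <- (bouts$theta0[b] + bouts$turnRate[b] * tt) %% 360
    tAll <- c(tAll, t0 + tt)
    horseCh <- rbind(horseCh, ch)
    theta <- c(theta, th)
    events[[b]] <- ev
  }
  events <- do.call(rbind, events)
  events <- events[order(events$t), ]
  events <- events[!duplicated(round(events$t, 9)), ]

  ## noise is added in the horse frame (isotropic, so frame-independent)
  noisy <- horseCh
  noisy[, 1:3] <- noisy[, 1:3] +
    matrix(stats::rnorm(3 * nrow(noisy), 0, plan$noiseAcc), ncol = 3)
  noisy[, 4:6] <- noisy[, 4:6] +
    matrix(stats::rnorm(3 * nrow(noisy), 0, plan$noiseGyro), ncol = 3)

  ## horse -> world (inverse of worldToHorse's yaw rotation)
  s <- sin(theta * pi / 180); co <- cos(theta * pi / 180)
  toWorld <- function(front, left, up) {
    cbind(e = front * s - left * co, n = front * co + left * s, u = up)
  }
  accW <- toWorld(noisy[, "ax"], noisy[, "ay"], noisy[, "az"])
  gyrW <- toWorld(noisy[, "gx"], noisy[, "gy"], noisy[, "gz"])
  ## world -> device with the conjugate of the device->world quaternion
  qc <- quaternionConjugate(q)
  accD <- applyQuaternion(accW, qc)
  gyrD <- applyQuaternion(gyrW, qc)
  devCh <- cbind(accD, gyrD,
                 matrix(q, nrow(accD), 4, byrow = TRUE))
  colnames(devCh) <- c("ax", "ay", "az", "gx", "gy", "gz",
                       "qw", "qx", "qy", "qz")

  deviceTrace <- SensorTrace(tAll, devCh, rate = rate, frame = "device")
  horseTruth <- SensorTrace(tAll, noisy, rate = rate, frame = "horse")
  headingTrue <- data.frame(t = tAll, theta = theta)

  gps <- .synthGpsTrack(bouts, startTimes)
  judges <- .synthJudgeStreams(bouts, startTimes, plan)

  truthLab <- vapply(seq_len(nb), function(b)
    if (bouts$gait[b] == "Standing") "Discarded" else bouts$gait[b], "")
  keep <- c(TRUE, truthLab[-1] != truthLab[-nb])
  timeline <- GaitTimeline(startTimes[-(nb + 1)][keep], truthLab[keep])

  list(deviceTrace = deviceTrace, horseTruth = horseTruth,
       headingTrue = headingTrue, gps = gps, labelEvents = events,
       judgeStreams = judges, timeline = timeline, deviceQuat = q,
       plan = plan, bouts = bouts)
}

#' Synthesize the 1 Hz GPS track of a plan
#'
#' Integrates the position along each bout's speed and heading profile and
#' emits one fix per second. On straight bouts the bearing of consecutive
#' fixes recovers the bout heading to within a degree.
#'
#' @param plan a \code{\link{ridePlan}} whose bouts carry \code{theta0}
#'   (and optionally \code{turnRate}, \code{speed}).
#' @return data.frame \code{t,lat,lon,speed}.
#' @export
synthGps <- function(plan) {
  bouts <- plan$bouts
  if (is.null(bouts$theta0)) eqConfigError("bouts need a theta0 column")
  if (is.null(bouts$turnRate)) bouts$turnRate <- 0
  if (is.null(bouts$speed) || anyNA(bouts$speed)) {
    pr <- defaultGaitProfiles()
    sp <- vapply(bouts$gait, function(g)
      if (g == "Standing") 0 else pr[[g]]$speed, numeric(1))
    if (is.null(bouts$speed)) bouts$speed <- sp
    bouts$speed[is.na(bouts$speed)] <- sp[is.na(bouts$speed)]
  }
  .synthGpsTrack(bouts, cumsum(c(0, bouts$duration)))
}

## 1 Hz GPS track integrated along the bout speed/heading profile.
.synthGpsTrack <- function(bouts, startTimes, lat0 = 64.0, lon0 = -21.0) {
  R <- 6371000
  tEnd <- startTimes[length(startTimes)]
  fixT <- seq(0, floor(tEnd), by = 1)
  lat <- numeric(length(fixT)); lon <- lat; spd <- lat
  lat[1] <- lat0; lon[1] <- lon0
  dt <- 0.1
  curLat <- lat0; curLon <- lon0
  for (i in seq_len(length(fixT) - 1)) {
    tt <- seq(fixT[i], fixT[i + 1] - dt, by = dt)
    b <- findInterval(tt, startTimes, rightmost.closed = TRUE)
    b[b < 1] <- 1; b[b > nrow(bouts)] <- nrow(bouts)
    v <- bouts$speed[b]
    v[bouts$gait[b] == "Standing"] <- 0
    th <- (bouts$theta0[b] + bouts$turnRate[b] * (tt - startTimes[b])) * pi / 180
    curLat <- curLat + sum(v * cos(th) * dt) / R * 180 / pi
    curLon <- curLon + sum(v * sin(th) * dt) / (R * cos(curLat * pi / 180)) * 180 / pi
    lat[i + 1] <- curLat; lon[i + 1] <- curLon
    spd[i + 1] <- mean(v)
  }
  spd[1] <- spd[2]
  data.frame(t = fixT, lat = lat, lon = lon, speed = spd)
}

.synthJudgeStreams <- function(bouts, startTimes, plan) {
  nb <- nrow(bouts)
  codes <- vapply(seq_len(nb), function(b)
    .judgeCodeFor(bouts$gait[b], bouts$lead[b]), integer(1))
  lapply(seq_len(plan$nJudges), function(j) {
    t <- numeric(0); code <- integer(0)
    for (b in seq_len(nb)) {
      lag <- stats::runif(1, plan$judgeLag[1], plan$judgeLag[2])
      if (plan$disagreeProb > 0 && b > 1 &&
          stats::runif(1) < plan$disagreeProb) {
        wrong <- sample(setdiff(0:6, codes[b]), 1)
        t <- c(t, startTimes[b] + lag)
        code <- c(code, wrong)
        lag <- lag + stats::runif(1, 0.1, 0.3)
      }
      t <- c(t, startTimes[b] + lag)
      code <- c(code, codes[b])
    }
    data.frame(t = t, code = code)
  })
}

#' Write a simulated ride to CSV logs
#'
#' Emits the ride bundle in the package's CSV dialects: IMU (with
#' quaternions), GPS, label events and one click stream per judge.
#'
#' @param ride bundle from \code{\link{simulateRide}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of written paths.
#' @export
writeRideBundle <- function(ride, dir, prefix = "ride") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(imu = file.path(dir, paste0(prefix, "_imu.csv")),
             gps = file.path(dir, paste0(prefix, "_gps.csv")),
             labels = file.path(dir, paste0(prefix, "_labels.csv")))
  writeSensorLog(ride$deviceTrace, paths[["imu"]])
  writeGpsLog(ride$gps, paths[["gps"]])
  writeLabelLog(ride$labelEvents, paths[["labels"]])
  for (j in seq_along(ride$judgeStreams)) {
    p <- file.path(dir, sprintf("%s_judge%d.csv", prefix, j))
    writeJudgeLog(ride$judgeStreams[[j]], p)
    paths[[paste0("judge", j)]] <- p
  }
  invisible(paths)
}

#' Simulate a multi-horse corpus
#'
#' Builds one ride per horse with per-gait bout durations proportional to
#' the gait mix each horse contributed in the reference duration table
#' (clamped to 6--20 s so every available gait yields segments at desk
#' scale; gaits a horse never performed are absent, so only three horses
#' pace). Headings vary between and within bouts so world-frame and
#' horse-frame signals genuinely differ.
#'
#' @param seed corpus seed; ride \code{h} uses seed \code{seed + h}.
#' @param horses number of horses (default 17, matching the reference
#'   table).
#' @param rate sample rate in Hz.
#' @param noiseAcc,noiseGyro noise levels passed to every ride.
#' @return list of ride bundles, one per horse.
#' @export
simulateCorpus <- function(seed = 1L, horses = 17L, rate = 50,
                           noiseAcc = 0.3, noiseGyro = 3) {
  dur <- referenceGaitDurations()
  dur <- dur[dur$horseId <= horses, ]
  rides <- vector("list", nrow(dur))
  for (i in seq_len(nrow(dur))) {
    h <- dur$horseId[i]
    gaits <- gaitLevels()[vapply(gaitLevels(),
                                 function(g) dur[[g]][i] > 0, logical(1))]
    boutDur <- vapply(gaits, function(g)
      min(20, max(6, round(dur[[g]][i] / 40))), numeric(1))
    set.seed(seed + 1000L + h)
    bouts <- data.frame(gait = gaits, duration = boutDur,
                        theta0 = stats::runif(length(gaits), 0, 360),
                        turnRate = sample(c(-12, 0, 12), length(gaits),
                                          replace = TRUE))
    plan <- ridePlan(bouts, horseId = h, riderId = ((h * 5) %% 14) + 1L,
                     rideId = h, rate = rate, noiseAcc = noiseAcc,
                     noiseGyro = noiseGyro, seed = seed + h)
    rides[[i]] <- simulateRide(plan)
  }
  rides
}

#' Run the preprocessing pipeline on simulated rides
#'
#' For each ride: rotate the device trace to the world frame with the
#' stored quaternions; for the horse frame, additionally estimate the
#' heading from the 1 Hz GPS track (bearing of consecutive fixes, circular
#' 1 s smoothing, zero-order hold) exactly as for real data; select the
#' feature channels; build the label timeline from the label events; and
#' cut segments.
#'
#' @param rides list from \code{\link{simulateCorpus}}.
#' @param frame \code{"world"} or \code{"horse"}.
#' @param use feature channels (see \code{\link{buildFeatureChannels}}).
#' @param window segment window in seconds (default 1.5).
#' @param overlap fractional overlap (default 0.9).
#' @param exclusion transition exclusion in seconds (default 2).
#' @return a combined \linkS4class{SegmentSet}.
#' @export
corpusSegments <- function(rides, frame = c("horse", "world"),
                           use = c("accel", "gyro"), window = 1.5,
                           overlap = 0.9, exclusion = 2.0) {
  frame <- match.arg(frame)
  sets <- lapply(rides, function(rd) {
    tr <- deviceToWorld(rd$deviceTrace)
    if (frame == "horse") {
      hd <- smoothHeading(headingFromGps(rd$gps), window = 1.0)
      tr <- worldToHorse(tr, hd)
    }
    tr <- buildFeatureChannels(tr, gps = rd$gps, use = use)
    tl <- buildTimeline(rd$labelEvents)
    generateSegments(tr, tl, window = window, overlap = overlap,
                     exclusion = exclusion, horseId = rd$plan$horseId,
                     riderId = rd$plan$riderId, rideId = rd$plan$rideId)
  })
  bindSegmentSets(sets)
}
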