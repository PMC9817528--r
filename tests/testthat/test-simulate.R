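test_that("default profiles encode the five footfall patterns", {
  pr <- defaultGaitProfiles()
  expect_setequal(names(pr), gaitLevels())

  nBeats <- vapply(pr, function(p) length(unique(p$phases)), 0L)
  expect_equal(nBeats[["Walk"]], 4L)
  expect_equal(nBeats[["Tolt"]], 4L)
  expect_equal(nBeats[["Trot"]], 2L)
  expect_equal(nBeats[["FlyingPace"]], 2L)
  expect_equal(nBeats[["Canter"]], 3L)

  ## trot beats in diagonal pairs, pace in lateral pairs
  expect_equal(pr$Trot$phases[["LH"]], pr$Trot$phases[["RF"]])
  expect_equal(pr$FlyingPace$phases[["LH"]], pr$FlyingPace$phases[["LF"]])
  ## toelt can reach 2.5 strides/s
  expect_equal(pr$Tolt$strideFreq[2], 2.5)

  ## pairwise distinguishable by (beat count, phase pattern, lateral signs,
  ## duty, stride-frequency band) -- walk and toelt share the four-beat
  ## lateral footfall order and differ in tempo and duty
  sig <- vapply(pr, function(p) {
    paste(length(unique(p$phases)),
          paste(sort(round(unique(p$phases), 3)), collapse = ","),
          paste(names(sort(p$phases)), collapse = ","),
          p$duty, paste(p$strideFreq, collapse = "-"))
  }, "")
  expect_equal(anyDuplicated(sig), 0L)
})

test_that("footfall schedules follow phases, duty and duration", {
  pr <- defaultGaitProfiles()
  sch <- footfallSchedule(pr$Walk, duration = 2, strideFreq = 1)
  expect_equal(nrow(sch), 8)                       # 4 limbs x 2 strides
  expect_true(all(sch$on >= 0 & sch$on <= 2))
  expect_true(all(sch$off - sch$on <= pr$Walk$duty / 1 + 1e-12))

  tr <- footfallSchedule(pr$Trot, 2, 1.5)
  expect_true(all(table(round(tr$on, 9)) == 2))    # simultaneous pairs

  ## fast toelt: 4 hoof-ons per stride at 2.5 strides/s -> 10 events/s
  plan <- ridePlan(data.frame(gait = "Tolt", duration = 10, theta0 = 0,
                              strideFreq = 2.5), seed = 2)
  rd <- simulateRide(plan)
  expect_equal(nrow(rd$labelEvents) / 10, 10, tolerance = 0.05)
})

test_that("vertical spectra peak at the beat frequency", {
  pr <- defaultGaitProfiles()
  for (g in names(pr)) {
    f <- mean(pr[[g]]$strideFreq)
    sch <- footfallSchedule(pr[[g]], 20, f)
    tr <- synthImu(sch, pr[[g]], 20, rate = 50, strideFreq = f)
    z <- traceChannels(tr)[, "az"]; z <- z - mean(z)
    sp <- Mod(stats::fft(z))^2
    n <- length(z)
    freqs <- (seq_len(n) - 1) * 50 / n
    half <- 2:(n %/% 2)
    peak <- freqs[half][which.max(sp[half])]
    beats <- f * length(unique(pr[[g]]$phases))
    expect_lt(abs(peak - beats), 50 / n + 1e-9)    # within one FFT bin
  }
})

test_that("GPS tracks follow heading and speed", {
  plan <- ridePlan(data.frame(gait = "Tolt", duration = 10, theta0 = 0,
                              turnRate = 0, speed = 4), seed = 3)
  gps <- synthGps(plan)
  for (i in 1:(nrow(gps) - 1)) {
    th <- gpsBearing(gps[i, ], gps[i + 1, ])
    expect_true(min(th, 360 - th) < 1)             # due north
  }
  ## consecutive fixes ~4 m apart (haversine oracle)
  d <- geosphere::distHaversine(cbind(gps$lon[-nrow(gps)], gps$lat[-nrow(gps)]),
                                cbind(gps$lon[-1], gps$lat[-1]))
  expect_true(all(abs(d - 4) < 0.1))

  ## a full lap sweeps the heading through 360 degrees
  plan <- ridePlan(data.frame(gait = "Canter", duration = 10, theta0 = 0,
                              turnRate = 36, speed = 5), seed = 3)
  gps <- synthGps(plan)
  hd <- headingFromGps(gps)
  expect_gt(diff(range(unwrapDegrees(hd$theta))), 300)
})

test_that("ride bundles are deterministic in the seed", {
  plan <- ridePlan(data.frame(gait = c("Walk", "FlyingPace"),
                              duration = c(4, 4)), seed = 77)
  a <- simulateRide(plan)
  b <- simulateRide(plan)
  expect_identical(traceChannels(a$deviceTrace), traceChannels(b$deviceTrace))
  expect_identical(a$labelEvents, b$labelEvents)
  expect_identical(a$judgeStreams, b$judgeStreams)
  expect_identical(a$deviceQuat, b$deviceQuat)
})

test_that("label events carry the bout's label and canter alternates lead", {
  plan <- ridePlan(data.frame(gait = "Walk", duration = 5, theta0 = 10),
                   seed = 1)
  rd <- simulateRide(plan)
  expect_true(all(rd$labelEvents$label == "Walk"))

  plan <- ridePlan(data.frame(gait = c("Canter", "Walk", "Canter"),
                              duration = c(5, 5, 5)), seed = 1)
  rd <- simulateRide(plan)
  expect_setequal(unique(rd$labelEvents$label),
                  c("L Canter", "Walk", "R Canter"))

  ## judges code the same gaits with lead-specific canter labels
  codes <- unique(do.call(rbind, rd$judgeStreams)$code)
  expect_true(all(c(4L, 5L, 1L) %in% codes))
})

test_that("judge disagreement concentrates near transitions", {
  plan <- ridePlan(data.frame(gait = c("Walk", "Trot", "Tolt"),
                              duration = c(8, 8, 8),
                              theta0 = c(0, 10, 20)), seed = 9)
  rd <- simulateRide(plan)
  agg <- aggregateJudges(rd$judgeStreams, tEnd = 24)
  truthCode <- function(t) {
    lab <- labelAt(rd$timeline, t)
    vapply(lab, function(l) switch(l, Walk = 1L, Trot = 2L, Tolt = 3L, -1L),
           1L)
  }
  ticks <- seq(0.25, 23.75, by = 0.25)
  held <- vapply(ticks, function(x)
    agg$code[findInterval(x, agg$t)], 1L)
  bad <- ticks[held >= 0 & held != truthCode(ticks)]
  trans <- transitionTimes(rd$timeline)
  if (length(bad))
    expect_true(all(vapply(bad, function(x) min(abs(x - trans)), 0) <= 1))
})
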