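test_that("the ten-label vocabulary maps onto the five gaits", {
  expect_equal(mapTsLabel("L Cross Canter"), "Canter")
  expect_equal(mapTsLabel("Standing"), "Discarded")
  expect_equal(mapTsLabel("Flying Pace"), "FlyingPace")
  expect_equal(mapTsLabel(c("Walk", "Trot", "Tölt", "L Canter", "R Canter",
                            "R Cross Canter", "Halt")),
               c("Walk", "Trot", "Tolt", "Canter", "Canter", "Canter",
                 "Discarded"))
  expect_error(mapTsLabel("Piaffe"), class = "eqVocabularyError")
})

test_that("timelines merge equal-label runs and hold until the next event", {
  ev <- data.frame(t = c(0, 0.2, 0.4), label = c("Walk", "Walk", "Tölt"))
  tl <- buildTimeline(ev)
  iv <- timelineIntervals(tl)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$start, c(0, 0.4))
  expect_equal(iv$label, c("Walk", "Tolt"))

  one <- buildTimeline(data.frame(t = 3, label = "Trot"))
  expect_equal(nrow(timelineIntervals(one)), 1)
  expect_true(is.na(timelineIntervals(one)$end))

  alt <- data.frame(t = seq(0, 1.75, by = 0.25),
                    label = rep(c("Walk", "Tölt"), 4))
  expect_equal(nrow(timelineIntervals(buildTimeline(alt))), 8)

  expect_error(buildTimeline(data.frame(t = numeric(0), label = character(0))),
               class = "eqInsufficientDataError")
})

test_that("segment generation reproduces the worked examples", {
  rate <- 100
  tr <- makeTrace(10, rate, function(t) sin(t))

  s1 <- generateSegments(tr, GaitTimeline(0, "Walk"), window = 1.5)
  expect_equal(nSegments(s1), 57)
  expect_equal(segmentInfo(s1)$tStart, seq(0, 8.4, by = 0.15),
               tolerance = 1e-9)

  tl <- GaitTimeline(c(0, 5), c("Walk", "Trot"))
  s2 <- generateSegments(tr, tl, window = 1, exclusion = 2)
  st <- segmentInfo(s2)$tStart
  expect_equal(nSegments(s2), 42)
  expect_equal(sum(st <= 2 + 1e-9), 21)
  expect_equal(sum(st >= 7 - 1e-9), 21)
  expect_equal(as.character(unique(segmentLabels(s2)[st <= 2 + 1e-9])), "Walk")

  short <- makeTrace(1, rate, function(t) t)
  expect_equal(nSegments(generateSegments(short, GaitTimeline(0, "Walk"),
                                          window = 1.5)), 0)
})

test_that("flying-pace intervals are stepped every 20 ms", {
  rate <- 50
  tr <- makeTrace(10, rate, function(t) t)
  tl <- GaitTimeline(0, "FlyingPace")
  s <- generateSegments(tr, tl, window = 1.5)
  st <- segmentInfo(s)$tStart
  expect_equal(unique(round(diff(st), 9)), 0.02)
  expect_equal(st, bruteForceStarts(traceTimes(tr), tl, 1.5, rate),
               tolerance = 1e-9)
})

test_that("segment starts agree with the brute-force enumerator on random timelines", {
  set.seed(14)
  rate <- 50
  for (rep in 1:8) {
    dur <- sample(8:14, 1)
    tr <- makeTrace(dur, rate, function(t) cos(t))
    nInt <- sample(1:4, 1)
    starts <- sort(c(0, runif(nInt - 1, 0.5, dur - 0.5)))
    labs <- character(nInt)
    pool <- c(gaitLevels(), "Discarded")
    labs[1] <- sample(pool, 1)
    for (i in seq_len(nInt - 1))
      labs[i + 1] <- sample(setdiff(pool, labs[i]), 1)
    tl <- GaitTimeline(starts, labs)
    win <- sample(c(1, 1.5, 2), 1)
    ex <- sample(c(1, 2), 1)
    got <- segmentInfo(generateSegments(tr, tl, window = win,
                                        exclusion = ex))$tStart
    want <- bruteForceStarts(traceTimes(tr), tl, win, rate, exclusion = ex)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("no kept segment straddles a label change", {
  set.seed(5)
  rate <- 50
  tr <- makeTrace(12, rate, function(t) t)
  tl <- GaitTimeline(c(0, 4, 7.3), c("Walk", "Tolt", "Trot"))
  s <- generateSegments(tr, tl, window = 1.5, exclusion = 0.5)
  info <- segmentInfo(s)
  for (i in seq_len(nSegments(s))) {
    times <- info$tStart[i] + (0:(1.5 * rate - 1)) / rate
    expect_equal(unique(labelAt(tl, times)), as.character(info$y[i]))
  }
  ## consecutive starts inside one region differ by 0.1 * window
  ## (within one sample period)
  st <- info$tStart[info$y == "Walk"]
  expect_true(all(abs(diff(st) - 0.15) <= 1 / rate + 1e-9))
})

test_that("feature channel assembly yields 3, 6 or 7 input dimensions", {
  plan <- ridePlan(data.frame(gait = "Walk", duration = 4, theta0 = 0),
                   seed = 3)
  rd <- simulateRide(plan)
  w <- deviceToWorld(rd$deviceTrace)
  expect_equal(ncol(traceChannels(buildFeatureChannels(w, use = "accel"))), 3)
  expect_equal(ncol(traceChannels(buildFeatureChannels(w))), 6)
  both <- buildFeatureChannels(w, gps = rd$gps,
                               use = c("accel", "gyro", "speed"))
  expect_equal(ncol(traceChannels(both)), 7)
  expect_error(buildFeatureChannels(w, gps = NULL,
                                    use = c("accel", "speed")),
               class = "eqMissingChannelError")
})

test_that("dataset splits are horse-disjoint, 85/15 and reproducible", {
  set.seed(2)
  n <- 1100
  x <- array(rnorm(n * 2 * 5), c(n, 2, 5))
  horses <- c(rep(1L, 50), rep(2L, 50), rep(3:12, each = 100))
  seg <- SegmentSet(x, gaitLevels()[(1:n) %% 5 + 1], horses, horses, horses,
                    seq_len(n), 50)
  ## the default held-out set mirrors the study's leave-out horses
  expect_equal(eval(formals(splitDataset)$testHorses), c(1L, 2L, 8L, 9L, 11L))
  sp <- splitDataset(seg, testHorses = c(1L, 2L), seed = 4)
  expect_equal(nSegments(sp$test), 100)       # horses 1 and 2
  expect_equal(sort(unique(segmentInfo(sp$test)$horseId)), c(1L, 2L))
  expect_equal(nSegments(sp$train), 850)
  expect_equal(nSegments(sp$val), 150)
  expect_length(intersect(segmentInfo(sp$train)$tStart,
                          segmentInfo(sp$val)$tStart), 0)
  sp2 <- splitDataset(seg, testHorses = c(1L, 2L), seed = 4)
  expect_identical(segmentInfo(sp$train), segmentInfo(sp2$train))
  expect_warning(splitDataset(seg, testHorses = 99L, seed = 1), "absent")
})
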