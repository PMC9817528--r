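test_that("well-formed IMU logs read into device-frame traces", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t = c(0, 0.02, 0.04), ax = 1:3, ay = 0, az = 9.81,
                   gx = 0, gy = 0, gz = 0)
  write.csv(df, f, row.names = FALSE)
  tr <- readSensorLog(f)$trace
  expect_s4_class(tr, "SensorTrace")
  expect_equal(length(traceTimes(tr)), 3)
  expect_identical(traceFrame(tr), "device")
  expect_false("qw" %in% colnames(traceChannels(tr)))  # quaternion-free
  expect_equal(traceRate(tr), 50)
})

test_that("malformed logs are rejected with informative conditions", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(t = c(0, 0.02, 0.01), ax = 0, ay = 0, az = 0,
                       gx = 0, gy = 0, gz = 0), f, row.names = FALSE)
  expect_error(readSensorLog(f), class = "eqIntegrityError")
  expect_error(readSensorLog(f), "index 3")

  write.csv(data.frame(t = 0, ax = 0, ay = 0, gx = 0, gy = 0, gz = 0),
            f, row.names = FALSE)
  expect_error(readSensorLog(f), class = "eqFormatError")
  expect_error(readSensorLog(f), "az")
})

test_that("label logs enforce the closed vocabulary", {
  f <- withr::local_tempfile(fileext = ".csv")
  ev <- data.frame(t = seq(0, 0.9, by = 0.1), label = "Tölt")
  writeLabelLog(ev, f)
  got <- readLabelLog(f)
  expect_equal(nrow(got), 10)
  expect_true(all(got$label == "Tölt"))

  write.csv(data.frame(t = 0, label = "Gallop"), f, row.names = FALSE,
            fileEncoding = "UTF-8")
  expect_error(readLabelLog(f), class = "eqVocabularyError")
  expect_error(readLabelLog(f), "Gallop")
})

test_that("write/read round trip of a simulated ride is lossless", {
  plan <- ridePlan(data.frame(gait = c("Walk", "Trot"), duration = c(3, 3),
                              theta0 = c(0, 90)), seed = 5)
  rd <- simulateRide(plan)
  dir <- withr::local_tempdir()
  paths <- writeRideBundle(rd, dir)
  back <- readSensorLog(paths[["imu"]], paths[["gps"]])
  expect_lt(max(abs(traceChannels(back$trace) -
                    traceChannels(rd$deviceTrace))), 1e-9)
  expect_lt(max(abs(back$trace@t - rd$deviceTrace@t)), 1e-9)
  expect_lt(max(abs(back$gps$lat - rd$gps$lat)), 1e-12)
  lab <- readLabelLog(paths[["labels"]])
  expect_equal(lab$label, rd$labelEvents$label)
})

test_that("resampling interpolates linearly and spans the input range", {
  ## constant stays constant
  tr <- makeTrace(2, 80, function(t) rep(3.3, length(t)))
  out <- resampleTrace(tr, 50)
  expect_true(all(abs(traceChannels(out) - 3.3) < 1e-12))
  expect_equal(traceRate(out), 50)
  expect_identical(traceFrame(out), "device")

  ## exact on a linear ramp
  tr <- makeTrace(2, 100, function(t) t)
  out <- resampleTrace(tr, 50)
  expect_equal(as.numeric(traceChannels(out)), traceTimes(out),
               tolerance = 1e-12)

  ## 1 Hz sine, 200 -> 50 Hz, versus the closed form
  tr <- makeTrace(2, 200, function(t) sin(2 * pi * t))
  out <- resampleTrace(tr, 50)
  expect_lt(max(abs(as.numeric(traceChannels(out)) -
                    sin(2 * pi * traceTimes(out)))), 1e-3)
})

test_that("resampling at the native rate is the identity and idempotent", {
  tr <- makeTrace(2, 50, function(t) sin(7 * t) + t)
  same <- resampleTrace(tr, 50)
  expect_lt(max(abs(traceChannels(same) - traceChannels(tr))), 1e-9)
  twice <- resampleTrace(resampleTrace(tr, 25), 25)
  once <- resampleTrace(tr, 25)
  expect_equal(traceChannels(twice), traceChannels(once), tolerance = 1e-12)

  single <- SensorTrace(0, cbind(az = 1))
  expect_error(resampleTrace(single, 50), class = "eqInsufficientDataError")
})

test_that("quaternion columns are validated on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t = c(0, 0.02), ax = 0, ay = 0, az = 9.81,
                   gx = 0, gy = 0, gz = 0, qw = c(1, 0.9), qx = 0,
                   qy = 0, qz = 0)
  write.csv(df, f, row.names = FALSE)
  expect_error(readSensorLog(f), class = "eqNormalizationError")
})
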