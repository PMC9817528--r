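test_that("quaternion rotation matches the rotation-matrix oracle", {
  expect_equal(applyQuaternion(c(1, 2, 3), c(1, 0, 0, 0)), c(1, 2, 3))

  qz90 <- c(cos(pi / 4), 0, 0, sin(pi / 4))
  expect_equal(applyQuaternion(c(1, 0, 0), qz90), c(0, 1, 0),
               tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    q <- randomQuat()
    v <- rnorm(3)
    got <- applyQuaternion(v, q)
    expect_equal(got, as.numeric(quatMatrix(q) %*% v), tolerance = 1e-9)
    expect_lt(abs(sqrt(sum(got^2)) - sqrt(sum(v^2))), 1e-9)
  }
})

test_that("non-unit quaternions are rejected, not normalized", {
  expect_error(applyQuaternion(c(1, 0, 0), c(1, 0, 0, 0.1)),
               class = "eqNormalizationError")
})

test_that("GPS bearing follows the equirectangular convention", {
  n0 <- list(lat = 64, lon = -21)
  expect_equal(gpsBearing(n0, list(lat = 64.001, lon = -21)), 0)
  expect_equal(gpsBearing(n0, list(lat = 64, lon = -20.999)), 90)
  eq <- list(lat = 0, lon = 0)
  expect_equal(gpsBearing(eq, list(lat = 0.001, lon = 0.001)), 45,
               tolerance = 1e-6)
  expect_error(gpsBearing(n0, n0), class = "eqUndefinedHeadingError")
})

test_that("unwrap removes jumps over 180 degrees and keeps congruence", {
  expect_equal(unwrapDegrees(c(10, 20, 30)), c(10, 20, 30))
  expect_equal(unwrapDegrees(c(350, 10)), c(350, 370))
  expect_equal(unwrapDegrees(c(10, 350)), c(10, -10))

  set.seed(7)
  for (i in 1:10) {
    x <- runif(50, 0, 360)
    u <- unwrapDegrees(x)
    expect_true(all(abs(diff(u)) <= 180 + 1e-9))
    expect_equal(u %% 360, x %% 360, tolerance = 1e-9)
  }
})

test_that("heading smoothing is a circular moving average", {
  h <- data.frame(t = c(0, 0.5), theta = c(90, 90))
  expect_equal(smoothHeading(h)$theta, c(90, 90))

  h <- data.frame(t = c(0, 0.5), theta = c(350, 10))
  expect_equal(smoothHeading(h)$theta, c(0, 0), tolerance = 1e-9)

  ## difference of exactly 180 is not unwrapped
  h <- data.frame(t = c(0, 0.5), theta = c(0, 180))
  expect_equal(smoothHeading(h)$theta, c(90, 90))
})

test_that("heading smoothing commutes with constant offsets (mod 360)", {
  set.seed(3)
  t <- seq(0, 5, by = 0.25)
  base <- (200 + cumsum(rnorm(length(t), 0, 15)))
  for (off in c(37, 180, 301)) {
    a <- smoothHeading(data.frame(t = t, theta = base %% 360))$theta
    b <- smoothHeading(data.frame(t = t, theta = (base + off) %% 360))$theta
    d <- (b - a - off) %% 360
    expect_true(all(pmin(d, 360 - d) < 1e-9))
  }
})

test_that("world-to-horse is a pure yaw rotation", {
  t <- c(0, 0.02)
  mk <- function(acc, gyr = c(0.5, -0.5, 2)) {
    ch <- rbind(c(acc, gyr), c(acc, gyr))
    colnames(ch) <- c("ax", "ay", "az", "gx", "gy", "gz")
    SensorTrace(t, ch, rate = 50, frame = "world")
  }
  north <- data.frame(t = 0, theta = 0)
  hz <- worldToHorse(mk(c(0, 2, 9.8)), north)
  expect_equal(unname(traceChannels(hz)[1, 1:3]), c(2, 0, 9.8))

  east <- data.frame(t = 0, theta = 90)
  hz <- worldToHorse(mk(c(1, 0, 0)), east)
  expect_equal(unname(traceChannels(hz)[1, 1:3]), c(1, 0, 0),
               tolerance = 1e-12)

  ## z channels bitwise identical, horizontal norms preserved
  set.seed(9)
  tr <- makeWorldTrace(60)
  hd <- data.frame(t = c(0, 0.4, 0.9), theta = runif(3, 0, 360))
  hz <- worldToHorse(tr, hd)
  expect_identical(traceChannels(hz)[, "az"], traceChannels(tr)[, "az"])
  expect_identical(traceChannels(hz)[, "gz"], traceChannels(tr)[, "gz"])
  nw <- sqrt(rowSums(traceChannels(tr)[, c("ax", "ay")]^2))
  nh <- sqrt(rowSums(traceChannels(hz)[, c("ax", "ay")]^2))
  expect_lt(max(abs(nw - nh)), 1e-9)
})

test_that("noise-free simulated rides survive the full frame round trip", {
  plan <- ridePlan(data.frame(gait = c("Tolt", "Canter"), duration = c(5, 5),
                              theta0 = c(120, 310), turnRate = c(0, 20)),
                   noiseAcc = 0, noiseGyro = 0, seed = 21)
  rd <- simulateRide(plan)
  recovered <- worldToHorse(deviceToWorld(rd$deviceTrace), rd$headingTrue)
  err <- traceChannels(recovered) - traceChannels(rd$horseTruth)
  expect_lt(sqrt(mean(err^2)), 1e-6)
})
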