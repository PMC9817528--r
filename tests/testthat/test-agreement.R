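streamOf <- function(t, code) data.frame(t = t, code = as.integer(code))

test_that("judge aggregation takes strict plurality, ties disputed", {
  s <- lapply(1:4, function(j) streamOf(0, 3))
  agg <- aggregateJudges(s, tEnd = 1)
  expect_equal(agg$code, 3)                       # unanimity

  s <- list(streamOf(0, 3), streamOf(0, 3), streamOf(0, 2), streamOf(0, 6))
  expect_equal(aggregateJudges(s, tEnd = 1)$code, 3)   # plurality 2>1=1

  s <- list(streamOf(0, 3), streamOf(0, 3), streamOf(0, 2), streamOf(0, 2))
  expect_equal(aggregateJudges(s, tEnd = 1)$code, -2)  # tie -> disputed

  ## before any click a judge is unclassified (-1)
  s <- lapply(1:4, function(j) streamOf(1.0, 1))
  agg <- aggregateJudges(s, tEnd = 2)
  expect_equal(agg$code[1], -1)
  expect_equal(agg$code[2], 1)
})

test_that("prediction timelines start at zero and take window modes", {
  ev <- data.frame(t = seq(100, 104, by = 0.25), label = "Tölt")
  tl <- tsTimeline(ev)
  expect_equal(tl$t, seq(0, 4, by = 0.5))
  expect_true(all(tl$label == "Tölt"))
  expect_true(all(tl$code == 3))

  ## 3 Trot vs 2 Tölt inside one window
  ev <- data.frame(t = c(0, 0.2, 0.4, 0.6, 0.8),
                   label = c("Trot", "Trot", "Trot", "Tölt", "Tölt"))
  expect_equal(tsTimeline(ev)$label[1], "Trot")
  expect_error(tsTimeline(data.frame(t = numeric(0), label = character(0))),
               class = "eqInsufficientDataError")
})

test_that("test-case pairing discards unclassified and disputed truth", {
  ts <- data.frame(t = seq(0, 4.5, by = 0.5), code = 3)
  judge <- streamOf(c(0, 2.0, 3.0), c(3, -2, 3))
  cases <- pairTestCases(ts, judge)
  expect_equal(nrow(cases), 8)                    # 2 points in the -2 gap
  expect_true(all(cases$truth == 3))

  judge <- streamOf(c(1.0, 2.0), c(1, 3))         # -1 before first click
  cases <- pairTestCases(data.frame(t = c(0.5, 1.5, 2.5), code = 3), judge)
  expect_equal(cases$t, c(1.5, 2.5))

  expect_error(pairTestCases(data.frame(t = 0:3, code = 1),
                             streamOf(10, 1), tEnd = 8),
               class = "eqCoverageError")
})

test_that("exclusion radii drop cases near transitions, inclusively", {
  cases <- data.frame(t = seq(0.5, 5, by = 0.5), predicted = 1, truth = 1)
  expect_equal(nrow(applyExclusions(cases, 3.0, numeric(0), 0, 0)), 10)
  kept <- applyExclusions(cases, 3.0, numeric(0), 1000, 0)
  expect_equal(nrow(kept), 5)
  expect_equal(kept$t, c(0.5, 1.0, 1.5, 4.5, 5.0))
  expect_error(applyExclusions(cases, 3.0, numeric(0), -1, 0),
               class = "eqConfigError")
})

test_that("left and right canter stay distinct in the protocol", {
  expect_equal(tsToJudgeCode(c("L Canter", "R Canter")), c(4L, 5L))
  ts <- data.frame(t = c(0, 0.5), code = tsToJudgeCode(c("L Canter",
                                                         "L Canter")))
  judge <- streamOf(0, 5)                          # judges saw right canter
  cases <- pairTestCases(ts, judge)
  expect_true(all(cases$predicted != cases$truth))
})

test_that("the exclusion grid is monotone and saturates on lag fixtures", {
  ## simulated ride: disagreements only near transitions (judge lags < 1 s)
  plan <- ridePlan(data.frame(gait = c("Walk", "Tolt", "Trot", "Canter"),
                              duration = c(8, 8, 8, 8),
                              theta0 = c(0, 90, 180, 270)),
                   seed = 17)
  rd <- simulateRide(plan)
  ts <- tsTimeline(rd$labelEvents)
  agg <- aggregateJudges(rd$judgeStreams,
                         tEnd = max(vapply(rd$judgeStreams,
                                           function(s) max(s$t), 0)) + 8)
  cases <- pairTestCases(ts, agg)
  tab <- agreementTable(cases, seriesTransitions(ts),
                        seriesTransitions(agg))

  ## errors, if any, lie within 1 s of a transition
  err <- cases[cases$predicted != cases$truth, ]
  allTrans <- c(seriesTransitions(ts), seriesTransitions(agg))
  if (nrow(err))
    expect_true(all(vapply(err$t, function(x)
      min(abs(x - allTrans)), 0) <= 1))

  ## counts non-increasing in each radius; (0,0) maximal
  expect_equal(max(tab$n_cases), tab$n_cases[tab$ts_ms == 0 & tab$judge_ms == 0])
  for (a in unique(tab$ts_ms)) {
    sub <- tab[tab$ts_ms == a, ]
    expect_true(all(diff(sub$n_cases[order(sub$judge_ms)]) <= 0))
  }
  for (b in unique(tab$judge_ms)) {
    sub <- tab[tab$judge_ms == b, ]
    expect_true(all(diff(sub$n_cases[order(sub$ts_ms)]) <= 0))
  }

  ## with 2 s exclusion on both sides all remaining cases agree
  cell <- tab[tab$ts_ms == 2000 & tab$judge_ms == 2000, ]
  expect_gt(cell$n_cases, 0)
  expect_equal(cell$accuracy, 100)
})

test_that("a perfect fixture scores 100 percent in every cell", {
  ts <- data.frame(t = seq(0, 10, by = 0.5), code = 1)
  judge <- streamOf(0, 1)
  cases <- pairTestCases(ts, judge)
  tab <- agreementTable(cases, numeric(0), numeric(0))
  expect_true(all(tab$accuracy == 100))
  expect_true(all(tab$n_cases == nrow(cases)))
})
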