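test_that("segmentation recovers a two-level disk up to its boundary band", {
  cal <- mkCal()
  fr <- diskFrame(120, 120, 60, 60, 40, inside = 20, outside = 200)
  m <- segmentContactZone(fr, cal)
  expect_false(attr(m, "flagged"))
  truth <- diskMask(120, 120, 60, 60, 40)
  ## area error bounded by one boundary band: perimeter x 1 px
  expect_lt(sum(xor(m, truth)), 2 * pi * 40 + 8)
  expect_gt(sum(m & truth) / sum(truth), 0.95)
})

test_that("frames without a dark footprint give a flagged empty mask", {
  cal <- mkCal()
  m1 <- segmentContactZone(matrix(200, 64, 64), cal)
  expect_true(attr(m1, "flagged"))
  expect_false(any(m1))
  set.seed(1)
  m2 <- segmentContactZone(matrix(200 + rnorm(64^2, 0, 5), 64, 64), cal)
  expect_true(attr(m2, "flagged"))
  expect_false(any(m2))
})

test_that("segmentation tracks the simulated footprint area", {
  p <- quickParams(grid = c(120L, 120L, 30L), rMaxUm = 3.0, seed = 4L)
  sim <- renderMovie(p)
  masks <- segmentMovie(getChannel(sim$movie, "irm"))
  areas <- pxAreaToUm2(calibration(sim$movie),
                       vapply(masks, sum, numeric(1)))
  truth <- areasUm2(sim$truth)
  rel <- abs(areas - truth) / truth
  expect_lt(max(rel[5:30]), 0.05)   # within 5% of pi R(t)^2 once spread
})

test_that("areaTrace converts pixels and smooths with a centred window", {
  cal <- mkCal()
  masks <- rep(list(diskMask(50, 50, 25, 25, 17)), 4)
  masks <- lapply(masks, function(m) { m[1:2, 1:2] <- TRUE; m })
  n <- sum(masks[[1]])
  tr <- areaTrace(masks, cal)
  expect_equal(areasUm2(tr), rep(n * 0.01, 4))
  expect_equal(timesS(tr), c(0, 2, 4, 6))

  constMask <- matrix(TRUE, 20, 50)   # 1000 px at 100 nm -> 10 um^2
  tr1 <- areaTrace(list(constMask), cal)
  expect_equal(areasUm2(tr1), 10)
  expect_equal(smoothedAreasUm2(tr1), 10)   # single frame: smoothed = raw

  ## step trace {10,10,10,20,20}, window 3: middle value 13.333...
  step <- mkTrace(c(10, 10, 10, 20, 20), window = 3L)
  expect_equal(step@smoothedAreasUm2[3], 40 / 3)
})

test_that("contraction calls follow the sustained-drop rule", {
  ## constant trace: never contracting
  expect_false(isContracting(classifyContraction(mkTrace(rep(50, 100),
                                                         window = 1L))))
  ## rise to 100 at 120 s then 94 for the rest: 6% drop sustained
  a <- c(seq(40, 100, length.out = 61), rep(94, 90))
  call <- classifyContraction(mkTrace(a, window = 1L))
  expect_true(isContracting(call))
  expect_equal(onsetS(call), 120)
  expect_equal(tMaxSpreadS(call), 120)
  expect_equal(maxAreaUm2(call), 100)
  ## 8-s dip (4 frames at 2 s) does not qualify
  a8 <- c(seq(40, 100, length.out = 61), rep(94, 4), rep(97, 40))
  expect_false(isContracting(classifyContraction(mkTrace(a8, window = 1L))))
  ## 10-s dip does
  a10 <- c(seq(40, 100, length.out = 61), rep(94, 5), rep(97, 40))
  expect_true(isContracting(classifyContraction(mkTrace(a10, window = 1L))))
})

test_that("short post-maximum observation is flagged non-contracting", {
  a <- c(seq(10, 100, length.out = 50), 90, 90)
  call <- classifyContraction(mkTrace(a, window = 1L))
  expect_false(isContracting(call))
  expect_match(call@note, "insufficient")
})

test_that("classifier agrees with the brute-force run-enumeration oracle", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(40:120, 1)
    tmax <- sample(10:(n - 10), 1)
    drop <- runif(1, 0, 0.15)
    a <- c(seq(5, 100, length.out = tmax), rep(100 * (1 - drop), n - tmax))
    if (runif(1) < 0.5) a <- a * (1 + rnorm(n, 0, 0.01))
    a <- pmax(a, 0)
    tr <- mkTrace(a)
    got <- isContracting(classifyContraction(tr))
    want <- oracleContraction(tr@smoothedAreasUm2, tr@timesS)
    expect_identical(got, want)
  }
})

test_that("stricter thresholds never create a contraction call", {
  set.seed(7)
  for (i in 1:20) {
    n <- 80
    a <- pmax(cumsum(rnorm(n, 0.5, 2)), 1)
    tr <- mkTrace(a)
    base <- isContracting(classifyContraction(tr, minDrop = 0.05,
                                              minDurationS = 10))
    harder1 <- isContracting(classifyContraction(tr, minDrop = 0.08,
                                                 minDurationS = 10))
    harder2 <- isContracting(classifyContraction(tr, minDrop = 0.05,
                                                 minDurationS = 20))
    if (!base) {
      expect_false(harder1)
      expect_false(harder2)
    }
  }
})

test_that("channel MFI traces average over the mask", {
  cal <- mkCal()
  st <- ChannelStack("x", array(7, c(20, 20, 3)), cal)
  masks <- rep(list(diskMask(20, 20, 10, 10, 5)), 3)
  tr <- channelMfiTrace(st, masks)
  expect_equal(tr$mfi, rep(7, 3))

  two <- matrix(10, 20, 20); two[, 11:20] <- 99
  st2 <- ChannelStack("x", array(two, c(20, 20, 1)), cal)
  half <- matrix(FALSE, 20, 20); half[, 1:10] <- TRUE
  expect_equal(channelMfiTrace(st2, list(half))$mfi, 10)

  ## empty-mask frames give NA; all-empty errors
  masks[[2]] <- matrix(FALSE, 20, 20)
  expect_true(is.na(channelMfiTrace(st, masks)$mfi[2]))
  expect_error(channelMfiTrace(st, rep(list(matrix(FALSE, 20, 20)), 3)),
               "empty")
})

test_that("initial rates are OLS slopes from landing", {
  tt <- seq(0, 60, by = 2)
  tr <- data.frame(time_s = tt, mfi = 100 + 2 * tt)
  expect_equal(initialRate(tr)$slope, 2)
  expect_equal(initialRate(data.frame(time_s = tt, mfi = rep(5, 31)))$slope, 0)

  ## landing shift: NA frames before landing move the window
  tr2 <- data.frame(time_s = tt, mfi = c(rep(NA, 5), 100 + 3 * (tt[-(1:5)] - 10)))
  out <- initialRate(tr2)
  expect_equal(out$landing_s, 10)
  expect_equal(out$slope, 3)

  ## noisy planted slope recovered within 3 analytic SE (16 samples)
  set.seed(11)
  for (i in 1:10) {
    t16 <- seq(0, 30, by = 2)
    y <- 50 + 1.7 * t16 + rnorm(16, 0, 1)
    fit <- initialRate(data.frame(time_s = t16, mfi = y), c(0, 30))
    expect_lt(abs(fit$slope - 1.7), 3 * fit$se)
  }
  expect_error(initialRate(data.frame(time_s = 0:1, mfi = c(1, 2))), "3 samples")
})

test_that("phase rates split the MFI slope at contraction onset", {
  ## area: rise to 100 at t=60, decline to 85 at t=100, flat after
  a <- c(seq(50, 100, length.out = 31), seq(99.5, 85, length.out = 20),
         rep(85, 29))
  tr <- mkTrace(a, window = 1L)
  call <- classifyContraction(tr)
  expect_true(isContracting(call))
  win <- contractionWindow(tr, call)
  expect_equal(unname(win[1]), 60)
  expect_equal(unname(win[2]), 100)

  tt <- tr@timesS
  mfi <- ifelse(tt < 60, 10 + 1 * tt, 70 + 3 * (tt - 60))
  pr <- phaseRates(data.frame(time_s = tt, mfi = mfi), tr, call)
  expect_equal(pr$rate_before, 1, tolerance = 1e-9)
  expect_equal(pr$rate_during, 3, tolerance = 1e-9)

  ## globally linear MFI: equal slopes in both phases
  pr2 <- phaseRates(data.frame(time_s = tt, mfi = 5 + 2 * tt), tr, call)
  expect_equal(pr2$rate_before, pr2$rate_during, tolerance = 1e-12)
})
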