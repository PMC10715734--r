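## Build a synthetic kymograph directly: S bins x T frames with a moving
## Gaussian ridge on a flat background.
ridgeKymo <- function(S = 40, T = 50, bg = 100, amp = 200, r0 = 30,
                      speed = 0.05, binUm = 0.1, dt = 2, sigmaBins = 1.5,
                      tOn = 1, tOff = T, noise = 0, seed = 1) {
  set.seed(seed)
  samp <- matrix(bg, S, T)
  for (t in seq_len(T)) {
    if (t >= tOn && t <= tOff) {
      pos <- (r0 - speed * (t - tOn) * dt / binUm)
      samp[, t] <- samp[, t] + amp * exp(-(seq_len(S) - 1 - pos)^2 /
                                           (2 * sigmaBins^2))
    }
  }
  if (noise > 0) samp <- samp + matrix(rnorm(S * T, 0, noise), S, T)
  new("Kymograph", originUm = c(0, 0), angleDeg = 0, samples = samp,
      binSizeUm = binUm, lineHalfwidthPx = 1, calibration = Calibration(100, dt))
}

test_that("kymographs of a temporally constant movie have identical columns", {
  cal <- mkCal()
  fr <- addGauss(matrix(100, 60, 60), 30, 42, 150, 2)
  st <- ChannelStack("actin", array(rep(fr, 5), c(60, 60, 5)), cal)
  masks <- rep(list(diskMask(60, 60, 30, 30, 25)), 5)
  ks <- makeKymographs(st, masks, nLines = 4L, tRefFrame = 1L)
  expect_length(ks, 4L)
  for (k in ks)
    expect_equal(kymoSamples(k), kymoSamples(k)[, c(1, 1, 1, 1, 1)],
                 tolerance = 1e-12)
})

test_that("eight lines are spaced 45 degrees apart", {
  cal <- mkCal()
  st <- ChannelStack("actin", array(100, c(60, 60, 2)), cal)
  masks <- rep(list(diskMask(60, 60, 30, 30, 20)), 2)
  ks <- makeKymographs(st, masks, nLines = 8L, tRefFrame = 1L)
  expect_equal(vapply(ks, angleDeg, numeric(1)), seq(0, 315, by = 45))
})

test_that("a rotationally symmetric scene gives equal kymographs", {
  p <- quickParams(grid = c(100L, 100L, 8L), rMaxUm = 2.5, noiseSigma = 0,
                   nClusters = 0L, focusBirthRatePerMin = 0)
  sim <- renderMovie(p)
  masks <- segmentMovie(getChannel(sim$movie, "irm"))
  ks <- makeKymographs(getChannel(sim$movie, "actin"), masks, nLines = 8L,
                       tRefFrame = 5L)
  ref <- kymoSamples(ks[[1]])
  for (k in ks[-1]) {
    d <- abs(kymoSamples(k) - ref)
    ## bilinear interpolation across the hard rim step differs by up to a
    ## fraction of the step height between axis-aligned and oblique lines;
    ## away from the step the profiles agree tightly
    expect_lt(mean(d), 4)
    expect_lt(max(d), 0.5 * (2.5 - 1) * 100)   # half the rim step height
  }
})

test_that("a single planted ridge yields one accurate track", {
  k <- ridgeKymo(speed = 0.02)
  tr <- extractTracks(k)
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$lifetime_s, 100)                 # 50 frames x 2 s
  ## displacement runs over 49 inter-frame intervals, lifetime over 50
  expect_equal(tr$speed_um_s, 0.02 * 49 / 50, tolerance = 0.02)
  ## per-column position error bounded by one spatial bin
  pos <- tr$positions_um[[1]]
  truth <- 3.0 - 0.02 * (seq_len(50) - 1) * 2
  expect_lt(max(abs(pos - truth)), 0.1)
})

test_that("short ridges fall to the duration filter", {
  k <- ridgeKymo(tOn = 10, tOff = 10)    # 1 frame = 2 s
  expect_identical(nrow(extractTracks(k, minDurationS = 4)), 0L)
  k2 <- ridgeKymo(tOn = 10, tOff = 11)   # 2 frames = 4 s
  expect_identical(nrow(extractTracks(k2, minDurationS = 4)), 1L)
})

test_that("two parallel ridges stay distinct tracks without identity swaps", {
  k <- ridgeKymo(r0 = 32, speed = 0.01)
  k@samples <- k@samples + (ridgeKymo(r0 = 12, speed = 0.01)@samples - 100)
  tr <- extractTracks(k)
  expect_identical(nrow(tr), 2L)
  expect_equal(sort(tr$birth_radius_um), c(1.2, 3.2), tolerance = 0.05)
  ## both speeds near planted; a swap would show as a huge displacement
  expect_lt(max(abs(tr$speed_um_s - 0.01 * 49 / 50)), 0.004)
})

test_that("speed equals displacement over lifetime for every track", {
  k <- ridgeKymo(noise = 8, seed = 3)
  tr <- extractTracks(k)
  for (i in seq_len(nrow(tr)))
    expect_equal(tr$speed_um_s[i],
                 tr$displacement_um[i] / tr$lifetime_s[i], tolerance = 1e-12)
})

test_that("origin classification needs rim birth, inward motion, duration", {
  dt <- 2
  edge <- rep(4, 100)
  mk <- function(birth_s, lifetime_s, r0, r1)
    data.frame(birth_s = birth_s, death_s = birth_s + lifetime_s,
               lifetime_s = lifetime_s, birth_radius_um = r0,
               death_radius_um = r1,
               displacement_um = abs(r1 - r0),
               speed_um_s = abs(r1 - r0) / lifetime_s)
  ## born 0.5 um inside the edge, 1.5 um inward over 12 s: positive
  expect_true(classifyOrigin(mk(10, 12, 3.5, 2.0), edge, dt))
  ## born 3 um inside the edge: band criterion fails
  expect_false(classifyOrigin(mk(10, 12, 1.0, 0.5), edge, dt))
  ## inward track lasting 6 s: duration criterion fails
  expect_false(classifyOrigin(mk(10, 6, 3.5, 2.5), edge, dt))
  ## outward drift: displacement criterion fails
  expect_false(classifyOrigin(mk(10, 12, 3.5, 3.6), edge, dt))
  ## anti-monotone: shrinking the band or raising the duration never adds
  tr <- mk(10, 12, 3.2, 2.0)
  expect_true(classifyOrigin(tr, edge, dt, lamBandUm = 1.0))
  expect_false(classifyOrigin(tr, edge, dt, lamBandUm = 0.5))
  expect_false(classifyOrigin(tr, edge, dt, minDurationS = 12))
})

test_that("per-cell kymograph positivity fractions count correctly", {
  pos <- data.frame(lamellipodial_origin = c(TRUE, FALSE))
  neg <- data.frame(lamellipodial_origin = logical(0))
  out <- fractionLamellipodiaDerived(c(rep(list(pos), 6), rep(list(neg), 2)))
  expect_equal(out$fraction, 0.75)
  expect_equal(out$percent, 75)
  out0 <- fractionLamellipodiaDerived(rep(list(neg), 8))
  expect_equal(out0$fraction, 0)
})

test_that("lifetime/speed stats use the emergence window and 4-s filter", {
  tracks <- data.frame(
    birth_s = c(70, 100, 130, 40),
    lifetime_s = c(20, 10, 2, 30),
    speed_um_s = c(0.05, 0.03, 0.2, 0.01))
  out <- lifetimeSpeedStats(tracks, tMaxSpreadS = 60, windowS = 60)
  ## only the first two qualify: born in [60, 120], lifetime >= 4
  expect_identical(out$n_tracks, 2L)
  expect_equal(out$mean_lifetime_s, 15)
  expect_equal(out$mean_speed_um_s, 0.04)
  none <- lifetimeSpeedStats(tracks[4, ], tMaxSpreadS = 60)
  expect_identical(none$n_tracks, 0L)
  expect_true(is.na(none$mean_lifetime_s))
})

test_that("a 10-frame track at 2 s/frame lives 20 s (inclusive span)", {
  k <- ridgeKymo(tOn = 5, tOff = 14)
  tr <- extractTracks(k)
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$lifetime_s, 20)
})

test_that("emergence histograms are percent-normalized around the onset", {
  ## all births at onset: one bin holds 100%
  h <- emergenceHistogram(rep(120, 7), rep(120, 7), binS = 10)
  expect_equal(sum(h$percent), 100)
  expect_equal(h$percent[h$bin_left_s == 0], 100)

  ## no tracks
  h0 <- emergenceHistogram(numeric(0), numeric(0))
  expect_identical(nrow(h0), 0L)

  ## cells without an onset are excluded and counted
  h2 <- emergenceHistogram(c(100, 110, 90), c(100, NA, 80), binS = 10)
  expect_equal(attr(h2, "n_excluded"), 1L)
  expect_equal(sum(h2$count), 2L)
  expect_equal(sum(h2$percent), 100)
})

test_that("kymograph edge radius follows the mask along the line", {
  cal <- mkCal()
  masks <- list(diskMask(60, 60, 30, 30, 10), diskMask(60, 60, 30, 30, 20))
  st <- ChannelStack("actin", array(100, c(60, 60, 2)), cal)
  k <- makeKymographs(st, masks, nLines = 1L, tRefFrame = 2L)[[1]]
  edge <- kymoEdgeRadius(masks, k)
  expect_equal(edge, c(1.0, 2.0), tolerance = 0.1)
})
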