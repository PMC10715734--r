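test_that("area trace rises logistically and contracts to the exact plateau", {
  p <- quickParams(contractionFraction = 0)
  a <- simulateAreaTrace(p)
  expect_true(all(diff(a) >= -1e-9))                      # monotone
  expect_gt(a[length(a)], 0.99 * pi * p@rMaxUm^2)          # reaches A_max
  iMax <- round(p@tMaxSpreadS / 2) + 1L
  expect_gte(a[iMax + 1L], 0.99 * pi * p@rMaxUm^2)         # >= 99% by t_max

  p15 <- quickParams(contractionFraction = 0.15)
  a15 <- simulateAreaTrace(p15)
  expect_equal(a15[length(a15)], 0.85 * pi * p15@rMaxUm^2)  # exact plateau

  pc <- quickParams(rInitialUm = 2.5, rMaxUm = 2.5, contractionFraction = 0)
  expect_equal(simulateAreaTrace(pc), rep(pi * 2.5^2, 90))  # identity
})

test_that("SimParams invariants are enforced", {
  expect_error(quickParams(contractionFraction = 1), "contractionFraction")
  expect_error(quickParams(rInitialUm = 5, rMaxUm = 3), "rMaxUm")
  expect_error(simParams(grid = c(40L, 40L, 10L)), "grid too small")
  expect_error(quickParams(bogus = 1), "unknown")
})

test_that("ratioProfile is biphasic: linear rise then monotone decline", {
  rp <- c(dRise = 150, peak = 1, base = 0.2, declineSlope = 0.004,
          floorEnd = 0.05)
  expect_equal(ratioProfile(0, rp), 0.2)              # floor at zero density
  expect_equal(ratioProfile(150, rp), 1)              # maximum at dRise
  d <- seq(150, 500, by = 10)
  expect_true(all(diff(ratioProfile(d, rp)) <= 1e-12))  # non-increasing
  expect_equal(ratioProfile(1000, rp), 0.05)          # floored
  expect_error(ratioProfile(-1, rp), ">= 0")
})

test_that("rendered movies are bit-identical for identical parameters", {
  p <- quickParams(grid = c(100L, 100L, 20L), rMaxUm = 2.5, seed = 5L)
  s1 <- renderMovie(p)
  s2 <- renderMovie(p)
  for (ch in channelNames(s1$movie))
    expect_identical(getChannel(s1$movie, ch)@frames,
                     getChannel(s2$movie, ch)@frames)
  expect_identical(s1$truth@focusTracks, s2$truth@focusTracks)
  expect_identical(s1$truth@clusterTracks, s2$truth@clusterTracks)
  ## a different seed changes the noise
  s3 <- renderMovie(quickParams(grid = c(100L, 100L, 20L), rMaxUm = 2.5,
                                seed = 6L))
  expect_false(identical(getChannel(s1$movie, "fab")@frames,
                         getChannel(s3$movie, "fab")@frames))
})

test_that("zero birth rate leaves the actin channel rim-only", {
  p <- quickParams(grid = c(100L, 100L, 30L), rMaxUm = 2.5,
                   focusBirthRatePerMin = 0, nClusters = 2L, noiseSigma = 0)
  sim <- renderMovie(p)
  expect_identical(nrow(sim$truth@focusTracks), 0L)
  act <- getChannel(sim$movie, "actin")@frames
  ## rim-only: nothing above rimAmp x background anywhere
  expect_lte(max(act), p@rimAmp * p@backgroundFi + 1e-9)
})

test_that("a noise-free static focus renders at focusAmp x background", {
  ## odd grid puts the cell centre on a pixel, so a 10-px radius at 90 deg
  ## lands the focus centre exactly on a pixel
  fo <- data.frame(birth_s = 0, angle_deg = 90, speed_um_s = 0,
                   lifetime_s = 1e4, birth_radius_um = 1.0)
  p <- quickParams(grid = c(101L, 101L, 45L), rMaxUm = 2.5, noiseSigma = 0,
                   focusAmp = 3, nClusters = 0L, fociOverride = fo)
  sim <- renderMovie(p)
  ## frame past maximal spreading: the rim band (R - 1, R] = (1.5, 2.5] is
  ## clear of the focus at radius 1.0, so rim/cluster terms vanish there
  act <- getFrame(getChannel(sim$movie, "actin"), 45)
  cRow <- (101 + 1) / 2
  expect_equal(act[cRow + 10, cRow], 3 * p@backgroundFi, tolerance = 1e-6)
})

test_that("background noise has the planted scale (patch-mean check)", {
  p <- quickParams(grid = c(120L, 120L, 3L), rMaxUm = 2.0, noiseSigma = 5,
                   backgroundFi = 100, nClusters = 0L,
                   focusBirthRatePerMin = 0, seed = 3L)
  sim <- renderMovie(p)
  act <- getFrame(getChannel(sim$movie, "actin"), 1)
  patch <- act[1:50, 1:50]   # object-free corner (outside the cell)
  expect_lt(abs(mean(patch) - 100), 3 * 5 / 50)
})

test_that("the noise-free fab peak equals the ground-truth ramp", {
  co <- data.frame(angle_deg = c(0, 180), frac = c(0.3, 0.4),
                   peak0 = c(150, 200), ramp_fi_s = c(0.5, 1))
  ## wide spots (sigma 3 px) make the off-pixel peak attenuation negligible
  p <- quickParams(grid = c(100L, 100L, 40L), rMaxUm = 2.5, noiseSigma = 0,
                   clustersOverride = co, focusBirthRatePerMin = 0,
                   contractionFraction = 0.15, psfSigmaUm = 0.3)
  sim <- renderMovie(p)
  tru <- sim$truth@clusterTracks

  ## ground truth follows the analytic ramp with a 3x boost in [onset,
  ## onset + ramp]: peak(t) = peak0 + ramp * (t + 2 * overlap(t))
  eff <- function(t) t + 2 * pmax(0, pmin(t, 60 + 60) - 60)
  for (k in 1:2) {
    tk <- tru[tru$cluster == k, ]
    expect_equal(tk$peak_fi, co$peak0[k] + co$ramp_fi_s[k] * eff(tk$t_s),
                 tolerance = 1e-12)
  }

  ## and the rendered noise-free pixels reach that peak
  for (t in c(5L, 20L, 35L)) {
    fab <- getFrame(getChannel(sim$movie, "fab"), t)
    for (k in 1:2) {
      row <- tru[tru$frame == t & tru$cluster == k, ]
      rPx <- round(row$y_um / 0.1 + (100 + 1) / 2)
      cPx <- round(row$x_um / 0.1 + (100 + 1) / 2)
      expect_equal(max(fab[(rPx - 2):(rPx + 2), (cPx - 2):(cPx + 2)]),
                   row$peak_fi, tolerance = 0.02)
    }
  }
})

test_that("ground-truth onset follows the contraction fraction", {
  expect_equal(onsetS(renderMovie(quickParams(grid = c(100L, 100L, 10L),
    rMaxUm = 2.5, contractionFraction = 0.1))$truth), 60)
  expect_true(is.na(onsetS(renderMovie(quickParams(grid = c(100L, 100L, 10L),
    rMaxUm = 2.5, contractionFraction = 0))$truth)))
})

test_that("writeSimulation emits TIFFs, truth tables and a parameter echo", {
  d <- tempfile()
  p <- quickParams(grid = c(100L, 100L, 6L), rMaxUm = 2.5, seed = 2L)
  sim <- writeSimulation(p, d)
  expect_true(all(file.exists(file.path(d,
    c("irm.tif", "actin.tif", "fab.tif", "signal.tif", "movie.yaml",
      "truth_area.csv", "truth_focus_tracks.csv", "truth_cluster_tracks.csv",
      "params.yaml")))))
  back <- readMovie(d)
  expect_equal(nFrames(back), 6L)
  ## 16-bit quantization: intensities agree to the stored precision
  expect_lt(max(abs(getChannel(back, "fab")@frames -
                    getChannel(sim$movie, "fab")@frames)), 1)
  unlink(d, recursive = TRUE)
})
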