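test_that("background is the median of a matched outside band", {
  mask <- diskMask(80, 80, 40, 40, 20)
  fr <- matrix(50, 80, 80)
  fr[mask] <- 500
  bg <- estimateBackground(fr, mask)
  expect_equal(as.numeric(bg), 50)
  expect_gte(attr(bg, "n_pixels"), sum(mask))

  ## 1% debris at 5000 does not move the median
  set.seed(5)
  fr2 <- fr
  out <- which(!mask)
  fr2[sample(out, round(0.01 * length(out)))] <- 5000
  expect_equal(as.numeric(estimateBackground(fr2, mask)), 50)

  ## mask nearly filling the frame: cannot accumulate the band
  big <- diskMask(40, 40, 20, 20, 19)
  expect_error(estimateBackground(matrix(1, 40, 40), big), "too small")
})

test_that("graded thresholds retain each object at its highest fold", {
  cal <- mkCal()
  mask <- diskMask(64, 64, 32, 32, 26)

  ## flat background frame: nothing detected
  expect_identical(
    nrow(gradedThresholdDetect(matrix(100, 64, 64), mask, 100, cal)), 0L)

  ## wide plateau at exactly 2.0x background -> retained at fold 1.9
  fr <- matrix(100, 64, 64)
  fr[28:36, 28:36] <- 200
  det <- gradedThresholdDetect(fr, mask, 100, cal)
  expect_identical(nrow(det), 1L)
  expect_equal(det$threshold_fold, 1.9)

  ## a bright and a dim blob: each at its own highest size-passing fold
  fr2 <- addGauss(addGauss(matrix(100, 64, 64), 32, 22, 320, 2),
                  32, 44, 40, 2)
  det2 <- gradedThresholdDetect(fr2, mask, 100, cal)
  expect_identical(nrow(det2), 2L)
  ## dim blob (peak 1.4x) at fold 1.3; bright blob (peak 4.2x) at the
  ## highest fold whose superlevel set still spans >= 250 nm (3.7)
  expect_equal(sort(det2$threshold_fold), c(1.3, 3.7))
  expect_identical(length(intersect(det2$pixels[[1]], det2$pixels[[2]])), 0L)
})

test_that("graded detection equals the 16-mask brute-force oracle", {
  cal <- mkCal()
  mask <- diskMask(64, 64, 32, 32, 28)
  for (s in 1:20) {
    fr <- randomBlobFrame(400 + s)
    got <- gradedThresholdDetect(fr, mask, 100, cal)
    want <- oracleGraded(fr, mask, 100, cal)
    expect_identical(nrow(got), length(want))
    if (nrow(got)) {
      gotKey <- sort(paste(got$threshold_fold,
                           vapply(got$pixels, function(px)
                             paste(sort(px), collapse = ","), character(1))))
      wantKey <- sort(vapply(want, function(a)
        paste(a$fold, paste(a$idx, collapse = ",")), character(1)))
      expect_identical(gotKey, wantKey)
      ## disjointness of accepted pixel sets
      allPx <- unlist(got$pixels)
      expect_identical(anyDuplicated(allPx), 0L)
    }
  }
})

## helper: per-frame detections for blobs at given centroids
detFrames <- function(paths, cal, amp = 150, sigmaPx = 2, h = 64, w = 64) {
  mask <- diskMask(h, w, h / 2, w / 2, h / 2 - 4)
  lapply(seq_len(nrow(paths[[1]])), function(t) {
    fr <- matrix(100, h, w)
    for (p in paths) fr <- addGauss(fr, p$row[t], p$col[t], amp, sigmaPx)
    gradedThresholdDetect(fr, mask, 100, cal)
  })
}

test_that("a static blob tracks to movie end with the inclusive duration", {
  cal <- mkCal()
  paths <- list(data.frame(row = rep(30, 30), col = rep(30, 30)))
  tr <- trackClusters(detFrames(paths, cal), cal)
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$duration_s, 60)
  expect_identical(tr$end_reason, "movie_end")
})

test_that("converging blobs end merged and a fresh track starts", {
  cal <- mkCal()
  ## two blobs approach and fuse into one component by frame 12
  rows <- cbind(seq(22, 31, length.out = 15), seq(42, 33, length.out = 15))
  paths <- list(data.frame(row = rows[, 1], col = rep(32, 15)),
                data.frame(row = rows[, 2], col = rep(32, 15)))
  det <- detFrames(paths, cal)
  nPer <- vapply(det, nrow, integer(1))
  expect_identical(nPer[1], 2L)
  expect_identical(nPer[15], 1L)
  tr <- trackClusters(det, cal)
  expect_identical(sum(tr$end_reason == "merged"), 2L)
  merged <- tr[tr$end_reason == "movie_end", ]
  expect_identical(nrow(merged), 1L)
  expect_gt(merged$birth_s, 0)
})

test_that("simulated non-merging clusters are recovered one to one", {
  co <- data.frame(angle_deg = seq(0, 330, by = 30) + 10,
                   frac = rep(c(0.35, 0.6), 6), peak0 = 180, ramp_fi_s = 0.5)
  p <- quickParams(grid = c(120L, 120L, 40L), seed = 31L, noiseSigma = 8,
                   clustersOverride = co, focusBirthRatePerMin = 0)
  sim <- renderMovie(p)
  masks <- segmentMovie(getChannel(sim$movie, "irm"))
  fab <- getChannel(sim$movie, "fab")
  cal <- calibration(sim$movie)
  det <- lapply(seq_len(40), function(t) {
    bg <- estimateBackground(getFrame(fab, t), masks[[t]])
    gradedThresholdDetect(getFrame(fab, t), masks[[t]], bg, cal)
  })
  tracks <- filterTrackable(trackClusters(det, cal), 20)
  ## the 12 planted clusters persist to movie end once the footprint has
  ## spread enough to separate them
  long <- tracks[tracks$end_reason == "movie_end" & tracks$duration_s >= 40, ]
  expect_identical(nrow(long), 12L)
  ## match to ground truth by mean centroid distance < 300 nm
  tru <- sim$truth@clusterTracks
  for (k in seq_len(nrow(long))) {
    fr <- long$frames[[k]]
    xs <- long$x_um[[k]] - pxToUm(cal, (120 + 1) / 2 - 1)
    ys <- long$y_um[[k]] - pxToUm(cal, (120 + 1) / 2 - 1)
    dBest <- Inf
    for (cl in unique(tru$cluster)) {
      tc <- tru[tru$cluster == cl & tru$frame %in% fr, ]
      dBest <- min(dBest, mean(sqrt((tc$x_um - xs)^2 + (tc$y_um - ys)^2)))
    }
    expect_lt(dBest, 0.3)
  }
})

test_that("the 20-s trackability filter is boundary inclusive", {
  tr <- data.frame(track = 1:3, duration_s = c(20, 18, 60),
                   end_reason = "lost")
  out <- filterTrackable(tr, 20)
  expect_identical(out$track, c(1L, 3L))
  expect_identical(attr(out, "n_eliminated"), 1L)
  empty <- filterTrackable(tr[0, ], 20)
  expect_identical(nrow(empty), 0L)
})

test_that("peak-FI rates are OLS slopes with analytic uncertainty", {
  cal <- mkCal()
  mkTrack <- function(pk) {
    out <- data.frame(track = 1L)
    out$frames <- list(seq_along(pk))
    out$peak_fi <- list(pk)
    out
  }
  ## 100, 102, 104, ... at 2-s spacing -> 1 FI/s
  expect_equal(peakFiRate(mkTrack(seq(100, 140, by = 2)), cal)$slope, 1)
  expect_equal(peakFiRate(mkTrack(rep(77, 10)), cal)$slope, 0)
  expect_error(peakFiRate(mkTrack(c(1, 2)), cal), "fewer than 3")

  ## planted 5 FI/s ramp with sigma = 2 noise over 20 frames: within 3 SE
  set.seed(13)
  for (i in 1:10) {
    tt <- seq(0, 38, by = 2)
    fit <- peakFiRate(mkTrack(200 + 5 * tt + rnorm(20, 0, 2)), cal)
    expect_lt(abs(fit$slope - 5), 3 * fit$se)
  }
})

test_that("per-cell rate summaries average tracks by phase", {
  cal <- mkCal()
  mk2 <- function(slopes) {
    out <- data.frame(track = seq_along(slopes))
    out$frames <- rep(list(1:20), length(slopes))
    out$peak_fi <- lapply(slopes, function(s) 100 + s * (0:19) * 2)
    out
  }
  rs <- perCellRateSummary(mk2(c(2, 4)), cal, list(all = c(0, 38)))
  expect_equal(rs$mean_slope, 3)
  expect_identical(rs$n_tracks, 2L)
  one <- perCellRateSummary(mk2(5), cal, list(all = c(0, 38)))
  expect_equal(one$mean_slope, 5)
  none <- perCellRateSummary(mk2(1), cal, list(late = c(100, 120)))
  expect_true(is.na(none$mean_slope))
})
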