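#' Contact-area time series
#'
#' Per-frame contact-zone area (um^2) with the smoothed version used for
#' contraction classification.
#'
#' @slot timesS per-frame time (s), strictly increasing with the frame interval step.
#' @slot areasUm2 raw per-frame areas (um^2), >= 0.
#' @slot smoothedAreasUm2 moving-average filtered areas.
#'
#' @aliases AreaTrace
#' @exportClass AreaTrace
setClass("AreaTrace",
  representation(timesS = "numeric", areasUm2 = "numeric",
                 smoothedAreasUm2 = "numeric"))

setValidity("AreaTrace", function(object) {
  msg <- character()
  n <- length(object@timesS)
  if (length(object@areasUm2) != n || length(object@smoothedAreasUm2) != n)
    msg <- c(msg, "times and areas must have equal lengths")
  if (any(object@areasUm2 < 0)) msg <- c(msg, "areas must be >= 0")
  if (n > 1 && any(diff(object@timesS) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname AreaTrace-class
#' @param x an \code{AreaTrace}.
#' @export
setMethod("timesS", "AreaTrace", function(x) x@timesS)

#' @rdname AreaTrace-class
#' @export
setMethod("areasUm2", "AreaTrace", function(x) x@areasUm2)

#' @rdname AreaTrace-class
#' @export
setMethod("smoothedAreasUm2", "AreaTrace", function(x) x@smoothedAreasUm2)

setMethod("show", "AreaTrace", function(object) {
  cat(sprintf("AreaTrace: %d frames, area %.3g-%.3g um^2\n",
              length(object@timesS), min(object@areasUm2), max(object@areasUm2)))
})

#' Contraction classification of one cell
#'
#' Result of \code{\link{classifyContraction}}: whether the cell's contact
#' zone underwent a sustained area reduction after maximal spreading, and
#' when. The onset, when present, equals the time of maximal spreading.
#'
#' @slot contracting logical(1).
#' @slot tMaxSpreadS time (s) the smoothed area first attains its maximum.
#' @slot onsetS contraction start time (s) or \code{NA}.
#' @slot maxAreaUm2 maximum smoothed area (um^2).
#' @slot note character(1): "" or a flag such as "insufficient observation".
#'
#' @aliases ContractionCall
#' @exportClass ContractionCall
setClass("ContractionCall",
  representation(contracting = "logical", tMaxSpreadS = "numeric",
                 onsetS = "numeric", maxAreaUm2 = "numeric", note = "character"))

setValidity("ContractionCall", function(object) {
  msg <- character()
  if (object@contracting != !is.na(object@onsetS))
    msg <- c(msg, "contracting must hold exactly when onsetS is present")
  if (!is.na(object@onsetS) && object@onsetS < object@tMaxSpreadS)
    msg <- c(msg, "onsetS must be >= tMaxSpreadS")
  if (length(msg)) msg else TRUE
})

#' @rdname ContractionCall-class
#' @param x a \code{ContractionCall}.
#' @export
setMethod("isContracting", "ContractionCall", function(x) x@contracting)

#' @rdname ContractionCall-class
#' @export
setMethod("onsetS", "ContractionCall", function(x) x@onsetS)

#' @rdname ContractionCall-class
#' @export
setMethod("tMaxSpreadS", "ContractionCall", function(x) x@tMaxSpreadS)

#' @rdname ContractionCall-class
#' @export
setMethod("maxAreaUm2", "ContractionCall", function(x) x@maxAreaUm2)

setMethod("show", "ContractionCall", function(object) {
  cat(sprintf("ContractionCall: %s (max %.3g um^2 at %.4g s)%s\n",
              if (object@contracting)
                sprintf("contracting, onset %.4g s", object@onsetS)
              else "non-contracting",
              object@maxAreaUm2, object@tMaxSpreadS,
              if (nzchar(object@note)) paste0(" [", object@note, "]") else ""))
})

#' Segment the contact zone from one IRM frame
#'
#' The cell-bilayer contact footprint appears dark in interference reflection
#' microscopy. The frame is Gaussian-smoothed (sigma 1 px), globally
#' thresholded with Otsu's method, holes are filled and the largest
#' 8-connected below-threshold component is returned. A frame without a
#' genuinely dark class (constant frame, or dark/bright class means closer
#' than \code{contrastMin}) yields an empty mask flagged via
#' \code{attr(mask, "flagged")} — the cell has not landed.
#'
#' @param frame numeric IRM intensity matrix.
#' @param calibration a \code{\linkS4class{Calibration}} (carried for
#'   interface symmetry; segmentation itself is calibration-free).
#' @param sigmaPx Gaussian pre-smoothing sigma in pixels.
#' @param contrastMin maximum dark/bright class mean ratio accepted as a
#'   genuine footprint.
#' @return logical H x W matrix; attribute \code{"flagged"} is TRUE when no
#'   footprint was found.
#' @export
segmentContactZone <- function(frame, calibration, sigmaPx = 1,
                               contrastMin = 0.7) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  empty <- function(reason) {
    m <- matrix(FALSE, nrow(frame), ncol(frame))
    attr(m, "flagged") <- TRUE
    attr(m, "reason") <- reason
    m
  }
  g <- EBImage::gblur(frame, sigma = sigmaPx)
  rng <- range(g)
  if (diff(rng) < max(1e-12, 1e-9 * abs(rng[2])))
    return(empty("constant frame"))
  gn <- (g - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(gn), range = c(0, 1), levels = 256L)
  dark <- gn < th
  if (!any(dark) || all(dark)) return(empty("degenerate threshold"))
  if (mean(g[dark]) > contrastMin * mean(g[!dark]))
    return(empty("insufficient contrast"))
  filled <- EBImage::fillHull(matrix(as.integer(dark), nrow(frame))) > 0
  lab <- label8(filled)
  counts <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(counts)
  attr(mask, "flagged") <- FALSE
  mask
}

#' Segment every IRM frame of a movie
#'
#' @param stack the IRM \code{\linkS4class{ChannelStack}}.
#' @param ... passed to \code{\link{segmentContactZone}}.
#' @return list of logical masks, one per frame.
#' @export
segmentMovie <- function(stack, ...) {
  lapply(seq_len(nFrames(stack)), function(i)
    segmentContactZone(getFrame(stack, i), calibration(stack), ...))
}

#' Build the contact-area trace from per-frame masks
#'
#' Areas are mask pixel counts converted to um^2; the smoothed series is a
#' centred moving average (edges truncated) used by
#' \code{\link{classifyContraction}} so single-frame noise dips cannot
#' satisfy the sustained-drop rule.
#'
#' @param masks list of per-frame logical masks.
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param smoothWindowFrames moving-average window (frames).
#' @return an \code{\linkS4class{AreaTrace}}.
#' @export
areaTrace <- function(masks, calibration, smoothWindowFrames = 5L) {
  stopifnot(length(masks) >= 1L)
  areas <- pxAreaToUm2(calibration, vapply(masks, sum, numeric(1)))
  new("AreaTrace",
      timesS = frameToS(calibration, seq_along(masks)),
      areasUm2 = areas,
      smoothedAreasUm2 = movingAverage(areas, smoothWindowFrames))
}

#' Classify a cell as contracting or not
#'
#' A cell is called contracting when its (smoothed) contact area is reduced
#' by at least \code{minDrop} (default 5\%) for at least \code{minDurationS}
#' (default 10 s) after reaching its maximum value. Let A* be the reference
#' maximum of the trace and t* its first attainment: the call is positive iff
#' some contiguous run of frames after t*, of duration >= \code{minDurationS}
#' (run length x frame interval), stays at or below (1 - minDrop) A*. The
#' contraction onset is t*, the spreading-to-contraction transition.
#'
#' A trace whose post-maximum tail is shorter than \code{minDurationS} is
#' classified non-contracting with note "insufficient observation".
#'
#' @param trace an \code{\linkS4class{AreaTrace}}.
#' @param minDrop fractional drop threshold.
#' @param minDurationS minimum sustained duration (s).
#' @param use classify on the \code{"smoothed"} (default) or \code{"raw"} series.
#' @param reference \code{"global"} (default): A* is the global maximum;
#'   \code{"running"}: every attained maximum is tried in turn and the call is
#'   positive if the rule holds after any of them (onset = the earliest such
#'   maximum).
#' @return a \code{\linkS4class{ContractionCall}}.
#' @export
classifyContraction <- function(trace, minDrop = 0.05, minDurationS = 10,
                                use = c("smoothed", "raw"),
                                reference = c("global", "running")) {
  use <- match.arg(use)
  reference <- match.arg(reference)
  a <- if (use == "smoothed") trace@smoothedAreasUm2 else trace@areasUm2
  tt <- trace@timesS
  n <- length(a)
  stopifnot(n >= 2L)
  dt <- tt[2] - tt[1]
  stopifnot(minDurationS >= dt)
  minFrames <- ceiling(minDurationS / dt - 1e-9)

  sustainedAfter <- function(iMax) {
    below <- a <= (1 - minDrop) * a[iMax]
    below[seq_len(iMax)] <- FALSE
    r <- rle(below)
    any(r$values & r$lengths >= minFrames)
  }

  iStar <- which.max(a)            # first attainment of the global maximum
  if (reference == "global") {
    cand <- iStar
  } else {
    runmax <- cummax(a)
    cand <- which(a == runmax)     # frames attaining a running maximum
    cand <- cand[!duplicated(a[cand])]
  }
  hit <- cand[vapply(cand, sustainedAfter, logical(1))]
  contracting <- length(hit) > 0L
  iRef <- if (contracting) hit[1] else iStar
  note <- ""
  if (!contracting && (n - iStar) * dt < minDurationS)
    note <- "insufficient observation"
  new("ContractionCall",
      contracting = contracting,
      tMaxSpreadS = tt[iRef],
      onsetS = if (contracting) tt[iRef] else NA_real_,
      maxAreaUm2 = a[iRef],
      note = note)
}

#' Contraction window of a contracting cell
#'
#' The interval over which the smoothed area is actually declining: from the
#' onset to the first frame after it where the area stops decreasing.
#'
#' @param trace an \code{\linkS4class{AreaTrace}}.
#' @param call a contracting \code{\linkS4class{ContractionCall}}.
#' @return numeric(2): (onset_s, decline_end_s).
#' @export
contractionWindow <- function(trace, call) {
  stopifnot(isContracting(call))
  a <- trace@smoothedAreasUm2
  tt <- trace@timesS
  i0 <- which.min(abs(tt - onsetS(call)))
  j <- i0
  while (j < length(a) && a[j + 1] < a[j]) j <- j + 1L
  c(onset_s = tt[i0], decline_end_s = tt[j])
}

#' Mean fluorescence intensity inside the contact zone over time
#'
#' @param stack a fluorescence \code{\linkS4class{ChannelStack}}.
#' @param masks per-frame masks from \code{\link{segmentMovie}}.
#' @return data.frame with columns \code{time_s} and \code{mfi} (\code{NA}
#'   for empty-mask frames).
#' @export
channelMfiTrace <- function(stack, masks) {
  stopifnot(length(masks) == nFrames(stack))
  mfi <- vapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    if (!any(m)) NA_real_ else mean(getFrame(stack, i)[m])
  }, numeric(1))
  if (all(is.na(mfi))) stop("all masks are empty: no contact zone in any frame")
  data.frame(time_s = frameToS(calibration(stack), seq_along(masks)), mfi = mfi)
}

#' Initial recruitment rate from an MFI trace
#'
#' Ordinary least-squares slope of MFI versus time restricted to
#' \code{windowS} measured from cell landing (the first frame with a
#' non-empty mask, i.e. the first non-missing MFI value).
#'
#' @param mfiTrace data.frame from \code{\link{channelMfiTrace}}.
#' @param windowS numeric(2) window in seconds relative to landing.
#' @return list with \code{slope} (FI/s), \code{se}, \code{n} and
#'   \code{landing_s}.
#' @export
initialRate <- function(mfiTrace, windowS = c(0, 30)) {
  ok <- !is.na(mfiTrace$mfi)
  if (!any(ok)) stop("empty MFI trace")
  t0 <- mfiTrace$time_s[which(ok)[1]]
  rel <- mfiTrace$time_s - t0
  sel <- ok & rel >= windowS[1] & rel <= windowS[2]
  if (sum(sel) < 3L) stop("fewer than 3 samples in the initial window")
  fit <- olsSlope(rel[sel], mfiTrace$mfi[sel])
  list(slope = fit$slope, se = fit$se, n = fit$n, landing_s = t0)
}

#' MFI accumulation rates before and during contraction
#'
#' OLS slopes of the MFI trace over the phases (landing, onset) and
#' (onset, end of area decline), the latter from
#' \code{\link{contractionWindow}}.
#'
#' @param mfiTrace data.frame from \code{\link{channelMfiTrace}}.
#' @param trace the cell's \code{\linkS4class{AreaTrace}}.
#' @param call its contracting \code{\linkS4class{ContractionCall}}.
#' @return list with \code{rate_before}, \code{rate_during} (FI/s), their
#'   standard errors and sample counts.
#' @export
phaseRates <- function(mfiTrace, trace, call) {
  stopifnot(isContracting(call))
  win <- contractionWindow(trace, call)
  ok <- !is.na(mfiTrace$mfi)
  t0 <- mfiTrace$time_s[which(ok)[1]]
  before <- ok & mfiTrace$time_s >= t0 & mfiTrace$time_s < win[1]
  during <- ok & mfiTrace$time_s >= win[1] & mfiTrace$time_s <= win[2]
  if (sum(before) < 3L) stop("fewer than 3 samples before contraction onset")
  if (sum(during) < 3L) stop("fewer than 3 samples during contraction")
  fb <- olsSlope(mfiTrace$time_s[before], mfiTrace$mfi[before])
  fd <- olsSlope(mfiTrace$time_s[during], mfiTrace$mfi[during])
  list(rate_before = fb$slope, se_before = fb$se, n_before = fb$n,
       rate_during = fd$slope, se_during = fd$se, n_during = fd$n)
}
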