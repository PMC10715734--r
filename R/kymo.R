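#' Radial kymograph
#'
#' Space x time intensity matrix sampled along a fixed radial line from the
#' contact-zone centroid at maximal spreading. Each spatial sample is the
#' mean of bilinear interpolations across a perpendicular stencil of
#' \code{2 * lineHalfwidthPx + 1} pixels.
#'
#' @slot originUm numeric(2), line start (x, y) in um.
#' @slot angleDeg line angle (degrees, measured from the +x axis with y
#'   pointing down the rows).
#' @slot samples S x T matrix (S spatial bins along the line, T frames).
#' @slot binSizeUm spatial bin size (um).
#' @slot lineHalfwidthPx half-width of the perpendicular stencil (px).
#' @slot calibration a \code{\linkS4class{Calibration}}.
#'
#' @aliases Kymograph
#' @exportClass Kymograph
setClass("Kymograph",
  representation(originUm = "numeric", angleDeg = "numeric",
                 samples = "matrix", binSizeUm = "numeric",
                 lineHalfwidthPx = "numeric", calibration = "Calibration"))

#' @rdname Kymograph-class
#' @param x a \code{Kymograph}.
#' @export
setMethod("kymoSamples", "Kymograph", function(x) x@samples)

#' @rdname Kymograph-class
#' @export
setMethod("sampleRadiiUm", "Kymograph", function(x)
  (seq_len(nrow(x@samples)) - 1) * x@binSizeUm)

#' @rdname Kymograph-class
#' @export
setMethod("angleDeg", "Kymograph", function(x) x@angleDeg)

#' @rdname Kymograph-class
#' @export
setMethod("calibration", "Kymograph", function(x) x@calibration)

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph at %.4g deg: %d bins x %d frames (%.3g um/bin)\n",
              object@angleDeg, nrow(object@samples), ncol(object@samples),
              object@binSizeUm))
})

#' Build radially spaced kymographs for one cell
#'
#' \code{nLines} lines at equally spaced angles k * 360 / nLines start at the
#' contact-zone centroid of frame \code{tRefFrame} (the frame of maximal
#' spreading) and extend to the largest radial extent of the mask over all
#' frames plus 1 um, so the lamellipodial edge stays in view throughout.
#'
#' @param stack the channel to sample (typically actin).
#' @param masks per-frame contact masks from \code{\link{segmentMovie}}.
#' @param nLines number of lines (8 for origin scoring, 3 for lifetime/speed
#'   measurements are the conventional choices).
#' @param tRefFrame frame index of maximal spreading.
#' @param binSizeUm spatial bin size; defaults to one pixel.
#' @param lineHalfwidthPx perpendicular stencil half-width.
#' @return list of \code{\linkS4class{Kymograph}} objects.
#' @export
makeKymographs <- function(stack, masks, nLines = 8L, tRefFrame,
                           binSizeUm = NULL, lineHalfwidthPx = 1L) {
  stopifnot(nLines >= 1L, length(masks) == nFrames(stack))
  cal <- calibration(stack)
  pxUm <- pixelSizeNm(cal) / 1000
  if (is.null(binSizeUm)) binSizeUm <- pxUm
  mRef <- masks[[tRefFrame]]
  if (!any(mRef)) stop("empty contact mask at the reference frame")
  idx <- which(mRef)
  cRow <- mean((idx - 1L) %% nrow(mRef) + 1L)
  cCol <- mean((idx - 1L) %/% nrow(mRef) + 1L)
  maxR <- 0
  for (m in masks) {
    if (!any(m)) next
    i <- which(m)
    r <- (i - 1L) %% nrow(m) + 1L
    cc <- (i - 1L) %/% nrow(m) + 1L
    maxR <- max(maxR, max(sqrt((r - cRow)^2 + (cc - cCol)^2)) * pxUm)
  }
  radii <- seq(0, maxR + 1, by = binSizeUm)
  offs <- seq(-lineHalfwidthPx, lineHalfwidthPx)
  T <- nFrames(stack)
  angles <- (seq_len(nLines) - 1L) * 360 / nLines
  lapply(angles, function(a) {
    dx <- cospi(a / 180); dy <- sinpi(a / 180)
    samp <- matrix(0, length(radii), T)
    rowPts <- outer(radii / pxUm * dy, offs * dx, "+") + cRow
    colPts <- outer(radii / pxUm * dx, offs * (-dy), "+") + cCol
    for (t in seq_len(T)) {
      fr <- getFrame(stack, t)
      v <- bilinear(fr, as.numeric(rowPts), as.numeric(colPts))
      samp[, t] <- rowMeans(matrix(v, length(radii)))
    }
    new("Kymograph",
        originUm = c(pxToUm(cal, cCol - 1), pxToUm(cal, cRow - 1)),
        angleDeg = a, samples = samp, binSizeUm = binSizeUm,
        lineHalfwidthPx = as.numeric(lineHalfwidthPx), calibration = cal)
  })
}

#' Contact-zone edge radius along a kymograph line
#'
#' Per-frame radial position (um) of the last mask sample along the line:
#' the contemporaneous lamellipodial edge used by \code{\link{classifyOrigin}}.
#'
#' @param masks per-frame logical masks.
#' @param kymo a \code{\linkS4class{Kymograph}}.
#' @return numeric vector, one edge radius per frame (\code{NA} where the
#'   mask does not intersect the line).
#' @export
kymoEdgeRadius <- function(masks, kymo) {
  cal <- kymo@calibration
  pxUm <- pixelSizeNm(cal) / 1000
  radii <- sampleRadiiUm(kymo)
  a <- kymo@angleDeg
  rowPts <- kymo@originUm[2] / pxUm + 1 + radii / pxUm * sinpi(a / 180)
  colPts <- kymo@originUm[1] / pxUm + 1 + radii / pxUm * cospi(a / 180)
  vapply(masks, function(m) {
    v <- bilinear(m * 1, rowPts, colPts) > 0.5
    if (!any(v)) NA_real_ else radii[max(which(v))]
  }, numeric(1))
}

#' Extract foci tracks from a kymograph
#'
#' Automated surrogate for manual kymograph track tracing. Per frame
#' (column), spatial local maxima with intensity >= \code{fold} x the
#' column-local reference (the column median, excluding the outermost
#' \code{rimExcludeUm} of the line where the lamellipodial rim and exterior
#' live) become detections; maxima positions are refined to sub-bin accuracy
#' by a three-point parabolic fit. Detections in consecutive frames are
#' linked greedily by nearest radial position with jumps <= \code{maxJumpUm}
#' and no gap frames; tracks shorter than \code{minDurationS} are discarded.
#'
#' The reported lifetime uses the inclusive span convention: a track
#' detected in frames f..g has lifetime (g - f + 1) x frame interval, so a
#' 2-frame track at 2 s/frame lives 4 s. Because a focus can leave the
#' sampled line or the TIRF field, lifetimes and speeds are relative
#' (apparent) quantities.
#'
#' @param kymo a \code{\linkS4class{Kymograph}}.
#' @param fold intensity criterion (fold of the column reference).
#' @param maxJumpUm maximum per-frame radial jump (um).
#' @param minDurationS minimum track duration (s).
#' @param rimExcludeUm outer line length excluded from the column reference.
#' @param smoothBins moving-average window (bins) applied to each column
#'   before maxima detection; suppresses single-bin noise maxima.
#' @param minSepUm non-maximum-suppression radius: of detections closer than
#'   this within one column, only the brightest is kept (a broad rim plateau
#'   then yields one detection, not a comb of noise maxima).
#' @param edgeRadiusPerFrame optional per-frame contact-zone edge radius (um)
#'   along this line, from \code{\link{kymoEdgeRadius}}. When given,
#'   detections within \code{edgeExcludeUm} of the contemporaneous edge are
#'   dropped: the bright lamellipodial rim is lamellipodial F-actin itself,
#'   not an inner focus, so "inner" tracks begin once a focus emerges from
#'   under the rim band.
#' @param edgeExcludeUm width of the excluded rim zone (um).
#' @return data.frame with one row per track: \code{birth_s}, \code{death_s},
#'   \code{lifetime_s}, \code{displacement_um}, \code{speed_um_s},
#'   \code{birth_radius_um}, \code{death_radius_um}; list columns
#'   \code{frames} and \code{positions_um}.
#' @export
extractTracks <- function(kymo, fold = 2.0, maxJumpUm = 0.4,
                          minDurationS = 4, rimExcludeUm = 1.0,
                          smoothBins = 3L, minSepUm = 0.5,
                          edgeRadiusPerFrame = NULL, edgeExcludeUm = 1.3) {
  samp <- kymo@samples
  radii <- sampleRadiiUm(kymo)
  dt <- frameIntervalS(kymo@calibration)
  S <- nrow(samp); T <- ncol(samp)
  refSel <- radii <= max(radii) - rimExcludeUm
  if (!any(refSel)) refSel <- rep(TRUE, S)

  detections <- vector("list", T)
  for (t in seq_len(T)) {
    v <- movingAverage(samp[, t], smoothBins)
    ## robust column reference: exclude ridge pixels (rim, foci) so dense
    ## bright structure cannot inflate the 2-fold threshold
    vr <- v[refSel]
    ref <- stats::median(vr[vr <= 1.5 * stats::median(vr)])
    if (S < 3L) { detections[[t]] <- numeric(0); next }
    isMax <- c(FALSE, v[2:(S - 1)] > v[1:(S - 2)] & v[2:(S - 1)] >= v[3:S], FALSE)
    hit <- which(isMax & v >= fold * ref)
    ## non-maximum suppression first (so a plateau's main maximum can veto
    ## its shoulders), then the rim-zone exclusion
    if (length(hit) > 1L) {
      keep <- logical(length(hit))
      for (k in order(v[hit], decreasing = TRUE)) {
        if (any(keep & abs(radii[hit] - radii[hit[k]]) < minSepUm)) next
        keep[k] <- TRUE
      }
      hit <- hit[keep]
    }
    if (!is.null(edgeRadiusPerFrame) && length(hit)) {
      edge <- edgeRadiusPerFrame[t]
      if (!is.na(edge)) hit <- hit[radii[hit] <= edge - edgeExcludeUm]
    }
    pos <- vapply(hit, function(i) {
      den <- v[i - 1] - 2 * v[i] + v[i + 1]
      delta <- if (den < 0) 0.5 * (v[i - 1] - v[i + 1]) / den else 0
      (i - 1 + max(-0.5, min(0.5, delta))) * kymo@binSizeUm
    }, numeric(1))
    detections[[t]] <- pos
  }

  ## greedy nearest-neighbour linking, no gap closing
  tracks <- list()
  active <- list()   # each: list(frames, positions)
  for (t in seq_len(T)) {
    det <- detections[[t]]
    nA <- length(active); nD <- length(det)
    linkA <- integer(0); linkD <- integer(0)
    if (nA > 0L && nD > 0L) {
      lastPos <- vapply(active, function(a) a$positions[length(a$positions)],
                        numeric(1))
      dmat <- abs(outer(lastPos, det, "-"))
      ord <- order(dmat)
      usedA <- logical(nA); usedD <- logical(nD)
      for (k in ord) {
        if (dmat[k] > maxJumpUm) break
        i <- (k - 1L) %% nA + 1L
        j <- (k - 1L) %/% nA + 1L
        if (usedA[i] || usedD[j]) next
        usedA[i] <- TRUE; usedD[j] <- TRUE
        linkA <- c(linkA, i); linkD <- c(linkD, j)
      }
    }
    nextActive <- list()
    if (nA > 0L) for (i in seq_len(nA)) {
      m <- match(i, linkA)
      if (!is.na(m)) {
        a <- active[[i]]
        a$frames <- c(a$frames, t)
        a$positions <- c(a$positions, det[linkD[m]])
        nextActive[[length(nextActive) + 1L]] <- a
      } else {
        tracks[[length(tracks) + 1L]] <- active[[i]]
      }
    }
    if (nD > 0L) for (j in seq_len(nD)) {
      if (!j %in% linkD)
        nextActive[[length(nextActive) + 1L]] <-
          list(frames = t, positions = det[j])
    }
    active <- nextActive
  }
  tracks <- c(tracks, active)

  if (!length(tracks)) return(emptyTrackFrame())
  out <- do.call(rbind, lapply(tracks, function(a) {
    f0 <- a$frames[1]; f1 <- a$frames[length(a$frames)]
    life <- (f1 - f0 + 1L) * dt
    disp <- abs(a$positions[length(a$positions)] - a$positions[1])
    data.frame(birth_s = (f0 - 1L) * dt, death_s = (f0 - 1L) * dt + life,
               lifetime_s = life, displacement_um = disp,
               speed_um_s = disp / life,
               birth_radius_um = a$positions[1],
               death_radius_um = a$positions[length(a$positions)])
  }))
  out$frames <- lapply(tracks, `[[`, "frames")
  out$positions_um <- lapply(tracks, `[[`, "positions")
  out <- out[out$lifetime_s >= minDurationS - 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  out
}

emptyTrackFrame <- function() {
  data.frame(birth_s = numeric(0), death_s = numeric(0),
             lifetime_s = numeric(0), displacement_um = numeric(0),
             speed_um_s = numeric(0), birth_radius_um = numeric(0),
             death_radius_um = numeric(0))
}

#' Lamellipodial origin of a kymograph track
#'
#' A track is lamellipodia-derived when it is born within \code{lamBandUm}
#' of the contemporaneous contact-zone edge radius, moves centripetally
#' (its radial coordinate decreases by more than \code{minInwardUm} over the
#' track) and lasts longer than \code{minDurationS}.
#'
#' @param track one row of the \code{\link{extractTracks}} result.
#' @param edgeRadiusPerFrame per-frame edge radius (um) from
#'   \code{\link{kymoEdgeRadius}}.
#' @param frameIntervalS frame interval (s).
#' @param lamBandUm lamellipodial band width (um).
#' @param minDurationS minimum lifetime (s), strict.
#' @param minInwardUm minimum centripetal displacement (um).
#' @param rimOffsetUm extra allowance subtracted from the edge radius before
#'   the band test; set to the rim-exclusion width used in
#'   \code{\link{extractTracks}} so foci first detected just inside the
#'   excluded rim zone still count as born at the lamellipodium.
#' @return logical(1).
#' @export
classifyOrigin <- function(track, edgeRadiusPerFrame, frameIntervalS,
                           lamBandUm = 1.0, minDurationS = 8,
                           minInwardUm = 0.25, rimOffsetUm = 0) {
  f0 <- round(track$birth_s / frameIntervalS) + 1L
  edge <- edgeRadiusPerFrame[min(max(f0, 1L), length(edgeRadiusPerFrame))]
  if (is.na(edge)) return(FALSE)
  bornAtRim <- track$birth_radius_um >= edge - lamBandUm - rimOffsetUm &&
    track$birth_radius_um <= edge + lamBandUm
  inward <- (track$birth_radius_um - track$death_radius_um) > minInwardUm
  longEnough <- track$lifetime_s > minDurationS
  isTRUE(bornAtRim && inward && longEnough)
}

#' Fraction of kymographs with lamellipodia-derived foci
#'
#' @param trackSets list with one \code{\link{extractTracks}} data.frame per
#'   kymograph, each carrying a logical column \code{lamellipodial_origin}.
#' @return list with \code{fraction}, \code{percent} and \code{n_positive}.
#' @export
fractionLamellipodiaDerived <- function(trackSets) {
  stopifnot(length(trackSets) >= 1L)
  pos <- vapply(trackSets, function(tr)
    nrow(tr) > 0L && any(tr$lamellipodial_origin), logical(1))
  list(fraction = mean(pos), percent = 100 * mean(pos),
       n_positive = sum(pos), n_kymographs = length(trackSets))
}

#' Per-cell relative lifetime and speed of inner foci
#'
#' Restricts tracks to those born within \code{windowS} after maximal
#' spreading and trackable for at least \code{minLifetimeS}, then averages
#' their relative lifetimes and speeds (displacement / lifetime) per cell.
#'
#' @param tracks combined \code{\link{extractTracks}} rows from the cell's
#'   kymographs.
#' @param tMaxSpreadS time of maximal spreading (s).
#' @param windowS emergence window after maximal spreading (s).
#' @param minLifetimeS minimum trackable lifetime (s), inclusive.
#' @return list with \code{mean_lifetime_s}, \code{mean_speed_um_s} and
#'   \code{n_tracks} (both means \code{NA} with \code{n_tracks = 0} when no
#'   track qualifies).
#' @export
lifetimeSpeedStats <- function(tracks, tMaxSpreadS, windowS = 60,
                               minLifetimeS = 4) {
  sel <- tracks$birth_s >= tMaxSpreadS &
    tracks$birth_s <= tMaxSpreadS + windowS &
    tracks$lifetime_s >= minLifetimeS - 1e-9
  if (!any(sel))
    return(list(mean_lifetime_s = NA_real_, mean_speed_um_s = NA_real_,
                n_tracks = 0L))
  list(mean_lifetime_s = mean(tracks$lifetime_s[sel]),
       mean_speed_um_s = mean(tracks$speed_um_s[sel]),
       n_tracks = sum(sel))
}

#' Histogram of focus emergence relative to contraction onset
#'
#' Bins focus birth times relative to each cell's contraction onset and
#' normalizes to percent of all events. Tracks from cells without an onset
#' contribute nothing and are counted in \code{n_excluded}.
#'
#' @param birthS focus birth times (s), one per track.
#' @param onsetS matching contraction onsets (s), \code{NA} for cells that
#'   never contracted.
#' @param binS bin width (s).
#' @return data.frame with \code{bin_left_s}, \code{bin_right_s},
#'   \code{count}, \code{percent}; attribute \code{"n_excluded"}.
#' @export
emergenceHistogram <- function(birthS, onsetS, binS = 10) {
  stopifnot(length(birthS) == length(onsetS))
  ok <- !is.na(onsetS)
  rel <- birthS[ok] - onsetS[ok]
  if (!length(rel)) {
    out <- data.frame(bin_left_s = numeric(0), bin_right_s = numeric(0),
                      count = integer(0), percent = numeric(0))
    attr(out, "n_excluded") <- sum(!ok)
    return(out)
  }
  lo <- floor(min(rel) / binS) * binS
  hi <- ceiling(max(rel) / binS) * binS
  if (hi == lo) hi <- lo + binS
  edges <- seq(lo, hi, by = binS)
  cnt <- as.integer(table(cut(rel, edges, right = FALSE, include.lowest = TRUE)))
  out <- data.frame(bin_left_s = edges[-length(edges)],
                    bin_right_s = edges[-1],
                    count = cnt, percent = 100 * cnt / sum(cnt))
  attr(out, "n_excluded") <- sum(!ok)
  out
}
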