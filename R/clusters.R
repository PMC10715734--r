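#' Background intensity of the bilayer near the contact zone
#'
#' The antigen-channel background is the median FI of the bilayer in a band
#' outside but near the contact zone whose pixel count matches the contact
#' zone itself: the mask is dilated ring by ring (8-connected) and outside
#' rings are accumulated until the band is at least as large as the mask.
#' The median (not the mean) keeps debris from inflating the estimate.
#'
#' @param frame antigen (fab) intensity matrix.
#' @param contactMask logical contact-zone mask.
#' @return background FI (numeric scalar); attribute \code{"n_pixels"} gives
#'   the band size.
#' @export
estimateBackground <- function(frame, contactMask) {
  stopifnot(any(contactMask), length(frame) > sum(contactMask))
  need <- sum(contactMask)
  kern <- EBImage::makeBrush(3L, "box")
  cur <- contactMask
  band <- matrix(FALSE, nrow(frame), ncol(frame))
  repeat {
    dil <- EBImage::dilate(cur * 1, kern) > 0
    ring <- dil & !cur & !contactMask
    band <- band | ring
    if (sum(band) >= need) break
    if (all(dil == cur))
      stop("image too small to accumulate a background band matching the mask")
    cur <- dil
  }
  out <- stats::median(frame[band])
  attr(out, "n_pixels") <- sum(band)
  out
}

#' Graded-threshold antigen-cluster detection
#'
#' Detects clusters of widely varying brightness as distinct objects with 16
#' graded intensity thresholds, 1.1 to 4.1 fold of the background in steps
#' of 0.2. Folds are visited from highest to lowest; at each fold the
#' 8-connected components of above-threshold pixels inside the contact mask
#' are labelled, and a component is accepted iff its diameter (lesser
#' bounding-box extent) is >= \code{minDiamUm} and it shares no pixel with a
#' previously accepted (higher-fold) detection. Each cluster is therefore
#' retained at the highest threshold that still detects it.
#'
#' @param frame antigen (fab) intensity matrix.
#' @param contactMask logical contact-zone mask.
#' @param background background FI from \code{\link{estimateBackground}}.
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param folds threshold grid (fold of background).
#' @param minDiamUm diameter criterion (um).
#' @return data.frame with one row per detection: region summaries plus
#'   \code{threshold_fold} and \code{background_fi}; pixel sets in the list
#'   column \code{pixels}.
#' @export
gradedThresholdDetect <- function(frame, contactMask, background, calibration,
                                  folds = round(seq(1.1, 4.1, by = 0.2), 1),
                                  minDiamUm = 0.25) {
  stopifnot(background > 0)
  claimed <- matrix(FALSE, nrow(frame), ncol(frame))
  out <- list()
  for (fold in sort(folds, decreasing = TRUE)) {
    cand <- contactMask & frame >= fold * background
    if (!any(cand)) next
    tab <- regionTable(label8(cand), frame, calibration)
    if (!nrow(tab)) next
    for (i in seq_len(nrow(tab))) {
      px <- tab$pixels[[i]]
      if (tab$diameter_um[i] < minDiamUm || any(claimed[px])) next
      claimed[px] <- TRUE
      row <- tab[i, , drop = FALSE]
      row$threshold_fold <- fold
      row$background_fi <- background
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) {
    res <- regionTable(matrix(0L, 1, 1), matrix(0), calibration)
    res$threshold_fold <- numeric(0)
    res$background_fi <- numeric(0)
    res$pixels <- list()
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Track antigen clusters across frames
#'
#' Greedy mutual-nearest-neighbour linking of detection centroids between
#' consecutive frames, with link distance <= \code{maxLinkUm} and no gap
#' closing. When two or more tracks converge on one detection the incoming
#' tracks end with \code{end_reason = "merged"} and a fresh track starts at
#' the merged detection (the merged object is a new identity). Tracks whose
#' nearest detection is taken end \code{"lost"}; tracks alive in the last
#' frame end \code{"movie_end"}.
#'
#' @param detectionsPerFrame list (one element per frame) of
#'   \code{\link{gradedThresholdDetect}} data.frames.
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param maxLinkUm maximum per-frame centroid displacement (um).
#' @return data.frame with one row per track: \code{track}, \code{birth_s},
#'   \code{death_s}, \code{duration_s}, \code{end_reason}, \code{n_frames};
#'   list columns \code{frames}, \code{peak_fi}, \code{mfi},
#'   \code{diameter_um}, \code{x_um}, \code{y_um}, \code{threshold_fold}.
#' @export
trackClusters <- function(detectionsPerFrame, calibration, maxLinkUm = 0.5) {
  T <- length(detectionsPerFrame)
  stopifnot(T >= 2L)
  dt <- frameIntervalS(calibration)
  tracks <- list()
  active <- list()

  closeTrack <- function(a, reason) {
    a$end_reason <- reason
    tracks[[length(tracks) + 1L]] <<- a
  }
  newTrack <- function(det, j, t) {
    list(frames = t, det_index = j,
         x = det$centroid_x_um[j], y = det$centroid_y_um[j],
         peak_fi = det$peak_fi[j], mfi = det$mfi[j],
         diameter_um = det$diameter_um[j],
         threshold_fold = det$threshold_fold[j])
  }
  extendTrack <- function(a, det, j, t) {
    a$frames <- c(a$frames, t)
    a$det_index <- c(a$det_index, j)
    a$x <- c(a$x, det$centroid_x_um[j]); a$y <- c(a$y, det$centroid_y_um[j])
    a$peak_fi <- c(a$peak_fi, det$peak_fi[j])
    a$mfi <- c(a$mfi, det$mfi[j])
    a$diameter_um <- c(a$diameter_um, det$diameter_um[j])
    a$threshold_fold <- c(a$threshold_fold, det$threshold_fold[j])
    a
  }

  det1 <- detectionsPerFrame[[1]]
  if (nrow(det1)) for (j in seq_len(nrow(det1)))
    active[[length(active) + 1L]] <- newTrack(det1, j, 1L)

  for (t in 2L:T) {
    det <- detectionsPerFrame[[t]]
    nA <- length(active); nD <- nrow(det)
    nearest <- rep(NA_integer_, nA)
    if (nA > 0L && nD > 0L) {
      ax <- vapply(active, function(a) a$x[length(a$x)], numeric(1))
      ay <- vapply(active, function(a) a$y[length(a$y)], numeric(1))
      dmat <- sqrt(outer(ax, det$centroid_x_um, "-")^2 +
                   outer(ay, det$centroid_y_um, "-")^2)
      for (i in seq_len(nA)) {
        j <- which.min(dmat[i, ])
        if (dmat[i, j] <= maxLinkUm) nearest[i] <- j
      }
    }
    nextActive <- list()
    usedDet <- logical(max(nD, 1L))
    if (nD > 0L) for (j in seq_len(nD)) {
      inc <- which(nearest == j)
      if (length(inc) >= 2L) {
        for (i in inc) closeTrack(active[[i]], "merged")
        nextActive[[length(nextActive) + 1L]] <- newTrack(det, j, t)
        usedDet[j] <- TRUE
      } else if (length(inc) == 1L) {
        i <- inc
        ## mutual check: is this track also the detection's nearest?
        dx <- det$centroid_x_um[j] - vapply(active, function(a) a$x[length(a$x)], numeric(1))
        dy <- det$centroid_y_um[j] - vapply(active, function(a) a$y[length(a$y)], numeric(1))
        if (which.min(dx^2 + dy^2) == i) {
          nextActive[[length(nextActive) + 1L]] <- extendTrack(active[[i]], det, j, t)
          usedDet[j] <- TRUE
        } else {
          closeTrack(active[[i]], "lost")
          nextActive[[length(nextActive) + 1L]] <- newTrack(det, j, t)
          usedDet[j] <- TRUE
        }
      }
    }
    if (nA > 0L) for (i in seq_len(nA)) {
      if (is.na(nearest[i])) closeTrack(active[[i]], "lost")
      else if (length(which(nearest == nearest[i])) >= 2L) next  # closed above
      ## singly-linked tracks were handled (extended or lost) above
    }
    if (nD > 0L) for (j in seq_len(nD)) if (!usedDet[j])
      nextActive[[length(nextActive) + 1L]] <- newTrack(det, j, t)
    active <- nextActive
  }
  for (a in active) closeTrack(a, "movie_end")

  if (!length(tracks))
    return(data.frame(track = integer(0), birth_s = numeric(0),
                      death_s = numeric(0), duration_s = numeric(0),
                      end_reason = character(0), n_frames = integer(0)))
  out <- do.call(rbind, lapply(seq_along(tracks), function(k) {
    a <- tracks[[k]]
    f0 <- a$frames[1]; f1 <- a$frames[length(a$frames)]
    data.frame(track = k, birth_s = (f0 - 1L) * dt,
               death_s = (f1 - 1L) * dt + dt,
               duration_s = (f1 - f0 + 1L) * dt,
               end_reason = a$end_reason,
               n_frames = length(a$frames))
  }))
  out$frames <- lapply(tracks, `[[`, "frames")
  out$det_index <- lapply(tracks, `[[`, "det_index")
  out$peak_fi <- lapply(tracks, `[[`, "peak_fi")
  out$mfi <- lapply(tracks, `[[`, "mfi")
  out$diameter_um <- lapply(tracks, `[[`, "diameter_um")
  out$x_um <- lapply(tracks, `[[`, "x")
  out$y_um <- lapply(tracks, `[[`, "y")
  out$threshold_fold <- lapply(tracks, `[[`, "threshold_fold")
  rownames(out) <- NULL
  out
}

#' Detections belonging to tracked clusters
#'
#' Subsets per-frame detection tables to the detections that are part of the
#' given (typically trackability-filtered) tracks, so downstream per-cluster
#' measurements inherit the >= 20 s trackability criterion that removes
#' transient noise components.
#'
#' @param detectionsPerFrame list of per-frame detection data.frames.
#' @param tracks data.frame from \code{\link{trackClusters}} (carrying the
#'   \code{det_index} list column).
#' @return list of per-frame detection data.frames restricted to tracked
#'   detections, with an added \code{track} column.
#' @export
trackedDetections <- function(detectionsPerFrame, tracks) {
  keep <- lapply(detectionsPerFrame, function(d) integer(0))
  trk <- lapply(detectionsPerFrame, function(d) integer(0))
  for (k in seq_len(nrow(tracks))) {
    fr <- tracks$frames[[k]]
    di <- tracks$det_index[[k]]
    for (m in seq_along(fr)) {
      keep[[fr[m]]] <- c(keep[[fr[m]]], di[m])
      trk[[fr[m]]] <- c(trk[[fr[m]]], tracks$track[k])
    }
  }
  lapply(seq_along(detectionsPerFrame), function(t) {
    d <- detectionsPerFrame[[t]][keep[[t]], , drop = FALSE]
    d$track <- trk[[t]]
    rownames(d) <- NULL
    d
  })
}

#' Keep tracks trackable for a minimum duration
#'
#' Objects that cannot be tracked for at least \code{minDurationS} (default
#' 20 s, boundary inclusive: a 10-frame track at 2 s/frame survives) are
#' eliminated.
#'
#' @param tracks data.frame from \code{\link{trackClusters}}.
#' @param minDurationS minimum inclusive track duration (s).
#' @return the surviving rows; attribute \code{"n_eliminated"} counts the
#'   removed tracks.
#' @export
filterTrackable <- function(tracks, minDurationS = 20) {
  keep <- tracks$duration_s >= minDurationS - 1e-9
  out <- tracks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_eliminated") <- sum(!keep)
  out
}

#' Rate of increase of a cluster's peak FI
#'
#' OLS slope of the track's per-frame peak FI versus time restricted to a
#' window; the standard metric for the growth of the cluster's molecular
#' density (peak FI does not depend on the area occupied by the cluster).
#'
#' @param track one row of the \code{\link{trackClusters}} result.
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param windowS numeric(2) absolute time window (s); defaults to the whole
#'   track.
#' @return list with \code{slope} (FI/s), \code{se}, \code{n}.
#' @export
peakFiRate <- function(track, calibration, windowS = NULL) {
  tt <- (track$frames[[1]] - 1) * frameIntervalS(calibration)
  pk <- track$peak_fi[[1]]
  if (!is.null(windowS)) {
    sel <- tt >= windowS[1] & tt <= windowS[2]
    tt <- tt[sel]; pk <- pk[sel]
  }
  if (length(tt) < 3L) stop("fewer than 3 detections in the window")
  fit <- olsSlope(tt, pk)
  list(slope = fit$slope, se = fit$se, n = fit$n)
}

#' Per-cell peak-FI rate summary by contraction phase
#'
#' Averages per-track peak-FI slopes over the tracks alive in each phase
#' window (a track contributes when it has >= 3 detections inside the
#' window). Phase windows typically come from
#' \code{\link{contractionWindow}}: during = (onset, decline end), after =
#' (decline end, movie end).
#'
#' @param tracks data.frame from \code{\link{trackClusters}} (filtered).
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param phaseWindows named list of numeric(2) windows (s).
#' @return data.frame with one row per phase: \code{phase},
#'   \code{mean_slope}, \code{n_tracks} (\code{NA} slope when no track
#'   qualifies).
#' @export
perCellRateSummary <- function(tracks, calibration, phaseWindows) {
  stopifnot(length(phaseWindows) >= 1L, !is.null(names(phaseWindows)))
  do.call(rbind, lapply(names(phaseWindows), function(ph) {
    win <- phaseWindows[[ph]]
    slopes <- numeric(0)
    for (k in seq_len(nrow(tracks))) {
      tr <- tracks[k, , drop = FALSE]
      tt <- (tr$frames[[1]] - 1) * frameIntervalS(calibration)
      if (sum(tt >= win[1] & tt <= win[2]) >= 3L)
        slopes <- c(slopes, peakFiRate(tr, calibration, win)$slope)
    }
    data.frame(phase = ph,
               mean_slope = if (length(slopes)) mean(slopes) else NA_real_,
               n_tracks = length(slopes))
  }))
}
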