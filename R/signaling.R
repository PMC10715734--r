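#' Per-cluster signaling/antigen intensity ratios
#'
#' For every antigen-cluster detection, the signaling-channel MFI is
#' measured over the detection's exact pixel set in the same frame and the
#' ratio signal MFI / fab MFI is recorded: the standard per-cluster estimate
#' of the relative phosphorylation (or recruitment) level, plotted against
#' the cluster's fab peak FI (the molecular-density proxy).
#'
#' @param detections \code{\link{gradedThresholdDetect}} result for one
#'   frame, or a list of such data.frames (one per frame).
#' @param signalStack the signaling \code{\linkS4class{ChannelStack}}.
#' @param frame frame index when \code{detections} is a single data.frame.
#' @param timeLabel optional stimulation-time class attached to the records.
#' @return data.frame of ratio records: \code{source}, \code{frame_index},
#'   \code{fab_peak_fi}, \code{fab_mfi}, \code{signal_mfi}, \code{ratio},
#'   \code{time_label}.
#' @export
clusterRatioRecords <- function(detections, signalStack, frame = NULL,
                                timeLabel = NA_character_) {
  if (is.data.frame(detections)) {
    stopifnot(!is.null(frame))
    detections <- stats::setNames(list(detections), frame)
    frames <- frame
  } else {
    frames <- seq_along(detections)
  }
  rows <- list()
  for (k in seq_along(detections)) {
    det <- detections[[k]]
    if (!nrow(det)) next
    fr <- getFrame(signalStack, frames[k])
    sMfi <- vapply(det$pixels, function(px) mean(fr[px]), numeric(1))
    stopifnot(all(det$mfi > 0))
    rows[[length(rows) + 1L]] <- data.frame(
      source = "fab_cluster", frame_index = frames[k],
      fab_peak_fi = det$peak_fi, fab_mfi = det$mfi,
      signal_mfi = sMfi, ratio = sMfi / det$mfi,
      time_label = timeLabel)
  }
  if (!length(rows))
    return(data.frame(source = character(0), frame_index = integer(0),
                      fab_peak_fi = numeric(0), fab_mfi = numeric(0),
                      signal_mfi = numeric(0), ratio = numeric(0),
                      time_label = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect signaling puncta and measure their antigen context
#'
#' Signaling puncta (e.g. pSyk at 1.3-fold, pSHIP-1 at 1.5-fold of the
#' outside-background) are detected independently of antigen clusters:
#' 8-connected components >= \code{fold} x background inside the contact
#' mask with diameter >= \code{minDiamUm}. For each punctum the fab peak FI
#' and MFI are measured over the punctum's pixel set in the fab channel, and
#' ratio = signal MFI / fab MFI.
#'
#' @param signalFrame signaling-channel intensity matrix.
#' @param fabFrame antigen-channel intensity matrix (same frame).
#' @param contactMask logical contact-zone mask.
#' @param background signaling-channel background outside the contact zone
#'   (from \code{\link{estimateBackground}} on the signal frame).
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param fold channel-specific intensity criterion.
#' @param minDiamUm diameter criterion (um).
#' @param frame frame index recorded with the records.
#' @param timeLabel optional stimulation-time class.
#' @return list with \code{puncta} (region table) and \code{records}
#'   (ratio records with \code{source = "signal_punctum"}).
#' @export
detectPuncta <- function(signalFrame, fabFrame, contactMask, background,
                         calibration, fold, minDiamUm = 0.25, frame = 1L,
                         timeLabel = NA_character_) {
  stopifnot(background > 0)
  cand <- contactMask & signalFrame >= fold * background
  tab <- regionTable(label8(cand), signalFrame, calibration)
  if (nrow(tab)) {
    tab <- tab[tab$diameter_um >= minDiamUm, , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (!nrow(tab)) {
    rec <- data.frame(source = character(0), frame_index = integer(0),
                      fab_peak_fi = numeric(0), fab_mfi = numeric(0),
                      signal_mfi = numeric(0), ratio = numeric(0),
                      time_label = character(0))
    return(list(puncta = tab, records = rec))
  }
  fabPeak <- vapply(tab$pixels, function(px) max(fabFrame[px]), numeric(1))
  fabMfi <- vapply(tab$pixels, function(px) mean(fabFrame[px]), numeric(1))
  stopifnot(all(fabMfi > 0))
  rec <- data.frame(source = "signal_punctum", frame_index = frame,
                    fab_peak_fi = fabPeak, fab_mfi = fabMfi,
                    signal_mfi = tab$mfi, ratio = tab$mfi / fabMfi,
                    time_label = timeLabel)
  list(puncta = tab, records = rec)
}

#' Balanced random subsample across stimulation times
#'
#' Draws an equal number of records (the minimum group size) without
#' replacement from every \code{time_label} group, deterministically for a
#' given seed, so that no time point dominates the pooled
#' ratio-versus-density analysis.
#'
#' @param records ratio-record data.frame with a \code{time_label} column.
#' @param seed integer RNG seed.
#' @return the balanced subset (row order: groups in their original label
#'   order).
#' @export
equalRandomSample <- function(records, seed) {
  stopifnot(nrow(records) >= 1L)
  groups <- split(seq_len(nrow(records)), records$time_label)
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  n <- min(vapply(groups, length, integer(1)))
  idx <- withSeed(seed, unlist(lapply(groups, function(g)
    if (length(g) == n) g else sample(g, n)), use.names = FALSE))
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ratio-versus-density binned curve
#'
#' Bins ratio records by fab peak FI into half-open bins of
#' \code{binWidth} FI units (edges aligned to multiples of the width below
#' the observed minimum) and reports the mean ratio, the count and the
#' fraction of all records per bin — the two curves conventionally overlaid
#' on ratio-versus-peak-FI dot plots.
#'
#' @param records ratio-record data.frame.
#' @param binWidth bin width in FI units.
#' @return data.frame with \code{bin_left}, \code{bin_right},
#'   \code{bin_center}, \code{mean_ratio}, \code{n}, \code{fraction}.
#' @export
binCurve <- function(records, binWidth = 20) {
  stopifnot(nrow(records) >= 1L)
  pk <- records$fab_peak_fi
  lo <- floor(min(pk) / binWidth) * binWidth
  hi <- max(pk)
  edges <- seq(lo, hi + binWidth, by = binWidth)
  bin <- findInterval(pk, edges, rightmost.closed = FALSE)
  out <- do.call(rbind, lapply(seq_len(length(edges) - 1L), function(b) {
    sel <- bin == b
    data.frame(bin_left = edges[b], bin_right = edges[b + 1L],
               bin_center = (edges[b] + edges[b + 1L]) / 2,
               mean_ratio = if (any(sel)) mean(records$ratio[sel]) else NA_real_,
               n = sum(sel), fraction = sum(sel) / length(pk))
  }))
  rownames(out) <- NULL
  out
}

#' Compare low/medium/high density populations
#'
#' Splits records into three populations by fab peak FI — low (< c1),
#' medium ([c1, c2], endpoints included) and high (> c2; typically detected
#' only in contracted cells) — and compares their ratios pairwise with
#' two-sided Mann-Whitney tests, FDR-corrected.
#'
#' @param records ratio-record data.frame.
#' @param cutoffs numeric(2) strictly increasing (c1, c2); (190, 280) for
#'   pCD79a/Syk/pSyk-type analyses, (200, 300) for SHIP-1/pSHIP-1-type
#'   analyses.
#' @param method FDR method, \code{"BH"} or \code{"BY"}.
#' @return list with \code{sizes} (named integer(3)) and \code{tests}
#'   (data.frame: pair, n1, n2, statistic, p_value, p_adjusted; \code{NA}
#'   for pairs with an empty side).
#' @export
populationCompare <- function(records, cutoffs = c(190, 280), method = "BH") {
  stopifnot(length(cutoffs) == 2L)
  if (cutoffs[1] >= cutoffs[2]) stop("cutoffs must be strictly increasing")
  pk <- records$fab_peak_fi
  pop <- ifelse(pk < cutoffs[1], "low",
                ifelse(pk <= cutoffs[2], "medium", "high"))
  sizes <- c(low = sum(pop == "low"), medium = sum(pop == "medium"),
             high = sum(pop == "high"))
  pairs <- list(c("low", "medium"), c("medium", "high"), c("low", "high"))
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    x <- records$ratio[pop == pr[1]]
    y <- records$ratio[pop == pr[2]]
    if (length(x) == 0L || length(y) == 0L)
      return(data.frame(pair = paste(pr, collapse = " vs "),
                        n1 = length(x), n2 = length(y),
                        statistic = NA_real_, p_value = NA_real_))
    tr <- mannWhitneyU(x, y)
    data.frame(pair = paste(pr, collapse = " vs "),
               n1 = length(x), n2 = length(y),
               statistic = tr@statistic, p_value = tr@pValue)
  }))
  ok <- !is.na(tests$p_value)
  tests$p_adjusted <- NA_real_
  if (any(ok)) tests$p_adjusted[ok] <- fdrAdjust(tests$p_value[ok], method)
  rownames(tests) <- NULL
  list(sizes = sizes, tests = tests)
}
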