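#' Default analysis parameters
#'
#' Central parameter block consumed by \code{\link{runPipeline}}. Every
#' threshold defaults to the convention of this assay family: 5\% sustained
#' area drop for >= 10 s (contraction), 2-fold / 250 nm / 1 um (inner actin
#' foci), 8 kymograph lines, >= 4 s tracks with a 60 s emergence window and
#' > 8 s for lamellipodial origin, 16 graded thresholds 1.1-4.1 fold with
#' >= 20 s trackability (antigen clusters), 1.3/1.5-fold signaling puncta,
#' (190, 280) or (200, 300) density cutoffs, 20-FI-unit bins, and a 0-30 s
#' initial-rate window.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
analysisParams <- function(...) {
  def <- list(
    smoothWindowFrames = 5L,
    minDrop = 0.05, minDurationS = 10,
    fociFold = 2.0, fociMinDiamUm = 0.25, fociEdgeMarginUm = 1.0,
    ringMinFoci = 4L, ringMinCoverage = 0.5, ringSectorDeg = 30,
    fociFrameOffsetS = 60,
    kymoLines = 8L, kymoFold = 2.0, kymoMaxJumpUm = 0.4,
    kymoMinDurationS = 4, kymoEdgeExcludeUm = 1.3,
    originBandUm = 1.0, originMinDurationS = 8,
    lifetimeWindowS = 60, lifetimeMinS = 4,
    clusterFolds = round(seq(1.1, 4.1, by = 0.2), 1),
    clusterMinDiamUm = 0.25, clusterMaxLinkUm = 0.5, clusterMinDurationS = 20,
    punctaFold = 1.3,
    densityCutoffs = c(190, 280), binWidth = 20,
    initialRateWindowS = c(0, 30),
    fdrMethod = "BH")
  args <- list(...)
  unknown <- setdiff(names(args), names(def))
  if (length(unknown)) stop("unknown parameters: ",
                            paste(unknown, collapse = ", "))
  def[names(args)] <- args
  def
}

#' Run the full analysis pipeline on one cell movie
#'
#' Executes the enabled stages in order — contact-zone segmentation and
#' contraction classification, inner-foci detection and ring scoring,
#' kymograph track analytics, graded-threshold cluster detection/tracking
#' with peak-FI rates, and cluster-density-versus-signaling ratios — on the
#' channels present in \code{movie}. Stage results are returned in one list
#' and, when \code{outDir} is given, written as CSV tables plus a one-row
#' per-cell summary. The run is deterministic for a given movie and
#' parameter set.
#'
#' @param movie a \code{\linkS4class{CellMovie}} with an \code{irm} channel
#'   and any of \code{actin}, \code{fab}, \code{signal}.
#' @param params list from \code{\link{analysisParams}}.
#' @param outDir optional output directory for CSV tables.
#' @param stages character subset of
#'   \code{c("contact", "foci", "kymo", "clusters", "signaling")}.
#' @return named list with the per-stage results and \code{summary}, the
#'   per-cell summary row.
#' @export
runPipeline <- function(movie, params = analysisParams(), outDir = NULL,
                        stages = c("contact", "foci", "kymo", "clusters",
                                   "signaling")) {
  cal <- calibration(movie)
  dt <- frameIntervalS(cal)
  res <- list(cell_id = cellId(movie), params = params)
  have <- channelNames(movie)

  ## ---- contact zone (always needed) ----
  masks <- segmentMovie(getChannel(movie, "irm"))
  trace <- areaTrace(masks, cal, params$smoothWindowFrames)
  call <- classifyContraction(trace, minDrop = params$minDrop,
                              minDurationS = params$minDurationS)
  res$masks <- masks
  res$area_trace <- trace
  res$call <- call
  landed <- which(vapply(masks, any, logical(1)))
  landingFrame <- if (length(landed)) landed[1] else NA_integer_
  tMaxFrame <- round(tMaxSpreadS(call) / dt) + 1L

  summary <- data.frame(
    cell_id = cellId(movie),
    contracting = isContracting(call),
    t_max_spread_s = tMaxSpreadS(call),
    onset_s = onsetS(call),
    max_area_um2 = maxAreaUm2(call))

  ## ---- inner actin foci ----
  if ("foci" %in% stages && "actin" %in% have) {
    fociFrame <- min(tMaxFrame + round(params$fociFrameOffsetS / dt),
                     nFrames(movie))
    mask <- masks[[fociFrame]]
    if (any(mask)) {
      foci <- detectInnerFoci(getFrame(getChannel(movie, "actin"), fociFrame),
                              mask, cal, fold = params$fociFold,
                              minDiamUm = params$fociMinDiamUm,
                              edgeMarginUm = params$fociEdgeMarginUm)
      ring <- ringCall(foci, mask, cal, minFoci = params$ringMinFoci,
                       minCoverage = params$ringMinCoverage,
                       sectorDeg = params$ringSectorDeg)
      res$foci <- foci
      res$ring <- ring
      summary$foci_frame <- fociFrame
      summary$n_foci <- nrow(foci)
      summary$is_ring <- ring$is_ring
    }
  }

  ## ---- kymograph analytics ----
  if ("kymo" %in% stages && "actin" %in% have) {
    kymos <- makeKymographs(getChannel(movie, "actin"), masks,
                            nLines = params$kymoLines, tRefFrame = tMaxFrame)
    trackSets <- lapply(kymos, function(k) {
      edge <- kymoEdgeRadius(masks, k)
      tr <- extractTracks(k, fold = params$kymoFold,
                          maxJumpUm = params$kymoMaxJumpUm,
                          minDurationS = params$kymoMinDurationS,
                          edgeRadiusPerFrame = edge,
                          edgeExcludeUm = params$kymoEdgeExcludeUm)
      tr$lamellipodial_origin <- if (nrow(tr))
        vapply(seq_len(nrow(tr)), function(i)
          classifyOrigin(tr[i, , drop = FALSE], edge, dt,
                         lamBandUm = params$originBandUm,
                         minDurationS = params$originMinDurationS,
                         rimOffsetUm = params$kymoEdgeExcludeUm), logical(1))
      else logical(0)
      tr
    })
    allTracks <- do.call(rbind, trackSets)
    lam <- fractionLamellipodiaDerived(trackSets)
    ls <- lifetimeSpeedStats(allTracks, tMaxSpreadS(call),
                             windowS = params$lifetimeWindowS,
                             minLifetimeS = params$lifetimeMinS)
    res$kymographs <- kymos
    res$kymo_tracks <- allTracks
    res$lamellipodial <- lam
    res$lifetime_speed <- ls
    summary$lamellipodial_pct <- lam$percent
    summary$mean_lifetime_s <- ls$mean_lifetime_s
    summary$mean_speed_um_s <- ls$mean_speed_um_s
  }

  ## ---- antigen clusters ----
  if (any(c("clusters", "signaling") %in% stages) && "fab" %in% have) {
    fabStack <- getChannel(movie, "fab")
    detections <- vector("list", nFrames(movie))
    for (t in seq_len(nFrames(movie))) {
      m <- masks[[t]]
      if (!any(m)) {
        detections[[t]] <- gradedThresholdDetect(
          getFrame(fabStack, t), m & FALSE, 1, cal)  # empty frame table
        next
      }
      bg <- estimateBackground(getFrame(fabStack, t), m)
      detections[[t]] <- gradedThresholdDetect(
        getFrame(fabStack, t), m, bg, cal,
        folds = params$clusterFolds, minDiamUm = params$clusterMinDiamUm)
    }
    res$detections <- detections
    if ("clusters" %in% stages) {
      tracks <- trackClusters(detections, cal,
                              maxLinkUm = params$clusterMaxLinkUm)
      tracks <- filterTrackable(tracks, params$clusterMinDurationS)
      res$cluster_tracks <- tracks
      summary$n_cluster_tracks <- nrow(tracks)
      if (isContracting(call) && nrow(tracks)) {
        win <- contractionWindow(trace, call)
        phases <- list(
          before = c(frameToS(cal, landingFrame), win[[1]]),
          during = c(win[[1]], win[[2]]),
          after = c(win[[2]], frameToS(cal, nFrames(movie))))
        rates <- perCellRateSummary(tracks, cal, phases)
        res$rate_summary <- rates
        summary$rate_before <- rates$mean_slope[rates$phase == "before"]
        summary$rate_during <- rates$mean_slope[rates$phase == "during"]
        summary$rate_after <- rates$mean_slope[rates$phase == "after"]
      }
    }
  }

  ## ---- signaling ratios ----
  if ("signaling" %in% stages && all(c("fab", "signal") %in% have)) {
    dets <- if (!is.null(res$cluster_tracks))
      trackedDetections(res$detections, res$cluster_tracks)
    else res$detections
    records <- clusterRatioRecords(dets, getChannel(movie, "signal"))
    res$ratio_records <- records
    if (nrow(records)) {
      res$bin_curve <- binCurve(records, binWidth = params$binWidth)
      res$populations <- populationCompare(records,
                                           cutoffs = params$densityCutoffs,
                                           method = params$fdrMethod)
      summary$n_ratio_records <- nrow(records)
    }
  }

  res$summary <- summary
  if (!is.null(outDir)) writePipelineOutputs(res, trace, outDir)
  res
}

writePipelineOutputs <- function(res, trace, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeRecords(data.frame(time_s = timesS(trace),
                          area_um2 = areasUm2(trace),
                          smoothed_area_um2 = smoothedAreasUm2(trace)),
               file.path(outDir, "area_trace.csv"))
  writeRecords(res$summary, file.path(outDir, "summary.csv"))
  if (!is.null(res$foci))
    writeRecords(res$foci, file.path(outDir, "foci.csv"))
  if (!is.null(res$kymo_tracks))
    writeRecords(res$kymo_tracks, file.path(outDir, "kymo_tracks.csv"))
  if (!is.null(res$cluster_tracks))
    writeRecords(res$cluster_tracks, file.path(outDir, "cluster_tracks.csv"))
  if (!is.null(res$ratio_records))
    writeRecords(res$ratio_records, file.path(outDir, "ratio_records.csv"))
  if (!is.null(res$bin_curve))
    writeRecords(res$bin_curve, file.path(outDir, "bin_curve.csv"))
  if (!is.null(res$populations))
    writeRecords(res$populations$tests, file.path(outDir, "population_tests.csv"))
  invisible(outDir)
}
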