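#' Reference intensity of the foci-free interior
#'
#' The fold-intensity criterion for inner F-actin foci is anchored to the
#' mean intensity of a "no foci" area. That reference is operationalized
#' robustly: over the mask interior (pixels at least \code{edgeMarginUm}
#' inside the contact-zone boundary, which excludes the bright lamellipodial
#' rim), bright candidate-focus pixels (above 1.5 x the interior median) are
#' discarded and the median of the remainder is returned.
#'
#' @param frame actin intensity matrix.
#' @param contactMask logical contact-zone mask.
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param edgeMarginUm interior margin (um).
#' @return list with \code{reference} and \code{n_pixels} used.
#' @export
noFociReference <- function(frame, contactMask, calibration,
                            edgeMarginUm = 1.0) {
  d <- edgeDistanceUm(contactMask, calibration)
  interior <- contactMask & d >= edgeMarginUm
  if (!any(interior)) stop("mask interior is empty: cell too small")
  v <- frame[interior]
  med <- stats::median(v)
  keep <- v <= 1.5 * med
  list(reference = stats::median(v[keep]), n_pixels = sum(keep))
}

#' Detect inner F-actin foci
#'
#' Implements the three-criteria definition of an inner focus: an
#' 8-connected component of pixels at least \code{fold} x the foci-free
#' reference intensity, with diameter (lesser bounding-box extent) >=
#' \code{minDiamUm}, whose centroid lies >= \code{edgeMarginUm} interior to
#' the contact-zone edge (Euclidean distance transform of the mask, sampled
#' at the centroid pixel). The lamellipodial rim fails the edge criterion by
#' construction, so only interior foci are returned.
#'
#' @param frame actin intensity matrix.
#' @param contactMask logical contact-zone mask.
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param fold peak-intensity criterion (fold of the reference).
#' @param minDiamUm diameter criterion (um).
#' @param edgeMarginUm edge-distance criterion (um).
#' @param preSmoothSigmaPx optional Gaussian smoothing (sigma in px) applied
#'   to the frame before detection; 0 disables it. Smoothing keeps pixel
#'   noise from fragmenting the above-threshold core of a focus at low SNR;
#'   all criteria and intensity summaries then refer to the smoothed frame.
#' @return data.frame with one row per focus: region summaries
#'   (\code{peak_fi}, \code{mfi}, \code{diameter_um}, centroid columns),
#'   \code{peak_fold} (peak FI / reference) and \code{edge_distance_um};
#'   the pixel sets as a list column \code{pixels}. Attribute
#'   \code{"reference"} carries the reference intensity used.
#' @export
detectInnerFoci <- function(frame, contactMask, calibration, fold = 2.0,
                            minDiamUm = 0.25, edgeMarginUm = 1.0,
                            preSmoothSigmaPx = 0) {
  stopifnot(any(contactMask))
  if (preSmoothSigmaPx > 0)
    frame <- EBImage::gblur(frame, sigma = preSmoothSigmaPx)
  ref <- noFociReference(frame, contactMask, calibration,
                         edgeMarginUm = edgeMarginUm)$reference
  cand <- contactMask & frame >= fold * ref
  lab <- label8(cand)
  tab <- regionTable(lab, frame, calibration)
  d <- edgeDistanceUm(contactMask, calibration)
  if (nrow(tab)) {
    cIdx <- cbind(pmin(pmax(round(tab$centroid_row), 1L), nrow(frame)),
                  pmin(pmax(round(tab$centroid_col), 1L), ncol(frame)))
    tab$edge_distance_um <- d[cIdx]
    tab$peak_fold <- tab$peak_fi / ref
    ## the centroid pixel must belong to the component: a compact focus
    ## always satisfies this, while rim arcs/annuli (whose centroid falls in
    ## the actin-poor centre, far from the edge) never do
    compact <- lab[cIdx] == tab$label
    keep <- compact & tab$diameter_um >= minDiamUm &
      tab$edge_distance_um >= edgeMarginUm
    tab <- tab[keep, , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab$edge_distance_um <- numeric(0)
    tab$peak_fold <- numeric(0)
  }
  attr(tab, "reference") <- ref
  tab
}

#' Foci count per cell at a stated frame
#'
#' @param movie a \code{\linkS4class{CellMovie}} with \code{actin} and
#'   \code{irm} channels.
#' @param frame frame index at which foci are counted.
#' @param masks optional precomputed per-frame masks.
#' @param ... detector parameters for \code{\link{detectInnerFoci}}.
#' @return integer foci count.
#' @export
countFoci <- function(movie, frame, masks = NULL, ...) {
  mask <- if (is.null(masks))
    segmentContactZone(getFrame(getChannel(movie, "irm"), frame),
                       calibration(movie))
  else masks[[frame]]
  if (!any(mask)) return(0L)
  nrow(detectInnerFoci(getFrame(getChannel(movie, "actin"), frame), mask,
                       calibration(movie), ...))
}

#' Ring-likeness of the foci arrangement
#'
#' Automated surrogate for the visual ring-like classification: the angular
#' positions of foci centroids about the contact-zone centroid are binned
#' into \code{360/sectorDeg} sectors; the arrangement is called a ring when
#' at least \code{minFoci} foci cover at least \code{minCoverage} of the
#' sectors. All three thresholds are surrogates for visual inspection and
#' should be reported alongside results.
#'
#' @param foci data.frame from \code{\link{detectInnerFoci}}.
#' @param contactMask logical contact-zone mask.
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param minFoci minimum foci count.
#' @param minCoverage minimum occupied-sector fraction.
#' @param sectorDeg sector width (degrees).
#' @return list with \code{n_foci}, \code{angular_coverage_frac} and
#'   \code{is_ring}.
#' @export
ringCall <- function(foci, contactMask, calibration, minFoci = 4L,
                     minCoverage = 0.5, sectorDeg = 30) {
  stopifnot(any(contactMask))
  nSect <- round(360 / sectorDeg)
  n <- nrow(foci)
  if (n == 0L)
    return(list(n_foci = 0L, angular_coverage_frac = 0, is_ring = FALSE))
  idx <- which(contactMask)
  crow <- mean((idx - 1L) %% nrow(contactMask) + 1L)
  ccol <- mean((idx - 1L) %/% nrow(contactMask) + 1L)
  ang <- atan2(foci$centroid_row - crow, foci$centroid_col - ccol) * 180 / pi
  sect <- floor(((ang %% 360) / sectorDeg)) + 1L
  cov <- length(unique(sect)) / nSect
  list(n_foci = n, angular_coverage_frac = cov,
       is_ring = n >= minFoci && cov >= minCoverage)
}

#' Percentage of positive cells per image
#'
#' Summarizes per-cell boolean calls (e.g. "has a foci ring") at the image
#' level, the unit of replication used for population comparisons: percent
#' positive per image, plus the group mean and standard error across images.
#'
#' @param positive logical vector, one element per cell.
#' @param image grouping factor (image id per cell).
#' @return list with \code{per_image} (data.frame image, n, percent),
#'   \code{mean} and \code{sem} across images.
#' @export
percentPositivePerImage <- function(positive, image) {
  stopifnot(length(positive) == length(image), length(positive) >= 1L)
  sp <- split(positive, image)
  per <- data.frame(image = names(sp),
                    n = vapply(sp, length, integer(1)),
                    percent = vapply(sp, function(x) 100 * mean(x), numeric(1)),
                    row.names = NULL)
  ms <- meanSem(per$percent)
  list(per_image = per, mean = unname(ms["mean"]), sem = unname(ms["sem"]))
}
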