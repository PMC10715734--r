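#' Parameters of the synthetic movie generator
#'
#' \code{SimParams} collects every knob of the synthetic TIRF/IRM movie
#' generator: the raster grid and calibration, the spreading/contraction
#' geometry of the contact footprint, the lamellipodial rim, the inner-foci
#' birth process, the antigen-cluster intensity ramp, the density-to-signal
#' ratio profile, and the noise model. Defaults describe a typical
#' contracting splenic B cell on a Fab'-coated bilayer imaged at 2 s/frame;
#' see the methods vignette for the rationale behind each value.
#'
#' @slot grid integer(3): H, W (pixels) and T (frames).
#' @slot calibration a \code{\linkS4class{Calibration}}.
#' @slot rInitialUm,rMaxUm contact radius at landing and at maximal spreading (um).
#' @slot tMaxSpreadS time of maximal spreading (s).
#' @slot contractionFraction fractional area lost after maximal spreading
#'   (0 = non-contracting; must be < 1).
#' @slot contractionRampS duration of the linear area decline (s).
#' @slot rimWidthUm,rimAmp width (um) and intensity (fold of background) of
#'   the lamellipodial actin rim.
#' @slot focusBirthRatePerMin Poisson rate of inner-focus births after
#'   maximal spreading (per minute).
#' @slot focusSpeedUmS centripetal focus speed (um/s).
#' @slot focusLifetimeS mean focus lifetime (s; exponential).
#' @slot focusAmp focus peak as fold of background.
#' @slot psfSigmaUm Gaussian spot sigma (um) for foci and clusters.
#' @slot nClusters number of antigen clusters.
#' @slot clusterPeakStartFi,clusterPeakStartJitterFi initial true peak FI of a
#'   cluster and the half-width of its uniform jitter.
#' @slot clusterPeakRampFiS per-second increase of true cluster peak FI.
#' @slot clusterRampBoost multiplicative ramp boost during the contraction window.
#' @slot clusterMinSepUm minimum separation between cluster centres (um).
#' @slot ratioParams named numeric: \code{dRise}, \code{peak}, \code{base},
#'   \code{declineSlope}, \code{floorEnd} of the density-to-signal profile
#'   (see \code{\link{ratioProfile}}).
#' @slot backgroundFi baseline fluorescence intensity.
#' @slot irmBrightFi,irmDarkFi IRM levels outside/inside the contact footprint.
#' @slot noiseSigma additive Gaussian noise scale (FI units).
#' @slot seed integer RNG seed; identical parameters give bit-identical movies.
#' @slot fociOverride \code{NULL}, or a data.frame with columns
#'   \code{birth_s}, \code{angle_deg} and optionally \code{speed_um_s},
#'   \code{lifetime_s}, \code{birth_radius_um} to plant foci deterministically
#'   instead of drawing the Poisson process.
#' @slot clustersOverride \code{NULL}, or a data.frame with columns
#'   \code{angle_deg}, \code{frac} (radial position as a fraction of the
#'   current radius) and optionally \code{peak0}, \code{ramp_fi_s}.
#'
#' @aliases SimParams
#' @seealso \code{\link{renderMovie}}, \code{\link{simulateAreaTrace}}
#' @exportClass SimParams
setClass("SimParams",
  representation(
    grid = "integer", calibration = "Calibration",
    rInitialUm = "numeric", rMaxUm = "numeric", tMaxSpreadS = "numeric",
    contractionFraction = "numeric", contractionRampS = "numeric",
    rimWidthUm = "numeric", rimAmp = "numeric",
    focusBirthRatePerMin = "numeric", focusSpeedUmS = "numeric",
    focusLifetimeS = "numeric", focusAmp = "numeric", psfSigmaUm = "numeric",
    nClusters = "integer", clusterPeakStartFi = "numeric",
    clusterPeakStartJitterFi = "numeric", clusterPeakRampFiS = "numeric",
    clusterRampBoost = "numeric", clusterMinSepUm = "numeric",
    ratioParams = "numeric", backgroundFi = "numeric",
    irmBrightFi = "numeric", irmDarkFi = "numeric",
    noiseSigma = "numeric", seed = "integer",
    fociOverride = "ANY", clustersOverride = "ANY"))

setValidity("SimParams", function(object) {
  msg <- character()
  g <- object@grid
  if (length(g) != 3L || any(g < 1L))
    msg <- c(msg, "'grid' must be positive (H, W, T)")
  pos <- c(rMaxUm = object@rMaxUm, rimWidthUm = object@rimWidthUm,
           rimAmp = object@rimAmp, focusAmp = object@focusAmp,
           psfSigmaUm = object@psfSigmaUm, backgroundFi = object@backgroundFi)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "radii, widths, amplitudes, sigma and background must be > 0")
  nonneg <- c(object@rInitialUm, object@tMaxSpreadS, object@contractionRampS,
              object@focusBirthRatePerMin, object@focusSpeedUmS,
              object@focusLifetimeS, object@noiseSigma)
  if (any(!is.finite(nonneg)) || any(nonneg < 0))
    msg <- c(msg, "rates, times, speeds and noise must be >= 0")
  if (object@rMaxUm < object@rInitialUm)
    msg <- c(msg, "rMaxUm must be >= rInitialUm")
  if (object@contractionFraction < 0 || object@contractionFraction >= 1)
    msg <- c(msg, "contractionFraction must be in [0, 1)")
  halfUm <- min(g[1], g[2]) / 2 * object@calibration@pixelSizeNm / 1000
  if (halfUm < object@rMaxUm + 2)
    msg <- c(msg, sprintf(
      "grid too small: needs >= 2 um background margin around the r_max disk (half-extent %.2f um < %.2f um)",
      halfUm, object@rMaxUm + 2))
  need <- c("dRise", "peak", "base", "declineSlope", "floorEnd")
  if (!all(need %in% names(object@ratioParams)))
    msg <- c(msg, paste("ratioParams must name:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @param ... slot values overriding the defaults (see slots above).
#' @rdname SimParams-class
#' @export
simParams <- function(...) {
  args <- list(...)
  def <- list(
    grid = c(128L, 128L, 210L),
    calibration = Calibration(107.5, 2),
    rInitialUm = 1.5, rMaxUm = 4.0, tMaxSpreadS = 60,
    contractionFraction = 0.15, contractionRampS = 60,
    rimWidthUm = 1.0, rimAmp = 2.5,
    focusBirthRatePerMin = 20, focusSpeedUmS = 0.05,
    focusLifetimeS = 20, focusAmp = 3.0, psfSigmaUm = 0.15,
    nClusters = 12L, clusterPeakStartFi = 130,
    clusterPeakStartJitterFi = 15, clusterPeakRampFiS = 0.5,
    clusterRampBoost = 3, clusterMinSepUm = 1.2,
    ratioParams = c(dRise = 150, peak = 1.0, base = 0.2,
                    declineSlope = 0.004, floorEnd = 0.05),
    backgroundFi = 100, irmBrightFi = 200, irmDarkFi = 50,
    noiseSigma = 10, seed = 1L,
    fociOverride = NULL, clustersOverride = NULL)
  unknown <- setdiff(names(args), names(def))
  if (length(unknown)) stop("unknown SimParams fields: ",
                            paste(unknown, collapse = ", "))
  def[names(args)] <- args
  def$grid <- as.integer(def$grid)
  def$nClusters <- as.integer(def$nClusters)
  def$seed <- as.integer(def$seed)
  do.call(new, c(list("SimParams"), def))
}

setMethod("show", "SimParams", function(object) {
  g <- object@grid
  cat(sprintf(
    "SimParams: %d x %d px, %d frames; r %.2g -> %.2g um, t_max %.4g s, contraction %.0f%%; %d clusters; seed %d\n",
    g[1], g[2], g[3], object@rInitialUm, object@rMaxUm, object@tMaxSpreadS,
    100 * object@contractionFraction, object@nClusters, object@seed))
})

#' Ground truth of a synthetic movie
#'
#' Exact per-frame truth emitted by \code{\link{renderMovie}}: the contact
#' area trace, the contraction onset (\code{NA} when the footprint never
#' contracts), one row per planted focus track, one row per cluster per frame
#' (position, true peak FI, true signal/fab ratio) and the static per-cluster
#' draw.
#'
#' @slot areaTraceUm2 numeric per-frame contact area (um^2).
#' @slot contractionOnsetS onset time (s) or \code{NA}.
#' @slot focusTracks data.frame: id, birth_s, death_s, lifetime_s, angle_deg,
#'   birth_radius_um, speed_um_s, clipped.
#' @slot clusterTracks data.frame: cluster, frame, t_s, x_um, y_um, peak_fi, ratio.
#' @slot clusterMeta data.frame: cluster, angle_deg, frac, peak0, ramp_fi_s.
#' @slot params the generating \code{SimParams}.
#'
#' @aliases GroundTruth
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(areaTraceUm2 = "numeric", contractionOnsetS = "numeric",
                 focusTracks = "data.frame", clusterTracks = "data.frame",
                 clusterMeta = "data.frame", params = "SimParams"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d frames, onset %s, %d focus tracks, %d clusters\n",
    length(object@areaTraceUm2),
    if (is.na(object@contractionOnsetS)) "none"
    else sprintf("%.4g s", object@contractionOnsetS),
    nrow(object@focusTracks), nrow(object@clusterMeta)))
})

#' @rdname GroundTruth-class
#' @param x a \code{GroundTruth}.
#' @export
setMethod("onsetS", "GroundTruth", function(x) x@contractionOnsetS)

#' @rdname GroundTruth-class
#' @export
setMethod("areasUm2", "GroundTruth", function(x) x@areaTraceUm2)

#' @rdname GroundTruth-class
#' @export
focusTracks <- function(x) x@focusTracks

#' @rdname GroundTruth-class
#' @export
clusterTracksTruth <- function(x) x@clusterTracks
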