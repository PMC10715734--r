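#' Simulate a contact-area trace
#'
#' The contact footprint is modelled as a disk whose area rises logistically
#' from \eqn{\pi r_{initial}^2} to \eqn{A_{max} = \pi r_{max}^2}, reaching
#' 99.5\% of the rise at \code{tMaxSpreadS}. When
#' \code{contractionFraction} \eqn{c > 0}, the area then declines linearly to
#' \eqn{(1 - c) A_{max}} over \code{contractionRampS} seconds and stays
#' constant afterwards; a non-contracting cell (\eqn{c = 0}) keeps the
#' logistic plateau.
#'
#' @param p a \code{\linkS4class{SimParams}}.
#' @return numeric vector of per-frame contact areas (um^2).
#' @examples
#' p <- simParams(grid = c(96L, 96L, 60L), rMaxUm = 2.5, contractionFraction = 0.15)
#' a <- simulateAreaTrace(p)
#' tail(a, 1) / (pi * 2.5^2)  # 0.85
#' @export
simulateAreaTrace <- function(p) {
  validObject(p)
  dt <- frameIntervalS(p@calibration)
  tt <- (seq_len(p@grid[3]) - 1) * dt
  a0 <- pi * p@rInitialUm^2
  amax <- pi * p@rMaxUm^2
  if (amax - a0 < .Machine$double.eps || p@tMaxSpreadS <= 0) {
    areas <- rep(amax, length(tt))
  } else {
    k <- 2 * log(199) / p@tMaxSpreadS   # 99.5% of the rise at tMaxSpreadS
    areas <- a0 + (amax - a0) / (1 + exp(-k * (tt - p@tMaxSpreadS / 2)))
  }
  if (p@contractionFraction > 0) {
    post <- tt > p@tMaxSpreadS
    frac <- pmin(1, (tt[post] - p@tMaxSpreadS) / max(p@contractionRampS, dt))
    areas[post] <- amax - p@contractionFraction * amax * frac
  }
  areas
}

#' Density-to-signal ratio profile
#'
#' Relative signaling level (signal MFI / antigen MFI) as a function of the
#' antigen cluster density proxy (cluster peak FI). The profile rises
#' linearly from \code{base} at density 0 to \code{peak} at \code{dRise},
#' then declines linearly at \code{declineSlope} per FI unit, floored at
#' \code{floorEnd}: a biphasic dependence in which sparse clusters signal
#' more per antigen as they grow, while densely packed clusters signal
#' progressively less.
#'
#' @param density non-negative numeric vector of cluster peak FI values.
#' @param ratioParams named numeric with \code{dRise}, \code{peak},
#'   \code{base}, \code{declineSlope}, \code{floorEnd}.
#' @return numeric vector of relative signal levels.
#' @export
ratioProfile <- function(density, ratioParams) {
  if (any(density < 0)) stop("density must be >= 0")
  rp <- ratioParams
  ifelse(density < rp[["dRise"]],
         rp[["base"]] + (rp[["peak"]] - rp[["base"]]) * density / rp[["dRise"]],
         pmax(rp[["floorEnd"]],
              rp[["peak"]] - rp[["declineSlope"]] * (density - rp[["dRise"]])))
}

## Add a 2D Gaussian of absolute amplitude `amp` and sigma `sigmaPx` centred
## at fractional pixel (rowC, colC), truncated at 4 sigma.
addSpot <- function(frame, rowC, colC, amp, sigmaPx) {
  H <- nrow(frame); W <- ncol(frame)
  r0 <- max(1L, floor(rowC - 4 * sigmaPx)); r1 <- min(H, ceiling(rowC + 4 * sigmaPx))
  c0 <- max(1L, floor(colC - 4 * sigmaPx)); c1 <- min(W, ceiling(colC + 4 * sigmaPx))
  if (r0 > r1 || c0 > c1) return(frame)
  rows <- r0:r1; cols <- c0:c1
  g <- outer(exp(-(rows - rowC)^2 / (2 * sigmaPx^2)),
             exp(-(cols - colC)^2 / (2 * sigmaPx^2)))
  frame[rows, cols] <- frame[rows, cols] + amp * g
  frame
}

## Effective ramp time at clock time tS: real elapsed time plus the extra
## (boost - 1)-weighted overlap with the contraction window.
effectiveRampTime <- function(tS, onset, rampS, boost) {
  ov <- pmax(0, pmin(tS, onset + rampS) - onset)
  tS + (boost - 1) * ov
}

#' Render a synthetic multi-channel movie with ground truth
#'
#' Generates the four channels the analysis pipeline consumes, with exact
#' ground truth for every rendered object:
#' \itemize{
#'   \item \strong{irm}: bright field with a dark disk of the current contact
#'     radius (from \code{\link{simulateAreaTrace}}).
#'   \item \strong{actin}: uniform background, a lamellipodial rim band of
#'     \code{rimAmp}-fold intensity at the footprint edge, and diffraction-limited
#'     foci (2D Gaussians peaking at \code{focusAmp} x background) born on the
#'     rim circle at radius \eqn{R - rimWidth/2} at the stated Poisson rate
#'     after maximal spreading, moving centripetally at \code{focusSpeedUmS}
#'     and removed after exponential lifetimes.
#'   \item \strong{fab}: background plus one Gaussian per antigen cluster
#'     whose true peak FI ramps at \code{clusterPeakRampFiS} FI/s, boosted
#'     \code{clusterRampBoost}-fold during the contraction window; cluster
#'     centres sit at a fixed fraction of the current radius, so they move
#'     centripetally as the footprint contracts.
#'   \item \strong{signal}: the noise-free fab channel scaled, within a
#'     2.5-sigma disk around each cluster, by
#'     \code{\link{ratioProfile}}(true peak FI), and by the profile's base
#'     level elsewhere, so each cluster's true signal/fab MFI ratio equals the
#'     profile exactly.
#' }
#' I.i.d. Gaussian noise of scale \code{noiseSigma} is added to every pixel
#' of every channel (clamped at 0). Identical \code{SimParams} (including the
#' seed) give bit-identical output. Foci whose trajectory would cross the
#' footprint centre are truncated there and flagged \code{clipped} in the
#' ground truth.
#'
#' @param p a \code{\linkS4class{SimParams}}.
#' @return list with elements \code{movie} (a
#'   \code{\linkS4class{CellMovie}}) and \code{truth} (a
#'   \code{\linkS4class{GroundTruth}}).
#' @export
renderMovie <- function(p) {
  validObject(p)
  cal <- p@calibration
  pxUm <- pixelSizeNm(cal) / 1000
  dt <- frameIntervalS(cal)
  H <- p@grid[1]; W <- p@grid[2]; T <- p@grid[3]
  areas <- simulateAreaTrace(p)
  Rt <- sqrt(areas / pi)
  tEnd <- (T - 1) * dt
  onset <- if (p@contractionFraction > 0) p@tMaxSpreadS else NA_real_
  cRow <- (H + 1) / 2; cCol <- (W + 1) / 2
  xs <- ((seq_len(W)) - cCol) * pxUm
  ys <- ((seq_len(H)) - cRow) * pxUm
  rr <- sqrt(outer(ys^2, xs^2, "+"))
  sigPx <- p@psfSigmaUm / pxUm
  bg <- p@backgroundFi

  res <- withSeed(p@seed, {
    ## ---- antigen clusters ----
    if (!is.null(p@clustersOverride)) {
      cm <- as.data.frame(p@clustersOverride)
      if (is.null(cm$peak0)) cm$peak0 <- rep(p@clusterPeakStartFi, nrow(cm))
      if (is.null(cm$ramp_fi_s)) cm$ramp_fi_s <- rep(p@clusterPeakRampFiS, nrow(cm))
      clusterMeta <- data.frame(cluster = seq_len(nrow(cm)),
                                angle_deg = cm$angle_deg, frac = cm$frac,
                                peak0 = cm$peak0, ramp_fi_s = cm$ramp_fi_s)
    } else {
      nC <- p@nClusters
      ang <- numeric(nC); frac <- numeric(nC)
      for (i in seq_len(nC)) {
        ok <- FALSE
        for (try in seq_len(200L)) {
          a <- stats::runif(1, 0, 360); f <- stats::runif(1, 0.15, 0.7)
          x <- f * p@rMaxUm * cospi(a / 180); y <- f * p@rMaxUm * sinpi(a / 180)
          if (i == 1L) { ok <- TRUE }
          else {
            px0 <- frac[seq_len(i - 1L)] * p@rMaxUm * cospi(ang[seq_len(i - 1L)] / 180)
            py0 <- frac[seq_len(i - 1L)] * p@rMaxUm * sinpi(ang[seq_len(i - 1L)] / 180)
            ok <- min(sqrt((px0 - x)^2 + (py0 - y)^2)) >= p@clusterMinSepUm
          }
          if (ok) { ang[i] <- a; frac[i] <- f; break }
        }
        if (!ok) { ang[i] <- a; frac[i] <- f }  # dense packing: accept last draw
      }
      clusterMeta <- data.frame(
        cluster = seq_len(nC), angle_deg = ang, frac = frac,
        peak0 = p@clusterPeakStartFi +
          stats::runif(nC, -1, 1) * p@clusterPeakStartJitterFi,
        ramp_fi_s = rep(p@clusterPeakRampFiS, nC))
    }

    ## ---- inner actin foci ----
    if (!is.null(p@fociOverride)) {
      fo <- as.data.frame(p@fociOverride)
      nF <- nrow(fo)
      birth <- fo$birth_s
      angF <- fo$angle_deg
      speed <- if (is.null(fo$speed_um_s)) rep(p@focusSpeedUmS, nF) else fo$speed_um_s
      life <- if (is.null(fo$lifetime_s)) rep(p@focusLifetimeS, nF) else fo$lifetime_s
      bRad <- if (is.null(fo$birth_radius_um))
        stats::approx(c(-dt, (seq_len(T) - 1) * dt), c(Rt[1], Rt),
                      xout = birth, rule = 2)$y - p@rimWidthUm / 2
      else fo$birth_radius_um
    } else if (p@focusBirthRatePerMin > 0 && tEnd > p@tMaxSpreadS) {
      nF <- stats::rpois(1, p@focusBirthRatePerMin / 60 * (tEnd - p@tMaxSpreadS))
      birth <- sort(stats::runif(nF, p@tMaxSpreadS, tEnd))
      angF <- stats::runif(nF, 0, 360)
      life <- stats::rexp(nF, 1 / p@focusLifetimeS)
      speed <- rep(p@focusSpeedUmS, nF)
      bRad <- stats::approx((seq_len(T) - 1) * dt, Rt, xout = birth, rule = 2)$y -
        p@rimWidthUm / 2
    } else {
      nF <- 0L
      birth <- angF <- life <- speed <- bRad <- numeric(0)
    }
    death <- birth + life
    clipped <- bRad - speed * pmin(life, pmax(0, tEnd - birth)) < 0
    focusTracks <- data.frame(
      id = seq_len(nF), birth_s = birth, death_s = death,
      lifetime_s = death - birth, angle_deg = angF,
      birth_radius_um = bRad, speed_um_s = speed, clipped = clipped)

    ## ---- per-frame rendering ----
    chIrm <- array(0, c(H, W, T)); chAct <- chIrm; chFab <- chIrm; chSig <- chIrm
    ctRows <- vector("list", T)
    rp <- p@ratioParams
    for (t in seq_len(T)) {
      tS <- (t - 1) * dt
      R <- Rt[t]
      inside <- rr <= R
      irm <- matrix(p@irmBrightFi, H, W)
      irm[inside] <- p@irmDarkFi

      act <- matrix(bg, H, W)
      rim <- inside & rr >= max(0, R - p@rimWidthUm)
      act[rim] <- act[rim] + (p@rimAmp - 1) * bg
      if (nF > 0L) {
        alive <- which(birth <= tS & tS < death)
        for (i in alive) {
          rF <- bRad[i] - speed[i] * (tS - birth[i])
          if (rF < 0) next  # crossed the centre: clipped
          rowC <- cRow + rF * sinpi(angF[i] / 180) / pxUm
          colC <- cCol + rF * cospi(angF[i] / 180) / pxUm
          act <- addSpot(act, rowC, colC, (p@focusAmp - 1) * bg, sigPx)
        }
      }

      fab <- matrix(bg, H, W)
      nC <- nrow(clusterMeta)
      eff <- effectiveRampTime(tS, if (is.na(onset)) Inf else onset,
                               p@contractionRampS, p@clusterRampBoost)
      peakT <- clusterMeta$peak0 + clusterMeta$ramp_fi_s * eff
      ratioT <- ratioProfile(peakT, rp)
      rUm <- clusterMeta$frac * R
      xUm <- rUm * cospi(clusterMeta$angle_deg / 180)
      yUm <- rUm * sinpi(clusterMeta$angle_deg / 180)
      for (i in seq_len(nC))
        fab <- addSpot(fab, cRow + yUm[i] / pxUm, cCol + xUm[i] / pxUm,
                       peakT[i] - bg, sigPx)

      sig <- rp[["base"]] * fab
      for (i in seq_len(nC)) {
        dUm2 <- outer((ys - yUm[i])^2, (xs - xUm[i])^2, "+")
        disk <- dUm2 <= (2.5 * p@psfSigmaUm)^2
        sig[disk] <- ratioT[i] * fab[disk]
      }
      ctRows[[t]] <- data.frame(cluster = clusterMeta$cluster,
                                frame = rep(t, nC), t_s = rep(tS, nC),
                                x_um = xUm, y_um = yUm,
                                peak_fi = peakT, ratio = ratioT)

      if (p@noiseSigma > 0) {
        irm <- pmax(0, irm + stats::rnorm(H * W, 0, p@noiseSigma))
        act <- pmax(0, act + stats::rnorm(H * W, 0, p@noiseSigma))
        fab <- pmax(0, fab + stats::rnorm(H * W, 0, p@noiseSigma))
        sig <- pmax(0, sig + stats::rnorm(H * W, 0, p@noiseSigma))
      }
      chIrm[, , t] <- irm; chAct[, , t] <- act
      chFab[, , t] <- fab; chSig[, , t] <- sig
    }
    list(clusterMeta = clusterMeta, focusTracks = focusTracks,
         clusterTracks = do.call(rbind, ctRows),
         chIrm = chIrm, chAct = chAct, chFab = chFab, chSig = chSig)
  })

  movie <- CellMovie(list(
    irm = ChannelStack("irm", res$chIrm, cal),
    actin = ChannelStack("actin", res$chAct, cal),
    fab = ChannelStack("fab", res$chFab, cal),
    signal = ChannelStack("signal", res$chSig, cal)),
    cellId = sprintf("sim%d", p@seed))
  truth <- new("GroundTruth", areaTraceUm2 = areas, contractionOnsetS = onset,
               focusTracks = res$focusTracks, clusterTracks = res$clusterTracks,
               clusterMeta = res$clusterMeta, params = p)
  list(movie = movie, truth = truth)
}

#' Write a simulation to disk
#'
#' Renders a movie and writes one TIFF per channel, the ground-truth tables
#' as CSV and a parameter echo as YAML into \code{dir}.
#'
#' @param p a \code{\linkS4class{SimParams}}.
#' @param dir output directory.
#' @return the \code{renderMovie} result, invisibly.
#' @export
writeSimulation <- function(p, dir) {
  sim <- renderMovie(p)
  writeMovie(sim$movie, dir)
  writeRecords(sim$truth@focusTracks, file.path(dir, "truth_focus_tracks.csv"))
  writeRecords(sim$truth@clusterTracks, file.path(dir, "truth_cluster_tracks.csv"))
  writeRecords(data.frame(frame = seq_along(sim$truth@areaTraceUm2),
                          area_um2 = sim$truth@areaTraceUm2),
               file.path(dir, "truth_area.csv"))
  yaml::write_yaml(simParamsAsList(p), file.path(dir, "params.yaml"))
  invisible(sim)
}

simParamsAsList <- function(p) {
  list(grid = as.integer(p@grid),
       pixel_size_nm = pixelSizeNm(p@calibration),
       frame_interval_s = frameIntervalS(p@calibration),
       r_initial_um = p@rInitialUm, r_max_um = p@rMaxUm,
       t_max_spread_s = p@tMaxSpreadS,
       contraction_fraction = p@contractionFraction,
       contraction_ramp_s = p@contractionRampS,
       rim_width_um = p@rimWidthUm, rim_amp = p@rimAmp,
       focus_birth_rate_per_min = p@focusBirthRatePerMin,
       focus_speed_um_s = p@focusSpeedUmS,
       focus_lifetime_s = p@focusLifetimeS, focus_amp = p@focusAmp,
       psf_sigma_um = p@psfSigmaUm, n_clusters = p@nClusters,
       cluster_peak_start_fi = p@clusterPeakStartFi,
       cluster_peak_ramp_fi_s = p@clusterPeakRampFiS,
       cluster_ramp_boost = p@clusterRampBoost,
       ratio_params = as.list(p@ratioParams),
       background_fi = p@backgroundFi,
       irm_bright_fi = p@irmBrightFi, irm_dark_fi = p@irmDarkFi,
       noise_sigma = p@noiseSigma, seed = p@seed)
}
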