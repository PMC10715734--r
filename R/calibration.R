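#' Physical calibration of a raster time-lapse
#'
#' A \code{Calibration} couples the two acquisition constants through which
#' every physical quantity reported by this package (micrometres, square
#' micrometres, seconds, micrometres per second) is derived: the lateral
#' pixel size in nanometres and the frame interval in seconds.
#'
#' @slot pixelSizeNm numeric(1), length of one pixel side in nanometres.
#' @slot frameIntervalS numeric(1), time between consecutive frames in seconds.
#'
#' @examples
#' cal <- Calibration(pixelSizeNm = 100, frameIntervalS = 2)
#' pxToUm(cal, 10)   # 1 um
#' umToPx(cal, 1)    # 10 px
#'
#' @aliases Calibration
#' @exportClass Calibration
setClass("Calibration",
  representation(pixelSizeNm = "numeric", frameIntervalS = "numeric"))

setValidity("Calibration", function(object) {
  msg <- character()
  if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
      object@pixelSizeNm <= 0)
    msg <- c(msg, "'pixelSizeNm' must be a single strictly positive number")
  if (length(object@frameIntervalS) != 1L || !is.finite(object@frameIntervalS) ||
      object@frameIntervalS <= 0)
    msg <- c(msg, "'frameIntervalS' must be a single strictly positive number")
  if (length(msg)) msg else TRUE
})

#' @param pixelSizeNm numeric(1), pixel size in nm.
#' @param frameIntervalS numeric(1), frame interval in s.
#' @rdname Calibration-class
#' @export
Calibration <- function(pixelSizeNm, frameIntervalS) {
  new("Calibration", pixelSizeNm = as.numeric(pixelSizeNm),
      frameIntervalS = as.numeric(frameIntervalS))
}

#' @rdname Calibration-class
#' @param x a \code{Calibration}.
#' @export
setMethod("pixelSizeNm", "Calibration", function(x) x@pixelSizeNm)

#' @rdname Calibration-class
#' @export
setMethod("frameIntervalS", "Calibration", function(x) x@frameIntervalS)

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %.4g nm/px, %.4g s/frame\n",
              object@pixelSizeNm, object@frameIntervalS))
})

#' Unit conversions
#'
#' Convert pixel counts to micrometres and back, and frame indices to seconds.
#' \code{frameToS} maps frame 1 to 0 s (time is measured from the first frame).
#'
#' @param cal a \code{Calibration}.
#' @param px,um,frame numeric vectors.
#' @return numeric vector in the target unit.
#' @export
pxToUm <- function(cal, px) px * cal@pixelSizeNm / 1000

#' @rdname pxToUm
#' @export
umToPx <- function(cal, um) um * 1000 / cal@pixelSizeNm

#' @rdname pxToUm
#' @export
frameToS <- function(cal, frame) (frame - 1) * cal@frameIntervalS

#' @rdname pxToUm
#' @export
pxAreaToUm2 <- function(cal, px) px * (cal@pixelSizeNm / 1000)^2
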