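#' Single-channel intensity time-lapse
#'
#' A \code{ChannelStack} holds one fluorescence or reflection channel of a
#' per-cell movie as an H x W x T array of non-negative intensities (rows,
#' columns, frames) together with its \code{\linkS4class{Calibration}}.
#' Channel labels follow the acquisition design: \code{"irm"} (interference
#' reflection, used for contact-zone segmentation), \code{"actin"} (F-actin
#' reporter), \code{"fab"} (fluorescent Fab' antigen) and \code{"signal"}
#' (immunostained signaling molecule).
#'
#' @slot label character(1) channel name.
#' @slot frames numeric H x W x T array, finite and >= 0.
#' @slot calibration a \code{Calibration}.
#'
#' @aliases ChannelStack
#' @exportClass ChannelStack
setClass("ChannelStack",
  representation(label = "character", frames = "array",
                 calibration = "Calibration"))

setValidity("ChannelStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L || d[3] < 1L)
    msg <- c(msg, "'frames' must be an H x W x T array with T >= 1")
  if (!all(is.finite(object@frames)))
    msg <- c(msg, "intensities must be finite")
  else if (min(object@frames) < 0)
    msg <- c(msg, "intensities must be >= 0")
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "'label' must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

#' @param label character(1) channel name.
#' @param frames H x W x T array (a matrix is promoted to a single frame).
#' @param calibration a \code{Calibration}.
#' @rdname ChannelStack-class
#' @export
ChannelStack <- function(label, frames, calibration) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  new("ChannelStack", label = label, frames = frames, calibration = calibration)
}

#' @rdname ChannelStack-class
#' @param x a \code{ChannelStack}.
#' @export
setMethod("nFrames", "ChannelStack", function(x) dim(x@frames)[3])

#' @rdname ChannelStack-class
#' @export
setMethod("frameDim", "ChannelStack", function(x) dim(x@frames)[1:2])

#' @rdname ChannelStack-class
#' @export
setMethod("channelLabel", "ChannelStack", function(x) x@label)

#' @rdname ChannelStack-class
#' @export
setMethod("calibration", "ChannelStack", function(x) x@calibration)

#' @rdname ChannelStack-class
#' @param i frame index.
#' @export
setMethod("getFrame", "ChannelStack", function(x, i) x@frames[, , i])

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ChannelStack '%s': %d x %d px, %d frames (%.4g nm/px, %.4g s/frame)\n",
              object@label, d[1], d[2], d[3],
              object@calibration@pixelSizeNm, object@calibration@frameIntervalS))
})

#' Aligned multi-channel movie of one cell
#'
#' A \code{CellMovie} bundles the per-channel stacks of one cell; all member
#' stacks must agree in height, width, frame count and calibration.
#'
#' @slot channels named list of \code{ChannelStack}s.
#' @slot cellId character(1) identifier.
#'
#' @aliases CellMovie
#' @exportClass CellMovie
setClass("CellMovie",
  representation(channels = "list", cellId = "character"))

setValidity("CellMovie", function(object) {
  msg <- character()
  ch <- object@channels
  if (length(ch) < 1L)
    msg <- c(msg, "at least one channel is required")
  else {
    if (!all(vapply(ch, is, logical(1), "ChannelStack")))
      msg <- c(msg, "all channels must be ChannelStack objects")
    else {
      dims <- vapply(ch, function(s) dim(s@frames), numeric(3))
      if (length(ch) > 1L && any(apply(dims, 1, function(v) length(unique(v)) > 1L)))
        msg <- c(msg, "all channels must share H, W and T")
      cals <- vapply(ch, function(s)
        c(s@calibration@pixelSizeNm, s@calibration@frameIntervalS), numeric(2))
      if (length(ch) > 1L && any(apply(cals, 1, function(v) length(unique(v)) > 1L)))
        msg <- c(msg, "all channels must share one calibration")
      if (is.null(names(ch)) || any(!nzchar(names(ch))))
        msg <- c(msg, "'channels' must be a named list")
    }
  }
  if (length(object@cellId) != 1L)
    msg <- c(msg, "'cellId' must be a single string")
  if (length(msg)) msg else TRUE
})

#' @param channels list of \code{ChannelStack}s; names default to the stack labels.
#' @param cellId character(1).
#' @rdname CellMovie-class
#' @export
CellMovie <- function(channels, cellId = "cell") {
  if (is.null(names(channels)))
    names(channels) <- vapply(channels, channelLabel, character(1))
  new("CellMovie", channels = channels, cellId = as.character(cellId))
}

#' @rdname CellMovie-class
#' @param x a \code{CellMovie}.
#' @export
setMethod("channelNames", "CellMovie", function(x) names(x@channels))

#' @rdname CellMovie-class
#' @param label channel name.
#' @export
setMethod("getChannel", "CellMovie", function(x, label) {
  if (!label %in% names(x@channels))
    stop("no channel '", label, "' in movie (have: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[label]]
})

#' @rdname CellMovie-class
#' @export
setMethod("cellId", "CellMovie", function(x) x@cellId)

#' @rdname CellMovie-class
#' @export
setMethod("nFrames", "CellMovie", function(x) nFrames(x@channels[[1]]))

#' @rdname CellMovie-class
#' @export
setMethod("frameDim", "CellMovie", function(x) frameDim(x@channels[[1]]))

#' @rdname CellMovie-class
#' @export
setMethod("calibration", "CellMovie", function(x) calibration(x@channels[[1]]))

setMethod("show", "CellMovie", function(object) {
  d <- dim(object@channels[[1]]@frames)
  cat(sprintf("CellMovie '%s': %d x %d px, %d frames, channels: %s\n",
              object@cellId, d[1], d[2], d[3],
              paste(names(object@channels), collapse = ", ")))
})
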