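#' Read a grayscale TIFF time-lapse into a ChannelStack
#'
#' Reads a single- or multi-page grayscale TIFF. Page count becomes the frame
#' count. Stored sample values are rescaled by \code{scale} so that integer
#' TIFFs written by \code{\link{writeStack}} round-trip bit-exactly.
#'
#' @param path TIFF file path.
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param label channel name.
#' @param scale multiplier applied to the [0, 1] sample values read from the
#'   file; the default 65535 recovers 16-bit integer counts.
#' @return a \code{\linkS4class{ChannelStack}}.
#' @seealso \code{\link{writeStack}}, \code{\link{readMovie}}
#' @export
readStack <- function(path, calibration, label, scale = 65535) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF has zero pages: ", path)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L && dim(p)[3] > 1L,
                 logical(1))))
    stop("non-grayscale (multi-sample) TIFF pages in ", path)
  pages <- lapply(pages, function(p) if (length(dim(p)) > 2L) p[, , 1] else p)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages have differing sizes in ", path)
  fr <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (i in seq_along(pages)) fr[, , i] <- pages[[i]] * scale
  fr <- round(fr, 6)
  fr[fr < 0] <- 0
  ChannelStack(label, fr, calibration)
}

#' Write a ChannelStack as a multi-page 16-bit TIFF
#'
#' Intensities are divided by \code{scale} before writing; values must lie in
#' [0, scale]. Integer counts up to \code{scale} round-trip exactly through
#' \code{\link{readStack}}.
#'
#' @param stack a \code{ChannelStack}.
#' @param path output file path.
#' @param scale full-scale intensity mapped to the TIFF sample maximum.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, scale = 65535) {
  fr <- stack@frames
  if (max(fr) > scale)
    stop("intensities exceed 'scale' (", scale, "); pass a larger scale")
  pages <- lapply(seq_len(dim(fr)[3]), function(i) fr[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write analysis records to CSV
#'
#' Plain CSV writer for the per-frame, per-focus, per-track and per-cluster
#' tables the pipeline emits. List columns (e.g. pixel sets) are dropped with
#' a message since they are not representable in flat CSV.
#'
#' @param records a data.frame with a homogeneous column schema.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRecords <- function(records, path) {
  stopifnot(is.data.frame(records))
  isList <- vapply(records, is.list, logical(1))
  if (any(isList)) records <- records[!isList]
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecords
#' @export
readRecords <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write or read a multi-channel movie directory
#'
#' A movie directory contains one 16-bit TIFF per channel plus a
#' \code{movie.yaml} sidecar carrying the calibration (pixel size in nm and
#' frame interval in s), the cell id and the channel-to-file mapping.
#'
#' @param movie a \code{\linkS4class{CellMovie}}.
#' @param dir directory to create/read.
#' @param scale see \code{\link{writeStack}}.
#' @return \code{writeMovie}: \code{dir}, invisibly. \code{readMovie}: a
#'   \code{CellMovie}.
#' @export
writeMovie <- function(movie, dir, scale = 65535) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cal <- calibration(movie)
  files <- list()
  for (lab in channelNames(movie)) {
    fn <- paste0(lab, ".tif")
    writeStack(getChannel(movie, lab), file.path(dir, fn), scale = scale)
    files[[lab]] <- fn
  }
  meta <- list(cell_id = cellId(movie),
               pixel_size_nm = pixelSizeNm(cal),
               frame_interval_s = frameIntervalS(cal),
               intensity_scale = scale,
               channels = files)
  yaml::write_yaml(meta, file.path(dir, "movie.yaml"))
  invisible(dir)
}

#' @rdname writeMovie
#' @export
readMovie <- function(dir) {
  metaPath <- file.path(dir, "movie.yaml")
  if (!file.exists(metaPath)) stop("no movie.yaml in ", dir)
  meta <- yaml::read_yaml(metaPath)
  cal <- Calibration(meta$pixel_size_nm, meta$frame_interval_s)
  sc <- if (is.null(meta$intensity_scale)) 65535 else meta$intensity_scale
  chans <- lapply(names(meta$channels), function(lab)
    readStack(file.path(dir, meta$channels[[lab]]), cal, lab, scale = sc))
  names(chans) <- names(meta$channels)
  CellMovie(chans, cellId = meta$cell_id)
}
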