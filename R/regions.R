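#' Connected pixel region with intensity summaries
#'
#' A \code{Region} is a non-empty 8-connected set of pixels together with the
#' summaries used throughout the package: peak FI (maximum intensity), MFI
#' (mean intensity), the bounding box and the intensity-weighted-free centroid
#' in micrometres (origin at the centre of the top-left pixel).
#'
#' @slot pixels integer n x 2 matrix of (row, col) indices, 1-based.
#' @slot centroidUm numeric(2), (x, y) centroid in um.
#' @slot bbox integer(4): row_min, row_max, col_min, col_max.
#' @slot peakFi,mfi numeric(1) intensity summaries, peakFi >= mfi >= 0.
#'
#' @aliases Region
#' @exportClass Region
setClass("Region",
  representation(pixels = "matrix", centroidUm = "numeric",
                 bbox = "integer", peakFi = "numeric", mfi = "numeric"))

setValidity("Region", function(object) {
  msg <- character()
  if (nrow(object@pixels) < 1L) msg <- c(msg, "pixel set must be non-empty")
  if (object@mfi < 0 || object@peakFi < object@mfi)
    msg <- c(msg, "peakFi >= mfi >= 0 must hold")
  b <- object@bbox
  if (length(b) != 4L || b[1] > b[2] || b[3] > b[4])
    msg <- c(msg, "bbox must be (row_min, row_max, col_min, col_max)")
  if (length(msg)) msg else TRUE
})

#' @param pixels n x 2 matrix of (row, col) indices.
#' @param frame intensity matrix the region lives in.
#' @param calibration a \code{Calibration} used for the centroid in um.
#' @rdname Region-class
#' @export
Region <- function(pixels, frame, calibration) {
  pixels <- matrix(as.integer(pixels), ncol = 2)
  v <- frame[pixels]
  new("Region", pixels = pixels,
      centroidUm = c(pxToUm(calibration, mean(pixels[, 2]) - 1),
                     pxToUm(calibration, mean(pixels[, 1]) - 1)),
      bbox = c(range(pixels[, 1]), range(pixels[, 2]))[c(1, 2, 3, 4)],
      peakFi = max(v), mfi = mean(v))
}

#' Region diameter
#'
#' The diameter of a region is the lesser of its bounding-box height and
#' width, converted to micrometres. Using the smaller of the two axis extents
#' makes the measure conservative for elongated regions.
#'
#' @param region a \code{\linkS4class{Region}}.
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @return diameter in um.
#' @examples
#' cal <- Calibration(110, 2)
#' f <- matrix(1, 10, 10)
#' r <- Region(cbind(rep(1:3, 5), rep(1:5, each = 3)), f, cal)
#' regionDiameter(r, cal)  # 3 px * 110 nm = 0.33 um
#' @export
setMethod("regionDiameter", signature("Region", "Calibration"),
  function(region, calibration) {
    b <- region@bbox
    pxToUm(calibration, min(b[2] - b[1] + 1L, b[4] - b[3] + 1L))
  })

## 8-connected labeling. EBImage::bwlabel is 4-connected; merge labels that
## touch diagonally with a union-find pass so diagonal diffraction-limited
## spots are not split.
label8 <- function(mask) {
  mask <- mask & !is.na(mask)
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask)) return(matrix(0L, H, W))
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), H, W)
  n <- max(lab)
  if (n > 1L && H > 1L && W > 1L) {
    a1 <- lab[-H, -W]; b1 <- lab[-1, -1]       # down-right diagonal
    a2 <- lab[-1, -W]; b2 <- lab[-H, -1]       # up-right diagonal
    s1 <- a1 > 0L & b1 > 0L & a1 != b1
    s2 <- a2 > 0L & b2 > 0L & a2 != b2
    prs <- unique(rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2])))
    if (nrow(prs)) {
      parent <- seq_len(n)
      findRoot <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(prs))) {
        ra <- findRoot(prs[k, 1]); rb <- findRoot(prs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(n), findRoot, integer(1))
      relab <- match(roots, sort(unique(roots)))
      lab[lab > 0L] <- relab[lab[lab > 0L]]
    }
  }
  lab
}

## Per-component summary table for a label matrix. Columns: label, n_px,
## peak_fi, mfi, diameter_um, centroid row/col (px, 1-based), centroid x/y
## (um), bbox, plus a list column of linear pixel indices.
regionTable <- function(lab, frame, cal) {
  idx <- which(lab > 0L)
  if (!length(idx))
    return(data.frame(label = integer(), n_px = integer(), peak_fi = numeric(),
                      mfi = numeric(), diameter_um = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric()))
  g <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  v <- frame[idx]
  np <- tabulate(g)
  labs <- which(np > 0L)
  rmin <- vapply(split(rows, g), min, numeric(1))
  rmax <- vapply(split(rows, g), max, numeric(1))
  cmin <- vapply(split(cols, g), min, numeric(1))
  cmax <- vapply(split(cols, g), max, numeric(1))
  crow <- vapply(split(rows, g), mean, numeric(1))
  ccol <- vapply(split(cols, g), mean, numeric(1))
  out <- data.frame(
    label = labs,
    n_px = np[labs],
    peak_fi = vapply(split(v, g), max, numeric(1)),
    mfi = vapply(split(v, g), mean, numeric(1)),
    diameter_um = pxToUm(cal, pmin(rmax - rmin + 1, cmax - cmin + 1)),
    centroid_row = crow, centroid_col = ccol,
    centroid_x_um = pxToUm(cal, ccol - 1),
    centroid_y_um = pxToUm(cal, crow - 1),
    row.names = NULL)
  out$pixels <- split(idx, g)
  out
}
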