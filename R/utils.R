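## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Centred moving average with truncated edges (window w frames, odd).
movingAverage <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 1L) return(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

## Ordinary least-squares slope of y on x with analytic standard error.
olsSlope <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) stop("degenerate design: all x equal")
  slope <- sum((x - xb) * (y - yb)) / sxx
  res <- y - yb - slope * (x - xb)
  se <- if (n > 2L) sqrt(sum(res^2) / (n - 2L) / sxx) else NA_real_
  list(slope = slope, se = se, intercept = yb - slope * xb, n = n)
}

## Bilinear interpolation of matrix `m` at fractional (row, col) positions,
## clamped to the image border.
bilinear <- function(m, row, col) {
  H <- nrow(m); W <- ncol(m)
  row <- pmin(pmax(row, 1), H)
  col <- pmin(pmax(col, 1), W)
  r0 <- pmin(floor(row), H - 1L); c0 <- pmin(floor(col), W - 1L)
  if (H == 1L) r0 <- rep(1L, length(row))
  if (W == 1L) c0 <- rep(1L, length(col))
  fr <- row - r0; fc <- col - c0
  i00 <- cbind(r0, c0); i10 <- cbind(pmin(r0 + 1L, H), c0)
  i01 <- cbind(r0, pmin(c0 + 1L, W)); i11 <- cbind(pmin(r0 + 1L, H), pmin(c0 + 1L, W))
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

## Mean and standard error of the mean.
meanSem <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x),
    sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_)
}

## Distance (um) of each pixel of `mask` to the mask boundary, via the
## Euclidean distance transform. A one-pixel background frame is enforced so
## masks touching the border stay finite.
edgeDistanceUm <- function(mask, cal) {
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(FALSE, H + 2L, W + 2L)
  padded[2:(H + 1L), 2:(W + 1L)] <- mask
  d <- EBImage::distmap(padded)
  pxToUm(cal, as.numeric(d[2:(H + 1L), 2:(W + 1L)]))  |> matrix(H, W)
}
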