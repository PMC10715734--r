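## Shared fixtures and independent oracles. Oracles deliberately avoid the
## package's own code paths (flood-fill labeling, run enumeration, rank
## enumeration) so they can certify the production implementations.

mkCal <- function(px = 100, dt = 2) Calibration(px, dt)

## Build an AreaTrace directly from an area vector (centred moving average,
## truncated edges — recomputed here, independently of the package helper).
mkTrace <- function(areas, dt = 2, window = 5L) {
  n <- length(areas)
  h <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i)
    mean(areas[max(1L, i - h):min(n, i + h)]), numeric(1))
  new("AreaTrace", timesS = (seq_len(n) - 1) * dt, areasUm2 = areas,
      smoothedAreasUm2 = if (window <= 1L) areas else sm)
}

## Frame with a uniform disk on a uniform background.
diskFrame <- function(h, w, cRow, cCol, radiusPx, inside, outside) {
  rr <- sqrt(outer((seq_len(h) - cRow)^2, (seq_len(w) - cCol)^2, "+"))
  m <- matrix(outside, h, w)
  m[rr <= radiusPx] <- inside
  m
}

diskMask <- function(h, w, cRow, cCol, radiusPx) {
  rr <- sqrt(outer((seq_len(h) - cRow)^2, (seq_len(w) - cCol)^2, "+"))
  rr <= radiusPx
}

## Add a 2D Gaussian spot (absolute amplitude) to a frame.
addGauss <- function(frame, cRow, cCol, amp, sigmaPx) {
  H <- nrow(frame); W <- ncol(frame)
  g <- outer(exp(-(seq_len(H) - cRow)^2 / (2 * sigmaPx^2)),
             exp(-(seq_len(W) - cCol)^2 / (2 * sigmaPx^2)))
  frame + amp * g
}

## ---- independent 8-connected labeling (BFS flood fill) ----
floodLabel8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- (q - 1L) %% H + 1L; cc <- (q - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc2 <- cc + dc
        if (rr < 1L || rr > H || cc2 < 1L || cc2 > W) next
        i <- (cc2 - 1L) * H + rr
        if (mask[i] && lab[i] == 0L) {
          lab[i] <- cur
          queue <- c(queue, i)
        }
      }
    }
  }
  lab
}

## ---- brute-force contraction oracle: enumerate every post-maximum run ----
oracleContraction <- function(smoothed, times, minDrop = 0.05,
                              minDurationS = 10) {
  n <- length(smoothed)
  dt <- times[2] - times[1]
  iMax <- which.max(smoothed)
  thr <- (1 - minDrop) * smoothed[iMax]
  if (iMax >= n) return(FALSE)
  for (i in (iMax + 1L):n) {
    if (smoothed[i] > thr) next
    j <- i
    while (j < n && smoothed[j + 1L] <= thr) j <- j + 1L
    if ((j - i + 1L) * dt >= minDurationS - 1e-9) return(TRUE)
  }
  FALSE
}

## ---- brute-force graded-threshold oracle: materialize all 16 masks ----
oracleGraded <- function(frame, mask, background, cal,
                         folds = round(seq(1.1, 4.1, by = 0.2), 1),
                         minDiamUm = 0.25) {
  pxUm <- pixelSizeNm(cal) / 1000
  comps <- list()
  for (fold in folds) {
    bm <- mask & frame >= fold * background
    lab <- floodLabel8(bm)
    if (max(lab) == 0L) next
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l)
      rows <- (idx - 1L) %% nrow(frame) + 1L
      cols <- (idx - 1L) %/% nrow(frame) + 1L
      diam <- min(diff(range(rows)) + 1L, diff(range(cols)) + 1L) * pxUm
      if (diam >= minDiamUm)
        comps[[length(comps) + 1L]] <- list(fold = fold, idx = sort(idx))
    }
  }
  if (!length(comps)) return(list())
  ## resolve overlaps in descending fold order by exhaustive intersection
  ord <- order(vapply(comps, `[[`, numeric(1), "fold"), decreasing = TRUE)
  accepted <- list()
  for (k in ord) {
    idx <- comps[[k]]$idx
    if (any(vapply(accepted, function(a) length(intersect(a$idx, idx)) > 0L,
                   logical(1)))) next
    accepted[[length(accepted) + 1L]] <- comps[[k]]
  }
  accepted
}

## ---- brute-force inner-foci oracle ----
oracleFoci <- function(frame, mask, cal, fold = 2, minDiamUm = 0.25,
                       edgeMarginUm = 1.0) {
  pxUm <- pixelSizeNm(cal) / 1000
  ## reference: robust interior median (same definition, independent code)
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  d <- as.matrix(EBImage::distmap(pad))[2:(H + 1L), 2:(W + 1L)] * pxUm
  interior <- mask & d >= edgeMarginUm
  v <- frame[interior]
  ref <- stats::median(v[v <= 1.5 * stats::median(v)])
  lab <- floodLabel8(mask & frame >= fold * ref)
  out <- list()
  if (max(lab) == 0L) return(out)
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    rows <- (idx - 1L) %% H + 1L
    cols <- (idx - 1L) %/% H + 1L
    diam <- min(diff(range(rows)) + 1L, diff(range(cols)) + 1L) * pxUm
    cI <- cbind(round(mean(rows)), round(mean(cols)))
    if (diam >= minDiamUm && d[cI] >= edgeMarginUm && lab[cI] == l)
      out[[length(out) + 1L]] <- sort(idx)
  }
  out
}

## ---- exact Mann-Whitney oracle by full enumeration of labelings ----
oracleMW <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  uObs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, function(ix)
    sum(rank(pool)[ix]) - n1 * (n1 + 1) / 2)
  pLow <- mean(us <= uObs)
  pHigh <- mean(us >= uObs)
  list(U = uObs, p = min(1, 2 * min(pLow, pHigh)))
}

## ---- direct step-up FDR formulas ----
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}
oracleBY <- function(p) {
  cm <- sum(1 / seq_along(p))
  pmin(1, oracleBH(p) * cm)
}

## ---- exhaustive KS D over pooled breakpoints ----
oracleKSD <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

## Random blob frame for detector oracle equivalence.
randomBlobFrame <- function(seed, h = 64, w = 64, bg = 100) {
  set.seed(seed)
  f <- matrix(bg, h, w)
  n <- sample(2:6, 1)
  for (i in seq_len(n))
    f <- addGauss(f, runif(1, 10, h - 10), runif(1, 10, w - 10),
                  amp = runif(1, 20, 350), sigmaPx = runif(1, 1, 3))
  f + matrix(rnorm(h * w, 0, 4), h, w)
}

## Small quick simulation defaults used across tests.
quickParams <- function(...) {
  simParams(grid = c(120L, 120L, 90L), calibration = Calibration(100, 2),
            rMaxUm = 3.5, rInitialUm = 1.2, ...)
}
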