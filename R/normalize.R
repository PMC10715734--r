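#' Normalize a group of intensity traces to its dimmest member
#'
#' Fluorescence-intensity time series acquired across cells or experiments
#' are put on a common relative scale by dividing every trace by the lowest
#' per-trace mean in the group, so the dimmest trace maps to mean 1. The
#' granularity of the group (cells, conditions, experiments) is the caller's
#' choice: pass whichever set of traces should share one normalizer.
#'
#' @param traces list of numeric vectors (MFI-vs-time series).
#' @return list of normalized traces with attribute \code{"normalizer"}, the
#'   minimum per-trace mean that was divided out.
#' @examples
#' tr <- normalizeGroupIntensity(list(rep(2, 4), rep(4, 4), rep(8, 4)))
#' sapply(tr, mean)  # 1 2 4
#' @export
normalizeGroupIntensity <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  m <- vapply(traces, function(x) mean(x, na.rm = TRUE), numeric(1))
  norm <- min(m)
  if (!is.finite(norm) || norm <= 0)
    stop("non-positive normalizer: the dimmest trace has mean ", norm)
  out <- lapply(traces, function(x) x / norm)
  attr(out, "normalizer") <- norm
  out
}
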