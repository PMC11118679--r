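#' Mean intensity of a B-scan frame
#'
#' The sweep metric: the arithmetic mean over every pixel of the frame.
#'
#' @param frame Numeric matrix.
#' @return Scalar mean intensity.
#' @export
mean_frame_intensity <- function(frame) {
  if (!is.matrix(frame) || length(frame) == 0L)
    stop_param("frame must be a non-empty matrix")
  mean(frame)
}

#' Select the optimal axial stage position from a depth sweep
#'
#' Scans the stack's frames for the position of greatest mean intensity —
#' the brightest B-scan marks the optimal optical path length for the
#' sample arm, and that stage position is used to trigger volume
#' acquisition. Ties are broken by the lowest index. When the stack (or
#' the `restrict_range` argument) carries a position window, the search is
#' restricted to it, mirroring the practice of sweeping only a narrow
#' range once the plate's approximate optimum is known.
#'
#' @param stack A [depth_stack()].
#' @param restrict_range Optional `(lo, hi)` overriding the stack's own
#'   restriction window.
#' @return A list with `position` (stage coordinate), `index` (1-based
#'   frame index into the full stack) and `mean_intensities` (per-frame
#'   means over the searched window, named by index).
#' @export
find_optimal_depth <- function(stack, restrict_range = NULL) {
  stopifnot(inherits(stack, "depth_stack"))
  rng <- restrict_range %||% stack$restrict_range
  idx <- seq_along(stack$positions)
  if (!is.null(rng)) {
    idx <- which(stack$positions >= rng[1] & stack$positions <= rng[2])
    if (length(idx) == 0L)
      stop_param("restriction window contains no sweep positions")
  }
  mi <- vapply(stack$frames[idx], mean_frame_intensity, numeric(1))
  best <- idx[which.max(mi)]  # which.max: first maximum = lowest index
  list(position = stack$positions[best], index = best,
       mean_intensities = stats::setNames(mi, idx))
}
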