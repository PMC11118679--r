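# Core containers shared across the pipeline. Conventions, stated once and
# asserted in tests: B-scan matrices are (rows = axial depth increasing
# downward, cols = lateral); bounding boxes are half-open, 0-based,
# (x = column, y = row); mm coordinates originate at the image top-left;
# pixel (r, c) has centre ((c - 0.5) * dx, (r - 0.5) * dy) mm.

stop_param <- function(msg) {
  stop(errorCondition(msg, class = c("octscreen_param_error", "error")))
}

stop_unsegmentable <- function(msg) {
  stop(errorCondition(msg, class = c("octscreen_unsegmentable", "error")))
}

#' Bounding box in half-open pixel coordinates
#'
#' Boxes are 0-based and half-open on both axes: a box `(x0, y0, x1, y1)`
#' covers pixel columns `x0..x1-1` and rows `y0..y1-1`, so its area in
#' pixels is `(x1 - x0) * (y1 - y0)`.
#'
#' @param x0,y0,x1,y1 Box coordinates; requires `x0 < x1`, `y0 < y1`,
#'   all non-negative.
#' @param confidence Detection score in \[0, 1\].
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(x0, y0, x1, y1, confidence = 1) {
  if (any(c(x0, y0) < 0) || x0 >= x1 || y0 >= y1)
    stop_param("degenerate bounding box: need 0 <= x0 < x1, 0 <= y0 < y1")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 confidence = confidence),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> [%g, %g) x [%g, %g) px, confidence %.3f\n",
              x$x0, x$x1, x$y0, x$y1, x$confidence))
  invisible(x)
}

#' OCT volume container
#'
#' An ordered stack of B-scan intensity matrices with the lateral and axial
#' voxel spacings, the unit of acquisition per sample.
#'
#' @param frames List of numeric matrices, all of identical dimensions
#'   (axial rows x lateral columns); element `j` is the B-scan at lateral
#'   position `y = (j - 0.5) * dy_um`.
#' @param dx_um,dy_um,dz_um Voxel spacings in um (A-line pitch, B-scan
#'   pitch, axial pitch).
#' @param n_repeats Number of repeated acquisitions averaged per B-scan.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(frames, dx_um, dy_um, dz_um, n_repeats = 1L) {
  check_frame_stack(frames, dx_um, dy_um, dz_um)
  structure(list(frames = frames, dx_um = dx_um, dy_um = dy_um,
                 dz_um = dz_um, n_repeats = as.integer(n_repeats)),
            class = "oct_volume")
}

#' Segmented volume container
#'
#' An ordered stack of binary masks (one per B-scan) with voxel spacings.
#' Values are strictly 0/1; shapes must agree across the stack.
#'
#' @param masks List of 0/1 integer matrices, one per B-scan.
#' @inheritParams oct_volume
#' @return An object of class `seg_volume`.
#' @export
seg_volume <- function(masks, dx_um, dy_um, dz_um) {
  check_frame_stack(masks, dx_um, dy_um, dz_um)
  for (m in masks)
    if (!all(m %in% c(0L, 1L)))
      stop_param("seg_volume masks must be exactly {0,1}-valued")
  structure(list(masks = masks, dx_um = dx_um, dy_um = dy_um, dz_um = dz_um),
            class = "seg_volume")
}

check_frame_stack <- function(frames, dx_um, dy_um, dz_um) {
  if (!is.list(frames) || length(frames) == 0L)
    stop_param("frames must be a non-empty list of matrices")
  d <- dim(frames[[1]])
  for (f in frames)
    if (!is.matrix(f) || !identical(dim(f), d))
      stop_param("all frames must be matrices of identical dimensions")
  if (any(c(dx_um, dy_um, dz_um) <= 0))
    stop_param("voxel spacings must be strictly positive")
  invisible(TRUE)
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<oct_volume> %d B-scans of %d x %d px (dx %.2f, dy %.2f, dz %.2f um)\n",
    length(x$frames), d[1], d[2], x$dx_um, x$dy_um, x$dz_um))
  invisible(x)
}

#' @export
print.seg_volume <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf(
    "<seg_volume> %d masks of %d x %d px (dx %.2f, dy %.2f, dz %.2f um)\n",
    length(x$masks), d[1], d[2], x$dx_um, x$dy_um, x$dz_um))
  invisible(x)
}

#' Depth-sweep stack
#'
#' Candidate B-scans acquired while sweeping the axial stage, one frame per
#' stage position.
#'
#' @param positions Strictly increasing numeric stage coordinates (mm).
#' @param frames List of B-scan matrices, one per position.
#' @param restrict_range Optional `(lo, hi)` sub-interval of stage
#'   positions to which the optimum search is restricted.
#' @return An object of class `depth_stack`.
#' @export
depth_stack <- function(positions, frames, restrict_range = NULL) {
  if (length(positions) != length(frames) || length(frames) < 1L)
    stop_param("need one frame per position and at least one position")
  if (length(positions) > 1L && any(diff(positions) <= 0))
    stop_param("positions must be strictly increasing")
  if (!is.null(restrict_range) &&
      (length(restrict_range) != 2L || restrict_range[1] > restrict_range[2]))
    stop_param("restrict_range must be (lo, hi) with lo <= hi")
  structure(list(positions = positions, frames = frames,
                 restrict_range = restrict_range),
            class = "depth_stack")
}

new_thickness_map <- function(values_um, dx_um, dy_um) {
  if (any(values_um < 0)) stop_param("thickness must be non-negative")
  structure(values_um, dx_um = dx_um, dy_um = dy_um,
            class = c("thickness_map", "matrix", "array"))
}

#' @export
print.thickness_map <- function(x, ...) {
  nz <- sum(x > 0)
  cat(sprintf(
    "<thickness_map> %d x %d columns (dx %.2f, dy %.2f um); %d tissue columns, mean %.1f um\n",
    nrow(x), ncol(x), attr(x, "dx_um"), attr(x, "dy_um"), nz,
    if (nz > 0) mean(x[x > 0]) else 0))
  invisible(x)
}
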