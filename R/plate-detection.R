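#' Detect a tissue explant in a plate-view well image
#'
#' Deterministic classical detector used as the reference detection path:
#' the image is smoothed, thresholded against a robust background estimate
#' (median +/- k MAD of the smoothed intensities), connected components
#' below `min_area_mm2` are discarded, and the largest surviving component
#' (ties broken by the smaller top-left corner in row-major order) yields a
#' tight half-open bounding box and an intensity-weighted centroid in mm.
#' An image with no surviving component reports an explicit void, so empty
#' wells are never measured.
#'
#' @param image 2-D numeric grayscale matrix (rows = y, cols = x).
#' @param mm_per_pixel Pixel pitch in mm; taken from the image attribute
#'   when present.
#' @param background_quantile Quantile of smoothed intensities used as the
#'   background level estimate.
#' @param min_area_mm2 Minimum component area retained, in mm^2.
#' @param smooth_mm Gaussian smoothing scale in mm.
#' @param k_mad Threshold in robust SD units: pixels deviating from the
#'   background by more than `k_mad * MAD` (and at least `min_contrast`)
#'   are candidate tissue.
#' @param min_contrast Absolute deviation floor, guarding against noise-only
#'   images whose MAD is tiny.
#' @return A `detection_result`: list with `status` (`"found"` or
#'   `"void"`), `box` (a [bounding_box()] or `NULL`) and `centroid_mm`
#'   (`c(x, y)` or `NULL`).
#' @export
#' @examples
#' w <- make_well_image(phantom_spec(image_size_px = c(240, 240)), seed = 3)
#' detect_tissue_baseline(w$image)
detect_tissue_baseline <- function(image, mm_per_pixel = NULL,
                                   background_quantile = 0.5,
                                   min_area_mm2 = 1,
                                   smooth_mm = 0.25,
                                   k_mad = 6,
                                   min_contrast = 0.1) {
  if (!is.matrix(image) || length(image) == 0L)
    stop_param("image must be a non-empty 2-D matrix")
  if (is.null(mm_per_pixel)) mm_per_pixel <- attr(image, "mm_per_pixel")
  if (is.null(mm_per_pixel) || mm_per_pixel <= 0)
    stop_param("mm_per_pixel must be a positive scalar")

  sigma_px <- max(smooth_mm / mm_per_pixel, 0.5)
  sm <- unclass(EBImage::gblur(image, sigma = sigma_px))
  bg <- stats::quantile(sm, background_quantile, names = FALSE)
  dev <- abs(sm - bg)
  thr <- max(k_mad * stats::mad(sm, center = bg), min_contrast)
  fg <- dev > thr
  if (!any(fg)) return(detection_void())

  lab <- EBImage::bwlabel(fg)
  min_px <- min_area_mm2 / mm_per_pixel^2
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  if (length(keep) == 0L) return(detection_void())

  best <- largest_component(lab, keep, sizes)
  comp <- lab == best
  rows <- which(apply(comp, 1, any)); cols <- which(apply(comp, 2, any))
  box <- bounding_box(min(cols) - 1, min(rows) - 1, max(cols), max(rows),
                      confidence = 1)
  w <- dev[comp]
  rc <- which(comp, arr.ind = TRUE)
  centroid_px <- c(sum(rc[, 2] * w), sum(rc[, 1] * w)) / sum(w)  # (col,row)
  centroid_mm <- (centroid_px - 0.5) * mm_per_pixel
  structure(list(status = "found", box = box, centroid_mm = centroid_mm),
            class = "detection_result")
}

detection_void <- function() {
  structure(list(status = "void", box = NULL, centroid_mm = NULL),
            class = "detection_result")
}

# Largest candidate component by pixel count; ties broken by the smaller
# top-left corner of the tight box in row-major (y0, then x0) order.
largest_component <- function(lab, keep, sizes) {
  if (length(keep) == 1L) return(keep)
  mx <- max(sizes[keep])
  cand <- keep[sizes[keep] == mx]
  if (length(cand) == 1L) return(cand)
  corners <- t(vapply(cand, function(k) {
    rc <- which(lab == k, arr.ind = TRUE)
    c(min(rc[, 1]), min(rc[, 2]))
  }, numeric(2)))
  cand[order(corners[, 1], corners[, 2])][1]
}

#' @export
print.detection_result <- function(x, ...) {
  if (x$status == "void") {
    cat("<detection_result> void\n")
  } else {
    cat(sprintf("<detection_result> found at (%.3f, %.3f) mm\n",
                x$centroid_mm[1], x$centroid_mm[2]))
    print(x$box)
  }
  invisible(x)
}

#' Intersection over union of two bounding boxes
#'
#' Overlap ratio |a intersect b| / |a union b| under half-open box
#' semantics, so touching boxes overlap in zero area.
#'
#' @param a,b [bounding_box()] objects.
#' @return Ratio in \[0, 1\]; 1 iff the boxes are identical.
#' @export
iou <- function(a, b) {
  for (bx in list(a, b))
    if (!inherits(bx, "bounding_box")) stop_param("iou expects bounding_box")
  iw <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  ih <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- iw * ih
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) +
           (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  inter / union
}

#' Mean average precision over an IoU threshold grid
#'
#' Single-class detection score: at each IoU threshold, predictions pooled
#' over all images are matched to ground-truth boxes greedily in order of
#' descending confidence (each truth matched at most once; a match requires
#' IoU >= threshold, taking the highest-IoU unmatched truth in the same
#' image), the precision-recall curve is accumulated, and AP is the area
#' under its all-point-interpolated (precision envelope) form. The score is
#' the mean AP over the threshold grid, by default 0.50 to 0.95 in steps
#' of 0.05.
#'
#' @param predictions,truths Data frames (or tibbles) of boxes with columns
#'   `image`, `x0`, `y0`, `x1`, `y1`, and for predictions `confidence`.
#' @param iou_thresholds Numeric vector of IoU thresholds.
#' @return A tibble with one row per threshold (`iou_threshold`, `ap`) plus
#'   attribute `mAP`; use [map_score()] for the scalar.
#' @export
mean_average_precision <- function(predictions, truths,
                                   iou_thresholds = seq(0.50, 0.95, by = 0.05)) {
  truths <- tibble::as_tibble(truths)
  predictions <- tibble::as_tibble(predictions)
  if (nrow(truths) == 0L)
    stop_param("mAP is undefined with an empty ground-truth set")
  if (nrow(predictions) > 0L)
    predictions <- dplyr::arrange(predictions, dplyr::desc(.data$confidence))
  ap <- vapply(iou_thresholds, function(thr)
    average_precision_at(predictions, truths, thr), numeric(1))
  out <- tibble::tibble(iou_threshold = iou_thresholds, ap = ap)
  attr(out, "mAP") <- mean(ap)
  out
}

#' @rdname mean_average_precision
#' @param ... Passed on to [mean_average_precision()].
#' @export
map_score <- function(predictions, truths, ...) {
  attr(mean_average_precision(predictions, truths, ...), "mAP")
}

average_precision_at <- function(pred, truth, thr) {
  n_truth <- nrow(truth)
  if (nrow(pred) == 0L) return(0)
  matched <- rep(FALSE, n_truth)
  tp <- logical(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    p <- bounding_box(pred$x0[i], pred$y0[i], pred$x1[i], pred$y1[i])
    cand <- which(!matched & truth$image == pred$image[i])
    if (length(cand) > 0L) {
      ious <- vapply(cand, function(j)
        iou(p, bounding_box(truth$x0[j], truth$y0[j],
                            truth$x1[j], truth$y1[j])), numeric(1))
      best <- cand[which.max(ious)]
      if (max(ious) >= thr) { matched[best] <- TRUE; tp[i] <- TRUE }
    }
  }
  recall <- cumsum(tp) / n_truth
  precision <- cumsum(tp) / seq_along(tp)
  # all-point interpolation: area under the running-max precision envelope
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Centroid localisation error
#'
#' Euclidean distance between a predicted and a true centroid, reported in
#' um (inputs in mm).
#'
#' @param pred_centroid_mm,true_centroid_mm Numeric `(x, y)` pairs in mm.
#' @return Distance in um.
#' @export
centroid_shift <- function(pred_centroid_mm, true_centroid_mm) {
  sqrt(sum((pred_centroid_mm - true_centroid_mm)^2)) * 1000
}

#' Stage calibration record
#'
#' Affine map between well-image mm coordinates and stage command voltages:
#' `volts = reference_voltage + (centroid_mm + webcam_to_oct_offset_mm) /
#' mm_per_volt`, per axis. The offset is the measured displacement between
#' the camera and OCT probe axes.
#'
#' @param webcam_to_oct_offset_mm Numeric pair (dx, dy) in mm.
#' @param mm_per_volt Numeric pair, mm of travel per volt per axis;
#'   components must be nonzero.
#' @param reference_voltage Numeric pair, voltage at the well origin.
#' @return An object of class `stage_calibration`.
#' @export
stage_calibration <- function(webcam_to_oct_offset_mm = c(0, 0),
                              mm_per_volt = c(1, 1),
                              reference_voltage = c(0, 0)) {
  if (any(mm_per_volt == 0))
    stop_param("mm_per_volt components must be nonzero")
  structure(list(webcam_to_oct_offset_mm = as.numeric(webcam_to_oct_offset_mm),
                 mm_per_volt = as.numeric(mm_per_volt),
                 reference_voltage = as.numeric(reference_voltage)),
            class = "stage_calibration")
}

#' Convert a centroid to stage voltages (and back)
#'
#' @param centroid_mm Numeric `(x, y)` centroid in well coordinates.
#' @param cal A [stage_calibration()].
#' @return `centroid_to_stage()`: voltages `(x, y)`;
#'   `stage_to_centroid()`: the inverse map, recovering the centroid.
#' @export
centroid_to_stage <- function(centroid_mm, cal) {
  stopifnot(inherits(cal, "stage_calibration"))
  cal$reference_voltage +
    (centroid_mm + cal$webcam_to_oct_offset_mm) / cal$mm_per_volt
}

#' @rdname centroid_to_stage
#' @param volts Numeric `(x, y)` stage voltages.
#' @export
stage_to_centroid <- function(volts, cal) {
  stopifnot(inherits(cal, "stage_calibration"))
  (volts - cal$reference_voltage) * cal$mm_per_volt -
    cal$webcam_to_oct_offset_mm
}
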