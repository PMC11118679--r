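#' En-face thickness map of a segmented volume
#'
#' Reduces a segmented OCT volume to per-column tissue thickness on the
#' en-face grid: for each lateral position (B-scan y, A-line x), thickness
#' is the number of tissue voxels in that column times the axial spacing.
#' The voxel-count rule (rather than top-minus-bottom span) is additive and
#' robust to interior holes; see [thickness_map_span()] for the span
#' variant.
#'
#' @param v A [seg_volume()].
#' @return A `thickness_map`: matrix of um values, shape
#'   `(n_bscans, n_alines)`, with `dx_um`/`dy_um` attributes.
#' @export
thickness_map <- function(v) {
  stopifnot(inherits(v, "seg_volume"))
  tm <- do.call(rbind, lapply(v$masks, colSums)) * v$dz_um
  new_thickness_map(tm, dx_um = v$dx_um, dy_um = v$dy_um)
}

#' @rdname thickness_map
#' @details `thickness_map_span()` measures each column as the axial span
#'   from the topmost to the bottommost tissue voxel (inclusive), bridging
#'   any interior gaps.
#' @export
thickness_map_span <- function(v) {
  stopifnot(inherits(v, "seg_volume"))
  span <- function(m) {
    apply(m, 2, function(col) {
      w <- which(col == 1L)
      if (length(w) == 0L) 0 else max(w) - min(w) + 1
    })
  }
  tm <- do.call(rbind, lapply(v$masks, span)) * v$dz_um
  new_thickness_map(tm, dx_um = v$dx_um, dy_um = v$dy_um)
}

#' Tissue footprint area
#'
#' Area of the en-face support of the tissue: the count of columns with
#' nonzero thickness times the lateral pixel area. Depends only on the
#' support, not on the thickness values.
#'
#' @param map A `thickness_map` (see [thickness_map()]).
#' @return Area in mm^2.
#' @export
tissue_area <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  sum(map > 0) * attr(map, "dx_um") * attr(map, "dy_um") * 1e-6
}

#' Tissue volume
#'
#' Integral of the thickness map over the en-face grid — equivalently the
#' tissue voxel count times the voxel volume.
#'
#' @inheritParams tissue_area
#' @return Volume in mm^3.
#' @export
tissue_volume <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  sum(map) * attr(map, "dx_um") * attr(map, "dy_um") * 1e-9
}

#' Mean thickness of the central tissue region
#'
#' The headline thickness readout. To avoid bias from the thin, sloping
#' periphery of an explant, the mean is taken only over the central region
#' where the tissue is flatter: columns whose thickness reaches at least
#' the median thickness of the tissue columns (zero-background columns are
#' excluded from the median, which would otherwise degenerate for small
#' explants in a wide field). The inclusive `>=` comparison keeps the
#' region nonempty for perfectly uniform tissue; `strict = TRUE` selects
#' the strictly-greater variant.
#'
#' @inheritParams tissue_area
#' @param strict Use strictly-greater-than-median selection.
#' @return Mean central thickness in um.
#' @export
central_mean_thickness <- function(map, strict = FALSE) {
  stopifnot(inherits(map, "thickness_map"))
  vals <- map[map > 0]
  if (length(vals) == 0L)
    stop_param("thickness map contains no tissue columns")
  m <- stats::median(vals)
  sel <- if (strict) vals[vals > m] else vals[vals >= m]
  if (length(sel) == 0L) sel <- vals[vals == max(vals)]
  mean(sel)
}

#' En-face projection of a raw OCT volume
#'
#' Mean-intensity projection along depth for each lateral column — over
#' all depths, or over masked depths only when a segmentation is supplied —
#' normalised to \[0, 1\] for display.
#'
#' @param volume An [oct_volume()].
#' @param mask Optional [seg_volume()] restricting the projection to
#'   tissue voxels (columns without tissue project to 0).
#' @return Numeric matrix of shape `(n_bscans, n_alines)` in \[0, 1\].
#' @export
en_face_projection <- function(volume, mask = NULL) {
  stopifnot(inherits(volume, "oct_volume"))
  nx <- ncol(volume$frames[[1]])
  if (is.null(mask)) {
    proj <- do.call(rbind, lapply(volume$frames, colMeans))
  } else {
    stopifnot(inherits(mask, "seg_volume"))
    proj <- do.call(rbind, lapply(seq_along(volume$frames), function(j) {
      s <- colSums(volume$frames[[j]] * (mask$masks[[j]] == 1L))
      n <- colSums(mask$masks[[j]] == 1L)
      ifelse(n > 0, s / pmax(n, 1), 0)
    }))
  }
  rng <- range(proj)
  if (rng[2] > rng[1]) (proj - rng[1]) / (rng[2] - rng[1])
  else matrix(0, nrow(proj), ncol(proj))
}

#' All morphometric readouts of a segmented volume
#'
#' Convenience wrapper reducing a segmented volume to the three screen
#' readouts in one call.
#'
#' @param v A [seg_volume()].
#' @param sample_id,timepoint,repetition Identifiers carried into the
#'   output row.
#' @return One-row tibble with `sample_id`, `timepoint`, `repetition`,
#'   `thickness_um` (central mean), `area_mm2`, `volume_mm3`.
#' @export
measure_readouts <- function(v, sample_id = NA_character_,
                             timepoint = NA_character_,
                             repetition = NA_integer_) {
  map <- thickness_map(v)
  thick <- if (any(map > 0)) central_mean_thickness(map) else 0
  tibble::tibble(sample_id = sample_id, timepoint = timepoint,
                 repetition = repetition,
                 thickness_um = thick,
                 area_mm2 = tissue_area(map),
                 volume_mm3 = tissue_volume(map))
}
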