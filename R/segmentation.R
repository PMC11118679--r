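#' Segment tissue in a B-scan (classical reference path)
#'
#' Deterministic segmenter designed around the three artifact classes that
#' defeat naive thresholding of explant B-scans: saturated specular
#' columns, smooth reflectance inhomogeneity, and the thin bright
#' supporting membrane beneath the tissue. Pipeline:
#'
#' 1. flag saturated columns (a column in which at least
#'    `max_specular_col_frac` of pixels sit at the intensity cap) and
#'    exclude them from all estimation;
#' 2. Gaussian-smooth the remaining columns;
#' 3. threshold with Otsu's method after min-max normalisation, which makes
#'    the rule invariant to global affine intensity rescaling;
#' 4. remove candidate components whose axial extent never exceeds
#'    `membrane_max_thickness_um` (membrane suppression — position-free, so
#'    it tolerates tissue sag);
#' 5. keep the largest remaining component and fill its holes;
#' 6. in-paint flagged columns by horizontal linear interpolation of the
#'    mask between their non-flagged neighbours.
#'
#' @param bscan Numeric matrix (rows = depth, cols = lateral) or a list
#'   with `$frame`; intensities on any affine scale.
#' @param dz_um Axial pixel spacing in um.
#' @param smooth_px Gaussian smoothing sigma in pixels.
#' @param membrane_max_thickness_um Components at most this thick (axially)
#'   everywhere are treated as membrane and removed.
#' @param min_component_px Minimum component size (pixels) retained before
#'   the membrane rule.
#' @param max_specular_col_frac Fraction of at-cap pixels above which a
#'   column is treated as a specular artifact.
#' @param sat_quantile Quantile of the frame used to locate the intensity
#'   cap.
#' @return A 0/1 integer matrix of the same shape as the input.
#' @export
segment_classical <- function(bscan, dz_um = 2,
                              smooth_px = 1.5,
                              membrane_max_thickness_um = 30,
                              min_component_px = 64,
                              max_specular_col_frac = 0.5,
                              sat_quantile = 0.995) {
  if (is.list(bscan) && !is.null(bscan$frame)) bscan <- bscan$frame
  if (!is.matrix(bscan) || length(bscan) == 0L)
    stop_param("bscan must be a non-empty matrix")
  nz <- nrow(bscan); nx <- ncol(bscan)

  cap <- stats::quantile(bscan, sat_quantile, names = FALSE)
  at_cap <- bscan >= cap
  flagged <- colMeans(at_cap) >= max_specular_col_frac
  if (all(flagged))
    stop_unsegmentable("every column is saturated; frame is unsegmentable")

  work <- bscan[, !flagged, drop = FALSE]
  rng <- range(work)
  if (rng[2] > rng[1]) {
    norm <- (work - rng[1]) / (rng[2] - rng[1])
  } else {
    norm <- matrix(0, nrow(work), ncol(work))
  }
  sm <- if (min(dim(norm)) > 4) unclass(EBImage::gblur(norm, sigma = smooth_px))
        else norm
  thr <- EBImage::otsu(EBImage::Image(pmin(pmax(sm, 0), 1)))
  # estimate the threshold on the smoothed frame (stable under speckle) but
  # apply it to the raw frame, so clean frames segment pixel-exactly; the
  # component and hole-filling steps absorb isolated speckle misclassification
  fg <- norm > thr

  lab <- EBImage::bwlabel(fg)
  n_comp <- max(lab)
  keep <- integer(0)
  if (n_comp > 0L) {
    mem_px <- membrane_max_thickness_um / dz_um
    sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
    for (k in seq_len(n_comp)) {
      if (sizes[k] < min_component_px) next
      ext <- max(colSums(lab == k))  # thickest axial run of the component
      if (ext > mem_px) keep <- c(keep, k)
    }
  }
  mask_work <- matrix(0L, nrow(work), ncol(work))
  if (length(keep) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
    best <- largest_component(lab, keep, sizes)
    mask_work <- EBImage::fillHull(lab == best)
    storage.mode(mask_work) <- "integer"
  }

  mask <- matrix(0L, nz, nx)
  mask[, !flagged] <- mask_work
  if (any(flagged) && any(mask_work == 1L)) {
    good <- which(!flagged)
    for (r in seq_len(nz)) {
      v <- mask[r, good]
      if (any(v == 1L)) {
        interp <- stats::approx(good, v, xout = which(flagged),
                                rule = 2)$y
        mask[r, flagged] <- as.integer(interp >= 0.5)
      }
    }
  }
  mask
}

#' Segment every B-scan of a volume
#'
#' Applies [segment_classical()] frame-wise; frames that are unsegmentable
#' (all columns saturated) yield empty masks with a warning.
#'
#' @param volume An [oct_volume()].
#' @param ... Passed to [segment_classical()].
#' @return A [seg_volume()] with the volume's voxel spacings.
#' @export
segment_volume <- function(volume, ...) {
  stopifnot(inherits(volume, "oct_volume"))
  masks <- lapply(volume$frames, function(f) {
    tryCatch(segment_classical(f, dz_um = volume$dz_um, ...),
             octscreen_unsegmentable = function(e) {
               warning("unsegmentable frame replaced by empty mask",
                       call. = FALSE)
               matrix(0L, nrow(f), ncol(f))
             })
  })
  seg_volume(masks, dx_um = volume$dx_um, dy_um = volume$dy_um,
             dz_um = volume$dz_um)
}

#' Segmentation metrics: recall, precision, Dice
#'
#' Voxel-wise overlap metrics between a predicted and a reference binary
#' mask: recall = TP/(TP+FN), precision = TP/(TP+FP),
#' dice = 2TP/(2TP+FP+FN). When both masks are empty all three are 1 (the
#' prediction is vacuously perfect); when exactly one is empty all three
#' are 0.
#'
#' @param pred,truth Binary matrices (or [seg_volume()] objects) of
#'   identical shape.
#' @return A one-row tibble with `recall`, `precision`, `dice`.
#' @export
seg_metrics <- function(pred, truth) {
  if (inherits(pred, "seg_volume")) pred <- pred$masks
  if (inherits(truth, "seg_volume")) truth <- truth$masks
  if (is.list(pred)) pred <- do.call(cbind, pred)
  if (is.list(truth)) truth <- do.call(cbind, truth)
  if (!identical(dim(pred), dim(truth)))
    stop_param("pred and truth must have identical shapes")
  p <- pred == 1; t <- truth == 1
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0) {
    out <- c(recall = 1, precision = 1, dice = 1)
  } else if (tp == 0 && (fp == 0 || fn == 0)) {
    out <- c(recall = 0, precision = 0, dice = 0)
  } else {
    out <- c(recall = tp / (tp + fn), precision = tp / (tp + fp),
             dice = 2 * tp / (2 * tp + fp + fn))
  }
  tibble::tibble(recall = out[["recall"]], precision = out[["precision"]],
                 dice = out[["dice"]])
}

#' Paired image/mask augmentation
#'
#' Training-set augmentation for segmentation: translation, contrast
#' adjustment, and horizontal/vertical flips. Geometric operations are
#' applied identically to image and mask; contrast affects the image only;
#' translation pads with a background value.
#'
#' `apply_augment()` applies one fully specified transform;
#' `augment()` draws `n` seeded random transforms from the requested
#' operation set and returns the augmented pairs.
#'
#' @param image,mask Matrices of identical shape (mask binary).
#' @param translate Integer `(rows, cols)` shift; positive shifts move
#'   content down/right.
#' @param contrast Multiplicative contrast factor about the image mean.
#' @param flip_h,flip_v Horizontal / vertical flips.
#' @param bg Background pad value for the image (mask pads with 0).
#' @return `apply_augment()`: a list `(image, mask)`; `augment()`: a list
#'   of such pairs, each carrying its transform as attribute `params`.
#' @export
apply_augment <- function(image, mask, translate = c(0L, 0L), contrast = 1,
                          flip_h = FALSE, flip_v = FALSE, bg = 0) {
  if (!identical(dim(image), dim(mask)))
    stop_param("image and mask must share a shape")
  shift <- function(m, dr, dc, fill) {
    out <- matrix(fill, nrow(m), ncol(m))
    src_r <- seq_len(nrow(m)) - dr; src_c <- seq_len(ncol(m)) - dc
    ok_r <- src_r >= 1 & src_r <= nrow(m); ok_c <- src_c >= 1 & src_c <= ncol(m)
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out
  }
  img <- image; msk <- mask
  if (any(translate != 0L)) {
    img <- shift(img, translate[1], translate[2], bg)
    msk <- shift(msk, translate[1], translate[2], 0L)
  }
  if (flip_h) { img <- img[, rev(seq_len(ncol(img)))]
                msk <- msk[, rev(seq_len(ncol(msk)))] }
  if (flip_v) { img <- img[rev(seq_len(nrow(img))), ]
                msk <- msk[rev(seq_len(nrow(msk))), ] }
  if (contrast != 1) img <- mean(img) + contrast * (img - mean(img))
  list(image = img, mask = msk)
}

#' @rdname apply_augment
#' @param ops Subset of `c("translate", "contrast", "flip_h", "flip_v")`.
#' @param n Number of augmented pairs to draw.
#' @param seed Integer seed.
#' @param max_translate_px Largest absolute shift drawn per axis.
#' @param contrast_range Range the contrast factor is drawn from.
#' @export
augment <- function(image, mask,
                    ops = c("translate", "contrast", "flip_h", "flip_v"),
                    n = 4L, seed = 1L, max_translate_px = 10L,
                    contrast_range = c(0.7, 1.3), bg = 0) {
  ops <- match.arg(ops, several.ok = TRUE)
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      tr <- if ("translate" %in% ops)
        sample(seq(-max_translate_px, max_translate_px), 2L, replace = TRUE)
      else c(0L, 0L)
      ct <- if ("contrast" %in% ops)
        stats::runif(1, contrast_range[1], contrast_range[2]) else 1
      fh <- "flip_h" %in% ops && stats::runif(1) < 0.5
      fv <- "flip_v" %in% ops && stats::runif(1) < 0.5
      out <- apply_augment(image, mask, translate = tr, contrast = ct,
                           flip_h = fh, flip_v = fv, bg = bg)
      attr(out, "params") <- list(translate = tr, contrast = ct,
                                  flip_h = fh, flip_v = fv)
      out
    })
  })
}
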