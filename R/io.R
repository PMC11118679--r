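# File formats: volumes and masks as multi-page TIFF (16-bit / 8-bit),
# well images as PNG or single-page TIFF, ground truth as JSON sidecars,
# detection boxes as JSON lines, screen tables as CSV, configs as YAML or
# JSON.

#' Read and write OCT volumes as multi-page TIFF
#'
#' One page per B-scan, 16-bit unsigned storage; intensities are clamped
#' to \[0, 1\] and quantised to the 16-bit grid on write (round-trip exact
#' on that grid). Voxel spacings travel in a JSON sidecar
#' (`<basename>.meta.json`) next to the TIFF.
#'
#' @param volume An [oct_volume()].
#' @param path Output `.tif` path.
#' @return `write_volume_tiff()` returns `path` invisibly;
#'   `read_volume_tiff()` returns an [oct_volume()].
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  frames <- lapply(volume$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  meta <- list(dx_um = volume$dx_um, dy_um = volume$dy_um,
               dz_um = volume$dz_um, n_repeats = volume$n_repeats)
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param dx_um,dy_um,dz_um Spacings used when no sidecar is present.
#' @export
read_volume_tiff <- function(path, dx_um = NULL, dy_um = NULL,
                             dz_um = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta <- if (file.exists(meta_path(path)))
    jsonlite::read_json(meta_path(path), simplifyVector = TRUE) else list()
  oct_volume(frames,
             dx_um = dx_um %||% meta$dx_um %||% 1,
             dy_um = dy_um %||% meta$dy_um %||% 1,
             dz_um = dz_um %||% meta$dz_um %||% 1,
             n_repeats = meta$n_repeats %||% 1L)
}

meta_path <- function(path) sub("\\.tiff?$", ".meta.json", path)

#' Read and write segmentation masks as multi-page TIFF
#'
#' Masks are stored as 8-bit pages with values \{0, 255\} on disk and
#' normalised back to \{0, 1\} in memory; the round trip is exact.
#'
#' @param mask A [seg_volume()].
#' @param path Output `.tif` path.
#' @return `write_mask_tiff()` returns `path` invisibly;
#'   `read_mask_tiff()` returns a [seg_volume()].
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "seg_volume"))
  pages <- lapply(mask$masks, function(m) {
    mm <- m; storage.mode(mm) <- "double"; mm
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(dx_um = mask$dx_um, dy_um = mask$dy_um, dz_um = mask$dz_um)
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @inheritParams read_volume_tiff
#' @export
read_mask_tiff <- function(path, dx_um = NULL, dy_um = NULL, dz_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  masks <- lapply(pages, function(p) {
    m <- (p >= 0.5) * 1L
    storage.mode(m) <- "integer"
    m
  })
  meta <- if (file.exists(meta_path(path)))
    jsonlite::read_json(meta_path(path), simplifyVector = TRUE) else list()
  seg_volume(masks, dx_um = dx_um %||% meta$dx_um %||% 1,
             dy_um = dy_um %||% meta$dy_um %||% 1,
             dz_um = dz_um %||% meta$dz_um %||% 1)
}

#' Read and write plate-view well images as PNG
#'
#' Grayscale PNG in \[0, 1\]; the mm-per-pixel scale travels as a JSON
#' sidecar and is restored on read.
#'
#' @param image Numeric matrix with optional `mm_per_pixel` attribute.
#' @param path Output `.png` path.
#' @param mm_per_pixel Scale override.
#' @return `write_well_png()` returns `path` invisibly;
#'   `read_well_png()` returns the image matrix with its `mm_per_pixel`
#'   attribute.
#' @export
write_well_png <- function(image, path, mm_per_pixel = NULL) {
  mpp <- mm_per_pixel %||% attr(image, "mm_per_pixel")
  png::writePNG(pmin(pmax(unclass(image), 0), 1), path)
  if (!is.null(mpp))
    jsonlite::write_json(list(mm_per_pixel = mpp),
                         sub("\\.png$", ".meta.json", path),
                         auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_well_png
#' @export
read_well_png <- function(path, mm_per_pixel = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  side <- sub("\\.png$", ".meta.json", path)
  if (is.null(mm_per_pixel) && file.exists(side))
    mm_per_pixel <- jsonlite::read_json(side,
                                        simplifyVector = TRUE)$mm_per_pixel
  attr(img, "mm_per_pixel") <- mm_per_pixel
  img
}

#' Serialise bounding boxes as JSON lines
#'
#' One JSON object per line with fields `image`, `x0`, `y0`, `x1`, `y1`,
#' `confidence`.
#'
#' @param boxes Tibble/data frame with those columns.
#' @param path Output `.jsonl` path.
#' @return `write_boxes_jsonl()` returns `path` invisibly;
#'   `read_boxes_jsonl()` returns a tibble.
#' @export
write_boxes_jsonl <- function(boxes, path) {
  boxes <- tibble::as_tibble(boxes)
  lines <- vapply(seq_len(nrow(boxes)), function(i)
    jsonlite::toJSON(as.list(boxes[i, ]), auto_unbox = TRUE, digits = NA),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_boxes_jsonl
#' @export
read_boxes_jsonl <- function(path) {
  lines <- readLines(path)
  purrr::map_dfr(lines, function(l)
    tibble::as_tibble(jsonlite::fromJSON(l)))
}

#' Ground-truth JSON sidecar
#'
#' Writes the scalar/box parts of a phantom ground truth (detection box,
#' centroid, analytic readouts) as `<basename>.gt.json`; voxel masks are
#' stored separately as mask TIFFs.
#'
#' @param truth A ground-truth record from a phantom generator.
#' @param data_path Path of the data file the sidecar annotates.
#' @return The sidecar path, invisibly.
#' @export
write_ground_truth_json <- function(truth, data_path) {
  path <- paste0(tools::file_path_sans_ext(data_path), ".gt.json")
  out <- list(has_tissue = truth$has_tissue,
              centroid_mm = truth$centroid_mm,
              area_mm2 = truth$area_mm2,
              volume_mm3 = truth$volume_mm3,
              central_thickness_um = truth$central_thickness_um,
              optimal_z_index = truth$optimal_z_index)
  if (!is.null(truth$bbox_px))
    out$bbox_px <- truth$bbox_px[c("x0", "y0", "x1", "y1")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read and write screen readout tables as CSV
#'
#' Schema: `sample_id`, `group`, `timepoint`, `repetition`,
#' `thickness_um`, `area_mm2`, `volume_mm3`. A zero-row table round-trips
#' to zero rows with the schema header intact.
#'
#' @param data Screen tibble.
#' @param path CSV path.
#' @return `write_screen_csv()` returns `path` invisibly;
#'   `read_screen_csv()` returns a tibble.
#' @export
write_screen_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' @rdname write_screen_csv
#' @export
read_screen_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    group = readr::col_character(),
                    timepoint = readr::col_character(),
                    repetition = readr::col_integer(),
                    .default = readr::col_double()))
}

#' Load a screen configuration from YAML or JSON
#'
#' Unknown top-level keys are warned about and ignored (forward
#' compatibility); known keys override the [screen_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` config file.
#' @return A `screen_config` object.
#' @export
read_screen_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(screen_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    warning("ignoring unknown config keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(screen_config, raw[intersect(names(raw), known)])
}
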