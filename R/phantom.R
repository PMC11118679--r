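#' Specification of a synthetic tissue phantom
#'
#' A `phantom_spec` fully describes one synthetic well / OCT acquisition:
#' the plate-view camera geometry, the OCT sampling grid, the explant
#' footprint and thickness profile, the supporting-membrane layer, and the
#' intensity-artifact model (multiplicative speckle, smooth reflectance
#' drift, saturated specular columns). Together with a seed it determines
#' every generated pixel bit-for-bit, and each generator returns the exact
#' ground truth alongside the data, so downstream detection, segmentation
#' and morphometry can be tested without any instrument data.
#'
#' The default geometry mirrors a visible-light OCT explant screen: a
#' 30 x 30 mm well field of view for the plate camera, a 6 x 6 mm OCT field
#' sampled at 500 A-lines x 500 B-scans with 2 repeated A-scans averaged
#' per position, and an axial grid of 512 pixels at 2 um spacing.
#'
#' @param image_size_px Integer pair, well-image size as (rows, cols).
#' @param well_fov_mm Width of the square well field of view in mm.
#' @param oct_fov_mm Width of the square OCT field of view in mm.
#' @param n_alines Lateral A-line samples per B-scan.
#' @param n_bscans Number of B-scans per volume.
#' @param n_repeats Repeated acquisitions averaged into each stored B-scan.
#' @param axial_px Depth samples per A-line.
#' @param dz_um Axial pixel spacing in um.
#' @param tissue_center_mm Numeric pair (x, y): explant centroid in well
#'   coordinates (mm, origin at the image top-left).
#' @param tissue_radii_mm Numeric pair: semi-axes of the elliptical explant
#'   footprint in mm.
#' @param thickness_profile Named list describing the explant thickness
#'   field: `list(type = "uniform", thickness_um = )`,
#'   `list(type = "dome", peak_um = , edge_um = )` (paraboloid, thickest at
#'   the centre), or `list(type = "bimodal", low_um = , high_um = )`
#'   (step along the x axis).
#' @param membrane_thickness_um,membrane_brightness Supporting-membrane
#'   layer: its thickness in um and its (bright) reflectance level.
#' @param membrane_gap_um Clear gap between the tissue underside and the
#'   membrane top, in um.
#' @param speckle_sd Log-normal sigma of the multiplicative speckle; 0
#'   gives a noise-free phantom.
#' @param reflectance_drift Amplitude of the smooth multiplicative
#'   reflectance-inhomogeneity field (fraction of the base reflectance).
#' @param specular_column_rate Probability that any given lateral position
#'   is replaced by a fully saturated specular-reflection column.
#' @param occupancy Probability that the well contains a tissue explant.
#' @param seed Default integer seed used when a generator is called without
#'   an explicit one.
#'
#' @return An object of class `phantom_spec` (a validated list).
#' @seealso [make_well_image()], [make_oct_volume()], [make_depth_stack()],
#'   [make_screen_dataset()]
#' @export
#' @examples
#' spec <- phantom_spec(n_alines = 64, n_bscans = 16, axial_px = 128)
#' vol <- make_oct_volume(spec, seed = 1)
#' vol$truth$area_mm2
phantom_spec <- function(image_size_px = c(600L, 600L),
                         well_fov_mm = 30,
                         oct_fov_mm = 6,
                         n_alines = 500L,
                         n_bscans = 500L,
                         n_repeats = 2L,
                         axial_px = 512L,
                         dz_um = 2,
                         tissue_center_mm = c(15, 15),
                         tissue_radii_mm = c(2.2, 2.2),
                         thickness_profile = list(type = "uniform",
                                                  thickness_um = 180),
                         membrane_thickness_um = 10,
                         membrane_brightness = 0.9,
                         membrane_gap_um = 20,
                         speckle_sd = 0.3,
                         reflectance_drift = 0.2,
                         specular_column_rate = 0.02,
                         occupancy = 1,
                         seed = 1L) {
  spec <- list(
    image_size_px = as.integer(image_size_px),
    well_fov_mm = well_fov_mm, oct_fov_mm = oct_fov_mm,
    n_alines = as.integer(n_alines), n_bscans = as.integer(n_bscans),
    n_repeats = as.integer(n_repeats), axial_px = as.integer(axial_px),
    dz_um = dz_um,
    tissue_center_mm = as.numeric(tissue_center_mm),
    tissue_radii_mm = as.numeric(tissue_radii_mm),
    thickness_profile = thickness_profile,
    membrane_thickness_um = membrane_thickness_um,
    membrane_brightness = membrane_brightness,
    membrane_gap_um = membrane_gap_um,
    speckle_sd = speckle_sd,
    reflectance_drift = reflectance_drift,
    specular_column_rate = specular_column_rate,
    occupancy = occupancy,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$image_size_px) != 2L || any(spec$image_size_px <= 0L))
    stop_param("image_size_px must be two positive integers")
  for (f in c("well_fov_mm", "oct_fov_mm", "dz_um", "membrane_thickness_um",
              "membrane_gap_um"))
    if (!is.numeric(spec[[f]]) || length(spec[[f]]) != 1L || spec[[f]] <= 0)
      stop_param(sprintf("%s must be a single positive number", f))
  for (f in c("n_alines", "n_bscans", "n_repeats", "axial_px"))
    if (spec[[f]] <= 0L) stop_param(sprintf("%s must be positive", f))
  if (any(spec$tissue_radii_mm <= 0))
    stop_param("tissue_radii_mm must be strictly positive")
  if (spec$occupancy < 0 || spec$occupancy > 1)
    stop_param("occupancy must lie in [0, 1]")
  if (spec$specular_column_rate < 0 || spec$specular_column_rate > 1)
    stop_param("specular_column_rate must lie in [0, 1]")
  if (spec$speckle_sd < 0 || spec$reflectance_drift < 0)
    stop_param("noise amplitudes must be non-negative")
  tp <- spec$thickness_profile
  if (is.null(tp$type) ||
      !tp$type %in% c("uniform", "dome", "bimodal"))
    stop_param("thickness_profile$type must be uniform, dome or bimodal")
  spec
}

# Thickness (um) of the profile at elliptical radius^2 rho2 and lateral
# x offset (mm, relative to footprint centre); vectorised over columns.
profile_thickness_um <- function(tp, rho2, x_rel_mm) {
  switch(tp$type,
    uniform = rep(tp$thickness_um, length(rho2)),
    dome = tp$peak_um - (tp$peak_um - tp$edge_um) * rho2,
    bimodal = ifelse(x_rel_mm < 0, tp$high_um, tp$low_um)
  )
}

# Closed-form integral of the profile over the elliptical footprint, mm^3.
profile_volume_mm3 <- function(tp, radii_mm) {
  ab <- prod(radii_mm)
  um_to_mm <- 1e-3
  switch(tp$type,
    uniform = pi * ab * tp$thickness_um * um_to_mm,
    dome = pi * ab * (tp$peak_um + tp$edge_um) / 2 * um_to_mm,
    bimodal = pi * ab * (tp$low_um + tp$high_um) / 2 * um_to_mm
  )
}

new_ground_truth <- function(has_tissue, bbox_px = NULL, centroid_mm = NULL,
                             mask = NULL, thickness_map_um = NULL,
                             area_mm2 = NA_real_, volume_mm3 = NA_real_,
                             central_thickness_um = NA_real_,
                             optimal_z_index = NA_integer_) {
  structure(list(has_tissue = has_tissue, bbox_px = bbox_px,
                 centroid_mm = centroid_mm, mask = mask,
                 thickness_map_um = thickness_map_um,
                 area_mm2 = area_mm2, volume_mm3 = volume_mm3,
                 central_thickness_um = central_thickness_um,
                 optimal_z_index = optimal_z_index),
            class = "oct_ground_truth")
}

#' Simulate a plate-view well image
#'
#' Emulates the picture a plate camera takes of one well: a bright, nearly
#' uniform background, optionally containing one darker elliptical explant,
#' with additive sensor noise. The returned ground truth carries the exact
#' half-open pixel bounding box and the centroid in mm.
#'
#' Whether the well is occupied is drawn with probability
#' `spec$occupancy`; `occupancy = 0` always yields an empty well and
#' `occupancy = 1` always an occupied one.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; identical `(spec, seed)` give bit-identical
#'   output.
#' @return A list with `image` (numeric matrix in \[0, 1\] with attribute
#'   `mm_per_pixel`) and `truth` (ground-truth record).
#' @export
make_well_image <- function(spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
  mm_per_pixel <- spec$well_fov_mm / nc
  withr::with_seed(seed, {
    has_tissue <- stats::runif(1) < spec$occupancy
    img <- matrix(0.82, nr, nc) +
      matrix(stats::rnorm(nr * nc, sd = 0.015), nr, nc)
    truth <- new_ground_truth(has_tissue = FALSE)
    if (has_tissue) {
      cx <- spec$tissue_center_mm[1]; cy <- spec$tissue_center_mm[2]
      a <- spec$tissue_radii_mm[1]; b <- spec$tissue_radii_mm[2]
      x <- (seq_len(nc) - 0.5) * mm_per_pixel
      y <- (seq_len(nr) - 0.5) * mm_per_pixel
      inside <- outer(((y - cy) / b)^2, ((x - cx) / a)^2, `+`) <= 1
      img[inside] <- 0.45 + stats::rnorm(sum(inside), sd = 0.02)
      cols <- which(apply(inside, 2, any)); rows <- which(apply(inside, 1, any))
      truth <- new_ground_truth(
        has_tissue = TRUE,
        bbox_px = bounding_box(min(cols) - 1, min(rows) - 1,
                               max(cols), max(rows), confidence = 1),
        centroid_mm = c(cx, cy)
      )
    }
    img <- pmin(pmax(img, 0), 1)
    attr(img, "mm_per_pixel") <- mm_per_pixel
    list(image = img, truth = truth)
  })
}

#' Simulate an OCT volume of a cultured explant
#'
#' Builds a stack of B-scans containing (top to bottom along depth)
#' background, a tissue slab whose thickness follows the spec's profile,
#' a clear gap, and a thin bright supporting membrane. The intensity model
#' is `base reflectance x (1 + drift field) x speckle`, with speckle drawn
#' log-normally (`sdlog = speckle_sd`, unit mean), plus a seeded fraction
#' `specular_column_rate` of lateral positions replaced by fully saturated
#' columns. `n_repeats` independent speckle realisations are averaged into
#' each stored B-scan, as repeated A-scans would be on the instrument.
#'
#' The ground truth marks tissue voxels only — never the membrane — and
#' carries the per-column thickness map (voxel count times `dz_um`) plus
#' analytic area and volume of the footprint/profile.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @param render If `FALSE`, skip the intensity rendering and return only
#'   the geometry and ground truth (fast path for morphometry tests on
#'   large grids).
#' @return A list with `volume` (class `oct_volume`: list of B-scan
#'   matrices `axial_px x n_alines` plus voxel spacings; `NULL` when
#'   `render = FALSE`) and `truth`, whose `mask` is a [seg_volume()].
#' @export
make_oct_volume <- function(spec, seed = spec$seed, render = TRUE) {
  validate_phantom_spec(spec)
  nx <- spec$n_alines; ny <- spec$n_bscans; nz <- spec$axial_px
  dz <- spec$dz_um
  dx <- spec$oct_fov_mm * 1000 / nx
  dy <- spec$oct_fov_mm * 1000 / ny
  tp <- spec$thickness_profile
  a <- spec$tissue_radii_mm[1]; b <- spec$tissue_radii_mm[2]
  cx <- spec$oct_fov_mm / 2; cy <- spec$oct_fov_mm / 2

  n_mem <- max(1L, round(spec$membrane_thickness_um / dz))
  gap_px <- max(1L, round(spec$membrane_gap_um / dz))
  mem_top <- nz - n_mem - round(0.1 * nz)  # membrane near the bottom
  tissue_bottom <- mem_top - gap_px - 1L   # deepest row tissue may occupy
  max_t <- switch(tp$type, uniform = tp$thickness_um, dome = tp$peak_um,
                  bimodal = max(tp$low_um, tp$high_um))
  if (round(max_t / dz) > tissue_bottom)
    stop_param("thickness profile exceeds the axial range axial_px * dz_um")

  x_mm <- (seq_len(nx) - 0.5) * dx / 1000
  y_mm <- (seq_len(ny) - 0.5) * dy / 1000

  # per-column tissue voxel counts (ny x nx)
  rho2 <- outer(((y_mm - cy) / b)^2, ((x_mm - cx) / a)^2, `+`)
  in_fp <- rho2 <= 1
  nvox <- matrix(0L, ny, nx)
  if (any(in_fp)) {
    xr <- matrix(rep(x_mm - cx, each = ny), ny, nx)
    t_um <- profile_thickness_um(tp, rho2[in_fp], xr[in_fp])
    nvox[in_fp] <- pmax(0L, as.integer(round(t_um / dz)))
  }
  thickness_gt <- new_thickness_map(nvox * dz, dx_um = dx, dy_um = dy)

  depth <- seq_len(nz)
  mem_rows <- depth >= mem_top & depth < mem_top + n_mem
  mask_frame <- function(j) {
    nv <- nvox[j, ]
    # tissue occupies rows (tissue_bottom - nv + 1) .. tissue_bottom
    m <- outer(depth, nv, function(z, n) z > tissue_bottom - n &
                                          z <= tissue_bottom)
    storage.mode(m) <- "integer"
    m
  }
  masks <- lapply(seq_len(ny), mask_frame)
  mask_vol <- seg_volume(masks, dx_um = dx, dy_um = dy, dz_um = dz)

  truth <- new_ground_truth(
    has_tissue = any(in_fp),
    centroid_mm = c(cx, cy),
    mask = mask_vol,
    thickness_map_um = thickness_gt,
    area_mm2 = pi * a * b,
    volume_mm3 = profile_volume_mm3(tp, spec$tissue_radii_mm),
    central_thickness_um = if (any(nvox > 0))
      central_mean_thickness(thickness_gt) else NA_real_
  )

  vol <- NULL
  if (render) {
    withr::with_seed(seed, {
      # one smooth multiplicative drift field per volume
      fx <- sample(1:2, 1); fy <- sample(1:2, 1)
      phx <- stats::runif(1, 0, 2 * pi); phy <- stats::runif(1, 0, 2 * pi)
      drift <- spec$reflectance_drift *
        outer(sin(2 * pi * fy * seq_len(ny) / ny + phy),
              sin(2 * pi * fx * seq_len(nx) / nx + phx))
      specular <- matrix(stats::runif(ny * nx) < spec$specular_column_rate,
                         ny, nx)
      bg0 <- 0.05; tis0 <- 0.55
      frames <- vector("list", ny)
      for (j in seq_len(ny)) {
        level <- matrix(bg0, nz, nx)
        tis <- masks[[j]] == 1L
        level[tis] <- tis0 * (1 + rep(drift[j, ], each = nz)[tis])
        level[mem_rows, ] <- spec$membrane_brightness
        if (spec$speckle_sd > 0) {
          acc <- matrix(0, nz, nx)
          for (r in seq_len(spec$n_repeats)) {
            spk <- matrix(stats::rlnorm(nz * nx,
                                        meanlog = -spec$speckle_sd^2 / 2,
                                        sdlog = spec$speckle_sd), nz, nx)
            acc <- acc + level * spk
          }
          frame <- acc / spec$n_repeats
        } else {
          frame <- level
        }
        if (any(specular[j, ])) frame[, specular[j, ]] <- 1
        frames[[j]] <- pmin(frame, 1)
      }
      vol <- oct_volume(frames, dx_um = dx, dy_um = dy, dz_um = dz,
                        n_repeats = spec$n_repeats)
    })
  }
  list(volume = vol, truth = truth)
}

#' Simulate an axial depth-sweep stack
#'
#' Produces `n_positions` B-scan frames whose mean intensities form a
#' strictly unimodal profile peaking at `optimal_index`: the construction
#' centres the per-frame noise so the frame mean equals the designed value
#' exactly, guaranteeing that an argmax over mean frame intensity recovers
#' the configured optimum.
#'
#' @param spec A [phantom_spec()]; only used for the frame size default.
#' @param n_positions Number of swept stage positions.
#' @param optimal_index 1-based index of the brightest position, in
#'   `[1, n_positions]`.
#' @param seed Integer seed.
#' @param frame_px Frame size (rows, cols) of each sweep B-scan.
#' @param step_mm Stage step between positions, in mm.
#' @return A list with `stack` (a [depth_stack()]) and `truth` with
#'   `optimal_z_index` set.
#' @export
make_depth_stack <- function(spec, n_positions, optimal_index,
                             seed = spec$seed, frame_px = c(48L, 48L),
                             step_mm = 0.1) {
  validate_phantom_spec(spec)
  if (n_positions < 1L) stop_param("n_positions must be >= 1")
  if (optimal_index < 1L || optimal_index > n_positions)
    stop_param("optimal_index must lie in [1, n_positions]")
  withr::with_seed(seed, {
    i <- seq_len(n_positions)
    w <- max(n_positions / 6, 1)
    target <- 0.1 + 0.7 * exp(-((i - optimal_index)^2) / (2 * w^2))
    frames <- lapply(i, function(k) {
      noise <- matrix(stats::rnorm(prod(frame_px), sd = 0.05),
                      frame_px[1], frame_px[2])
      target[k] + (noise - mean(noise))
    })
    stack <- depth_stack(positions = (i - 1) * step_mm, frames = frames)
    list(stack = stack,
         truth = new_ground_truth(has_tissue = TRUE,
                                  optimal_z_index = as.integer(optimal_index)))
  })
}

#' Simulate a grouped longitudinal screen table
#'
#' Draws per-sample, per-timepoint, per-repetition readouts for a two-group
#' control screen (negative = progressive thinning, positive = protective
#' treatment) under a normal hierarchical model: each sample's true readout
#' at a timepoint is drawn from `Normal(group mean, group SD)`, repetition
#' noise is `Normal(0, repeat_sd)`, and group means at the follow-up
#' timepoint equal `baseline x (1 + change_frac)` (group SDs scale by
#' `|1 + change_frac|`). Thickness parameters default to a
#' retinal-explant degeneration scenario (baseline 191.8 +/- 11.5 um; -30.3% in the negative
#' group, +30% in the positive group; repetition SD 0.4 um over 5 repeated
#' volumes); area and volume readouts are drawn under the same model with
#' their own defaults.
#'
#' @param n_negative,n_positive Samples per control group.
#' @param baseline_mean_um,baseline_sd_um Baseline thickness mean / SD (um).
#' @param negative_change_frac,positive_change_frac Fractional change of the
#'   group mean thickness from baseline to follow-up.
#' @param repeat_sd Thickness repetition (within-sample) SD in um.
#' @param n_repeats Repeated acquisitions (volumes) per sample & timepoint.
#' @param seed Integer seed.
#' @param area_params,volume_params Named lists with elements `mean`, `sd`,
#'   `negative_change`, `positive_change`, `repeat_sd` for the area (mm^2)
#'   and volume (mm^3) readouts.
#' @param timepoints Character pair naming the two timepoints.
#' @return A tibble with columns `sample_id`, `group`, `timepoint`,
#'   `repetition`, `thickness_um`, `area_mm2`, `volume_mm3`.
#' @export
make_screen_dataset <- function(n_negative = 4L, n_positive = 8L,
                                baseline_mean_um = 191.8,
                                baseline_sd_um = 11.5,
                                negative_change_frac = -0.303,
                                positive_change_frac = 0.30,
                                repeat_sd = 0.4,
                                n_repeats = 5L,
                                seed = 1L,
                                area_params = list(mean = 15.2, sd = 0.755,
                                                   negative_change = -0.20,
                                                   positive_change = 0,
                                                   repeat_sd = 0.039),
                                volume_params = list(mean = 2.92, sd = 0.107,
                                                     negative_change = -0.44,
                                                     positive_change = 0.30,
                                                     repeat_sd = 0.005),
                                timepoints = c("baseline", "day10")) {
  if (n_negative < 1L || n_positive < 1L)
    stop_param("group sizes must be positive")
  readouts <- list(
    thickness_um = list(mean = baseline_mean_um, sd = baseline_sd_um,
                        negative_change = negative_change_frac,
                        positive_change = positive_change_frac,
                        repeat_sd = repeat_sd),
    area_mm2 = area_params,
    volume_mm3 = volume_params
  )
  n_tot <- n_negative + n_positive
  design <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n_tot)),
    group = rep(c("negative", "positive"), c(n_negative, n_positive))
  )
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(design, timepoint = timepoints)
    for (nm in names(readouts)) {
      p <- readouts[[nm]]
      change <- ifelse(grid$group == "negative",
                       p$negative_change, p$positive_change)
      fac <- ifelse(grid$timepoint == timepoints[1], 1, 1 + change)
      grid[[paste0(".true_", nm)]] <-
        stats::rnorm(nrow(grid), mean = p$mean * fac, sd = p$sd * abs(fac))
    }
    out <- tidyr::expand_grid(grid, repetition = seq_len(n_repeats))
    for (nm in names(readouts)) {
      p <- readouts[[nm]]
      out[[nm]] <- out[[paste0(".true_", nm)]] +
        stats::rnorm(nrow(out), sd = p$repeat_sd)
      out[[paste0(".true_", nm)]] <- NULL
    }
    dplyr::arrange(out, .data$sample_id, .data$timepoint, .data$repetition)
  })
}
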