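#' Idealised motorised stage
#'
#' Stands in for the three linear stages of the instrument: it holds the
#' current (x, y, z) command voltages, moves exactly to every commanded
#' position, and records each motion so a screen run is fully auditable
#' (and a hardware driver could later implement the same interface).
#'
#' @param mm_per_volt Numeric pair for the x/y axes.
#' @return An object of class `simulated_stage` with methods accessed via
#'   [stage_move_xy()], [stage_move_z()] and [stage_log()].
#' @export
simulated_stage <- function(mm_per_volt = c(1, 1)) {
  env <- new.env(parent = emptyenv())
  env$voltage <- c(x = 0, y = 0, z = 0)
  env$mm_per_volt <- mm_per_volt
  env$log <- list()
  structure(env, class = "simulated_stage")
}

#' @rdname simulated_stage
#' @param stage A `simulated_stage`.
#' @param volts Numeric pair (x, y) of command voltages.
#' @param well Well id recorded with the motion.
#' @export
stage_move_xy <- function(stage, volts, well = NA_character_) {
  stopifnot(inherits(stage, "simulated_stage"))
  stage$voltage[c("x", "y")] <- volts
  stage$log[[length(stage$log) + 1L]] <-
    tibble::tibble(well = well, action = "move_xy",
                   x = volts[1], y = volts[2], z = stage$voltage[["z"]])
  invisible(stage)
}

#' @rdname simulated_stage
#' @param z Scalar z-axis command.
#' @export
stage_move_z <- function(stage, z, well = NA_character_) {
  stopifnot(inherits(stage, "simulated_stage"))
  stage$voltage[["z"]] <- z
  stage$log[[length(stage$log) + 1L]] <-
    tibble::tibble(well = well, action = "move_z",
                   x = stage$voltage[["x"]], y = stage$voltage[["y"]], z = z)
  invisible(stage)
}

#' @rdname simulated_stage
#' @export
stage_log <- function(stage) {
  stopifnot(inherits(stage, "simulated_stage"))
  if (length(stage$log) == 0L)
    return(tibble::tibble(well = character(), action = character(),
                          x = double(), y = double(), z = double()))
  dplyr::bind_rows(stage$log)
}

#' Screen configuration
#'
#' Describes one simulated plate pass: the plate layout (default 2 x 3,
#' the six-well format), the group assignment of each well (`"negative"`,
#' `"positive"`, or `"empty"`), the phantom acquisition geometry, the
#' per-group thickness model, the sweep policy (including the
#' skip-after-first-well cache, since the optimal axial position stays
#' constant across a plate), calibration, and the master seed that makes
#' the whole run reproducible.
#'
#' The default acquisition grid is deliberately smaller than a production
#' scan (64 A-lines x 24 B-scans x 96 depth pixels) so that simulated
#' screens run in seconds; pass a full-size [phantom_spec()] for
#' production-scale geometry.
#'
#' @param plate_rows,plate_cols Plate layout.
#' @param well_groups Character vector, one entry per well in row-major
#'   order from A1.
#' @param spec Base [phantom_spec()] for OCT acquisition.
#' @param group_thickness_um,group_thickness_sd_um Named vectors (by
#'   group) of the true mean thickness and its between-sample SD.
#' @param n_repetitions Volumes acquired per occupied well.
#' @param calibration A [stage_calibration()].
#' @param sweep List: `n_positions`, `optimal_index`, `skip_after_first`,
#'   optional `range`.
#' @param segmentation `"classical"` (reference path) or `"truth"`
#'   (oracle masks, for pipeline-closure testing).
#' @param timepoint Timepoint label stamped on the readouts.
#' @param seed Master seed.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(plate_rows = 2L, plate_cols = 3L,
                          well_groups = c("negative", "negative",
                                          "positive", "positive",
                                          "positive", "positive"),
                          spec = phantom_spec(n_alines = 64L, n_bscans = 24L,
                                              axial_px = 224L,
                                              image_size_px = c(240L, 240L)),
                          group_thickness_um = c(negative = 133.7,
                                                 positive = 249.3),
                          group_thickness_sd_um = c(negative = 8.4,
                                                    positive = 14.9),
                          n_repetitions = 5L,
                          calibration = stage_calibration(),
                          sweep = list(n_positions = 11L, optimal_index = 6L,
                                       skip_after_first = TRUE, range = NULL),
                          segmentation = c("classical", "truth"),
                          timepoint = "day10",
                          seed = 1L) {
  n_wells <- plate_rows * plate_cols
  if (length(well_groups) != n_wells)
    stop_param("well_groups must have one entry per well")
  bad <- setdiff(setdiff(unique(well_groups), "empty"),
                 names(group_thickness_um))
  if (length(bad) > 0L)
    stop_param(paste("no thickness model for group(s):",
                     paste(bad, collapse = ", ")))
  structure(list(plate_rows = as.integer(plate_rows),
                 plate_cols = as.integer(plate_cols),
                 well_groups = well_groups, spec = spec,
                 group_thickness_um = group_thickness_um,
                 group_thickness_sd_um = group_thickness_sd_um,
                 n_repetitions = as.integer(n_repetitions),
                 calibration = calibration, sweep = sweep,
                 segmentation = match.arg(segmentation),
                 timepoint = timepoint, seed = as.integer(seed)),
            class = "screen_config")
}

well_ids <- function(rows, cols) {
  as.vector(t(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0)))
}

# Deterministic per-(well, repetition) seed below 2^31.
derive_seed <- function(master, i, j = 0L) {
  as.integer((as.double(master) * 7919 + i * 104729 + j * 131) %% 2147483647)
}

#' Run a simulated screening pass over a plate
#'
#' Executes the full pipeline over every well in row-major order starting
#' at A1: simulate the plate-view image, detect the explant (empty wells
#' are logged as void and skipped), move the simulated stage to the
#' centroid, find the optimal axial position by depth sweep (performed
#' once per plate when `sweep$skip_after_first` is set, then reused),
#' acquire `n_repetitions` phantom volumes, segment each B-scan, and
#' reduce to thickness/area/volume readouts. When both control groups are
#' present with at least two samples each, an assay-quality report is
#' computed from the readouts.
#'
#' @param cfg A [screen_config()].
#' @param out_dir Optional output directory; when given, the readout CSV
#'   (`screen.csv`), QC report (`qc.json`) and run log (`log.csv`) are
#'   written there.
#' @return A list with `readouts` (tibble), `qc` (tibble or `NULL`),
#'   `log` (one row per pipeline stage per well) and `stage_log`.
#' @export
run_screen <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "screen_config"))
  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                            showWarnings = FALSE)
    if (!ok || file.access(out_dir, 2) != 0)
      stop(errorCondition(paste("output directory not writable:", out_dir),
                          class = c("octscreen_io_error", "error")))
  }
  ids <- well_ids(cfg$plate_rows, cfg$plate_cols)
  stage <- simulated_stage()
  log <- list()
  add_log <- function(well, step, detail = "") {
    log[[length(log) + 1L]] <<- tibble::tibble(well = well, step = step,
                                               detail = detail)
  }
  readouts <- list()
  cached_z <- NULL

  for (i in seq_along(ids)) {
    id <- ids[i]; grp <- cfg$well_groups[i]
    wseed <- derive_seed(cfg$seed, i)
    wspec <- cfg$spec
    wspec$occupancy <- if (grp == "empty") 0 else 1

    wi <- make_well_image(wspec, seed = wseed)
    det <- detect_tissue_baseline(wi$image)
    add_log(id, "detect", det$status)
    if (det$status == "void") next

    volts <- centroid_to_stage(det$centroid_mm, cfg$calibration)
    stage_move_xy(stage, volts, well = id)
    add_log(id, "move", sprintf("x=%.4f y=%.4f", volts[1], volts[2]))

    if (is.null(cached_z) || !isTRUE(cfg$sweep$skip_after_first)) {
      ds <- make_depth_stack(wspec, cfg$sweep$n_positions,
                             cfg$sweep$optimal_index,
                             seed = derive_seed(cfg$seed, i, 999L))
      opt <- find_optimal_depth(ds$stack, restrict_range = cfg$sweep$range)
      cached_z <- opt$position
      add_log(id, "sweep", sprintf("index=%d", opt$index))
    } else {
      add_log(id, "sweep", "skipped (cached)")
    }
    stage_move_z(stage, cached_z, well = id)

    true_thick <- withr::with_seed(derive_seed(cfg$seed, i, 1L),
      stats::rnorm(1, cfg$group_thickness_um[[grp]],
                   cfg$group_thickness_sd_um[[grp]]))
    vspec <- wspec
    vspec$thickness_profile <- list(type = "uniform",
                                    thickness_um = max(true_thick, 40))

    for (r in seq_len(cfg$n_repetitions)) {
      acq <- make_oct_volume(vspec, seed = derive_seed(cfg$seed, i, 10L + r))
      seg <- if (cfg$segmentation == "classical")
        segment_volume(acq$volume) else acq$truth$mask
      readouts[[length(readouts) + 1L]] <-
        dplyr::mutate(measure_readouts(seg, sample_id = id,
                                       timepoint = cfg$timepoint,
                                       repetition = r),
                      group = grp, .after = "sample_id")
    }
    add_log(id, "acquire", sprintf("%d repetitions", cfg$n_repetitions))
    add_log(id, "measure", "")
  }

  readouts <- if (length(readouts) > 0L) dplyr::bind_rows(readouts)
    else tibble::tibble(sample_id = character(), group = character(),
                        timepoint = character(), repetition = integer(),
                        thickness_um = double(), area_mm2 = double(),
                        volume_mm3 = double())
  qc <- NULL
  grp_n <- table(unique(readouts[c("sample_id", "group")])$group)
  if (all(c("negative", "positive") %in% names(grp_n)) &&
      all(grp_n[c("negative", "positive")] >= 2))
    qc <- qc_report(readouts)

  log_tbl <- dplyr::bind_rows(log)
  if (!is.null(out_dir)) {
    write_screen_csv(readouts, file.path(out_dir, "screen.csv"))
    readr::write_csv(log_tbl, file.path(out_dir, "log.csv"))
    if (!is.null(qc))
      jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(readouts = readouts, qc = qc, log = log_tbl,
       stage_log = stage_log(stage))
}
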