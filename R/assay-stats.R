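#' Per-group control statistics of one readout
#'
#' Summarises a screen table into the mean/SD/sample-count of the positive
#' and negative control groups for one readout, the inputs of the
#' Z'-factor and SSMD. Repetitions of the same sample are averaged first,
#' so within-sample repetition noise does not inflate the group SDs.
#'
#' @param data Screen table (tibble/data frame) with at least the columns
#'   `sample_id`, `group` and the readout.
#' @param readout Readout column name, e.g. `"thickness_um"`.
#' @param positive,negative Group labels of the positive / negative
#'   controls.
#' @param timepoint Optional timepoint to filter to (requires a
#'   `timepoint` column).
#' @param average_repetitions Average repetitions per sample before
#'   computing group statistics.
#' @return An object of class `group_stats`: list with `mu_positive`,
#'   `sigma_positive`, `n_positive`, `mu_negative`, `sigma_negative`,
#'   `n_negative`, `readout`.
#' @export
group_stats <- function(data, readout = "thickness_um",
                        positive = "positive", negative = "negative",
                        timepoint = NULL, average_repetitions = TRUE) {
  data <- tibble::as_tibble(data)
  if (!readout %in% names(data))
    stop_param(sprintf("readout column '%s' not found", readout))
  if (!is.null(timepoint))
    data <- dplyr::filter(data, .data$timepoint == !!timepoint)
  if (average_repetitions && "repetition" %in% names(data)) {
    data <- data |>
      dplyr::summarise(value = mean(.data[[readout]]),
                       .by = c("sample_id", "group"))
  } else {
    data <- dplyr::transmute(data, group = .data$group,
                             value = .data[[readout]])
  }
  one <- function(g) {
    v <- data$value[data$group == g]
    if (length(v) < 2L)
      stop_param(sprintf("group '%s' needs >= 2 samples", g))
    list(mu = mean(v), sigma = stats::sd(v), n = length(v))
  }
  p <- one(positive); n <- one(negative)
  structure(list(mu_positive = p$mu, sigma_positive = p$sigma,
                 n_positive = p$n, mu_negative = n$mu,
                 sigma_negative = n$sigma, n_negative = n$n,
                 readout = readout),
            class = "group_stats")
}

#' @rdname group_stats
#' @param mu_positive,sigma_positive,n_positive,mu_negative,sigma_negative,n_negative
#'   Directly supplied group statistics.
#' @export
group_stats_values <- function(mu_positive, sigma_positive,
                               mu_negative, sigma_negative,
                               n_positive = NA_integer_,
                               n_negative = NA_integer_,
                               readout = NA_character_) {
  if (sigma_positive < 0 || sigma_negative < 0)
    stop_param("group SDs must be non-negative")
  structure(list(mu_positive = mu_positive, sigma_positive = sigma_positive,
                 n_positive = n_positive, mu_negative = mu_negative,
                 sigma_negative = sigma_negative, n_negative = n_negative,
                 readout = readout),
            class = "group_stats")
}

#' Z'-factor of a control pair
#'
#' Screening-assay separability score
#' `Z' = 1 - 3 (sigma_p + sigma_n) / |mu_p - mu_n|`. Always at most 1;
#' values in \[0.5, 1\] are conventionally rated excellent for a
#' plate-based screen. The absolute value in the denominator makes the
#' score invariant to which group is labelled positive.
#'
#' @param g A [group_stats()] object.
#' @return Scalar Z'-factor.
#' @export
zprime <- function(g) {
  stopifnot(inherits(g, "group_stats"))
  d <- g$mu_positive - g$mu_negative
  if (d == 0)
    stop_param("Z'-factor is undefined when the group means coincide")
  1 - 3 * (g$sigma_positive + g$sigma_negative) / abs(d)
}

#' Strictly standardised mean difference (SSMD)
#'
#' Effect-strength score
#' `beta = (mu_p - mu_n) / sqrt(sigma_p^2 + sigma_n^2)`; its sign follows
#' the sign of the mean difference, and for typical control sample sizes
#' |beta| > 2 is rated excellent.
#'
#' @inheritParams zprime
#' @return Scalar SSMD.
#' @export
ssmd <- function(g) {
  stopifnot(inherits(g, "group_stats"))
  v <- g$sigma_positive^2 + g$sigma_negative^2
  if (v == 0)
    stop_param("SSMD is undefined when both group SDs are zero")
  (g$mu_positive - g$mu_negative) / sqrt(v)
}

#' Pooled standard deviation of replicate sets
#'
#' `sqrt( sum_i (n_i - 1) s_i^2 / sum_i (n_i - 1) )` over the supplied
#' sets, with `s_i` the sample SD (n-1 denominator) of set `i`. A single
#' set reduces to its own sample SD.
#'
#' @param sets A list of numeric vectors, each of length >= 2.
#' @return Scalar pooled SD.
#' @export
pooled_sd <- function(sets) {
  if (!is.list(sets)) sets <- list(sets)
  if (length(sets) == 0L) stop_param("need at least one replicate set")
  n <- lengths(sets)
  if (any(n < 2L)) stop_param("every replicate set needs >= 2 values")
  s2 <- vapply(sets, stats::var, numeric(1))
  sqrt(sum((n - 1) * s2) / sum(n - 1))
}

#' Repeatability of a readout
#'
#' Measurement repeatability: the pooled SD of the repeated acquisitions
#' of each sample, pooled over all samples (and conditions) in the design.
#' Requires >= 2 repetitions per sample.
#'
#' @param data Screen table with `sample_id`, `repetition`, the readout,
#'   and optionally grouping columns (`group`, `timepoint`) that define
#'   conditions.
#' @param readout Readout column name.
#' @return Scalar pooled SD in the readout's units.
#' @export
repeatability <- function(data, readout = "thickness_um") {
  data <- tibble::as_tibble(data)
  keys <- intersect(c("sample_id", "group", "timepoint"), names(data))
  sets <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_split() |>
    lapply(function(d) d[[readout]])
  pooled_sd(sets)
}

#' Reproducibility of a readout
#'
#' Between-sample spread under identical conditions: repetitions are first
#' averaged per sample, then the SD across sample means is computed per
#' condition (group x timepoint) and pooled across conditions. Averaging
#' repetitions first keeps repetition noise from inflating the
#' between-sample spread. Restrict to one condition via `condition`.
#'
#' @inheritParams repeatability
#' @param condition Optional named list / vector filtering condition
#'   columns, e.g. `c(group = "negative", timepoint = "baseline")`.
#' @return Scalar pooled between-sample SD.
#' @export
reproducibility <- function(data, readout = "thickness_um",
                            condition = NULL) {
  data <- tibble::as_tibble(data)
  if (!is.null(condition))
    for (nm in names(condition))
      data <- data[data[[nm]] == condition[[nm]], ]
  if (nrow(data) == 0L) stop_param("no rows left after condition filter")
  keys <- intersect(c("sample_id", "group", "timepoint"), names(data))
  per_sample <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(value = mean(.data[[readout]]), .groups = "drop")
  cond_keys <- setdiff(keys, "sample_id")
  sets <- if (length(cond_keys) > 0L) {
    per_sample |>
      dplyr::group_by(dplyr::across(dplyr::all_of(cond_keys))) |>
      dplyr::group_split() |>
      lapply(function(d) d$value)
  } else list(per_sample$value)
  pooled_sd(sets)
}

#' Percent change of a readout between timepoints
#'
#' `100 * (followup - baseline) / baseline`.
#'
#' @param baseline,followup Scalar readout values; `baseline` must be
#'   nonzero.
#' @return Signed percent change.
#' @export
percent_change <- function(baseline, followup) {
  if (any(baseline == 0)) stop_param("baseline must be nonzero")
  100 * (followup - baseline) / baseline
}

#' Qualitative assay-quality flags
#'
#' Labels the two quality axes: a Z'-factor in \[0.5, 1\] is "excellent"
#' (the conventional bar for plate-based screens), as is |SSMD| > 2 for
#' moderate control sample sizes; anything else is "below-threshold".
#'
#' @param zprime,ssmd Scalar scores.
#' @return Tibble with `metric`, `value`, `flag`.
#' @export
quality_flag <- function(zprime, ssmd) {
  tibble::tibble(
    metric = c("zprime", "ssmd"),
    value = c(zprime, ssmd),
    flag = c(if (zprime >= 0.5 && zprime <= 1) "excellent"
             else "below-threshold",
             if (abs(ssmd) > 2) "excellent" else "below-threshold")
  )
}

#' Two-group comparison of a readout
#'
#' Two-sided Welch two-sample t-test between the groups (the conventional
#' unequal-variance choice when only two control arms are compared).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2 with
#'   nonzero combined variance.
#' @return Two-sided p-value in (0, 1\].
#' @export
group_compare <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop_param("each group needs >= 2 values")
  if (stats::var(values_a) + stats::var(values_b) == 0)
    stop_param("groups have zero combined variance")
  stats::t.test(values_a, values_b, var.equal = FALSE)$p.value
}

#' Assay-quality report for one readout
#'
#' Computes the full QC panel of a two-group screen for one readout:
#' group statistics at the chosen timepoint, Z'-factor, SSMD, quality
#' flags, repeatability, reproducibility, and a Welch test p-value between
#' the control groups.
#'
#' @inheritParams group_stats
#' @return An object of class `assay_quality`; see [tidy.assay_quality()]
#'   and [glance.assay_quality()].
#' @export
assay_quality <- function(data, readout = "thickness_um",
                          positive = "positive", negative = "negative",
                          timepoint = NULL) {
  g <- group_stats(data, readout, positive, negative, timepoint)
  z <- zprime(g); b <- ssmd(g)
  data_t <- tibble::as_tibble(data)
  if (!is.null(timepoint))
    data_t <- dplyr::filter(data_t, .data$timepoint == !!timepoint)
  per_sample <- data_t |>
    dplyr::summarise(value = mean(.data[[readout]]),
                     .by = c("sample_id", "group"))
  p <- group_compare(per_sample$value[per_sample$group == positive],
                     per_sample$value[per_sample$group == negative])
  has_reps <- "repetition" %in% names(data_t) &&
    any(duplicated(data_t[intersect(c("sample_id", "group", "timepoint"),
                                    names(data_t))]))
  structure(list(
    readout = readout, group_stats = g, zprime = z, ssmd = b,
    flags = quality_flag(z, b),
    repeatability = if (has_reps) repeatability(data_t, readout) else NA_real_,
    reproducibility = reproducibility(data_t, readout),
    p_value = p, timepoint = timepoint
  ), class = "assay_quality")
}

#' @export
print.assay_quality <- function(x, ...) {
  g <- x$group_stats
  cat(sprintf("<assay_quality> readout: %s%s\n", x$readout,
              if (!is.null(x$timepoint)) paste0(" @ ", x$timepoint) else ""))
  cat(sprintf("  positive: %.3f +/- %.3f (n=%d)   negative: %.3f +/- %.3f (n=%d)\n",
              g$mu_positive, g$sigma_positive, g$n_positive,
              g$mu_negative, g$sigma_negative, g$n_negative))
  cat(sprintf("  Z' = %.3f (%s)   SSMD = %.3f (%s)\n",
              x$zprime, x$flags$flag[1], x$ssmd, x$flags$flag[2]))
  cat(sprintf("  repeatability = %.4g   reproducibility = %.4g   p = %.3g\n",
              x$repeatability, x$reproducibility, x$p_value))
  invisible(x)
}

#' Tidy an assay-quality report
#'
#' @param x An [assay_quality()] object.
#' @param ... Unused.
#' @return A tibble with one row per QC metric (`metric`, `value`,
#'   `flag`).
#' @method tidy assay_quality
#' @export
tidy.assay_quality <- function(x, ...) {
  tibble::tibble(
    metric = c("zprime", "ssmd", "repeatability", "reproducibility",
               "p_value"),
    value = c(x$zprime, x$ssmd, x$repeatability, x$reproducibility,
              x$p_value),
    flag = c(x$flags$flag, NA_character_, NA_character_,
             if (x$p_value < 0.05) "significant" else "not-significant")
  )
}

#' Glance at an assay-quality report
#'
#' @inheritParams tidy.assay_quality
#' @return A one-row tibble summarising the report.
#' @method glance assay_quality
#' @export
glance.assay_quality <- function(x, ...) {
  g <- x$group_stats
  tibble::tibble(readout = x$readout,
                 mu_positive = g$mu_positive, sigma_positive = g$sigma_positive,
                 mu_negative = g$mu_negative, sigma_negative = g$sigma_negative,
                 zprime = x$zprime, ssmd = x$ssmd,
                 repeatability = x$repeatability,
                 reproducibility = x$reproducibility,
                 p_value = x$p_value)
}

#' Assay-quality reports for every readout of a screen table
#'
#' @inheritParams assay_quality
#' @param readouts Readout columns to report on.
#' @return A tibble with one row per readout (the [glance.assay_quality()]
#'   rows bound together) plus a `flag_zprime` / `flag_ssmd` pair.
#' @export
qc_report <- function(data,
                      readouts = c("thickness_um", "area_mm2", "volume_mm3"),
                      positive = "positive", negative = "negative",
                      timepoint = NULL) {
  purrr::map_dfr(readouts, function(r) {
    q <- assay_quality(data, r, positive, negative, timepoint)
    dplyr::mutate(glance.assay_quality(q),
                  flag_zprime = q$flags$flag[1],
                  flag_ssmd = q$flags$flag[2])
  })
}
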