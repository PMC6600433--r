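#' Background-subtracted spot intensities
#'
#' Adds the raw spot intensity, median local foreground minus median local
#' background, to a spot table. The difference may be zero or negative for
#' spots near background; such values are kept here (the detection threshold
#' is computed in the raw domain) and become missing only at the log2 step.
#'
#' @param spots Spot tibble with columns `f_median` and `b_median`
#'   (see [simulate_spot_arrays()] for the full layout).
#' @return The input with an added `intensity` column; rows where either
#'   median is missing get `NA` intensity.
#' @export
spot_intensity <- function(spots) {
  stopifnot(all(c("f_median", "b_median") %in% names(spots)))
  mutate(as_tibble(spots), intensity = .data$f_median - .data$b_median)
}

#' Per-array detection threshold
#'
#' T_raw = trimmed mean of the negative-control spot intensities plus
#' `k_sd` times the array's background-region standard deviation;
#' T_log2 = log2(T_raw). The trim removes `trim` of the observations from
#' each tail (truncated to whole counts).
#'
#' @param spots Spot tibble with `intensity` (see [spot_intensity()]),
#'   `is_control` and `array_id` columns.
#' @param arrays Array tibble with `array_id` and `bg_sd` (background-region
#'   SD, raw intensity units).
#' @param trim Fraction trimmed from each tail of the control intensities.
#' @param k_sd Multiplier on the background SD.
#' @return Tibble with `array_id`, `t_raw`, `t_log2`.
#' @export
detection_threshold <- function(spots, arrays, trim = 0.10, k_sd = 5) {
  stopifnot("intensity" %in% names(spots))
  ctrl <- filter(spots, .data$is_control)
  out <- arrays %>%
    select("array_id", "bg_sd") %>%
    left_join(
      ctrl %>% group_by(.data$array_id) %>%
        summarise(ctrl_trim_mean = trimmed_mean(.data$intensity, trim),
                  n_controls = dplyr::n(), .groups = "drop"),
      by = "array_id"
    )
  if (any(is.na(out$ctrl_trim_mean))) {
    abort(sprintf("arrays without negative-control spots: %s",
                  paste(out$array_id[is.na(out$ctrl_trim_mean)], collapse = ", ")),
          class = "concordx_threshold_error")
  }
  out <- mutate(out, t_raw = .data$ctrl_trim_mean + k_sd * .data$bg_sd)
  if (any(out$t_raw <= 0)) {
    abort(sprintf("non-positive detection threshold (cannot log2-transform) on: %s",
                  paste(out$array_id[out$t_raw <= 0], collapse = ", ")),
          class = "concordx_threshold_error")
  }
  mutate(out, t_log2 = log2(.data$t_raw)) %>%
    select("array_id", "t_raw", "t_log2")
}

#' Log2-transform spot intensities
#'
#' Positive background-subtracted intensities become log2 values;
#' non-positive intensities become missing (they can never exceed a positive
#' detection threshold, so detection semantics are unaffected).
#'
#' @param spots Spot tibble with an `intensity` column.
#' @return The input with an added `log2_intensity` column.
#' @export
log2_spot_intensities <- function(spots) {
  stopifnot("intensity" %in% names(spots))
  mutate(as_tibble(spots),
         log2_intensity = if_else(.data$intensity > 0,
                                  log2(pmax(.data$intensity, 1e-300)),
                                  NA_real_))
}

# probe-level mean of unflagged log2 spot intensities, one row per
# array x probe (controls included; callers filter). 0 contributors -> NA.
probe_means <- function(spots) {
  spots %>%
    group_by(.data$array_id, .data$probe_id, .data$is_control) %>%
    summarise(
      n_spots = sum(!.data$flagged & !is.na(.data$log2_intensity)),
      mean_log2 = {
        v <- .data$log2_intensity[!.data$flagged & !is.na(.data$log2_intensity)]
        if (length(v) == 0) NA_real_ else mean(v)
      },
      .groups = "drop"
    )
}

#' Per-array normalization factors
#'
#' For each array, N is the trimmed mean (each tail) of that array's
#' unflagged log2 spot intensities restricted to the probes detected
#' (probe-level mean above T_log2) in every array. The grand mean of N
#' across arrays is the rescaling constant used by [normalize_spots()].
#'
#' @param spots Spot tibble with `log2_intensity`, `flagged`, `is_control`.
#' @param thresholds Output of [detection_threshold()].
#' @param trim Fraction trimmed from each tail.
#' @return Tibble with `array_id`, `n_factor`, `grand_mean_n`, and the size
#'   of the common detected probe set as attribute `"n_common"`.
#' @export
normalization_factor <- function(spots, thresholds, trim = 0.20) {
  stopifnot("log2_intensity" %in% names(spots))
  pm <- probe_means(filter(spots, !.data$is_control)) %>%
    left_join(thresholds, by = "array_id") %>%
    mutate(above = !is.na(.data$mean_log2) & .data$mean_log2 > .data$t_log2)
  n_arrays <- dplyr::n_distinct(spots$array_id)
  common <- pm %>%
    group_by(.data$probe_id) %>%
    summarise(all_above = sum(.data$above) == n_arrays, .groups = "drop") %>%
    filter(.data$all_above) %>%
    pull("probe_id")
  if (length(common) == 0) {
    n_above <- pm %>% group_by(.data$array_id) %>%
      summarise(n = sum(.data$above), .groups = "drop")
    abort(paste0(
      "no probe is detected in all arrays; per-array detected counts: ",
      paste(sprintf("%s=%d", n_above$array_id, n_above$n), collapse = ", ")),
      class = "concordx_normalization_error")
  }
  out <- spots %>%
    filter(!.data$is_control, .data$probe_id %in% common,
           !.data$flagged, !is.na(.data$log2_intensity)) %>%
    group_by(.data$array_id) %>%
    summarise(n_factor = trimmed_mean(.data$log2_intensity, trim),
              .groups = "drop")
  out <- mutate(out, grand_mean_n = mean(.data$n_factor))
  attr(out, "n_common") <- length(common)
  out
}

#' Normalize spot intensities and carry thresholds along
#'
#' Subtracts each array's normalization factor N from its log2 spot
#' intensities and rescales by adding the grand mean of N, so the
#' experiment-wide mean shift is zero. Detection thresholds are mapped into
#' the same normalized scale.
#'
#' @param spots Spot tibble with `log2_intensity`.
#' @param factors Output of [normalization_factor()].
#' @param thresholds Output of [detection_threshold()].
#' @return List with `spots` (added `log2_norm` column) and `thresholds`
#'   (added `t_log2_norm` column).
#' @export
normalize_spots <- function(spots, factors, thresholds) {
  sp <- spots %>%
    left_join(select(factors, "array_id", "n_factor", "grand_mean_n"),
              by = "array_id") %>%
    mutate(log2_norm = .data$log2_intensity - .data$n_factor + .data$grand_mean_n) %>%
    select(-"n_factor", -"grand_mean_n")
  th <- thresholds %>%
    left_join(select(factors, "array_id", "n_factor", "grand_mean_n"),
              by = "array_id") %>%
    mutate(t_log2_norm = .data$t_log2 - .data$n_factor + .data$grand_mean_n) %>%
    select(-"n_factor", -"grand_mean_n")
  list(spots = sp, thresholds = th)
}

#' Collapse triplicate spots to probe intensities
#'
#' Per probe per array, the mean over unflagged, non-missing normalized spot
#' intensities; flagged spots are omitted before averaging and a cell with
#' zero contributing spots is missing.
#'
#' @param spots Normalized spot tibble with a `log2_norm` column.
#' @return Tibble with `array_id`, `probe_id`, `is_control`, `intensity`
#'   (mean normalized log2), `n_spots` (contributing spot count).
#' @export
collapse_triplicates <- function(spots) {
  stopifnot("log2_norm" %in% names(spots))
  spots %>%
    group_by(.data$array_id, .data$probe_id, .data$is_control) %>%
    summarise(
      n_spots = sum(!.data$flagged & !is.na(.data$log2_norm)),
      intensity = {
        v <- .data$log2_norm[!.data$flagged & !is.na(.data$log2_norm)]
        if (length(v) == 0) NA_real_ else mean(v)
      },
      .groups = "drop"
    ) %>%
    select("array_id", "probe_id", "is_control", "intensity", "n_spots")
}

#' Detection filter
#'
#' A probe is retained when there is at least one treatment group in which
#' its intensity exceeds the (normalized) detection threshold in every
#' sample of that group; missing cells count as not above.
#'
#' @param probe_mat Output of [collapse_triplicates()].
#' @param thresholds Threshold tibble with `array_id` and `t_log2_norm`
#'   (or `t_log2` if the data are unnormalized).
#' @param design Tibble mapping `array_id` to a treatment `label`.
#' @return Tibble with `probe_id` and logical `detected`.
#' @export
detection_filter <- function(probe_mat, thresholds, design) {
  stopifnot(all(c("array_id", "label") %in% names(design)))
  tcol <- if ("t_log2_norm" %in% names(thresholds)) "t_log2_norm" else "t_log2"
  if (any(!probe_mat$array_id %in% design$array_id)) {
    abort("`design` does not cover every array.",
          class = "concordx_config_error")
  }
  groups <- unique(design$label)
  if (length(groups) == 0) {
    abort("`design` has no treatment groups.", class = "concordx_config_error")
  }
  dat <- probe_mat %>%
    filter(!.data$is_control) %>%
    left_join(select(design, "array_id", "label"), by = "array_id") %>%
    left_join(thresholds[, c("array_id", tcol)], by = "array_id") %>%
    mutate(above = !is.na(.data$intensity) & .data$intensity > .data[[tcol]])
  dat %>%
    group_by(.data$probe_id, .data$label) %>%
    summarise(all_above = all(.data$above), .groups = "drop") %>%
    group_by(.data$probe_id) %>%
    summarise(detected = any(.data$all_above), .groups = "drop")
}

#' Run the complete spot-level miRNA preprocessing chain
#'
#' Background subtraction, per-array detection thresholds (trim-mean of
#' negative controls + `k_sd` x background SD), log2 transform, trim-mean
#' normalization over the commonly detected probe set, triplicate collapse
#' and the detection filter.
#'
#' @inheritParams detection_threshold
#' @param design Tibble mapping `array_id` to treatment `label`.
#' @param trim_neg Trim fraction for the negative-control trimmed mean.
#' @param trim_norm Trim fraction for the normalization trimmed mean.
#' @return A list with `probe_matrix` (collapsed probe intensities, wide
#'   tibble `probe_id` x arrays), `probes` (long form with spot counts),
#'   `detected` (detection-filter verdicts), `thresholds`, `factors`, and
#'   `qc` (per-array threshold, factor and detected-probe count).
#' @export
preprocess_mirna <- function(spots, arrays, design = NULL,
                             trim_neg = 0.10, k_sd = 5, trim_norm = 0.20) {
  if (is.null(design)) design <- select(arrays, "array_id", "label")
  spots <- spot_intensity(spots)
  thresholds <- detection_threshold(spots, arrays, trim = trim_neg, k_sd = k_sd)
  spots <- log2_spot_intensities(spots)
  factors <- normalization_factor(spots, thresholds, trim = trim_norm)
  norm <- normalize_spots(spots, factors, thresholds)
  probes <- collapse_triplicates(norm$spots)
  detected <- detection_filter(probes, norm$thresholds, design)
  wide <- probes %>%
    filter(!.data$is_control) %>%
    select("probe_id", "array_id", "intensity") %>%
    tidyr::pivot_wider(names_from = "array_id", values_from = "intensity")
  qc <- norm$thresholds %>%
    left_join(factors, by = "array_id") %>%
    left_join(
      probes %>%
        filter(!.data$is_control) %>%
        left_join(norm$thresholds, by = "array_id") %>%
        group_by(.data$array_id) %>%
        summarise(n_detected_cells = sum(!is.na(.data$intensity) &
                                           .data$intensity > .data$t_log2_norm),
                  .groups = "drop"),
      by = "array_id")
  list(probe_matrix = wide, probes = probes, detected = detected,
       thresholds = norm$thresholds, factors = factors, qc = qc)
}
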