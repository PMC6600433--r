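#' Mask unreliable in vitro feature values
#'
#' Replaces values by `NA` according to the two-colour feature-extraction
#' quality rules: control spots; spots saturated on either channel; spots
#' reported as non-uniform outliers on either channel; and spots not well
#' above background on at least one channel (i.e. above background on
#' neither channel). Every value gets exactly one reason code; "present"
#' means reliable.
#'
#' @param features Long feature tibble with columns `probe_id`, `sample_id`,
#'   `value` and QC columns `is_control`, `saturated_ch1`, `saturated_ch2`,
#'   `nonuniform_ch1`, `nonuniform_ch2`, `above_bg_ch1`, `above_bg_ch2`
#'   (logicals).
#' @return The input with `value` masked to `NA` where unreliable and an
#'   added `reason` column with levels control spot / saturated /
#'   non-uniform outlier / not above background / present.
#' @export
mask_unreliable <- function(features) {
  qc_cols <- c("is_control", "saturated_ch1", "saturated_ch2",
               "nonuniform_ch1", "nonuniform_ch2",
               "above_bg_ch1", "above_bg_ch2")
  missing_cols <- setdiff(c("probe_id", "sample_id", "value", qc_cols),
                          names(features))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing QC column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "concordx_config_error")
  }
  features %>%
    as_tibble() %>%
    mutate(
      reason = case_when(
        .data$is_control ~ "control spot",
        .data$saturated_ch1 | .data$saturated_ch2 ~ "saturated",
        .data$nonuniform_ch1 | .data$nonuniform_ch2 ~ "non-uniform outlier",
        !(.data$above_bg_ch1 | .data$above_bg_ch2) ~ "not above background",
        TRUE ~ "present"
      ),
      value = if_else(.data$reason == "present", .data$value, NA_real_)
    )
}

#' Collate masked features into an expression matrix
#'
#' @param masked Output of [mask_unreliable()].
#' @param drop_controls Drop control-spot rows entirely (default).
#' @return Wide expression tibble (`probe_id` + one column per sample).
#' @export
collate_features <- function(masked, drop_controls = TRUE) {
  if (drop_controls) masked <- filter(masked, !.data$is_control)
  masked %>%
    select("probe_id", "sample_id", "value") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
}

#' Minimum-present filter
#'
#' Retains probes with at least `min_present` non-missing values across all
#' samples.
#'
#' @param expr Expression tibble (`probe_id` + samples) possibly with `NA`.
#' @param min_present Minimum number of present values.
#' @return Tibble with `probe_id`, `n_present`, `retained`.
#' @export
filter_min_present <- function(expr, min_present = 10) {
  m <- expr_to_matrix(expr)
  n_present <- unname(rowSums(!is.na(m)))
  tibble(probe_id = rownames(m), n_present = n_present,
         retained = n_present >= min_present)
}

#' Average replicate probes
#'
#' Collapses multiple probes of the same gene/composite probe to their
#' per-sample mean, omitting `NA`; a cell whose replicates are all `NA`
#' stays `NA`.
#'
#' @param expr Expression tibble (`probe_id` + samples).
#' @param probe_map Tibble mapping `probe_id` to `gene_id`. Probes absent
#'   from the map keep their own id.
#' @return Collapsed expression tibble with `probe_id` = gene id.
#' @export
average_replicate_probes <- function(expr, probe_map) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  expr %>%
    left_join(probe_map, by = "probe_id") %>%
    mutate(gene_id = dplyr::coalesce(.data$gene_id, .data$probe_id)) %>%
    select(-"probe_id") %>%
    group_by(.data$gene_id) %>%
    summarise(across(dplyr::everything(),
                     ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
              .groups = "drop") %>%
    rename(probe_id = "gene_id")
}

#' k-nearest-neighbour imputation
#'
#' Each missing value is replaced by the average of the values, at that
#' sample, of the `k` nearest probes (Euclidean distance over co-present
#' samples, rescaled by the fraction of co-present samples so sparsity does
#' not shrink distances). Present values are never altered. Neighbours must
#' be present at the target sample; if fewer than `k` candidates exist for
#' some missing cell after that restriction, the available ones are used,
#' and if none exist the probe's own mean is used.
#'
#' @param expr Expression tibble (`probe_id` + samples).
#' @param k Number of neighbours.
#' @return Complete expression tibble of the same shape.
#' @export
knn_impute <- function(expr, k = 10) {
  m <- expr_to_matrix(expr)
  if (!anyNA(m)) return(as_tibble(expr))
  p <- nrow(m)
  if (k >= p) {
    abort(sprintf("k = %d but only %d probes are available as neighbours.",
                  k, p),
          class = "concordx_config_error")
  }
  present <- !is.na(m)
  need <- which(rowSums(!present) > 0)
  out <- m
  n_col <- ncol(m)
  for (i in need) {
    xi <- m[i, ]
    pi_ <- present[i, ]
    # rescaled squared distance to every other probe
    diffs <- sweep(m, 2, xi)
    co <- present & matrix(pi_, nrow = p, ncol = n_col, byrow = TRUE)
    n_co <- rowSums(co)
    ss <- rowSums((diffs^2) * co, na.rm = TRUE)
    dist2 <- ifelse(n_co > 0, ss / n_co * n_col, Inf)
    dist2[i] <- Inf
    for (j in which(!pi_)) {
      cand <- which(present[, j] & is.finite(dist2))
      if (length(cand) == 0) {
        out[i, j] <- mean(xi, na.rm = TRUE)
      } else {
        nb <- cand[order(dist2[cand])][seq_len(min(k, length(cand)))]
        out[i, j] <- mean(m[nb, j])
      }
    }
  }
  matrix_to_expr(out)
}

# NA-omitting group means on the pre-imputation matrix; returns per-probe
# log2 fold change pieces and all-NA exclusion reasons for one contrast
pre_imputation_fc <- function(m_pre, treated_ids, control_ids) {
  mt <- m_pre[, treated_ids, drop = FALSE]
  mc <- m_pre[, control_ids, drop = FALSE]
  mean_t <- rowMeans(mt, na.rm = TRUE)
  mean_c <- rowMeans(mc, na.rm = TRUE)
  all_na_t <- rowSums(!is.na(mt)) == 0
  all_na_c <- rowSums(!is.na(mc)) == 0
  diff <- mean_t - mean_c
  tibble(
    probe_id = rownames(m_pre),
    log2_fc = unname(diff),
    fc = unname(sign(diff + (diff == 0)) * 2^abs(diff)),
    direction = if_else(diff >= 0, "up", "down"),
    excluded = all_na_t | all_na_c,
    exclude_reason = case_when(
      all_na_t & all_na_c ~ "all-NA in both groups",
      all_na_t ~ "all-NA in treated group",
      all_na_c ~ "all-NA in control group",
      TRUE ~ NA_character_
    )
  )
}

#' In vitro differential expression (SAM + pre-imputation fold change)
#'
#' Runs the full in vitro calling chain: minimum-present filtering,
#' optional replicate-probe averaging, k-NN imputation, then per contrast
#' (cell type x culture x time, treated vs vehicle control) a two-class
#' unpaired SAM at the target FDR. The final called set additionally
#' requires a linear fold change of at least `fc` computed from the data
#' before imputation, and takes its direction from the pre-imputation group
#' means. Probes with an all-`NA` group pre-imputation are excluded from
#' that contrast with a reason.
#'
#' @param expr Expression tibble (`probe_id` + samples) with `NA` where
#'   values were masked unreliable.
#' @param samples Sample sheet with `sample_id`, `exposure` plus optional
#'   `cell_type`, `culture`, `time` columns defining the contrasts.
#' @param control Exposure label of the vehicle control.
#' @param fdr Target SAM false discovery rate.
#' @param fc Linear fold-change threshold on pre-imputation fold changes.
#' @param min_present Minimum present values per probe.
#' @param k Neighbours for [knn_impute()].
#' @param probe_map Optional `probe_id` to `gene_id` map for
#'   [average_replicate_probes()].
#' @param n_perm,seed,s0 Passed to [sam_call()].
#' @param control_by_time Prefer control samples from the matching time
#'   point; falls back to all control samples of the cell type/culture.
#' @return Tibble of per-probe, per-contrast results with columns
#'   `cell_type`, `culture`, `time` (those present), `probe_id`, `log2_fc`,
#'   `fc`, `direction`, `d`, `sam_called`, `called`, `excluded`,
#'   `exclude_reason`. SAM fits are attached as attribute `"sam_fits"`.
#' @export
de_invitro <- function(expr, samples, control = "DM", fdr = 0.10, fc = 1.5,
                       min_present = 10, k = 10, probe_map = NULL,
                       n_perm = 500, seed = NULL, s0 = NULL,
                       control_by_time = TRUE) {
  samples <- as_tibble(samples)
  stopifnot(all(c("sample_id", "exposure") %in% names(samples)))
  fc_threshold <- fc  # result tibbles carry an `fc` column; avoid shadowing
  keep <- filter_min_present(expr, min_present = min_present)
  expr <- filter(expr, .data$probe_id %in% keep$probe_id[keep$retained])
  if (nrow(expr) == 0) {
    abort(sprintf(
      "no probe has >= %d present values (%d samples in the matrix).",
      min_present, nrow(samples)),
      class = "concordx_config_error")
  }
  if (!is.null(probe_map)) expr <- average_replicate_probes(expr, probe_map)
  m_pre <- expr_to_matrix(expr)
  imputed <- knn_impute(expr, k = k)
  m_imp <- expr_to_matrix(imputed)

  strata <- intersect(c("cell_type", "culture", "time"), names(samples))
  combos <- samples %>%
    filter(.data$exposure != control) %>%
    distinct(across(all_of(strata)))
  if (nrow(combos) == 0) {
    abort("no treated samples found.", class = "concordx_config_error")
  }
  sam_fits <- list()
  res <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    sel <- samples
    for (s in strata) {
      if (s == "time") next
      sel <- filter(sel, .data[[s]] == combos[[s]][i])
    }
    treated_sel <- sel$exposure != control
    if ("time" %in% strata) {
      treated_sel <- treated_sel & sel$time == combos[["time"]][i]
    }
    treated_s <- sel$sample_id[treated_sel]
    ctrl_pool <- filter(sel, .data$exposure == control)
    ctrl_s <- if (control_by_time && "time" %in% strata &&
                  any(ctrl_pool$time == combos[["time"]][i])) {
      ctrl_pool$sample_id[ctrl_pool$time == combos[["time"]][i]]
    } else {
      ctrl_pool$sample_id
    }
    labels <- c(rep("treated", length(treated_s)),
                rep("control", length(ctrl_s)))
    mm <- m_imp[, c(treated_s, ctrl_s), drop = FALSE]
    fit <- sam_call(mm, labels, target_fdr = fdr, n_perm = n_perm,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, i),
                    s0 = s0, treated = "treated")
    key <- paste(unlist(combos[i, ]), collapse = "|")
    sam_fits[[key]] <<- fit
    fc_tab <- pre_imputation_fc(m_pre, treated_s, ctrl_s)
    out <- fc_tab %>%
      left_join(select(fit$stats, "probe_id", "d", sam_called = "called"),
                by = "probe_id") %>%
      mutate(called = .data$sam_called & abs(.data$fc) >= fc_threshold &
               !.data$excluded)
    bind_cols(combos[rep(i, nrow(out)), , drop = FALSE], out)
  })
  attr(res, "sam_fits") <- sam_fits
  attr(res, "min_present") <- keep
  res
}
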