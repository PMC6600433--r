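#' Variance filter
#'
#' Removes probes whose sample variance across all samples exceeds
#' `cutoff`. Note the direction: high-variance probes are removed; this is
#' the screening rule as used, not a minimum-variability filter, and on
#' well-behaved log2 data it is typically vacuous.
#'
#' @param expr Expression tibble (`probe_id` + one column per sample).
#' @param cutoff Variance cutoff (log2 units squared).
#' @return Tibble with `probe_id`, `variance`, `retained`.
#' @export
variance_filter <- function(expr, cutoff = 0.2) {
  m <- expr_to_matrix(expr)
  if (ncol(m) < 2) abort("variance_filter needs >= 2 samples.",
                         class = "concordx_config_error")
  v <- unname(apply(m, 1, stats::var))
  tibble(probe_id = rownames(m), variance = v, retained = v <= cutoff)
}

# vectorized two-group pooled statistics; returns list of per-probe pieces
two_group_stats <- function(m, idx_t, idx_c) {
  n1 <- length(idx_c); n2 <- length(idx_t)
  m1 <- rowMeans(m[, idx_c, drop = FALSE])
  m2 <- rowMeans(m[, idx_t, drop = FALSE])
  ss1 <- rowSums((m[, idx_c, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, idx_t, drop = FALSE] - m2)^2)
  pooled <- (ss1 + ss2) / (n1 + n2 - 2)
  list(diff = m2 - m1, pooled = pooled, n1 = n1, n2 = n2,
       se = sqrt(pooled * (1 / n1 + 1 / n2)))
}

#' Two-group contrast test (one-way ANOVA)
#'
#' Compares one treatment group with its vehicle control: per probe, a
#' two-group one-way analysis-of-variance F test (identical to the square of
#' the pooled-variance t statistic) plus log2 and signed linear fold
#' changes. Probes with zero pooled variance are degenerate and get p = 1
#' with a warning.
#'
#' @param expr Expression tibble (`probe_id` + samples).
#' @param samples Sample sheet with `sample_id` and `label`.
#' @param treated Label of the treatment group.
#' @param control Label of the control group.
#' @return Tibble with `probe_id`, `log2_fc` (treated minus control),
#'   `fc` (2^|log2_fc| signed by direction), `direction`, `f_stat`,
#'   `p_value`.
#' @export
contrast_test <- function(expr, samples, treated, control = "DM") {
  m <- expr_to_matrix(expr)
  idx_t <- which(colnames(m) %in% samples$sample_id[samples$label == treated])
  idx_c <- which(colnames(m) %in% samples$sample_id[samples$label == control])
  if (length(idx_t) < 2 || length(idx_c) < 2) {
    abort(sprintf("contrast %s vs %s needs >= 2 samples per group.",
                  treated, control),
          class = "concordx_config_error")
  }
  st <- two_group_stats(m, idx_t, idx_c)
  f_stat <- (st$diff / st$se)^2
  df2 <- st$n1 + st$n2 - 2
  p <- pf(f_stat, 1, df2, lower.tail = FALSE)
  degen <- st$pooled <= 0
  if (any(degen)) {
    warn(sprintf("%d probe(s) with zero pooled variance; p set to 1.",
                 sum(degen)))
    p[degen] <- 1
    f_stat[degen] <- 0
  }
  # identical group means on constant data: define p = 1, not NaN
  p[st$diff == 0 & degen] <- 1
  tibble(
    probe_id = rownames(m),
    log2_fc = unname(st$diff),
    fc = unname(sign(st$diff + (st$diff == 0)) * 2^abs(st$diff)),
    direction = if_else(st$diff >= 0, "up", "down"),
    f_stat = unname(f_stat),
    p_value = unname(p)
  )
}

#' Call differential expression with p, FDR and fold-change thresholds
#'
#' Benjamini-Hochberg q-values are computed within the contrast; a probe is
#' called when p < `alpha`, q <= `fdr` and linear |FC| >= `fc` (i.e. at
#' least `fc`-fold up or down).
#'
#' @param results Tibble from [contrast_test()] (columns `p_value`, `fc`).
#' @param alpha Raw p-value threshold.
#' @param fdr False-discovery-rate threshold on BH q-values.
#' @param fc Linear fold-change threshold (>= 1).
#' @return The input with added `q_value` and `called` columns.
#' @export
call_de <- function(results, alpha = 0.05, fdr = 0.10, fc = 1.5) {
  stopifnot(all(c("p_value", "fc") %in% names(results)))
  fc_threshold <- fc  # the tibble has an `fc` column; don't let it shadow
  mutate(as_tibble(results),
         q_value = p.adjust(.data$p_value, method = "BH"),
         called = .data$p_value < alpha & .data$q_value <= fdr &
           abs(.data$fc) >= fc_threshold)
}

#' In vivo differential expression across all dose-by-time contrasts
#'
#' Applies the variance filter, then for every non-control treatment group
#' at every time point runs the two-group contrast against the vehicle
#' control of the same time point and calls significance with
#' p < `alpha`, BH FDR <= `fdr` and |FC| >= `fc`.
#'
#' @param expr Expression tibble (`probe_id` + samples); must be complete
#'   (no missing values).
#' @param samples Sample sheet with `sample_id`, `label` and optionally
#'   `group`, `time`, `compartment`. When `group`/`time` are absent, `label`
#'   itself is the group and a single implicit time point is used.
#' @param control Group label of the vehicle control.
#' @param alpha,fdr,fc Calling thresholds, see [call_de()].
#' @param variance_cutoff Cutoff for [variance_filter()].
#' @return Tibble of per-probe results for all contrasts, with columns
#'   `group`, `time`, `compartment` (if present), `probe_id`, `log2_fc`,
#'   `fc`, `direction`, `f_stat`, `p_value`, `q_value`, `called`.
#' @export
de_invivo <- function(expr, samples, control = "DM",
                      alpha = 0.05, fdr = 0.10, fc = 1.5,
                      variance_cutoff = 0.2) {
  m <- expr_to_matrix(expr)
  if (anyNA(m)) {
    abort("in vivo matrices must be complete (no NA).",
          class = "concordx_config_error")
  }
  samples <- as_tibble(samples)
  if (!"group" %in% names(samples)) samples$group <- samples$label
  if (!"time" %in% names(samples)) samples$time <- "all"
  vf <- variance_filter(expr, cutoff = variance_cutoff)
  keep <- vf$probe_id[vf$retained]
  expr_f <- filter(expr, .data$probe_id %in% keep)

  combos <- samples %>%
    filter(.data$group != control) %>%
    distinct(.data$group, .data$time)
  res <- purrr::pmap_dfr(combos, function(group, time) {
    sub <- filter(samples, .data$time == !!time,
                  .data$group %in% c(!!group, control))
    sub <- mutate(sub, label = .data$group)
    out <- contrast_test(
      expr_f[, c("probe_id", intersect(names(expr_f), sub$sample_id))],
      sub, treated = group, control = control)
    out <- call_de(out, alpha = alpha, fdr = fdr, fc = fc)
    mutate(out, group = !!group, time = !!time, .before = 1)
  })
  if ("compartment" %in% names(samples)) {
    comp <- distinct(samples, .data$compartment)
    if (nrow(comp) == 1) res <- mutate(res, compartment = comp$compartment[[1]], .before = 1)
  }
  attr(res, "variance_filter") <- vf
  res
}
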