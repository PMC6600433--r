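#' Simulation configuration for synthetic microarray experiments
#'
#' Bundles and validates the knobs of the synthetic-data generators:
#' spot-level miRNA arrays, probe-level log2 expression matrices (in vivo
#' and in vitro designs) and human-mouse ortholog maps. The defaults emulate
#' a long-term rodent inhalation study design: eight animals per exposure
#' group, probes spotted in triplicate, a handful of negative-control spots
#' per array.
#'
#' @param n_probes Number of (non-control) probes in the probe universe.
#' @param n_negative_controls Number of negative-control spot positions per
#'   array (miRNA spot arrays only).
#' @param spots_per_probe Technical replicate spots per probe per array.
#' @param groups Data frame with columns `label` and `n` giving the sample
#'   (or animal) count per stratum; extra columns (e.g. `time`, `compartment`,
#'   `cell_type`, `culture`, `exposure`) are carried into the sample sheet.
#' @param control_label Label of the vehicle-control stratum (dispersion
#'   media); planted effects are expressed relative to it.
#' @param planted_effects Data frame with columns `probe_id`, `label`
#'   (stratum) and `lfc` (log2 fold change planted in that stratum). Empty by
#'   default (pure null).
#' @param noise_sd Between-sample biological + technical noise, log2 units.
#' @param spot_noise_sd Extra spot-to-spot noise within a triplicate, log2
#'   units (spot arrays only).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-probe
#'   baseline log2 signal.
#' @param nc_log2 Log2 of the non-specific signal at negative-control spots.
#' @param background_mean,background_sd Raw-intensity background level and
#'   its spatial standard deviation (the "non-spot area" SD recorded per
#'   array).
#' @param flag_rate Probability that a spot is flagged poor-quality
#'   (independently per spot).
#' @param na_rate Probability that a value is masked unreliable (in vitro
#'   matrices only).
#' @param seed Integer seed; all generators are fully reproducible from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 50, groups = data.frame(label = c("DM", "MWCNT"), n = c(4, 4)))
sim_config <- function(n_probes = 500,
                       n_negative_controls = 24,
                       spots_per_probe = 3,
                       groups = data.frame(label = c("DM", "MWCNT_80"), n = c(8L, 8L)),
                       control_label = "DM",
                       planted_effects = NULL,
                       noise_sd = 0.2,
                       spot_noise_sd = 0.1,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       nc_log2 = 3,
                       background_mean = 50,
                       background_sd = 4,
                       flag_rate = 0.02,
                       na_rate = 0,
                       seed = 1L) {
  assert_count(n_probes, "n_probes")
  assert_count(n_negative_controls, "n_negative_controls")
  assert_count(spots_per_probe, "spots_per_probe")
  assert_prob(flag_rate, "flag_rate")
  assert_prob(na_rate, "na_rate")
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    abort("`noise_sd` must be > 0.", class = "concordx_config_error")
  }
  if (!is.data.frame(groups) || !all(c("label", "n") %in% names(groups))) {
    abort("`groups` must be a data frame with columns `label` and `n`.",
          class = "concordx_config_error")
  }
  if (any(groups$n < 1)) {
    abort("`groups$n` must all be >= 1.", class = "concordx_config_error")
  }
  if (anyDuplicated(groups$label)) {
    abort("`groups$label` must be unique.", class = "concordx_config_error")
  }
  if (!control_label %in% groups$label) {
    abort("`control_label` must appear in `groups$label`.",
          class = "concordx_config_error")
  }
  probe_ids <- sprintf("probe_%04d", seq_len(n_probes))
  if (is.null(planted_effects)) {
    planted_effects <- tibble(probe_id = character(), label = character(),
                              lfc = numeric())
  }
  planted_effects <- as_tibble(planted_effects)
  if (nrow(planted_effects) > 0) {
    if (!all(c("probe_id", "label", "lfc") %in% names(planted_effects))) {
      abort("`planted_effects` needs columns probe_id, label, lfc.",
            class = "concordx_config_error")
    }
    bad <- setdiff(planted_effects$probe_id, probe_ids)
    if (length(bad) > 0) {
      abort(sprintf("`planted_effects` names probes outside the universe: %s",
                    paste(head(bad, 5), collapse = ", ")),
            class = "concordx_config_error")
    }
    if (!all(planted_effects$label %in% groups$label)) {
      abort("`planted_effects$label` must match `groups$label`.",
            class = "concordx_config_error")
    }
  }
  structure(list(
    n_probes = as.integer(n_probes),
    n_negative_controls = as.integer(n_negative_controls),
    spots_per_probe = as.integer(spots_per_probe),
    groups = as_tibble(groups),
    control_label = control_label,
    planted_effects = planted_effects,
    noise_sd = noise_sd,
    spot_noise_sd = spot_noise_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    nc_log2 = nc_log2,
    background_mean = background_mean,
    background_sd = background_sd,
    flag_rate = flag_rate,
    na_rate = na_rate,
    seed = as.integer(seed),
    probe_ids = probe_ids
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_probes, "probes,",
      sum(x$groups$n), "samples in", nrow(x$groups), "groups,",
      nrow(x$planted_effects), "planted effects, seed", x$seed, "\n")
  invisible(x)
}

# ground truth shared by the generators
planted_truth <- function(config) {
  pe <- config$planted_effects
  tibble(
    probe_id = pe$probe_id,
    label = pe$label,
    lfc = pe$lfc,
    direction = if_else(pe$lfc >= 0, "up", "down")
  )
}

#' Simulate spot-level miRNA microarrays
#'
#' Emits one array per sample with `spots_per_probe` triplicate spots per
#' probe plus negative-control spots. The raw foreground of a spot is
#' background + 2^(baseline + planted shift + noise), so downstream
#' median-background subtraction recovers a log-normal probe signal;
#' negative controls carry only a small non-specific signal. A fraction of
#' spots is flagged poor-quality (independently per spot) and each array
#' records its background-region standard deviation.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{spots}{tibble of all spots: `array_id`, `block`, `row`, `column`,
#'       `probe_id`, `f_median`, `b_median`, `flagged`, `is_control`.}
#'     \item{arrays}{tibble with one row per array: `array_id`, `sample_id`,
#'       `label` (stratum) and `bg_sd` plus any extra design columns.}
#'     \item{truth}{planted ground truth, see [sim_config()].}
#'   }
#' @export
simulate_spot_arrays <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  groups <- config$groups
  design <- tidyr::uncount(groups, weights = .data$n, .id = "replicate")
  design <- mutate(design,
                   sample_id = sprintf("%s_s%02d", .data$label, .data$replicate),
                   array_id = sprintf("array_%03d", row_number()))
  # per-probe baselines are drawn once so arrays share a probe-level profile
  set.seed(derive_seed(config$seed, 0L))
  baseline <- rnorm(config$n_probes, config$baseline_log2_mean,
                    config$baseline_log2_sd)
  names(baseline) <- config$probe_ids
  shift <- matrix(0, nrow = config$n_probes, ncol = nrow(groups),
                  dimnames = list(config$probe_ids, groups$label))
  pe <- config$planted_effects
  if (nrow(pe) > 0) shift[cbind(pe$probe_id, pe$label)] <- pe$lfc

  nc_ids <- sprintf("NC_%03d", seq_len(config$n_negative_controls))
  spp <- config$spots_per_probe

  one_array <- function(i) {
    set.seed(derive_seed(config$seed, i))
    lab <- design$label[i]
    # sample-level expression, shared by the triplicate spots of a probe
    expr <- baseline + shift[, lab] + rnorm(config$n_probes, 0, config$noise_sd)
    probe_rep <- rep(config$probe_ids, each = spp)
    sig_log2 <- rep(expr, each = spp) +
      rnorm(config$n_probes * spp, 0, config$spot_noise_sd)
    nc_sig <- 2^(config$nc_log2 +
                   rnorm(config$n_negative_controls, 0, config$spot_noise_sd))
    signal <- c(2^sig_log2, nc_sig)
    n_spot <- length(signal)
    b <- pmax(0, rnorm(n_spot, config$background_mean, config$background_sd))
    f <- pmax(0, b + signal + rnorm(n_spot, 0, config$background_sd))
    tibble(
      array_id = design$array_id[i],
      block = 1L,
      row = ((seq_len(n_spot) - 1L) %/% 40L) + 1L,
      column = ((seq_len(n_spot) - 1L) %% 40L) + 1L,
      probe_id = c(probe_rep, nc_ids),
      f_median = f,
      b_median = b,
      flagged = runif(n_spot) < config$flag_rate,
      is_control = c(rep(FALSE, config$n_probes * spp),
                     rep(TRUE, config$n_negative_controls)),
      bg_sd = sd(b)
    )
  }

  spots <- purrr::map_dfr(seq_len(nrow(design)), one_array)
  arrays <- distinct(spots, .data$array_id, .data$bg_sd) %>%
    left_join(select(design, -dplyr::any_of(c("n", "replicate"))), by = "array_id") %>%
    select("array_id", "sample_id", "label", "bg_sd", dplyr::everything())
  spots$bg_sd <- NULL
  list(spots = spots, arrays = arrays, truth = planted_truth(config))
}

#' Simulate a probe-level log2 expression matrix
#'
#' In the in vivo design the matrix is complete (single-channel log2
#' intensities); in the in vitro design values are centred log-ratios against
#' a universal reference and a fraction `na_rate` of cells is masked `NA`,
#' emulating unreliable spots.
#'
#' @param config A [sim_config()].
#' @param design `"invivo"` or `"invitro"`.
#' @return A list with `expr` (tibble: `probe_id` + one column per sample),
#'   `samples` (the sample sheet) and `truth`.
#' @export
simulate_expr_matrix <- function(config, design = c("invivo", "invitro")) {
  stopifnot(inherits(config, "sim_config"))
  design <- match.arg(design)
  if (design == "invivo" && config$na_rate > 0) {
    abort("in vivo matrices are complete: `na_rate` must be 0 for design = \"invivo\".",
          class = "concordx_config_error")
  }
  groups <- config$groups
  sheet <- tidyr::uncount(groups, weights = .data$n, .id = "replicate")
  sheet <- mutate(sheet,
                  sample_id = sprintf("%s_s%02d", .data$label, .data$replicate)) %>%
    select("sample_id", "label", dplyr::everything(),
           -dplyr::any_of(c("replicate", "n")))

  set.seed(derive_seed(config$seed, 0L))
  base_mu <- if (design == "invivo") config$baseline_log2_mean else 0
  base_sd <- if (design == "invivo") config$baseline_log2_sd else 0.25
  baseline <- rnorm(config$n_probes, base_mu, base_sd)
  shift <- matrix(0, nrow = config$n_probes, ncol = nrow(groups),
                  dimnames = list(config$probe_ids, groups$label))
  pe <- config$planted_effects
  if (nrow(pe) > 0) shift[cbind(pe$probe_id, pe$label)] <- pe$lfc

  n_samp <- nrow(sheet)
  set.seed(derive_seed(config$seed, 1L))
  m <- baseline +
    shift[, sheet$label, drop = FALSE] +
    matrix(rnorm(config$n_probes * n_samp, 0, config$noise_sd),
           nrow = config$n_probes)
  dimnames(m) <- list(config$probe_ids, sheet$sample_id)
  if (design == "invitro" && config$na_rate > 0) {
    set.seed(derive_seed(config$seed, 2L))
    m[runif(length(m)) < config$na_rate] <- NA_real_
  }
  list(expr = matrix_to_expr(m), samples = sheet, truth = planted_truth(config))
}

#' Simulate a human-mouse ortholog map
#'
#' Builds a symbol-level map with the requested counts of one-to-one,
#' one-to-many (one human symbol to `fan_out` mouse symbols) and many-to-many
#' (two human symbols fully crossed with `fan_out` mouse symbols) relation
#' clusters. Symbols are disjoint across classes.
#'
#' @param n_one_to_one,n_one_to_many,n_many_to_many Cluster counts (>= 0).
#' @param fan_out Mouse symbols per ambiguous cluster.
#' @param seed Integer seed (used only to shuffle row order, so the emitted
#'   file order is not informative).
#' @return A tibble with columns `human_symbol`, `mouse_symbol`, `relation`.
#' @export
simulate_ortholog_map <- function(n_one_to_one, n_one_to_many = 0,
                                  n_many_to_many = 0, fan_out = 2, seed = 1L) {
  assert_count(n_one_to_one, "n_one_to_one", min = 0L)
  assert_count(n_one_to_many, "n_one_to_many", min = 0L)
  assert_count(n_many_to_many, "n_many_to_many", min = 0L)
  assert_count(fan_out, "fan_out", min = 2L)
  oo <- if (n_one_to_one > 0) {
    tibble(human_symbol = sprintf("HOO%04d", seq_len(n_one_to_one)),
           mouse_symbol = sprintf("Moo%04d", seq_len(n_one_to_one)),
           relation = "one-to-one")
  }
  om <- if (n_one_to_many > 0) {
    tidyr::crossing(i = seq_len(n_one_to_many), j = seq_len(fan_out)) %>%
      mutate(human_symbol = sprintf("HOM%04d", .data$i),
             mouse_symbol = sprintf("Mom%04d_%d", .data$i, .data$j),
             relation = "one-to-many") %>%
      select("human_symbol", "mouse_symbol", "relation")
  }
  mm <- if (n_many_to_many > 0) {
    tidyr::crossing(i = seq_len(n_many_to_many), h = 1:2, j = seq_len(fan_out)) %>%
      mutate(human_symbol = sprintf("HMM%04d_%d", .data$i, .data$h),
             mouse_symbol = sprintf("Mmm%04d_%d", .data$i, .data$j),
             relation = "many-to-many") %>%
      select("human_symbol", "mouse_symbol", "relation")
  }
  map <- bind_rows(oo, om, mm)
  set.seed(derive_seed(seed, 3L))
  map[sample.int(nrow(map)), ]
}
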