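#' Simulate a full cross-species concordance experiment
#'
#' Builds matched in vivo and in vitro datasets with a shared ortholog map
#' and planted ground truth for end-to-end recovery testing. The in vivo
#' arm emulates the long-term rodent study design — vehicle control, four
#' nanotube doses and a fibre positive control, three post-exposure time
#' points, eight animals per cell — and the in vitro arm a co-culture
#' exposure with vehicle and treated samples at two time points, three
#' replicates each. Concordant genes are planted with the same direction in
#' one in vivo dose-time cell and in both in vitro time points; discordant
#' decoys with opposite directions; one-sided decoys on a single side only.
#'
#' Because a planted effect lives in one of 18 in vivo dose-time cells, the
#' whole-experiment variance of a planted gene stays well under the 0.2
#' screening cutoff, as in the source study where the screen removed no
#' probes.
#'
#' @param n_genes Genes per species (one-to-one orthologs).
#' @param n_concordant,n_discordant,n_invivo_only,n_invitro_only Planted
#'   class sizes.
#' @param n_ambiguous Extra one-to-many ortholog clusters appended to the
#'   map (resolution decoys; their symbols are absent from the matrices).
#' @param invivo_lfc,invitro_lfc Planted |log2 fold change| per arm.
#' @param noise_sd Between-sample noise, log2 units.
#' @param n_per_group_invivo,n_per_group_invitro Samples per design cell.
#' @param na_rate Unreliable-value rate injected into the in vitro matrix.
#' @param seed Integer seed.
#' @return List with `invivo` (`expr` + `samples`), `invitro`
#'   (`expr` + `samples`), `orthologs` (raw map), and `truth`: one row per
#'   planted gene with its human symbol, class and direction.
#' @export
simulate_concordance_experiment <- function(n_genes = 2000,
                                            n_concordant = 12,
                                            n_discordant = 10,
                                            n_invivo_only = 8,
                                            n_invitro_only = 8,
                                            n_ambiguous = 20,
                                            invivo_lfc = 1.0,
                                            invitro_lfc = 1.5,
                                            noise_sd = 0.2,
                                            n_per_group_invivo = 8,
                                            n_per_group_invitro = 3,
                                            na_rate = 0.05,
                                            seed = 1L) {
  n_planted <- n_concordant + n_discordant + n_invivo_only + n_invitro_only
  stopifnot(n_planted <= n_genes)
  map <- simulate_ortholog_map(n_genes, n_one_to_many = n_ambiguous,
                               seed = derive_seed(seed, 31L))
  oo <- filter(map, .data$relation == "one-to-one") %>%
    arrange(.data$human_symbol)
  mouse_syms <- oo$mouse_symbol
  human_syms <- oo$human_symbol

  # planted classes occupy the first n_planted ortholog pairs
  cls <- rep(c("concordant", "discordant", "invivo_only", "invitro_only"),
             c(n_concordant, n_discordant, n_invivo_only, n_invitro_only))
  idx <- seq_len(n_planted)
  sgn <- rep_len(c(1, -1), n_planted)
  truth <- tibble(
    gene = toupper(human_syms[idx]),
    mouse_symbol = mouse_syms[idx],
    human_symbol = human_syms[idx],
    class = cls,
    direction = if_else(sgn > 0, "up", "down")
  )

  # ---- in vivo arm: 6 exposure groups x 3 times, one compartment
  doses <- c("MWCNT_1", "MWCNT_10", "MWCNT_40", "MWCNT_80")
  groups_iv <- tidyr::crossing(
    group = c("DM", doses, "asbestos_120"),
    time = c("1m", "6m", "12m")
  ) %>%
    mutate(label = paste(.data$group, .data$time, sep = "."),
           compartment = "lung", n = n_per_group_invivo)
  probe_ids <- sprintf("probe_%04d", seq_len(n_genes))
  vivo_sign <- if_else(truth$class == "discordant", -sgn, sgn)
  plant_iv <- tibble(
    probe_id = probe_ids[idx],
    label = paste(rep_len(doses, n_planted),
                  rep_len(c("1m", "6m", "12m"), n_planted), sep = "."),
    lfc = vivo_sign * invivo_lfc
  ) %>%
    filter(truth$class %in% c("concordant", "discordant", "invivo_only"))
  cfg_iv <- sim_config(
    n_probes = n_genes, groups = as.data.frame(groups_iv),
    control_label = "DM.1m", planted_effects = as.data.frame(plant_iv),
    noise_sd = noise_sd, seed = derive_seed(seed, 32L))
  invivo <- simulate_expr_matrix(cfg_iv, "invivo")
  invivo$expr$probe_id <- mouse_syms[match(invivo$expr$probe_id, probe_ids)]
  invivo$samples <- select(invivo$samples, -"label") %>%
    rename(label = "group") %>%
    mutate(group = .data$label)

  # ---- in vitro arm: vehicle and treated, mono- and co-culture, two times
  groups_ic <- tidyr::crossing(culture = c("mono", "co"),
                               exposure = c("DM", "MWCNT"),
                               time = c("6h", "24h")) %>%
    mutate(label = paste(.data$culture, .data$exposure, .data$time, sep = "."),
           cell_type = "SAEC", n = n_per_group_invitro)
  vitro_sign <- sgn
  keep_ic <- truth$class %in% c("concordant", "discordant", "invitro_only")
  plant_ic <- tidyr::crossing(
    i = idx[keep_ic], cu = c("mono", "co"), t = c("6h", "24h")
  ) %>%
    mutate(probe_id = probe_ids[.data$i],
           label = paste(.data$cu, "MWCNT", .data$t, sep = "."),
           lfc = vitro_sign[.data$i] * invitro_lfc) %>%
    select("probe_id", "label", "lfc")
  cfg_ic <- sim_config(
    n_probes = n_genes, groups = as.data.frame(groups_ic),
    control_label = "mono.DM.6h", planted_effects = as.data.frame(plant_ic),
    noise_sd = noise_sd, na_rate = na_rate,
    seed = derive_seed(seed, 33L))
  invitro <- simulate_expr_matrix(cfg_ic, "invitro")
  invitro$expr$probe_id <- human_syms[match(invitro$expr$probe_id, probe_ids)]
  invitro$samples$label <- NULL

  list(invivo = invivo, invitro = invitro, orthologs = map, truth = truth)
}

#' Run DE and concordance on a simulated experiment
#'
#' Convenience wrapper: in vivo calling, in vitro calling, ortholog
#' resolution and concordance on the output of
#' [simulate_concordance_experiment()], using the study thresholds.
#'
#' @param experiment Output of [simulate_concordance_experiment()].
#' @param seed Seed for ortholog resolution and SAM permutation sampling.
#' @param ... Threshold overrides passed to the stage functions
#'   (`alpha`, `fdr`, `fc`, `variance_cutoff`, `min_present`, `k`).
#' @return List with `de_invivo`, `de_invitro`, `records`, and
#'   `recovered_genes` (unique concordant human symbols found).
#' @export
analyze_concordance_experiment <- function(experiment, seed = 1L,
                                           alpha = 0.05, fdr = 0.10,
                                           fc = 1.5, variance_cutoff = 0.2,
                                           min_present = 10, k = 10) {
  iv <- de_invivo(experiment$invivo$expr, experiment$invivo$samples,
                  alpha = alpha, fdr = fdr, fc = fc,
                  variance_cutoff = variance_cutoff) %>%
    rename(gene = "probe_id") %>%
    mutate(compartment = "lung")
  ic <- de_invitro(experiment$invitro$expr, experiment$invitro$samples,
                   fdr = fdr, fc = fc, min_present = min_present, k = k,
                   seed = derive_seed(seed, 41L)) %>%
    rename(gene = "probe_id")
  pairing <- resolve_orthologs(experiment$orthologs,
                               seed = derive_seed(seed, 42L))
  records <- find_concordant(iv, ic, pairing, exclude_groups = "asbestos")
  list(de_invivo = iv, de_invitro = ic, records = records,
       recovered_genes = sort(unique(records$gene)))
}
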