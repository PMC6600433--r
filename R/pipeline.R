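#' Pipeline run configuration
#'
#' Validates the thresholds and seeds of an end-to-end run. All thresholds
#' default to the study values: p < 0.05, FDR 10%, fold change 1.5, probe
#' variance cutoff 0.2, minimum 10 present values, 10 imputation
#' neighbours, 10%/20% trim fractions and a 5x background-SD margin.
#'
#' @param invivo List with `expr` and `samples` (or NULL to simulate from
#'   `sim_invivo`).
#' @param invitro List with `expr` and `samples` (or NULL to simulate from
#'   `sim_invitro`).
#' @param orthologs Ortholog map tibble (or NULL to simulate).
#' @param sim_invivo,sim_invitro Optional [sim_config()]s used when the
#'   corresponding input is NULL.
#' @param sim_orthologs Optional list of arguments to
#'   [simulate_ortholog_map()].
#' @param alpha,fdr,fc,variance_cutoff,min_present,k,trim_neg,trim_norm,k_sd
#'   Stage thresholds (see the stage functions).
#' @param n_perm SAM permutations.
#' @param exclude_groups In vivo dose groups excluded from concordance.
#' @param seed Top-level seed; per-stage seeds are derived from it.
#' @return A validated list of class `run_config`.
#' @export
pipeline_config <- function(invivo = NULL, invitro = NULL, orthologs = NULL,
                            sim_invivo = NULL, sim_invitro = NULL,
                            sim_orthologs = NULL,
                            alpha = 0.05, fdr = 0.10, fc = 1.5,
                            variance_cutoff = 0.2, min_present = 10,
                            k = 10, trim_neg = 0.10, trim_norm = 0.20,
                            k_sd = 5, n_perm = 500,
                            exclude_groups = "asbestos", seed = 1L) {
  assert_prob(alpha, "alpha")
  assert_prob(fdr, "fdr", allow_one = TRUE)
  if (fc < 1) abort("`fc` must be >= 1.", class = "concordx_config_error")
  assert_count(min_present, "min_present")
  assert_count(k, "k")
  assert_prob(trim_neg, "trim_neg", allow_one = FALSE)
  assert_prob(trim_norm, "trim_norm", allow_one = FALSE)
  if (is.null(invivo) && is.null(sim_invivo)) {
    abort("provide `invivo` data or a `sim_invivo` config.",
          class = "concordx_config_error")
  }
  if (is.null(invitro) && is.null(sim_invitro)) {
    abort("provide `invitro` data or a `sim_invitro` config.",
          class = "concordx_config_error")
  }
  structure(list(invivo = invivo, invitro = invitro, orthologs = orthologs,
                 sim_invivo = sim_invivo, sim_invitro = sim_invitro,
                 sim_orthologs = sim_orthologs,
                 alpha = alpha, fdr = fdr, fc = fc,
                 variance_cutoff = variance_cutoff,
                 min_present = min_present, k = k,
                 trim_neg = trim_neg, trim_norm = trim_norm, k_sd = k_sd,
                 n_perm = n_perm, exclude_groups = exclude_groups,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the end-to-end concordance pipeline
#'
#' Simulates (or accepts) an in vivo expression matrix, an in vitro matrix
#' and an ortholog map, runs in vivo DE calling, in vitro SAM calling,
#' ortholog resolution and direction-concordance identification, and
#' returns the concordant records with set-algebra summaries and a run
#' manifest (configuration hash, seeds, per-stage row counts). Re-running
#' with the same configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV.
#' @return List with `de_invivo`, `de_invitro`, `pairing`, `records`,
#'   `summary` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "concordx_pipeline_error")
    })
  }

  invivo <- config$invivo %||% stage("simulate-invivo", {
    cfg <- config$sim_invivo
    cfg$seed <- derive_seed(config$seed, 101L)
    simulate_expr_matrix(do.call(sim_config, cfg), design = "invivo")
  })
  invitro <- config$invitro %||% stage("simulate-invitro", {
    cfg <- config$sim_invitro
    cfg$seed <- derive_seed(config$seed, 102L)
    simulate_expr_matrix(do.call(sim_config, cfg), design = "invitro")
  })
  orthologs <- config$orthologs %||% stage("simulate-orthologs", {
    do.call(simulate_ortholog_map,
            c(config$sim_orthologs, list(seed = derive_seed(config$seed, 103L))))
  })
  counts$invivo_probes <- nrow(invivo$expr)
  counts$invitro_probes <- nrow(invitro$expr)
  counts$ortholog_records <- nrow(orthologs)

  de_vivo <- stage("de-invivo", {
    res <- de_invivo(invivo$expr, invivo$samples,
                     alpha = config$alpha, fdr = config$fdr, fc = config$fc,
                     variance_cutoff = config$variance_cutoff)
    rename(res, gene = "probe_id")
  })
  counts$invivo_calls <- sum(de_vivo$called)

  de_vitro <- stage("de-invitro", {
    res <- de_invitro(invitro$expr, invitro$samples,
                      fdr = config$fdr, fc = config$fc,
                      min_present = config$min_present, k = config$k,
                      n_perm = config$n_perm,
                      seed = derive_seed(config$seed, 104L))
    rename(res, gene = "probe_id")
  })
  counts$invitro_calls <- sum(de_vitro$called)

  pairing <- stage("resolve-orthologs",
                   resolve_orthologs(orthologs,
                                     seed = derive_seed(config$seed, 105L)))
  counts$resolved_pairs <- nrow(pairing)

  records <- stage("concordance", {
    iv <- de_vivo
    if (!"compartment" %in% names(iv)) iv$compartment <- "lung"
    find_concordant(iv, de_vitro, pairing,
                    exclude_groups = config$exclude_groups)
  })
  counts$concordant_records <- nrow(records)
  summ <- summarize_sets(records)

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    thresholds = config[c("alpha", "fdr", "fc", "variance_cutoff",
                          "min_present", "k", "trim_neg", "trim_norm",
                          "k_sd", "n_perm")],
    counts = counts
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(de_vivo, file.path(out_dir, "de_invivo.tsv"),
                     progress = FALSE)
    readr::write_tsv(select(de_vitro, -dplyr::any_of("exclude_reason")),
                     file.path(out_dir, "de_invitro.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(records),
                     file.path(out_dir, "concordant_records.tsv"),
                     progress = FALSE)
    readr::write_tsv(summ$by_analysis, file.path(out_dir, "summary.tsv"),
                     progress = FALSE)
  }
  list(de_invivo = de_vivo, de_invitro = de_vitro, pairing = pairing,
       records = records, summary = summ, manifest = manifest)
}
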