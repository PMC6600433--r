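#' Resolve an ortholog map to a one-to-one pairing
#'
#' One-to-one records are kept verbatim. Records of the ambiguous classes
#' (one-to-many, many-to-many) are grouped into connected symbol clusters
#' (human and mouse symbols linked by any record) and exactly one
#' human-mouse pair is drawn uniformly at random per cluster, deterministic
#' in `seed`.
#'
#' @param map Tibble with columns `human_symbol`, `mouse_symbol`,
#'   `relation` (one-to-one / one-to-many / many-to-many).
#' @param seed Integer seed for the per-cluster draws.
#' @return Tibble with the same columns restricted to the resolved pairs;
#'   the result is bijective (each symbol appears at most once).
#' @export
resolve_orthologs <- function(map, seed = 1L) {
  map <- as_tibble(map)
  stopifnot(all(c("human_symbol", "mouse_symbol", "relation") %in% names(map)))
  if (nrow(map) == 0) abort("empty ortholog map.", class = "concordx_config_error")
  oo <- filter(map, .data$relation == "one-to-one")
  dup_h <- oo$human_symbol[duplicated(oo$human_symbol)]
  dup_m <- oo$mouse_symbol[duplicated(oo$mouse_symbol)]
  if (length(dup_h) > 0 || length(dup_m) > 0) {
    abort(sprintf("conflicting duplicate one-to-one records for: %s",
                  paste(unique(c(dup_h, dup_m)), collapse = ", ")),
          class = "concordx_ortholog_error")
  }
  amb <- filter(map, .data$relation != "one-to-one")
  if (nrow(amb) == 0) return(map)

  # connected components over the bipartite symbol graph (union-find)
  nodes <- unique(c(paste0("h:", amb$human_symbol),
                    paste0("m:", amb$mouse_symbol)))
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(amb))) {
    a <- find(which(nodes == paste0("h:", amb$human_symbol[r])))
    b <- find(which(nodes == paste0("m:", amb$mouse_symbol[r])))
    if (a != b) parent[b] <- a
  }
  comp_of <- vapply(seq_along(nodes), find, integer(1))
  amb$cluster <- comp_of[match(paste0("h:", amb$human_symbol), nodes)]

  set.seed(derive_seed(seed, 17L))
  picked <- amb %>%
    arrange(.data$cluster, .data$human_symbol, .data$mouse_symbol) %>%
    group_by(.data$cluster) %>%
    dplyr::slice_sample(n = 1) %>%
    ungroup() %>%
    select(-"cluster")
  bind_rows(oo, picked)
}

#' Harmonize miRNA names across species
#'
#' Strips species prefixes (e.g. `mmu-`, `hsa-`), normalizes the `miR`
#' casing, and preserves mature-arm suffixes (`-3p`/`-5p`), which must match
#' exactly downstream.
#'
#' @param x Character vector of miRNA names.
#' @return Harmonized names (e.g. `"mmu-mir-183"` -> `"miR-183"`).
#' @export
harmonize_mirna_names <- function(x) {
  out <- stringr::str_remove(x, "^[a-zA-Z]{3,4}-")
  out <- stringr::str_replace(out, stringr::regex("^mir-", ignore_case = TRUE),
                              "miR-")
  out <- stringr::str_replace(out, stringr::regex("^let-", ignore_case = TRUE),
                              "let-")
  out
}

# collapse called DE rows to one direction per key, dropping keys whose
# directions conflict; returns list(tab, conflicts)
consistent_direction <- function(df, keys) {
  grouped <- df %>%
    group_by(across(all_of(keys))) %>%
    summarise(n_dir = dplyr::n_distinct(.data$direction),
              direction = unique(.data$direction)[1],
              .groups = "drop")
  list(tab = filter(grouped, .data$n_dir == 1) %>% select(-"n_dir"),
       conflicts = filter(grouped, .data$n_dir > 1) %>% select(-"direction", -"n_dir"))
}

#' Identify direction-concordant genes across species
#'
#' A concordant record is emitted for (gene, mouse compartment, human cell
#' type, in vivo time point) when the mouse ortholog is called in that
#' compartment at that time in any included dose group, the human gene is
#' called in that cell type at any in vitro time point, and the directions
#' agree. Genes called with opposite directions in different dose groups
#' (or different in vitro conditions of the same cell type) are excluded as
#' direction-ambiguous and reported in the `"conflicts"` attribute.
#'
#' @param in_vivo Tibble of in vivo DE results with columns `compartment`,
#'   `time`, `group`, `gene` (mouse symbol), `direction`, `called`.
#' @param in_vitro Tibble of in vitro DE results with columns `cell_type`,
#'   `time`, `gene` (human symbol), `direction`, `called`.
#' @param pairing Resolved ortholog pairing ([resolve_orthologs()]), or
#'   `NULL` to match by identical (harmonized) names — the miRNA path.
#' @param exclude_groups In vivo dose groups excluded from concordance
#'   (e.g. a positive-control exposure); regular-expression matched against
#'   `group`.
#' @param doses Optional character vector restricting the in vivo dose
#'   groups considered.
#' @param harmonize Apply [harmonize_mirna_names()] to both gene columns
#'   before matching (used when `pairing` is `NULL`).
#' @return Tibble of class `concordant_records` with columns `gene`
#'   (human symbol, uppercase unless harmonized miRNA names), `compartment`,
#'   `cell_type`, `invivo_time`, `invitro_times`, `direction`.
#' @export
find_concordant <- function(in_vivo, in_vitro, pairing = NULL,
                            exclude_groups = "asbestos", doses = NULL,
                            harmonize = is.null(pairing)) {
  stopifnot(all(c("compartment", "time", "group", "gene", "direction", "called")
                %in% names(in_vivo)),
            all(c("cell_type", "time", "gene", "direction", "called")
                %in% names(in_vitro)))
  iv <- filter(as_tibble(in_vivo), .data$called)
  if (!is.null(exclude_groups) && nzchar(exclude_groups)) {
    iv <- filter(iv, !stringr::str_detect(tolower(.data$group),
                                          tolower(exclude_groups)))
  }
  if (!is.null(doses)) iv <- filter(iv, .data$group %in% doses)
  ic <- filter(as_tibble(in_vitro), .data$called)

  if (harmonize) {
    iv <- mutate(iv, gene = harmonize_mirna_names(.data$gene))
    ic <- mutate(ic, gene = harmonize_mirna_names(.data$gene))
  }
  if (!is.null(pairing)) {
    iv <- mutate(iv, gene = toupper(.data$gene))
    iv <- iv %>%
      inner_join(pairing %>%
                   mutate(mouse_key = toupper(.data$mouse_symbol),
                          human = toupper(.data$human_symbol)) %>%
                   select("mouse_key", "human"),
                 by = c(gene = "mouse_key")) %>%
      mutate(gene = .data$human) %>% select(-"human")
    ic <- mutate(ic, gene = toupper(.data$gene))
  }

  vivo <- consistent_direction(iv, c("gene", "compartment", "time"))
  vitro_records <- ic %>%
    distinct(.data$gene, .data$cell_type, .data$time, .data$direction)
  vitro <- consistent_direction(vitro_records, c("gene", "cell_type"))
  vitro_times <- vitro_records %>%
    group_by(.data$gene, .data$cell_type) %>%
    summarise(invitro_times = paste(sort(unique(.data$time)), collapse = ";"),
              .groups = "drop")

  records <- vivo$tab %>%
    rename(invivo_time = "time") %>%
    inner_join(vitro$tab, by = "gene", suffix = c("_vivo", "_vitro"),
               relationship = "many-to-many") %>%
    filter(.data$direction_vivo == .data$direction_vitro) %>%
    left_join(vitro_times, by = c("gene", "cell_type")) %>%
    mutate(direction = .data$direction_vivo) %>%
    select("gene", "compartment", "cell_type", "invivo_time",
           "invitro_times", "direction") %>%
    arrange(.data$compartment, .data$cell_type, .data$invivo_time, .data$gene)
  attr(records, "conflicts") <- list(in_vivo = vivo$conflicts,
                                     in_vitro = vitro$conflicts)
  class(records) <- c("concordant_records", class(records))
  records
}
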