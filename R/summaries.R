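#' Set-algebra summaries of concordant records
#'
#' Produces the reporting-stage summaries over a table of concordant
#' records: per (compartment, cell type) record counts and up/down tallies,
#' per in vivo time point counts, the unique-gene union per compartment
#' across cell types, and the cross-compartment intersection — genes
#' concordant in the analyses of both compartments with the same direction
#' everywhere.
#'
#' @param records A [find_concordant()] result or any tibble with columns
#'   `gene`, `compartment`, `cell_type`, `invivo_time`, `direction`.
#' @return An object of class `concord_summary`: a list with tibbles
#'   `by_analysis`, `by_time`, `unique_by_compartment`, `cross_compartment`
#'   and the input `records`.
#' @export
summarize_sets <- function(records) {
  records <- as_tibble(records)
  need <- c("gene", "compartment", "cell_type", "invivo_time", "direction")
  stopifnot(all(need %in% names(records)))

  by_analysis <- records %>%
    group_by(.data$compartment, .data$cell_type) %>%
    summarise(n_records = dplyr::n(),
              n_up = sum(.data$direction == "up"),
              n_down = sum(.data$direction == "down"),
              n_unique_genes = dplyr::n_distinct(.data$gene),
              .groups = "drop")

  by_time <- records %>%
    count(.data$compartment, .data$cell_type, .data$invivo_time,
          name = "n_records")

  unique_by_compartment <- records %>%
    group_by(.data$compartment) %>%
    summarise(n_unique_genes = dplyr::n_distinct(.data$gene),
              genes = list(sort(unique(.data$gene))),
              .groups = "drop")

  # direction-aware intersection: a gene qualifies when it appears in every
  # compartment and carries a single direction across all its records
  comps <- unique(records$compartment)
  cross_compartment <- records %>%
    group_by(.data$gene) %>%
    summarise(n_compartments = dplyr::n_distinct(.data$compartment),
              n_directions = dplyr::n_distinct(.data$direction),
              direction = .data$direction[1],
              .groups = "drop") %>%
    filter(.data$n_compartments == length(comps), .data$n_directions == 1,
           length(comps) > 1) %>%
    select("gene", "direction") %>%
    arrange(.data$gene)

  structure(list(
    by_analysis = by_analysis,
    by_time = by_time,
    unique_by_compartment = unique_by_compartment,
    cross_compartment = cross_compartment,
    records = records
  ), class = "concord_summary")
}

#' @export
print.concord_summary <- function(x, ...) {
  cat("<concord_summary>\n")
  cat("Per-analysis record counts:\n")
  print(x$by_analysis)
  cat("Unique genes per compartment:\n")
  print(select(x$unique_by_compartment, -"genes"))
  if (nrow(x$cross_compartment) > 0) {
    cat("Cross-compartment concordant genes:",
        paste(x$cross_compartment$gene, collapse = ", "), "\n")
  } else {
    cat("No cross-compartment concordant genes.\n")
  }
  invisible(x)
}

#' Tidy a concordance summary
#'
#' @param x A `concord_summary`.
#' @param ... Unused.
#' @return The per-analysis tibble with record counts and direction tallies.
#' @method tidy concord_summary
#' @export
tidy.concord_summary <- function(x, ...) x$by_analysis

#' One-row overview of a concordance summary
#'
#' @param x A `concord_summary`.
#' @param ... Unused.
#' @return Tibble with total record count, unique gene count, and the size
#'   of the cross-compartment intersection.
#' @method glance concord_summary
#' @export
glance.concord_summary <- function(x, ...) {
  tibble(n_records = nrow(x$records),
         n_unique_genes = dplyr::n_distinct(x$records$gene),
         n_cross_compartment = nrow(x$cross_compartment))
}
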