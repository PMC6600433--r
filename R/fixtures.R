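#' Packaged concordant-gene reference tables
#'
#' The package ships transcriptions of the study's six printed
#' concordant-gene tables as plain TSV under `inst/extdata/`: four mRNA
#' tables (lung x SAEC, lung x HMVEC, blood x SAEC, blood x HMVEC) and two
#' miRNA tables (lung and blood). `load_concordant_tables()` reads them
#' into the record layout consumed by [summarize_sets()].
#'
#' @param type `"mrna"` (tables 1-4) or `"mirna"` (tables 5-6).
#' @return A tibble of concordant records with columns `gene`,
#'   `compartment`, `cell_type`, `invivo_time`, `direction`, `annotation`
#'   and `table` (source table number).
#' @export
load_concordant_tables <- function(type = c("mrna", "mirna")) {
  type <- match.arg(type)
  nums <- if (type == "mrna") 1:4 else 5:6
  purrr::map_dfr(nums, function(i) {
    path <- system.file("extdata", sprintf("table%d.tsv", i),
                        package = "concordx", mustWork = TRUE)
    read_concordant_table(path) %>% mutate(table = i)
  })
}

#' Read a concordant-record TSV
#'
#' @param path Path to a TSV with columns `gene`, `compartment`,
#'   `cell_type`, `invivo_time`, `direction` (and optionally `annotation`).
#' @return A tibble of concordant records.
#' @export
read_concordant_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    invivo_time = readr::col_integer(),
                    .default = readr::col_character()))
}
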