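#' Write and read spot tables in a GenePix-like tab-delimited dialect
#'
#' One file per array with columns Block, Row, Column, Name, F_Median,
#' B_Median, Flags, ControlType, preceded by a comment header carrying the
#' array id and the background-region SD
#' (`# array_id=...` / `# background_sd=...`).
#'
#' @param spots Spot tibble (see [simulate_spot_arrays()]).
#' @param arrays Array tibble with `array_id` and `bg_sd`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_spot_tables <- function(spots, arrays, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(arrays$array_id, function(a) {
    path <- file.path(dir, paste0(a, ".tsv"))
    sub <- filter(spots, .data$array_id == a)
    gpr <- tibble(Block = sub$block, Row = sub$row, Column = sub$column,
                  Name = sub$probe_id,
                  F_Median = sub$f_median, B_Median = sub$b_median,
                  Flags = as.integer(sub$flagged) * -100L,
                  ControlType = as.integer(sub$is_control))
    writeLines(c(sprintf("# array_id=%s", a),
                 sprintf("# background_sd=%.10g",
                         arrays$bg_sd[arrays$array_id == a])), path)
    readr::write_tsv(gpr, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
    path
  })
  invisible(paths)
}

#' @rdname write_spot_tables
#' @return `read_spot_tables()` returns a list with `spots` and `arrays`
#'   tibbles in the layout produced by [simulate_spot_arrays()].
#' @export
read_spot_tables <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) {
    abort(sprintf("no spot tables found in %s", dir),
          class = "concordx_io_error")
  }
  parts <- purrr::map(files, function(path) {
    hdr <- readLines(path, n = 2)
    meta <- stringr::str_match(hdr, "^# *([a-z_]+)=(.*)$")
    meta <- setNames(meta[, 3], meta[, 2])
    tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    spots <- tibble(array_id = meta[["array_id"]],
                    block = as.integer(tab$Block),
                    row = as.integer(tab$Row),
                    column = as.integer(tab$Column),
                    probe_id = tab$Name,
                    f_median = tab$F_Median,
                    b_median = tab$B_Median,
                    flagged = tab$Flags < 0,
                    is_control = tab$ControlType != 0)
    list(spots = spots,
         arrays = tibble(array_id = meta[["array_id"]],
                         bg_sd = as.numeric(meta[["background_sd"]])))
  })
  list(spots = bind_rows(purrr::map(parts, "spots")),
       arrays = bind_rows(purrr::map(parts, "arrays")))
}

#' Write/read an expression matrix with its sample sheet
#'
#' The matrix is a TSV with a `probe_id` column plus one column per sample;
#' the sample sheet is a CSV.
#'
#' @param expr Expression tibble.
#' @param samples Sample sheet tibble.
#' @param matrix_path,samples_path Output paths.
#' @return Invisibly the paths; the readers return the tibbles.
#' @export
write_expr_matrix <- function(expr, samples, matrix_path, samples_path) {
  readr::write_tsv(expr, matrix_path, progress = FALSE)
  readr::write_csv(samples, samples_path, progress = FALSE)
  invisible(c(matrix_path, samples_path))
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(matrix_path, samples_path) {
  list(expr = readr::read_tsv(matrix_path, show_col_types = FALSE,
                              progress = FALSE),
       samples = readr::read_csv(samples_path, show_col_types = FALSE,
                                 progress = FALSE))
}

#' Write/read an ortholog map as three-column TSV
#'
#' @param map Tibble with `human_symbol`, `mouse_symbol`, `relation`.
#' @param path File path.
#' @export
write_ortholog_map <- function(map, path) {
  readr::write_tsv(map[, c("human_symbol", "mouse_symbol", "relation")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_map
#' @export
read_ortholog_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = "ccc")
}
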