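test_that("one-to-one records pass through resolution verbatim", {
  map <- tibble::tibble(human_symbol = c("A", "B"), mouse_symbol = c("a", "b"),
                        relation = "one-to-one")
  expect_equal(nrow(resolve_orthologs(map)), 2)
  dup <- dplyr::bind_rows(map, tibble::tibble(human_symbol = "A",
                                              mouse_symbol = "c",
                                              relation = "one-to-one"))
  expect_error(resolve_orthologs(dup), class = "concordx_ortholog_error")
  expect_error(resolve_orthologs(map[0, ]), class = "concordx_config_error")
})

test_that("ambiguous clusters resolve to one pair each, deterministically", {
  map <- simulate_ortholog_map(4, n_one_to_many = 3, n_many_to_many = 2,
                               fan_out = 3, seed = 6L)
  r1 <- resolve_orthologs(map, seed = 5L)
  r2 <- resolve_orthologs(map, seed = 5L)
  expect_identical(r1, r2)
  # 4 one-to-one + 3 one-to-many clusters + 2 many-to-many clusters
  expect_equal(nrow(r1), 4 + 3 + 2)
  expect_equal(anyDuplicated(r1$human_symbol), 0)
  expect_equal(anyDuplicated(r1$mouse_symbol), 0)
  # every resolved pair is a record of the input map
  expect_equal(nrow(dplyr::anti_join(r1, map,
                                     by = c("human_symbol", "mouse_symbol"))), 0)
  # different seeds can pick different pairs within a cluster
  picks <- vapply(1:20, function(s) {
    amb <- dplyr::filter(resolve_orthologs(map, seed = s),
                         relation != "one-to-one")
    paste(sort(paste(amb$human_symbol, amb$mouse_symbol)), collapse = ";")
  }, character(1))
  expect_gt(length(unique(picks)), 1)
})

test_that("a bridged many-to-many cluster collapses to a single pair", {
  # h1-m1, h1-m2, h2-m2: one connected component despite two human symbols
  map <- tibble::tibble(human_symbol = c("h1", "h1", "h2"),
                        mouse_symbol = c("m1", "m2", "m2"),
                        relation = "many-to-many")
  out <- resolve_orthologs(map, seed = 1L)
  expect_equal(nrow(out), 1)
})

test_that("miRNA name harmonization strips species and fixes case", {
  expect_equal(harmonize_mirna_names(c("mmu-mir-183", "hsa-miR-183")),
               c("miR-183", "miR-183"))
  expect_equal(harmonize_mirna_names("mmu-miR-29b-3p"), "miR-29b-3p")
  expect_equal(harmonize_mirna_names("hsa-let-7a"), "let-7a")
  # arm suffixes stay distinct
  expect_false(harmonize_mirna_names("mmu-miR-29b-3p") ==
                 harmonize_mirna_names("hsa-miR-29b-5p"))
})

de_row <- function(gene, called = TRUE, direction = "up", group = "MWCNT_40",
                   time = "12m", compartment = "lung") {
  tibble::tibble(compartment = compartment, time = time, group = group,
                 gene = gene, direction = direction, called = called)
}

vitro_row <- function(gene, called = TRUE, direction = "up",
                      cell_type = "SAEC", time = "6h") {
  tibble::tibble(cell_type = cell_type, time = time, gene = gene,
                 direction = direction, called = called)
}

test_that("find_concordant requires call + direction agreement on both sides", {
  pairing <- tibble::tibble(human_symbol = c("GENEA", "GENEB", "GENEC"),
                            mouse_symbol = c("Genea", "Geneb", "Genec"),
                            relation = "one-to-one")
  iv <- dplyr::bind_rows(
    de_row("Genea"),                                  # concordant
    de_row("Geneb", direction = "down"),              # direction clash
    de_row("Genec", called = FALSE))                  # not called in vivo
  ic <- dplyr::bind_rows(vitro_row("GENEA"), vitro_row("GENEB"),
                         vitro_row("GENEC"))
  rec <- find_concordant(iv, ic, pairing)
  expect_equal(rec$gene, "GENEA")
  expect_equal(rec$compartment, "lung")
  expect_equal(rec$invivo_time, "12m")
  expect_equal(rec$direction, "up")
})

test_that("asbestos-group calls are excluded; dose restriction works", {
  pairing <- tibble::tibble(human_symbol = "GENEA", mouse_symbol = "Genea",
                            relation = "one-to-one")
  iv <- de_row("Genea", group = "asbestos_120")
  ic <- vitro_row("GENEA")
  expect_equal(nrow(find_concordant(iv, ic, pairing)), 0)
  iv2 <- de_row("Genea", group = "MWCNT_10")
  expect_equal(nrow(find_concordant(iv2, ic, pairing,
                                    doses = "MWCNT_40")), 0)
  expect_equal(nrow(find_concordant(iv2, ic, pairing,
                                    doses = "MWCNT_10")), 1)
})

test_that("within-side direction conflicts drop the gene and are reported", {
  pairing <- tibble::tibble(human_symbol = "GENEA", mouse_symbol = "Genea",
                            relation = "one-to-one")
  iv <- dplyr::bind_rows(
    de_row("Genea", group = "MWCNT_10", direction = "up"),
    de_row("Genea", group = "MWCNT_80", direction = "down"))
  ic <- vitro_row("GENEA")
  rec <- find_concordant(iv, ic, pairing)
  expect_equal(nrow(rec), 0)
  expect_equal(attr(rec, "conflicts")$in_vivo$gene, "GENEA")
})

test_that("miRNA path matches by harmonized name without a pairing", {
  iv <- de_row("mmu-miR-183")
  ic <- vitro_row("hsa-miR-183")
  rec <- find_concordant(iv, ic)
  expect_equal(rec$gene, "miR-183")
  # arm mismatch does not match
  rec2 <- find_concordant(de_row("mmu-miR-29b-3p"), vitro_row("hsa-miR-29b-5p"))
  expect_equal(nrow(rec2), 0)
})

test_that("set summaries tally records, times, unions and intersections", {
  rec <- tibble::tibble(
    gene = c("A", "B", "A", "C", "A", "D"),
    compartment = c("lung", "lung", "lung", "lung", "blood", "blood"),
    cell_type = c("SAEC", "SAEC", "HMVEC", "HMVEC", "SAEC", "HMVEC"),
    invivo_time = c(1L, 12L, 12L, 12L, 6L, 1L),
    direction = c("up", "down", "up", "down", "up", "down"))
  s <- summarize_sets(rec)
  expect_equal(sum(s$by_analysis$n_records), 6)
  lung <- dplyr::filter(s$unique_by_compartment, compartment == "lung")
  expect_equal(lung$n_unique_genes, 3)
  expect_equal(lung$genes[[1]], c("A", "B", "C"))
  # A is in both compartments, always up -> the only cross-compartment gene
  expect_equal(s$cross_compartment$gene, "A")
  # a direction conflict across compartments disqualifies
  rec2 <- dplyr::mutate(rec,
                        direction = ifelse(gene == "A" & compartment == "blood",
                                           "down", direction))
  expect_equal(nrow(summarize_sets(rec2)$cross_compartment), 0)
  expect_equal(glance(s)$n_records, 6)
  expect_equal(nrow(tidy(s)), nrow(s$by_analysis))
  expect_output(print(s), "concord_summary")
})

test_that("packaged fixture tables load with the documented layout", {
  rec <- load_concordant_tables("mrna")
  expect_named(rec, c("gene", "compartment", "cell_type", "invivo_time",
                      "direction", "annotation", "table"))
  expect_setequal(unique(rec$compartment), c("lung", "blood"))
  expect_setequal(unique(rec$cell_type), c("SAEC", "HMVEC"))
  expect_true(all(rec$invivo_time %in% c(1L, 6L, 12L)))
  expect_true(all(rec$direction %in% c("up", "down")))
  mi <- load_concordant_tables("mirna")
  expect_true(all(grepl("^miR-", mi$gene)))
})

test_that("ortholog map round-trips through TSV", {
  map <- simulate_ortholog_map(3, n_one_to_many = 1, seed = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ortholog_map(map, path)
  expect_equal(as.data.frame(read_ortholog_map(path)), as.data.frame(map))
})
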