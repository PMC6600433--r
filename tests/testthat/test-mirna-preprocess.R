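# hand-built two-array spot table used by the arithmetic tests
tiny_spots <- function() {
  tibble::tibble(
    array_id = rep(c("a1", "a2"), each = 8),
    probe_id = rep(c("p1", "p1", "p2", "p2", "p3", "p3", "NC1", "NC2"), 2),
    f_median = c(1100, 1120, 600, 640, 2100, 2060, 160, 140,
                 1180, 1230, 680, 700, 2260, 2220, 170, 150),
    b_median = rep(100, 16),
    flagged = FALSE,
    is_control = rep(c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE), 2)
  )
}

tiny_arrays <- function() {
  tibble::tibble(array_id = c("a1", "a2"), bg_sd = c(4, 5),
                 label = c("DM", "MW"))
}

test_that("spot_intensity is foreground minus background", {
  sp <- spot_intensity(tiny_spots())
  expect_equal(sp$intensity, tiny_spots()$f_median - 100)
  sp2 <- spot_intensity(dplyr::mutate(tiny_spots(),
                                      f_median = dplyr::if_else(probe_id == "p2",
                                                                NA_real_, f_median)))
  expect_true(all(is.na(sp2$intensity[sp2$probe_id == "p2"])))
})

test_that("detection_threshold matches the hand formula and oracle", {
  sp <- spot_intensity(tiny_spots())
  th <- detection_threshold(sp, tiny_arrays(), trim = 0.10, k_sd = 5)
  # a1 controls: 60, 40 -> 10% trim drops nothing (floor(2*0.1)=0) -> mean 50
  expect_equal(th$t_raw[th$array_id == "a1"], 50 + 5 * 4)
  expect_equal(th$t_raw[th$array_id == "a2"], 60 + 5 * 5)
  expect_equal(th$t_log2, log2(th$t_raw))

  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 100, 30)
    sp_r <- tibble::tibble(array_id = "a", probe_id = paste0("NC", seq_len(n)),
                           intensity = x, is_control = TRUE, flagged = FALSE)
    th_r <- detection_threshold(sp_r,
                                tibble::tibble(array_id = "a", bg_sd = 3),
                                trim = 0.10, k_sd = 5)
    expect_equal(th_r$t_raw, bf_trimmed_mean(x, 0.10) + 15, tolerance = 1e-12)
  }
  expect_error(detection_threshold(dplyr::filter(sp, !is_control),
                                   tiny_arrays()),
               class = "concordx_threshold_error")
  sp_neg <- dplyr::mutate(sp, intensity = dplyr::if_else(is_control,
                                                         -1000, intensity))
  expect_error(detection_threshold(sp_neg, tiny_arrays()),
               class = "concordx_threshold_error")
})

test_that("log2 transform masks non-positive intensities", {
  sp <- tibble::tibble(intensity = c(8, 1, 0, -3, NA))
  out <- log2_spot_intensities(sp)
  expect_equal(out$log2_intensity, c(3, 0, NA, NA, NA))
})

test_that("normalization factor uses the common detected set and recentres", {
  sp <- log2_spot_intensities(spot_intensity(tiny_spots()))
  th <- detection_threshold(sp, tiny_arrays())
  nf <- normalization_factor(sp, th, trim = 0.20)
  # all 3 probes beat both thresholds (min intensity 500 >> t_raw <= 85)
  expect_equal(attr(nf, "n_common"), 3)
  # per array: 6 unflagged spot log2 values, floor(6*.2)=1 trimmed per tail
  for (a in c("a1", "a2")) {
    v <- sp$log2_intensity[sp$array_id == a & !sp$is_control]
    expect_equal(nf$n_factor[nf$array_id == a], bf_trimmed_mean(v, 0.20),
                 tolerance = 1e-12)
  }
  expect_equal(unique(nf$grand_mean_n), mean(nf$n_factor))

  norm <- normalize_spots(sp, nf, th)
  # normalized grand means agree across arrays up to the common-set shift
  shifted <- norm$spots %>%
    dplyr::filter(!is_control) %>%
    dplyr::group_by(array_id) %>%
    dplyr::summarise(tm = bf_trimmed_mean(log2_norm, 0.20))
  expect_equal(shifted$tm[1], shifted$tm[2], tolerance = 1e-12)
  expect_equal(norm$thresholds$t_log2_norm,
               th$t_log2 - nf$n_factor + nf$grand_mean_n)

  # empty common set aborts with diagnostics
  th_hi <- dplyr::mutate(th, t_log2 = 99)
  expect_error(normalization_factor(sp, th_hi),
               class = "concordx_normalization_error")
})

test_that("triplicate collapse averages unflagged non-missing spots", {
  sp <- tibble::tibble(
    array_id = "a1",
    probe_id = c("p1", "p1", "p1", "p2", "p2", "p2", "p3", "p3", "p3"),
    log2_norm = c(4, 6, 8, 5, 7, NA, NA, NA, NA),
    flagged = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_control = FALSE
  )
  out <- collapse_triplicates(sp)
  expect_equal(out$intensity[out$probe_id == "p1"], 5)   # flagged 8 dropped
  expect_equal(out$n_spots[out$probe_id == "p1"], 2)
  expect_equal(out$intensity[out$probe_id == "p2"], 6)   # NA dropped
  expect_true(is.na(out$intensity[out$probe_id == "p3"]))
  expect_equal(out$n_spots[out$probe_id == "p3"], 0)
})

test_that("detection filter matches the brute-force oracle", {
  set.seed(22)
  for (rep in 1:40) {
    n_arr <- sample(2:6, 1)
    n_probe <- sample(3:12, 1)
    thr <- runif(n_arr, 4, 6)
    grp <- sample(c("A", "B"), n_arr, replace = TRUE)
    if (length(unique(grp)) == 1) grp[1] <- setdiff(c("A", "B"), grp[1])
    m <- matrix(runif(n_probe * n_arr, 3, 7), n_probe)
    m[sample(length(m), floor(length(m) * 0.1))] <- NA
    arr_ids <- sprintf("a%d", seq_len(n_arr))
    pm <- tidyr::crossing(probe_id = sprintf("p%02d", seq_len(n_probe)),
                          array_id = arr_ids) %>%
      dplyr::arrange(array_id, probe_id) %>%
      dplyr::mutate(intensity = as.vector(m), is_control = FALSE, n_spots = 3L)
    got <- detection_filter(
      pm, tibble::tibble(array_id = arr_ids, t_log2 = thr),
      tibble::tibble(array_id = arr_ids, label = grp))
    want <- bf_detection_filter(m, thr, grp)
    expect_equal(got$detected[match(sprintf("p%02d", seq_len(n_probe)),
                                    got$probe_id)],
                 want)
  }
})

test_that("boundary semantics: exactly-at-threshold is NOT detected", {
  pm <- tibble::tibble(probe_id = "p1", array_id = c("a1", "a2"),
                       intensity = c(5, 5 + 1e-9), is_control = FALSE,
                       n_spots = 3L)
  th <- tibble::tibble(array_id = c("a1", "a2"), t_log2 = 5)
  des <- tibble::tibble(array_id = c("a1", "a2"), label = c("g", "g"))
  expect_false(detection_filter(pm, th, des)$detected)
  pm$intensity <- c(5 + 1e-9, 5 + 1e-9)
  expect_true(detection_filter(pm, th, des)$detected)
})

test_that("preprocess_mirna runs end to end on simulated arrays", {
  cfg <- sim_config(n_probes = 30, n_negative_controls = 8,
                    groups = data.frame(label = c("DM", "MW"), n = c(3, 3)),
                    seed = 13L)
  sim <- simulate_spot_arrays(cfg)
  out <- preprocess_mirna(sim$spots, sim$arrays)
  expect_named(out, c("probe_matrix", "probes", "detected", "thresholds",
                      "factors", "qc"))
  expect_equal(nrow(out$probe_matrix), 30)
  expect_equal(ncol(out$probe_matrix), 1 + 6)
  expect_equal(nrow(out$detected), 30)
  # detection verdicts agree with the brute-force oracle on the collapsed
  # matrix (probes with weak baselines may legitimately fall below T)
  mat <- as.matrix(out$probe_matrix[-1])
  arr_order <- colnames(out$probe_matrix)[-1]
  thr <- out$thresholds$t_log2_norm[match(arr_order, out$thresholds$array_id)]
  grp <- sim$arrays$label[match(arr_order, sim$arrays$array_id)]
  want <- bf_detection_filter(mat, thr, grp)
  expect_equal(out$detected$detected[match(out$probe_matrix$probe_id,
                                           out$detected$probe_id)], want)
  expect_gt(mean(out$detected$detected), 0.8)
  # normalization recentres: per-array trimmed means of common probes agree
  expect_equal(length(unique(round(out$factors$grand_mean_n, 10))), 1)
})

test_that("spot table round-trips through the GPR-like text format", {
  cfg <- sim_config(n_probes = 10, n_negative_controls = 4,
                    groups = data.frame(label = c("DM", "MW"), n = c(2, 2)),
                    seed = 4L)
  sim <- simulate_spot_arrays(cfg)
  dir <- withr::local_tempdir()
  write_spot_tables(sim$spots, sim$arrays, dir)
  back <- read_spot_tables(dir)
  expect_equal(nrow(back$spots), nrow(sim$spots))
  expect_equal(back$spots$f_median, sim$spots$f_median, tolerance = 1e-9)
  expect_equal(back$spots$flagged, sim$spots$flagged)
  expect_equal(back$arrays$bg_sd, sim$arrays$bg_sd, tolerance = 1e-9)
})
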