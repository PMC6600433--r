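#' Two-class unpaired SAM relative-difference statistic
#'
#' d_i = (mean treated - mean control) / (s_i + s0), where s_i is the
#' pooled-standard-error gene-specific scatter
#' sqrt((1/n1 + 1/n2) * (ss1 + ss2) / (n1 + n2 - 2)) and s0 is the fudge
#' factor stabilizing low-variance genes. With s0 = 0 the statistic reduces
#' to the ordinary pooled-variance t statistic.
#'
#' @param expr Expression tibble (`probe_id` + samples) or numeric matrix
#'   (probes x samples).
#' @param labels Vector of class labels aligned with the sample columns;
#'   exactly two distinct values.
#' @param s0 Fudge factor (>= 0, log2-intensity units).
#' @param treated Which label is the treated class; defaults to the second
#'   level of `factor(labels)`.
#' @return Tibble with `probe_id`, `d`, `s` (gene-specific scatter),
#'   `diff` (treated minus control mean).
#' @export
sam_statistic <- function(expr, labels, s0 = 0, treated = NULL) {
  m <- if (is.matrix(expr)) expr else expr_to_matrix(expr)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) {
    abort("`labels` must have exactly two classes.",
          class = "concordx_config_error")
  }
  if (is.null(treated)) treated <- lev[2]
  control <- setdiff(lev, treated)
  idx_t <- which(labels == treated)
  idx_c <- which(labels == control)
  if (length(idx_t) < 2 || length(idx_c) < 2) {
    abort("each class needs >= 2 samples.", class = "concordx_config_error")
  }
  st <- two_group_stats(m, idx_t, idx_c)
  tibble(probe_id = rownames(m) %||% as.character(seq_len(nrow(m))),
         d = unname(st$diff / (st$se + s0)),
         s = unname(st$se),
         diff = unname(st$diff))
}

#' Choose the SAM fudge factor s0
#'
#' Candidates are the percentiles (0, 5, ..., 100) of the gene-specific
#' scatter s. For each candidate, genes are windowed by s-quantiles and the
#' spread (median absolute deviation) of d is computed per window; the
#' candidate minimizing the coefficient of variation of these window
#' spreads is returned. This stabilizes |d| against its dependence on s.
#' If the s distribution is degenerate (all windows identical) the median
#' of s is returned with a warning.
#'
#' @inheritParams sam_statistic
#' @param n_windows Number of s-quantile windows (capped by probe count).
#' @return s0 (single non-negative number) with the chosen percentile in
#'   attribute `"percentile"`.
#' @export
choose_s0 <- function(expr, labels, treated = NULL, n_windows = 100) {
  base <- sam_statistic(expr, labels, s0 = 0, treated = treated)
  s <- base$s
  r <- base$diff
  p <- length(s)
  if (p < 10) {
    warn("too few probes to tune s0; using median(s).")
    return(structure(median(s), percentile = 50))
  }
  n_windows <- max(2L, min(n_windows, floor(p / 10)))
  brks <- unique(quantile(s, probs = seq(0, 1, length.out = n_windows + 1)))
  if (length(brks) < 3) {
    warn("degenerate s distribution; using median(s).")
    return(structure(median(s), percentile = 50))
  }
  win <- cut(s, breaks = brks, include.lowest = TRUE)
  pcts <- seq(0, 100, by = 5)
  cand <- quantile(s, probs = pcts / 100, names = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, mad)
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  }, numeric(1))
  if (all(is.na(cv))) {
    warn("degenerate s distribution; using median(s).")
    return(structure(median(s), percentile = 50))
  }
  best <- which.min(cv)
  structure(max(0, cand[best]), percentile = pcts[best])
}

# all distinct two-class label assignments as a matrix of treated-index sets
exhaustive_splits <- function(n, n_treated) {
  combn(n, n_treated)
}

# cut points for a given delta on sorted d vs expected dbar
sam_cutpoints <- function(d_sorted, dbar, delta) {
  res <- d_sorted - dbar
  up <- which(res >= delta & d_sorted >= 0)
  lo <- which(res <= -delta & d_sorted <= 0)
  list(cut_up = if (length(up)) min(d_sorted[up]) else Inf,
       cut_low = if (length(lo)) max(d_sorted[lo]) else -Inf)
}

#' Two-class unpaired SAM with permutation null and delta selection
#'
#' Computes the SAM statistic, builds expected order statistics from label
#' permutations (exhaustive when the number of distinct label splits is
#' small, random otherwise), scans a delta grid, estimates the FDR at each
#' delta as pi0 x (median permutation false positives) / (number called),
#' monotonizes the FDR curve in delta, and returns the smallest delta whose
#' estimated FDR is at or below `target_fdr` together with the called set.
#'
#' @inheritParams sam_statistic
#' @param target_fdr Target false discovery rate for delta selection.
#' @param n_perm Number of random permutations when the split count exceeds
#'   `exhaustive_max`.
#' @param seed Integer seed for the permutation sampling (ignored in
#'   exhaustive mode, which is deterministic).
#' @param s0 Fudge factor; `NULL` tunes it with [choose_s0()].
#' @param n_delta Number of grid points between 0 and max |d - dbar|.
#' @param exhaustive_max Use all distinct label splits when their count is
#'   at most this.
#' @return An object of class `sam_result`; see [tidy.sam_result()] and
#'   [glance.sam_result()].
#' @export
sam_call <- function(expr, labels, target_fdr = 0.10, n_perm = 500,
                     seed = NULL, s0 = NULL, treated = NULL,
                     n_delta = 100, exhaustive_max = 10000) {
  m <- if (is.matrix(expr)) expr else expr_to_matrix(expr)
  if (anyNA(m)) {
    abort("SAM needs a complete matrix; impute missing values first.",
          class = "concordx_config_error")
  }
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (is.null(treated)) treated <- lev[2]
  if (is.null(s0)) s0 <- choose_s0(m, labels, treated = treated)
  obs <- sam_statistic(m, labels, s0 = s0, treated = treated)
  p <- nrow(obs)

  idx_t <- which(labels == treated)
  n <- length(labels)
  n_splits <- choose(n, length(idx_t))
  exhaustive <- n_splits <= exhaustive_max
  if (exhaustive) {
    splits <- exhaustive_splits(n, length(idx_t))
  } else {
    if (n_perm < 100) {
      abort("n_perm must be >= 100 (or the design small enough for exhaustive permutations).",
            class = "concordx_config_error")
    }
    if (!is.null(seed)) set.seed(derive_seed(seed, 11L))
    splits <- replicate(n_perm, sort(sample.int(n, length(idx_t))))
  }
  nb <- ncol(splits)
  perm_lab <- character(n)
  control <- setdiff(lev, treated)
  d_perm <- matrix(0, nrow = p, ncol = nb)
  for (b in seq_len(nb)) {
    perm_lab[] <- control
    perm_lab[splits[, b]] <- treated
    d_perm[, b] <- sam_statistic(m, perm_lab, s0 = s0, treated = treated)$d
  }
  d_perm_sorted <- apply(d_perm, 2, sort)
  dbar <- rowMeans(d_perm_sorted)

  ord <- order(obs$d)
  d_sorted <- obs$d[ord]

  # pi0 from the proportion of observed d inside the central 50% of the
  # permutation distribution
  qq <- quantile(d_perm, c(0.25, 0.75))
  pi0 <- min(1, max(0, sum(obs$d > qq[1] & obs$d < qq[2]) / (0.5 * p)))

  delta_max <- max(abs(d_sorted - dbar))
  deltas <- seq(0, delta_max, length.out = n_delta)
  tab <- purrr::map_dfr(deltas, function(delta) {
    cp <- sam_cutpoints(d_sorted, dbar, delta)
    called <- obs$d >= cp$cut_up | obs$d <= cp$cut_low
    fp <- apply(d_perm, 2, function(db) sum(db >= cp$cut_up | db <= cp$cut_low))
    n_called <- sum(called)
    tibble(delta = delta,
           cut_up = cp$cut_up, cut_low = cp$cut_low,
           n_called = n_called,
           fp_median = median(fp),
           fdr = if (n_called == 0) 0 else pi0 * median(fp) / n_called)
  })
  tab$fdr_mono <- cummin(tab$fdr)

  sel <- which(tab$fdr_mono <= target_fdr)
  if (length(sel) == 0) {
    # no delta reaches the target: report an empty called set, keep the table
    delta_star <- Inf
    fdr_star <- NA_real_
    cp <- list(cut_up = Inf, cut_low = -Inf)
  } else {
    delta_star <- deltas[sel[1]]
    fdr_star <- tab$fdr_mono[sel[1]]
    cp <- sam_cutpoints(d_sorted, dbar, delta_star)
  }
  stats <- obs %>%
    mutate(dbar = dbar[rank(.data$d, ties.method = "first")],
           called = .data$d >= cp$cut_up | .data$d <= cp$cut_low,
           direction = if_else(.data$d >= 0, "up", "down"))
  structure(list(
    stats = stats,
    s0 = as.numeric(s0),
    pi0 = pi0,
    delta = delta_star,
    fdr_at_delta = fdr_star,
    cut_up = cp$cut_up, cut_low = cp$cut_low,
    delta_table = tab,
    target_fdr = target_fdr,
    n_perm = nb,
    exhaustive = exhaustive,
    treated = treated,
    seed = seed
  ), class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("<sam_result>", nrow(x$stats), "probes;",
      sprintf("s0 = %.4g, delta = %.4g, est. FDR = %.3g, called = %d (%s permutations%s)",
              x$s0, x$delta, x$fdr_at_delta, sum(x$stats$called), x$n_perm,
              if (x$exhaustive) ", exhaustive" else ""), "\n")
  invisible(x)
}

#' Tidy a SAM fit
#'
#' @param x A `sam_result`.
#' @param ... Unused.
#' @return Per-probe tibble with `probe_id`, `d`, `dbar` (expected order
#'   statistic), `s`, `diff`, `called`, `direction`.
#' @method tidy sam_result
#' @export
tidy.sam_result <- function(x, ...) {
  select(x$stats, "probe_id", "d", "dbar", "s", "diff", "called", "direction")
}

#' One-row summary of a SAM fit
#'
#' @param x A `sam_result`.
#' @param ... Unused.
#' @return Tibble with `s0`, `pi0`, `delta`, `fdr`, `n_called`, `n_up`,
#'   `n_down`, `n_perm`, `exhaustive`.
#' @method glance sam_result
#' @export
glance.sam_result <- function(x, ...) {
  tibble(s0 = x$s0, pi0 = x$pi0, delta = x$delta, fdr = x$fdr_at_delta,
         n_called = sum(x$stats$called),
         n_up = sum(x$stats$called & x$stats$direction == "up"),
         n_down = sum(x$stats$called & x$stats$direction == "down"),
         n_perm = x$n_perm, exhaustive = x$exhaustive)
}
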