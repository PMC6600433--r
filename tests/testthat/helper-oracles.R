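# Independent brute-force oracles. These deliberately share no code with the
# package: plain sort/slice/loop implementations used to freeze expected
# values.

bf_trimmed_mean <- function(x, trim) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  k <- floor(n * trim)
  if (2 * k >= n) return(NA_real_)
  sum(x[(k + 1):(n - k)]) / (n - 2 * k)
}

bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# rule: probe retained iff some group has all samples strictly above its
# array threshold; mat is probes x arrays, thr per array, grp per array
bf_detection_filter <- function(mat, thr, grp) {
  keep <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    for (g in unique(grp)) {
      cols <- which(grp == g)
      ok <- TRUE
      for (j in cols) {
        v <- mat[i, j]
        if (is.na(v) || v <= thr[j]) { ok <- FALSE; break }
      }
      if (ok) { keep[i] <- TRUE; break }
    }
  }
  keep
}

bf_mask_reason <- function(df) {
  out <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    out[i] <-
      if (r$is_control) "control spot"
      else if (r$saturated_ch1 || r$saturated_ch2) "saturated"
      else if (r$nonuniform_ch1 || r$nonuniform_ch2) "non-uniform outlier"
      else if (!(r$above_bg_ch1 || r$above_bg_ch2)) "not above background"
      else "present"
  }
  out
}

# pooled-variance two-sample t statistic, one probe
bf_pooled_t <- function(x_treat, x_ctrl) {
  n1 <- length(x_ctrl); n2 <- length(x_treat)
  sp2 <- (sum((x_ctrl - mean(x_ctrl))^2) + sum((x_treat - mean(x_treat))^2)) /
    (n1 + n2 - 2)
  (mean(x_treat) - mean(x_ctrl)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Brute-force SAM over an exhaustive label enumeration: returns the
# per-delta table (n_called, median FP, fdr) for the same conventions the
# package documents, computed with plain loops.
bf_sam_table <- function(m, labels, s0, deltas, treated) {
  control <- setdiff(unique(labels), treated)
  d_of <- function(lab) {
    it <- which(lab == treated); ic <- which(lab == control)
    n1 <- length(ic); n2 <- length(it)
    d <- numeric(nrow(m))
    for (i in seq_len(nrow(m))) {
      x1 <- m[i, ic]; x2 <- m[i, it]
      s <- sqrt((1 / n1 + 1 / n2) *
                  (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) /
                  (n1 + n2 - 2))
      d[i] <- (mean(x2) - mean(x1)) / (s + s0)
    }
    d
  }
  d_obs <- d_of(labels)
  n <- length(labels)
  n_t <- sum(labels == treated)
  combos <- combn(n, n_t)
  d_perm <- matrix(0, nrow(m), ncol(combos))
  for (b in seq_len(ncol(combos))) {
    lab <- rep(control, n)
    lab[combos[, b]] <- treated
    d_perm[, b] <- d_of(lab)
  }
  dbar <- rowMeans(apply(d_perm, 2, sort))
  d_sorted <- sort(d_obs)
  qs <- quantile(d_perm, c(0.25, 0.75))
  pi0 <- min(1, max(0, sum(d_obs > qs[1] & d_obs < qs[2]) / (0.5 * nrow(m))))
  res <- NULL
  for (delta in deltas) {
    up <- which(d_sorted - dbar >= delta & d_sorted >= 0)
    lo <- which(d_sorted - dbar <= -delta & d_sorted <= 0)
    cut_up <- if (length(up)) min(d_sorted[up]) else Inf
    cut_low <- if (length(lo)) max(d_sorted[lo]) else -Inf
    n_called <- sum(d_obs >= cut_up | d_obs <= cut_low)
    fp <- numeric(ncol(combos))
    for (b in seq_len(ncol(combos))) {
      fp[b] <- sum(d_perm[, b] >= cut_up | d_perm[, b] <= cut_low)
    }
    fdr <- if (n_called == 0) 0 else pi0 * median(fp) / n_called
    res <- rbind(res, data.frame(delta = delta, n_called = n_called,
                                 fp_median = median(fp), fdr = fdr))
  }
  res
}
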