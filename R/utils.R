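# internal helpers shared across modules

# derive a deterministic 32-bit sub-seed from a top-level seed; `k` indexes the
# consumer (array number, stage number, replicate). Linear mixing keeps every
# intermediate below 2^31 so the value survives as.integer() on all platforms.
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 99991 * (k %% 20011) + k) %% 2147483647)
}

# trimmed mean with the both-tails convention: floor(n * trim) observations
# removed from each tail before averaging (base R's convention).
trimmed_mean <- function(x, trim) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean(x, trim = trim)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "concordx_config_error")
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    abort(sprintf("`%s` must be a probability in [0, 1%s.", name,
                  if (allow_one) "]" else ")"),
          class = "concordx_config_error")
  }
  invisible(as.numeric(x))
}

# convert a probe_id + sample-columns tibble to a numeric matrix
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "probe_id" %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), "probe_id")])
  storage.mode(m) <- "double"
  rownames(m) <- expr$probe_id
  m
}

matrix_to_expr <- function(m) {
  dplyr::bind_cols(tibble(probe_id = rownames(m)), as_tibble(m))
}
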