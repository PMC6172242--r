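# shared fixture builders for the test suite

random_rna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small probe library tiling nothing in particular; 12-mers, unique ids
random_probe_table <- function(n, len = 12L) {
  data.frame(probe_id = sprintf("p%02d", seq_len(n)),
             probe_seq = replicate(n, random_rna(len)))
}

# independent structure counter (shares nothing with enumerate_structures):
# counts nested pair sets by last-position recursion
count_structures <- function(seq, model = energy_model()) {
  b <- strsplit(normalize_rna(seq), "")[[1]]
  h <- model$min_hairpin_loop
  memo <- new.env()
  cnt <- function(i, j) {
    if (j - i < h + 1L) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i, j - 1L)
    for (k in i:(j - h - 1L)) {
      if (is.finite(model$emat[b[k], b[j]]))
        total <- total + cnt(i, k - 1L) * cnt(k + 1L, j - 1L)
    }
    memo[[key]] <- total
    total
  }
  n <- length(b)
  if (n < 2L) 1 else cnt(1L, n)
}

# exhaustive optimal weighted set cover (objective max sum v - lambda * |I|)
optimal_cover_objective <- function(starts, ends, v, lambda, L) {
  n <- length(starts)
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    covered <- rep(FALSE, L)
    for (k in idx) covered[starts[k]:ends[k]] <- TRUE
    if (all(covered)) best <- max(best, sum(v[idx]) - lambda * length(idx))
  }
  best
}
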