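# Independent oracles used across tests.

# Literal O(N) running-sum enrichment walk: hits add |stat|^p normalized
# over the set, misses subtract 1/(N - N_hit); returns the signed maximum
# deviation from zero. Positive branch wins ties, matching the engine.
oracle_es <- function(stats, set, p = 1) {
  hit <- names(stats) %in% set
  w <- abs(stats)^p
  w[!hit] <- 0
  w <- w / sum(w[hit])
  step <- ifelse(hit, w, -1 / sum(!hit))
  rs <- cumsum(step)
  mx <- max(rs); mn <- min(rs)
  if (mx >= -mn) mx else mn
}

# Textbook Pearson correlation on raw sums.
oracle_pcc <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Small CPM matrix builder for filter tests.
make_cpm <- function(values, genes = sprintf("g%d", seq_len(nrow(values))),
                     samples = sprintf("s%d", seq_len(ncol(values)))) {
  m <- matrix(values, nrow = length(genes),
              dimnames = list(genes, samples))
  expr_matrix(m, unit = "CPM")
}

# Shared small fixture: a simulated panel at reduced size, built once per
# test run (cached in the test environment).
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_ccl_panel(n_lines = 60, n_genes = 300,
                                   n_markers = 20, seed = 101)
    cache
  }
})
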