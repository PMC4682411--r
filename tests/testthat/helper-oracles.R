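# Independent oracles used across the suite. These deliberately avoid the
# package's code paths (and stats::fisher.test): direct enumeration and
# plain loops only.

# One-sided (enrichment) Fisher p by exhaustive hypergeometric enumeration:
# sum the point probabilities of every table with the same margins whose
# top-left cell is at least the observed one.
fisher_greater_oracle <- function(a, b, c, d) {
  K <- a + c            # sensitive margin
  n1 <- a + b           # inhibited margin
  N <- a + b + c + d
  xs <- max(0, n1 - (N - K)):min(n1, K)
  logpr <- lchoose(K, xs) + lchoose(N - K, n1 - xs) - lchoose(N, n1)
  sum(exp(logpr)[xs >= a])
}

# Signed running-max rank-enrichment statistic by a plain element-wise loop
# over the matched positions.
ks_oracle <- function(V, n) {
  t <- length(V)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - V[j] / n)
    b <- max(b, V[j] / n - (j - 1) / t)
  }
  if (a >= b) a else -b
}

# Brute-force kinase scoring straight off the (compound, kinase, bin)
# incidence list.
score_oracle <- function(bins, inh, scheme) {
  bins <- bins[!is.na(bins)]
  out <- list()
  for (d in names(bins)) {
    for (k in colnames(inh)) {
      if (inh[d, k]) out[[k]] <- (out[[k]] %||% 0L) + scheme$points[[as.character(bins[[d]])]]
    }
  }
  unlist(out)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# the implementation's one-sided Fisher p for a 2x2 given cell-wise
fisher_p_impl <- function(a, b, c, d) {
  association_test(matrix(c(a, b, c, d), 2, byrow = TRUE))$fisher_p
}

# minimal reference profile (Kd readout, potency = rank index)
make_profile <- function(n, inhibitor = "INH", source = "default") {
  list(inhibitor = inhibitor, source = source, measure = "Kd_uM",
       kinases = sprintf("K%02d", seq_len(n)), potencies = seq_len(n) / 10)
}

toy_dir <- function() system.file("extdata", "toy", package = "karmap")

small_sim_config <- function(seed, ...) {
  sim_config(n_cell_lines = 4L, n_compounds = 20L, n_kinases = 50L,
             seed = seed, ...)
}
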