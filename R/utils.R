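# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state.
# Mersenne-Twister / Inversion are pinned so outputs are stable across machines.
with_preserved_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == trunc(x)
}

# first slash component of a canonical kinase label = the gene symbol used
# for expression lookup; complex partners (cyclins, p25, ...) follow the "/"
gene_of <- function(kinase_label) sub("/.*$", "", kinase_label)
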