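#' Build potency-ranked inhibitor reference profiles
#'
#' Each inhibitor's kinase measurements are turned into a rank-ordered list,
#' most potently inhibited kinase first: ascending Kd/IC50, or descending
#' percent inhibition. Ties are broken alphabetically by kinase label so
#' that profiles are deterministic. Profiles from different sources are kept
#' separate (the panels use incommensurable readouts), and an inhibitor
#' mixing measure types within one source is an error.
#'
#' @param binding a [binding_profile()].
#' @param min_kinases inhibitors with fewer measured kinases are skipped
#'   with a warning (default 2).
#' @return list of class `kmap_reference`; each element has fields
#'   `inhibitor`, `source`, `measure`, `kinases` (ordered canonical labels)
#'   and `potencies`.
#' @export
build_reference <- function(binding, min_kinases = 2L) {
  stopifnot(inherits(binding, "binding_profile"))
  key <- paste(binding$compound, binding$source, sep = "\r")
  groups <- split(seq_len(nrow(binding)), key)
  profiles <- list()
  for (g in groups) {
    d <- binding[g, , drop = FALSE]
    inhibitor <- d$compound[1]
    src <- d$source[1]
    if (length(unique(d$measure)) > 1L)
      stop("inhibitor ", sQuote(inhibitor), " (source ", sQuote(src),
           ") mixes measure types; profiles must be single-readout")
    if (length(unique(d$kinase)) < nrow(d))
      stop("inhibitor ", sQuote(inhibitor), " has duplicate kinase entries")
    if (nrow(d) < min_kinases) {
      warning("inhibitor ", sQuote(inhibitor), " has fewer than ",
              min_kinases, " measured kinases; skipped")
      next
    }
    ord <- if (d$measure[1] == "percent_inhibition")
      order(-d$value, d$kinase) else order(d$value, d$kinase)
    profiles[[length(profiles) + 1L]] <- list(
      inhibitor = inhibitor, source = src, measure = d$measure[1],
      kinases = d$kinase[ord], potencies = d$value[ord])
  }
  # deterministic profile order regardless of input row order
  ord <- order(vapply(profiles, function(p) paste(p$inhibitor, p$source),
                      character(1)))
  structure(profiles[ord], class = "kmap_reference")
}

#' @export
print.kmap_reference <- function(x, ...) {
  cat("connectivity-map reference:", length(x), "inhibitor profile(s)\n")
  invisible(x)
}

# core statistic on 1-based ranks V (sorted ascending) within a profile of
# length n: signed running-max enrichment of the matched query positions
ks_from_ranks <- function(V, n) {
  t <- length(V)
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  # ties resolve to the positive (top-enrichment) side so that a query
  # occupying exactly the top t ranks always attains the maximum statistic,
  # including the degenerate n = t + 1 profile
  if (a >= b) a else -b
}

#' Kolmogorov-Smirnov enrichment of a query kinase set in a profile
#'
#' The rank-based pattern-matching statistic of the connectivity-map
#' approach. With `n` the profile length, `t` the number of query kinases
#' present in the profile and `V(j)` the 1-based profile rank of the j-th
#' matched kinase (ascending), the statistic is `a = max_j (j/t - V(j)/n)`
#' if it exceeds `b = max_j (V(j)/n - (j-1)/t)`, else `-b`. Positive values
#' mean the query concentrates near the top (most potently inhibited end)
#' of the profile.
#'
#' Query kinases absent from the profile are ignored; their number is
#' reported so callers can penalize incomplete coverage.
#'
#' @param query character vector of kinase labels (canonicalized with
#'   [parse_kinase_label()]).
#' @param profile one element of a [build_reference()] result.
#' @return list with `raw_ks` (`NA` when no query kinase matches),
#'   `n_matched` and `n` (profile length).
#' @export
ks_statistic <- function(query, profile) {
  q <- unique(parse_kinase_label(query)$display)
  n <- length(profile$kinases)
  V <- sort(match(q, profile$kinases))
  V <- V[!is.na(V)]
  if (length(V) == 0L)
    return(list(raw_ks = NA_real_, n_matched = 0L, n = n))
  list(raw_ks = ks_from_ranks(V, n), n_matched = length(V), n = n)
}

#' Normalize the KS statistic to a connectivity score in \[0, 1\]
#'
#' Only top-of-profile enrichment counts as efficacy: the positive part of
#' the raw statistic is divided by its achievable maximum `1 - t/n`, so a
#' query occupying exactly the top `t` ranks scores 1 (maximal efficacy)
#' and bottom- or non-enrichment scores 0 (minimal efficacy).
#'
#' @param raw_ks raw statistic from [ks_statistic()].
#' @param t number of matched query kinases (>= 1).
#' @param n profile length (> t).
#' @return connectivity score in \[0, 1\].
#' @export
connectivity_score <- function(raw_ks, t, n) {
  stopifnot(t >= 1, n > t)
  pmin(1, pmax(0, raw_ks) / (1 - t / n))
}

# vectorized null connectivity scores for random t-subsets of an n-profile
null_connectivity_scores <- function(n, t, n_perm) {
  V <- matrix(0L, n_perm, t)
  for (i in seq_len(n_perm)) V[i, ] <- sort.int(sample.int(n, t))
  jt <- matrix(rep(seq_len(t) / t, each = n_perm), n_perm)
  jt0 <- matrix(rep((seq_len(t) - 1) / t, each = n_perm), n_perm)
  A <- jt - V / n
  B <- V / n - jt0
  a <- A[cbind(seq_len(n_perm), max.col(A, ties.method = "first"))]
  b <- B[cbind(seq_len(n_perm), max.col(B, ties.method = "first"))]
  raw <- ifelse(a >= b, a, -b)
  pmin(1, pmax(0, raw) / (1 - t / n))
}

#' Permutation p-value for a connectivity score
#'
#' Null model: connectivity scores of uniformly random kinase subsets of the
#' same size drawn from the profile. The default p-value uses add-one
#' smoothing, `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, which is
#' valid (super-uniform) but conservative because null scores are discrete
#' with a large atom at 0. `randomized = TRUE` instead breaks ties with a
#' uniform draw, `p = (#\{null > obs\} + U (1 + #\{null = obs\})) / (1 +
#' n_perm)`, which is exactly uniform when the observed score is itself a
#' null draw — the form used for calibration checks.
#'
#' @param query_size number of matched query kinases (t).
#' @param profile one reference profile.
#' @param observed_score connectivity score to test.
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed integer seed (mandatory; the caller owns reproducibility).
#' @param randomized use the tie-randomized p-value (default FALSE).
#' @return p-value in (0, 1].
#' @export
permutation_p <- function(query_size, profile, observed_score,
                          n_perm = 10000L, seed, randomized = FALSE) {
  stopifnot(n_perm >= 100L, query_size >= 1L)
  n <- length(profile$kinases)
  stopifnot(query_size < n)
  if (missing(seed)) stop("`seed` is required for reproducible permutation")
  with_preserved_seed(seed, {
    null <- null_connectivity_scores(n, query_size, n_perm)
    eps <- 1e-12
    if (randomized) {
      (sum(null > observed_score + eps) +
         stats::runif(1) * (1 + sum(abs(null - observed_score) <= eps))) /
        (1 + n_perm)
    } else {
      (1 + sum(null >= observed_score - eps)) / (1 + n_perm)
    }
  })
}

#' Query the connectivity map
#'
#' Scores every reference inhibitor against a query kinase set (by default
#' the top-ranked kinases of a dependency ranking), computes permutation
#' p-values, and returns both the full table and the hit list filtered to
#' `perm_p < alpha`, sorted by score descending (ties: p ascending, then
#' inhibitor label). Inhibitors whose profile contains no query kinase are
#' not connectable: score 0, `perm_p` 1.
#'
#' @param query character vector of kinase labels.
#' @param reference a [build_reference()] result.
#' @param alpha significance level for the hit list (default 0.05).
#' @param n_perm permutations per inhibitor (default 10000).
#' @param seed integer seed; per-inhibitor streams are derived from it.
#' @return list of class `kmap_result` with data.frames `results` (all
#'   inhibitors) and `hits` (filtered), columns: rank, inhibitor, source,
#'   score, raw_ks, n_matched, perm_p, passes_alpha.
#' @export
query_kmap <- function(query, reference, alpha = 0.05, n_perm = 10000L,
                       seed = 1L) {
  stopifnot(inherits(reference, "kmap_reference"), length(reference) > 0L)
  q <- unique(parse_kinase_label(query)$display)
  rows <- lapply(seq_along(reference), function(i) {
    p <- reference[[i]]
    ks <- ks_statistic(q, p)
    if (ks$n_matched == 0L || ks$n_matched >= ks$n) {
      # no overlap (not connectable) or full coverage leaves no ranking
      # freedom; a profile made entirely of query kinases is trivially 1
      score <- if (ks$n_matched == 0L) 0 else 1
      perm_p <- 1
      raw <- ks$raw_ks
    } else {
      score <- connectivity_score(ks$raw_ks, ks$n_matched, ks$n)
      perm_p <- permutation_p(ks$n_matched, p, score, n_perm,
                              seed = seed + i)
      raw <- ks$raw_ks
    }
    data.frame(inhibitor = p$inhibitor, source = p$source, score = score,
               raw_ks = raw, n_matched = ks$n_matched, perm_p = perm_p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$perm_p, res$inhibitor), , drop = FALSE]
  res$passes_alpha <- res$perm_p < alpha
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res <- res[, c("rank", "inhibitor", "source", "score", "raw_ks",
                 "n_matched", "perm_p", "passes_alpha")]
  hits <- res[res$passes_alpha, , drop = FALSE]
  if (nrow(hits) > 0L) hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  structure(list(results = res, hits = hits, query = q, alpha = alpha),
            class = "kmap_result")
}

#' @export
print.kmap_result <- function(x, ...) {
  cat("connectivity query [", paste(x$query, collapse = ", "), "]: ",
      nrow(x$hits), " of ", nrow(x$results), " inhibitors pass alpha = ",
      x$alpha, "\n", sep = "")
  if (nrow(x$hits) > 0L) print(utils::head(x$hits, 10))
  invisible(x)
}

#' Write connectivity-map results as TSV
#' @param x a `kmap_result`.
#' @param path output path for the full table; the filtered hit list goes to
#'   `<path>` with suffix `.hits.tsv` unless `hits_path` is given.
#' @param hits_path optional path for the hit list.
#' @return invisibly, the paths written.
#' @export
write_kmap_results <- function(x, path, hits_path = NULL) {
  utils::write.table(x$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hits_path <- hits_path %||% sub("(\\.tsv)?$", ".hits.tsv", path)
  utils::write.table(x$hits, hits_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, hits_path))
}
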