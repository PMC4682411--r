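#' Dichotomize quantitative binding data into an inhibition matrix
#'
#' A kinase counts as inhibited by a compound when any of its records
#' satisfies the potency threshold: Kd or IC50 strictly below `kd_thresh`
#' (uM), or percent inhibition strictly above `inh_thresh`. Boundary values
#' (Kd = 1 uM, 85\%) are therefore *not* inhibited.
#'
#' @param profile a [binding_profile()].
#' @param kd_thresh Kd/IC50 cutoff in uM (default 1).
#' @param inh_thresh percent-inhibition cutoff (default 85).
#' @return logical matrix, compounds x kinases (canonical display labels,
#'   sorted), with the thresholds recorded in attributes `kd_thresh` and
#'   `inh_thresh`.
#' @export
dichotomize <- function(profile, kd_thresh = 1, inh_thresh = 85) {
  stopifnot(kd_thresh > 0, inh_thresh > 0)
  cmp <- unique(profile$compound)
  kin <- sort(unique(profile$kinase))
  m <- matrix(FALSE, length(cmp), length(kin), dimnames = list(cmp, kin))
  if (nrow(profile) > 0L) {
    hit <- (profile$measure %in% c("Kd_uM", "IC50_uM") & profile$value < kd_thresh) |
           (profile$measure == "percent_inhibition" & profile$value > inh_thresh)
    idx <- cbind(match(profile$compound, cmp), match(profile$kinase, kin))[hit, , drop = FALSE]
    m[idx] <- TRUE
  }
  attr(m, "kd_thresh") <- kd_thresh
  attr(m, "inh_thresh") <- inh_thresh
  m
}

#' Select compounds usable for kinase scoring
#'
#' A compound is usable when it appears in both the drug screen and the
#' binding data (compound names matched case-insensitively) and inhibits at
#' least one kinase above threshold.
#'
#' @param screen a [drug_screen()].
#' @param inh inhibition matrix from [dichotomize()].
#' @return character vector of usable compounds in the screen's spelling.
#' @export
select_usable_drugs <- function(screen, inh) {
  sc <- compounds(screen)
  bc <- rownames(inh)
  common <- bc[toupper(bc) %in% toupper(sc)]
  usable_b <- common[rowSums(inh[common, , drop = FALSE]) >= 1L]
  usable <- sc[match(toupper(usable_b), toupper(sc))]
  if (length(usable) == 0L)
    stop("no usable compounds: none are present in both the screen and the ",
         "binding data with at least one inhibited kinase")
  usable
}

#' Assign compounds of one cell line to sensitivity bins
#'
#' Bin b covers EC50 in `(boundary[b-1], boundary[b]]` with `boundary[0] = 0`
#' and `boundary[5] = Inf`. Inactive-at-max-dose compounds go to bin 5;
#' missing EC50s stay unassigned (`NA`, compound skipped for this cell line).
#'
#' @param ec50 named numeric vector of EC50s (uM) for one cell line; `NA`
#'   where missing or inactive.
#' @param scheme a [bin_scheme()].
#' @param inactive logical vector parallel to `ec50` flagging
#'   tested-but-inactive compounds.
#' @return named integer vector of bins in 1..5 (`NA` = unassigned).
#' @export
assign_bins <- function(ec50, scheme = bin_scheme(), inactive = NULL) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (is.null(inactive)) inactive <- rep(FALSE, length(ec50))
  stopifnot(length(inactive) == length(ec50))
  bins <- rep(NA_integer_, length(ec50))
  present <- !is.na(ec50)
  if (any(present)) {
    # number of boundaries strictly below the value -> (lo, hi] bins
    bins[present] <- 1L + as.integer(
      rowSums(outer(ec50[present], scheme$boundaries, ">")))
  }
  bins[inactive] <- 5L
  names(bins) <- names(ec50)
  bins
}

#' Per-cell-line quantile bin boundaries
#'
#' Boundaries at the given quantiles of the observed (non-missing,
#' non-inactive) EC50s, for screens whose potency range is shifted relative
#' to the default absolute cutoffs.
#'
#' @param ec50 numeric vector of EC50s with `NA` for unobserved entries.
#' @param probs four ascending probabilities (default 20/40/60/80th
#'   percentiles).
#' @return numeric vector of 4 boundaries.
#' @export
quantile_boundaries <- function(ec50, probs = c(0.2, 0.4, 0.6, 0.8)) {
  stopifnot(length(probs) == 4L)
  q <- stats::quantile(ec50, probs = probs, na.rm = TRUE, names = FALSE)
  if (is.unsorted(q, strictly = TRUE))
    stop("quantile boundaries are not strictly ascending; ",
         "too few distinct EC50 values for quantile binning")
  q
}

#' Filter kinases on expression in one sample
#'
#' Low-expressed kinases are removed before scoring: a kinase is kept when
#' its first gene component has log2 expression at or above the cutoff in
#' the sample. Kinases whose gene is absent from the expression table are
#' kept and flagged `"unmeasured"` rather than silently dropped.
#'
#' @param kinases character vector of canonical kinase labels.
#' @param expr genes x samples expression matrix ([read_expression()]).
#' @param sample sample (cell line) identifier, must be a column of `expr`.
#' @param cutoff numeric cutoff; a quantile in \[0,1\] when
#'   `type = "percentile"` (taken over the sample's per-gene values), or
#'   absolute log2 units when `type = "absolute"`.
#' @param type cutoff interpretation.
#' @return data.frame with columns `kinase`, `gene`, `expression`,
#'   `status` (`"expressed"`, `"low"`, `"unmeasured"`) and `keep`
#'   (`status != "low"`).
#' @export
filter_expressed <- function(kinases, expr, sample, cutoff = 0.25,
                             type = c("percentile", "absolute")) {
  type <- match.arg(type)
  if (!sample %in% colnames(expr))
    stop("sample ", sQuote(sample), " not found in the expression table")
  v <- expr[, sample]
  cut_val <- if (type == "percentile")
    stats::quantile(v, probs = cutoff, names = FALSE) else cutoff
  genes <- gene_of(kinases)
  measured <- genes %in% rownames(expr)
  value <- rep(NA_real_, length(kinases))
  value[measured] <- expr[genes[measured], sample]
  status <- ifelse(!measured, "unmeasured",
                   ifelse(value >= cut_val, "expressed", "low"))
  data.frame(kinase = kinases, gene = genes, expression = value,
             status = status, keep = status != "low",
             stringsAsFactors = FALSE)
}

#' Score kinases from sensitivity bins and the inhibition matrix
#'
#' Each kinase accumulates the bin point value of every usable compound that
#' inhibits it: `raw_score(k) = sum over assigned compounds c inhibiting k
#' of points[bin(c)]`. Kinases inhibited by no assigned compound get no
#' record.
#'
#' @param bins named integer vector of bins (from [assign_bins()]); `NA`
#'   entries are skipped.
#' @param inh inhibition matrix (compounds x kinases); row names must cover
#'   the named bins.
#' @param kinases kinase labels to score (default: all columns of `inh`).
#' @param scheme a [bin_scheme()] supplying the point values.
#' @return named integer vector of raw scores for the kinases inhibited by
#'   at least one assigned compound.
#' @export
score_kinases <- function(bins, inh, kinases = colnames(inh),
                          scheme = bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  bins <- bins[!is.na(bins)]
  if (length(bins) == 0L) return(stats::setNames(integer(0), character(0)))
  missing_rows <- setdiff(names(bins), rownames(inh))
  if (length(missing_rows) > 0L)
    stop("compounds without binding rows: ", paste(missing_rows, collapse = ", "))
  sub <- inh[names(bins), intersect(kinases, colnames(inh)), drop = FALSE]
  hit_counts <- colSums(sub)
  pts <- scheme$points[as.character(bins)]
  scores <- as.integer(round(drop(crossprod(sub, pts))))
  names(scores) <- colnames(sub)
  scores[hit_counts >= 1L]
}

#' Contingency table of inhibition vs drug sensitivity for one kinase
#'
#' Rows: kinase inhibited / not inhibited by the compound. Columns: compound
#' sensitive (bins 1-3) / insensitive (bins 4-5). Cells sum to the number of
#' usable compounds assigned a bin in the cell line.
#'
#' @param bins named integer bins (`NA` skipped).
#' @param inh inhibition matrix.
#' @param kinase a kinase label (column of `inh`).
#' @return 2x2 integer matrix.
#' @export
kinase_contingency <- function(bins, inh, kinase) {
  bins <- bins[!is.na(bins)]
  hit <- inh[names(bins), kinase]
  sens <- bins <= 3L
  matrix(c(sum(hit & sens), sum(hit & !sens),
           sum(!hit & sens), sum(!hit & !sens)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("inhibited", "not_inhibited"),
                         c("sensitive", "insensitive")))
}

#' Chi-square and one-sided Fisher tests on a 2x2 table
#'
#' Tests the association between a kinase being inhibited and the inhibiting
#' compound being sensitive (bins 1-3). The chi-square test is Pearson's
#' without continuity correction (1 df); when a row or column margin is
#' zero the statistic is undefined and `chi2_p` is reported as 1. The Fisher
#' test is one-sided for *enrichment* of sensitive compounds among the
#' inhibitors (dependency is a directional hypothesis).
#'
#' @param contingency 2x2 matrix of non-negative integer counts, rows =
#'   inhibited / not inhibited, columns = sensitive / insensitive.
#' @return list with `chi2_p`, `fisher_p`, `min_expected` (smallest expected
#'   cell count, `Inf` when a margin is zero) and `reported_p`
#'   (`fisher_p` when any expected count < 5, else `chi2_p`).
#' @export
association_test <- function(contingency) {
  tab <- as.matrix(contingency)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("`contingency` must be a 2x2 table")
  if (any(tab < 0) || any(tab != trunc(tab)) || sum(tab) < 1)
    stop("`contingency` must hold non-negative integer counts, total >= 1")
  n <- sum(tab)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    chi2_p <- 1
    min_expected <- Inf
  } else {
    expected <- outer(rowSums(tab), colSums(tab)) / n
    min_expected <- min(expected)
    chi2_p <- suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  fisher_p <- stats::fisher.test(tab, alternative = "greater")$p.value
  reported_p <- if (degenerate || min_expected < 5) fisher_p else chi2_p
  list(chi2_p = chi2_p, fisher_p = fisher_p,
       min_expected = min_expected, reported_p = reported_p)
}

#' Rank scored kinases for one cell line
#'
#' Order: reported p ascending, then raw score descending, then kinase label
#' ascending. A kinase is flagged significant when its reported p-value is
#' below `alpha` *and* its raw score is non-negative (the bin-5 penalty
#' encodes evidence against dependency, so net-negative kinases are never
#' called dependent). A BH-adjusted column (`fdr`) is emitted for reference;
#' the significance flag uses the unadjusted p.
#'
#' @param records data.frame with one row per scored kinase, columns
#'   `kinase`, `raw_score`, the four contingency cells (`n_inh_sens`,
#'   `n_inh_insens`, `n_noninh_sens`, `n_noninh_insens`), `chi2_p`,
#'   `fisher_p`, `reported_p`, `direction`, `expressed`.
#' @param alpha significance level (default 0.05).
#' @param cell_line identifier stored on the result.
#' @return data.frame of class `kinase_ranking` sorted as above with added
#'   columns `rank`, `fdr`, `significant`; attributes `cell_line` and
#'   `n_significant`.
#' @export
rank_kinases <- function(records, alpha = 0.05, cell_line = NA_character_) {
  if (nrow(records) > 0L) {
    ord <- order(records$reported_p, -records$raw_score, records$kinase)
    records <- records[ord, , drop = FALSE]
    records$rank <- seq_len(nrow(records))
    records$fdr <- stats::p.adjust(records$reported_p, method = "BH")
    records$significant <- records$reported_p < alpha & records$raw_score >= 0
    rownames(records) <- NULL
  } else {
    records$rank <- integer(0)
    records$fdr <- numeric(0)
    records$significant <- logical(0)
  }
  attr(records, "cell_line") <- cell_line
  attr(records, "n_significant") <- sum(records$significant)
  class(records) <- c("kinase_ranking", "data.frame")
  records
}

#' Run the kinase dependency ranking pipeline
#'
#' For every cell line of the screen: select usable compounds (present in
#' both screen and binding data and inhibiting at least one kinase), assign
#' sensitivity bins from the EC50s, filter out low-expressed kinases, score
#' each remaining kinase by summing bin points over the compounds that
#' inhibit it, test the inhibition-sensitivity association (chi-square and
#' one-sided Fisher) and rank by p-value with the score as tie-break.
#' Deterministic for fixed inputs and configuration and invariant to the
#' row/column order of all inputs.
#'
#' @param screen a [drug_screen()].
#' @param binding a [binding_profile()].
#' @param expr optional genes x samples expression matrix; every cell line
#'   must be among its samples. `NULL` skips expression filtering.
#' @param config a [kar_config()].
#' @return named list of [rank_kinases()] results (class `kar_result`), one
#'   per cell line, with attributes `usable_drugs` and `config`.
#' @export
run_kar <- function(screen, binding, expr = NULL, config = kar_config()) {
  stopifnot(inherits(screen, "drug_screen"),
            inherits(binding, "binding_profile"),
            inherits(config, "kar_config"))
  inh <- dichotomize(binding, config$kd_thresh, config$inh_thresh)
  usable <- select_usable_drugs(screen, inh)
  # binding-side spelling of the usable compounds
  brow <- rownames(inh)[match(toupper(usable), toupper(rownames(inh)))]

  out <- lapply(cell_lines(screen), function(cl) {
    ec50 <- screen$ec50[cl, usable]
    inactive <- screen$inactive[cl, usable]
    names(ec50) <- names(inactive) <- brow
    scheme <- config$scheme
    if (config$bin_mode == "quantile") {
      scheme <- tryCatch(
        bin_scheme(quantile_boundaries(ec50, config$quantile_probs),
                   config$scheme$points),
        error = function(e) stop("cell line ", sQuote(cl), ": ",
                                 conditionMessage(e)))
    }
    bins <- assign_bins(ec50, scheme, inactive)
    assigned <- !is.na(bins)
    if (!any(assigned)) {
      warning("cell line ", sQuote(cl), ": no usable compound has an ",
              "assigned bin; returning an empty ranking")
      return(rank_kinases(empty_records(), config$alpha, cl))
    }
    bins <- bins[assigned]
    hit_any <- colSums(inh[names(bins), , drop = FALSE]) >= 1L
    kin <- colnames(inh)[hit_any]
    expressed <- rep("unfiltered", length(kin))
    names(expressed) <- kin
    if (!is.null(expr)) {
      if (!cl %in% colnames(expr))
        stop("cell line ", sQuote(cl), " not found in the expression table")
      flt <- filter_expressed(kin, expr, cl, config$expr_cutoff,
                              config$expr_cutoff_type)
      expressed <- stats::setNames(flt$status, flt$kinase)
      kin <- flt$kinase[flt$keep]
    }
    if (length(kin) == 0L) {
      warning("cell line ", sQuote(cl), ": no kinase passes the expression ",
              "filter; returning an empty ranking")
      return(rank_kinases(empty_records(), config$alpha, cl))
    }
    scores <- score_kinases(bins, inh, kin, scheme)
    recs <- lapply(names(scores), function(k) {
      tab <- kinase_contingency(bins, inh, k)
      tst <- association_test(tab)
      cross <- tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]
      data.frame(kinase = k, raw_score = scores[[k]],
                 n_inh_sens = tab[1, 1], n_inh_insens = tab[1, 2],
                 n_noninh_sens = tab[2, 1], n_noninh_insens = tab[2, 2],
                 chi2_p = tst$chi2_p, fisher_p = tst$fisher_p,
                 reported_p = tst$reported_p,
                 direction = if (cross > 0) "positive"
                             else if (cross < 0) "negative" else "none",
                 expressed = unname(expressed[k]),
                 stringsAsFactors = FALSE)
    })
    rank_kinases(do.call(rbind, recs), config$alpha, cl)
  })
  names(out) <- cell_lines(screen)
  structure(out, class = "kar_result", usable_drugs = usable, config = config)
}

empty_records <- function() {
  data.frame(kinase = character(0), raw_score = integer(0),
             n_inh_sens = integer(0), n_inh_insens = integer(0),
             n_noninh_sens = integer(0), n_noninh_insens = integer(0),
             chi2_p = numeric(0), fisher_p = numeric(0),
             reported_p = numeric(0), direction = character(0),
             expressed = character(0), stringsAsFactors = FALSE)
}

#' Read per-cell-line ranking TSVs back into a result object
#'
#' Inverse of [write_kar_rankings()] for the `ranking_<cell line>.tsv`
#' files (the cell line is recovered from the file name, so characters
#' sanitized on writing stay sanitized).
#'
#' @param dir directory holding `ranking_*.tsv` files.
#' @return a `kar_result` list usable by the reporting functions.
#' @export
read_kar_rankings <- function(dir) {
  files <- sort(list.files(dir, pattern = "^ranking_.*\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no ranking_*.tsv files found under ", sQuote(dir))
  out <- list()
  for (f in files) {
    cl <- sub("^ranking_", "", sub("\\.tsv$", "", basename(f)))
    r <- utils::read.table(f, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
    attr(r, "cell_line") <- cl
    attr(r, "n_significant") <- sum(r$significant)
    class(r) <- c("kinase_ranking", "data.frame")
    out[[cl]] <- r
  }
  structure(out, class = "kar_result")
}

#' @export
print.kar_result <- function(x, ...) {
  cat("kinase dependency rankings for", length(x), "cell line(s):\n")
  for (cl in names(x)) {
    cat("  ", cl, ": ", nrow(x[[cl]]), " kinases scored, ",
        attr(x[[cl]], "n_significant"), " significant\n", sep = "")
  }
  invisible(x)
}

RANKING_COLUMNS <- c("rank", "kinase", "raw_score", "chi2_p", "fisher_p",
                     "reported_p", "fdr", "significant", "direction",
                     "expressed", "n_inh_sens", "n_inh_insens",
                     "n_noninh_sens", "n_noninh_insens")

#' Write per-cell-line rankings and the combined score matrix
#'
#' One `ranking_<cell line>.tsv` per cell line (fixed column order:
#' rank, kinase, raw_score, chi2_p, fisher_p, reported_p, fdr, significant,
#' direction, expressed, then the four contingency cells) plus
#' `score_matrix.tsv`, the cell-line x kinase raw-score matrix over all
#' scored kinases (0 where a kinase was not scored in a cell line).
#'
#' @param result a `kar_result` from [run_kar()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_kar_rankings <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cl in names(result)) {
    p <- file.path(dir, paste0("ranking_", gsub("[^A-Za-z0-9._-]", "_", cl), ".tsv"))
    utils::write.table(result[[cl]][, RANKING_COLUMNS], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  m <- score_matrix(result, kinases = sort(unique(unlist(
    lapply(result, function(r) r$kinase)))))
  mp <- file.path(dir, "score_matrix.tsv")
  out <- data.frame(cell_line = rownames(m), m, check.names = FALSE)
  utils::write.table(out, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, mp))
}
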