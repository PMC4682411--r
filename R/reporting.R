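#' Kinases significant in at least one cell line
#'
#' @param result a `kar_result` from [run_kar()].
#' @return sorted character vector (possibly empty, with a warning).
#' @export
significant_union <- function(result) {
  stopifnot(length(result) >= 1L)
  u <- sort(unique(unlist(lapply(result, function(r) r$kinase[r$significant]))))
  if (length(u) == 0L)
    warning("no kinase is significant in any cell line; empty score matrix")
  u
}

#' Cell-line x kinase raw-score matrix
#'
#' Builds the matrix underlying the clustered dependency heatmap. By default
#' it is restricted to kinases significant in at least one cell line;
#' kinases not scored in a given cell line contribute a raw score of 0.
#'
#' @param result a `kar_result`.
#' @param kinases kinase labels to include (default [significant_union()]).
#' @return numeric matrix, cell lines x kinases.
#' @export
score_matrix <- function(result, kinases = significant_union(result)) {
  m <- matrix(0, length(result), length(kinases),
              dimnames = list(names(result), kinases))
  for (cl in names(result)) {
    r <- result[[cl]]
    keep <- r$kinase %in% kinases
    m[cl, r$kinase[keep]] <- r$raw_score[keep]
  }
  m
}

#' Standardize matrix columns to mean 0, SD 1
#'
#' Population standard deviation (divisor `n`, not `n - 1`). Zero-variance
#' columns become all-zero rather than NaN.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape.
#' @export
zscore_columns <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(!is.finite(m))) stop("matrix entries must be finite")
  mu <- colMeans(m)
  centered <- sweep(m, 2, mu)
  sd_pop <- sqrt(colMeans(centered^2))
  z <- sweep(centered, 2, ifelse(sd_pop > 0, sd_pop, 1), "/")
  z[, sd_pop == 0] <- 0
  z
}

#' Hierarchical clustering of both matrix axes
#'
#' Agglomerative clustering of rows and of columns with the given distance
#' metric and linkage (defaults: Euclidean, average). Returns leaf orders,
#' the merge trees, and newick renderings of the trees. `stats::hclust` is
#' deterministic (equal-height merges are taken in input index order), so
#' results are reproducible for a fixed matrix.
#'
#' @param m numeric matrix with >= 2 rows and >= 2 columns, finite entries.
#' @param metric distance method passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `row_order`, `col_order` (leaf label orders),
#'   `row_tree`, `col_tree` (`hclust` objects) and `row_newick`,
#'   `col_newick` (newick strings).
#' @export
cluster_axes <- function(m, metric = "euclidean", linkage = "average") {
  stopifnot(is.matrix(m), nrow(m) >= 2L, ncol(m) >= 2L)
  if (any(!is.finite(m))) stop("matrix entries must be finite")
  ht <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  vt <- stats::hclust(stats::dist(t(m), method = metric), method = linkage)
  list(row_order = rownames(m)[ht$order],
       col_order = colnames(m)[vt$order],
       row_tree = ht, col_tree = vt,
       row_newick = ape::write.tree(ape::as.phylo(ht)),
       col_newick = ape::write.tree(ape::as.phylo(vt)))
}

#' Log-scale EC50 matrix for sensitivity clustering
#'
#' Counterpart of the dependency-score heatmap built directly from the drug
#' screen: log10(EC50) per cell line and compound. EC50 spans orders of
#' magnitude, so distances on the raw uM scale would be dominated by the
#' least potent drugs. Missing and inactive-at-max-dose entries are imputed
#' to the maximum tested concentration (default: the largest observed EC50),
#' recorded in attribute `imputed_value`.
#'
#' @param screen a [drug_screen()].
#' @param max_conc imputation concentration in uM (default: max observed).
#' @return numeric matrix of log10(EC50), cell lines x compounds.
#' @export
ec50_cluster_matrix <- function(screen, max_conc = NULL) {
  stopifnot(inherits(screen, "drug_screen"))
  max_conc <- max_conc %||% max(screen$ec50, na.rm = TRUE)
  m <- screen$ec50
  m[is.na(m)] <- max_conc
  out <- log10(m)
  attr(out, "imputed_value") <- max_conc
  out
}

#' Write the clustered, z-scored dependency report
#'
#' Emits the canonical text artifacts of the heatmap figure: the z-scored
#' score matrix (TSV), the row/column leaf orders, and the merge trees in
#' newick form. An optional PNG heatmap is drawn when `heatmap = TRUE` and
#' the `pheatmap` package is available.
#'
#' @param result a `kar_result`.
#' @param dir output directory.
#' @param metric,linkage clustering parameters, see [cluster_axes()].
#' @param heatmap draw a convenience PNG (default FALSE).
#' @return invisibly, the list from [cluster_axes()] (NULL when no kinase is
#'   significant anywhere).
#' @export
write_report <- function(result, dir, metric = "euclidean",
                         linkage = "average", heatmap = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kin <- significant_union(result)
  if (length(kin) == 0L) return(invisible(NULL))
  z <- zscore_columns(score_matrix(result, kin))
  out <- data.frame(cell_line = rownames(z), z, check.names = FALSE)
  utils::write.table(out, file.path(dir, "zscored_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cl <- NULL
  if (nrow(z) >= 2L && ncol(z) >= 2L) {
    cl <- cluster_axes(z, metric, linkage)
    writeLines(cl$row_order, file.path(dir, "row_order.txt"))
    writeLines(cl$col_order, file.path(dir, "col_order.txt"))
    writeLines(cl$row_newick, file.path(dir, "row_tree.nwk"))
    writeLines(cl$col_newick, file.path(dir, "col_tree.nwk"))
    if (heatmap && requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(file.path(dir, "heatmap.png"), width = 1200, height = 900)
      pheatmap::pheatmap(z, clustering_distance_rows = metric,
                         clustering_distance_cols = metric,
                         clustering_method = linkage)
      grDevices::dev.off()
    }
  }
  invisible(cl)
}
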