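#' Sensitivity bin scheme
#'
#' Compounds are assigned to one of five sensitivity bins per cell line from
#' their EC50: bin b covers EC50 in `(boundary[b-1], boundary[b]]` uM with
#' `boundary[0] = 0` and `boundary[5] = Inf`. Each bin carries a point value
#' awarded to every kinase target of a compound in that bin; bins 4 and 5
#' hold compounds that fail the sensitivity threshold, with bin 5 penalized.
#'
#' @param boundaries four strictly ascending positive EC50 cutoffs in uM.
#'   Default `c(0.1, 1, 5, 10)`.
#' @param points named integer vector of point values for bins `"1"`..`"5"`,
#'   non-increasing with bin number. Default `20, 10, 5, 0, -10`.
#' @return object of class `bin_scheme`.
#' @export
bin_scheme <- function(boundaries = c(0.1, 1, 5, 10),
                       points = c(`1` = 20, `2` = 10, `3` = 5, `4` = 0, `5` = -10)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 4L || any(!is.finite(boundaries)) ||
      any(boundaries <= 0) || is.unsorted(boundaries, strictly = TRUE))
    stop("`boundaries` must be 4 strictly ascending positive EC50 cutoffs (uM)")
  points <- points[as.character(1:5)]
  if (anyNA(points))
    stop("`points` must provide values for all five bins named \"1\"..\"5\"")
  if (any(diff(as.numeric(points)) > 0))
    stop("bin point values must be non-increasing with bin number")
  if (any(points != trunc(points))) stop("bin point values must be integers")
  structure(list(boundaries = boundaries,
                 points = stats::setNames(as.integer(points), as.character(1:5))),
            class = "bin_scheme")
}

#' Configuration for the kinase dependency ranking pipeline
#'
#' Collects every tunable threshold of [run_kar()].
#'
#' @param kd_thresh Kd/IC50 dichotomization cutoff in uM; a kinase counts as
#'   inhibited when the measured value is strictly below it. Default 1 uM.
#' @param inh_thresh percent-inhibition cutoff; inhibited when strictly above.
#'   Default 85.
#' @param scheme a [bin_scheme()].
#' @param bin_mode `"absolute"` (fixed uM boundaries) or `"quantile"`
#'   (per-cell-line boundaries at `quantile_probs` of the observed EC50s,
#'   for screens with shifted potency ranges).
#' @param quantile_probs probabilities used in quantile mode.
#' @param expr_cutoff_type `"percentile"` (cutoff is a quantile of the
#'   sample's per-gene log2 values) or `"absolute"` (log2 units).
#' @param expr_cutoff numeric cutoff; default the 25th percentile.
#' @param alpha significance level on the reported p-value. Default 0.05;
#'   no multiple-testing correction is applied to the flag, but a BH-FDR
#'   column is emitted alongside.
#' @param sentinel inactive-at-max-dose token used by the readers/writers.
#' @return list of class `kar_config`.
#' @export
kar_config <- function(kd_thresh = 1, inh_thresh = 85,
                       scheme = bin_scheme(),
                       bin_mode = c("absolute", "quantile"),
                       quantile_probs = c(0.2, 0.4, 0.6, 0.8),
                       expr_cutoff_type = c("percentile", "absolute"),
                       expr_cutoff = 0.25,
                       alpha = 0.05,
                       sentinel = "GT_MAX") {
  bin_mode <- match.arg(bin_mode)
  expr_cutoff_type <- match.arg(expr_cutoff_type)
  stopifnot(kd_thresh > 0, inh_thresh > 0, inherits(scheme, "bin_scheme"),
            alpha > 0, alpha < 1, is.numeric(expr_cutoff))
  if (expr_cutoff_type == "percentile" && (expr_cutoff < 0 || expr_cutoff > 1))
    stop("percentile expression cutoff must lie in [0, 1]")
  structure(list(kd_thresh = kd_thresh, inh_thresh = inh_thresh,
                 scheme = scheme, bin_mode = bin_mode,
                 quantile_probs = quantile_probs,
                 expr_cutoff_type = expr_cutoff_type, expr_cutoff = expr_cutoff,
                 alpha = alpha, sentinel = sentinel),
            class = "kar_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [kar_config()]; `boundaries` and
#' `points` populate the [bin_scheme()]. Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a `kar_config`.
#' @export
read_kar_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", sQuote(path))
  y <- yaml::read_yaml(path) %||% list()
  sch <- bin_scheme(
    boundaries = y$boundaries %||% c(0.1, 1, 5, 10),
    points = if (!is.null(y$points)) stats::setNames(unlist(y$points), names(y$points))
             else c(`1` = 20, `2` = 10, `3` = 5, `4` = 0, `5` = -10)
  )
  args <- y[intersect(names(y), c("kd_thresh", "inh_thresh", "bin_mode",
                                  "quantile_probs", "expr_cutoff_type",
                                  "expr_cutoff", "alpha", "sentinel"))]
  do.call(kar_config, c(args, list(scheme = sch)))
}
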