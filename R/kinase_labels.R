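#' Parse kinase labels, including kinase-complex entries
#'
#' Binding panels report some targets as complexes, e.g. `"CDK2 / cyclin A"`
#' or `"CDK5 / p25"`. The slash-separated components are split, stray markup
#' (`*`, backticks, underscores) and whitespace are removed, and every
#' component is upper-cased. The first component is taken as the kinase gene
#' symbol (the unit used for expression filtering); the remaining components
#' are regulatory partners kept only for display.
#'
#' Parsing is deterministic and idempotent: re-parsing a canonical display
#' label returns the same label.
#'
#' @param raw character vector of kinase labels.
#' @return data.frame with one row per input label and columns
#'   `raw` (the input), `gene` (first component, upper-cased),
#'   `display` (canonical label, components joined by `/` without spaces)
#'   and `n_components`.
#' @examples
#' parse_kinase_label(c("CDK2 / cyclin A", "EGFR", "*CDK5 */ p25"))
#' @export
parse_kinase_label <- function(raw) {
  if (!is.character(raw) || length(raw) == 0L)
    stop("`raw` must be a non-empty character vector")
  parts <- lapply(raw, function(x) {
    x <- gsub("[*_`]", "", x)
    comp <- strsplit(x, "/", fixed = TRUE)[[1]]
    comp <- toupper(gsub("[[:space:]]+", "", comp))
    comp <- comp[nzchar(comp)]
    if (length(comp) == 0L)
      stop("kinase label ", sQuote(x), " is empty after trimming")
    comp
  })
  data.frame(
    raw = raw,
    gene = vapply(parts, `[[`, character(1), 1L),
    display = vapply(parts, paste, character(1), collapse = "/"),
    n_components = lengths(parts),
    stringsAsFactors = FALSE
  )
}

#' Canonical display label for kinase identifiers
#'
#' Shorthand for `parse_kinase_label(raw)$display`.
#' @param raw character vector of kinase labels.
#' @return character vector of canonical labels.
#' @export
canonical_kinase_label <- function(raw) parse_kinase_label(raw)$display
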