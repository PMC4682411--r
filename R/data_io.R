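ALLOWED_MEASURES <- c("Kd_uM", "IC50_uM", "percent_inhibition")

# comma/tab auto-detection from the header line; decimal point only
detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("file ", sQuote(path), " is empty")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate ", what, ": ", paste(sQuote(dup), collapse = ", "))
  invisible(ids)
}

#' Construct and validate a drug-sensitivity screen
#'
#' A `drug_screen` holds a cell-line x compound matrix of EC50 values in
#' micromolar. Two kinds of non-numeric entry are distinguished because they
#' must contribute differently to kinase scoring:
#' * *missing* (`NA`, blank cell on disk): the compound was not tested in
#'   that cell line and is skipped when scoring it;
#' * *inactive at the top dose* (sentinel token on disk, default `"GT_MAX"`):
#'   the compound was tested but produced no EC50 below the maximal
#'   concentration, and is assigned to the least-sensitive bin.
#'
#' @param ec50 numeric matrix (cell lines x compounds), entries in uM; `NA`
#'   where missing or inactive.
#' @param inactive logical matrix of the same shape; `TRUE` marks
#'   tested-but-inactive entries. Default: none.
#' @return object of class `drug_screen` with elements `ec50` and `inactive`.
#' @export
drug_screen <- function(ec50, inactive = NULL) {
  if (!is.matrix(ec50) || !is.numeric(ec50))
    stop("`ec50` must be a numeric matrix")
  if (is.null(rownames(ec50)) || is.null(colnames(ec50)))
    stop("`ec50` must have cell-line row names and compound column names")
  if (nrow(ec50) < 1L || ncol(ec50) < 2L)
    stop("need at least 1 cell line and 2 compounds")
  check_unique(rownames(ec50), "cell-line identifiers")
  dup_cmp <- unique(colnames(ec50)[duplicated(toupper(colnames(ec50)))])
  if (length(dup_cmp) > 0L)
    stop("duplicate compound identifiers (case-insensitive): ",
         paste(sQuote(dup_cmp), collapse = ", "))
  if (is.null(inactive)) {
    inactive <- matrix(FALSE, nrow(ec50), ncol(ec50), dimnames = dimnames(ec50))
  }
  if (!identical(dim(inactive), dim(ec50)))
    stop("`inactive` must match the shape of `ec50`")
  if (any(!is.na(ec50) & inactive))
    stop("inactive entries must not carry an EC50 value")
  bad <- which(!is.na(ec50) & ec50 <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-positive EC50 at cell line ", sQuote(rownames(ec50)[bad[1, 1]]),
         ", compound ", sQuote(colnames(ec50)[bad[1, 2]]))
  structure(list(ec50 = ec50, inactive = inactive), class = "drug_screen")
}

#' @export
print.drug_screen <- function(x, ...) {
  cat("drug_screen:", nrow(x$ec50), "cell lines x", ncol(x$ec50), "compounds;",
      sum(is.na(x$ec50) & !x$inactive), "missing,",
      sum(x$inactive), "inactive-at-max-dose\n")
  invisible(x)
}

#' Cell-line identifiers of a drug screen
#' @param x a `drug_screen`.
#' @return character vector.
#' @export
cell_lines <- function(x) rownames(x$ec50)

#' Compound identifiers of a drug screen
#' @param x a `drug_screen`.
#' @return character vector (first-seen spelling).
#' @export
compounds <- function(x) colnames(x$ec50)

#' Read a drug-sensitivity screen from TSV/CSV
#'
#' Wide format: header row of compound names, first column of cell-line
#' names, EC50 values in micromolar. The field separator (comma or tab) is
#' auto-detected from the header line. Blank cells are missing (not tested);
#' the `sentinel` token marks tested-but-inactive entries.
#'
#' @param path file path.
#' @param sentinel token for inactive-at-max-dose entries (default `"GT_MAX"`).
#' @return a [drug_screen()].
#' @export
read_drug_screen <- function(path, sentinel = "GT_MAX") {
  if (!file.exists(path)) stop("file not found: ", sQuote(path))
  sep <- detect_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("screen table needs >= 2 compound columns")
  cl <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  # data.frame subsetting uniquifies duplicate headers; restore the raw ones
  colnames(vals) <- names(tab)[-1]
  rownames(vals) <- cl
  inactive <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  ec50 <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (j in seq_len(ncol(vals))) {
    v <- trimws(vals[, j])
    blank <- !nzchar(v) | v %in% c("NA", "na")
    inact <- v == sentinel
    num <- suppressWarnings(as.numeric(v))
    bad <- !blank & !inact & is.na(num)
    if (any(bad))
      stop("unparseable EC50 ", sQuote(v[which(bad)[1]]), " at cell line ",
           sQuote(cl[which(bad)[1]]), ", compound ", sQuote(colnames(vals)[j]))
    num[blank | inact] <- NA_real_
    ec50[, j] <- num
    inactive[, j] <- inact
  }
  drug_screen(ec50, inactive)
}

#' Write a drug screen as TSV
#'
#' Inverse of [read_drug_screen()]: missing entries become blank cells,
#' inactive entries the sentinel token. Numeric values are written with
#' full (round-trippable) precision.
#'
#' @param x a `drug_screen`.
#' @param path output path.
#' @param sep field separator (default tab).
#' @param sentinel inactive-at-max-dose token.
#' @export
write_drug_screen <- function(x, path, sep = "\t", sentinel = "GT_MAX") {
  chr <- matrix("", nrow(x$ec50), ncol(x$ec50), dimnames = dimnames(x$ec50))
  present <- !is.na(x$ec50)
  chr[present] <- sprintf("%.17g", x$ec50[present])
  chr[x$inactive] <- sentinel
  out <- data.frame(cell_line = rownames(chr), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate a kinase-binding profile
#'
#' Long-format records of quantitative compound-kinase measurements. Kinase
#' labels are canonicalized with [parse_kinase_label()]; compound names are
#' matched case-insensitively and stored with their first-seen spelling.
#'
#' Value ranges enforced: Kd/IC50 strictly positive; percent inhibition in
#' \[-100, 120\] (assays can report slightly out-of-range values).
#'
#' @param records data.frame with columns `compound`, `kinase`, `value`,
#'   `measure` (one of `Kd_uM`, `IC50_uM`, `percent_inhibition`) and an
#'   optional `source` column naming the originating panel.
#' @return data.frame of class `binding_profile` with columns `compound`,
#'   `kinase` (canonical display label), `gene`, `value`, `measure`, `source`.
#' @export
binding_profile <- function(records) {
  need <- c("compound", "kinase", "value", "measure")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("binding records lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("binding profile has no records")
  bad_measure <- setdiff(unique(records$measure), ALLOWED_MEASURES)
  if (length(bad_measure) > 0L)
    stop("unknown measure token(s) ", paste(sQuote(bad_measure), collapse = ", "),
         "; allowed: ", paste(ALLOWED_MEASURES, collapse = ", "))
  value <- as.numeric(records$value)
  if (anyNA(value)) stop("non-numeric binding value")
  aff <- records$measure %in% c("Kd_uM", "IC50_uM")
  if (any(aff & value <= 0))
    stop("Kd/IC50 values must be > 0 (offending compound: ",
         sQuote(records$compound[which(aff & value <= 0)[1]]), ")")
  pct <- records$measure == "percent_inhibition"
  if (any(pct & (value < -100 | value > 120)))
    stop("percent_inhibition outside [-100, 120] (offending compound: ",
         sQuote(records$compound[which(pct & (value < -100 | value > 120))[1]]), ")")

  parsed <- parse_kinase_label(as.character(records$kinase))
  # compound names: case-insensitive identity, first-seen spelling kept
  cmp_raw <- as.character(records$compound)
  first_seen <- cmp_raw[!duplicated(toupper(cmp_raw))]
  cmp <- first_seen[match(toupper(cmp_raw), toupper(first_seen))]
  src <- if ("source" %in% names(records)) as.character(records$source)
         else rep("default", nrow(records))

  key <- paste(toupper(cmp), parsed$display, records$measure, src, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    f <- strsplit(dup[1], "\r", fixed = TRUE)[[1]]
    stop("duplicate binding record: compound ", sQuote(f[1]), ", kinase ",
         sQuote(f[2]), ", measure ", sQuote(f[3]))
  }
  out <- data.frame(compound = cmp, kinase = parsed$display, gene = parsed$gene,
                    value = value, measure = as.character(records$measure),
                    source = src, stringsAsFactors = FALSE)
  class(out) <- c("binding_profile", "data.frame")
  out
}

#' Read a kinase-binding profile from TSV/CSV
#'
#' Long format with columns `compound`, `kinase`, `value`, `measure`
#' (and optionally `source`); separator auto-detected.
#'
#' @param path file path.
#' @return a [binding_profile()].
#' @export
read_binding <- function(path) {
  if (!file.exists(path)) stop("file not found: ", sQuote(path))
  sep <- detect_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  binding_profile(tab)
}

#' Write a binding profile as TSV
#' @param x a `binding_profile`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_binding <- function(x, path, sep = "\t") {
  out <- data.frame(compound = x$compound, kinase = x$kinase,
                    value = sprintf("%.17g", x$value), measure = x$measure,
                    source = x$source, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a log2 expression table from TSV/CSV
#'
#' Wide format: first column gene symbols, remaining columns samples, values
#' log2-normalized expression (e.g. RMA output; normalization itself is
#' upstream of this package). Gene symbols are upper-cased and must be
#' unique after upper-casing; all values must be finite.
#'
#' @param path file path.
#' @return numeric matrix, genes (upper-cased) x samples.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", sQuote(path))
  sep <- detect_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  genes <- toupper(as.character(tab[[1]]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expression_table(m)
}

#' Validate an expression matrix
#' @param values numeric matrix, genes x samples, log2 scale.
#' @return the validated matrix (genes upper-cased).
#' @export
expression_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must form a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  rownames(values) <- toupper(rownames(values))
  check_unique(rownames(values), "gene symbols (after upper-casing)")
  check_unique(colnames(values), "sample identifiers")
  if (any(!is.finite(values))) stop("expression values must be finite")
  values
}

#' Write an expression table as TSV
#' @param x genes x samples numeric matrix.
#' @param path output path.
#' @param sep field separator.
#' @export
write_expression <- function(x, path, sep = "\t") {
  chr <- matrix(sprintf("%.17g", x), nrow(x), dimnames = dimnames(x))
  out <- data.frame(gene = rownames(x), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
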