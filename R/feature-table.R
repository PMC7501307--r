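#' The 20 canonical amino acids in AAindex I-line order
#'
#' One-letter codes in the fixed order used by the AAindex1 `I` line
#' (`A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V`, first row then second row).
#' All membership bit vectors and code strings in this package index residues
#' in this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a residue-by-feature table
#'
#' A feature table holds one numeric value per residue per feature (an
#' "index" in AAindex parlance), together with per-feature metadata:
#' a free-text description, the set of residues whose value was missing in
#' the source and imputed to zero, and any correlated-accession listing
#' carried along from an AAindex `C` line (metadata only; never used in
#' computations).
#'
#' @param values Numeric matrix, rows = residues (rownames are the residue
#'   labels, defining the table's alphabet and its order), columns = features
#'   (colnames are the accessions).
#' @param descriptions Optional named character vector of feature
#'   descriptions, names matching accessions. Missing entries default to `""`.
#' @param missing Optional named list mapping accession to a character vector
#'   of residue labels whose value was absent in the source and set to 0.
#' @param correlated Optional named list mapping accession to a data frame
#'   with columns `accession` and `correlation`.
#' @return An object of class `feature_table`: a list with elements
#'   `alphabet`, `values`, `descriptions`, `missing`, `correlated`.
#' @examples
#' ft <- feature_table(matrix(1:20, 20, 1,
#'   dimnames = list(AA_ALPHABET, "TOY00001")))
#' ft
#' @export
feature_table <- function(values, descriptions = NULL, missing = list(),
                          correlated = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  alphabet <- rownames(values)
  acc <- colnames(values)
  if (ncol(values) > 0L && is.null(acc))
    stop("feature values must have accession column names")
  if (nrow(values) > 0L && is.null(alphabet))
    stop("feature values must have residue row names")
  if (anyDuplicated(alphabet))
    stop("duplicate residue labels in alphabet: ",
         paste(unique(alphabet[duplicated(alphabet)]), collapse = ", "))
  if (anyDuplicated(acc))
    stop("duplicate accessions: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  if (any(!nzchar(acc)))
    stop("accessions must be non-empty strings")
  if (any(!is.finite(values)))
    stop("feature values must be finite numbers (missing values are ",
         "imputed to 0 at parse time and flagged)")
  desc <- setNames(rep("", length(acc)), acc)
  if (!is.null(descriptions)) {
    keep <- intersect(names(descriptions), acc)
    desc[keep] <- descriptions[keep]
  }
  miss <- setNames(vector("list", length(acc)), acc)
  for (a in acc) {
    m <- if (a %in% names(missing)) as.character(missing[[a]]) else character(0)
    bad <- setdiff(m, alphabet)
    if (length(bad))
      stop("missing-value labels not in alphabet for ", a, ": ",
           paste(bad, collapse = ", "))
    if (length(m) && any(values[m, a] != 0))
      stop("missing-flagged values must be exactly 0 (accession ", a, ")")
    miss[[a]] <- m
  }
  corr <- setNames(vector("list", length(acc)), acc)
  for (a in intersect(names(correlated), acc)) corr[[a]] <- correlated[[a]]
  structure(list(alphabet = alphabet, values = values, descriptions = desc,
                 missing = miss, correlated = corr),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table: ", length(x$alphabet), " residues x ",
      ncol(x$values), " features\n", sep = "")
  if (length(x$alphabet))
    cat("  alphabet: ", paste(x$alphabet, collapse = " "), "\n", sep = "")
  acc <- colnames(x$values)
  if (length(acc)) {
    show <- utils::head(acc, 6L)
    cat("  features: ", paste(show, collapse = ", "),
        if (length(acc) > 6L) ", ..." else "", "\n", sep = "")
  }
  nmiss <- sum(lengths(x$missing))
  if (nmiss) cat("  ", nmiss, " missing value(s) imputed to 0\n", sep = "")
  invisible(x)
}

#' Accessions of a feature table
#' @param table A `feature_table`.
#' @return Character vector of accessions in table order.
#' @export
accessions <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  colnames(table$values)
}

#' Values of one feature over the alphabet
#' @param table A `feature_table`.
#' @param accession Single accession present in the table.
#' @return Named numeric vector over the alphabet, in alphabet order.
#' @export
feature_values <- function(table, accession) {
  stopifnot(inherits(table, "feature_table"))
  if (!accession %in% colnames(table$values))
    stop("unknown accession: ", accession)
  setNames(table$values[, accession], table$alphabet)
}

#' Restrict a table to a subset of features
#'
#' Keeps the listed accessions in list order. Unknown accessions are dropped
#' with a warning and recorded in the result's `"unknown_accessions"`
#' attribute, so a curation list can be applied verbatim even when some of
#' its entries are absent from the input file.
#'
#' @param table A `feature_table`.
#' @param keep Non-empty character vector of accessions.
#' @return A `feature_table` with the selected features, in `keep` order.
#' @export
filter_features <- function(table, keep) {
  stopifnot(inherits(table, "feature_table"))
  keep <- as.character(keep)
  if (!length(keep)) stop("accession list must be non-empty")
  acc <- colnames(table$values)
  unknown <- setdiff(keep, acc)
  found <- keep[keep %in% acc]
  if (length(unknown))
    warning("unknown accession(s) ignored: ", paste(unknown, collapse = ", "))
  out <- feature_table(table$values[, found, drop = FALSE],
                       descriptions = table$descriptions[found],
                       missing = table$missing[found],
                       correlated = table$correlated[found])
  attr(out, "unknown_accessions") <- unknown
  out
}

#' Drop one residue from a table
#'
#' Used by the leave-one-residue-out redundancy profile: the returned table
#' has a 19-letter alphabet and medians/cuts recomputed downstream refer to
#' the reduced value sets.
#'
#' @param table A `feature_table`.
#' @param residue Single residue label present in the alphabet.
#' @return A `feature_table` without that residue.
#' @export
drop_residue <- function(table, residue) {
  stopifnot(inherits(table, "feature_table"))
  if (!residue %in% table$alphabet)
    stop("residue not in alphabet: ", residue)
  keep <- setdiff(table$alphabet, residue)
  miss <- lapply(table$missing, function(m) setdiff(m, residue))
  feature_table(table$values[keep, , drop = FALSE],
                descriptions = table$descriptions,
                missing = miss, correlated = table$correlated)
}
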