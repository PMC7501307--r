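# AAindex1 flat-file dialect: entries are blocks of keyed lines (H accession,
# D description, R/A/T/J bibliography, C correlated accessions, I value
# header + two continuation rows of 10 values), terminated by "//".
# Continuation lines start with whitespace. The I header row
# "A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V" fixes the residue order: first
# value row -> A R N D C Q E G H I, second -> L K M F P S T W Y V.

.AAINDEX_I_HEADER <- c("A/L", "R/K", "N/M", "D/F", "C/P",
                       "Q/S", "E/T", "G/W", "H/Y", "I/V")

#' Parse AAindex1 flat-file text
#'
#' Reads zero or more AAindex1 entries from text. For each entry the `H`
#' accession, `D` description, `C` correlated-accession pairs and the 20
#' `I`-line values are retained. The token `NA` (used by AAindex for values
#' that are missing or not defined) is imputed to 0 and the residue is
#' recorded in the feature's missing set, matching the database's own
#' convention of arbitrarily setting absent values to zero.
#'
#' @param text Character vector of lines, or a single string containing
#'   newlines.
#' @return A [feature_table] over [AA_ALPHABET], one feature per entry, in
#'   entry order.
#' @seealso [read_aaindex()] to read from a file, [write_feature_table()]
#'   for the inverse.
#' @export
parse_aaindex1 <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  entries <- list()
  cur <- character(0)
  for (ln in text) {
    if (identical(trimws(ln), "//")) {
      if (length(cur)) entries[[length(entries) + 1L]] <- cur
      cur <- character(0)
    } else if (nzchar(trimws(ln)) || length(cur)) {
      cur <- c(cur, ln)
    }
  }
  if (length(cur) && any(nzchar(trimws(cur))))
    stop("truncated AAindex1 entry: no terminating //")

  recs <- lapply(entries, .parse_aaindex1_entry)
  acc <- vapply(recs, `[[`, "", "accession")
  if (anyDuplicated(acc))
    stop("duplicate accession in AAindex1 input: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  vals <- matrix(0, length(AA_ALPHABET), length(recs),
                 dimnames = list(AA_ALPHABET, acc))
  miss <- setNames(vector("list", length(recs)), acc)
  desc <- setNames(character(length(recs)), acc)
  corr <- setNames(vector("list", length(recs)), acc)
  for (i in seq_along(recs)) {
    vals[, i] <- recs[[i]]$values
    miss[[i]] <- recs[[i]]$missing
    desc[[i]] <- recs[[i]]$description
    corr[[i]] <- recs[[i]]$correlated
  }
  feature_table(vals, descriptions = desc, missing = miss, correlated = corr)
}

# One entry: lines without the trailing "//".
.parse_aaindex1_entry <- function(lines) {
  key <- ifelse(grepl("^[A-Z*] ?", lines) & !grepl("^\\s", lines),
                substr(lines, 1L, 1L), NA_character_)
  # carry keys forward over continuation lines
  for (i in seq_along(key)) if (is.na(key[i]) && i > 1L) key[i] <- key[i - 1L]
  body <- sub("^[A-Z*] ?", "", lines)
  body[grepl("^\\s", lines)] <- lines[grepl("^\\s", lines)]

  grab <- function(k) trimws(body[which(key == k)])
  h <- grab("H")
  h <- h[nzchar(h)]
  if (length(h) != 1L || !nzchar(h))
    stop("AAindex1 entry without a single H accession line")
  accession <- strsplit(h, "\\s+")[[1]][1]

  d <- paste(grab("D"), collapse = " ")

  corr <- NULL
  ctoks <- unlist(strsplit(paste(grab("C"), collapse = " "), "\\s+"))
  ctoks <- ctoks[nzchar(ctoks)]
  if (length(ctoks)) {
    if (length(ctoks) %% 2L != 0L)
      stop("malformed C line in entry ", accession,
           ": expected accession/coefficient pairs")
    cc <- suppressWarnings(as.numeric(ctoks[c(FALSE, TRUE)]))
    if (anyNA(cc))
      stop("non-numeric correlation coefficient in entry ", accession)
    corr <- data.frame(accession = ctoks[c(TRUE, FALSE)], correlation = cc,
                       stringsAsFactors = FALSE)
  }

  ilines <- grab("I")
  ilines <- ilines[nzchar(ilines)]
  if (length(ilines) < 1L)
    stop("entry ", accession, " has no I line")
  header <- strsplit(ilines[1], "\\s+")[[1]]
  if (!identical(header, .AAINDEX_I_HEADER))
    stop("entry ", accession, ": unrecognized I-line header (expected '",
         paste(.AAINDEX_I_HEADER, collapse = " "), "')")
  toks <- unlist(strsplit(ilines[-1], "\\s+"))
  toks <- toks[nzchar(toks)]
  if (length(toks) != 20L)
    stop("entry ", accession, ": expected 20 value tokens on the I line, got ",
         length(toks))
  isna <- toks %in% c("NA", "NA.")
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals) & !isna))
    stop("entry ", accession, ": non-numeric value token '",
         toks[which(is.na(vals) & !isna)[1]], "'")
  vals[isna] <- 0
  # first row of 10 -> A R N D C Q E G H I, second -> L K M F P S T W Y V,
  # which is exactly AA_ALPHABET order when read row by row
  values <- setNames(vals, AA_ALPHABET)
  list(accession = accession, description = d, values = values,
       missing = AA_ALPHABET[isna], correlated = corr)
}

#' Read an AAindex1 flat file
#'
#' @param path Path to an AAindex1-format file.
#' @return A [feature_table].
#' @export
read_aaindex <- function(path) parse_aaindex1(readLines(path))

# %.17g round-trips any double through decimal text exactly
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a feature table
#'
#' Two interchange formats are supported, both lossless round-trips with
#' their readers:
#' \describe{
#'   \item{`tsv`}{UTF-8, tab-delimited; header `residue` followed by the
#'     accessions, one row per residue. Missing-imputed cells are written as
#'     the literal token `NA` so the missing flags survive the round trip.}
#'   \item{`aaindex1`}{the standard entry layout (H/D/C/I lines, `//`
#'     terminator), `NA` tokens for missing-imputed values. Requires the
#'     20-residue canonical alphabet.}
#' }
#' Numbers are printed with enough digits to reproduce the double exactly.
#'
#' @param table A [feature_table].
#' @param path Output file path.
#' @param format `"tsv"` or `"aaindex1"`.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, format = c("tsv", "aaindex1")) {
  stopifnot(inherits(table, "feature_table"))
  format <- match.arg(format)
  lines <- if (format == "tsv") .format_tsv(table) else .format_aaindex1(table)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

.format_tsv <- function(table) {
  acc <- colnames(table$values)
  header <- paste(c("residue", acc), collapse = "\t")
  rows <- vapply(seq_along(table$alphabet), function(i) {
    r <- table$alphabet[i]
    cells <- vapply(acc, function(a) {
      if (r %in% table$missing[[a]]) "NA" else .fmt_num(table$values[r, a])
    }, "")
    paste(c(r, cells), collapse = "\t")
  }, "")
  c(header, rows)
}

.format_aaindex1 <- function(table) {
  if (!identical(table$alphabet, AA_ALPHABET))
    stop("aaindex1 output requires the canonical 20-residue alphabet")
  acc <- colnames(table$values)
  unlist(lapply(acc, function(a) {
    cells <- vapply(AA_ALPHABET, function(r) {
      if (r %in% table$missing[[a]]) "NA" else .fmt_num(table$values[r, a])
    }, "")
    entry <- c(paste("H", a),
               paste("D", table$descriptions[[a]]))
    cr <- table$correlated[[a]]
    if (!is.null(cr) && nrow(cr))
      entry <- c(entry, paste("C", paste(cr$accession, .fmt_num(cr$correlation),
                                         collapse = " ")))
    c(entry,
      paste("I ", paste(.AAINDEX_I_HEADER, collapse = "  ")),
      paste0("    ", paste(cells[1:10], collapse = "  ")),
      paste0("    ", paste(cells[11:20], collapse = "  ")),
      "//")
  }))
}

#' Read a feature-table TSV
#'
#' Inverse of [write_feature_table()] with `format = "tsv"`. The alphabet is
#' taken from the row order; `NA` cells become value 0 with the residue
#' flagged missing.
#'
#' @param path Path to a TSV file.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty feature-table file")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (header[1] != "residue")
    stop("feature-table TSV must start with a 'residue' header column")
  acc <- header[-1]
  body <- cells[-1]
  if (any(lengths(body) != length(header)))
    stop("ragged rows in feature-table TSV")
  alphabet <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(alphabet))
    stop("duplicate residue labels in feature-table TSV")
  vals <- matrix(0, length(alphabet), length(acc),
                 dimnames = list(alphabet, acc))
  miss <- setNames(rep(list(character(0)), length(acc)), acc)
  for (i in seq_along(body)) {
    toks <- body[[i]][-1]
    isna <- toks == "NA"
    v <- suppressWarnings(as.numeric(toks))
    if (any(is.na(v) & !isna))
      stop("non-numeric cell in row ", alphabet[i])
    v[isna] <- 0
    vals[i, ] <- v
    for (j in which(isna)) miss[[acc[j]]] <- c(miss[[acc[j]]], alphabet[i])
  }
  feature_table(vals, missing = miss)
}

#' Read an accession-list config file
#'
#' Plain text, one accession per line; `#` starts a comment; blank lines are
#' ignored. Used to apply a curated feature selection to a parsed database.
#'
#' @param path Path to the list file.
#' @return Character vector of accessions in file order.
#' @export
read_accession_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
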