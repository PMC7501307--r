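# Downstream analyses on solution sets: which residues are redundant (the
# search finds more classifications when they are left out), and where a
# candidate non-canonical amino acid would land in the code space of each
# solution.

#' Restrict a separation pool to a reduced alphabet
#'
#' Drops one residue from every membership vector, leaving thresholds and
#' separations otherwise untouched; cut sizes are recounted on the reduced
#' alphabet. Used by the leave-one-out redundancy profile.
#'
#' @param pool A `separation_pool`.
#' @param residue Residue label to remove.
#' @return A `separation_pool` over the reduced alphabet.
#' @export
restrict_pool <- function(pool, residue) {
  stopifnot(inherits(pool, "separation_pool"))
  alpha <- attr(pool, "alphabet")
  i <- match(residue, alpha)
  if (is.na(i)) stop("residue not in pool alphabet: ", residue)
  df <- as.data.frame(pool)
  df$membership <- paste0(substr(df$membership, 1L, i - 1L),
                          substr(df$membership, i + 1L, length(alpha)))
  df$cut_size <- nchar(df$membership) -
    vapply(strsplit(df$membership, ""), function(b) sum(b == "1"), 0L)
  new_pool(df, alpha[-i])
}

#' Leave-one-residue-out redundancy profile
#'
#' For each residue, re-runs the solution search with that residue left out
#' and records the increase in solution count over the full-alphabet
#' baseline. The separation pool is the one learned from the full table
#' (each median or cut applied to all 20 amino acids, as in pool
#' construction itself); leaving a residue out only restricts the membership
#' vectors and the uniqueness requirement to the remaining 19. Under this
#' reading every full-alphabet solution stays valid after any deletion, so
#' the additional count is never negative, and residues whose removal
#' unlocks many new classifications are the redundant ones — they most often
#' share a code cell with another residue.
#'
#' @param table A [feature_table] over the full alphabet.
#' @param mode,k,size_bounds,f,force_median Passed to [candidate_pool()].
#' @param distinct_features Passed to [find_solutions()].
#' @return A `redundancy_profile`: list with `baseline_count` and
#'   `per_residue` (named integer vector of additional solutions).
#' @export
redundancy_profile <- function(table, mode = c("median", "cuts"), k = 3L,
                               size_bounds = NULL, f = 5L,
                               force_median = FALSE,
                               distinct_features = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  mode <- match.arg(mode)
  if (length(table$alphabet) < 2L)
    stop("redundancy profiling needs at least 2 residues")
  pool <- candidate_pool(table, mode, k, size_bounds, f, force_median)
  baseline <- length(find_solutions(pool, f, distinct_features))
  per <- vapply(table$alphabet, function(r) {
    length(find_solutions(restrict_pool(pool, r), f, distinct_features)) -
      baseline
  }, 0L)
  structure(list(baseline_count = baseline,
                 per_residue = setNames(per, table$alphabet)),
            class = "redundancy_profile")
}

#' @export
print.redundancy_profile <- function(x, ...) {
  cat("Redundancy profile (baseline: ", x$baseline_count,
      " solution(s))\n", sep = "")
  o <- order(-x$per_residue, names(x$per_residue))
  df <- data.frame(residue = names(x$per_residue)[o],
                   additional_solutions = unname(x$per_residue)[o])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a redundancy profile as TSV
#' @param profile A `redundancy_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_redundancy_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "redundancy_profile"))
  df <- data.frame(residue = names(profile$per_residue),
                   additional_solutions = unname(profile$per_residue))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Empty-niche assessment of a candidate amino acid
#'
#' Assigns the candidate an f-bit code in every solution by the same
#' threshold rule the canonical residues obeyed (low iff value <= the
#' separation's threshold; thresholds are those learned from the canonical
#' set — the candidate does not shift them), and counts how often that code
#' is an empty niche. Solutions requiring a feature value the candidate
#' lacks (absent or `NA`) are skipped and counted separately, since some
#' features (e.g. helix propensities) cannot be directly determined for
#' non-canonical amino acids.
#'
#' @param solutions An `aa_solutions` list (non-empty).
#' @param candidate Named numeric vector of feature values keyed by
#'   accession.
#' @param label Candidate name used in the report.
#' @return A `niche_report`: list with `candidate`, `per_solution` (data
#'   frame: solution, code, was_empty, skipped), `empty_niche_count`,
#'   `skipped_count`.
#' @export
niche_assessment <- function(solutions, candidate, label = "candidate") {
  if (!length(solutions)) stop("no solutions to assess against")
  candidate <- unlist(candidate)
  rows <- lapply(seq_along(solutions), function(i) {
    s <- solutions[[i]]
    acc <- s$separations$accession
    have <- acc %in% names(candidate) & !is.na(candidate[acc])
    if (!all(have))
      return(data.frame(solution = i, code = NA_character_,
                        was_empty = NA, skipped = TRUE,
                        stringsAsFactors = FALSE))
    bits <- ifelse(candidate[acc] <= s$separations$threshold, "0", "1")
    code <- paste(bits, collapse = "")
    data.frame(solution = i, code = code,
               was_empty = code %in% s$empty_codes, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  structure(list(candidate = label, per_solution = per,
                 empty_niche_count = sum(per$was_empty, na.rm = TRUE),
                 skipped_count = sum(per$skipped)),
            class = "niche_report")
}

#' @export
print.niche_report <- function(x, ...) {
  assessed <- nrow(x$per_solution) - x$skipped_count
  cat("Niche assessment for '", x$candidate, "': occupies an empty niche in ",
      x$empty_niche_count, " of ", assessed, " assessed solution(s)",
      if (x$skipped_count) paste0(" (", x$skipped_count,
                                  " skipped for missing values)"),
      "\n", sep = "")
  invisible(x)
}

#' Write a niche report as JSON
#' @param report A `niche_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_niche_json <- function(report, path) {
  stopifnot(inherits(report, "niche_report"))
  jsonlite::write_json(list(candidate = report$candidate,
                            per_solution = report$per_solution,
                            empty_niche_count = report$empty_niche_count,
                            skipped_count = report$skipped_count),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a candidate-values TSV
#'
#' Two columns, `accession` and `value`; `NA` allowed for unavailable
#' values.
#'
#' @param path Path to the TSV.
#' @return Named numeric vector keyed by accession.
#' @export
read_candidate_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "value") %in% names(df)))
    stop("candidate TSV needs columns 'accession' and 'value'")
  setNames(as.numeric(df$value), df$accession)
}

#' Adjective labels for a solution's groups
#'
#' Following the Taylor tradition of naming each binary feature by an
#' adjective ("small", "hydrophobic", ...), assigns each residue the
#' adjectives of the separations on whose labelled side it falls. Every
#' residue receives exactly one side per separation, hence at most f
#' adjectives.
#'
#' @param solution An `aa_solution`.
#' @param labels Data frame with columns `accession`, `adjective`, `side`
#'   (`"low"` or `"high"`), covering every accession of the solution.
#' @return Named list: residue to character vector of adjectives.
#' @export
label_groups <- function(solution, labels) {
  stopifnot(inherits(solution, "aa_solution"), is.data.frame(labels))
  need <- solution$separations$accession
  miss <- setdiff(need, labels$accession)
  if (length(miss))
    stop("label config missing accession(s): ", paste(miss, collapse = ", "))
  if (!all(labels$side %in% c("low", "high")))
    stop("label side must be 'low' or 'high'")
  out <- setNames(rep(list(character(0)), length(solution$alphabet)),
                  solution$alphabet)
  for (i in seq_along(need)) {
    lab <- labels[labels$accession == need[i], ][1, ]
    want_bit <- if (lab$side == "low") "0" else "1"
    hit <- substr(solution$codes, i, i) == want_bit
    for (r in solution$alphabet[hit])
      out[[r]] <- c(out[[r]], lab$adjective)
  }
  out
}

#' Do two separations classify identically?
#'
#' `TRUE` iff the membership vectors agree element-wise — the check used to
#' ask whether a correlated feature could substitute for another in a
#' solution.
#'
#' @param sep_a,sep_b One-row `separation_pool` objects over the same
#'   alphabet.
#' @return Logical.
#' @export
separation_identity <- function(sep_a, sep_b) {
  stopifnot(inherits(sep_a, "separation_pool"), nrow(sep_a) == 1L,
            inherits(sep_b, "separation_pool"), nrow(sep_b) == 1L)
  if (!identical(attr(sep_a, "alphabet"), attr(sep_b, "alphabet")))
    stop("separations are over different alphabets")
  identical(sep_a$membership, sep_b$membership)
}
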