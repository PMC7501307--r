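# A separation is one binary split of the residue set induced by a threshold
# on one feature: low set = {residue : value <= threshold}. Pools of
# separations are data frames (class "separation_pool") with columns
#   accession, cut_size, threshold, gap, score, is_median, membership
# where membership is a 0/1 string in alphabet order (0 = low side) and the
# alphabet rides along as an attribute.

new_pool <- function(df, alphabet) {
  rownames(df) <- NULL
  structure(df, alphabet = alphabet,
            class = c("separation_pool", "data.frame"))
}

#' @export
`[.separation_pool` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "alphabet") <- attr(x, "alphabet")
    class(out) <- c("separation_pool", "data.frame")
  }
  out
}

#' Alphabet of a separation pool or solution
#' @param x A `separation_pool` or `aa_solution`.
#' @return Character vector of residue labels.
#' @export
alphabet <- function(x) {
  if (inherits(x, "aa_solution")) return(x$alphabet)
  a <- attr(x, "alphabet")
  if (is.null(a)) stop("object carries no alphabet")
  a
}

# membership string -> integer 0/1 vector
memb_bits <- function(membership) {
  as.integer(strsplit(membership, "", fixed = TRUE)[[1]])
}

memb_string <- function(bits) paste(bits, collapse = "")

#' Sorted value profile of one feature
#'
#' Residue/value pairs in ascending value order, ties broken by alphabet
#' order, so cut enumeration is deterministic.
#'
#' @param table A [feature_table].
#' @param accession Feature to profile.
#' @return Data frame with columns `residue`, `value`.
#' @export
sorted_profile <- function(table, accession) {
  v <- feature_values(table, accession)
  o <- order(v, seq_along(v))
  data.frame(residue = names(v)[o], value = unname(v[o]),
             stringsAsFactors = FALSE)
}

#' Median of a numeric sample
#'
#' The value separating the upper from the lower half: the middle order
#' statistic for odd n, the mean of the two middle order statistics for
#' even n (delegates to [stats::median()], which implements exactly this).
#'
#' @param values Non-empty numeric vector.
#' @return The median.
#' @export
median_value <- function(values) {
  if (!length(values)) stop("median of an empty sample is undefined")
  stats::median(values)
}

# Build a one-row pool entry for a cut at sorted position `cs` of profile
# values v (ascending, length n): low set = first cs residues.
.cut_row <- function(accession, prof, cs, alphabet, is_median = FALSE) {
  low <- prof$residue[seq_len(cs)]
  bits <- as.integer(!(alphabet %in% low))
  data.frame(accession = accession, cut_size = cs,
             threshold = prof$value[cs],
             gap = prof$value[cs + 1L] - prof$value[cs],
             score = NA_integer_, is_median = is_median,
             membership = memb_string(bits), stringsAsFactors = FALSE)
}

#' Median separation of one feature
#'
#' Splits the alphabet into the residues with value less than or equal to
#' the feature's median (low set) versus greater (high set). Residues tied
#' at the median all fall in the low set, so tied medians can yield
#' unbalanced splits; with 20 all-distinct values the split is exactly
#' 10/10. The separation's gap-rank score is computed against all
#' realizable cuts of the feature.
#'
#' @param table A [feature_table].
#' @param accession Feature to split.
#' @return A one-row `separation_pool` with `is_median = TRUE`.
#' @export
median_separation <- function(table, accession) {
  prof <- sorted_profile(table, accession)
  med <- median_value(prof$value)
  cs <- sum(prof$value <= med)
  if (cs == 0L || cs == nrow(prof))
    stop("no realizable median split for ", accession,
         " (all residues fall on one side of the median)")
  row <- .cut_row(accession, prof, cs, table$alphabet, is_median = TRUE)
  gaps <- .realizable_gaps(prof$value)
  row$score <- sum(gaps < row$gap)
  new_pool(row, table$alphabet)
}

.realizable_gaps <- function(v) {
  d <- diff(v)
  d[d > 0]
}

#' Enumerate all realizable cuts of one feature
#'
#' One separation per pair of adjacent sorted values that differ strictly;
#' tied values can never be split, so a constant feature yields no cuts and
#' 20 all-distinct values yield exactly 19. No size filter is applied here.
#' Scores are left `NA`; see [score_cuts()].
#'
#' @param table A [feature_table].
#' @param accession Feature to enumerate.
#' @return A `separation_pool`, possibly with zero rows.
#' @export
enumerate_cuts <- function(table, accession) {
  prof <- sorted_profile(table, accession)
  n <- nrow(prof)
  pos <- which(diff(prof$value) > 0)
  med_cs <- if (length(pos)) sum(prof$value <= median_value(prof$value))
            else -1L
  rows <- lapply(pos, function(cs)
    .cut_row(accession, prof, cs, table$alphabet, is_median = cs == med_cs))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(0), cut_size = integer(0),
               threshold = numeric(0), gap = numeric(0), score = integer(0),
               is_median = logical(0), membership = character(0),
               stringsAsFactors = FALSE)
  new_pool(df, table$alphabet)
}

#' Gap-rank scores for the cuts of one feature
#'
#' The score of a separation is the number of other separations of the same
#' feature that cut across a strictly smaller value difference. Equal-gap
#' cuts share a score; with 19 all-distinct gaps the scores are the
#' permutation 0..18 and the widest gap scores 18.
#'
#' @param cuts The complete realizable cut set of one feature
#'   (from [enumerate_cuts()]).
#' @return The same pool with `score` filled in.
#' @export
score_cuts <- function(cuts) {
  stopifnot(inherits(cuts, "separation_pool"))
  if (!nrow(cuts)) return(cuts)
  if (length(unique(cuts$accession)) != 1L)
    stop("score_cuts expects cuts of a single feature")
  cuts$score <- vapply(cuts$gap, function(g) sum(cuts$gap < g), 0L)
  cuts
}

#' Build the candidate separation pool of a table
#'
#' In `median` mode the pool holds the median separation of every feature
#' (features with no realizable median split are skipped with a warning).
#' In `cuts` mode every realizable cut of every feature is enumerated and
#' gap-scored, cuts whose group sizes fall outside `size_bounds` are
#' discarded (they can never take part in an f-feature solution), the `k`
#' largest-gap survivors per feature are kept (ties by higher score, then
#' smaller cut size), and finally identically-classifying separations are
#' collapsed pool-wide by [deduplicate_pool()].
#'
#' @param table A [feature_table].
#' @param mode `"median"` or `"cuts"`.
#' @param k Cuts retained per feature in `cuts` mode (the largest-gap ones).
#' @param size_bounds Length-2 integer vector `c(lo, hi)`; both sides of a
#'   retained cut must have sizes within these bounds. `NULL` (default)
#'   uses the capacity bounds `c(n - 2^(f-1), 2^(f-1))` — `[4, 16]` for 20
#'   residues and f = 5.
#' @param f Number of features a solution will use (only sets the default
#'   `size_bounds`).
#' @param force_median In `cuts` mode, also include each feature's median
#'   separation when it passes the size filter, even if not among the top-k
#'   gaps.
#' @return A deduplicated `separation_pool`, ordered by accession then cut
#'   size.
#' @export
candidate_pool <- function(table, mode = c("median", "cuts"), k = 3L,
                           size_bounds = NULL, f = 5L, force_median = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  mode <- match.arg(mode)
  if (k < 1L) stop("k must be at least 1")
  n <- length(table$alphabet)
  if (is.null(size_bounds))
    size_bounds <- c(max(1L, n - 2L^(f - 1L)), min(n - 1L, 2L^(f - 1L)))
  acc <- accessions(table)
  parts <- lapply(acc, function(a) {
    if (mode == "median") {
      tryCatch(median_separation(table, a), error = function(e) {
        warning("skipping ", a, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    } else {
      cuts <- score_cuts(enumerate_cuts(table, a))
      if (!nrow(cuts)) return(NULL)
      ok <- cuts$cut_size >= size_bounds[1] & cuts$cut_size <= size_bounds[2] &
        (n - cuts$cut_size) >= size_bounds[1] &
        (n - cuts$cut_size) <= size_bounds[2]
      kept <- cuts[ok, ]
      if (!nrow(kept)) return(NULL)
      o <- order(-kept$gap, -kept$score, kept$cut_size)
      top <- kept[utils::head(o, k), ]
      if (force_median && any(kept$is_median) && !any(top$is_median))
        top <- rbind(top, kept[kept$is_median, ])
      top
    }
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts))
    stop("empty candidate pool; relax size_bounds, increase k, or supply ",
         "features with realizable splits")
  pool <- new_pool(do.call(rbind, parts), table$alphabet)
  if (mode == "cuts") pool <- deduplicate_pool(pool)
  pool[order(pool$accession, pool$cut_size), ]
}

#' Collapse identically-classifying separations
#'
#' Among separations with identical membership vectors (across features),
#' only the one with the highest score is kept; remaining ties go to the
#' lexicographically smallest accession, then the smallest cut size. Output
#' is ordered by accession then cut size.
#'
#' @param pool A scored `separation_pool`.
#' @return The deduplicated pool.
#' @export
deduplicate_pool <- function(pool) {
  stopifnot(inherits(pool, "separation_pool"))
  if (!nrow(pool)) return(pool)
  keep <- unlist(lapply(split(seq_len(nrow(pool)), pool$membership),
                        function(idx) {
    sub <- pool[idx, ]
    idx[order(-sub$score, sub$accession, sub$cut_size)[1]]
  }))
  out <- pool[sort(keep), ]
  out[order(out$accession, out$cut_size), ]
}

#' Write a separation pool as TSV
#'
#' Columns: accession, cut_size, threshold, gap, score, is_median,
#' membership (0/1 string in alphabet order).
#'
#' @param pool A `separation_pool`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pool_tsv <- function(pool, path) {
  stopifnot(inherits(pool, "separation_pool"))
  df <- as.data.frame(pool)
  df$threshold <- .fmt_num(df$threshold)
  df$gap <- .fmt_num(df$gap)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
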