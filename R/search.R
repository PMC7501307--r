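# Search for minimal f-feature solutions: sets of f separations whose
# combined f-bit codes are distinct for every residue. The key pruning rule
# is the capacity (non-redundancy) criterion: after n of f separations, no
# partition cell may hold more than 2^(f-n) residues, or the remaining
# features cannot tell its members apart.

#' Start a partition of the alphabet
#'
#' A partition maps bit-string prefixes to disjoint residue sets; depth 0 is
#' the single cell `""` holding the whole alphabet.
#'
#' @param alphabet Character vector of residue labels.
#' @return An `aa_partition`: a named list of residue-label vectors keyed by
#'   code prefix, with a `depth` attribute.
#' @export
new_partition <- function(alphabet) {
  structure(setNames(list(alphabet), ""), depth = 0L,
            alphabet = alphabet, class = "aa_partition")
}

#' Refine a partition by one separation
#'
#' Every cell with prefix `p` splits into `p0` (its low-side members) and
#' `p1` (high side). Empty children are kept as keys so the partition always
#' has 2^depth cells; the residue total is conserved.
#'
#' @param partition An `aa_partition`.
#' @param separation A one-row `separation_pool` over the same alphabet.
#' @return The refined `aa_partition`, depth one greater.
#' @export
refine <- function(partition, separation) {
  stopifnot(inherits(partition, "aa_partition"),
            inherits(separation, "separation_pool"), nrow(separation) == 1L)
  alpha <- attr(partition, "alphabet")
  if (!identical(alpha, attr(separation, "alphabet")))
    stop("separation alphabet does not match the partition's")
  bits <- memb_bits(separation$membership)
  high <- alpha[bits == 1L]
  cells <- vector("list", 2L * length(partition))
  keys <- character(2L * length(partition))
  for (i in seq_along(partition)) {
    members <- partition[[i]]
    keys[2L * i - 1L] <- paste0(names(partition)[i], "0")
    keys[2L * i] <- paste0(names(partition)[i], "1")
    cells[[2L * i - 1L]] <- setdiff(members, high)
    cells[[2L * i]] <- intersect(members, high)
  }
  structure(setNames(cells, keys), depth = attr(partition, "depth") + 1L,
            alphabet = alpha, class = "aa_partition")
}

#' Capacity admissibility of a partition
#'
#' After `n` of `f` binary features, unique classification is still possible
#' iff no cell holds more than `2^(f-n)` residues (e.g. a depth-1 split of
#' 3/17 fails for f = 5 because 17 > 2^4 = 16).
#'
#' @param partition An `aa_partition` at depth `n <= f`.
#' @param f Total number of features a solution will use.
#' @return `TRUE` iff every cell is within capacity.
#' @export
admissible <- function(partition, f) {
  stopifnot(inherits(partition, "aa_partition"))
  d <- attr(partition, "depth")
  if (d > f) stop("partition depth exceeds f")
  all(lengths(partition) <= 2^(f - d))
}

# ---- solutions ---------------------------------------------------------

.all_codes <- function(f) {
  g <- do.call(expand.grid, rep(list(c("0", "1")), f))
  # column 1 varies fastest in expand.grid; build strings with bit 1 leftmost
  sort(apply(g[, rev(seq_len(f)), drop = FALSE], 1, paste, collapse = ""))
}

# Assemble a canonical solution from pool rows (any order).
.make_solution <- function(rows, alpha) {
  o <- order(rows$accession, rows$cut_size)
  rows <- rows[o, ]
  bits <- vapply(rows$membership, memb_bits, integer(length(alpha)))
  codes <- setNames(apply(bits, 1, paste, collapse = ""), alpha)
  f <- nrow(rows)
  structure(list(separations = rows,
                 codes = codes,
                 cumulative_score = sum(rows$score),
                 empty_codes = setdiff(.all_codes(f), codes),
                 alphabet = alpha),
            class = "aa_solution")
}

solution_key <- function(s) {
  paste(s$separations$accession, s$separations$cut_size,
        sep = ":", collapse = "|")
}

.sort_solutions <- function(sols) {
  if (!length(sols)) return(structure(sols, class = "aa_solutions"))
  sc <- vapply(sols, `[[`, 0, "cumulative_score")
  keys <- vapply(sols, solution_key, "")
  structure(sols[order(-sc, keys)], class = "aa_solutions")
}

#' Find all minimal f-feature classifications
#'
#' Depth-first backtracking over the pool in canonical order (accession,
#' then cut size). A branch is extended only while the partition it induces
#' stays within capacity ([admissible()]); when a branch's cell exceeds
#' capacity the last separation is revoked and the next pool entry tried. A
#' completed depth-f partition is a solution iff every cell holds at most
#' one residue, i.e. all residue codes are distinct. Each unordered
#' separation set is emitted exactly once (an f-set corresponds to f!
#' ordered traversals, 120 for f = 5, but is one solution).
#'
#' @param pool A deduplicated `separation_pool`.
#' @param f Number of separations per solution; must satisfy
#'   `2^f >= |alphabet|`.
#' @param distinct_features If `TRUE` (default) at most one separation per
#'   accession may enter a solution.
#' @return An `aa_solutions` list of [aa_solution][find_solutions] objects,
#'   sorted by descending cumulative score then canonical key. The number of
#'   capacity-pruned branches is attached as attribute `"pruned"`.
#' @export
find_solutions <- function(pool, f = 5L, distinct_features = TRUE) {
  stopifnot(inherits(pool, "separation_pool"))
  alpha <- attr(pool, "alphabet")
  n <- length(alpha)
  if (2^f < n)
    stop("f = ", f, " features can separate at most 2^", f, " = ", 2^f,
         " elements, fewer than the ", n, "-residue alphabet")
  pool <- pool[order(pool$accession, pool$cut_size), ]
  m <- nrow(pool)
  if (m < f) return(.sort_solutions(list()))
  memb <- t(vapply(pool$membership, memb_bits, integer(n)))  # m x n, 1 = high
  acc <- pool$accession

  sols <- list()
  pruned <- 0L
  # explicit stack of frames; recursion depth is bounded by f but an
  # iterative stack keeps large pools trivially safe
  stack <- list(list(chosen = integer(0), cells = list(seq_len(n)),
                     next_i = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    d <- length(fr$chosen)
    if (d == f) {
      sols[[length(sols) + 1L]] <- fr$chosen
      next
    }
    cap <- 2^(f - d - 1L)
    for (i in fr$next_i:m) {
      if (m - i + 1L < f - d) break
      if (distinct_features && acc[i] %in% acc[fr$chosen]) next
      bits <- memb[i, ]
      newcells <- vector("list", 2L * length(fr$cells))
      nc <- 0L
      ok <- TRUE
      for (cell in fr$cells) {
        b <- bits[cell]
        lo <- cell[b == 0L]
        hi <- cell[b == 1L]
        if (length(lo) > cap || length(hi) > cap) { ok <- FALSE; break }
        if (length(lo)) { nc <- nc + 1L; newcells[[nc]] <- lo }
        if (length(hi)) { nc <- nc + 1L; newcells[[nc]] <- hi }
      }
      if (!ok) { pruned <- pruned + 1L; next }
      stack[[length(stack) + 1L]] <-
        list(chosen = c(fr$chosen, i), cells = newcells[seq_len(nc)],
             next_i = i + 1L)
    }
  }
  out <- .sort_solutions(lapply(sols, function(ix)
    .make_solution(as.data.frame(pool)[ix, ], alpha)))
  attr(out, "pruned") <- pruned
  out
}

#' Brute-force solution enumeration (verification oracle)
#'
#' Tests every f-subset of the pool directly for all-distinct residue codes,
#' with no pruning. Same canonical output contract as [find_solutions()];
#' used to verify that capacity pruning never discards a valid solution.
#'
#' @inheritParams find_solutions
#' @return An `aa_solutions` list.
#' @export
brute_force_solutions <- function(pool, f = 5L, distinct_features = TRUE) {
  stopifnot(inherits(pool, "separation_pool"))
  alpha <- attr(pool, "alphabet")
  n <- length(alpha)
  if (2^f < n)
    stop("f too small for a ", n, "-residue alphabet")
  pool <- pool[order(pool$accession, pool$cut_size), ]
  m <- nrow(pool)
  if (m < f) return(.sort_solutions(list()))
  if (choose(m, f) > 1e7)
    stop("refusing to enumerate ", format(choose(m, f)), " subsets")
  memb <- t(vapply(pool$membership, memb_bits, integer(n)))
  combos <- utils::combn(m, f)
  keep <- apply(combos, 2, function(ix) {
    if (distinct_features && anyDuplicated(pool$accession[ix])) return(FALSE)
    codes <- apply(memb[ix, , drop = FALSE], 2, paste, collapse = "")
    !anyDuplicated(codes)
  })
  .sort_solutions(lapply(which(keep), function(j)
    .make_solution(as.data.frame(pool)[combos[, j], ], alpha)))
}

#' Cumulative score of a solution
#'
#' The sum of the gap-rank scores of the solution's separations; with 20
#' all-distinct-valued residues the maximum is 5 * 18 = 90.
#'
#' @param solution An `aa_solution`.
#' @return Integer score.
#' @export
cumulative_score <- function(solution) {
  stopifnot(inherits(solution, "aa_solution"))
  solution$cumulative_score
}

#' Unoccupied codes of a solution
#'
#' The `2^f - n` bit strings assigned to no residue — the empty niches a
#' non-canonical amino acid could occupy (12 for 20 residues and f = 5).
#'
#' @param solution An `aa_solution`.
#' @return Sorted character vector of f-bit strings.
#' @export
empty_codes <- function(solution) {
  stopifnot(inherits(solution, "aa_solution"))
  solution$empty_codes
}

#' @export
print.aa_solution <- function(x, ...) {
  f <- nrow(x$separations)
  cat("Optimal classification: ", f, " separations, cumulative score ",
      x$cumulative_score, "\n", sep = "")
  for (i in seq_len(f)) {
    s <- x$separations[i, ]
    cat(sprintf("  %s  cut %d/%d at %.6g (gap %.4g, score %d%s)\n",
                s$accession, s$cut_size,
                length(x$alphabet) - s$cut_size, s$threshold, s$gap, s$score,
                if (s$is_median) ", median" else ""))
  }
  cat("  empty codes: ", length(x$empty_codes), " of ",
      2^f, "\n", sep = "")
  invisible(x)
}

#' @export
print.aa_solutions <- function(x, ...) {
  cat(length(x), " solution(s)\n", sep = "")
  if (length(x)) {
    sc <- vapply(x, `[[`, 0, "cumulative_score")
    cat("  cumulative scores: ", paste(utils::head(sc, 10L), collapse = ", "),
        if (length(x) > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

# ---- JSON interchange --------------------------------------------------

#' Write solutions to JSON
#'
#' Schema: a list of objects with `separations` (accession, cut_size,
#' threshold, score, is_median), `codes` (residue to bit string),
#' `cumulative_score` and `empty_codes`. Membership vectors are recoverable
#' from the codes, so [read_solutions_json()] reconstructs full solutions.
#'
#' @param solutions An `aa_solutions` list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_solutions_json <- function(solutions, path) {
  recs <- lapply(solutions, function(s) {
    list(separations = s$separations[, c("accession", "cut_size", "threshold",
                                         "score", "is_median")],
         codes = as.list(s$codes),
         cumulative_score = s$cumulative_score,
         empty_codes = s$empty_codes)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read solutions from JSON
#'
#' @param path Path written by [write_solutions_json()].
#' @return An `aa_solutions` list.
#' @export
read_solutions_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  sols <- lapply(recs, function(r) {
    alpha <- names(r$codes)
    codes <- vapply(r$codes, as.character, "")
    seps <- do.call(rbind, lapply(seq_along(r$separations), function(i) {
      s <- r$separations[[i]]
      bits <- vapply(codes, function(cd) substr(cd, i, i), "")
      data.frame(accession = s$accession, cut_size = as.integer(s$cut_size),
                 threshold = as.numeric(s$threshold), gap = NA_real_,
                 score = as.integer(s$score), is_median = isTRUE(s$is_median),
                 membership = paste(bits, collapse = ""),
                 stringsAsFactors = FALSE)
    }))
    structure(list(separations = seps, codes = setNames(codes, alpha),
                   cumulative_score = as.integer(r$cumulative_score),
                   empty_codes = sort(vapply(r$empty_codes, as.character, "")),
                   alphabet = alpha),
              class = "aa_solution")
  })
  structure(sols, class = "aa_solutions")
}
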