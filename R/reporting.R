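# Text exports of a solution: DOT tree graph, Euler-style set listing,
# groups TSV. All are pure functions of the solution record, so re-export is
# byte-identical.

#' Export a solution's separation tree as DOT
#'
#' A binary tree: the root holds the full alphabet, each level splits every
#' node by the next separation in `order` (left child = low side), and the
#' 2^f leaves are labelled with their residue or `"empty"`. Any of the f!
#' orderings gives the same leaf multiset; the default is the canonical
#' accession order.
#'
#' @param solution An `aa_solution`.
#' @param order Permutation of the solution's accessions giving the
#'   top-to-bottom layer order; `NULL` for canonical order.
#' @return A single string of DOT text.
#' @export
export_tree_dot <- function(solution, order = NULL) {
  stopifnot(inherits(solution, "aa_solution"))
  acc <- solution$separations$accession
  if (is.null(order)) order <- acc
  if (!identical(sort(order), sort(acc)))
    stop("order must be a permutation of the solution's accessions: ",
         paste(acc, collapse = ", "))
  f <- length(acc)
  perm <- match(order, acc)
  # residue code in layer order
  codes <- vapply(solution$codes, function(cd)
    paste(strsplit(cd, "")[[1]][perm], collapse = ""), "")
  node_id <- function(prefix)
    if (nchar(prefix)) paste0("n", prefix) else "root"
  lines <- c("digraph classification {",
             "  node [shape=box];")
  prefixes <- ""
  lines <- c(lines, sprintf("  %s [label=\"%s\"];", node_id(""),
                            paste(solution$alphabet, collapse = "")))
  for (d in seq_len(f)) {
    kids <- as.vector(t(outer(prefixes, c("0", "1"), paste0)))
    thr <- solution$separations$threshold[perm[d]]
    for (p in kids) {
      members <- solution$alphabet[startsWith(codes, p)]
      label <- if (length(members)) paste(members, collapse = "") else "empty"
      side <- substr(p, d, d)
      edge_label <- sprintf("%s %s %.6g", order[d],
                            if (side == "0") "<=" else ">", thr)
      lines <- c(lines,
                 sprintf("  %s [label=\"%s\"];", node_id(p), label),
                 sprintf("  %s -> %s [label=\"%s\"];",
                         node_id(substr(p, 1, d - 1)), node_id(p),
                         edge_label))
    }
    prefixes <- kids
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Euler-style set listing of a solution
#'
#' For each separation, the residues on the chosen side. A residue on the
#' other side of all f separations is absent from every set — the classic
#' glycine situation: low on all five features of the median-based
#' solution, so it vanishes from the high-side Euler diagram.
#'
#' @param solution An `aa_solution`.
#' @param side `"high"` (default) or `"low"`.
#' @return Named list: accession to character vector of residues.
#' @export
export_euler_sets <- function(solution, side = c("high", "low")) {
  stopifnot(inherits(solution, "aa_solution"))
  side <- match.arg(side)
  want <- if (side == "high") "1" else "0"
  acc <- solution$separations$accession
  setNames(lapply(seq_along(acc), function(i)
    solution$alphabet[substr(solution$codes, i, i) == want]), acc)
}

#' Write a groups TSV for a solution
#'
#' One row per residue: residue, f-bit code, and (optionally) its
#' adjectives per [label_groups()].
#'
#' @param solution An `aa_solution`.
#' @param path Output path.
#' @param labels Optional label config for [label_groups()].
#' @return Invisibly, `path`.
#' @export
write_groups_tsv <- function(solution, path, labels = NULL) {
  stopifnot(inherits(solution, "aa_solution"))
  df <- data.frame(residue = solution$alphabet,
                   code = unname(solution$codes),
                   stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    adj <- label_groups(solution, labels)
    df$adjectives <- vapply(df$residue, function(r)
      paste(adj[[r]], collapse = ","), "")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
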