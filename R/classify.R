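#' Fit an optimal binary-feature classification
#'
#' The package's front end: builds the candidate separation pool from a
#' feature table (median splits, or gap-ranked cuts) and enumerates every
#' set of `f` separations whose combined codes classify all residues
#' uniquely. The object bundles the table, the pool and the solution list;
#' `print`/`summary` report them, [predict.aa_classification()] assesses
#' candidate amino acids against the solutions' empty niches, and
#' [plot.aa_classification()] draws a solution's separation tree.
#'
#' @param table A [feature_table].
#' @param mode `"median"` or `"cuts"` (see [candidate_pool()]).
#' @param k,size_bounds,force_median Pool construction parameters, `cuts`
#'   mode only.
#' @param f Number of separations per solution (5 suffices for 20 residues:
#'   2^5 = 32 >= 20, while 2^4 = 16 does not).
#' @param distinct_features At most one separation per feature in a
#'   solution.
#' @return An `aa_classification` object: list with `table`, `pool`,
#'   `solutions`, `config`.
#' @examples
#' gen <- generate_planted_table(20, n_noise_features = 2, seed = 7)
#' fit <- aa_classify(gen$table, mode = "median")
#' fit
#' summary(fit)
#' @export
aa_classify <- function(table, mode = c("median", "cuts"), k = 3L,
                        size_bounds = NULL, f = 5L, force_median = FALSE,
                        distinct_features = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  mode <- match.arg(mode)
  pool <- candidate_pool(table, mode, k, size_bounds, f, force_median)
  sols <- find_solutions(pool, f, distinct_features)
  structure(list(table = table, pool = pool, solutions = sols,
                 config = list(mode = mode, k = k, f = f,
                               size_bounds = size_bounds,
                               distinct_features = distinct_features)),
            class = "aa_classification")
}

#' @export
print.aa_classification <- function(x, ...) {
  cat("Optimal amino-acid classification (", x$config$mode, " mode, f = ",
      x$config$f, ")\n", sep = "")
  cat("  pool: ", nrow(x$pool), " candidate separation(s) over ",
      ncol(x$table$values), " feature(s)\n", sep = "")
  cat("  solutions: ", length(x$solutions), sep = "")
  if (length(x$solutions))
    cat(" (top cumulative score ", x$solutions[[1]]$cumulative_score, ")",
        sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.aa_classification <- function(object, ...) {
  sols <- object$solutions
  freq <- if (length(sols)) {
    tab <- table(unlist(lapply(sols, function(s) s$separations$accession)))
    sort(tab, decreasing = TRUE)
  } else table(character(0))
  structure(list(fit = object, feature_frequency = freq),
            class = "summary.aa_classification")
}

#' @export
print.summary.aa_classification <- function(x, ...) {
  print(x$fit)
  if (length(x$fit$solutions)) {
    cat("\nFeature usage across solutions:\n")
    print(x$feature_frequency)
    cat("\nTop solution:\n")
    print(x$fit$solutions[[1]])
  }
  invisible(x)
}

#' Assess candidate amino acids against a fitted classification
#'
#' For each candidate (row of `newdata`, or a single named vector), computes
#' its code in every solution and counts empty-niche occupancy; see
#' [niche_assessment()].
#'
#' @param object An `aa_classification`.
#' @param newdata Named numeric vector of feature values keyed by accession,
#'   or a matrix/data frame with candidates in rows and accessions in
#'   columns.
#' @param ... Unused.
#' @return A `niche_report`, or a list of them for multiple candidates.
#' @export
predict.aa_classification <- function(object, newdata, ...) {
  if (is.matrix(newdata) || is.data.frame(newdata)) {
    nm <- rownames(newdata)
    if (is.null(nm)) nm <- paste0("candidate", seq_len(nrow(newdata)))
    out <- lapply(seq_len(nrow(newdata)), function(i)
      niche_assessment(object$solutions,
                       setNames(as.numeric(newdata[i, ]),
                                colnames(newdata)),
                       label = nm[i]))
    names(out) <- nm
    return(out)
  }
  niche_assessment(object$solutions, newdata)
}

#' Plot a solution's separation tree
#'
#' Base-graphics rendering of the binary separation tree of one solution:
#' internal nodes show the residues still together, leaves show the single
#' residue (or nothing for an empty niche).
#'
#' @param x An `aa_classification` with at least one solution.
#' @param which Index of the solution to draw.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.aa_classification <- function(x, which = 1L, ...) {
  if (!length(x$solutions)) stop("no solutions to plot")
  s <- x$solutions[[which]]
  f <- nrow(s$separations)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(-0.5, f + 0.5), axes = FALSE,
                 xlab = "", ylab = "",
                 main = paste0("Separation tree (score ",
                               s$cumulative_score, ")"), ...)
  xpos <- function(prefix) {
    d <- nchar(prefix)
    if (d == 0L) return(0.5)
    (strtoi(prefix, base = 2) + 0.5) / 2^d
  }
  draw <- function(prefix) {
    d <- nchar(prefix)
    members <- s$alphabet[startsWith(unname(s$codes), prefix)]
    lab <- if (length(members)) paste(members, collapse = "") else "."
    graphics::text(xpos(prefix), f - d, lab,
                   cex = max(0.3, 0.8 - 0.1 * d))
    if (d < f) {
      for (b in c("0", "1")) {
        child <- paste0(prefix, b)
        graphics::segments(xpos(prefix), f - d - 0.15,
                           xpos(child), f - d - 0.85, col = "grey50")
        draw(child)
      }
    }
  }
  draw("")
  graphics::mtext(paste(s$separations$accession, collapse = " / "),
                  side = 1, cex = 0.7)
  invisible(x)
}
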