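# Synthetic residue-by-feature tables with known ground truth, so the whole
# pipeline is testable without the AAindex database.

.synthetic_alphabet <- function(n) {
  pool <- c(AA_ALPHABET, c("B", "J", "O", "U", "X", "Z",
                           "b", "j", "o", "u", "x", "z"))
  if (n > length(pool)) stop("alphabet supports at most ", length(pool),
                             " residues")
  # keep canonical order for the first 20; extension letters beyond
  sort_within <- pool[seq_len(n)]
  sort_within
}

.code_string <- function(x, f) {
  paste(rev(as.integer(intToBits(x))[seq_len(f)]), collapse = "")
}

#' Generate a feature table with a planted perfect classification
#'
#' Builds `n_residues` residues with distinct f-bit codes and one feature
#' per code bit: bit-0 residues draw values from a low band `[0, 0.9]`,
#' bit-1 residues from a high band `[2, 2.9]`, so the between-band gap
#' (>= 1.1) strictly exceeds every within-band gap and the planted cut is
#' the feature's top-gap cut. With `balanced = TRUE` (default) codes are
#' drawn as complement pairs, so every planted bit-plane splits the residues
#' exactly in half and the planted cut is also the median split — the
#' condition under which median-based search recovers the planted solution.
#' Noise features take one near-constant value on all but two residues plus
#' two high outliers: their only realizable cuts isolate 1 or 2 residues,
#' outside the capacity size filter whenever `n_residues - 2` exceeds the
#' bound `2^(f-1)` (true for the 20-residue, f = 5 study setting), so they
#' can never enter a cuts-mode solution.
#'
#' @param n_residues Number of residues (2..2^f; even when `balanced`).
#' @param n_noise_features Number of ineligible noise features to add.
#' @param seed Integer seed; output is reproducible bit for bit.
#' @param f Code length (number of planted features).
#' @param balanced Draw codes as complement pairs (balanced bit-planes).
#' @return A list with `table` (a [feature_table]) and `design` (a
#'   `planted_design`: `codes`, `planted_accessions`, `noise_accessions`,
#'   `f`, `seed`).
#' @export
generate_planted_table <- function(n_residues = 20L, n_noise_features = 0L,
                                   seed = 1L, f = 5L, balanced = TRUE) {
  if (n_residues < 2L || n_residues > 2^f)
    stop("n_residues must be between 2 and 2^f = ", 2^f)
  set.seed(seed)
  alpha <- .synthetic_alphabet(n_residues)
  half <- as.integer(2^(f - 1L))

  if (balanced) {
    if (n_residues %% 2L != 0L)
      stop("balanced designs need an even number of residues")
    # complement pairs {c, 2^f - 1 - c}: each pair contributes one 0 and one
    # 1 to every bit-plane, so all planted splits are exactly half/half
    pairs <- sample(0:(half - 1L), n_residues %/% 2L)
    ints <- sample(c(pairs, 2L^f - 1L - pairs))
  } else {
    lo_bound <- n_residues - half
    for (try in 1:1000) {
      ints <- sample(0:(2L^f - 1L), n_residues)
      ones <- vapply(seq_len(f) - 1L, function(b)
        sum(bitwAnd(ints, bitwShiftL(1L, b)) > 0L), 0L)
      if (all(ones >= max(1L, lo_bound) & ones <= min(n_residues - 1L, half)))
        break
      if (try == 1000) stop("could not draw a feasible code set")
    }
  }
  codes <- setNames(vapply(ints, .code_string, "", f = f), alpha)

  planted_acc <- sprintf("PLNT%04d", seq_len(f))
  noise_acc <- if (n_noise_features > 0L)
    sprintf("NOIS%04d", seq_len(n_noise_features)) else character(0)
  vals <- matrix(0, n_residues, f + n_noise_features,
                 dimnames = list(alpha, c(planted_acc, noise_acc)))
  for (i in seq_len(f)) {
    bit <- as.integer(substr(codes, i, i))
    n0 <- sum(bit == 0L); n1 <- sum(bit == 1L)
    vals[bit == 0L, i] <- stats::runif(n0, 0, 0.9)
    vals[bit == 1L, i] <- stats::runif(n1, 2, 2.9)
  }
  for (j in seq_len(n_noise_features)) {
    v <- rep(stats::runif(1, 0, 0.1), n_residues)
    out <- sample(n_residues, min(2L, n_residues - 1L))
    v[out] <- stats::runif(length(out), 10, 20)
    vals[, f + j] <- v
  }
  desc <- setNames(c(sprintf("planted bit %d of the ground-truth code",
                             seq_len(f)),
                     rep("noise feature (size-filter ineligible)",
                         n_noise_features)),
                   c(planted_acc, noise_acc))
  list(table = feature_table(vals, descriptions = desc),
       design = structure(list(codes = codes,
                               planted_accessions = planted_acc,
                               noise_accessions = noise_acc,
                               f = f, seed = seed, balanced = balanced),
                          class = "planted_design"))
}

#' @export
print.planted_design <- function(x, ...) {
  cat("Planted design: ", length(x$codes), " residues, f = ", x$f,
      ", seed ", x$seed, if (x$balanced) ", balanced bit-planes", "\n",
      sep = "")
  invisible(x)
}

#' Write a planted design record as JSON
#' @param design A `planted_design`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "planted_design"))
  rec <- unclass(design)
  rec$codes <- as.list(rec$codes)  # keep residue names as JSON keys
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a random feature table
#'
#' Independent uniform values; optionally a share of each feature's entries
#' is overwritten with the value of another residue of the same feature, to
#' exercise tie handling in sorting, cut enumeration and median splits.
#'
#' @param n_residues Number of residues.
#' @param n_features Number of features.
#' @param seed Integer seed.
#' @param tie_fraction Fraction (0..1) of entries per feature duplicated
#'   from other entries of that feature.
#' @return A [feature_table].
#' @export
generate_random_table <- function(n_residues = 20L, n_features = 5L,
                                  seed = 1L, tie_fraction = 0) {
  stopifnot(tie_fraction >= 0, tie_fraction <= 1)
  set.seed(seed)
  alpha <- .synthetic_alphabet(n_residues)
  acc <- sprintf("RAND%04d", seq_len(n_features))
  vals <- matrix(stats::runif(n_residues * n_features), n_residues,
                 n_features, dimnames = list(alpha, acc))
  n_dup <- min(floor(tie_fraction * n_residues), n_residues - 1L)
  if (n_dup > 0L) {
    for (j in seq_len(n_features)) {
      pos <- sample(n_residues, n_dup)
      donors <- setdiff(seq_len(n_residues), pos)
      src <- donors[sample.int(length(donors), n_dup,
                               replace = n_dup > length(donors))]
      vals[pos, j] <- vals[src, j]
    }
  }
  feature_table(vals)
}
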