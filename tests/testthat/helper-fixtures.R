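# Fixtures built in code: tiny feature tables, AAindex1 text, and pools of
# separations constructed directly from bit patterns.

# A table whose single feature takes the given values in alphabet order.
one_feature_table <- function(values, accession = "TOY00001",
                              alphabet = AA_ALPHABET[seq_along(values)]) {
  feature_table(matrix(values, length(values), 1,
                       dimnames = list(alphabet, accession)))
}

# Multi-feature table from a values matrix (rows = residues).
table_from_matrix <- function(values, alphabet = AA_ALPHABET[1:nrow(values)],
                              accessions = sprintf("TOY%05d",
                                                   seq_len(ncol(values)))) {
  dimnames(values) <- list(alphabet, accessions)
  feature_table(values)
}

# One well-formed AAindex1 entry as text lines; values in alphabet order.
aaindex1_entry <- function(accession, values,
                           description = "toy feature") {
  toks <- ifelse(is.na(values), "NA", sprintf("%.17g", values))
  c(paste("H", accession),
    paste("D", description),
    "I    A/L  R/K  N/M  D/F  C/P  Q/S  E/T  G/W  H/Y  I/V",
    paste0("    ", paste(toks[1:10], collapse = "  ")),
    paste0("    ", paste(toks[11:20], collapse = "  ")),
    "//")
}

# Build a separation pool directly from membership bit vectors (a list of
# 0/1 integer vectors), bypassing value profiles. Scores default to 0.
pool_from_bits <- function(bits, alphabet, accessions = NULL,
                           scores = NULL) {
  if (is.null(accessions)) accessions <- sprintf("BIT%05d", seq_along(bits))
  if (is.null(scores)) scores <- rep(0L, length(bits))
  df <- data.frame(accession = accessions,
                   cut_size = vapply(bits, function(b) sum(b == 0L), 0L),
                   threshold = 0.5, gap = 1,
                   score = as.integer(scores), is_median = FALSE,
                   membership = vapply(bits, paste, "", collapse = ""),
                   stringsAsFactors = FALSE)
  structure(df, alphabet = alphabet,
            class = c("separation_pool", "data.frame"))
}

# The 5 bit-planes of codes 0..(n-1): separation j assigns residue i the
# j-th bit of i-1. A planted pool whose unique solution is the full set.
bitplane_pool <- function(n = 20, f = 5, alphabet = AA_ALPHABET[1:n]) {
  bits <- lapply(seq_len(f), function(j) {
    vapply(0:(n - 1), function(x) bitwAnd(bitwShiftR(x, f - j), 1L), 0L)
  })
  pool_from_bits(bits, alphabet, accessions = sprintf("PLANE%02d", seq_len(f)))
}

# Random pool of m separations with cut sizes inside the capacity bounds,
# some drawn from a planted table's cut pool so solutions often exist.
random_pool <- function(seed, m = 10, n = 20) {
  set.seed(seed)
  gen <- generate_planted_table(n, n_noise_features = 0,
                                seed = seed + 10000L)
  planted <- candidate_pool(gen$table, "cuts", k = 3)
  extra_bits <- lapply(seq_len(m), function(i) {
    cs <- sample(4:16, 1)
    b <- rep(1L, n)
    b[sample(n, cs)] <- 0L
    b
  })
  extras <- pool_from_bits(extra_bits, attr(planted, "alphabet"),
                           accessions = sprintf("RND%05d", seq_len(m)),
                           scores = sample(0:18, m, replace = TRUE))
  combined <- rbind(as.data.frame(planted), as.data.frame(extras))
  keep <- sort(sample(nrow(combined), min(m, nrow(combined))))
  out <- combined[keep, ]
  rownames(out) <- NULL
  structure(out, alphabet = attr(planted, "alphabet"),
            class = c("separation_pool", "data.frame"))
}

# Canonical identity of a solution for set comparisons.
sol_key <- function(s) {
  paste(s$separations$accession, s$separations$cut_size,
        sep = ":", collapse = "|")
}

sol_keys <- function(sols) sort(vapply(sols, sol_key, ""))
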