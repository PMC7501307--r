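test_that("sorted profiles are ascending with alphabet-stable ties", {
  tab <- one_feature_table(20:1)
  prof <- sorted_profile(tab, "TOY00001")
  expect_identical(prof$residue, rev(AA_ALPHABET))
  expect_identical(prof$value, as.numeric(1:20))
  # two residues tied keep alphabet adjacency
  v <- as.numeric(1:20); v[2] <- v[5]  # R tied with C
  tied <- sorted_profile(one_feature_table(v), "TOY00001")
  pos <- which(tied$value == v[5])
  expect_identical(tied$residue[pos], c("R", "C"))
  # random values agree with an independent comparison sort
  set.seed(77)
  for (i in 1:5) {
    r <- runif(20)
    prof <- sorted_profile(one_feature_table(r), "TOY00001")
    expect_identical(prof$value, sort(r))
  }
})

test_that("median_value matches the order-statistic definition", {
  expect_identical(median_value(1:20), 10.5)
  expect_identical(median_value(c(rep(0, 11), rep(1, 9))), 0)
  set.seed(123)
  x <- runif(20)
  s <- sort(x)
  expect_identical(median_value(x), (s[10] + s[11]) / 2)
  x9 <- runif(9)
  expect_identical(median_value(x9), sort(x9)[5])
  expect_error(median_value(numeric(0)), "empty")
})

test_that("median separation puts ties at the median in the low set", {
  sep <- median_separation(one_feature_table(1:20), "TOY00001")
  expect_identical(sep$membership, paste(rep(0:1, each = 10), collapse = ""))
  expect_identical(sep$cut_size, 10L)
  expect_true(sep$is_median)
  expect_identical(sep$threshold, 10)
  # eleven minimum-tied values: ties never split, so the low set has 11
  v <- c(rep(0, 11), 2:10)
  sep2 <- median_separation(one_feature_table(v), "TOY00001")
  expect_identical(sep2$cut_size, 11L)
  expect_error(median_separation(one_feature_table(rep(1, 20)), "TOY00001"),
               "no realizable median split")
})

test_that("cut enumeration yields one separation per strict adjacent gap", {
  expect_identical(nrow(enumerate_cuts(one_feature_table(sample(20)),
                                       "TOY00001")), 19L)
  expect_identical(nrow(enumerate_cuts(one_feature_table(rep(3, 20)),
                                       "TOY00001")), 0L)
  set.seed(5)
  for (i in 1:10) {
    v <- sample(1:8, 20, replace = TRUE)
    cuts <- enumerate_cuts(one_feature_table(v), "TOY00001")
    expect_identical(nrow(cuts), sum(diff(sort(v)) > 0))  # direct scan
    # realizability: every cut separates strictly
    for (j in seq_len(nrow(cuts))) {
      bits <- as.integer(strsplit(cuts$membership[j], "")[[1]])
      expect_gt(min(v[bits == 1]), max(v[bits == 0]))
      expect_equal(cuts$gap[j], min(v[bits == 1]) - max(v[bits == 0]))
    }
    # thresholds non-decreasing in cut size
    expect_true(!is.unsorted(cuts$threshold[order(cuts$cut_size)]))
  }
})

test_that("gap-rank scores count strictly smaller gaps", {
  cuts <- score_cuts(enumerate_cuts(one_feature_table((1:20)^2), "TOY00001"))
  expect_setequal(cuts$score, 0:18)  # all gaps distinct
  expect_identical(cuts$score[which.max(cuts$gap)], 18L)
  even <- score_cuts(enumerate_cuts(one_feature_table(1:20), "TOY00001"))
  expect_true(all(even$score == 0L))  # all gaps equal
  set.seed(21)
  for (i in 1:10) {
    v <- sample(1:12, 20, replace = TRUE)
    cuts <- score_cuts(enumerate_cuts(one_feature_table(v), "TOY00001"))
    # O(m^2) pairwise counting oracle
    oracle <- vapply(seq_len(nrow(cuts)), function(a)
      sum(vapply(seq_len(nrow(cuts)), function(b)
        b != a && cuts$gap[b] < cuts$gap[a], TRUE)), 0L)
    expect_identical(cuts$score, oracle)
  }
  two <- rbind(as.data.frame(cuts[1, ]), as.data.frame(cuts[1, ]))
  two$accession[2] <- "OTHER001"
  expect_error(score_cuts(structure(two, alphabet = attr(cuts, "alphabet"),
                                    class = class(cuts))), "single feature")
})

test_that("the candidate pool applies the size filter then keeps top gaps", {
  set.seed(42)
  v <- cumsum(c(1, runif(19, 0.5, 1.5)))
  tab <- one_feature_table(sample(v))
  full <- score_cuts(enumerate_cuts(tab, "TOY00001"))
  ok <- full$cut_size >= 4 & full$cut_size <= 16
  expect_identical(sum(ok), 13L)  # sizes 4..16 survive for 20 distinct values
  pool1 <- candidate_pool(tab, "cuts", k = 100)
  expect_identical(nrow(pool1), 13L)
  pool3 <- candidate_pool(tab, "cuts", k = 3)
  expect_identical(nrow(pool3), 3L)
  surv <- full[ok, ]
  expect_setequal(pool3$cut_size,
                  surv$cut_size[order(-surv$gap)][1:3])  # largest gaps kept
  # two features, k = 3: at most 6 separations
  tab2 <- generate_random_table(20, 2, seed = 1)
  expect_lte(nrow(candidate_pool(tab2, "cuts", k = 3)), 6L)
})

test_that("cuts-mode pools match an independent filter/sort oracle", {
  for (seed in c(2, 13, 77)) {
    tab <- generate_random_table(20, 4, seed = seed, tie_fraction = 0.15)
    k <- 3
    pool <- candidate_pool(tab, "cuts", k = k)
    oracle <- do.call(rbind, lapply(accessions(tab), function(a) {
      v <- feature_values(tab, a)
      s <- sort(v)
      pos <- which(diff(s) > 0)
      cand <- data.frame(accession = a, cut_size = pos,
                         gap = s[pos + 1] - s[pos])
      cand$score <- vapply(cand$gap, function(g) sum(cand$gap < g), 0L)
      cand <- cand[cand$cut_size >= 4 & cand$cut_size <= 16, ]
      head(cand[order(-cand$gap, -cand$score, cand$cut_size), ], k)
    }))
    # same separations survive (before pool-wide dedup removes vector clones)
    got <- paste(pool$accession, pool$cut_size)
    want <- paste(oracle$accession, oracle$cut_size)
    expect_true(all(got %in% want))
    dropped <- setdiff(want, got)
    # anything the oracle kept but the pool dropped must be a duplicate vector
    expect_true(all(table(pool$membership) == 1))
    if (length(dropped)) {
      full_oracle_pool <- do.call(rbind, lapply(seq_len(nrow(oracle)),
        function(i) {
          a <- oracle$accession[i]
          cuts <- enumerate_cuts(tab, a)
          as.data.frame(cuts[cuts$cut_size == oracle$cut_size[i], ])
        }))
      dup_memb <- full_oracle_pool$membership[
        paste(full_oracle_pool$accession, full_oracle_pool$cut_size)
        %in% dropped]
      expect_true(all(dup_memb %in% pool$membership))
    }
  }
})

test_that("median mode pools one median split per feature", {
  gen <- generate_planted_table(20, n_noise_features = 2, seed = 4)
  pool <- candidate_pool(gen$table, "median")
  expect_identical(nrow(pool), 7L)  # 5 planted + 2 noise medians
  expect_true(all(pool$is_median))
  const <- table_from_matrix(cbind(rep(1, 20), 1:20))
  expect_warning(p2 <- candidate_pool(const, "median"), "skipping")
  expect_identical(nrow(p2), 1L)
})

test_that("median consistency: the median cut appears flagged in cuts pools", {
  gen <- generate_planted_table(20, 0, seed = 6)  # balanced: median = top gap
  pool <- candidate_pool(gen$table, "cuts", k = 3)
  med <- candidate_pool(gen$table, "median")
  for (a in gen$design$planted_accessions) {
    in_cuts <- pool[pool$accession == a & pool$is_median, ]
    expect_identical(nrow(in_cuts), 1L)
    expect_identical(in_cuts$membership, med$membership[med$accession == a])
  }
})

test_that("identically-classifying separations collapse to the best score", {
  # two features with identical rankings share every membership vector
  set.seed(42)
  v <- sample(20)
  tab <- table_from_matrix(cbind(v, 2 * v))
  acc <- accessions(tab)
  a <- score_cuts(enumerate_cuts(tab, acc[1]))
  b <- score_cuts(enumerate_cuts(tab, acc[2]))
  both <- structure(rbind(as.data.frame(a), as.data.frame(b)),
                    alphabet = attr(a, "alphabet"), class = class(a))
  dedup <- deduplicate_pool(both)
  expect_identical(nrow(dedup), 19L)
  expect_true(all(table(dedup$membership) == 1))
  # distinct vectors pass through unchanged
  pool <- bitplane_pool()
  expect_identical(nrow(deduplicate_pool(pool)), nrow(pool))
  # grouped argmax oracle on random duplications
  set.seed(55)
  bits <- replicate(8, sample(0:1, 20, replace = TRUE), simplify = FALSE)
  dup <- pool_from_bits(c(bits, bits[c(2, 5)]), AA_ALPHABET,
                        scores = sample(0:18, 10, replace = TRUE))
  got <- deduplicate_pool(dup)
  oracle <- vapply(split(seq_len(10), dup$membership), function(ix)
    ix[order(-dup$score[ix], dup$accession[ix])][1], 0L)
  expect_setequal(paste(got$accession, got$cut_size),
                  paste(dup$accession[oracle], dup$cut_size[oracle]))
})
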