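test_that("the DOT tree has 2^f leaves labelled by code membership", {
  gen <- generate_planted_table(20, 0, seed = 16)
  s <- aa_classify(gen$table, mode = "cuts", k = 1)$solutions[[1]]
  dot <- export_tree_dot(s)
  lines <- strsplit(dot, "\n")[[1]]
  leaves <- grep("^  n[01]{5} \\[", lines, value = TRUE)
  expect_length(leaves, 32L)
  expect_length(grep("empty", leaves), 12L)
  # leaf labels equal the codes map
  for (r in s$alphabet) {
    code <- s$codes[[r]]
    leaf <- grep(sprintf("^  n%s \\[", code), lines, value = TRUE)
    expect_match(leaf, paste0("label=\"", r, "\""), fixed = FALSE)
  }
  # re-export is byte-identical
  expect_identical(export_tree_dot(s), dot)
})

test_that("layer permutations change structure but not the leaf multiset", {
  gen <- generate_planted_table(20, 0, seed = 17)
  s <- aa_classify(gen$table, mode = "cuts", k = 1)$solutions[[1]]
  acc <- s$separations$accession
  d1 <- export_tree_dot(s, acc)
  d2 <- export_tree_dot(s, rev(acc))
  expect_false(identical(d1, d2))
  leaf_labels <- function(dot) {
    lines <- strsplit(dot, "\n")[[1]]
    sort(sub('.*label="([^"]*)".*', "\\1",
             grep("^  n[01]{5} \\[", lines, value = TRUE)))
  }
  expect_identical(leaf_labels(d1), leaf_labels(d2))
  expect_error(export_tree_dot(s, acc[-1]), "permutation")
})

test_that("euler sets carry the chosen side and drop all-low residues", {
  pool <- bitplane_pool()  # codes 0..19: A (code 00000) is low everywhere
  s <- find_solutions(pool, f = 5)[[1]]
  high <- export_euler_sets(s, "high")
  expect_false("A" %in% unlist(high))
  low <- export_euler_sets(s, "low")
  for (a in names(high)) {
    expect_setequal(c(high[[a]], low[[a]]), s$alphabet)  # complements
    cs <- s$separations$cut_size[s$separations$accession == a]
    expect_length(low[[a]], cs)
    expect_length(high[[a]], 20L - cs)
  }
})

test_that("groups TSV lists residues, codes and adjectives", {
  gen <- generate_planted_table(20, 0, seed = 18)
  s <- aa_classify(gen$table, mode = "cuts", k = 1)$solutions[[1]]
  labels <- data.frame(accession = s$separations$accession,
                       adjective = paste0("adj", 1:5),
                       side = "high", stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  write_groups_tsv(s, f, labels)
  got <- utils::read.delim(f, colClasses = "character")
  expect_identical(got$residue, s$alphabet)
  expect_identical(got$code, unname(s$codes))
  n_adj <- vapply(strsplit(got$adjectives, ","), function(x)
    length(x[nzchar(x)]), 0L)
  ones <- vapply(strsplit(got$code, ""), function(b) sum(b == "1"), 0L)
  expect_identical(n_adj, ones)
})

test_that("the classification object prints, summarises and predicts", {
  gen <- generate_planted_table(20, 2, seed = 25)
  fit <- aa_classify(gen$table, mode = "median")
  out <- capture.output(print(fit))
  expect_match(out[1], "median mode")
  expect_match(paste(out, collapse = " "), "solutions: 1")
  sm <- capture.output(print(summary(fit)))
  expect_match(paste(sm, collapse = " "), "Feature usage")
  cands <- matrix(c(0.1, 0.1, 0.1, 0.1, 0.1,
                    2.5, 2.5, 2.5, 2.5, 2.5), 2, 5, byrow = TRUE,
                  dimnames = list(c("low_all", "high_all"),
                                  gen$design$planted_accessions))
  reps <- predict(fit, cands)
  expect_named(reps, c("low_all", "high_all"))
  expect_s3_class(reps$low_all, "niche_report")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("the CLI pipeline simulates, searches, scores and exports", {
  tdir <- withr::local_tempdir()
  tab <- file.path(tdir, "tab.tsv")
  sol <- file.path(tdir, "sol.json")
  expect_identical(run_cli(c("simulate", "--seed", "5", "--noise", "2",
                             "--out", tab)), 0L)
  # byte-identical on repeat
  tab2 <- file.path(tdir, "tab2.tsv")
  run_cli(c("simulate", "--seed", "5", "--noise", "2", "--out", tab2))
  expect_identical(readLines(tab), readLines(tab2))
  expect_identical(run_cli(c("search", "--input", tab, "--mode", "cuts",
                             "--top-cuts", "3", "--out", sol)), 0L)
  sols <- read_solutions_json(sol)
  expect_gte(length(sols), 1L)
  score_out <- file.path(tdir, "scores.tsv")
  run_cli(c("score", "--input", sol, "--out", score_out))
  scores <- utils::read.delim(score_out)
  # top score equals an independent recompute from the table
  refit <- aa_classify(read_feature_table(tab), mode = "cuts", k = 3)
  expect_identical(max(scores$cumulative_score),
                   max(vapply(refit$solutions, `[[`, 0L, "cumulative_score")))
  dot_out <- file.path(tdir, "tree.dot")
  run_cli(c("export", "--input", sol, "--what", "dot", "--out", dot_out))
  expect_match(readLines(dot_out)[1], "digraph")
  expect_identical(run_cli(c("frobnicate")), 2L)
  suppressWarnings(
    expect_identical(run_cli(c("search", "--input",
                               file.path(tdir, "nope.tsv"))), 1L))
  expect_identical(run_cli(c("search", "--badflag")), 2L)
})

test_that("CLI parse applies an accession-list filter from a config file", {
  tdir <- withr::local_tempdir()
  gen <- generate_planted_table(20, 3, seed = 41)
  aaix <- file.path(tdir, "toy.aaindex1")
  write_feature_table(gen$table, aaix, "aaindex1")
  listfile <- file.path(tdir, "curated.txt")
  writeLines(c("# planted only", gen$design$planted_accessions), listfile)
  cfg <- file.path(tdir, "cfg.yaml")
  writeLines(c(paste0("input: ", aaix), paste0("features: ", listfile)),
             cfg)
  out <- file.path(tdir, "filtered.tsv")
  expect_identical(run_cli(c("parse", "--config", cfg, "--out", out)), 0L)
  tab <- read_feature_table(out)
  expect_identical(accessions(tab), gen$design$planted_accessions)
  expect_identical(tab$values,
                   gen$table$values[, gen$design$planted_accessions])
})

test_that("the shipped synthetic fixture reproduces its design record", {
  flat <- system.file("extdata", "synthetic_planted.aaindex1",
                      package = "aaopt")
  curated <- system.file("extdata", "synthetic_curated.txt",
                         package = "aaopt")
  design <- jsonlite::read_json(system.file("extdata",
                                            "synthetic_planted_design.json",
                                            package = "aaopt"),
                                simplifyVector = TRUE)
  tab <- filter_features(read_aaindex(flat), read_accession_list(curated))
  expect_identical(accessions(tab), design$planted_accessions)
  fit <- aa_classify(tab, mode = "median")
  expect_length(fit$solutions, 1L)
  expect_identical(unname(fit$solutions[[1]]$codes[names(design$codes)]),
                   unlist(unname(design$codes)))
  sol_out <- withr::local_tempfile(fileext = ".json")
  expect_identical(run_cli(c("search", "--input", flat, "--mode", "median",
                             "--features", curated, "--out", sol_out)), 0L)
  expect_length(read_solutions_json(sol_out), 1L)
})
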