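test_that("FASTA parsing handles gaps, case, unknown letters and errors", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "MK", ">B", "M-"), p)
  a <- read_alignment(p, "fasta")
  expect_equal(n_taxa(a), 2)
  expect_equal(n_sites(a), 2)
  expect_equal(unname(a$mat["B", 2]), "-")

  writeLines(c(">A", "mkz"), p)  # lower case + unknown letter
  a <- read_alignment(p, "fasta")
  expect_equal(unname(a$mat[1, ]), c("M", "K", "X"))

  writeLines(c(">A", "MK", ">A", "MR"), p)
  expect_error(read_alignment(p, "fasta"), "duplicate")
  writeLines(c(">A", "MK", ">B", "MKR"), p)
  expect_error(read_alignment(p, "fasta"), "ragged")
  writeLines(character(0), p)
  expect_error(read_alignment(p, "fasta"), "empty")
})

test_that("write/read round-trips are lossless and byte-stable", {
  set.seed(1)
  mat <- matrix(sample(c(rootsignal:::AA_STATES, "-", "X"), 60,
                       replace = TRUE), 4, 15,
                dimnames = list(c("t1", "t2", "t3", "t4"), NULL))
  a <- new_alignment(mat)
  for (fmt in c("fasta", "phylip")) {
    p <- withr::local_tempfile()
    write_alignment(a, p, fmt)
    b <- read_alignment(p, fmt)
    expect_identical(b$mat, a$mat)
    p2 <- withr::local_tempfile()
    write_alignment(a, p2, fmt)
    expect_identical(readBin(p, "raw", file.size(p)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("dayhoff6 alignments round-trip through FASTA with a header comment", {
  a <- aln_from_strings(c(A = "ACDF", B = "AC-X", C = "GGDF", D = "GGDF"))
  d6 <- recode_dayhoff6(a)
  p <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(d6, p, "fasta")
  expect_match(readLines(p)[1], "^; dayhoff6")
  b <- read_alignment(p, "fasta", alphabet = "dayhoff6")
  expect_identical(b$mat, d6$mat)
})

test_that("concatenation tiles partitions and fills absent taxa with missing", {
  g1 <- aln_from_strings(c(A = strrep("M", 10), B = strrep("K", 10)))
  g2 <- aln_from_strings(c(A = strrep("R", 15), C = strrep("D", 15)))
  cc <- concatenate_alignments(list(g1, g2), c("g1", "g2"))
  expect_equal(n_sites(cc), 25)
  expect_equal(cc$partition$start, c(0, 10))
  expect_equal(cc$partition$end, c(10, 25))
  expect_true(all(cc$mat["B", 11:25] == "X"))
  expect_true(all(cc$mat["C", 1:10] == "X"))
  one <- concatenate_alignments(list(g1))
  expect_identical(one$mat, g1$mat)
  expect_equal(nrow(one$partition), 1)
  d6 <- recode_dayhoff6(g1)
  expect_error(concatenate_alignments(list(g1, d6)), "alphabet")
})

test_that("site jackknife samples without replacement, deterministically and uniformly", {
  set.seed(2)
  mat <- matrix(sample(rootsignal:::AA_STATES, 8 * 1000, replace = TRUE),
                8, 1000, dimnames = list(paste0("t", 1:8), NULL))
  a <- new_alignment(mat)
  expect_identical(jackknife_sites(a, 1000, seed = 5)$mat, a$mat)
  j1 <- jackknife_sites(a, 50, seed = 9)
  j2 <- jackknife_sites(a, 50, seed = 9)
  expect_identical(j1$mat, j2$mat)
  expect_equal(n_sites(j1), 50)
  # sampled columns are a sub-multiset of the original columns
  key <- function(x) apply(x$mat, 2, paste, collapse = "")
  expect_true(all(key(j1) %in% key(a)))
  expect_error(jackknife_sites(a, 1001, seed = 1), "n_sites")
  # uniformity over columns: 10,000 draws of 1 column from 10
  small <- new_alignment(a$mat[, 1:10])
  counts <- tabulate(vapply(1:10000, function(i)
    which(key(a)[1:10] == key(jackknife_sites(small, 1, seed = i))), 0L),
    nbins = 10)
  expect_gt(chisq_gof(counts)$p, 0.001)
})

test_that("dayhoff6 recoding follows the six exchange groups and is one-way", {
  a <- aln_from_strings(c(A = "ACDF", B = "ACDF", C = "----", D = "ILHW"))
  d6 <- recode_dayhoff6(a)
  expect_equal(unname(d6$mat["A", ]), c("1", "6", "2", "5"))
  expect_equal(unname(d6$mat["C", ]), rep("-", 4))
  expect_equal(unname(d6$mat["D", ]), c("4", "4", "3", "5"))
  expect_error(recode_dayhoff6(d6), "already")
  # surjection onto 6 states and div can only shrink
  set.seed(3)
  big <- new_alignment(matrix(sample(rootsignal:::AA_STATES, 5 * 400,
                                     replace = TRUE), 5, 400,
                              dimnames = list(paste0("t", 1:5), NULL)))
  r <- recode_dayhoff6(big)
  expect_setequal(unique(as.vector(r$mat)), as.character(1:6))
  expect_lte(diversity_statistic(r), diversity_statistic(big))
})

test_that("taxon removal keeps columns and enforces the 4-taxon floor", {
  a <- aln_from_strings(setNames(rep("MKRD", 10), paste0("t", 1:10)))
  expect_identical(remove_taxa(a, character(0))$mat, a$mat)
  r <- remove_taxa(a, "t3")
  expect_equal(n_taxa(r), 9)
  expect_equal(n_sites(r), 4)
  expect_error(remove_taxa(a, paste0("t", 1:7)), "fewer than 4")
  expect_error(remove_taxa(a, "nope"), "unknown")
})

test_that("empirical frequencies exclude gaps and support pseudocounts", {
  a <- aln_from_strings(c(A = "AAAC", B = "--X-"))
  f <- empirical_frequencies(a)
  expect_equal(unname(f["A"]), 0.75)
  expect_equal(unname(f["C"]), 0.25)
  expect_equal(sum(f), 1)
  expect_error(empirical_frequencies(a, per_taxon = TRUE), "zero counted")
  fp <- empirical_frequencies(a, per_taxon = TRUE, pseudocount = 0.5)
  expect_equal(rowSums(fp), c(A = 1, B = 1))
  allA <- aln_from_strings(c(A = "AA", B = "AA"))
  expect_equal(unname(empirical_frequencies(allA)["A"]), 1)
})

test_that("div counts distinct residues per column, ignoring gaps", {
  const <- aln_from_strings(c(A = "MMM", B = "MMM", C = "MMM"))
  expect_equal(diversity_statistic(const), 1)
  two <- aln_from_strings(c(A = "AA", B = "AC", C = "CD"))
  expect_equal(diversity_statistic(two), 2.5)
  gapcol <- aln_from_strings(c(A = "-A", B = "-A", C = "-A"))
  expect_equal(diversity_statistic(gapcol), 0.5)  # all-gap column adds 0
  full <- aln_from_strings(setNames(as.list(rootsignal:::AA_STATES),
                                    paste0("t", 1:20)))
  expect_equal(diversity_statistic(full), 20)
})

test_that("MAX is the largest per-taxon sum of squared frequency deviations", {
  same <- aln_from_strings(c(A = "ARND", B = "ARND", C = "ARND"))
  expect_equal(max_composition_deviation(same), 0)
  two <- aln_from_strings(c(A = "AAAA", B = "CCCC"))
  expect_equal(max_composition_deviation(two), 0.5)
  set.seed(4)
  mat <- matrix(sample(rootsignal:::AA_STATES, 6 * 100, replace = TRUE), 6, 100,
                dimnames = list(paste0("t", 1:6), NULL))
  a1 <- new_alignment(mat)
  a2 <- new_alignment(mat[sample(6), ])
  expect_equal(max_composition_deviation(a1), max_composition_deviation(a2))
})

test_that("per-taxon composition chi-squared matches hand computation", {
  same <- aln_from_strings(c(A = "ARND", B = "ARND"))
  r0 <- composition_chisq(same)
  expect_true(all(r0$table$chi2 == 0))
  expect_false(any(r0$table$fail))
  opp <- aln_from_strings(c(A = strrep("A", 100), B = strrep("C", 100)))
  r <- composition_chisq(opp, threshold = 0.05)
  expect_equal(r$table$chi2, c(100, 100))
  expect_equal(r$table$df, c(1, 1))   # two states in the pooled support
  expect_true(all(r$table$fail))
  r2 <- composition_chisq(opp, threshold = 1e-30)
  expect_false(any(r2$table$fail))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_composition_tsv(r, p)
  expect_equal(nrow(read.table(p, header = TRUE)), 2)
})

test_that("pattern compression is a faithful multiset encoding", {
  same <- aln_from_strings(c(A = "MMMM", B = "KKKK"))
  pc <- pattern_compress(same)
  expect_equal(ncol(pc$patterns), 1)
  expect_equal(pc$weights, 4)
  set.seed(5)
  mat <- matrix(sample(c("A", "C"), 3 * 40, replace = TRUE), 3, 40,
                dimnames = list(c("a", "b", "c"), NULL))
  a <- new_alignment(mat)
  pc <- pattern_compress(a)
  expect_equal(sum(pc$weights), 40)
  expect_identical(pc$patterns[, pc$index],
                   rootsignal:::alignment_states_int(a))
})
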