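test_that("collapse_reads preserves copy counts", {
  a <- strrep("A", 21)
  b <- strrep("C", 21)
  col <- collapse_reads(c(a, a, b))
  expect_equal(nrow(col), 2L)
  expect_equal(col$copy_count[col$sequence == a], 2L)
  expect_equal(col$copy_count[col$sequence == b], 1L)
  # all distinct -> identity
  withr::local_seed(21)
  seqs <- unique(vapply(1:50, function(i) rand_seq(21), character(1)))
  col2 <- collapse_reads(seqs)
  expect_equal(nrow(col2), length(seqs))
  expect_true(all(col2$copy_count == 1L))
  expect_equal(sum(collapse_reads(sample(seqs, 200, TRUE))$copy_count), 200L)
  expect_equal(nrow(collapse_reads(character(0))), 0L)
})

test_that("collapse matches the generator's planted duplication", {
  g <- simulate_genome(8000, seed = 14)
  lib <- simulate_srna_library(srna_library_spec(
    genome = g, n_reads = 5000, duplication_rate = 0.5, seed = 14))
  col <- collapse_reads(lib$reads$sequence)
  expect_equal(nrow(col), lib$truth$n_distinct)
  expect_equal(sum(col$copy_count), 5000L)
})

test_that("empty profile is the absent-virus case", {
  empty <- data.frame(read_sequence = character(0),
                      virus_abbrev = character(0), position = integer(0),
                      strand = character(0), mismatches = integer(0),
                      copy_count = integer(0))
  p <- profile_virus(empty, genome_length = 1000, n_unique_library = 500,
                     virus_abbrev = "CcaNV")
  expect_equal(p$n_unique_mapped, 0L)
  expect_equal(p$pct_unique_mapped, 0)
  expect_equal(sum(p$length_hist), 0L)
  expect_equal(p$uniformity, 0)
})

test_that("percentage arithmetic and integrity checks", {
  withr::local_seed(3)
  mk <- function(n) data.frame(
    read_sequence = vapply(seq_len(n), function(i) rand_seq(21),
                           character(1)),
    virus_abbrev = "v", position = sample(0:900, n, TRUE), strand = "+",
    mismatches = 0L, copy_count = 1L)
  p <- profile_virus(mk(10), 1000, n_unique_library = 1000)
  expect_equal(p$pct_unique_mapped, 1.0)
  expect_error(profile_virus(mk(10), 1000, n_unique_library = 5),
               "smaller than")
  bad <- mk(1)
  bad$position <- 990L
  expect_error(profile_virus(bad, 1000, 10), "exceeds genome length")
  two <- mk(2)
  two$virus_abbrev <- c("a", "b")
  expect_error(profile_virus(two, 1000, 10), "single virus")
})

test_that("simulated siRNA library yields the expected profile", {
  g <- simulate_genome(10000, seed = 11)
  idx <- build_index(c(v = g))
  lib <- simulate_srna_library(srna_library_spec(genome = g,
                                                 n_reads = 20000, seed = 11))
  mp <- map_reads(lib$reads$sequence, idx)
  p <- profile_virus(mp$mapped, nchar(g), mp$stats$n_unique,
                     virus_abbrev = "v")
  by_len <- rowSums(p$length_hist)
  expect_equal(as.integer(names(which.max(by_len))), 21L)
  # modal length is 21 on each strand separately
  expect_equal(as.integer(names(which.max(p$length_hist[, "+"]))), 21L)
  expect_equal(as.integer(names(which.max(p$length_hist[, "-"]))), 21L)
  expect_gt(p$uniformity, 0.95)
  # histogram equals direct tabulation of the generator truth
  truth_tab <- table(factor(lib$reads$length[!duplicated(lib$reads$sequence)],
                            levels = 18:32))
  expect_equal(as.integer(rowSums(p$length_hist)), as.integer(truth_tab))
})

test_that("profile conserves counts and is order-invariant", {
  g <- simulate_genome(6000, seed = 15)
  idx <- build_index(c(v = g))
  lib <- simulate_srna_library(srna_library_spec(
    genome = g, n_reads = 3000,
    class_mix = c(siRNA = 0.6, piRNA = 0.2, degradation = 0.2),
    seed = 15))
  mp <- map_reads(lib$reads$sequence, idx)
  p <- profile_virus(mp$mapped, nchar(g), mp$stats$n_unique,
                     virus_abbrev = "v")
  expect_equal(sum(p$length_hist), p$n_unique_mapped)
  expect_true(p$pct_unique_mapped >= 0 && p$pct_unique_mapped <= 100)
  # per (length, strand) cell the 5' base counts sum to the histogram cell
  expect_equal(apply(p$first_base_comp, c(1, 2), sum),
               unclass(p$length_hist), ignore_attr = TRUE)
  withr::local_seed(1)
  perm <- sample.int(nrow(mp$mapped))
  p2 <- profile_virus(mp$mapped[perm, , drop = FALSE], nchar(g),
                      mp$stats$n_unique, virus_abbrev = "v")
  expect_equal(p2$length_hist, p$length_hist)
  expect_equal(p2$first_base_comp, p$first_base_comp)
  expect_equal(p2$coverage, p$coverage)
})

test_that("5' base uses the read as sequenced, RNA alphabet", {
  # genome ...TTTT...; a minus-strand read over it starts with A
  g <- paste0(rand_seq(40), strrep("T", 21), rand_seq(40))
  idx <- build_index(c(v = g))
  minus_read <- revcomp(substr(g, 41, 61))  # AAAA...
  mp <- map_reads(minus_read, idx)
  expect_equal(mp$mapped$strand, "-")
  p <- profile_virus(mp$mapped, nchar(g), 1)
  expect_equal(sum(p$first_base_comp[, "-", "A"]), 1L)
  # plus-strand T-starting read is reported as U
  plus_read <- substr(g, 41, 61)
  mp2 <- map_reads(plus_read, idx)
  p2 <- profile_virus(mp2$mapped[mp2$mapped$strand == "+", , drop = FALSE],
                      nchar(g), 1)
  expect_equal(sum(p2$first_base_comp[, "+", "U"]), 1L)
})

test_that("coverage is per strand and matches read spans", {
  g <- rand_seq(100)
  reads <- data.frame(read_sequence = c(substr(g, 1, 20),
                                        revcomp(substr(g, 51, 70))),
                      virus_abbrev = "v", position = c(0L, 50L),
                      strand = c("+", "-"), mismatches = 0L,
                      copy_count = 1L)
  p <- profile_virus(reads, 100, 2)
  expect_equal(sum(p$coverage$plus), 20L)
  expect_equal(which(p$coverage$plus == 1L), 1:20)
  expect_equal(which(p$coverage$minus == 1L), 51:70)
  expect_equal(p$uniformity, 0.4)
})

test_that("profile TSV outputs are written and consistent", {
  g <- simulate_genome(2000, seed = 19)
  idx <- build_index(c(v = g))
  lib <- simulate_srna_library(srna_library_spec(genome = g, n_reads = 500,
                                                 seed = 19))
  mp <- map_reads(lib$reads$sequence, idx)
  p <- profile_virus(mp$mapped, nchar(g), mp$stats$n_unique,
                     virus_abbrev = "v", sample_id = "s1")
  dir <- withr::local_tempdir()
  paths <- write_profiles(list(p), dir)
  hist <- utils::read.delim(paths[["histogram"]])
  expect_equal(sum(hist$count), p$n_unique_mapped)
  cov <- utils::read.delim(paths[["coverage"]])
  expect_equal(sum(cov$depth[cov$strand == "+"]), sum(p$coverage$plus))
})
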