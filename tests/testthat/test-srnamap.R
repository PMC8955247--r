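test_that("FASTQ round-trips and malformed records are located", {
  reads <- data.frame(id = c("a", "b"), sequence = c("ACGTACGTACGTACGTACGT",
                                                     "TTTTACGTACGTACGTAC"),
                      quality = c(strrep("I", 20), strrep("5", 18)))
  tmp <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, tmp)
  back <- read_fastq(tmp)
  expect_equal(back, reads)
  lines <- readLines(tmp)
  lines[5] <- "not_a_header"
  writeLines(lines, tmp)
  expect_error(read_fastq(tmp), "record 2")
  writeLines(lines[1:7], tmp)
  expect_error(read_fastq(tmp), "multiple of 4")
})

test_that("clean_reads applies length, quality and complexity rules", {
  q <- function(n, bad = 0) paste0(strrep("I", n - bad), strrep("#", bad))
  reads <- data.frame(
    id = c("len17", "ok21", "lowq21", "len33", "homo20", "empty"),
    sequence = c(rand_seq(17), rand_seq(21), rand_seq(21), rand_seq(33),
                 paste0(strrep("A", 17), "CGT"), ""),
    quality = c(q(17), q(21), q(21, bad = 5), q(33), q(20), ""))
  res <- clean_reads(reads)
  expect_equal(res$reads$id, "ok21")
  expect_equal(res$stats$n_input, 6L)
  expect_equal(res$stats$n_kept, 1L)
  expect_equal(unname(res$stats$removed["length"]), 2L)
  expect_equal(unname(res$stats$removed["quality"]), 1L)  # 5/21 = 23.8% > 20%
  expect_equal(unname(res$stats$removed["low_complexity"]), 1L)
  expect_equal(unname(res$stats$removed["empty"]), 1L)
  # exactly 20% low-quality bases is tolerated (rule is strict >)
  ok20 <- data.frame(id = "x", sequence = rand_seq(20),
                     quality = q(20, bad = 4))
  expect_equal(clean_reads(ok20)$stats$n_kept, 1L)
})

test_that("planted cleaning violations are exactly the removed set", {
  withr::local_seed(13)
  n <- 1000
  len <- sample(18:32, n, replace = TRUE)
  violation <- sample(c("none", "short", "long", "lowq"), n, replace = TRUE,
                      prob = c(0.7, 0.1, 0.1, 0.1))
  len[violation == "short"] <- sample(1:17, sum(violation == "short"),
                                      replace = TRUE)
  len[violation == "long"] <- sample(33:45, sum(violation == "long"),
                                     replace = TRUE)
  seqs <- vapply(len, rand_seq, character(1))
  qual <- strrep("I", len)
  lowq <- violation == "lowq"
  # 30% of bases below Q20 for planted quality violations
  qual[lowq] <- vapply(len[lowq], function(L) {
    nb <- ceiling(0.3 * L)
    paste0(strrep("#", nb), strrep("I", L - nb))
  }, character(1))
  reads <- data.frame(id = sprintf("r%04d", 1:n), sequence = seqs,
                      quality = qual)
  res <- clean_reads(reads)
  expect_setequal(res$reads$id, reads$id[violation == "none"])
})

test_that("index lookups find planted substrings on both strands", {
  g <- simulate_genome(1000, seed = 2)
  idx <- build_index(c(v1 = g))
  q <- substr(g, 101, 121)
  hit <- lookup_read(idx, q)
  expect_true(any(hit$position == 100 & hit$strand == "+" &
                    hit$mismatches == 0))
  hit_rc <- lookup_read(idx, revcomp(q))
  expect_true(any(hit_rc$position == 100 & hit_rc$strand == "-"))
  expect_error(build_index(c(a = g, a = g)), "duplicate")
  expect_error(build_index(c(a = "")), "empty")
})

test_that("lookups agree with a full-scan oracle at 0 and 1 mismatches", {
  withr::local_seed(17)
  g <- simulate_genome(3000, seed = 17)
  idx <- build_index(c(v = g))
  mutate1 <- function(s) {
    i <- sample.int(nchar(s), 1)
    substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(s, i, i)), 1)
    s
  }
  for (i in 1:60) {
    L <- sample(18:32, 1)
    p <- sample.int(nchar(g) - L + 1, 1)
    q <- switch(sample(3, 1),
                substr(g, p, p + L - 1),          # exact substring
                mutate1(substr(g, p, p + L - 1)), # 1 mutation
                rand_seq(L))                      # random
    if (sample(c(TRUE, FALSE), 1)) q <- revcomp(q)
    for (mm in 0:1) {
      got <- lookup_read(idx, q, max_mismatch = mm)
      want <- oracle_hits(g, q, max_mismatch = mm)
      expect_equal(got[, c("position", "strand")], want,
                   info = paste("query", i, "mm", mm))
    }
  }
})

test_that("reads with N never map and negatives stay unmapped", {
  g <- simulate_genome(1000, seed = 4)
  idx <- build_index(c(v = g))
  q <- substr(g, 1, 21)
  substr(q, 5, 5) <- "N"
  expect_equal(nrow(lookup_read(idx, q, max_mismatch = 1)), 0L)
  mp <- map_reads(c(strrep("AC", 10), substr(g, 51, 72)), idx)
  expect_equal(nrow(mp$mapped), 1L)
  expect_equal(mp$stats$n_unique_mapped, 1L)
})

test_that("multi-mapping policy: leftmost within a virus, once per virus", {
  withr::local_seed(99)
  motif <- "ACGTGCATTGCAACGTGGTCA"  # 21 nt
  g1 <- paste0(rand_seq(100), motif, rand_seq(100), motif, rand_seq(100))
  g2 <- paste0(rand_seq(50), motif, rand_seq(50))
  idx <- build_index(c(a = g1, b = g2))
  mp <- map_reads(motif, idx)
  expect_equal(nrow(mp$mapped), 2L)  # once per virus
  a <- mp$mapped[mp$mapped$virus_abbrev == "a", ]
  expect_equal(a$position, 100L)     # leftmost of the two copies
  expect_equal(mp$mapped[mp$mapped$virus_abbrev == "b", "position"], 50L)
})

test_that("mapping is deterministic and order-independent", {
  g <- simulate_genome(5000, seed = 6)
  idx <- build_index(c(v = g))
  lib <- simulate_srna_library(srna_library_spec(genome = g, n_reads = 500,
                                                 seed = 6))
  m1 <- map_reads(lib$reads$sequence, idx)
  m2 <- map_reads(rev(lib$reads$sequence), idx)
  o <- function(m) {
    d <- m$mapped[order(m$mapped$read_sequence), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  expect_equal(o(m1), o(m2))
})

test_that("every reported mapping re-validates by string comparison", {
  g <- simulate_genome(4000, seed = 8)
  idx <- build_index(c(v = g))
  lib <- simulate_srna_library(srna_library_spec(
    genome = g, n_reads = 400,
    class_mix = c(siRNA = 0.5, piRNA = 0.3, degradation = 0.2),
    seed = 8))
  mp <- map_reads(lib$reads$sequence, idx, max_mismatch = 1)
  for (i in seq_len(nrow(mp$mapped))) {
    row <- mp$mapped[i, ]
    L <- nchar(row$read_sequence)
    sub <- substr(g, row$position + 1, row$position + L)
    target <- if (row$strand == "+") row$read_sequence
              else revcomp(row$read_sequence)
    expect_equal(sum(charToRaw(sub) != charToRaw(target)), row$mismatches)
  }
})

test_that("noiseless viral libraries map completely; SAM export is sane", {
  g <- simulate_genome(10000, seed = 3)
  idx <- build_index(c(v = g))
  lib <- simulate_srna_library(srna_library_spec(genome = g, n_reads = 2000,
                                                 seed = 3))
  mp <- map_reads(lib$reads$sequence, idx)
  # exact matching, noiseless generator: mapped fraction = planted fraction
  expect_equal(mp$stats$n_unique_mapped, mp$stats$n_unique)
  expect_equal(sum(mp$mapped$copy_count), nrow(lib$reads))
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "out.sam")
  write_sam(mp$mapped, idx, sam)
  lines <- readLines(sam)
  expect_true(any(startsWith(lines, "@SQ")))
  expect_equal(sum(!startsWith(lines, "@")), nrow(mp$mapped))
})
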