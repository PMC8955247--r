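test_that("find_orfs handles the minimal start-stop construction", {
  orfs <- find_orfs("ATGAAATAA", min_aa_length = 2, require_start = TRUE)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$frame, 1L)
  expect_equal(orfs$aa_length, 2L)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 9L)
  # stop codon included in span: aa_length = (end - start)/3 - 1
  expect_equal((orfs$end - orfs$start) / 3 - 1, orfs$aa_length)
})

test_that("find_orfs maps reverse-complement ORFs onto forward coordinates", {
  fwd <- find_orfs("ATGAAATAA", min_aa_length = 2, require_start = TRUE)
  rev <- find_orfs(revcomp("ATGAAATAA"), min_aa_length = 2,
                   require_start = TRUE)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$frame, -1L)
  expect_equal(rev$start, fwd$start)
  expect_equal(rev$end, fwd$end)
  expect_equal(rev$aa_length, fwd$aa_length)
})

test_that("codons containing N are non-coding", {
  expect_equal(nrow(find_orfs(strrep("N", 300), min_aa_length = 1)), 0L)
  # an N mid-run splits it without adding a stop codon
  s <- paste0("ATG", strrep("AAA", 10), "NNN", strrep("AAA", 10), "TAA")
  orfs <- find_orfs(s, min_aa_length = 5, require_start = FALSE)
  expect_true(all(orfs$aa_length <= 11))
})

test_that("find_orfs agrees with the naive all-triplet oracle", {
  withr::local_seed(42)
  for (i in 1:20) {
    s <- rand_seq(200)
    for (rs in c(FALSE, TRUE)) {
      for (min_aa in c(5, 25)) {
        got <- canon_orfs(find_orfs(s, min_aa_length = min_aa,
                                    require_start = rs))
        want <- oracle_orfs(s, min_aa_length = min_aa, require_start = rs)
        rownames(want) <- NULL
        expect_equal(got, want, info = paste("seq", i, "rs", rs, min_aa))
      }
    }
  }
})

test_that("triage applies the cascade with all applicable reasons", {
  withr::local_seed(7)
  contigs <- c(short_viral = paste0("ATG", rand_seq(1990), "TAA"),
               hosty = paste0("ATG", rand_seq(4991), "TAA"),
               keeper = paste0("ATG", rand_seq(2994), "TAA"),
               orphan = paste0("ATG", rand_seq(2194), "TAA"))
  vh <- data.frame(query_id = c("short_viral", "hosty", "keeper"),
                   evalue = c(1e-20, 1e-20, 1e-30))
  hh <- data.frame(query_id = "hosty", evalue = 1e-120)
  v <- triage_contigs(contigs, vh, hh)
  expect_equal(v$kept, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(v$reasons[[1]], "too_short")
  expect_equal(v$reasons[[2]], "host_genome")
  expect_equal(v$reasons[[3]], character(0))
  # absent from both hit tables -> fails the first filter
  expect_true("no_viral_hit" %in% v$reasons[[4]])
  # kept <=> no reasons
  expect_equal(v$kept, lengths(v$reasons) == 0L)
})

test_that("hits referencing unknown contigs are a referential error", {
  vh <- data.frame(query_id = "ghost", evalue = 1e-20)
  expect_error(triage_contigs(c(a = strrep("ACGT", 600)), vh, NULL),
               "unknown contig.*ghost")
})

test_that("triage verdicts equal planted ground truth on a simulated set", {
  sim <- simulate_contig_set(n = 60, seed = 3)
  v <- triage_contigs(sim$contigs, sim$viral_hits, sim$host_hits)
  expect_equal(v$kept, sim$truth$kept)
  expect_equal(vapply(v$reasons, paste, character(1), collapse = ","),
               sim$truth$reasons)
})

test_that("tightening thresholds only shrinks the kept set", {
  sim <- simulate_contig_set(n = 60, seed = 5)
  kept_at <- function(min_length, ev = 1e-5) {
    v <- triage_contigs(sim$contigs, sim$viral_hits, sim$host_hits,
                        triage_params(min_length = min_length,
                                      viral_evalue_max = ev))
    v$contig_id[v$kept]
  }
  k1000 <- kept_at(1000)
  k2000 <- kept_at(2000)
  k4000 <- kept_at(4000)
  expect_true(all(k4000 %in% k2000))
  expect_true(all(k2000 %in% k1000))
  expect_true(all(kept_at(2000, ev = 1e-20) %in% k2000))
})

test_that("terminal coverage check follows the two-window rule", {
  ok <- terminal_coverage_check(rep(10, 1000), end_window = 100)
  expect_true(ok$pass)
  expect_equal(ok$ratio_5p, 1.0)
  expect_equal(ok$ratio_3p, 1.0)
  bad <- terminal_coverage_check(c(rep(0, 100), rep(10, 900)),
                                 end_window = 100)
  expect_false(bad$pass)
  zero <- terminal_coverage_check(rep(0, 500), end_window = 100)
  expect_false(zero$pass)
  expect_true(zero$zero_coverage)
  expect_error(terminal_coverage_check(rep(1, 50), end_window = 100),
               "shorter")
  # decision equals direct recomputation on a simulated pileup
  g <- simulate_genome(2000, seed = 9)
  lib <- simulate_srna_library(srna_library_spec(genome = g, n_reads = 3000,
                                                 seed = 9))
  mp <- map_reads(lib$reads$sequence, build_index(c(v = g)))
  p <- profile_virus(mp$mapped, nchar(g), mp$stats$n_unique,
                     virus_abbrev = "v")
  depth <- p$coverage$plus + p$coverage$minus
  res <- terminal_coverage_check(depth, end_window = 50, min_ratio = 0.2)
  expect_equal(res$pass,
               mean(depth[1:50]) >= 0.2 * mean(depth) &&
                 mean(depth[1951:2000]) >= 0.2 * mean(depth))
})

test_that("verdict TSV and hit-table IO work", {
  sim <- simulate_contig_set(n = 20, seed = 11)
  dir <- withr::local_tempdir()
  paths <- write_contig_set(sim, dir)
  hits <- read_hits(paths[["viral_hits"]])
  expect_true(all(c("query_id", "evalue", "bitscore") %in% names(hits)))
  v <- triage_contigs(paths[["contigs"]], paths[["viral_hits"]],
                      paths[["host_hits"]])
  expect_equal(v$kept, sim$truth$kept)
  out <- file.path(dir, "verdicts.tsv")
  write_verdicts(v, out)
  back <- utils::read.delim(out)
  expect_equal(back$kept, sim$truth$kept)
  # malformed hit table
  bad <- file.path(dir, "bad.tsv")
  writeLines("only\tthree\tcols", bad)
  expect_error(read_hits(bad), "expected 12 columns")
})
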