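# Independent oracles used by unit and acceptance tests.  They share no
# code with the implementation paths they check.

# Naive six-frame ORF enumerator: walks codon by codon, strand by strand.
oracle_orfs <- function(seq, min_aa_length, require_start = FALSE) {
  seq <- toupper(seq)
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  rows <- list()
  emit <- function(run_positions, stop_included, strand_sign) {
    # run_positions: 1-based codon start positions on the scanned strand
    if (require_start) {
      strand_seq <- if (strand_sign > 0) seq else rc(seq)
      cods <- substring(strand_seq, run_positions, run_positions + 2L)
      first_atg <- which(cods == "ATG")
      if (length(first_atg) == 0L) return()
      run_positions <- run_positions[first_atg[1L]:length(run_positions)]
    }
    aa <- length(run_positions)
    if (aa < min_aa_length) return()
    s0 <- run_positions[1L] - 1L
    e0 <- run_positions[aa] + 2L + if (stop_included) 3L else 0L
    frame <- (run_positions[1L] - 1L) %% 3L + 1L
    if (strand_sign < 0) {
      tmp <- s0
      s0 <- n - e0
      e0 <- n - tmp
      frame <- -frame
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      frame = frame, start = s0, end = e0, aa_length = aa)
  }
  for (strand_sign in c(1L, -1L)) {
    s <- if (strand_sign > 0) seq else rc(seq)
    for (f in 1:3) {
      run <- integer(0)
      pos <- f
      while (pos + 2L <= n) {
        cod <- substr(s, pos, pos + 2L)
        if (cod %in% stops) {
          if (length(run) > 0L) emit(run, TRUE, strand_sign)
          run <- integer(0)
        } else if (grepl("N", cod, fixed = TRUE)) {
          if (length(run) > 0L) emit(run, FALSE, strand_sign)
          run <- integer(0)
        } else {
          run <- c(run, pos)
        }
        pos <- pos + 3L
      }
      if (length(run) > 0L) emit(run, FALSE, strand_sign)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), aa_length = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$frame, out$start, out$end), , drop = FALSE]
}

# Sort an ORF table into the oracle's canonical order for comparison.
canon_orfs <- function(df) {
  df <- df[, c("frame", "start", "end", "aa_length")]
  df <- df[order(df$frame, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Full-scan matcher oracle via Biostrings::matchPattern (substitutions
# only), both strands, forward-genome coordinates.
oracle_hits <- function(genome, query, max_mismatch = 0) {
  g <- Biostrings::DNAString(genome)
  hit_frame <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, g, max.mismatch = max_mismatch,
                                  with.indels = FALSE)
    if (length(m) == 0L)
      return(data.frame(position = integer(0), strand = character(0)))
    data.frame(position = Biostrings::start(m) - 1L, strand = strand,
               stringsAsFactors = FALSE)
  }
  rcq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(query)))
  out <- rbind(hit_frame(query, "+"), hit_frame(rcq, "-"))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random nucleotide string (test-local helper, not the package generator).
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
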