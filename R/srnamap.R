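# Small-RNA read cleaning and a built-in exact / 1-mismatch matcher of
# 18-32 nt reads against viral genomes (replaces an external aligner).
# Seed-and-verify design: genome k-mers (default k = 9) are hashed; with
# one mismatch allowed, the pigeonhole over two disjoint 9-mer seeds of an
# 18-nt read guarantees at least one exact seed.

#' Read a small-RNA FASTQ file
#'
#' Light four-line FASTQ parser (gzip transparent) that reports the index
#' of the first malformed record.  Qualities are kept as Phred+33 strings.
#'
#' @param path FASTQ path.
#' @return data.frame with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ parse error in ", path, ": line count not a multiple of 4 (",
         "truncated record ", length(lines) %/% 4L + 1L, ")")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  h <- lines[seq.int(1L, by = 4L, length.out = n)]
  s <- toupper(lines[seq.int(2L, by = 4L, length.out = n)])
  p <- lines[seq.int(3L, by = 4L, length.out = n)]
  q <- lines[seq.int(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(h, "@") | !startsWith(p, "+") |
                 nchar(s) != nchar(q))
  if (length(bad) > 0L)
    stop("FASTQ parse error in ", path, ": malformed record ", bad[1L])
  data.frame(id = sub("^@", "", sub("\\s.*$", "", h)), sequence = s,
             quality = q, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `id`, `sequence` and optionally `quality`
#'   (constant Q30 written when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if (!is.null(reads$quality)) reads$quality
          else strrep("?", nchar(reads$sequence))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L)
    writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual),
               con)
  invisible(path)
}

#' Clean small-RNA reads
#'
#' Applies the small-RNA cleaning rules to adapter-free reads: empty
#' sequences are dropped, reads outside the 18-32 nt window are dropped,
#' reads with more than `max_lowqual_frac` of bases below `qual_threshold`
#' are dropped, and low-complexity reads (longest homopolymer run covering
#' more than `max_homopolymer_frac` of the read) are dropped.  Rules are
#' applied in that order and each read is counted once, under the first
#' rule it violates.
#'
#' @param raw FASTQ path or data.frame with `id`, `sequence`, and
#'   optionally `quality` (Phred+33; reads without qualities pass the
#'   quality rule).
#' @param min_len,max_len Length window in nt (default 18-32).
#' @param max_lowqual_frac Maximum tolerated fraction of low-quality bases.
#' @param qual_threshold Phred score below which a base is low-quality.
#' @param max_homopolymer_frac Homopolymer-run fraction above which a read
#'   is low-complexity.
#' @return List with `reads` (the retained data.frame, plus `length`) and
#'   `stats` (counts: `n_input`, `n_kept`, and removals per rule).
#' @export
clean_reads <- function(raw, min_len = 18, max_len = 32,
                        max_lowqual_frac = 0.20, qual_threshold = 20,
                        max_homopolymer_frac = 0.8) {
  reads <- if (is.character(raw) && length(raw) == 1L) read_fastq(raw) else raw
  if (!is.data.frame(reads) || !all(c("id", "sequence") %in% names(reads)))
    stop("raw reads must be a FASTQ path or a data.frame with id, sequence")
  n <- nrow(reads)
  len <- nchar(reads$sequence)
  removed <- c(empty = 0L, length = 0L, quality = 0L, low_complexity = 0L)
  reason <- rep(NA_character_, n)

  reason[is.na(reason) & len == 0L] <- "empty"
  reason[is.na(reason) & (len < min_len | len > max_len)] <- "length"

  if (!is.null(reads$quality)) {
    todo <- which(is.na(reason))
    for (i in todo) {
      q <- utf8ToInt(reads$quality[i]) - 33L
      if (mean(q < qual_threshold) > max_lowqual_frac) reason[i] <- "quality"
    }
  }
  todo <- which(is.na(reason))
  for (i in todo) {
    r <- rle(strsplit(reads$sequence[i], "", fixed = TRUE)[[1L]])
    if (max(r$lengths) / len[i] > max_homopolymer_frac)
      reason[i] <- "low_complexity"
  }

  tab <- table(factor(reason, levels = names(removed)))
  removed[names(tab)] <- as.integer(tab)
  keep <- is.na(reason)
  out <- reads[keep, , drop = FALSE]
  out$length <- len[keep]
  rownames(out) <- NULL
  list(reads = out,
       stats = list(n_input = n, n_kept = sum(keep), removed = removed))
}

#' Build a k-mer seed index over viral genomes
#'
#' Hashes every genome k-mer position (forward strand) per genome.  With
#' `seed_length` 9, any 18-32 nt query can be located exactly or with one
#' mismatch by the pigeonhole principle over its two leading disjoint
#' seeds; minus-strand hits are found by looking up the reverse complement
#' of the query.
#'
#' @param genomes Named character vector, `DNAStringSet`, data.frame
#'   (id/sequence) or FASTA path.  Names are the virus abbreviations.
#' @param seed_length Seed k-mer length (default 9).
#' @return A `match_index` object.
#' @export
build_index <- function(genomes, seed_length = 9) {
  if (is.character(genomes) && length(genomes) == 1L && file.exists(genomes))
    genomes <- read_fasta_frame(genomes)
  g <- as_seq_frame(genomes, "genomes")
  if (anyDuplicated(g$id))
    stop("duplicate genome abbreviation(s): ",
         paste(unique(g$id[duplicated(g$id)]), collapse = ", "))
  if (any(nchar(g$sequence) == 0L)) stop("empty genome sequence")
  if (any(nchar(g$sequence) < seed_length))
    stop("genome shorter than seed_length")
  idx <- vector("list", nrow(g))
  names(idx) <- g$id
  for (i in seq_len(nrow(g))) {
    s <- g$sequence[i]
    n <- nchar(s)
    st <- seq_len(n - seed_length + 1L)
    kmers <- substring(s, st, st + seed_length - 1L)
    idx[[i]] <- list2env(split(st, kmers), hash = TRUE,
                         size = length(st))
  }
  structure(list(genomes = stats::setNames(g$sequence, g$id),
                 genome_length = stats::setNames(nchar(g$sequence), g$id),
                 k = as.integer(seed_length), index = idx),
            class = "match_index")
}

#' @export
print.match_index <- function(x, ...) {
  cat("k-mer match index: ", length(x$genomes), " genome(s), k = ", x$k,
      "\n", sep = "")
  invisible(x)
}

# Vectorised seed-and-verify matching of many queries against one genome.
# Returns all verified hits as a data.frame (read index i, 1-based start,
# strand, mismatches).  qplus/qminus are the query and reverse-complement
# sequences; `active` indexes the queries eligible for matching.
match_in_genome <- function(index, gi, qplus, qminus, active, max_mismatch) {
  k <- index$k
  env <- index$index[[gi]]
  genome <- index$genomes[[gi]]
  n <- index$genome_length[[gi]]
  L <- nchar(qplus)
  parts <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") qplus else qminus
    if (length(active) == 0L) next
    c1 <- mget(substr(q[active], 1L, k), envir = env,
               ifnotfound = list(NULL))
    reads <- rep(active, lengths(c1))
    pos <- unlist(c1, use.names = FALSE)
    if (max_mismatch >= 1L) {
      c2 <- mget(substr(q[active], k + 1L, 2L * k), envir = env,
                 ifnotfound = list(NULL))
      reads <- c(reads, rep(active, lengths(c2)))
      pos <- c(pos, unlist(c2, use.names = FALSE) - k)
    }
    if (length(reads) == 0L) next
    ok <- pos >= 1L & pos + L[reads] - 1L <= n
    reads <- reads[ok]
    pos <- pos[ok]
    if (max_mismatch >= 1L && length(reads) > 0L) {
      dup <- duplicated(paste0(reads, ":", pos))
      reads <- reads[!dup]
      pos <- pos[!dup]
    }
    if (length(reads) == 0L) next
    sub <- substring(genome, pos, pos + L[reads] - 1L)
    qv <- q[reads]
    eq <- sub == qv
    if (max_mismatch == 0L) {
      keep <- eq
      mm <- rep(0L, sum(keep))
    } else {
      mmv <- integer(length(reads))
      todo <- which(!eq)
      if (length(todo) > 0L)
        mmv[todo] <- mapply(hamming, sub[todo], qv[todo], USE.NAMES = FALSE)
      keep <- mmv <= max_mismatch
      mm <- mmv[keep]
    }
    if (!any(keep)) next
    parts[[strand]] <- data.frame(read = reads[keep], position = pos[keep],
                                  strand = strand, mismatches = mm,
                                  stringsAsFactors = FALSE)
  }
  if (length(parts) == 0L)
    return(data.frame(read = integer(0), position = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, parts)
}

#' Look up all matches of one query in an index
#'
#' Exhaustive within the guarantee of the seed scheme: complete for
#' `max_mismatch` 0 always, and for `max_mismatch` 1 when the query is at
#' least twice the seed length (true for 18-32 nt queries at the default
#' seed length 9).
#'
#' @param index A `match_index`.
#' @param query Query sequence (queries containing `N` never match).
#' @param max_mismatch 0 or 1.
#' @return data.frame `virus_abbrev`, `position` (0-based, forward
#'   strand), `strand`, `mismatches`; zero rows when unmapped.
#' @export
lookup_read <- function(index, query, max_mismatch = 0) {
  empty <- data.frame(virus_abbrev = character(0), position = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  query <- toupper(query)
  if (grepl("N", query, fixed = TRUE)) return(empty)
  if (max_mismatch >= 1L && nchar(query) < 2L * index$k)
    stop("1-mismatch lookup needs query length >= 2 * seed_length")
  out <- list()
  for (gi in names(index$genomes)) {
    h <- match_in_genome(index, gi, query, revcomp(query), 1L,
                         as.integer(max_mismatch))
    if (nrow(h) > 0L) {
      h$virus_abbrev <- gi
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res$position <- res$position - 1L
  res <- res[order(res$virus_abbrev, res$position, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("virus_abbrev", "position", "strand", "mismatches")]
}

#' Map cleaned small-RNA reads to viral genomes
#'
#' Collapses reads to unique sequences, then matches each against every
#' genome in the index.  Within one virus a multi-mapping read is reported
#' once at its leftmost position (ties broken to the + strand, then fewest
#' mismatches); across viruses the read is counted once per virus, so each
#' virus profile is computed independently.  Reads containing `N` never
#' map.  Every reported mapping is verified by direct string comparison.
#'
#' @param reads Cleaned reads: character vector of sequences or data.frame
#'   with a `sequence` column.
#' @param index A `match_index` from [build_index()].
#' @param max_mismatch Maximum mismatches (0, the default, or 1).
#' @return List with `mapped` (data.frame `read_sequence`, `virus_abbrev`,
#'   `position` 0-based, `strand`, `mismatches`, `copy_count`) and `stats`
#'   (`n_reads`, `n_unique`, `n_unique_mapped`, `per_virus` table).
#' @export
map_reads <- function(reads, index, max_mismatch = 0) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  max_mismatch <- as.integer(max_mismatch)
  collapsed <- collapse_reads(seqs)
  useqs <- collapsed$sequence
  nun <- length(useqs)
  has_n <- grepl("N", useqs, fixed = TRUE)
  if (max_mismatch >= 1L && any(nchar(useqs[!has_n]) < 2L * index$k))
    stop("1-mismatch lookup needs query length >= 2 * seed_length")
  rc <- character(nun)
  if (any(!has_n)) rc[!has_n] <- revcomp(useqs[!has_n])
  active <- which(!has_n)
  rows <- list()
  for (gi in names(index$genomes)) {
    h <- match_in_genome(index, gi, useqs, rc, active, max_mismatch)
    if (nrow(h) == 0L) next
    # per (read, virus): leftmost position, '+' before '-', fewest
    # mismatches
    h <- h[order(h$read, h$position, h$strand != "+", h$mismatches), ,
           drop = FALSE]
    best <- h[!duplicated(h$read), , drop = FALSE]
    rows[[gi]] <- data.frame(read_sequence = useqs[best$read],
                             virus_abbrev = gi,
                             position = best$position - 1L,
                             strand = best$strand,
                             mismatches = best$mismatches,
                             copy_count = collapsed$copy_count[best$read],
                             stringsAsFactors = FALSE)
  }
  mapped <- if (length(rows) == 0L) {
    data.frame(read_sequence = character(0), virus_abbrev = character(0),
               position = integer(0), strand = character(0),
               mismatches = integer(0), copy_count = integer(0),
               stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, rows)
    rownames(m) <- NULL
    m
  }
  per_virus <- data.frame(
    virus_abbrev = names(index$genomes),
    n_unique_mapped = vapply(names(index$genomes), function(v)
      sum(mapped$virus_abbrev == v), integer(1)),
    n_reads_mapped = vapply(names(index$genomes), function(v)
      sum(mapped$copy_count[mapped$virus_abbrev == v]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(per_virus) <- NULL
  list(mapped = mapped,
       stats = list(n_reads = length(seqs), n_unique = nun,
                    n_unique_mapped = length(unique(mapped$read_sequence)),
                    per_virus = per_virus))
}

#' Write read mappings to TSV
#'
#' Coordinates are converted to 1-based in the file, as is conventional
#' for tabular genome outputs.
#'
#' @param mapped Mapping data.frame from [map_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mappings <- function(mapped, path) {
  df <- mapped
  df$pos_1based <- df$position + 1L
  write_tsv(df[, c("read_sequence", "virus_abbrev", "pos_1based", "strand",
                   "mismatches", "copy_count")], path)
}

#' Export mappings as SAM for inspection
#'
#' Minimal single-end SAM: header plus one alignment line per mapping
#' (flag 0/16, MAPQ 255, simple match CIGAR).  Convenience output only.
#'
#' @param mapped Mapping data.frame from [map_reads()].
#' @param index The `match_index` used (for reference lengths).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(mapped, index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (v in names(index$genomes))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", v, index$genome_length[[v]]), con)
  if (nrow(mapped) > 0L) {
    L <- nchar(mapped$read_sequence)
    seqout <- ifelse(mapped$strand == "+", mapped$read_sequence,
                     revcomp(mapped$read_sequence))
    writeLines(sprintf("read_%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       seq_len(nrow(mapped)),
                       ifelse(mapped$strand == "+", 0L, 16L),
                       mapped$virus_abbrev, mapped$position + 1L, L,
                       seqout, mapped$mismatches), con)
  }
  invisible(path)
}
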