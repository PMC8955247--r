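# Synthetic-data generators with planted ground truth for every pipeline
# stage: genomes, class-structured small-RNA libraries, qPCR measurements
# and labelled contig sets.  All generators take an explicit seed and
# leave the global RNG state untouched.

# Repeating this unit places stop codons densely in all six reading
# frames (longest stop-free run: 4 codons), so contigs built from it
# carry no ORF of >= 25 codons even with short random flanks.
NO_ORF_UNIT <- "AACCGTTAGTTAATT"

#' Simulate a random genome sequence
#'
#' I.i.d. bases at a target GC content; deterministic for a fixed seed.
#'
#' @param length Genome length in nt (>= 100).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return Nucleotide string.
#' @export
#' @examples
#' nchar(simulate_genome(2896, seed = 1))
simulate_genome <- function(length, gc = 0.5, seed = 1) {
  if (length < 100) stop("genome length must be >= 100")
  stopifnot(gc >= 0, gc <= 1)
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = "")
  })
}

#' Specification of a synthetic small-RNA library
#'
#' States the read populations emulated over a known viral genome:
#' siRNA-like reads (21-nt peak, near-balanced strands), piRNA-like reads
#' (24-29 nt, 5'-U biased, strand-asymmetric), degradation-like reads
#' (flat 18-32 nt, strongly one-sided) and non-viral background reads
#' (random sequences).
#'
#' @param genome Viral genome sequence the viral reads are drawn from.
#' @param class_mix Named proportions over
#'   `c("siRNA","piRNA","degradation","nonviral")`, summing to 1.
#' @param n_reads Total reads to generate.
#' @param sirna_length_dist Named length distribution of siRNA reads
#'   (default mass 0.7 at 21 nt, 0.15 at 20 and 22 nt).
#' @param sirna_minor_strand Minor-strand fraction of siRNA reads
#'   (default 0.45, near-bidirectional).
#' @param pirna_length_dist Named length distribution of piRNA reads
#'   (default peaked at 26-28 nt).
#' @param pirna_u_bias Probability a piRNA read starts with 5' U
#'   (default 0.8).
#' @param pirna_minor_strand Minor-strand fraction of piRNA reads
#'   (default 0.2).
#' @param degradation_length_dist Length distribution of degradation
#'   reads (default uniform over 18-32 nt).
#' @param degradation_minor_strand Minor-strand fraction of degradation
#'   reads (default 0.1, the one-sided nora-virus-like signal).
#' @param duplication_rate Fraction of reads that are duplicates of
#'   earlier reads (default 0).
#' @param seed RNG seed.
#' @return An `srna_library_spec` list.
#' @export
srna_library_spec <- function(genome,
                              class_mix = c(siRNA = 1, piRNA = 0,
                                            degradation = 0, nonviral = 0),
                              n_reads = 10000,
                              sirna_length_dist = c("20" = 0.15, "21" = 0.7,
                                                    "22" = 0.15),
                              sirna_minor_strand = 0.45,
                              pirna_length_dist = c("24" = 0.05, "25" = 0.15,
                                                    "26" = 0.25, "27" = 0.25,
                                                    "28" = 0.20, "29" = 0.10),
                              pirna_u_bias = 0.8,
                              pirna_minor_strand = 0.2,
                              degradation_length_dist =
                                stats::setNames(rep(1 / 15, 15), 18:32),
                              degradation_minor_strand = 0.1,
                              duplication_rate = 0,
                              seed = 1) {
  classes <- c("siRNA", "piRNA", "degradation", "nonviral")
  mix <- stats::setNames(rep(0, 4), classes)
  mix[names(class_mix)] <- class_mix
  if (abs(sum(mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (any(mix < 0)) stop("class_mix proportions must be non-negative")
  for (d in list(sirna_length_dist, pirna_length_dist,
                 degradation_length_dist))
    if (abs(sum(d) - 1) > 1e-9 || any(d < 0))
      stop("length distributions must be probability vectors")
  for (p in c(sirna_minor_strand, pirna_minor_strand,
              degradation_minor_strand, pirna_u_bias, duplication_rate))
    stopifnot(p >= 0, p <= 1)
  structure(list(genome = toupper(genome), class_mix = mix,
                 n_reads = as.integer(n_reads),
                 sirna_length_dist = sirna_length_dist,
                 sirna_minor_strand = sirna_minor_strand,
                 pirna_length_dist = pirna_length_dist,
                 pirna_u_bias = pirna_u_bias,
                 pirna_minor_strand = pirna_minor_strand,
                 degradation_length_dist = degradation_length_dist,
                 degradation_minor_strand = degradation_minor_strand,
                 duplication_rate = duplication_rate,
                 seed = as.integer(seed)),
            class = "srna_library_spec")
}

# Draw one genome-derived read: length L, strand, uniform position; for
# 5'-U-forced reads the position is drawn among positions whose 5' base
# on the chosen strand is T (falls back to uniform when none exist).
draw_genomic_reads <- function(genome, n, length_dist, minor_strand,
                               force_u = logical(n)) {
  G <- nchar(genome)
  lens <- as.integer(sample(names(length_dist), n, replace = TRUE,
                            prob = length_dist))
  if (any(lens > G)) stop("read length exceeds genome length")
  strands <- ifelse(stats::runif(n) < minor_strand, "-", "+")
  chars <- strsplit(genome, "", fixed = TRUE)[[1L]]
  t_pos <- which(chars == "T")   # 5' U on + strand
  a_pos <- which(chars == "A")   # 5' U on - strand (complement of A)
  pos <- integer(n)
  for (i in seq_len(n)) {
    L <- lens[i]
    maxp <- G - L + 1L
    if (force_u[i]) {
      cand <- if (strands[i] == "+") t_pos[t_pos <= maxp]
              else a_pos[a_pos >= L] - L + 1L
      pos[i] <- if (length(cand) > 0L) cand[sample.int(length(cand), 1L)]
                else sample.int(maxp, 1L)
    } else {
      pos[i] <- sample.int(maxp, 1L)
    }
  }
  seqs <- substring(genome, pos, pos + lens - 1L)
  flip <- strands == "-"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  data.frame(sequence = seqs, strand = strands, position = pos - 1L,
             length = lens, stringsAsFactors = FALSE)
}

random_reads <- function(n, len_range = 18:32) {
  lens <- sample(len_range, n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""),
    character(1))
  data.frame(sequence = seqs, strand = NA_character_,
             position = NA_integer_, length = lens,
             stringsAsFactors = FALSE)
}

#' Simulate a small-RNA library with planted ground truth
#'
#' Draws reads class by class per the spec, then applies duplication: a
#' `duplication_rate` fraction of the final reads are resampled copies of
#' the base reads.  Viral reads are exact genome substrings (minus-strand
#' reads are reverse-complemented), so with exact matching the mapped set
#' equals the planted viral set.
#'
#' @param spec An [srna_library_spec()].
#' @return List: `reads` (data.frame `id`, `sequence`, `quality`
#'   (constant Q30), `class`, `strand`, `position`, `length`) and
#'   `truth` (list with per-class counts and the per-read labels).
#' @export
simulate_srna_library <- function(spec) {
  stopifnot(inherits(spec, "srna_library_spec"))
  n <- spec$n_reads
  empty <- data.frame(id = character(0), sequence = character(0),
                      quality = character(0), class = character(0),
                      strand = character(0), position = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(reads = empty,
                truth = list(class_counts = table(factor(character(0),
                  levels = names(spec$class_mix))), labels = character(0)),
                spec = spec))
  with_seed(spec$seed, {
    n_dup <- floor(n * spec$duplication_rate)
    n_base <- n - n_dup
    cls <- sample(names(spec$class_mix), n_base, replace = TRUE,
                  prob = spec$class_mix)
    parts <- list()
    for (k in names(spec$class_mix)) {
      nk <- sum(cls == k)
      if (nk == 0L) next
      part <- switch(k,
        siRNA = draw_genomic_reads(spec$genome, nk, spec$sirna_length_dist,
                                   spec$sirna_minor_strand),
        piRNA = draw_genomic_reads(spec$genome, nk, spec$pirna_length_dist,
                                   spec$pirna_minor_strand,
                                   force_u = stats::runif(nk) < spec$pirna_u_bias),
        degradation = draw_genomic_reads(spec$genome, nk,
                                         spec$degradation_length_dist,
                                         spec$degradation_minor_strand),
        nonviral = random_reads(nk))
      part$class <- k
      parts[[k]] <- part
    }
    base <- do.call(rbind, parts)
    base <- base[sample.int(nrow(base)), , drop = FALSE]  # interleave classes
    if (n_dup > 0L) {
      dup <- base[sample.int(nrow(base), n_dup, replace = TRUE), ,
                  drop = FALSE]
      base <- rbind(base, dup)
    }
    rownames(base) <- NULL
    base$id <- sprintf("r%06d", seq_len(nrow(base)))
    base$quality <- strrep("?", base$length)  # constant Q30
    reads <- base[, c("id", "sequence", "quality", "class", "strand",
                      "position", "length")]
    list(reads = reads,
         truth = list(
           class_counts = table(factor(reads$class,
                                       levels = names(spec$class_mix))),
           n_viral = sum(reads$class != "nonviral"),
           n_distinct = length(unique(reads$sequence)),
           labels = reads$class),
         spec = spec)
  })
}

#' Write a simulated library to FASTQ with truth sidecars
#'
#' @param lib Result of [simulate_srna_library()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Named vector of written paths, invisibly.
#' @export
write_srna_library <- function(lib, dir, prefix = "srna") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fastq = file.path(dir, paste0(prefix, ".fastq")),
             truth_tsv = file.path(dir, paste0(prefix, "_truth.tsv")),
             truth_json = file.path(dir, paste0(prefix, "_truth.json")))
  write_fastq(lib$reads, paths[["fastq"]])
  write_tsv(lib$reads[, c("id", "class", "strand", "position", "length")],
            paths[["truth_tsv"]])
  jsonlite::write_json(
    list(n_reads = nrow(lib$reads),
         class_counts = as.list(lib$truth$class_counts),
         n_distinct = lib$truth$n_distinct,
         seed = lib$spec$seed),
    paths[["truth_json"]], auto_unbox = TRUE)
  invisible(paths)
}

#' Simulate a qPCR measurement from true copy numbers
#'
#' `Ct = intercept + slope * log10(true_copies) + N(0, noise_sd)`.
#'
#' @param true_copies True template copies (> 0); vectorised.
#' @param curve A `standard_curve` (e.g. [ideal_standard_curve()]).
#' @param noise_sd Gaussian Ct noise standard deviation.
#' @param seed RNG seed.
#' @param sample_id,target Labels.
#' @return data.frame `sample_id`, `target`, `ct`, `efficiency_E`,
#'   `true_copies`.
#' @export
simulate_qpcr <- function(true_copies, curve, noise_sd = 0, seed = 1,
                          sample_id = NA_character_,
                          target = NA_character_) {
  stopifnot(all(true_copies > 0))
  ct <- with_seed(seed, {
    curve$intercept + curve$slope * log10(true_copies) +
      stats::rnorm(length(true_copies), 0, noise_sd)
  })
  data.frame(sample_id = sample_id, target = target, ct = ct,
             efficiency_E = curve$implied_efficiency,
             true_copies = true_copies, stringsAsFactors = FALSE)
}

# A contig guaranteed to contain no ORF of >= 25 codons: a rotated
# stop-dense repeat with short random flanks.
no_orf_sequence <- function(len) {
  flank5 <- sample(0:12, 1L)
  flank3 <- sample(0:12, 1L)
  core_len <- len - flank5 - flank3
  offset <- sample.int(nchar(NO_ORF_UNIT), 1L)
  rep_str <- strrep(NO_ORF_UNIT, ceiling((core_len + offset) /
                                           nchar(NO_ORF_UNIT)))
  core <- substr(rep_str, offset, offset + core_len - 1L)
  paste0(paste(sample(DNA_BASES, flank5, replace = TRUE), collapse = ""),
         core,
         paste(sample(DNA_BASES, flank3, replace = TRUE), collapse = ""))
}

# A contig guaranteed to contain at least one ORF: random background with
# a planted ATG + >= 30 non-stop codons + TAA.
orf_sequence <- function(len) {
  n_codons <- sample(30:60, 1L)
  sense <- c("GCT", "GCC", "AAA", "GAA", "CTG", "TTC", "GGT", "CAT",
             "ATC", "CTT", "ATG", "AAC", "CCA", "CAA", "CGT", "TCT",
             "ACT", "GTT", "TGG", "TAC")
  orf <- paste0("ATG", paste(sample(sense, n_codons, replace = TRUE),
                             collapse = ""), "TAA")
  stopifnot(nchar(orf) + 6L <= len)
  bg_len <- len - nchar(orf)
  bg <- paste(sample(DNA_BASES, bg_len, replace = TRUE), collapse = "")
  at <- sample.int(bg_len + 1L, 1L)
  paste0(substr(bg, 1L, at - 1L), orf, substr(bg, at, bg_len))
}

#' Simulate a labelled contig set with homology-hit tables
#'
#' Plants, independently per contig, the four triage-relevant properties:
#' a qualifying viral hit (e-value below 1e-5; some non-viral contigs get
#' decoy hits above the threshold), a sub-threshold length, a
#' disqualifying host-genome hit (e-value below 1e-100; decoys above),
#' and the absence of any ORF (stop-dense construction).  The ground
#' truth verdict follows the cascade rule by construction.
#'
#' @param n Number of contigs.
#' @param frac_viral Probability of a qualifying viral hit.
#' @param frac_short Probability of length < 2000 nt.
#' @param frac_host Probability of a disqualifying host hit.
#' @param frac_no_orf Probability of carrying no ORF.
#' @param seed RNG seed.
#' @return List: `contigs` (data.frame id/sequence/length), `viral_hits`,
#'   `host_hits` (12-column tabular hit data.frames) and `truth`
#'   (per-contig planted flags, `kept`, and comma-joined `reasons`).
#' @export
simulate_contig_set <- function(n, frac_viral = 0.6, frac_short = 0.25,
                                frac_host = 0.2, frac_no_orf = 0.25,
                                seed = 1) {
  for (p in c(frac_viral, frac_short, frac_host, frac_no_orf))
    stopifnot(p >= 0, p <= 1)
  with_seed(seed, {
    ids <- sprintf("contig_%04d", seq_len(n))
    has_viral <- stats::runif(n) < frac_viral
    short <- stats::runif(n) < frac_short
    host <- stats::runif(n) < frac_host
    no_orf <- stats::runif(n) < frac_no_orf
    lens <- ifelse(short, sample(500:1999, n, replace = TRUE),
                   sample(2000:4000, n, replace = TRUE))
    seqs <- vapply(seq_len(n), function(i) {
      if (no_orf[i]) no_orf_sequence(lens[i]) else orf_sequence(lens[i])
    }, character(1))

    hit_row <- function(qid, qlen, sid, evalue) {
      alen <- max(60L, as.integer(qlen * 0.3))
      data.frame(qseqid = qid, sseqid = sid,
                 pident = round(stats::runif(1, 40, 99), 2),
                 length = alen, mismatch = sample(0:30, 1L),
                 gapopen = sample(0:3, 1L), qstart = 1L, qend = alen,
                 sstart = 1L, send = alen,
                 evalue = evalue,
                 bitscore = round(stats::runif(1, 60, 900), 1),
                 stringsAsFactors = FALSE)
    }
    viral <- list()
    host_tab <- list()
    for (i in seq_len(n)) {
      if (has_viral[i])
        viral[[length(viral) + 1L]] <-
          hit_row(ids[i], lens[i], "viral_ref", 10^-stats::runif(1, 6, 30))
      else if (stats::runif(1) < 0.25)  # decoy above the 1e-5 threshold
        viral[[length(viral) + 1L]] <-
          hit_row(ids[i], lens[i], "viral_ref", 10^-stats::runif(1, 0, 4.9))
      if (host[i])
        host_tab[[length(host_tab) + 1L]] <-
          hit_row(ids[i], lens[i], "Ccap_genome",
                  10^-stats::runif(1, 105, 180))
      else if (stats::runif(1) < 0.25)  # decoy above the 1e-100 threshold
        host_tab[[length(host_tab) + 1L]] <-
          hit_row(ids[i], lens[i], "Ccap_genome",
                  10^-stats::runif(1, 5, 95))
    }
    bind_hits <- function(lst) {
      if (length(lst) == 0L)
        return(data.frame(qseqid = character(0), evalue = numeric(0)))
      do.call(rbind, lst)
    }
    kept <- has_viral & !short & !host & !no_orf
    reasons <- vapply(seq_len(n), function(i) {
      r <- c(if (!has_viral[i]) "no_viral_hit", if (short[i]) "too_short",
             if (host[i]) "host_genome", if (no_orf[i]) "no_orf")
      paste(r, collapse = ",")
    }, character(1))
    list(contigs = data.frame(id = ids, sequence = seqs, length = lens,
                              stringsAsFactors = FALSE),
         viral_hits = bind_hits(viral),
         host_hits = bind_hits(host_tab),
         truth = data.frame(contig_id = ids, has_viral = has_viral,
                            short = short, host = host, no_orf = no_orf,
                            kept = kept, reasons = reasons,
                            stringsAsFactors = FALSE),
         seed = seed)
  })
}

#' Write a simulated contig set to disk
#'
#' Emits the contig FASTA, the two 12-column hit tables (headerless TSV)
#' and the truth table (TSV + JSON summary).
#'
#' @param sim Result of [simulate_contig_set()].
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_contig_set <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(contigs = file.path(dir, "contigs.fasta"),
             viral_hits = file.path(dir, "viral_hits.tsv"),
             host_hits = file.path(dir, "host_hits.tsv"),
             truth = file.path(dir, "truth.tsv"),
             truth_json = file.path(dir, "truth.json"))
  write_fasta(sim$contigs, paths[["contigs"]])
  for (nm in c("viral_hits", "host_hits"))
    utils::write.table(sim[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  write_tsv(sim$truth, paths[["truth"]])
  jsonlite::write_json(list(n = nrow(sim$contigs),
                            n_kept = sum(sim$truth$kept),
                            seed = sim$seed),
                       paths[["truth_json"]], auto_unbox = TRUE)
  invisible(paths)
}
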