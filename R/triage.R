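# Viral-candidate triage over assembled contigs: conjunctive cascade of
# (1) viral homology hit, (2) contig length, (3) host-genome exclusion,
# (4) open reading frame, plus a separate terminal-coverage confirmation.

STOP_CODONS <- c("TAA", "TAG", "TGA")

TRIAGE_REASONS <- c("no_viral_hit", "too_short", "host_genome", "no_orf",
                    "low_terminal_coverage")
TRIAGE_FILTERS <- c("viral_hit", "length", "host", "orf", "terminal_coverage")

#' Triage parameters
#'
#' Thresholds of the contig filter cascade.  Defaults: viral homology hit
#' required at e-value <= 1e-5, contig length >= 2000 nt, contigs with a
#' host-genome hit at e-value <= 1e-100 are discarded, and at least one
#' ORF of >= 25 codons (start codon not required) must be present.
#'
#' @param viral_evalue_max Max e-value for a qualifying viral hit.
#' @param min_length Minimum contig length in nt.
#' @param host_evalue_max Max e-value at which a host hit disqualifies.
#' @param min_orf_aa Minimum ORF length in codons.
#' @param require_start Must ORFs begin with ATG?
#' @param end_window Terminal-coverage window in nt.
#' @param min_ratio Minimum terminal/global mean-depth ratio.
#' @return List of parameters.
#' @export
triage_params <- function(viral_evalue_max = 1e-5, min_length = 2000,
                          host_evalue_max = 1e-100, min_orf_aa = 25,
                          require_start = FALSE, end_window = 50,
                          min_ratio = 0.2) {
  list(viral_evalue_max = viral_evalue_max, min_length = min_length,
       host_evalue_max = host_evalue_max, min_orf_aa = min_orf_aa,
       require_start = require_start, end_window = end_window,
       min_ratio = min_ratio)
}

# Scan one strand of a sequence: returns ORFs as (start, end, frame) in
# 0-based half-open coordinates on THAT strand. Codons containing N break
# the reading frame without counting as stop codons.
scan_orfs_one_strand <- function(s, min_aa_length, require_start) {
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    if (n - 2L < 1L + f) next
    starts <- seq.int(1L + f, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    has_n <- grepl("N", codons, fixed = TRUE)
    coding <- !is_stop & !has_n
    r <- rle(coding)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts_idx[j]   # codon index of run start
      i1 <- ends_idx[j]     # codon index of run end
      # does a stop codon immediately follow?
      stop_follows <- i1 < length(codons) && is_stop[i1 + 1L]
      if (require_start) {
        atg <- which(codons[i0:i1] == "ATG")
        if (length(atg) == 0L) next
        i0 <- i0 + atg[1L] - 1L
      }
      aa_len <- i1 - i0 + 1L
      if (aa_len < min_aa_length) next
      start0 <- starts[i0] - 1L
      end0 <- starts[i1] + 2L + if (stop_follows) 3L else 0L
      out[[length(out) + 1L]] <- c(start = start0, end = end0,
                                   frame = f + 1L, aa = aa_len)
    }
  }
  out
}

#' Find open reading frames in all six frames
#'
#' Re-implementation of a six-frame ORF scan: maximal stop-free codon runs
#' on both strands, optionally anchored at the first ATG.  Coordinates are
#' 0-based half-open on the forward strand; a terminating stop codon is
#' included in the span, so `aa_length = (end - start)/3 - 1` for
#' stop-terminated ORFs and `(end - start)/3` for open-ended ones.  Codons
#' containing `N` are non-coding and break the frame.
#'
#' @param contig A nucleotide string, or a list/data.frame row with `id`
#'   and `sequence`.
#' @param min_aa_length Minimum ORF length in codons (>= 1).
#' @param require_start If `TRUE`, ORFs start at an ATG.
#' @param contig_id Optional id recorded in the output.
#' @return data.frame with columns `contig_id`, `frame` (+1..+3, -1..-3),
#'   `start`, `end` (0-based half-open, forward strand), `aa_length`,
#'   sorted by decreasing `aa_length`.
#' @export
#' @examples
#' find_orfs("ATGAAATAA", min_aa_length = 2, require_start = TRUE)
find_orfs <- function(contig, min_aa_length = 25, require_start = FALSE,
                      contig_id = NULL) {
  if (is.list(contig) && !is.null(contig$sequence)) {
    if (is.null(contig_id) && !is.null(contig$id)) contig_id <- contig$id
    contig <- contig$sequence
  }
  stopifnot(is.character(contig), length(contig) == 1L)
  if (min_aa_length < 1L) stop("min_aa_length must be >= 1")
  s <- toupper(contig)
  if (nchar(s) == 0L) stop("empty sequence")
  if (is.null(contig_id)) contig_id <- NA_character_
  n <- nchar(s)

  fwd <- scan_orfs_one_strand(s, min_aa_length, require_start)
  rev <- scan_orfs_one_strand(revcomp(s), min_aa_length, require_start)

  rows <- list()
  for (o in fwd)
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = contig_id, frame = o[["frame"]],
      start = o[["start"]], end = o[["end"]], aa_length = o[["aa"]],
      stringsAsFactors = FALSE)
  for (o in rev)
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = contig_id, frame = -o[["frame"]],
      start = n - o[["end"]], end = n - o[["start"]], aa_length = o[["aa"]],
      stringsAsFactors = FALSE)
  if (length(rows) == 0L)
    return(data.frame(contig_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa_length = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$aa_length, out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a 12-column tabular homology hit table
#'
#' Parses the standard 12-column tabular output of homology search tools
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), as consumed by the triage cascade.
#'
#' @param path TSV path (no header).
#' @return data.frame with the 12 standard columns plus aliases
#'   `query_id`, `subject_id`, `aln_start`, `aln_end`.
#' @export
read_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  no_lines <- length(readLines(path, n = 1L)) == 0L
  raw <- if (no_lines) {
    data.frame()
  } else {
    tryCatch(
      utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("hit table parse error in ", path, ": ",
                               conditionMessage(e)))
  }
  if (nrow(raw) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12), cols))
  } else {
    if (ncol(raw) != 12L)
      stop("hit table parse error in ", path, ": expected 12 columns, got ",
           ncol(raw))
    out <- stats::setNames(raw, cols)
  }
  for (nm in c("pident", "evalue", "bitscore")) {
    out[[nm]] <- suppressWarnings(as.numeric(out[[nm]]))
    if (anyNA(out[[nm]]))
      stop("hit table parse error in ", path, ": non-numeric ", nm)
  }
  if (any(out$evalue < 0)) stop("hit table integrity error: negative e-value")
  out$query_id <- as.character(out$qseqid)
  out$subject_id <- as.character(out$sseqid)
  out$aln_start <- as.integer(out$qstart)
  out$aln_end <- as.integer(out$qend)
  out
}

# Normalise a hit table (file path or data.frame) to query_id + evalue.
as_hit_frame <- function(hits, what) {
  if (is.null(hits))
    return(data.frame(query_id = character(0), evalue = numeric(0)))
  if (is.character(hits) && length(hits) == 1L) hits <- read_hits(hits)
  if (!is.data.frame(hits)) stop(what, " hits must be a path or data.frame")
  if (!"query_id" %in% names(hits) && "qseqid" %in% names(hits))
    hits$query_id <- hits$qseqid
  if (!all(c("query_id", "evalue") %in% names(hits)))
    stop(what, " hits need columns query_id (or qseqid) and evalue")
  hits
}

#' Triage contigs through the viral-candidate filter cascade
#'
#' A contig is kept iff it (1) has at least one viral homology hit with
#' e-value <= `viral_evalue_max`, (2) is at least `min_length` nt long,
#' (3) has no host-genome hit with e-value <= `host_evalue_max`, and
#' (4) contains at least one qualifying ORF.  Filters are evaluated in
#' that fixed order and every discarded contig records all reasons that
#' apply.  Contigs absent from both hit tables fail the first filter.
#'
#' @param contigs Contig sequences: FASTA path, `DNAStringSet`, named
#'   character vector, or data.frame(id, sequence).
#' @param viral_hits,host_hits Hit tables ([read_hits()] paths or
#'   data.frames); every `query_id` must name a contig.
#' @param params See [triage_params()].
#' @param depths Optional named list of per-position depth vectors; when a
#'   contig has one, the terminal-coverage check is applied as a fifth
#'   filter.
#' @return A `contig_verdicts` data.frame with `contig_id`, `kept`,
#'   `reasons` (list column), `passed_filters` (list column), `length`,
#'   `best_viral_evalue`, `best_host_evalue`.
#' @export
triage_contigs <- function(contigs, viral_hits = NULL, host_hits = NULL,
                           params = triage_params(), depths = NULL) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- read_fasta_frame(contigs)
  ctg <- as_seq_frame(contigs, "contigs")
  if (anyDuplicated(ctg$id)) stop("duplicate contig id(s)")
  vh <- as_hit_frame(viral_hits, "viral")
  hh <- as_hit_frame(host_hits, "host")
  unknown <- setdiff(unique(c(vh$query_id, hh$query_id)), ctg$id)
  if (length(unknown) > 0L)
    stop("referential error: hit(s) reference unknown contig id(s): ",
         paste(unknown, collapse = ", "))

  n <- nrow(ctg)
  lens <- nchar(ctg$sequence)
  best_v <- rep(NA_real_, n)
  best_h <- rep(NA_real_, n)
  if (nrow(vh) > 0L) {
    bv <- tapply(vh$evalue, vh$query_id, min)
    best_v[match(names(bv), ctg$id)] <- as.numeric(bv)
  }
  if (nrow(hh) > 0L) {
    bh <- tapply(hh$evalue, hh$query_id, min)
    best_h[match(names(bh), ctg$id)] <- as.numeric(bh)
  }

  verdicts <- vector("list", n)
  for (i in seq_len(n)) {
    reasons <- character(0)
    passed <- character(0)
    if (!is.na(best_v[i]) && best_v[i] <= params$viral_evalue_max)
      passed <- c(passed, "viral_hit") else reasons <- c(reasons, "no_viral_hit")
    if (lens[i] >= params$min_length)
      passed <- c(passed, "length") else reasons <- c(reasons, "too_short")
    if (is.na(best_h[i]) || best_h[i] > params$host_evalue_max)
      passed <- c(passed, "host") else reasons <- c(reasons, "host_genome")
    orfs <- find_orfs(ctg$sequence[i], min_aa_length = params$min_orf_aa,
                      require_start = params$require_start)
    if (nrow(orfs) > 0L)
      passed <- c(passed, "orf") else reasons <- c(reasons, "no_orf")
    if (!is.null(depths) && !is.null(depths[[ctg$id[i]]])) {
      tc <- terminal_coverage_check(depths[[ctg$id[i]]],
                                    end_window = params$end_window,
                                    min_ratio = params$min_ratio)
      if (tc$pass)
        passed <- c(passed, "terminal_coverage")
      else reasons <- c(reasons, "low_terminal_coverage")
    }
    verdicts[[i]] <- list(reasons = reasons, passed = passed)
  }

  out <- data.frame(contig_id = ctg$id,
                    kept = vapply(verdicts, function(v) length(v$reasons) == 0L,
                                  logical(1)),
                    length = lens,
                    best_viral_evalue = best_v,
                    best_host_evalue = best_h,
                    stringsAsFactors = FALSE)
  out$reasons <- lapply(verdicts, `[[`, "reasons")
  out$passed_filters <- lapply(verdicts, `[[`, "passed")
  class(out) <- c("contig_verdicts", "data.frame")
  out
}

#' Terminal-coverage confirmation check
#'
#' Confirms a putative full-length viral genome by requiring the mean read
#' depth in both terminal windows to reach at least `min_ratio` times the
#' global mean depth (the 5' and 3' ends of a complete genome should be
#' covered, not trailing off into unassembled sequence).
#'
#' @param depth Integer/numeric per-position depth vector.
#' @param end_window Window size in nt (depth must be >= 2 windows long).
#' @param min_ratio Minimum terminal/global mean ratio.
#' @return List: `pass` (logical), `five_prime_mean`, `three_prime_mean`,
#'   `global_mean`, `ratio_5p`, `ratio_3p`, `zero_coverage`.
#' @export
terminal_coverage_check <- function(depth, end_window = 50, min_ratio = 0.2) {
  depth <- as.numeric(depth)
  if (length(depth) < 2 * end_window)
    stop("depth vector shorter than two terminal windows")
  g <- mean(depth)
  m5 <- mean(depth[seq_len(end_window)])
  m3 <- mean(depth[seq.int(length(depth) - end_window + 1L, length(depth))])
  if (g == 0)
    return(list(pass = FALSE, five_prime_mean = m5, three_prime_mean = m3,
                global_mean = 0, ratio_5p = NA_real_, ratio_3p = NA_real_,
                zero_coverage = TRUE))
  list(pass = (m5 >= min_ratio * g) && (m3 >= min_ratio * g),
       five_prime_mean = m5, three_prime_mean = m3, global_mean = g,
       ratio_5p = m5 / g, ratio_3p = m3 / g, zero_coverage = FALSE)
}

#' Write triage verdicts to TSV
#'
#' @param verdicts A `contig_verdicts` data.frame.
#' @param path Output TSV path; reasons are comma-joined.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  df <- data.frame(contig_id = verdicts$contig_id,
                   kept = verdicts$kept,
                   reasons = vapply(verdicts$reasons, paste,
                                    character(1), collapse = ","),
                   length = verdicts$length,
                   best_viral_evalue = verdicts$best_viral_evalue,
                   best_host_evalue = verdicts$best_host_evalue,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
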