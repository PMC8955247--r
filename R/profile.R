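# Per-virus viral small-RNA (vsRNA) profiles over collapsed reads:
# unique-read percentage, length-by-strand histogram, 5' base
# composition, per-strand coverage, and coverage uniformity.

PROFILE_LENGTHS <- 18:32
RNA_BASES <- c("U", "A", "C", "G")

#' Collapse reads to unique sequences
#'
#' @param reads Character vector of read sequences, or a data.frame with a
#'   `sequence` column.
#' @return data.frame `sequence`, `copy_count`, ordered by decreasing
#'   count then sequence; copy counts sum to the input read count.
#' @export
collapse_reads <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  if (length(seqs) == 0L)
    return(data.frame(sequence = character(0), copy_count = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), copy_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$copy_count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Profile the vsRNAs of one virus
#'
#' Computes the per-virus profile from the unique reads mapping to one
#' viral genome: percentage of the library's unique reads, the unique-read
#' count per (length, strand) cell over 18-32 nt, the 5' nucleotide of
#' each read as sequenced (a minus-strand read's first base is reported in
#' its own reverse-complement orientation; T is reported as U), per-strand
#' coverage depth, and coverage breadth (fraction of genome positions with
#' depth >= 1 on either strand) as the uniformity statistic, with the
#' coefficient of variation of depth as an alternative.
#'
#' @param mapped Mapping data.frame (one virus) from [map_reads()].
#' @param genome_length Genome length in nt.
#' @param n_unique_library Number of unique reads in the whole cleaned
#'   library (denominator of the percentage).
#' @param virus_abbrev,sample_id Labels carried into the profile.
#' @param n_reads_library Optional raw read count for the diagnostic
#'   raw-count percentage.
#' @return A `vsrna_profile` object.
#' @export
profile_virus <- function(mapped, genome_length, n_unique_library,
                          virus_abbrev = NULL, sample_id = NA_character_,
                          n_reads_library = NA_real_) {
  if (nrow(mapped) > 0L) {
    vs <- unique(mapped$virus_abbrev)
    if (length(vs) > 1L)
      stop("profile_virus expects mappings of a single virus, got: ",
           paste(vs, collapse = ", "))
    if (is.null(virus_abbrev)) virus_abbrev <- vs
  }
  if (is.null(virus_abbrev)) virus_abbrev <- NA_character_
  n_unique_mapped <- nrow(mapped)
  if (n_unique_library < n_unique_mapped)
    stop("n_unique_library (", n_unique_library,
         ") smaller than unique mapped reads (", n_unique_mapped, ")")

  L <- nchar(mapped$read_sequence)
  if (n_unique_mapped > 0L && any(mapped$position + L > genome_length))
    stop("integrity error: mapping span exceeds genome length")

  len_f <- factor(L, levels = PROFILE_LENGTHS)
  strand_f <- factor(mapped$strand, levels = c("+", "-"))
  length_hist <- table(length = len_f, strand = strand_f)

  first <- substr(mapped$read_sequence, 1L, 1L)
  first <- chartr("T", "U", first)
  first_f <- factor(first, levels = RNA_BASES)
  first_base_comp <- table(length = len_f, strand = strand_f, base = first_f)

  # interval-stab coverage: +1 at read starts, -1 past read ends, cumsum
  strand_coverage <- function(sel) {
    if (!any(sel)) return(integer(genome_length))
    starts <- mapped$position[sel] + 1L
    ends <- mapped$position[sel] + L[sel]
    inc <- tabulate(starts, nbins = genome_length)
    dec <- tabulate(ends[ends < genome_length] + 1L,
                    nbins = genome_length)
    cumsum(inc - dec)
  }
  cov_plus <- strand_coverage(mapped$strand == "+")
  cov_minus <- strand_coverage(mapped$strand == "-")
  total <- cov_plus + cov_minus
  breadth <- if (genome_length > 0L) mean(total >= 1L) else 0
  cv <- if (mean(total) > 0) stats::sd(total) / mean(total) else NA_real_

  pct <- if (n_unique_library > 0L)
    100 * n_unique_mapped / n_unique_library else 0
  pct_raw <- if (!is.na(n_reads_library) && n_reads_library > 0)
    100 * sum(mapped$copy_count) / n_reads_library else NA_real_

  out <- list(virus_abbrev = virus_abbrev, sample_id = sample_id,
              n_unique_mapped = n_unique_mapped,
              n_unique_library = n_unique_library,
              pct_unique_mapped = pct,
              pct_raw_mapped = pct_raw,
              length_hist = length_hist,
              first_base_comp = first_base_comp,
              coverage = list(plus = cov_plus, minus = cov_minus),
              uniformity = breadth,
              coverage_cv = cv,
              genome_length = genome_length)
  class(out) <- "vsrna_profile"
  out
}

#' @export
print.vsrna_profile <- function(x, ...) {
  cat("vsRNA profile: ", x$virus_abbrev,
      if (!is.na(x$sample_id)) paste0(" (sample ", x$sample_id, ")"), "\n",
      sep = "")
  cat(sprintf("  unique reads mapped: %d / %d (%.2f%%)\n",
              x$n_unique_mapped, x$n_unique_library, x$pct_unique_mapped))
  cat(sprintf("  coverage breadth: %.3f\n", x$uniformity))
  invisible(x)
}

# Long-format data.frame of the (length, strand, first base) counts.
profile_hist_frame <- function(profile) {
  df <- as.data.frame(profile$first_base_comp, stringsAsFactors = FALSE)
  names(df) <- c("length", "strand", "first_base", "count")
  df$length <- as.integer(as.character(df$length))
  df$virus_abbrev <- profile$virus_abbrev
  df$sample_id <- profile$sample_id
  df[, c("virus_abbrev", "sample_id", "length", "strand", "first_base",
         "count")]
}

#' Write profile outputs to TSV
#'
#' Emits three plain-text tables for a list of profiles: a per-virus
#' summary, the length/strand/5'-base histogram, and bedgraph-style
#' per-position coverage (1-based positions, zero-depth rows omitted).
#'
#' @param profiles List of `vsrna_profile` objects.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(virus_abbrev = p$virus_abbrev, sample_id = p$sample_id,
               n_unique_mapped = p$n_unique_mapped,
               n_unique_library = p$n_unique_library,
               pct_unique_mapped = p$pct_unique_mapped,
               pct_raw_mapped = p$pct_raw_mapped,
               coverage_breadth = p$uniformity,
               coverage_cv = p$coverage_cv,
               stringsAsFactors = FALSE)))
  hist_df <- do.call(rbind, lapply(profiles, profile_hist_frame))
  cov_df <- do.call(rbind, lapply(profiles, function(p) {
    rows <- list()
    for (strand in c("plus", "minus")) {
      depth <- p$coverage[[strand]]
      nz <- which(depth > 0L)
      if (length(nz) > 0L)
        rows[[strand]] <- data.frame(
          virus_abbrev = p$virus_abbrev,
          pos = nz, strand = if (strand == "plus") "+" else "-",
          depth = depth[nz], stringsAsFactors = FALSE)
    }
    if (length(rows) > 0L) do.call(rbind, rows) else NULL
  }))
  paths <- c(summary = file.path(dir, "profiles.tsv"),
             histogram = file.path(dir, "histograms.tsv"),
             coverage = file.path(dir, "coverage.tsv"))
  write_tsv(summary_df, paths[["summary"]])
  write_tsv(hist_df, paths[["histogram"]])
  if (is.null(cov_df))
    cov_df <- data.frame(virus_abbrev = character(0), pos = integer(0),
                         strand = character(0), depth = integer(0))
  write_tsv(cov_df, paths[["coverage"]])
  invisible(paths)
}
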