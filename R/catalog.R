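# Catalogue of the 13 RNA viruses described for the medfly (Ceratitis
# capitata): 16 genome/segment records with type, family, length and
# accession.  Other modules key on the abbreviations used here.

CATALOG_COLUMNS <- c("virus_name", "abbreviation", "genome_type", "family",
                     "segment_label", "genome_length", "accession")

GENOME_TYPES <- c("positive_ssRNA", "negative_ssRNA", "dsRNA")

#' Path to the packaged medfly virus catalogue
#'
#' Returns the installed location of the tab-separated catalogue of the 13
#' medfly RNA viruses (16 genome/segment records).
#'
#' @return File path of the packaged catalogue TSV.
#' @export
medfly_catalog_path <- function() {
  system.file("extdata", "medfly_virus_catalog.tsv",
              package = "medflyvirome", mustWork = TRUE)
}

#' Load a virus catalogue
#'
#' Reads a catalogue TSV (one row per genome or genome segment) and
#' optionally cross-checks record lengths against a FASTA of genome
#' sequences whose headers carry the accessions.
#'
#' @param metadata_table Path to a tab-separated catalogue with columns
#'   `virus_name`, `abbreviation`, `genome_type`, `family`,
#'   `segment_label`, `genome_length`, `accession`.  Defaults to the
#'   packaged medfly catalogue.
#' @param genomes Optional FASTA path; every record's accession must be
#'   present and the sequence length must equal `genome_length`.
#' @return A `virus_catalog` data.frame, one row per record.  When
#'   `genomes` is given the sequences are attached as the `"sequences"`
#'   attribute (a named character vector keyed by accession).
#' @export
#' @examples
#' cat <- load_catalog()
#' nrow(cat)                       # 16 records
#' length(unique(cat$virus_name))  # 13 viruses
load_catalog <- function(metadata_table = medfly_catalog_path(),
                         genomes = NULL) {
  raw <- utils::read.delim(metadata_table, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(CATALOG_COLUMNS, names(raw))
  if (length(missing) > 0L)
    stop("catalogue schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  cat <- raw[, CATALOG_COLUMNS]
  cat$genome_length <- as.integer(cat$genome_length)
  if (nrow(cat) > 0L) {
    if (anyNA(cat$genome_length) || any(cat$genome_length <= 0L))
      stop("catalogue integrity error: genome_length must be a positive integer")
    bad <- setdiff(unique(cat$genome_type), GENOME_TYPES)
    if (length(bad) > 0L)
      stop("catalogue integrity error: unknown genome_type ",
           paste(bad, collapse = ", "))
    if (anyDuplicated(cat$abbreviation))
      stop("catalogue integrity error: duplicated abbreviation(s) ",
           paste(unique(cat$abbreviation[duplicated(cat$abbreviation)]),
                 collapse = ", "))
    # multi-segment viruses must not reuse a segment label
    key <- paste(cat$virus_name, cat$segment_label)
    if (anyDuplicated(key))
      stop("catalogue integrity error: duplicated (virus, segment) pair")
  }
  if (!is.null(genomes)) {
    seqs <- read_fasta_frame(genomes)
    idx <- match(cat$accession, seqs$id)
    if (anyNA(idx))
      stop("catalogue integrity error: accession(s) absent from FASTA: ",
           paste(cat$accession[is.na(idx)], collapse = ", "))
    fa_len <- nchar(seqs$sequence[idx])
    mism <- which(fa_len != cat$genome_length)
    if (length(mism) > 0L)
      stop("catalogue integrity error: FASTA/length mismatch for ",
           cat$accession[mism[1L]], ": table says ",
           cat$genome_length[mism[1L]], " nt, FASTA has ",
           fa_len[mism[1L]], " nt")
    sq <- seqs$sequence[idx]
    names(sq) <- cat$accession
    attr(cat, "sequences") <- sq
  }
  class(cat) <- c("virus_catalog", "data.frame")
  cat
}

#' Write a virus catalogue to TSV
#'
#' Inverse of [load_catalog()]: round-trips field-for-field.
#'
#' @param catalog A `virus_catalog` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv(as.data.frame(catalog)[, CATALOG_COLUMNS], path)
}

#' Summarise a virus catalogue
#'
#' Counts viruses and records, tallies genome types per virus (a
#' multi-segment virus counts once), and finds the genome-length extrema.
#' Segmented genomes are compared by their summed segment lengths, so the
#' "smallest virus" is the one with the smallest complete genome -- for the
#' medfly catalogue the 2896-nt narnavirus CcaNaV1, even though one
#' nodavirus segment is shorter on its own.
#'
#' @param records A `virus_catalog` data.frame from [load_catalog()].
#' @return A `catalog_summary` list with elements `n_viruses`, `n_records`,
#'   `counts_by_genome_type`, `min_genome_length`, `max_genome_length`,
#'   `smallest_virus`.
#' @export
#' @examples
#' summarize_catalog(load_catalog())
summarize_catalog <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("empty catalogue: nothing to summarise")
  per_virus <- tapply(records$genome_length, records$virus_name, sum)
  type_per_virus <- tapply(records$genome_type, records$virus_name,
                           function(x) {
                             u <- unique(x)
                             if (length(u) != 1L)
                               stop("catalogue integrity error: virus with mixed genome_type")
                             u
                           })
  counts <- table(factor(unlist(type_per_virus), levels = GENOME_TYPES))
  smallest_name <- names(per_virus)[which.min(per_virus)]
  rows <- records[records$virus_name == smallest_name, , drop = FALSE]
  smallest_abbrev <- if (nrow(rows) == 1L) rows$abbreviation[1L] else smallest_name
  out <- list(
    n_viruses = length(per_virus),
    n_records = nrow(records),
    counts_by_genome_type = stats::setNames(as.integer(counts), names(counts)),
    min_genome_length = as.integer(min(per_virus)),
    max_genome_length = as.integer(max(per_virus)),
    smallest_virus = smallest_abbrev
  )
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("Virus catalogue summary\n")
  cat("  viruses: ", x$n_viruses, "  records: ", x$n_records, "\n", sep = "")
  cat("  genome types (per virus): ",
      paste(names(x$counts_by_genome_type), x$counts_by_genome_type,
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  genome length range: ", x$min_genome_length, "-",
      x$max_genome_length, " nt (smallest: ", x$smallest_virus, ")\n",
      sep = "")
  invisible(x)
}

#' Deterministic placeholder genomes for a catalogue
#'
#' Generates synthetic pseudo-random sequences of exactly the catalogued
#' lengths (fixed seed, one sub-seed per accession) so that length checks
#' and the read matcher can be exercised without real sequence data.  The
#' sequences are synthetic stand-ins, not the deposited genomes.
#'
#' @param catalog A `virus_catalog` data.frame.
#' @param seed Master seed (default 101).
#' @return Named character vector of sequences keyed by accession.
#' @export
catalog_placeholder_genomes <- function(catalog = load_catalog(), seed = 101) {
  seqs <- vapply(seq_len(nrow(catalog)), function(i) {
    simulate_genome(catalog$genome_length[i], gc = 0.5,
                    seed = derive_seed(seed, i))
  }, character(1))
  names(seqs) <- catalog$accession
  seqs
}
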