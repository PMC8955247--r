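# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over the DNA alphabet (IUPAC codes are
#' handled by Biostrings; `N` maps to `N`).
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ATGAAATAA")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings; NA-free, byte-wise.
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# Run code with a private RNG state so no global seed leaks in or out.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a sub-seed from a master seed; keeps the result a valid 32-bit int.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483629)
}

# Write a data.frame as a plain TSV (no quoting, no row names).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}

# Normalise sequence input (character vector, DNAStringSet, or data.frame
# with id/sequence columns) to a data.frame(id, sequence).
as_seq_frame <- function(x, what = "sequences") {
  if (inherits(x, "DNAStringSet")) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(data.frame(id = sub("\\s.*$", "", ids),
                      sequence = as.character(x),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) {
    if (!all(c("id", "sequence") %in% names(x)))
      stop(what, " data.frame must have columns 'id' and 'sequence'")
    return(data.frame(id = as.character(x$id),
                      sequence = toupper(as.character(x$sequence)),
                      stringsAsFactors = FALSE))
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(data.frame(id = ids, sequence = toupper(unname(x)),
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret ", what, " of class ", paste(class(x), collapse = "/"))
}

# Read a FASTA file into a data.frame(id, sequence); ids are the first
# whitespace-delimited token of each header.
read_fasta_frame <- function(path) {
  as_seq_frame(Biostrings::readDNAStringSet(path))
}

write_fasta <- function(seqs, path) {
  df <- as_seq_frame(seqs)
  set <- Biostrings::DNAStringSet(df$sequence)
  names(set) <- df$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
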