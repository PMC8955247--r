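# Rule-based signature classification of vsRNA profiles into siRNA,
# piRNA, degradation, or absent.  The source signatures are qualitative
# ("distinctive 21-nt peak, both strands"; 24-29 nt with 5'-U bias), so
# every threshold is declared, configurable, and echoed with each call.

#' Signature classification thresholds
#'
#' @param min_reads Minimum unique mapped reads to call anything but
#'   absent (default 50).
#' @param peak_center,peak_halfwidth The siRNA length peak window
#'   (default 21 +/- 1 nt).
#' @param min_peak_fraction Minimum fraction of unique reads inside the
#'   peak window for an siRNA call (default 0.4).
#' @param min_minor_strand Minimum minor-strand fraction for an siRNA call
#'   (default 0.1) -- bidirectional mapping is the hallmark of Dicer
#'   products from dsRNA replication intermediates.
#' @param min_u_bias Minimum fraction of 24-29 nt reads with a 5' U for a
#'   piRNA call (default 0.5).
#' @param min_breadth Reported minimum coverage breadth (diagnostic; not
#'   used by the decision rule).
#' @param pirna_min,pirna_max piRNA length window (default 24-29 nt).
#' @return List of thresholds.
#' @export
signature_thresholds <- function(min_reads = 50, peak_center = 21,
                                 peak_halfwidth = 1, min_peak_fraction = 0.4,
                                 min_minor_strand = 0.1, min_u_bias = 0.5,
                                 min_breadth = 0.5, pirna_min = 24,
                                 pirna_max = 29) {
  list(min_reads = min_reads, peak_center = peak_center,
       peak_halfwidth = peak_halfwidth,
       min_peak_fraction = min_peak_fraction,
       min_minor_strand = min_minor_strand, min_u_bias = min_u_bias,
       min_breadth = min_breadth, pirna_min = pirna_min,
       pirna_max = pirna_max)
}

#' Classify a vsRNA profile
#'
#' Applies the decision rule, in order: (1) fewer than `min_reads` unique
#' mapped reads -> `absent`; (2) at least `min_peak_fraction` of reads at
#' `peak_center +/- peak_halfwidth` nt AND minor-strand fraction at least
#' `min_minor_strand` -> `siRNA`; (3) modal length within the piRNA window
#' AND 5'-U fraction of window reads at least `min_u_bias` -> `piRNA`;
#' (4) otherwise `degradation`.  A one-sided 21-nt profile therefore falls
#' through to `degradation` (or `absent` when shallow), mirroring the
#' nodavirus control-strain edge case; a flat length distribution is the
#' nora-virus-type degradation signal.
#'
#' @param profile A `vsrna_profile`.
#' @param thresholds See [signature_thresholds()].
#' @return A `signature_call` list: `virus_abbrev`, `sample_id`, `label`,
#'   `peak_length`, `peak_fraction`, `minor_strand_fraction`, `u_bias`,
#'   `breadth`, `n_unique_mapped`, `thresholds`.
#' @export
classify_profile <- function(profile, thresholds = signature_thresholds()) {
  if (!inherits(profile, "vsrna_profile"))
    stop("integrity error: not a vsrna_profile")
  h <- profile$length_hist
  n <- sum(h)
  if (n != profile$n_unique_mapped)
    stop("integrity error: histogram total != n_unique_mapped")
  lens <- as.integer(rownames(h))

  by_len <- rowSums(h)
  n_plus <- sum(h[, "+"])
  n_minus <- sum(h[, "-"])
  minor <- if (n > 0) min(n_plus, n_minus) / n else 0
  peak_win <- lens >= thresholds$peak_center - thresholds$peak_halfwidth &
    lens <= thresholds$peak_center + thresholds$peak_halfwidth
  peak_fraction <- if (n > 0) sum(by_len[peak_win]) / n else 0
  modal <- if (n > 0) lens[which.max(by_len)] else NA_integer_  # ties -> smaller
  pi_win <- lens >= thresholds$pirna_min & lens <= thresholds$pirna_max
  n_pi <- sum(by_len[pi_win])
  u_pi <- sum(profile$first_base_comp[pi_win, , "U"])
  u_bias <- if (n_pi > 0) u_pi / n_pi else 0

  label <- if (n < thresholds$min_reads) {
    "absent"
  } else if (peak_fraction >= thresholds$min_peak_fraction &&
             minor >= thresholds$min_minor_strand) {
    "siRNA"
  } else if (!is.na(modal) && modal >= thresholds$pirna_min &&
             modal <= thresholds$pirna_max &&
             u_bias >= thresholds$min_u_bias) {
    "piRNA"
  } else {
    "degradation"
  }

  out <- list(virus_abbrev = profile$virus_abbrev,
              sample_id = profile$sample_id,
              label = label,
              peak_length = modal,
              peak_fraction = peak_fraction,
              minor_strand_fraction = minor,
              u_bias = u_bias,
              breadth = profile$uniformity,
              n_unique_mapped = n,
              thresholds = thresholds)
  class(out) <- "signature_call"
  out
}

#' @export
print.signature_call <- function(x, ...) {
  cat(sprintf("signature call: %s [%s]\n", x$virus_abbrev, x$label))
  cat(sprintf("  n=%d peak=%s peak_frac=%.2f minor_strand=%.2f u_bias=%.2f breadth=%.2f\n",
              x$n_unique_mapped, x$peak_length, x$peak_fraction,
              x$minor_strand_fraction, x$u_bias, x$breadth))
  invisible(x)
}

#' Signature calls as a data.frame
#'
#' @param calls List of `signature_call` objects.
#' @return data.frame, one row per call, thresholds echoed as columns.
#' @export
calls_table <- function(calls) {
  do.call(rbind, lapply(calls, function(x) {
    th <- x$thresholds
    data.frame(virus_abbrev = x$virus_abbrev, sample_id = x$sample_id,
               label = x$label, peak_length = x$peak_length,
               peak_fraction = x$peak_fraction,
               minor_strand_fraction = x$minor_strand_fraction,
               u_bias = x$u_bias, breadth = x$breadth,
               n_unique_mapped = x$n_unique_mapped,
               min_reads = th$min_reads,
               min_peak_fraction = th$min_peak_fraction,
               min_minor_strand = th$min_minor_strand,
               min_u_bias = th$min_u_bias,
               stringsAsFactors = FALSE)
  }))
}

#' Class-recovery power curve of the signature classifier
#'
#' Simulates pure-class small-RNA libraries over a synthetic genome at a
#' grid of read depths and scores how often the classifier recovers the
#' generating class ("absent" is generated as a 100% non-viral library).
#'
#' @param generator_params List: `genome_length` (default 10000), `gc`
#'   (0.5), plus any [srna_library_spec()] override.
#' @param n_grid Integer vector of library sizes.
#' @param reps Simulations per (class, depth).
#' @param seed Master seed; sub-seeds are derived deterministically.
#' @param classes Classes to simulate.
#' @param thresholds See [signature_thresholds()].
#' @return data.frame `class`, `n_reads`, `recovery` (fraction of reps in
#'   which the call matched the generating class).
#' @export
signature_power_curve <- function(generator_params = list(),
                                  n_grid = c(100, 1000, 5000),
                                  reps = 5, seed = 1,
                                  classes = c("siRNA", "piRNA",
                                              "degradation", "absent"),
                                  thresholds = signature_thresholds()) {
  stopifnot(reps >= 1)
  gp <- utils::modifyList(list(genome_length = 10000, gc = 0.5),
                          generator_params)
  genome <- simulate_genome(gp$genome_length, gc = gp$gc,
                            seed = derive_seed(seed, 0))
  index <- build_index(c(virus = genome))
  grid <- expand.grid(class = classes, n_reads = n_grid,
                      stringsAsFactors = FALSE)
  grid$recovery <- NA_real_
  counter <- 0L
  for (g in seq_len(nrow(grid))) {
    cls <- grid$class[g]
    nr <- grid$n_reads[g]
    hit <- 0L
    for (r in seq_len(reps)) {
      counter <- counter + 1L
      mix <- c(siRNA = 0, piRNA = 0, degradation = 0, nonviral = 0)
      mix[[if (cls == "absent") "nonviral" else cls]] <- 1
      spec <- srna_library_spec(genome = genome, class_mix = mix,
                                n_reads = nr,
                                seed = derive_seed(seed, counter))
      lib <- simulate_srna_library(spec)
      mp <- map_reads(lib$reads$sequence, index)
      prof <- profile_virus(mp$mapped, nchar(genome),
                            n_unique_library = mp$stats$n_unique,
                            virus_abbrev = "virus")
      call <- classify_profile(prof, thresholds)
      if (call$label == cls) hit <- hit + 1L
    }
    grid$recovery[g] <- hit / reps
  }
  grid
}
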