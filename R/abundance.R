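# Viral abundance quantification: qPCR relative abundance against the
# endogenous L23a reference (E^-Ct(virus) / E^-Ct(L23a)), absolute
# genomes-per-microgram via a standard curve, and read-count relative
# abundance against L23a counts.

abundance_estimate <- function(sample_id, virus, mode, value, reference,
                               no_amplification = FALSE) {
  stopifnot(value >= 0)
  out <- data.frame(sample_id = sample_id, virus = virus, mode = mode,
                    value = value,
                    log_value = ifelse(value > 0, log10(value), -Inf),
                    reference = reference,
                    no_amplification = no_amplification,
                    stringsAsFactors = FALSE)
  class(out) <- c("abundance_estimate", "data.frame")
  out
}

check_efficiency <- function(E, what) {
  if (any(is.na(E)) || any(E <= 1) || any(E > 2.2))
    stop("parameter error: ", what, " amplification factor must be in (1, 2.2]")
  E
}

#' qPCR relative abundance against a reference gene
#'
#' Computes `E_virus^(-Ct_virus) / E_ref^(-Ct_ref)` in the log domain.
#' With both assays at perfect efficiency (E = 2) this is `2^(Ct_ref -
#' Ct_virus)`.  A missing virus Ct (`NA`, no amplification) yields
#' abundance 0 with the `no_amplification` flag set.
#'
#' @param virus_ct Virus Ct in cycles (> 0), or `NA` for no amplification.
#' @param ref_ct Reference (L23a) Ct in cycles (> 0).
#' @param E_virus,E_ref Amplification factors in (1, 2.2]; 2 = 100%
#'   primer efficiency.
#' @param sample_id,virus,reference Labels carried into the estimate.
#' @return One-row `abundance_estimate` data.frame (mode
#'   `qpcr_relative`).
#' @export
#' @examples
#' relative_abundance_qpcr(17, 20)$value  # 2^3 = 8
relative_abundance_qpcr <- function(virus_ct, ref_ct, E_virus = 2,
                                    E_ref = 2, sample_id = NA_character_,
                                    virus = NA_character_,
                                    reference = "L23a") {
  check_efficiency(E_virus, "virus")
  check_efficiency(E_ref, "reference")
  if (is.na(ref_ct) || ref_ct <= 0)
    stop("parameter error: reference Ct must be positive")
  if (is.na(virus_ct))
    return(abundance_estimate(sample_id, virus, "qpcr_relative", 0,
                              reference, no_amplification = TRUE))
  if (virus_ct <= 0) stop("parameter error: virus Ct must be positive")
  value <- exp(log(E_ref) * ref_ct - log(E_virus) * virus_ct)
  abundance_estimate(sample_id, virus, "qpcr_relative", value, reference)
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct against log10(copies) over a dilution series.
#' The implied amplification factor is `10^(-1/slope)`; a perfect two-fold
#' assay gives slope -log2(10) = -3.3219 cycles per decade.
#'
#' @param copies Known template copy numbers (> 0), at least 3 points.
#' @param cts Measured Ct values (same length).
#' @param target Label of the assay target.
#' @return A `standard_curve` list: `target`, `slope`, `intercept`,
#'   `r_squared`, `implied_efficiency`, `valid`.
#' @export
fit_standard_curve <- function(copies, cts, target = NA_character_) {
  if (length(copies) != length(cts))
    stop("copies and cts must have equal length")
  if (length(copies) < 3L)
    stop("insufficient data: a standard curve needs >= 3 dilution points")
  if (any(copies <= 0)) stop("copies must be strictly positive")
  x <- log10(copies)
  fit <- stats::lm(cts ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- if (stats::var(cts) > 0)
    suppressWarnings(summary(fit)$r.squared) else 1
  valid <- is.finite(slope) && slope < 0
  if (!valid)
    warning("standard curve has non-negative slope; marked invalid")
  out <- list(target = target, slope = slope, intercept = intercept,
              r_squared = r2,
              implied_efficiency = if (valid) 10^(-1 / slope) else NA_real_,
              valid = valid)
  class(out) <- "standard_curve"
  out
}

#' Construct an ideal standard curve
#'
#' Analytic curve for a given amplification factor, useful for simulation:
#' slope = -1/log10(E), so E = 2 gives -3.3219 cycles per decade.
#'
#' @param E Amplification factor in (1, 2.2].
#' @param intercept Ct at one template copy (default 40 cycles).
#' @param target Assay label.
#' @return A `standard_curve` list.
#' @export
ideal_standard_curve <- function(E = 2, intercept = 40,
                                 target = NA_character_) {
  check_efficiency(E, "assay")
  slope <- -1 / log10(E)
  out <- list(target = target, slope = slope, intercept = intercept,
              r_squared = 1, implied_efficiency = E, valid = TRUE)
  class(out) <- "standard_curve"
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve (%s): Ct = %.4f + %.4f * log10(copies), E = %.4f, R2 = %.4f%s\n",
              x$target, x$intercept, x$slope, x$implied_efficiency,
              x$r_squared, if (!x$valid) " [INVALID]" else ""))
  invisible(x)
}

#' Absolute abundance in genome copies per microgram of RNA
#'
#' Inverts a standard curve: `copies = 10^((ct - intercept)/slope)`,
#' scaled by the RNA input mass.
#'
#' @param ct Measured Ct.
#' @param curve A valid `standard_curve`.
#' @param rna_input_ug RNA input of the reaction in micrograms.
#' @param sample_id,virus Labels.
#' @return One-row `abundance_estimate` data.frame (mode `copies_per_ug`).
#' @export
copies_per_ug <- function(ct, curve, rna_input_ug = 1,
                          sample_id = NA_character_,
                          virus = NA_character_) {
  if (!inherits(curve, "standard_curve") || !isTRUE(curve$valid))
    stop("invalid standard curve")
  if (rna_input_ug <= 0) stop("rna_input_ug must be positive")
  copies <- 10^((ct - curve$intercept) / curve$slope) / rna_input_ug
  abundance_estimate(sample_id, virus, "copies_per_ug", copies,
                     reference = "standard_curve")
}

#' Read-count relative abundance against a reference gene
#'
#' `value = (virus_counts + pseudocount) / (ref_counts + pseudocount)`;
#' the default pseudocount of 1 keeps the log finite for absent viruses.
#'
#' @param virus_counts Mapped-read counts for the virus (>= 0).
#' @param ref_counts Mapped-read counts for the reference (> 0).
#' @param pseudocount Added to both counts (default 1).
#' @param sample_id,virus,reference Labels.
#' @return One-row `abundance_estimate` data.frame (mode
#'   `count_relative`).
#' @export
relative_abundance_counts <- function(virus_counts, ref_counts,
                                      pseudocount = 1,
                                      sample_id = NA_character_,
                                      virus = NA_character_,
                                      reference = "L23a") {
  if (is.na(ref_counts) || ref_counts <= 0)
    stop("reference counts must be positive")
  if (virus_counts < 0) stop("virus counts must be non-negative")
  value <- (virus_counts + pseudocount) / (ref_counts + pseudocount)
  abundance_estimate(sample_id, virus, "count_relative", value, reference)
}

#' Prevalence matrix from abundance estimates
#'
#' Samples x viruses presence/absence matrix: a virus is present in a
#' sample when its abundance is strictly positive (a no-amplification
#' qPCR estimate is 0, hence absent).
#'
#' @param estimates data.frame of abundance estimates (rbind of
#'   `abundance_estimate` rows).
#' @return Integer matrix (1 = present), rownames = samples, colnames =
#'   viruses.
#' @export
prevalence_matrix <- function(estimates) {
  samples <- unique(estimates$sample_id)
  viruses <- unique(estimates$virus)
  m <- matrix(0L, nrow = length(samples), ncol = length(viruses),
              dimnames = list(samples, viruses))
  for (i in seq_len(nrow(estimates)))
    m[estimates$sample_id[i], estimates$virus[i]] <-
      as.integer(estimates$value[i] > 0)
  m
}
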