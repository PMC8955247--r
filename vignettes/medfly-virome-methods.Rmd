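---
title: "Methods: virome triage, viral small-RNA profiling and abundance quantification in the medfly"
author: "medflyvirome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virome triage, viral small-RNA profiling and abundance quantification in the medfly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medflyvirome)
```

## The biological problem

The Mediterranean fruit fly (*Ceratitis capitata*, "medfly") carries a
covert RNA virome: persistent infections by insect-specific RNA viruses
that cause no overt symptoms but may affect fitness, mass rearing and
sterile-insect-technique programmes. Thirteen RNA viruses are currently
described for the medfly across sixteen genome or segment records,
spanning positive ssRNA (10 viruses), negative ssRNA (1) and dsRNA (2)
genomes. Three questions structure the analysis this package implements:

1. **Discovery** — which assembled transcriptome contigs are viral
   genomes rather than host transcripts or fragments?
2. **Host response** — does the fly's RNAi machinery process each virus,
   i.e. do the virus-derived small RNAs (vsRNAs) carry an siRNA
   signature (a sharp ~21-nt peak mapping to both genome strands), a
   piRNA-like signature (24–29 nt, 5′-uridine biased), or only
   unspecific degradation?
3. **Abundance** — how much of each virus is present, relative to the
   endogenous L23a reference gene (qPCR or read counts) or in absolute
   genome copies per µg of RNA (standard curve)?

## The virus catalogue

`load_catalog()` ships the thirteen-virus table (16 records: the
nodavirus has 2 segments, the reo-like virus 3). One convention needed a
decision: **what is the "smallest" virus when genomes are segmented?**
Per-record minima would crown a 1798-nt nodavirus *segment*, which is
not a complete genome. `summarize_catalog()` therefore compares
per-virus *summed* genome lengths, making the 2896-nt narnavirus
CcaNaV1 the smallest complete genome — the biologically meaningful
statement. Segment-level extremes remain available from the record
table itself.

Accessions are opaque strings; nothing is ever fetched remotely.
`catalog_placeholder_genomes()` generates deterministic pseudo-random
stand-in sequences of exactly the catalogued lengths (they are
synthetic, not the deposited genomes) so that length-integrity checks
and the mapper can be exercised without sequence downloads.

## Contig triage

`triage_contigs()` applies a conjunctive cascade in fixed order; a
contig is a viral candidate iff it

1. has a viral homology hit with e-value ≤ `viral_evalue_max` (1e-5);
2. is ≥ `min_length` (2000 nt);
3. has **no** host-genome hit with e-value ≤ `host_evalue_max` (1e-100);
4. contains at least one open reading frame.

Homology search itself is out of scope: the module consumes the
standard 12-column tabular hit format. Discarded contigs record *all*
applicable reasons, and because the predicates are conjunctive the kept
set is invariant to filter order and monotone in the thresholds.

The built-in six-frame ORF scanner reports maximal stop-free codon runs
(optionally anchored at the first ATG). Two parameters are genuinely
open in the source method and were fixed here: `min_orf_aa = 25` codons
(the conventional 75-nt default of common ORF finders) and
`require_start = FALSE` (the filter's wording is "without open reading
frames", not "without start-anchored ORFs"); both are configurable.
Codons containing `N` are non-coding and break a run without acting as
stop codons. A terminating stop codon is included in the reported span,
so `aa_length = (end - start)/3 - 1` for stop-terminated ORFs.

`terminal_coverage_check()` operationalises the full-length
confirmation ("high coverage at the 5′ and 3′ ends"): both terminal
windows (`end_window = 50` nt) must reach `min_ratio = 0.2` of the
global mean depth. The source describes this check qualitatively; the
defaults are deliberately permissive and configurable, and the check is
kept separate from the main cascade (it needs a read pileup, which the
hit tables do not provide).

## Small-RNA cleaning and mapping

`clean_reads()` assumes vendor-trimmed (adapter-free) input and
applies, in order: empty-read removal, the 18–32 nt length window, the
quality rule (> 20% of bases below Q20 — the "20% low-quality" rule
with the unstated threshold fixed at the conventional Q20), and a
low-complexity rule (longest homopolymer run > 80% of the read). Each
read is counted under the first rule it violates.

`build_index()` / `map_reads()` replace an external aligner with a
seed-and-verify exact matcher: every genome k-mer (k = 9) is hashed;
a query is located via its first seed and, when one mismatch is
allowed, also its second disjoint seed — by pigeonhole, one of the two
9-mers of an 18-nt read is exact under ≤ 1 mismatch, so the lookup is
complete for the whole 18–32 nt range. Every candidate is verified by
direct string comparison before being reported. Defaults follow the
declared approximation of the source pipeline: `max_mismatch = 0`
(the genomes are the consensus of the very samples sequenced), with 1
supported. Reads containing `N` never map. Multi-mapping policy: within
a virus, the leftmost position counts once (ties to the + strand);
across viruses a read counts once *per virus*, because each virus's
profile is an independent question. Minus-strand hits are genome
positions whose reverse complement equals the read.

## vsRNA profiles

`profile_virus()` works on **unique (collapsed) reads**, matching the
convention that per-virus percentages are unique reads mapped over
unique reads in the library, per library (raw-count percentages are
emitted as diagnostics). The 5′-base composition uses the read *as
sequenced* — for a minus-strand read that is the reverse complement of
the genome window — and reports T as U. Coverage is accumulated per
strand over every position a read spans; "uniformity" is coverage
breadth (fraction of positions with combined depth ≥ 1), chosen as the
operational form of "homogeneous distribution of the reads", with the
coefficient of variation as an alternative diagnostic.

## Signature classification

`classify_profile()` is a pure, deterministic rule evaluated in order:

1. fewer than `min_reads` (50) unique mapped reads → **absent**;
2. ≥ `min_peak_fraction` (0.4) of reads at 21 ± 1 nt **and**
   minor-strand fraction ≥ `min_minor_strand` (0.1) → **siRNA**;
3. modal length in 24–29 nt **and** 5′-U fraction of window reads ≥
   `min_u_bias` (0.5) → **piRNA**;
4. otherwise → **degradation**.

The source describes these signatures only qualitatively ("distinctive
peak of 21-nt sRNAs", "both strands"); every cutoff here is an
engineering default tuned on the simulator, declared, configurable and
echoed with each call — none is an inferred literature value. Modal-length
ties break toward the smaller length. Coverage breadth is reported with
each call but deliberately not consumed by the rule (the rule is the
spec'd four-step decision; breadth would make absent/degradation calls
depend on genome length in ways the depth threshold already handles).
The rule reproduces the two published edge cases by construction: a
flat-length, one-sided profile (the nora-virus pattern) is
*degradation*, and a one-sided 21-nt profile with few reads (the
nodavirus control-strain pattern) is *absent* under the depth gate,
*degradation* when deep. Ping-pong (10A/overlap) analysis is not
implemented because no such analysis is part of the source results.

`signature_power_curve()` is the validation harness: pure-class
libraries at a depth grid, scored for class recovery. At 5000 unique
reads and default generator parameters, recovery is 100% for all four
classes across 100 seeds (an acceptance criterion re-run by the tests).

## Abundance

Three modes, sharing the `AbundanceEstimate` row type:

* `relative_abundance_qpcr()` — `E_v^(−Ct_v) / E_r^(−Ct_r)` computed in
  the log domain; E defaults to 2 (100% primer efficiency) and must lie
  in (1, 2.2]. A no-amplification Ct (NA) maps to abundance 0 with a
  flag, feeding presence/absence in the prevalence matrix.
* `fit_standard_curve()` / `copies_per_ug()` — least squares of Ct on
  log10(copies); slope −log2(10) ≈ −3.3219 cycles per decade at E = 2;
  inversion gives genome copies per µg of RNA. Curves with
  non-negative slope are flagged invalid and refuse inversion.
* `relative_abundance_counts()` — `(virus + p) / (ref + p)` with
  pseudocount p = 1 by default so that log10 stays finite for absent
  viruses (p = 0 reproduces the raw ratio). Log base 10 is used and
  recorded in output metadata; the source figure's scale is unstated.

L23a is treated as an opaque reference target named "L23a" (the source
text calls it ribosomal in one place and mitochondrial in another).

## The synthetic world

`simulate_srna_library()` states the generator's world once:

* siRNA-like reads: lengths 20/21/22 at 0.15/0.70/0.15, minor-strand
  fraction 0.45, uniform positions — a sharp bidirectional Dicer-like
  peak;
* piRNA-like reads: lengths 24–29 peaked at 26–28, 5′-U probability
  0.8, minor strand 0.2 — the canonical piRNA asymmetry;
* degradation reads: uniform 18–32 nt, minor strand 0.1 — flat and
  one-sided, the nora-virus-like pattern;
* non-viral reads: i.i.d. random sequences (collision probability with
  a 10-kb genome is ≈ 2·10⁻⁷ per 18-nt read, negligible).

Where the source states no value (it reports profiles, not generator
parameters), these defaults are what a small-RNA practitioner would
call realistic for the three classes, were chosen once, and are not
tuned against test outcomes. 5′-U forcing is implemented by sampling
positions whose 5′ base on the chosen strand is T (complement A on the
minus strand), so *every* viral read remains an exact genome substring
— this preserves the identity "mapped fraction = planted viral
fraction" under exact matching, which several tests assert exactly.
Duplication is applied last by resampling reads. Qualities are constant
Q30.

`simulate_contig_set()` plants the four triage properties
independently per contig. Contigs destined to lack ORFs repeat a
15-mer (AACCGTTAGTTAATT) whose tiling contains stop codons in all six
frames with a longest stop-free run of 4 codons; with ≤ 12-nt random
flanks the longest possible ORF stays far below the 25-codon
threshold. Contigs with ORFs carry a planted ATG + 30–60 sense codons
+ TAA. Hit e-values are drawn on both sides of both thresholds
(qualifying: ≤ 1e-6 viral, ≤ 1e-105 host; decoys above). The truth
labels *are* the cascade rule applied to the planted flags, so triage
precision/recall of 1.0 is a consistency check of the implementation
against an independent evaluation path, not a biological claim.

`simulate_qpcr()` draws Ct on the standard-curve line with Gaussian
noise. All generators take explicit seeds, restore the global RNG
state, and are byte-identical across runs for a fixed seed.

### What a green test does and does not establish

The simulators emulate structure (length/strand/5′-base mixtures,
planted filter outcomes, on-line Ct values), not sequencing physics: no
sequencing-error model beyond the optional mismatch allowance, no
adapter read-through, no chimeras, no abundance-coupled PCR bias, and
random rather than real genome sequence (no secondary-structure or
repeat content). Green acceptance tests therefore establish that the
implementation computes its stated definitions exactly and recovers
planted truth; they do not re-derive the published biological results,
whose raw sequencing data are not desk-reproducible. The in-text
catalogue facts (13 viruses, 2896-nt narnavirus, 6132-nt totivirus,
10,332-nt iflavirus 2, 4177-nt reo-like segment 1 of 3, two dsRNA
viruses) are reproduced exactly from the packaged table.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, 1-based in TSV output.
* qPCR arithmetic is done in log space to avoid underflow at large Ct.
* Empty inputs are legal where vacuous (header-only catalogue, empty
  FASTQ/FASTA, zero-read profiles → absent) and errors where
  meaningless (empty catalogue summary, < 3 standard-curve points,
  zero reference counts).
* All-zero depth fails the terminal-coverage check with a dedicated
  zero-coverage diagnostic rather than dividing by zero.
* Modal-length ties and multi-mapping ties have deterministic
  tie-breaks (smaller length; leftmost position, then + strand).

## Known limitations

* The matcher is ungapped and caps mismatches at 1; it is not a
  general aligner (by design — the genomes are sample-consensus).
* Homology search, assembly, phylogenetics and primer design are out
  of scope; the package consumes their standard tabular/FASTA outputs.
* Classification thresholds are simulator-tuned engineering defaults;
  on real libraries they should be inspected alongside the reported
  metrics, which is why every call echoes its thresholds.
* The catalogue is a snapshot; adding viruses means editing one TSV.
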