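---
title: "Classifying miRNAs and their isoforms with armiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying miRNAs and their isoforms with armiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small RNA sequencing of a tissue or biofluid does not return one sequence
per mature miRNA. Around each database-annotated ("RefSeq") mature sits a
cloud of isoforms (isomiRs): *template* isomiRs, whose 5' and/or 3' ends are
shifted along the precursor but whose every nucleotide is genome-templated,
and *non-template* isomiRs, which carry 1-3 untemplated nucleotides
(typically A or U additions) at the 3' end. These species can be
differentially expressed independently of their parent miRNA, which makes
resolving them worthwhile — and requires a reference, a classification rule
and a naming scheme that keep every species distinct and comparable across
samples. armiR implements that workflow: reference construction, exact
alignment, hierarchical classification, count-matrix export for external
differential-expression tools, and reporting.

## Arm references

The alignment reference is not the mature sequence but the *arm*: the
mature extended on both sides by up to 8 templated nucleotides, taken
either from the stem-loop precursor (`build_arms_from_precursors()`) or
from genome coordinates (`build_arms_from_gff()`, minus-strand loci are
reverse-complemented so arms always read 5' to 3'). The default extension
is 6 nt; this window is what bounds detectable end shifts, so the offsets
of template isomiRs can never exceed it. Extensions are clamped at the
precursor or chromosome boundary and the achieved widening
(`ext5_applied`, `ext3_applied`) is recorded in the arm FASTA header
together with the mature length, so downstream classification can locate
the embedded reference window without re-deriving it.

A mature encoded at several loci yields one arm per locus; loci whose
widened sequences are identical are merged into a single record whose
identifier concatenates the locus suffixes (`miR-486-5p_chr8(-)_chr8(+)`).
In precursor mode there are no locus suffixes; should one mature produce
distinct widened windows from several precursors, the records are
disambiguated with a `_v<k>` suffix. A mature occurring more than once
*within* one precursor is reported as an error rather than guessed at —
such a repeat makes the offset definition ambiguous.

All sequences are normalized to uppercase DNA (U to T) on input: mature
databases distribute RNA, reads are DNA, and classification is exact string
matching.

## Alignment

Reads are aligned with zero mismatches, all hits reported, forward strand
only — the arms are already strand-resolved, so a reverse-strand match
would be biologically meaningless here. The package's internal aligner
(`align_exact()`) makes the pipeline self-contained; externally produced
SAM (e.g. from a short-read mapper run with equivalent settings) is
ingested by `read_sam()`, which re-verifies every mapped record against
the arm and demotes records that fail the zero-mismatch check, or that
carry the reverse-strand flag, to unmapped with a warning.

The length filter (default 18-26 nt inclusive, the usual mature-miR
window) is applied *after* alignment/ingest, so the profile report's
length-distribution chart can still show longer reads; classification
itself only ever sees length-filtered reads.

## Hierarchical classification

For each sample, reads are assigned in a strict hierarchy:

1. **RefSeq**: the read equals one or more mature sequences. All matching
   matures become parents and are collapsed into one entry.
2. **Template isomiR**: any other mapped read. With the mature embedded at
   offset `ext5_applied` in the arm, the end offsets are
   `d5 = pos - ext5_applied` and `d3 = read_end - mature_end`, both
   measured 5'→3' along the arm, and the entry is named
   `<parent>_t_<d5>_<d3>`.
3. **Non-template isomiR** (optional): an unmapped read that equals a
   reference sequence plus a 1-3 nt suffix, where the reference pool is
   every mature plus every template isomiR discovered in step 2 across
   *all* samples of the run. The entry is named
   `<reference>_nont_0_+<k>_<added nt>`.

Reads that survive none of the steps — including any read containing N,
which exact matching can never place — are counted as unassigned. The four
categories partition the length-filtered reads exactly; this conservation
is asserted by the test suite on randomized simulations.

Design choices worth spelling out:

* **Offset sign convention.** `d5 < 0` is a 5' extension, `d5 > 0` a 5'
  trimming, `d3 > 0` a 3' extension, `d3 < 0` a 3' trimming — one
  coordinate-delta rule for both ends rather than an "extension is
  positive" convention that flips sign between ends. The convention is
  isolated behind `format_name()`/`parse_name()` so it could be flipped in
  one place. It is consistent with 3'-trimmed species (`_t_0_-1`) being
  among the most abundant isomiRs in published profiles.
* **Run-wide non-template pool.** The pool of references for step 3 spans
  all samples, not just the current one. Entry names must be comparable
  across count-matrix columns; a per-sample pool could name the same
  sequence differently in different samples.
* **Smallest suffix wins.** A read is attributed the longest matching
  reference prefix, i.e. the smallest claimed untemplated suffix. This
  minimizes claimed non-templated content; a 1 nt addition is also far
  more frequent biologically than a 3 nt one.
* **Bare names for additions on matures.** A non-template isomiR of a
  mature is named after the mature's bare database name without locus
  suffixes (`miR-486-5p_nont_0_+1_A`), whereas one of a template isomiR
  inherits the template's full locus-qualified name. The mature is a
  database record, not a locus; the template was discovered at a locus.
* **Multi-reference collapsing.** Parents are deduplicated and sorted
  lexicographically in the C locale before joining — first-seen order
  would make output depend on input file order. Same-base parents merge
  their locus suffixes; different bases are joined as full names.
* **Conflicting placements.** If one sequence maps to two arms with
  *different* implied offsets, the per-parent variants are kept as
  separate entries and a message is logged; each variant row carries the
  read's count, so the count-matrix column-sum equals the assigned reads
  only in the absence of such conflicts. They require two arms sharing a
  long exact substring at different offsets relative to their matures and
  do not occur in the simulations; on real paralogous families they are
  logged for inspection rather than silently resolved.
* **Species prefixes** (`hsa-`) are preserved verbatim from the mature
  FASTA; no normalization is attempted.
* The name grammar emits ASCII `-` everywhere but `parse_name()` also
  accepts the Unicode minus (U+2212), which publication tables commonly
  typeset.

One known limitation: a read extending 3' beyond the arm window by
templated nucleotides cannot map and would be considered a non-template
candidate; with the default 6 nt extension and 26 nt maximum read length
this requires an extreme offset combination and is correspondingly rare.

## Count matrices and the arm database

`build_count_matrices()` produces the combined matrix (all categories,
rows the union of entries over samples, zeros filled in, columns ordered
group 1 then group 2) that DESeq2- or edgeR-style tools load directly,
plus six per-category, per-group matrices annotated with the entry
sequence. `export_arm_database()` writes one row per (arm, entry, sample)
with a positive count, sorted by arm and descending entry abundance, so
every detected species is traceable to the arm that produced it.

## Profile statistics and DE post-processing

`profile_stats()` reports (a) the read-length distribution over *all*
aligned-or-not reads in a 20-35 nt display window — computed before the
length filter precisely so that degradation or adapter artifacts outside
the miR window remain visible; (b) the percentage breakdown of
RefSeq/template/non-template/unassigned reads, whose denominator is the
length-filtered read count (reads the classifier actually saw — the
pie answers "of the classifiable reads, how many were assigned"); and (c)
template-subtype counts (5' shift, 3' shift, both) in redundant
(read-weighted) and non-redundant (unique-entry) modes.

Differential expression itself stays external: `read_de_table()` ingests
DESeq2 (`baseMean/log2FoldChange/pvalue/padj`) or edgeR
(`logFC/PValue/FDR`) dialects, auto-detected from the header.
`filter_de()` applies strict `padj < 0.05` and `|log2FC| > 1` by default
(the base-mean criterion is inclusive, `>=`, and skipped for edgeR input,
which carries no base mean; rows lacking an adjusted p are dropped while
that threshold is active). `top_de()` ranks by `|log2FC|` descending by
default — adjusted p is available as an alternative key — with ties broken
by name for determinism, and `n` is bounded to 10-50. `arm_summary()`
groups filtered rows by arm (base name plus locus suffixes, variant
segments stripped) and ranks arms by their strongest member.

Report rendering (`render_profile_report()`, `render_de_report()`) writes
multi-page PDFs, but every chart's numbers are also emitted as
tab-separated sidecar files, and all tests assert on those sidecars:
rendering is presentation, not scientific content. An empty DE input
yields an explicit "no entries passed filtering" page and a normal exit.

## The synthetic-data generator

`simulate_dataset()` plants a fully known composition: random 70-90 nt
precursors carrying one or two 20-23 nt matures, a genome embedding every
precursor on alternating strands with matching GFF3 loci (so both
reference-building modes are exercised on the same data), and per-sample
reads realizing each planted entry a Poisson-drawn number of times,
shuffled with seeded randomness. Defaults — 5 precursors, 6 nt extension,
two groups of three samples, about two template and two non-template
isomiRs per mature (roughly 35-40 entries), five contamination reads and
two over-length junk reads per sample — are sized so that an end-to-end
run takes seconds while still exercising every classification branch.

Planted entries are constructed to be unambiguously classifiable: offsets
stay within the applied extension and the read-length window; non-template
suffixes start with a nucleotide that differs from the templated
continuation; no shorter suffix of a planted addition resolves to any
reference; every planted sequence is verified to occur exactly where
intended across the whole arm set, and entries failing a check are
redrawn. Contamination reads are rejection-sampled to match neither any
arm substring nor any reference-plus-suffix pattern. Under these
conditions classification must recover the truth matrix cell-for-cell,
and the test suite asserts exactly that, in both reference modes.

What the generator does *not* emulate: sequencing errors and quality
scores, expression-level biology, internal (editing) variants, 5'
additions, and the genuine sequence ambiguity of paralogous miR families.
A perfect recovery on simulated data therefore validates the bookkeeping
and the classification logic, not robustness to noisy or ambiguous real
reads — on real data, ambiguous species surface as collapsed multi-parent
names or logged conflicts instead.

## Problem sizes and determinism

The test suite runs the demo simulation (about 2,000 reads across six
samples) once and twenty miniature simulations (two precursors, two
samples) for the property checks; the whole suite completes in roughly two
minutes on one CPU. All randomness is seeded — the generator from its
spec, test loops locally — and all outputs (matrices, arm database,
sidecars, SAM) are byte-identical across reruns on identical inputs, which
the suite also asserts. Sorting uses C-locale radix order throughout so
results do not depend on the session locale.
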