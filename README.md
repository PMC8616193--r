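# armiR

Arm-reference construction and hierarchical isomiR classification for
small RNA sequencing data.

Mature miRNAs observed in sRNA-seq are accompanied by isoforms (isomiRs):
**template** isomiRs whose 5'/3' ends are shifted along the precursor
(every nucleotide still genome-templated), and **non-template** isomiRs
carrying 1–3 untemplated nucleotides at the 3' end. These species can be
differentially expressed independently of their parent miRNA and are
candidate biomarkers in biofluids. armiR resolves them explicitly:

1. **Arm references** — each mature (RefSeq) miR is extended by up to 8
   templated nucleotides on both ends (default 6), from precursor
   sequences or from GFF3 genome coordinates. The arm, not the bare
   mature, is the alignment reference, and its header records where the
   mature sits.
2. **Zero-mismatch alignment** — all exact hits, forward strand, via the
   built-in aligner or ingested from external SAM (re-verified on input).
3. **Hierarchical classification** — reads equal to a mature are RefSeq
   entries; other mapped reads are template isomiRs with end offsets
   `d5 = start(isomiR) − start(RefSeq)` and `d3 = end(isomiR) − end(RefSeq)`,
   named `<parent>_t_<d5>_<d3>`; unmapped reads equal to a pooled
   reference (all matures + all discovered templates, run-wide) plus a
   1–3 nt suffix are non-template isomiRs, named
   `<reference>_nont_0_+<k>_<added nt>`. Everything else is unassigned.
4. **Count matrices** — a combined entries × samples matrix loadable by
   DESeq2/edgeR, six per-category/per-group matrices with sequences, and a
   per-arm sequence database.
5. **Reporting** — profile statistics (length distribution, category
   percentages, template-subtype radar) and, after an external DE step,
   filtering (`padj < 0.05`, `|log2FC| > 1` by default, strict), top-entry
   and per-arm summaries, rendered as PDFs with tab-separated sidecars.

A deterministic simulator (`simulate_dataset()`) plants a fully known
isomiR composition so the entire pipeline can be validated offline against
an exact truth matrix.

## Worked example

A 22 nt toy precursor carries the mature `GGAUCCGUACGU` (RNA input is
normalized to DNA). With a 3 nt extension the arm is built, five reads are
aligned and classified:

```r
library(armiR)

matures    <- mature_records("miR-T1-3p", "GGAUCCGUACGU")
precursors <- data.frame(name = "pre-T1", sequence = "AAGCTAGGATCCGTACGTTAGC")
arms       <- build_arms_from_precursors(matures, precursors, ext = 3)
arms
#>      arm_id           sequence ext5_applied ext3_applied mature_name mature_len
#> 1 miR-T1-3p CTAGGATCCGTACGTTAG            3            3   miR-T1-3p         12

reads <- data.frame(
  read_id  = paste0("r", 1:5),
  sequence = c("GGATCCGTACGT",     # the mature itself
               "AGGATCCGTACGT",    # one templated nt more at the 5' end
               "GGATCCGTACGTT",    # one templated nt more at the 3' end
               "GGATCCGTACGTA",    # untemplated A on the mature
               "AGGATCCGTACGTC"))  # untemplated C on the shifted isoform
res <- classify_samples(list(s1 = align_exact(reads, arms)), arms, matures)
res$entries[, c("name", "category", "subtype", "d5", "d3", "nta")]
#>                           name    category  subtype d5 d3 nta
#> 1                    miR-T1-3p      refseq     none  0  0
#> 2        miR-T1-3p_nont_0_+1_A nontemplate     none  0  0   A
#> 3             miR-T1-3p_t_-1_0    template 5p_shift -1  0
#> 4 miR-T1-3p_t_-1_0_nont_0_+1_C nontemplate 5p_shift -1  0   C
#> 5             miR-T1-3p_t_0_+1    template 3p_shift  0  1
```

The names read as: `_t_-1_0` — start one position before the RefSeq start,
same end (a 5' extension); `_t_0_+1` — same start, end one position past
the RefSeq end (a 3' extension); `_nont_0_+1_A` — one untemplated `A`
added at the 3' end. The addition on read r5 is attributed to the
*template isoform* discovered from r2, so its name carries both segments.

For a full run, `run_all(run_config(...))` (or the `inst/cli/armir`
script) chains arm building, alignment, classification, matrices, the
arm database and the profile report, and optionally filters and reports an
external DESeq2/edgeR result table; a `manifest.json` records checksums of
all inputs and outputs.

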