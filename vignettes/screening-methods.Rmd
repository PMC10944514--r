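---
title: "Screening tumor-specific splice junctions for cell-surface antigen candidates"
author: "neojx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening tumor-specific splice junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neojx)
```

## The problem

Tumors mis-splice. Some of the resulting non-annotated exon-exon junctions
("neojunctions") alter the extracellular portion of cell-surface proteins
without destroying the protein, and such altered surface proteins are
candidate antigens for MHC-independent immunotherapy (antibodies, CAR-T).
`neojx` implements the discovery side of that idea as a reusable, tested
pipeline over bulk RNA-seq junction output: detect junctions in a tumor
cohort, call per-sample positivity, keep events that are tumor-specific
(rare in a large normal cohort), shared (recurrent in at least one disease
group), restricted to expressed cell-surface ("surfaceome") genes, and
predicted by in-silico translation to change the extracellular domain while
leaving the transmembrane (TM) anchor intact. The same positivity machinery
then quantifies how spatially and longitudinally stable the surviving
events are within patients — the deciding question for any antigen-directed
therapy.

## The screening model

The screening unit is a splice junction keyed by chromosome, first and last
intronic base, and strand — exactly the first four columns of a STAR
`SJ.out.tab` record. Column 7 (uniquely mapped reads crossing the junction)
is the only count used; multi-mapped reads are ignored.

**Positivity.** A junction's evidence in one sample is judged against the
busiest competing splice form at its locus. For each junction the *most
dominant overlapping junction* is chosen once, on tumor-cohort totals: the
most abundant overlapping *annotated* junction, or, if no annotated
junction overlaps, the most abundant overlapping junction of any kind. Read
depth is the junction's own count plus the dominant junction's count in
that sample, and the supportive-read frequency is count / depth. A sample
is positive when count, depth and frequency all reach cohort-specific
thresholds:

| cohort | min count | min depth | min frequency |
|--------|-----------|-----------|---------------|
| tumor  | 10        | 20        | 0.01          |
| normal | 2         | 10        | 0.01          |

The normal cohort's looser count/depth thresholds compensate for its
smaller libraries; the frequency floor is shared. The positive-sample rate
(PSR) of a junction in a group divides its positive samples by the *full*
group size, never by the number of callable samples.

**The cascade.** Screening runs eight ordered stages, each recorded in a
ledger: (1) the junction universe — every junction reaching 10 unique reads
in at least one tumor sample on chromosomes 1–22/X/Y; (2) exclusion of
junctions present in the GTF-derived reference junction set (exact
coordinate match, strand participating only when both are defined); (3)
restriction to junctions overlapping any portion of a surfaceome gene whose
mean tumor TPM is at least 10; (4) tumor-specificity, pooled-normal
PSR < 0.01 (strict); (5) sharedness, PSR ≥ 0.10 in at least one disease
group (inclusive); (6) extracellular impact of the predicted protein
change; (7) the translation verdict — no premature termination codon (PTC),
TM segment intact, single-pass host protein (multi-pass proteins are
excluded as topologically unpredictable); (8) a machine-readable exclusion
list standing in for manual review, so that the pipeline remains
deterministic. Stage counts are non-increasing and every dropped junction
carries exactly one first-failure reason.

**In-silico translation.** Each surviving junction is applied to every
canonical template transcript of its host gene: template introns
overlapping the novel intron are merged into the locus and the novel
intron's bases excised, so exonic bases inside the novel intron are removed
and formerly intronic bases outside it become exonic. The altered mature
mRNA is re-assembled from the genome (reverse-complemented on minus-strand
templates), the CDS is re-extracted from the annotated start codon, and
translation proceeds with every stop marked `*`. Frame status follows the
signed nucleotide change (`in_frame` iff divisible by 3); a PTC is an
in-frame stop strictly upstream of the canonically aligned stop position.
Deleted/inserted amino-acid counts and the affected residue interval come
from the longest common prefix/suffix against the wild-type protein. As a
standing self-check, translating the unaltered template must reproduce the
reference protein exactly. A candidate passes when *any* canonical template
passes; all per-template reports are kept, because one junction may be an
alternative-acceptor event on one isoform and complex on another.

**Topology.** Surfaceome topology (extracellular / transmembrane /
intracellular segments in protein coordinates) is defined on one named
reference isoform per gene. For other templates the segments are
transferred by exact subsequence match of the TM amino-acid sequence and
clipped to the template protein; when the TM sequence cannot be located
intact, the template is non-assessable and fails with a logged reason. TM
integrity in the altered protein is likewise decided by exact subsequence
presence — a deliberately strict reading that treats any touch of the TM
segment as disqualifying.

## Heterogeneity summaries

For spatially mapped multi-region data, pieces are gated (purity ≥ 50% for
IDH-wildtype and IDH-O tumors; IDH1 R132 VAF > 25% for IDH-A, where
infiltrating non-tumor cells make purity estimates unreliable) and each
tumor × event pair is summarised by its positive-piece fraction;
*tumor-wide* means 100% of gated pieces. For primary/recurrent pairs, a
timepoint is positive when at least 50% of its pieces are positive
(boundary inclusive, applied symmetrically to both timepoints; a
single-piece timepoint is its piece's call), and each patient × event pair
is classified shared / primary-only / recurrent-only / absent. The cohort
gate for bulk screening is stricter (purity ≥ 0.6, unknown purity
excluded).

## What the simulator emulates

Real inputs at the original study's scale are controlled-access, so the
package ships a first-class generator that emulates the *data model* the
statistics consume, not reads: per-sample junction count tables, a matched
TPM matrix, and manifests for cohort, multi-region and paired-timepoint
designs, each with machine-readable planted truth.

Choices that define the default study conditions:

* **Reference.** 16 six-exon genes (13 surfaceome, alternating strands)
  with a fixed 300-codon architecture whose exons 2–4 code amino acids
  21–140, inside the extracellular segment (aa 1–180) and clear of the TM
  (aa 181–203). One gene carries a second canonical isoform (in-frame exon
  skip) to exercise multi-template evaluation; the last surfaceome gene is
  annotated multi-pass. Coding sequences are rejection-sampled so that the
  standard frameshift plant position guarantees an early PTC — the
  generator constructs validity rather than hoping for it.
* **Cohort.** Three tumor groups of 20 (IDHwt, IDH-A, IDH-O) and 300
  pooled normals across eight tissue labels, mirroring the
  several-groups-versus-large-normal-cohort shape of the original design at
  desk scale. Locus depths are negative-binomial (mean 600, size 8) —
  overdispersed RNA-seq coverage without read-level simulation, which adds
  nothing the junction statistics would consume.
* **Planted events.** Five pass-filter events covering the observed
  pattern spectrum (two cryptic introns, alternative acceptor, alternative
  donor, exon skip) at supportive-read frequencies of 5–8% and group PSRs
  of 15–45%, plus one decoy per failure class, each engineered to fail at
  exactly one cascade stage: an annotated junction (stage 2), a
  low-expression host (stage 3, mean TPM 2 versus the threshold 10), a
  normal-shared event (stage 4, normal PSR 5%), a rare event (stage 5,
  group PSR 5%) and a low-frequency event (frequency 0.5%, planted on a
  high-depth locus with mean 4000 so it still enters the universe while
  never reaching 1% frequency), an intracellular-only event (stage 6), a
  frameshift-PTC event and a multi-pass host event (stage 7).
* **Exact-count planting.** An event designed at probability *p* in a
  group of *n* is switched on in exactly `round(p * n)` samples drawn
  without replacement, rather than by independent coin flips. Realized
  PSRs then equal their designs up to rounding, so each decoy's
  pass/fail margin is deterministic and the end-to-end recovery check
  (precision = recall = 1) cannot flake; the realized count is always
  within the binomial tolerance an iid design would allow.
* **Frequency by construction.** An "on" sample's count is derived from
  the realized count *d* of the event's dominant overlapping junction:
  `ceil(f/(1-f) · d)` with floors that guarantee every positivity
  threshold is cleared with at least 2× margin for pass events, and
  `floor(f/(1-f) · d)` for the low-frequency decoy so its frequency can
  never round up to the 1% threshold. Cryptic-intron events have no
  overlapping junction; their depth is their own count (frequency 1), the
  documented degenerate case of the depth definition.

The simulator does *not* emulate alignment artifacts, fuzzy junction
boundaries, expression-coupled junction depths, batch effects, or the long
tail of sporadic novel junctions in real data. Passing the planted-truth
gate therefore demonstrates that the screening logic implements its
definitions exactly — not that the thresholds are well-calibrated for any
particular real cohort.

## Numerical and design choices

* Coordinates are uniformly 1-based inclusive internally (the native
  convention of both `SJ.out.tab` and GTF); any half-open export is the
  writer's explicit responsibility.
* The expression gate summarises a gene's tumor-cohort TPM with the mean
  by default; a median variant is available (`expression_stat`) since the
  two can disagree for heavy-tailed expression and field practice varies.
* A junction is excluded from being its own dominant junction by default;
  with no overlapping junction at all, depth equals the junction's own
  count. Both behaviors are available (`allow_self_dominant`), since
  letting a locus-dominating junction compete with itself roughly halves
  its frequency.
* Dominance ties break by larger tumor total, then lexicographic junction
  key — output is bit-identical across runs.
* Junctions with undefined strand (STAR code 0) inherit the strand of
  their overlapping gene; when overlapping genes disagree the junction is
  dropped with a log entry.
* Ambiguous multi-gene assignments (exact overlap-length ties) are
  reported and flagged rather than silently resolved.
* PTC means any premature in-frame stop; no 50-nt NMD boundary rule is
  applied.
* The per-tissue normal gate (< 1% in every normal tissue separately) is
  implemented but off by default; the headline tumor-specificity gate uses
  the pooled normal PSR.
* Degenerate inputs: zero-depth samples are negative by definition; an
  event that removes the start codon is non-translatable and fails the
  protein verdict; a stage emptying the candidate set is not an error and
  the ledger is still written.

## Problem sizes

The default conditions (60 tumor / 300 normal samples, ~95-junction
catalog) run the full screen in a few seconds on one CPU; the test suite's
property checks use 200-junction × 50-sample random catalogs for the
positivity oracle and 1,000 randomized events for the translation frame
law. These sizes were chosen so that every invariant is exercised at a
scale where a brute-force oracle is still exact.

## Limitations

Known limitations beyond the simulator's scope: no fuzzy junction matching
(±k nt clustering of wobbly junction calls), no intron-retention events
(a separate detection problem), no statistical testing of PSR differences
between groups, no signal-peptide or re-topologization prediction for
altered proteins, and no epitope or MHC prediction — the pipeline ends at
the predicted altered surface protein.

## A worked run

```{r, eval = FALSE}
reference <- generateReference(seed = 1)
cohort <- simulateCohort(seed = 2, reference)
catalog <- JunctionCatalog(cohort$tables, cohort$manifest)
result <- runScreen(catalog, reference$annotation, cohort$tpm,
                    reference$surfaceome, reference$genome)
screenLedger(result)
finalCandidates(result)
```

The README shows this run with its printed output; `scripts/acceptance.R`
recomputes the same quantities from scratch for a given seed.
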