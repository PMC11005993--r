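---
title: "Core promoter elements and DNA physical-property profiles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core promoter elements and DNA physical-property profiles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promdpp)
```

## The analysis

RNA polymerase II core promoters — of mRNA, lncRNA and miRNA genes alike —
can be characterized in two complementary ways:

1. **By sequence elements.** Short consensus motifs (core promoter elements,
   CPEs) occur at roughly fixed positions relative to the transcription
   start site (TSS): the TATA box around −31..−24, the initiator (Inr)
   straddling the TSS, the TFIIB recognition elements BREu/BREd flanking the
   TATA position, and the downstream promoter element (DPE) near +28.
   Classifying each promoter by which elements it carries yields promoter
   "species" such as `TATA+Inr`, with promoters carrying none called
   **core-less**.

2. **By physical properties.** Each dinucleotide (or tetranucleotide) step
   of duplex DNA carries measurable physical parameters — duplex free
   energy, base stacking energy, protein-induced deformability, rigidity,
   Z-DNA (anti-syn) stabilizing energy.  Sliding a k-wide window along a
   promoter with a 1-bp frameshift converts it into a numeric chain, and
   averaging chains over a TSS-aligned promoter set gives a meta-profile
   whose features (a sharp peak or cleft at the TSS, a smaller feature near
   −27 where TBP bends the duplex) are hypothesized prerequisites for
   pre-initiation complex assembly, DNA bending and promoter melting.

The same profiling applies to Pol III tRNA genes, using three separately
anchored regions: the 5′ flank (TSS = 0, covering −50..0), the
A-box-containing region (mature tRNA 5′ end = 0, covering 0..+30) and the
B-box-containing region (discriminator base = 0, covering −30..0).  The
A-box/B-box are gene-internal promoter elements with consensus
`TGGCNNAGTGG` (alternatively `TRGYNNARBGG`) and `GGTTCGANNCC`; their spacing
is irregular (introns, variable loop), which is why each region gets its own
anchor rather than a joint alignment.

This package implements both characterizations plus the supporting
machinery: genome/TSS I/O, representative-TSS selection, a sequence-logo
layer (position frequency matrices and information content), and a
synthetic-data generator with recorded ground truth so the entire pipeline
is testable without external downloads.

## Coordinates and extraction conventions

All user-facing coordinates are TSS-relative integers with the TSS at 0 and
upstream negative; internal genomic coordinates are 0-based.  A promoter
window with `upstream = U` and `downstream = D` has length `U + D + 1` and
the TSS base at offset `U`.  On the '−' strand the extracted sequence is the
reverse complement of the genomic slice `[pos − D, pos + U]`, so position 0
of the record is always the transcribed TSS base in sense orientation.

Records whose window would overrun a contig end are **skipped** (with a
counted warning) rather than padded: padding would silently distort the
per-position `n` of downstream profiles.

Defaults are `upstream = 100`, `downstream = 50`.  The defaults are
explicit, configurable choices: they cover every default element's
tolerance window (−43 for shifted BREu through +38 for shifted DPE) with
generous margins on both sides for baseline estimation.

## Step tables and chains

A step-parameter table maps every k-mer over {A,C,G,T} (k = 2 or 4) to a
real value; tables are shipped as editable TSV files with the citation in
the header, so any scale can be substituted via `load_step_table()`.  The
packaged set:

| property | k | source |
|---|---|---|
| duplex_free_energy | 2 | SantaLucia (1998) unified nearest-neighbor ΔG°37 |
| base_stacking_energy | 2 | Ornstein et al. (1978) |
| deformability | 2 | Olson et al. (1998) |
| rigidity | 4 | **synthetic composite** (see below) |
| zdna_as_energy | 2 | Ho et al. (1986) |

Published tetranucleotide rigidity values were not available for
transcription, so the packaged rigidity file is a clearly-labelled synthetic
stand-in: the mean of `10 / deformability` over the three dinucleotide steps
of each tetranucleotide.  It preserves the qualitative structure a rigidity
scale needs (stiff A-tracts, flexible pyrimidine–purine steps, reverse-
complement symmetry) and exercises every k = 4 code path; replace it with a
published scale for biological interpretation.

`sequence_to_chain()` assigns each step's value to the TSS-relative
coordinate of the step's **first base** (the assignment convention is not
canonical anywhere; picking the first base means profile features can appear
up to k − 1 bp left of their "true" center, material only for the k = 4
table, and is recorded here so users can re-index if needed).  Lowercase
(soft-masked) bases are folded to uppercase before lookup; any step touching
a non-ACGT character becomes `NA` rather than an error, and `NA`s simply
reduce the per-position `n` during aggregation.

## Element scanning and species labels

Scanning allows the whole consensus window to shift ±5 bp (configurable per
element) from its canonical start.  Three deliberate choices:

* **One hit per element**, the match with minimal |shift|; ties go to the
  upstream (negative) shift.  Multiple in-window matches are not
  enumerated — presence at the canonical position, not occupancy counting,
  is what the species label encodes.
* **Sense strand only.** Core promoter elements are defined on the
  transcribed orientation.
* **Unevaluable ≠ core-less.** If an element's tolerance window does not fit
  inside the extracted sequence, that element is reported unevaluable; a
  promoter for which *no* element was evaluable gets an `NA` label and is
  excluded from tabulation rather than mislabelled core-less.

Species labels join present elements by `+` in canonical-start order
(`BREu+TATA+Inr`), keeping BREu and BREd distinct.  Percentages are
computed group by group (e.g. the 16 lncRNA groups from 4 genomic contexts
× 4 DNase-hypersensitivity types, which arrive as input metadata), with a
top-five view for reporting.

## Aggregation and landmark detection

Per position, the profile records the mean, the **sample** standard
deviation (n − 1 denominator; the convention is written into every output
header since population-SD users differ by a factor √((n−1)/n)), and the
contributing count n.  Positions covered by zero chains are omitted.

`locate_landmarks()` operationalizes the qualitative "two distinctive
sites" reading of a profile.  Within a TSS window (default −5..+5) and an
upstream window (default −35..−20, bracketing the TATA/TBP-bend region near
−27) it finds the position maximizing |mean − baseline|, where the baseline
is the median of the mean over all positions outside both windows.  A
landmark counts as distinctive only if its deviation exceeds 5 MADs of that
outside region.  The factor 5 is conservative by design: across the ~100
outside positions of a default window the expected maximal noise excursion
is below 3.5 robust SDs, so a flat or noise-only profile is not flagged,
while a planted TATA signal at n = 500 exceeds the threshold by an order of
magnitude.  A completely flat profile has MAD 0 and deviation 0 and is
correctly not flagged.

## Sequence logos

`build_pfm()` counts sense-strand bases over a window every promoter must
cover (default −5..+5; narrow because single-base TSS annotations only
support claims right at the anchor).  Non-ACGT bases are tallied as "other"
and excluded from frequencies rather than spread fractionally.  Information
content is the relative entropy IC = Σ f·log₂(f/q) against a configurable
background (uniform by default), so IC ∈ [0, 2] bits; the small-sample
Miller correction is available as a flag but off by default since the
promoter sets profiled here are large.

## The synthetic generator

`generate_promoter_set()` emulates exactly the statistical structure the
pipeline consumes: fixed-length sequences (default 151 nt, anchor at 100,
matching the default extraction window) of i.i.d. background with
configurable GC content (default 0.5), a species label drawn per sequence
from a configurable mixture (default {core-less 0.55, Inr 0.30, TATA+Inr
0.15}, the fraction pattern real Pol II promoter sets show: a core-less
majority and an Inr-rich minority), and each element of the species planted
at its canonical start plus a uniform jitter (default ±5).  Planting draws
every degenerate consensus position uniformly from its IUPAC set.

Two properties matter for testing:

* **Accidental matches are not suppressed.**  Real genomes contain chance
  consensus matches; so does i.i.d. background (the degenerate Inr
  `BBCABW` matches ~1% of random windows, so with 11 candidate starts a
  noticeable fraction of background promoters acquires an accidental Inr).
  Mixture-recovery tests therefore compare against expectations corrected
  with the accidental rate measured on a zero-plant control set, under
  per-element independence.
* **Reproducibility is per-sequence.**  A single master seed drives
  everything through substreams derived from (seed, index), so enlarging n
  appends sequences without reshuffling earlier ones, and equal seeds give
  byte-identical outputs end to end.

`generate_trna_set()` builds one contig per synthetic tRNA gene in
transcript orientation — TSS, a 4–12 nt leader to the mature 5′ end, an
A-box instance at a configurable offset (+7 by default) from the mature 5′
end, a 15–30 nt variable spacer, a B-box instance and a discriminator base
5–15 nt further down — then places the gene on a random strand.  Annotations
always satisfy `tss ≤ mature5 < discriminator` in transcript orientation.
What the generator does **not** emulate: CAGE read-level noise, chromatin
or DHS signal, genuine promoter base composition (CpG islands, TATA-region
AT skew), or tRNA secondary structure beyond the two boxes.  Passing tests
therefore demonstrate correctness of the machinery, not biological claims
about real genomes.

## Problem sizes and runtimes

The shipped test-suite scales, chosen as the smallest sizes at which each
statistical check is well-powered: oracle equivalence on 100 random chain
sets; planted-element recovery at n = 2,000 (±5 jitter) and n = 500 (forced
±6); mixture recovery at n = 2,000 with a 2,000-sequence zero-plant
control (3 binomial SEs per species); landmark detection at n = 500; the
structural 16-group run at 25 promoters per group (80 unsorted profiles)
with a 40-gene tRNA set (15 profiles).  The full suite runs in well under a
minute on one CPU.

## Known limitations

* The rigidity table is a synthetic composite (above), not a published
  tetranucleotide scale.
* Consensus matching is binary; no PWM/log-odds scoring, by design.
* Element definitions ship as a transcription of the standard human set;
  the file is configuration, and the per-element `source` column is the
  audit trail.
* Profiles are descriptive: no smoothing and no significance testing of
  between-group profile differences.
* The step-value-to-first-base assignment makes k = 4 features appear up to
  3 bp upstream of their physical center.
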