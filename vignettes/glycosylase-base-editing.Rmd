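---
title: "Models and methods: guide design and outcome quantification for glycosylase base editors"
author: "gbekit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: guide design and outcome quantification for glycosylase base editors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbekit)
```

## The editing model

Deaminase-free glycosylase-based base editors (gBEs) couple a Cas9 D10A
nickase to an engineered DNA glycosylase. The glycosylase excises its
target base from the R-loop ssDNA, the nickase nicks the non-edited
strand, and repair or replication across the resulting abasic (AP) site
writes in a new base. Because the AP site is resolved by translesion
synthesis and/or replication, the product is a *mixture*: a thymine
editor (gTBE) yields predominantly T→C and T→G ("T-to-S"; S = C or G)
with a minor T→A fraction; gCBE- and CGBE-class cytosine editors yield
predominant C→G with secondary C→T; and all AP-site editors produce
indel byproducts at appreciable rates. `gbekit` models an editor as pure
data (`EditorSpec`):

* a `BaseConversion` — source base, ordered product set, and the subset
  flagged *predominant*. Design-time enumeration (guide candidates,
  codon outcomes) uses the predominant products only; minor products
  (e.g. a gTBE's T→A) are recorded but excluded, since a guide whose
  intended edit relies on a minor product is not a credible design.
* an `EditingWindow` — 1-based protospacer positions (PAM at 21–23)
  with an *editable* range (any detectable activity) and an *optimal*
  high-efficiency subrange, optionally with a single peak position.
  Editors whose characterization reports only one range carry it as both.
* a 3-letter IUPAC PAM (NGG for SpCas9; NGN selectable for SpG) and a
  nickase label (metadata).

The shipped registry (`builtinEditors()`, mirrored bit-identically by
`inst/extdata/editors.json`) covers the gTBE/gCBE family and the editors
they are commonly compared against. ABE and CBE windows are not
re-characterized by that comparison; we default both to the community
convention (optimal 4–8, editable 3–9), and use the same default for
gGBE, whose window is unpublished. All three are deliberately
config-overridable rather than asserted.

## Guide design

`scanProtospacers()` enumerates every 23-nt frame on both strands whose
positions 21–23 match the PAM (frames containing N are dropped). All
designers then reduce to one predicate: the targeted base, *as read on
the protospacer strand*, must equal the editor's source base and fall in
the requested window (`canEdit()`).

* **Splice-site disruption** (`findSpliceSiteGuides`): splice sites are
  the intronic GT donor / AG acceptor dinucleotides flanking each exon;
  non-canonical dinucleotides are flagged and excluded by default. A
  candidate is emitted for every (site, frame, dinucleotide base) triple
  passing the predicate. Any edit of either dinucleotide base is counted
  as disruptive — no splicing-strength model is attempted, since
  dinucleotide loss is treated as sufficient for exon skipping.
* **PTC introduction / bypass** (`findPtcIntroductionGuides`,
  `findPtcBypassGuides`): `codonEditOutcomes()` enumerates all
  single-base edits reachable on either strand (an antisense edit
  complements into the sense codon) and annotates translations.
  Introduction keeps stop-producing outcomes over in-frame codons,
  excluding the initiator and the natural stop; bypass keeps
  sense-codon outcomes of an annotated TAA/TAG/TGA.
* **Reporter restoration** (`predictReporterRestoration`): intron-split
  fluorescent reporters inactivate the acceptor AG by mutating its G to
  T or C, placing the mutated base at a fixed protospacer position
  (default 6); restoration requires an editor whose chemistry reaches G
  at that base. This is evaluated sense-strand-only, matching the
  reporter design in which the guide targets the mutated strand.
* **Off-target scan** (`findOffTargets`): every PAM-valid frame within a
  Hamming-distance budget of the query (default ≤ 3 mismatches, PAM
  excluded, no bulges). This is a deliberately naive re-implementation
  of the usual in-silico screening setting, suitable for the locus- and
  amplicon-scale sequences the package works with.

Candidate identity for the cross-editor Venn partition
(`classifyAcrossEditors`) is (protospacer sequence, locus interval,
strand): an sgRNA belongs to an editor's set if it is valid for at least
one targeted base, and region counts are computed over all editor
subsets, so they always sum to the union size.

**Coordinates.** All internal coordinates are 1-based inclusive
(IRanges/Biostrings convention), so GFF3 needs no conversion on input.
Minus-strand gene models are flipped to the coding strand at
construction; designers therefore always see transcription left to
right, and designing on a reverse-complemented locus yields the mirrored
candidate set (a property the test suite asserts).

## Amplicon quantification

Reads are aligned to the amplicon reference with global
(Needleman–Wunsch) affine-gap alignment via
`Biostrings::pairwiseAlignment`. Defaults — match +2, mismatch −2, gap
open −10, gap extend −1 — make a single substitution always preferable
to a gap pair, so single-event reads are unambiguous; they are exposed
in `AlignmentParams` rather than hard-coded because published amplicon
tools do not pin their scoring either. Duplicate reads are collapsed to
unique alleles before alignment and the tallies weighted by allele
count, which changes nothing statistically and makes 10,000-read sites
run in seconds.

A read is an **indel read** iff any gap event overlaps the
quantification window (protospacer ± `quantification_flank`, default 3
bp). Two denominators are always computed, because both are standard:
`with_indels` divides by all reads aligned across a position (deletion
calls included), `without_indels` by the indel-free subset. Purity and
the T-to-S ratio are ratios of conversion yields at one position:

* purity = count(T→G) / [count(T→A) + count(T→C) + count(T→G)]
* T-to-S ratio = [count(T→C) + count(T→G)] / same denominator

so ratio ≥ purity wherever both are defined, and both are reported as
absent (`NA`) on a zero denominator. No sequencing-error floor is
subtracted; if a control sample exists it can be quantified the same way
and compared, but background correction is intentionally out of scope.
Reads shorter than the quantification window are discarded and counted.

`windowProfile()` aggregates site-level per-position conversion
frequencies: the median across sites per position, the peak (ties break
toward the PAM-distal, lower position), and the inferred optimal window
as the contiguous run around the peak whose median exceeds a
configurable fraction of the peak median (default 0.5 — the natural
reading of "high-efficiency subrange", and robust here because
simulated and observed profiles fall off steeply outside the plateau).
`motifPreference()` groups each site's maximally edited base by its 5′
neighbor (AN/CN/GN/TN) and reports group means — the analysis behind
statements like "prefers AC/TC motifs".

## The synthetic-data generator

`OutcomeModel` + `simulateAmpliconReads()` generate reads the way the
outcome statistics are reported: each read draws at most one indel
(probability `indel_probability`, placed uniformly in the quantification
window, signed lengths from a small mixture of 1–3 bp deletions and 1 bp
insertions), *otherwise* draws per-position substitutions from the
probability map, then overlays uniform per-base sequencing error.
Indels and substitutions are mutually exclusive per read because
conversion and indel outcomes are reported as separate fractions; a
consequence is that substitution probabilities are conditional on
indel-free reads, so recovery checks compare the `without_indels`
estimator against the configured probabilities (the `with_indels`
estimator converges to p·(1−indel rate) by construction). Base
qualities are not simulated (constant quality on FASTQ output) and the
quantifier ignores them.

`simulateGeneModel()` builds toy loci: uniform-composition background
(GC fraction configurable), canonical GT/AG introns, a CDS forced to
start ATG and end TAA with internal stops scrubbed, an optional planted
in-frame PTC, and optional planted NGG PAMs that put a chosen
splice-site base at a chosen protospacer position on a chosen strand.
Every planted feature is recorded in a ground-truth ledger, and
infeasible placements (e.g. a PAM that would overwrite a splice
dinucleotide) error rather than silently corrupt the locus.

What the generator does *not* emulate — PCR amplification bias,
quality-correlated errors, paired-end structure, chromatin or
annotation complexity of real genes — bounds what green tests show:
they demonstrate that the estimators and designers are correct against
a known truth, not that real amplicon libraries are free of artifacts
the model lacks.

## Problem sizes, numerics, defaults

* Recovery tests use n = 10,000 reads per site and 20 replicates/sites,
  with acceptance at 3 binomial standard errors — the scale at which
  the statistics are customarily reported and comfortably computable.
* Window inference in the test suite uses 20 sites × 10,000 reads with
  per-position weights plateauing over positions 3–7 (peak 5, editable
  tail to position 11), each site carrying T at 5 of 20 positions so all
  positions accumulate coverage across sites.
* Fold changes are reported to 2 significant figures
  (`foldChange(10.2, 1.0)` = 10, `foldChange(51.4, 13.3)` = 3.9),
  matching how efficiency enhancements are conventionally quoted.
* Scanning-mutagenesis planning: the alanine scan substitutes native
  alanines with valine so every residue is covered; for the R/D/V
  schemes no fallback is defined, so native residues equal to the
  scheme target are skipped — no plan ever contains a no-op variant.
  Segment partitions are left-aligned 8-residue blocks (the last may be
  shorter); the UNG2 catalytic-domain region 98–313 yields 27 segments.
* UNG numbering: UNG2 = UNG1 + 9 everywhere in the shared domain;
  mapping UNG2 positions 1–9 back to UNG1 errors, as those N-terminal
  residues have no UNG1 equivalent.
* All randomness flows from explicit seeds (`OutcomeModel@seed`,
  `simulateGeneModel(seed=)`, `runPipeline(seed=)` fanned out
  deterministically per stage), and generator RNG state is restored
  after use, so identical configs reproduce outputs byte-identically.

## Known limitations

* Window membership is binary; per-position efficiency magnitudes are
  not modeled, so candidate *ranking* (as opposed to enumeration) is
  out of scope, as is Doench-style efficacy scoring.
* Published genome-scale candidate counts for specific human gene panels
  depend on the annotation build and isoform choices and are not
  reproducible from this package alone; the designers will re-run such
  enumerations given user-supplied FASTA+GFF3, which is the supported
  path for cross-checking published tables.
* The off-target scanner is exact and exhaustive, intended for loci and
  amplicons, not whole genomes.
* The aligner trusts `pairwiseAlignment` tie-breaking; alternative
  optimal alignments of a complex multi-indel read may place gaps
  differently than another tool would.
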