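# gbekit

Guide design and amplicon-sequencing quantification for **deaminase-free,
glycosylase-based base editors** (gTBE, gCBE, gGBE) and their
deaminase-based counterparts (ABE, CBE, CGBE-class editors).

Glycosylase-based editors fuse a Cas9 nickase to an engineered DNA
glycosylase (e.g. uracil DNA glycosylase variants that excise thymine or
cytosine). Excision leaves an abasic (AP) site whose repair yields a
*spectrum* of products — for a thymine editor predominantly T→C and T→G
("T-to-S", S = strong base) with a minor T→A fraction, plus indel
byproducts — rather than the single clean transition of a deaminase
editor. Working with these editors therefore needs tooling that is aware
of multi-product chemistries, per-editor protospacer editing windows, and
two-denominator outcome accounting. `gbekit` provides that for:

* **Editor models** — an immutable registry of editor specifications
  (conversion chemistry, PAM, editable/optimal windows, e.g. gTBEv3:
  editable positions 2–11, optimal 3–7, peak 5, PAM NGG), serializable to
  a JSON config.
* **Guide design** — enumeration of protospacer+PAM frames on both
  strands; sgRNAs that disrupt splice donor (GT) / acceptor (AG)
  dinucleotides for exon skipping; sgRNAs that introduce or bypass
  premature termination codons via codon-level edit enumeration on both
  strands; cross-editor Venn partition of candidate sets; intron-split
  reporter restoration prediction; a naive mismatch-tolerant off-target
  scanner (Hamming distance, no bulges).
* **Amplicon quantification** — global affine-gap alignment of reads to an
  amplicon reference, per-position A/C/G/T/deletion counts, conversion
  frequencies in both `with_indels` and `without_indels` denominators,
  indel frequency over a protospacer±flank window, and the two product
  statistics used for AP-site editors:

  * purity  = T→G yield / (T→A + T→C + T→G yield)
  * T-to-S ratio = (T→C + T→G yield) / (T→A + T→C + T→G yield)

  plus editing-window inference across sites (median profile, peak,
  contiguous run above a fraction of the peak) and 5′-motif preference.
* **Protein variant planning** — the UNG1↔UNG2 residue-numbering map
  (constant offset +9) and scanning/site-saturation mutagenesis library
  planners (X>A with A>V fallback, X>R/D/V, 19-variant saturation,
  8-residue segment partitions).
* **Synthetic data** — an `OutcomeModel` read simulator (per-position
  substitution probabilities, indel rate, sequencing error, ground-truth
  ledger) and a toy gene-model generator with canonical GT/AG introns and
  plantable PTCs/PAMs, so the whole pipeline is testable offline.

## Worked example

Simulate 10,000 reads from a site whose T at protospacer position 5 is
edited with p(T→G) = 0.40, p(T→C) = 0.20, p(T→A) = 0.04 and a 15% indel
rate, then quantify them:

```r
library(gbekit)
reg <- builtinEditors()
reg[["gTBEv3"]]
#> EditorSpec gTBEv3: T->{C,G,A} (predominant C,G), PAM NGG,
#>   editable window 2-11, optimal 3-7, peak 5

set.seed(7)
bases <- c("A","C","G","T")
flank <- paste(sample(bases, 20, replace = TRUE), collapse = "")
proto <- "ACGTTCATGACTGATCGTAC"           # T at protospacer position 5
ref   <- paste0(flank, proto, "AGG", flank)
model <- OutcomeModel(ref, proto,
                      sub_probs = list(`5` = c(G = 0.40, C = 0.20, A = 0.04)),
                      indel_probability = 0.15, seed = 7)
sim <- simulateAmpliconReads(model, 10000)
tab <- quantifyAmplicon(sim$reads, ref, proto)
tab
#> AmpliconOutcomeTable: 63 bp reference, protospacer 21-40
#>   10000 reads (1449 with window indel, 0 discarded)
round(conversionFrequency(tab, 5, "G"), 3)  # 0.390
round(conversionPurity(tab, 5), 3)          # 0.618
round(conversionRatioTS(tab, 5), 3)         # 0.941
round(indelFrequency(tab), 3)               # 0.145
```

The estimates recover the simulation truth: the T→G frequency (0.390 vs
0.40) is the fraction of indel-free reads calling G at position 5; purity
0.618 tracks 0.40/0.64 = 0.625 (the share of T→G among all T
conversions); the T-to-S ratio 0.941 tracks 0.60/0.64 = 0.9375; the indel
frequency 0.145 is the fraction of reads with a gap event overlapping the
protospacer ± 3 bp window.

Guide design runs off FASTA + GFF3 (or the built-in simulator):

```r
gm   <- simulateGeneModel(n_exons = 3, seed = 1)
cand <- findSpliceSiteGuides(gm$gene, reg[["gTBEv3"]], mode = "optimal")
venn <- classifyAcrossEditors(list(
  gTBE = cand,
  ABE  = findSpliceSiteGuides(gm$gene, reg[["ABE"]], "optimal")))
```

A thin command-line wrapper over the same functions is at
`inst/scripts/gbekit.R` (subcommands `simulate`, `design-splice`,
`design-ptc`, `offtarget-scan`, `quantify`, `compare-editors`).

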