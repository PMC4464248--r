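---
title: "Mining terpene synthase families: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining terpene synthase families: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpsminer)
```

# The problem

Terpene synthase (TPS) families in plants are large, tandemly duplicated,
and heavily pseudogenized. Cataloguing one from a genome assembly requires
a chain of judgements — where are TPS-like loci, what are their exon
structures, are their reading frames intact, are they expressed, which
subfamily do they belong to, and how do they relate to a sister species'
family. `tpsminer` encodes each of those judgements as an explicit,
parameterized rule so the whole chain is reproducible and, on synthetic
genomes with planted truth, measurable.

This vignette documents the models behind each stage, the tunable
parameters with their defaults and rationale, what the synthetic-data
forge does and does not emulate, and the places where a genuinely open
design choice was settled.

# Homology search

The search is a translated seed-and-extend: all six frame translations of
the genome are scanned for exact amino-acid k-mers shared with the seed
proteins, and every match nucleates an ungapped extension scored with
BLOSUM62, trimmed back to its maximum-scoring endpoints, and abandoned
when the running score falls `xdrop` below its best.

Defaults: `k = 5` residues, `xdrop = 20` (raw half-bit BLOSUM62 units),
`minScore = 50`. With ~4,000 distinct seed 5-mers, a random 5-mer hit
occurs roughly every 800 translated residues, and random extensions score
in the 20–30 range; planted exons of 25+ residues score well over 100.
The floor of 50 therefore separates signal from noise by a wide margin on
both sides. These are raw scores — no E-value statistics are attached;
the package's accuracy claims are made by planted-truth recovery rather
than score calibration, and the thresholds are all user-settable.

A design note: the classical pipeline follows ungapped extension with a
banded gapped extension. Here gapped refinement is deliberately deferred
to the model builder, which performs the actual gapped alignment against
a template CDS; at the search stage only block coordinates are needed, so
a gapped pass would add cost without changing downstream decisions.

**Chaining.** HSPs of one seed on one scaffold/strand are chained in
transcript order while the genomic gap stays ≤ `maxGap` (default 10 kb, a
generous bound on intron plus alignment slack) *and* the seed-protein
coordinates keep advancing. When the next HSP rewinds by more than
`resetTol = 50` residues, a new locus begins — this is what separates the
members of a tandem array, where copies sit a few hundred bp apart and a
pure distance rule would fuse them. Loci found by different seeds that
overlap reciprocally by ≥ 50% are redundant sightings of one gene; the
best-scoring one is kept.

**Exon filter.** True exon counts are unknown before modelling, so the
"at least three exons" rule is operationalized as ≥ 3 collapsed HSP
blocks. Filtered loci are flagged, never deleted, so the
found → filtered → confirmed accounting is always reconstructible from
the stage log.

**Reverse confirmation.** The locus peptide (best block per collapsed
region, translated in its own frame) is aligned global-locally against
every seed and every decoy; confirmation requires the best hit to be a
seed at ≥ 30% identity. The low threshold reflects the job: the reverse
search separates TPS from non-TPS, not subfamilies from each other.

# Gene models and defect counting

Models are template-guided. Chained blocks are grouped into exons: a
small genomic gap with contiguous seed coordinates is a frameshift split
*within* an exon (a 1-bp deletion moves the rest of the exon into another
frame, so the search reports it as two blocks); a gap with substantial
seed-coordinate overlap or length ≥ `minIntron = 50` bp is an intron.
Intron boundaries are then snapped to GT..AG: candidate donor/acceptor
dinucleotides within ± `snapWindow = 15` bp of the alignment breakpoints
(widened proportionally when the flanking extensions overran the intron)
are scored by aligning the resulting spliced junction against the
template CDS, and the best-scoring pair wins, ties to the smallest shift.
Junction re-scoring rather than nearest-GT matters: a random 31-bp window
contains about two GT dinucleotides, so proximity alone picks the wrong
donor roughly half the time.

Defects are counted on a local alignment of the model CDS against the
template CDS (match 2, mismatch −3, gap open 12, extend 3 — stiff gap
costs so that ~10% nucleotide divergence does not buy spurious indels):

* **Frameshifts**: indel clusters with net length ≢ 0 (mod 3). Indels
  within `collapseWindow = 30` bp collapse to their net length first so a
  single mutational event (or a compensating pair) is counted once.
* **Premature stops**: stop codons read in *template codon coordinates* —
  the alignment re-synchronizes the frame after each indel, so the
  scrambled translation downstream of a frameshift does not inflate the
  stop count. Stops at or past `prematureFraction = 0.95` of the expected
  protein length are ignored (near-terminal readthrough variants are not
  pseudogenizing), and the terminal stop is never counted. A stop codon
  read within 12 bp of an indel is also not counted: gap placement in an
  alignment is ambiguous by a few bases, and a codon read across the
  frame-repair boundary is an artifact of that ambiguity, not a
  mutation. The cost of this guard is that a genuine stop immediately
  adjacent to a frameshift would be missed — but such a pair is one
  mutational neighbourhood, and counting it once is consistent with the
  indel-collapse rule.

"Full length" for classification is template coverage ≥ 0.9, with
scaffold-edge or N-gap (≥ 50 Ns) truncation exempting a locus from the
length requirement, since missing assembly is not evidence about the
gene.

# The classification rubric

Rules fire in order: more than `maxDefects = 2` defects → category iv;
not full length → v; then expression and defect count split full-length
loci into i/ii/iii. Two cells deserve comment:

* The defect bound is ≤ 2 ("up to two"), which is the reading under
  which the category counts are internally consistent.
* Full-length, unexpressed loci with 1–2 defects are not covered by the
  four named cells; they are assigned to category iv. Without expression
  support a damaged locus has no evidence of function, so the
  conservative call is pseudogene. The fired rule is recorded in the
  `rationale` column either way.

Expression evidence is FPKM ≥ 1 in at least one tissue-replicate (the
threshold is a parameter; EST-style evidence can be injected as a boolean
override through the `expressed` column). Unknown expression is treated
as not expressed.

# Motifs

RR(x)8W, RLLR, DDxxD and NSE/DTE are scanned as position-restricted
patterns; mismatches are counted only at constrained positions (for
RR(x)8W that is R, R and W; for NSE/DTE the five constrained positions of
(N/D)-D-x-x-(S/T)-x-x-x-E, a conventional rendering since the motif has
no single canonical spelling). Search windows — starts within the first
60 residues for the N-terminal motifs, the C-terminal half for the
metal-binding motifs — prevent spurious matches in the wrong domain.
Quality is a pure function of the mismatch count: 0 → `+`, 1 → `•`,
2 → `>`, otherwise absent.

# Phylogeny and orthology

Tree building uses neighbor joining on Kimura-corrected protein
p-distances (`d = −ln(1 − p − 0.2p²)`, falling back to the raw
p-distance when `p ≥ 0.85`, where the correction is undefined).
Maximum-likelihood inference with substitution-model selection is out of
scope by design: the claims this package makes — subfamily placement,
ortholog pairing, duplication/loss structure — are distance-testable, and
the newick output remains compatible with external ML tools for anyone
who needs branch-support refinement. Bootstrap support is computed by
column resampling of the alignment, with edge support the fraction of
replicates containing the bipartition.

Alignments for ≥ 3 sequences go through the mafft progressive aligner
(FFT-NS-2, no iterative refinement — deterministic for a fixed input);
pairs are aligned exactly by global dynamic programming. Before tree
building the variable N-terminal region (all of exon 1 and the start of
exon 2, which carries chloroplast transit peptides in some lineages) is
truncated at the reference row's exon-2 midpoint; the midpoint is a
stand-in for a judgement call that has no exact published boundary, and
the fallback without an exon map drops mostly-gap columns in the
N-terminal third.

Orthologs are reciprocal best hits constrained to one subfamily, with a
70% identity floor. RBH was chosen over tree-eye inference because it is
deterministic and testable; tree-based event calling (`callEvents`) is
kept as corroboration: a same-species leaf cherry is a duplication, and a
leaf whose sister clade is purely its own species marks a candidate loss
in the other species. Pair percentages are rounded half-up to integers,
the convention of printed proportions. The identity floor doubles as the
loss criterion — a gene with no cross-species hit ≥ 70% has no surviving
counterpart at the divergence scale this package targets.

# Tandem clusters

Clusters chain same-subfamily genes (pseudogenes included — array
statistics count both) along a scaffold while the stop-codon-to-
start-codon gap stays ≤ 100 kb. The window is a reporting choice, echoed
in the output metadata, set so that biologically contiguous arrays of a
few hundred kb chain as one cluster. Density is span/n (not n−1) in kb
per gene, reported to one decimal: 317 kb holding 17 genes is one gene
per 18.6 kb. Cross-subfamily interleaving is not chained; each subfamily
is reported separately.

# Expression

FPKM matrices are transformed as log2(FPKM + 1); the pseudocount is the
standard resolution of zeros and is configurable. Bi-clustering is
complete-linkage agglomeration on Euclidean distances, rows and columns
separately, with the merge-height monotonicity that complete linkage
guarantees asserted on every run. The heatmap deliverable is data (an
ordered matrix plus two dendrograms), not an image, so tests are numeric.
Named expression clusters are a descriptive layer, not algorithmic
output; users who want discrete groups cut the dendrogram at a chosen k.

# The synthetic-data forge

`forgeGenome` emulates exactly the features the pipeline's claims rest
on, and nothing more:

* multi-exon genes from subfamily templates (7 exons for TPS-a/-b1/-b2/
  -g; 14/12/11 for TPS-c/-e/-f), GT..AG introns, intron 1 drawn longer
  and more variable (100–1,500 bp) than the others (70–300 bp);
* per-gene amino-acid divergence from the template (default 0.05/site,
  within-subfamily variation at which search sensitivity is still
  comfortably high);
* pseudogenization by injected 1-bp deletions and in-frame stop
  substitutions in the central 10–85% of the CDS, ≥ 34 bp apart so one
  injection is never double-counted; category ii genes get 1–2
  injections, category iv genes 3–5, category v genes are planted with
  only the 5' half of their exons;
* tandem runs of 2–6 same-subfamily genes, 0.5–8 kb apart, with explicit
  cluster geometry (n genes across an exact span) available for density
  worked examples;
* i.i.d. uniform-GC intergenic sequence. No repeats, no codon-usage
  realism, no sequencing reads — so passing tests demonstrate correctness
  of the algorithms under clean assembly conditions, not robustness to
  repeat-rich real assemblies, fragmented contigs or alignment-ambiguous
  deep divergence.

Default truth-category proportions (52/13/1/22/12% for i/ii/iii/iv/v)
mirror the composition observed in a genome-wide TPS survey of a woody
plant. `forgeSpeciesPair` evolves one ancestral gene set (ancestors drawn
at 0.2/site from their template so paralogs sit near ~65% identity,
below the RBH floor) through two lineages at 0.03/site each (orthologs
~94% identity, far above it), with loss and duplication probabilities of
0.1 per lineage. `forgeFpkm` assigns expressed genes to archetypes
(green-tissue-high, root-high, wood-high, constitutive, low) over the
seven-tissue, three-replicate panel and scales archetype means by
log-normal noise (sd 0.25); unexpressed genes draw FPKM < 0.5, below the
expression threshold.

Every forge records the seed, and identical configs reproduce identical
genomes and ledgers byte for byte.

# Numerical choices and degenerate inputs

* All internal coordinates are 1-based closed `GRanges`/`IRanges`;
  conversion to 0-based conventions happens only inside format writers
  (BED via rtracklayer).
* NJ tie-breaks follow ape's canonical agglomeration; negative NJ branch
  lengths are clamped to zero.
* `roundHalfUp` (half away from zero) is used wherever a printed-style
  integer or one-decimal figure is produced, avoiding banker's-rounding
  surprises at .5 boundaries.
* Constant expression matrices collapse to a flat clade (all merge
  heights zero) rather than erroring; empty gene sets propagate as empty
  results through orthology; an empty forge config yields pure intergenic
  scaffolds and an empty ledger.
* Problem sizes in the test suite: the recovery test plants 60 genes of
  all seven subfamilies on a 2 Mb, 10-scaffold genome; the two-species
  test evolves 29 ancestors; motif scanning is cross-checked against a
  brute-force oracle on 1,000 random proteins; NJ topology recovery is
  checked on 50 random additive matrices of up to 8 taxa. These sizes
  were chosen as the smallest at which the claimed ≥ 95% recovery rates
  are meaningful proportions rather than small-sample artifacts.

# Known limitations

* Non-canonical splice sites are not modelled, in the generator or the
  snapper.
* The search has no repeat masking; on repeat-rich real genomes the
  locus list would need post-filtering.
* Defect counting needs a template CDS; when only a seed protein is
  available, a back-translated stand-in CDS degrades indel placement
  near synonymous-divergent positions.
* RBH orthology is blind to synteny and to many-to-many orthology;
  duplication/loss calls are heuristics, not a reconciliation.
* Expression evidence is consumed, never computed: read mapping and FPKM
  quantification live upstream of this package.
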