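---
title: "Characterizing scleractinian mitochondrial genomes with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing scleractinian mitochondrial genomes with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

## Scope and model organisms

Scleractinian (stony) coral mitogenomes are compact circular molecules of
roughly 16–19 kb carrying 13 oxidative-phosphorylation protein-coding
genes (PCGs), two tRNAs (Met, Trp) and two rRNAs, all encoded on the
heavy (H) strand. Two features make them awkward for generic annotation
tooling: the molecule is circular, so genes may span the sequence origin,
and ND5 is interrupted by a group-I-type intron so large that ten other
PCGs and one rRNA sit inside it. mitochar characterizes genomes of this
type at the annotation level: composition and strand-asymmetry (skew)
statistics, codon usage (RSCU), pairwise Ka/Ks by the Nei–Gojobori
counting method, per-gene architecture tables with signed intergenic
spacers, and a concatenated 13-PCG supermatrix with a neighbor-joining
sanity tree. A seeded generator produces synthetic genomes with this
architecture so the entire pipeline is testable without downloads.

## Coordinates and the split ND5

Coordinates are 1-based inclusive, GenBank style. Circularity is encoded
by letting a segment end run past the sequence length — a segment
`(L-3, L+4)` wraps through the origin — rather than by splitting wrapped
features into two segments; the GenBank writer emits the equivalent
`join(start..L,1..rest)` and the reader folds it back, so the two
encodings round-trip. The origin of generated genomes sits at the first
base of tRNA-Met, the customary anchor for presenting this gene order.

ND5 is stored as two features, `ND5-5prime` and `ND5-3prime`, because
annotation tables report the exons separately; the intron is not a
stored feature, it is simply the span between them. Translation and
Ka/Ks operate on the joined exons (`pcg_sequences()` performs the join).

One accounting convention deserves emphasis. Published per-gene tables
count a product of `size/3 - 1` amino acids for *every* coding segment —
including the 5′ ND5 exon, which has no stop codon (its final codon abuts
the intron and is discarded). Summed over the 14 coding segments this
gives the published concatenated length of 3,915 aa for this
architecture, whereas translating joined ND5 as one gene would give
3,916. The supermatrix builder therefore drops the terminal codon of
every coding segment (the stop for complete genes, the intron-boundary
codon for the exons), which reproduces the 3,915-column amino-acid
matrix and keeps the nucleotide matrix at exactly three times that.

## Composition statistics

AT-skew is `(A - T)/(A + T)` and GC-skew `(G - C)/(G + C)`, computed on
counts; `N` bases are excluded from numerator and denominator, and a zero
denominator yields `NA` rather than an error. For reported tables,
percentages are rounded to 1 decimal and skews to 3 decimals (half away
from zero), the print precision of published composition tables; full
precision is kept internally.

`skew_from_percentages()` exists for desk-scale validation of printed
tables: skews are scale-free, so printed percentages determine them up to
the rounding of the percentages themselves. `audit_skew_consistency()`
recomputes every row of the bundled 14-species reference table and flags
which printed skew cells are exactly recoverable; the remainder differ in
the third decimal because their authors used unrounded counts. Only
rounding-consistent cells are meaningful printed-number checks, and only
those are asserted in the test suite.

Region profiles (`region_composition()`) pool features by class. Bases
shared by overlapping features are counted once per class, so class
counts over PCG/tRNA/rRNA/intergenic partition the genome exactly when
features do not overlap.

## Codon usage

The genetic code defaults to NCBI translation table 4 (the
mold/protozoan/coelenterate mitochondrial code): TGA encodes tryptophan
and only TAA/TAG terminate. No published table of these genomes names the
code, but the observed initiation codons (ATG, with GTG for COIII and ATA
for ND2) and the cnidarian convention force table 4; the table id is a
configuration knob throughout. RSCU is
`count * k / (family total)` over each amino-acid family of `k`
synonymous codons, with stops excluded; the six-codon families (Leu, Ser,
Arg) are treated as single families of size 6, matching how codon-usage
figures for these genomes are drawn. Families with zero usage report `NA`
rather than 0, to distinguish "unused" from "biased against".

## Ka/Ks

`ng86()` implements the Nei–Gojobori (1986) counting method with
Jukes–Cantor correction. This choice follows the common practice of the
mitogenome-characterization literature, where Ka/Ks is produced by
DnaSP-style counting rather than maximum-likelihood codon models; the
counting method is fully determined, easy to verify by enumeration, and
adequate at the low divergences of congeneric corals. Per codon, each
position contributes the fraction of its three single-base changes that
are synonymous (changes to stops count as nonsynonymous); differing
codons are classified by averaging over all mutational pathways, with
pathways through stop codons excluded and the remainder reweighted (all
retained if none survive — a degenerate case that only arises on
adversarial toys). Proportions are corrected by
`K = -(3/4) ln(1 - (4/3) p)`; `p >= 3/4` flags saturation, and the ratio
is reported only when `Ks > 0`. Sequences are compared ungapped: for
equal-architecture genomes the orthologs are length-identical, and a
length mismatch is an error instructing external alignment rather than a
silent trigger for one — auto-aligning would fabricate methodology the
analysis never states.

The test suite holds this implementation against an independently written
brute-force pathway enumerator on every ordered pair of non-stop codons,
exactly, and against exact-count mutation scenarios (below).

## The synthetic generator

`generate_genome()` emulates the merulinid architecture: canonical gene
order and sizes, all features on the H strand, published start/stop
codons per gene, ND5 split 711 + 1,104 bp with the gene-rich intron span
between the exons, and a default composition target of A 25.2, T 41.6,
G 20.3, C 12.9 per cent — the T-rich profile of these genomes, giving
negative AT-skew and positive GC-skew. Where published spacer values are
ranges, the default takes the midpoint, clipped at zero: the generator
lays genes out without overlaps, because an overlap would force shared
bases to satisfy two coding constraints at once; negative spacers are
accordingly rejected with an error rather than approximated. The default
genome is 17,170 bp — inside the published 16.5–18 kb span.

Composition targeting works by quota sampling: the free (non-start,
non-stop) codons of all PCGs are drawn as a largest-remainder quota from
the stop-excluded codon distribution whose per-base marginals are
calibrated to the targets by a short fixed-point iteration; non-coding
bases are quota-sampled from the targets directly. The achieved
composition therefore deviates from the targets only through integer
rounding and the 26 forced start/stop codons — well under a tenth of a
percentage point — and the deviation is essentially identical across
seeds, which makes composition assertions stable. The cost is realism:
within a region the sequence is an exchangeable codon soup. Real
mitogenomes have region-specific composition (T-dominant PCGs,
A-dominant RNAs), autocorrelated composition along the molecule, and
structured RNA genes; none of this is emulated, so passing composition
tests demonstrates correct counting arithmetic, not that the generator
fools a biologist. An optional `pos3_t_bias` knob reweights T at third
codon positions to emulate the stronger third-position bias of real
coding sequence, for tests that need codon-position contrasts.

`mutate_cds()` applies exactly `k_syn` synonymous and `k_nonsyn`
nonsynonymous single-base substitutions, never creating a stop; with
disjoint sites (one substitution per codon) an NG86 recount recovers the
counts exactly, which is the sharpest possible oracle for the difference
counting. `evolve_on_tree()` runs Jukes–Cantor substitution along a
phylogeny (the per-branch kernel is the exact JC transition, so distances
compose correctly); start and terminal stop codons are held invariant and
internal substitutions that would create a stop are redrawn among allowed
bases, so evolved genomes still pass every validator. Both are seeded;
all package randomness flows through one explicit seed with the caller's
RNG state restored afterwards.

## Supermatrix and tree

`build_supermatrix()` concatenates the 13 genes in circle order at
nucleotide or amino-acid level, with partitions recorded and exported as
a NEXUS charset block (FASTA and relaxed PHYLIP writers are also
provided). `nj_tree()` computes p- or Jukes–Cantor distances (4-state for
nucleotides, 20-state for amino acids) and runs neighbor joining; taxa
are sorted by label before distance computation so the output is
invariant to input order. This tree is pipeline plumbing — a sanity check
that concatenation preserved signal — not a substitute for model-based
phylogenetics, which is deliberately out of scope.

## Problem sizes and numerical choices

The default test and acceptance runs use full-size synthetic genomes
(~17 kb), 20-seed batches for composition and topology-recovery checks,
six-taxon trees with branch lengths of 0.05–0.1 substitutions/site, and
the complete 62 x 62 codon-pair sweep for the counting oracle; the whole
suite runs in about a minute on one core. Ties in reported rounding are
broken half away from zero (`round_half_up()`), matching printed tables
rather than R's round-half-even. Degenerate inputs are errors with named
context (all-N sequences, empty region classes, length-discordant
orthologs, internal stops), not silent repairs.

## Known limitations

- The GenBank reader targets the minimal single-record dialect this
  pipeline writes plus common annotation spellings; it is not a general
  GenBank parser (no multi-record files, no qualifier continuation
  lines spanning sequences, no de novo gene naming).
- Ka/Ks is NG86 only; no codon-frequency corrections or ML variants.
- The generator does not emulate gene overlaps, indels, or structured
  RNA; tRNA/rRNA regions are compositionally realistic only in aggregate.
- Per-gene GC% of generated genomes scatters around the genome-wide
  target rather than matching each gene's published GC% individually.
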