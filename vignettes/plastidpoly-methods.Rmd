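---
title: "Methods: plastome structure, diversity and heteroplasmy in plastidpoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome structure, diversity and heteroplasmy in plastidpoly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind each analysis
stage, the parameters that matter, and the choices made where the design
was genuinely open. Everything empirical stated here is computed by the
test suite or by `scripts/acceptance.R`; nothing is quoted from outside
the package.

## The biological setting

Angiosperm chloroplast genomes are circular, 120–160 kb, and almost
universally quadripartite: a large and a small single-copy region (LSC,
SSC) separated by two identical inverted-repeat copies (IRa, IRb).
Because a plant cell carries many plastome copies, deep sequencing of
one individual samples a *population* of organelle genomes; positions
where a second allele segregates within that population (heteroplasmy)
appear in read pileups as minor alleles. The package treats the assembled
genome as the major-allele consensus and studies (i) its structure and
repeat content, (ii) its divergence from other genomes, and (iii) the
minor-allele landscape across strains.

## Coordinate conventions

All coordinates are 1-based inclusive; genomes are circular and a
feature or interval may wrap the origin (`start > end`). The canonical
rotation places the first LSC base at position 1 with region order
LSC–IRa–SSC–IRb. The canonical strand is chosen by annotation when
available (a `psbA`-like gene, by convention the first LSC gene on the
plus strand, must be `+`), and otherwise by the lexicographically
smaller of the two candidate LSC sequences — an arbitrary but
deterministic rule, so that rotated or reverse-complemented inputs yield
byte-identical canonical output (a property the tests assert).

## Inverted-repeat detection

Detection seeks the *maximal-length pair of exact inverted repeats* that
partitions the circle into four arcs. The implementation seeds exact
32-mer matches between the genome and its reverse complement, groups
seed pairs by anti-diagonal (an exact inverted-repeat pair keeps
`i + j` constant), and extends one representative per anti-diagonal in
both directions, capping extension so the two arms never meet (each arc
must retain at least one base). The longer single-copy arc is labelled
LSC. Two equal-length, non-identical maximal candidates raise an
ambiguity error listing both; no candidate at least `min_ir_len`
(default 1000, minimum 100) raises a "no quadripartite structure"
error. Tests verify detection against an O(n²) anti-diagonal oracle and
assert the tiling and reverse-complement invariants on 200 random
synthetic genomes. Only exact IR copies are supported: the species this
tooling targets have identical IRs, and mismatch-tolerant IR detection
is explicitly out of scope.

Junction reporting computes, for each of the four boundaries, the gene
crossing it (or the nearest gene within a configurable 1000-bp window)
and the length of that gene's overlap with the adjacent IR copy — the
ψ-fragment length that IR duplication creates from junction-spanning
genes. The report states what it finds at each boundary rather than
assuming which gene belongs where, since IR expansion and contraction
move these junctions between species.

## Tandem-repeat scanning

Both scanners enumerate *maximal perfect* tandem repeats via the shifted
self-comparison `x[i] == x[i+u]`: a maximal run of matches of length m
at shift u is a perfect tract of m + u bases, reported with
`floor((m+u)/u)` whole copies anchored at the tract start (the phase of
first occurrence). Units that are themselves periodic are suppressed in
favour of their primitive unit, `N`-containing windows are skipped, and
on circular genomes the sequence is scanned doubled so an
origin-spanning repeat is reported once with a wrap flag. Rule defaults:
SSRs are homopolymers with total ≥ 10, or units of 2–6 bp with ≥ 3
copies and total ≥ 10; long repeats are units ≥ 7 bp with ≥ 3 copies and
total ≥ 20. The long-repeat rule is a configurable default chosen to
reproduce the published long-repeat inventories (smallest listed case:
a 7-bp unit × 3 = 21 bp); neither rule is hard-coded. Compound-repeat
merging (as in MISA) is deliberately not implemented: the target
inventories list simple repeats. The scanner is validated against an
exhaustive oracle that tests every (start, unit-size) pair on 50 random
2-kb sequences.

## Orthologous fragments, NP/ND and Ka/Ks

Two annotated genomes are cut at the exon boundaries of their
protein-coding genes; intervals flanked by the same exon anchors pair
up. Exons pair as CDS fragments; a between-exon gap is an intron when
both anchors belong to the same gene copy and an intergenic spacer
otherwise. Exons present in one annotation only are dropped and listed
in a skipped-anchor report; inconsistent anchor order is an error (it
signals rearrangement, which this machinery does not model).

Each fragment pair is globally aligned with affine gaps (defaults match
+1, mismatch −1, gap open 5, gap extend 1 — configurable, since no
standard exists for these inputs), and alignments are concatenated per
region × class. `NP` counts columns with two differing bases; `ND` is
NP over ungapped comparable columns (p-distance). Columns involving
IUPAC ambiguity codes are excluded from both numerator and denominator.
`TOTAL` rows sum NP and compute ND over the pooled columns, i.e.
length-weighted. IR categories are computed on one IR copy (IRa) so the
duplicated copy is not double-counted; which copy is immaterial because
the copies are exact reverse complements.

Ka/Ks uses Nei–Gojobori (1986) with Jukes–Cantor correction rather than
a model-averaged estimator: synonymous site counts per codon are the
fraction of one-step changes that preserve the amino acid (changes to a
stop codon count as nonsynonymous, which keeps syn + nonsyn sites
exactly 3 per codon); substitution counts between differing codons are
averaged over all minimal mutational pathways with equal weights,
excluding pathways through intermediate stop codons (falling back to all
pathways in the rare case every one is excluded); `d = −(3/4)·ln(1 −
4p/3)` is applied separately to pS and pN; and the Ka = Ks test is a
two-tailed z-test with the delta-method variance `9p(1−p) /
((3−4p)²·sites)`. Identical orthologs report Ka = Ks = 0 with ratio NA,
matching the convention of reporting NA for invariant IR genes. The
NG86 choice means published model-averaged values are matched
approximately, not bit-exactly; the per-codon machinery itself is
validated against an independent pathway-enumeration oracle on 1000
random codon pairs, and the z-test's rejection rate under neutral
simulation is checked to sit at the nominal 5% ± 2% over 1000
replicates (200 codons, 15 substitutions per lineage — enough
divergence for the large-sample variance to be usable).

## Within-species variant calling

Whole-plastome comparison assumes near-identical inputs (guarded at 95%
alignment identity; more divergent pairs are directed to the
orthologous-fragment machinery). A full affine dynamic program over two
156-kb sequences is quadratic and unnecessary at this identity, so the
aligner is anchored: a 64-mer occurring exactly once in each genome near
the midpoint splits the problem recursively, and segments below 3 kb are
aligned with the affine-gap aligner. Gap runs merge into single indel
events (so an n-base gap is one event, matching the indel/substitution
dichotomy of variant tables); adjacent insertion+deletion runs convert
into single-base substitutions; indels are left-normalised against the
reference (VCF-style, anchor base included) so placement inside
homopolymers is deterministic; multi-base substitutions are reported as
adjacent single-base substitutions. Positions where one genome carries
an IUPAC ambiguity code consistent with the other genome's base are
excluded from the variant list (they are unresolved sequencing, not
variation) and tallied separately. Each variant carries its reference
homopolymer run length (0 when the run is a single base), feeding the
repeat-context profile that counts indels inside runs of ≥ 5 — the
classic slippage signature.

## Minor-allele calling and classification

A pileup column yields a site when depth ≥ `depth_min` (default 10 — a
package decision; the source protocols state no explicit floor) and the
second-most-frequent allele has frequency ≥ `maf_min`, inclusively, so
a 5/95 column is called at the 0.05 cutoff. Ties for the major allele
break lexicographically. Indel minor alleles additionally require ≥
`indel_depth_min` reads (default 5, mirroring the common mpileup indel
floor). The threshold tiers 0.01 / 0.05 / 0.1 give nested site sets by
construction (asserted as a property); 0.05 is the conventional cutoff
separating credible heteroplasmy from sequencing error and
organelle-to-nucleus transfer artefacts, which this package handles
solely via the threshold. Sites are keyed by (position, minor allele)
for cross-strain work. Both IR copies are reported with per-copy counts
kept separate; `collapse_ir_pairs()` maps IRb sites onto their IRa
mirror (complementing base alleles) when single-counting is wanted.
Coding effects substitute the minor allele into its codon,
strand-corrected and exon-aware, under the bacterial/plastid genetic
code (table 11), validated against a whole-CDS retranslation oracle.
Display densities (sites per kb) round half-up to two decimals —
ordinary round-half-even would misreport borderline values.

## MAF phylogeny

The strain × site MAF matrix assigns 0 where a strain lacks a site
(absence of the minor allele is information, not missingness). The
distance is Euclidean by default (Manhattan available); no standard
exists for distances on MAF profiles, so the choice is exposed as
configuration. UPGMA is implemented directly: merge the closest pair,
update distances by size-weighted average (the arithmetic mean over
member pairs), node height = merge distance / 2, ties broken by
lexicographically smallest member label so leaf-order permutations can
never change the topology. The result is ultrametric by construction;
`stats::hclust(method = "average")` serves as an independent
cross-check in the tests, and recovery on planted ultrametric matrices
is exact (100/100 random trees up to 8 leaves). The outgroup attaches
above the ingroup root at half the supplied divergence, which must
exceed the ingroup height; Newick branch lengths are height
differences.

## The synthetic-data generator

`simulate_genome()` builds LSC + IRa + SSC + revcomp(IRa) over i.i.d.
bases at the requested GC (default 0.38, the AT-rich regime typical of
plastomes), with defaults LSC 8000 / SSC 2000 / IR 3000 — a 16-kb
miniature that preserves every structural feature at roughly 1/10 scale
while keeping the test suite fast; the methods do not depend on genome
size. Planted protein-coding genes are valid ORFs (start codon, no
internal stops, terminal stop) written into the sequence on either
strand, with codons weighted by the background base composition so
coding regions do not distort genome GC; one gene is multi-exon on each
strand class, genes inside IRa are mirrored into IRb with flipped
strand, and one gene crosses each of the LSC/IRa and SSC/IRb junctions
with recorded IR overlaps (300 and 240 bp) to exercise ψ-fragment
reporting. Planted repeats get flanking bases forced off-phase so they
are maximal exactly as recorded, and the region-boundary bases are
adjusted so the planted IR pair cannot extend by chance — otherwise
roughly a third of seeds would report an IR one or two bases longer
than planted.

`simulate_heteroplasmy()` draws per-position depth ~ Poisson(coverage),
minor-allele counts ~ Binomial(depth, MAF) at designed sites, and
errors ~ Binomial(depth, error_rate ≤ 0.01) spread uniformly over the
three non-reference bases elsewhere. `simulate_strain_family()` evolves
a root MAF vector (uniform on [0.08, 0.42], 200 sites) along the fixed
topology ((A,B),(C,D)) by Gaussian perturbations truncated to [0, 0.5]
— one clade-level draw per clade (sd 0.10) and one strain-level draw
per strain (sd 0.02), a 5× separation of between- to within-clade
scales. All randomness flows from one explicit seed; identical seeds
give byte-identical outputs.

What the generator does *not* emulate — mapping bias, duplicate reads
surviving deduplication, overdispersed coverage, nuclear/mitochondrial
plastid-like sequences, imperfect IR copies — bounds what passing tests
show: they demonstrate correctness of the algorithms on clean evidence
conforming to the stated models, not robustness to upstream artefacts
of real short-read data.

## Numerical and degenerate-input choices

- Round-half-up at 2 decimals for displayed densities; all internal
  arithmetic is double precision, unrounded.
- Empty diversity categories report ND = NA (0/0 is undefined, not 0).
- Zero-depth pileup columns are skipped with a warning; depth is always
  recomputed from allele counts on ingestion.
- Alignment of an empty fragment against a non-empty one is all-gap and
  contributes nothing to NP or the ND denominator.
- UPGMA tie-breaks and the no-annotation strand rule are lexicographic:
  arbitrary, but deterministic and permutation-stable.
- `jukes_cantor()` returns NA at p ≥ 0.75 (saturation) rather than an
  error; Ka/Ks ratio is NA when Ks = 0.

## Problem sizes used by the tests

The suite runs entirely on synthetic data: 16-kb genomes for
integration tests, 2-kb sequences for exhaustive-oracle comparisons (50
sequences for SSR rules, 12 for long-repeat rules), 200 random
quadripartite genomes for structure invariants, 1000 random codon pairs
for the NG86 oracle, 1000 neutral replicates for the z-test calibration,
coverage 1000 for MAF-recovery checks, and 100 seeded replicates each
for ultrametric-tree recovery and strain-family topology recovery.
These sizes make every check statistically meaningful while keeping a
full run in the low minutes. One acceptance test targets real GenBank
accessions and requires a one-time download described in
`inst/extdata/accessions/README.md`; it reports failure when the files
are absent.

## Known limitations

- Exact-match IRs only; species with diverged IR copies will report "no
  quadripartite structure" at the default threshold.
- The within-species variant caller's event decomposition (and hence
  the substitution/indel split) is one deterministic convention among
  several defensible ones; counts of *substitutions* are robust, indel
  event counts can differ by one where an insertion directly abuts a
  deletion.
- NG86 is a counting method: at very low Ks the Ka/Ks ratio is
  unstable, and genes with zero synonymous differences report NA rather
  than an inflated ratio.
- UPGMA assumes clock-like evolution of MAF profiles; it is the right
  tool for the within-species clustering it serves here, not a general
  phylogeny estimator.
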