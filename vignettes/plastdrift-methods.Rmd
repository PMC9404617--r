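---
title: "Methods: quantifying plastome degradation in holoparasites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying plastome degradation in holoparasites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastdrift)
```

## The problem

Plastid genomes of photosynthetic plants are strongly conserved: a circular
molecule of 120–160 kb with a quadripartite layout — a large and a small
single-copy region (LSC, SSC) separated by two identical inverted repeats
(IRb, IRa) — and a stable complement of roughly 80 protein-coding genes.
Holoparasitic plants have abandoned photosynthesis, and their plastomes decay
along predictable lines: photosynthesis genes are deleted or pseudogenized,
the SSC can contract to a few hundred bases, the IRs expand or shrink, and
intergenic spacers (IGS) accumulate substitutions fast enough to carry
species-diagnostic sites. `plastdrift` implements the comparative workflow
that quantifies this decay and turns it into PCR-ready barcode markers, plus
a seeded simulator that generates degraded plastomes with a complete truth
manifest so every stage of the workflow is testable offline.

## Quadripartite detection and junctions

`detect_inverted_repeat()` finds the longest pair of *exact* maximal
inverted repeats by seeding 31-mers of the sequence against its reverse
complement and extending matches maximally. Exact matching is a deliberate
choice: assembled plastomes carry two literally identical IR copies, so a
mismatch-tolerant aligner buys nothing and costs determinism. Because an IR
arm may straddle the arbitrary origin of a circular record, detection runs on
two rotations half a genome apart and keeps the better result; a planted-IR
property test asserts that every rotation of the same molecule yields
identical region lengths.

The longer region between the arms is labelled LSC, the shorter SSC, and the
genome is rotated so LSC starts at coordinate 0 with order LSC–IRb–SSC–IRa.
Ties between equally long repeat pairs are broken by minimal SSC length, then
by smallest start coordinate. A junction is the coordinate of the first base
of the downstream region (all internal coordinates are 0-based half-open), so
a gene ending exactly at a junction has distance 0 — the convention every
junction-distance figure in this field uses, made explicit.
`min_len` defaults to 1000 nt; real holoparasite IRs below ~6 kb are still
well above this, while spurious short repeats stay below it.

## Gene census

Each protein-coding gene of a non-degraded reference is classified in each
target as **present**, **pseudogene** or **lost**. The field's rule is
qualitative — a gene is a pseudogene when truncated or frameshifted relative
to the reference, lost when missing — so the quantitative cutoffs are package
parameters (`census_thresholds()`), not hidden constants:

* hit acceptance: best local alignment with identity ≥ 0.6 covering ≥ 30%
  of the reference CDS; below that the gene is *lost*;
* *frameshift*: an internal alignment indel run whose length is not a
  multiple of 3;
* *premature stop*: an in-frame stop before the final 5% of codons (the
  grace window tolerates annotation slop around the true stop);
* *truncated*: aligned coverage of the reference CDS below 0.9.

The similarity search runs `Biostrings::pairwiseAlignment()` (local, both
strands, subject extended across the circular origin); an exact full-length
match short-circuits to *present*. The local alignment doubles as the refit:
non-homologous reference ends are clipped and counted as missing coverage
rather than forced into noisy terminal alignments. Inverted-repeat gene
copies collapse to one symbol (`normalize_gene_name()`), and when several
copies exist the best status wins — one intact copy means a functional gene.

Degradation ratios divide lost (pseudogene) counts by the number of
reference PCGs; the denominator is always reported, never hard-coded.
Species are clustered on the ratio vectors with UPGMA
(`stats::hclust(method = "average")` on Euclidean distances), exported as
Newick via `ape`; a naive O(n³) agglomeration in the test suite serves as
the independent oracle.

## Spacer divergence (K2p)

Spacers are enumerated between consecutive genes on the canonical rotation;
a spacer is *shared* when the same unordered flanking-gene pair bounds a
spacer in every genome, and occurrences with reversed flank order are
reverse-complemented before comparison (otherwise an inversion masquerades as
divergence). When an IR-duplicated adjacency yields the same flank pair
twice, the first occurrence on the canonical rotation is used.

Every species pair is aligned per spacer with an affine-gap
Needleman–Wunsch (match +2, mismatch −1, gap open 10, gap extend 2 — the
classic ClustalW-style DNA settings; a run of *L* gaps costs
`open + (L−1)·ext`). The aligner lives in `src/` with a fixed traceback
preference (diagonal, up, left) so reruns are byte-identical; tests check its
scores against exhaustive enumeration on tiny strings and an independent
plain DP on random pairs. The Kimura 2-parameter distance

\[ d = -\tfrac12 \ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right] \]

uses transition (P) and transversion (Q) proportions over columns with two
unambiguous bases; gapped or ambiguous columns are excluded from the site
count, and `(1−2P−Q) ≤ 0` or `(1−2Q) ≤ 0` is reported as saturation.
Regions are summarized by min/mean/max over species pairs (the ×100 scaling
mirrors how distmat-style tools print percentages — presentation only) and
ranked by mean. Exact reproduction of any published K2p value is not claimed
— those depend on the original alignment binaries — only the ranking
behaviour, which the planted-hypervariable-spacer test pins down.

## dN/dS screening (NG86)

Shared present genes are codon-aligned (translate, progressively align the
proteins on a UPGMA guide tree, back-thread nucleotides so every gap is a
multiple of 3 on a codon boundary) and each species pair is scored with the
Nei–Gojobori (1986) counting method: per-codon synonymous site fractions
from the three possible changes at each position, multi-hit codons averaged
over all minimal substitution pathways with pathways through stop codons
excluded, and Jukes–Cantor correction `d = -3/4 ln(1 − 4p/3)`. Two
conventions the original description leaves open are fixed as follows:
changes that create a stop codon count as nonsynonymous in the site
fractions, which keeps `S + N = 3 × codons` exactly; and when every pathway
between two codons passes through a stop, the unrestricted average is used
rather than dropping the codon. A proportion at or beyond 0.75 saturates the
correction; the affected rate becomes `NA` with a warning instead of
aborting the whole gene (a single synonymous codon difference already
saturates dS at one-codon scale while dN remains exactly 0). A brute-force
pathway-permutation enumerator in the tests checks all counts exhaustively
up to 10 codons. Genes with median pairwise ω > 1 are flagged as
positive-selection candidates; this is a screen, not a likelihood test —
branch-site machinery is out of scope.

## Barcode markers

Within one locus (typically the most divergent shared spacer), a
*diagnostic SNP* is an alignment column where exactly one species differs
from an otherwise unanimous background, and a *diagnostic indel* is a
maximal gap run private to one species, counted as one site regardless of
width. Columns containing ambiguity codes are skipped. Primer discovery is
deliberately strict and simple, mirroring zero-mismatch taxon-coverage
tools: enumerate all alignment windows of primer length (default 20 nt)
that are fully conserved — no substitutions, no gaps — across all species
and pass a GC-fraction filter of 0.3–0.7 (primer thermodynamics beyond that
is intentionally out of scope; the downstream validation step in practice is
PCR, not a Tm model), then pair windows whose product length lies within
100–1000 nt in *every* species, score pairs by enclosed diagnostic sites,
and keep non-overlapping top candidates. Reported primers are re-scanned
verbatim against the raw, unaligned sequences as an invariant. A species
pair counts as discriminated when some retained candidate encloses a site
private to either of them, so the all-pairs success flag requires every
species pair to be separated by at least one site — which holds exactly when
at most one species lacks a private site.

### Alignment normalization

Progressive MSAs of near-identical sequences can place equivalent-score gaps
inconsistently across merge steps, manufacturing spurious "private" columns.
`build_msa()` therefore (1) runs two deterministic leave-one-out refinement
passes, (2) merges adjacent complementary columns — two half-gap columns
that no row occupies simultaneously become one substitution column, the
representation an optimal aligner prefers whenever a gap costs more than a
mismatch — and (3) repositions split gaps: when two nearby columns carry
gaps for disjoint row sets with gap-free columns between, the minority gaps
move onto the majority column if that does not increase mismatches. A side
effect of (2) is that independent single-base insertions by two species at
the same position are represented as one substitution column rather than two
private indels; at the divergence levels this package targets that trade is
strictly conservative for diagnostic-site calling.

## The simulator and what passing tests mean

`simulate_plastomes()` builds a reference as LSC–IRb–SSC–IRa from region
strings: valid random ORFs (start codon, sense codons, stop) with real
plastid gene symbols, tRNA placeholders, an rRNA-like block duplicated in
the IRs, and random spacers. Degradation applies, in order: deletions,
pseudogenization (frameshift, premature stop, truncation), a signed IR
boundary shift that duplicates or releases sequence while keeping
IRa = revcomp(IRb), an optional SSC inversion, and intergenic point
mutations with transition probability κ/(κ+2). Defaults are toy-scale —
~18 kb, 30 PCGs, four species with 3–6 deletions, 4–6 pseudogenizations,
IR shifts of ±60–150 nt, IGS substitution rate 0.02 and κ = 2 — values a
comparative plastome study of congeneric holoparasites would call
realistic in miniature; they keep the full pipeline under a minute. One
long (400 nt) spacer is always created, and its flanking genes are kept
intact in every species, because marker design presupposes conserved
anchors.

Determinism is a contract: a single master seed derives per-stage and
per-species substreams (hashed from the species id, so adding a species
never perturbs the others), and same-seed reruns are byte-identical through
the entire pipeline. Two construction details matter for exactness. First,
the generator forces the bases adjacent to the planted IR boundaries not to
extend the repeat by chance, so detected junctions equal planted junctions
*exactly* rather than off-by-one on ~1/4 of seeds. Second, planted
frameshifts sit in the first 70% of the CDS: an indel in the final few
codons is invisible to any coverage-based rule (the local aligner clips a
handful of terminal bases), so placing it there would make 100% recovery
unattainable by construction rather than by implementation error. For the
same reason, `plant_marker()` adjusts two bases around each planted 3-nt
deletion so the deletion window has a unique alignment placement.

What the synthetic data does **not** emulate: codon-usage bias, rate
heterogeneity along the genome, gene transfers to the nucleus, multi-exon
genes, annotation errors, or phylogenetic structure (species radiate
star-like from the reference). Passing the planted-truth suite therefore
shows the *algorithms* recover what they are defined to recover; it does not
certify behaviour on noisy real annotations, where the census thresholds
are the knobs to revisit.

## Numerical and degenerate-input choices

* All coordinates 0-based half-open internally; GenBank I/O converts at the
  boundary, BED passes through unchanged.
* `N` and IUPAC codes are preserved on read and excluded from every distance
  count and diagnostic column.
* Zero-length spacers in any species exclude a region from ranking; a
  species pair whose spacer comparison saturates is skipped with a warning,
  and the region is dropped only if no pair is computable.
* Genes present in fewer than two species are skipped by the dN/dS screen
  with a warning; ω is `NA` when dS = 0.
* Empty sequences, references with internal stops, overlapping IR arms, and
  genomes shorter than `2 × min_len` are rejected with specific errors.

## Problem sizes

The test suite and the acceptance script run on toy genomes of 8–18 kb with
10–30 protein-coding genes, 2–4 degraded species, 20–25 simulation seeds
for recovery rates, 10 kb sites for K2p consistency, and brute-force NG86
checks up to 10 codons — sizes chosen so the whole battery completes in a
few minutes while every planted quantity is still recovered exactly.

## Known limitations

* IR detection is exact-match only; assemblies with polymorphic IR copies
  would need the (unimplemented) mismatch-tolerant mode.
* The progressive MSA is a general-purpose small-n aligner, not a
  large-alignment tool; beyond ~20 sequences or very divergent inputs a
  dedicated MSA program is the right choice.
* The dN/dS screen is a counting method with JC correction; it ignores
  transition/transversion bias and codon frequencies, and is reported as a
  screen for candidates, not as evidence of selection.
* Primer scoring ignores melting temperature, hairpins and dimers beyond the
  GC filter.
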