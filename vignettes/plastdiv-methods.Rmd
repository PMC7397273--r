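---
title: "Screening chloroplast genomes for high-variation marker loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening chloroplast genomes for high-variation marker loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastdiv)
```

## The problem

Many plant groups — cacti are a notorious example — radiated recently
enough that the classic chloroplast markers (*trnL-trnF*, *trnK-matK*,
*psbA-trnH*, the *rpl16* intron) carry too little variation to resolve
species-level phylogenies. When complete, annotated chloroplast genomes
are available for a handful of congeneric species, a comparative screen
can rank every shared locus by its observed divergence and nominate new,
group-specific markers. `plastdiv` implements that screen end to end:
repeat content, microsatellite (SSR) content and cross-species homology,
a shared locus catalogue, a per-locus percent-variation statistic, and a
marker ranking with a practical amplicon-length filter.

## Inputs and the structural partition

Genomes enter as GenBank flat files (or FASTA plus a feature TSV) and are
held as `plastome_record` objects: a circular DNA string plus a feature
table in 0-based half-open coordinates, with origin-wrapping features kept
as a single span. The quadripartite LSC/IRa/SSC/IRb partition is inferred
by `infer_region_map()` as the longest pair of disjoint, *exactly*
reverse-complementary segments on the circle (at least `min_ir_len`
= 1000 bp by default; `N` never matches). Exact matching is deliberate:
the structural partition anchors region assignment for SSRs and loci, so
it must not drift with a mismatch budget. A genome without such a
duplication gets a degenerate all-LSC map, flagged as such — some taxa
genuinely have reduced or divergent IRs. Spans are assigned to regions by
the circular midpoint rule, and both IR copies share the label `IR`.

## Repeats

`find_repeats()` enumerates maximal repeated pairs of the four classic
orientation types — forward, reverse, palindromic (reverse complement)
and complement — with a Hamming mismatch budget, defaulting to the
standard screen settings: minimum length 30 bp, at most 3 mismatches. A
pair is *maximal* when extending both endpoints jointly one base in
either direction would exceed the budget or leave the sequence. The
implementation seeds on exact k-mers (k = `min_len %/% (max_mm + 1)`, so
the pigeonhole principle guarantees every qualifying pair contains a
seed) and enumerates maximal windows from mismatch positions around each
seed cluster. Correctness is owed entirely to the brute-force oracle in
the test suite, which walks every diagonal of the comparison and checks
maximality by definition; the suite asserts exact set equality on
hundreds of random sequences for budgets 0, 1 and 3.

The two structural IRs are themselves one giant palindromic pair. The hit
is real and is reported, but it is flagged `ir_artifact` when it
coincides with the inferred IR arms (at least 90% reciprocal overlap), so
type-count summaries can include or exclude it explicitly. The scan runs
on the linearized published sequence; repeats spanning the origin are not
searched, matching how such screens are conventionally run.

## SSRs

`scan_ssrs()` reports perfect, simple microsatellites only: maximal
tandem runs of a primitive 1-6 bp motif meeting the per-motif-length unit
thresholds 10 (mono), 6 (di) and 5 (tri- through hexanucleotide). A run
that satisfies thresholds at two motif lengths (12 x A is also 6 x AA) is
reported once, at the primitive motif; phase-rotated re-reports collapse
to the leftmost phase; runs break at `N`. Motifs are classified by
`canonical_class()`: the lexicographically smallest string among all
rotations of the motif and of its reverse complement names the class
(`TTC` is a rotation of `CTT`, so its class is `AAG/CTT`), making counts
invariant under strand and phase. Compound or interrupted SSRs are out of
scope by design — the tabulated categories of comparative plastome
screens are simple classes.

Cross-species homology of SSRs is not something an annotation gives you;
`plastdiv` construes two same-class SSRs in different genomes as
homologous when both 100 bp flanking windows align at 80% identity or
better (both knobs exposed), and takes connected components as groups. A
group is `shared_by_all` when every input species contributes a hit and
`length_variable` when members differ in span — the property that makes
an SSR a candidate length-polymorphism marker.

## The locus catalogue and the divergence statistic

`derive_loci()` turns each annotation into a locus list: one locus per
gene (the strand-corrected union of its exons), one per intron, one
intergenic spacer (IGS) per nonempty gap between consecutive features
around the circle (named `A-B` in genome order; overlapping features
yield none), and pseudogene loci. tRNA anticodon suffixes are stripped
for naming, IR-duplicated names are disambiguated by structural arm, and
IGS names match their reversal (`A-B` = `B-A`) so that strand and
rotation differences between genomes do not break homology.
`intersect_across_species()` keeps the loci named in every genome.

Each shared locus is aligned for every unordered species pair (21
comparisons for seven species) and scored by `count_divergence()`:

> pct = 100 x (NS + ID) / L

where `NS` counts columns with two differing bases, `ID` counts indel
*events* — one maximal run of contiguous gap columns counts once,
whatever its length — and `L` is the alignment length in columns. The
per-locus score is the plain arithmetic mean over pairs. Two worked
alignments pin the statistic down: `ACGTACGT` vs `ACCTA-GT` gives
NS = 1, ID = 1, L = 8, pct = 25.0; `AAAA----TT` vs `AAAACCCCTT` gives
NS = 0, ID = 1, L = 10, pct = 10.0. `L` is the alignment length rather
than the unaligned locus length: `NS` and `ID` are alignment-defined, so
the denominator must be too. Columns pairing `N` with a base count
neither as substitutions nor against `L`'s definition; this is the
conservative reading of ambiguous bases.

Pairwise alignment is global with affine gaps (match +1, mismatch -1,
gap open -2, gap extend -0.5), delegated to
`Biostrings::pairwiseAlignment()`; an independent quadratic Gotoh dynamic
program in the test helpers verifies score optimality on short sequences.
The pair is canonically ordered before aligning, which makes NS/ID/L
exactly symmetric in the species pair without constraining the traceback.
Externally produced pairwise alignments (e.g. from MAFFT) can be supplied
verbatim through the `alignments` argument, so the statistic can be run
unchanged on an external aligner's output. Substitution-model-corrected
distances are deliberately not offered: the statistic is an uncorrected
p-distance plus indel events, and transitions and transversions weigh
equally.

`rank_loci()` orders loci by mean percent variation (ties: longer average
length first, then name) and flags the top 20 plus an amplicon screen
(average unaligned length 150-1000 bp — the range that Sanger sequencing
of a single PCR product handles comfortably). `export_supermatrix()`
concatenates selected loci — per-locus multiple alignments built by
progressively merging pairwise alignments onto the first species, which
is adequate for near-identical plastome loci — and writes FASTA, relaxed
PHYLIP and a RAxML-style partition table. Model-based tree inference is
out of scope; `nj_sanity_tree()` offers a neighbor-joining check only.

## The simulator and what passing tests mean

`simulate_plastomes()` generates the study conditions the screen assumes:
by default seven species on a balanced ultrametric tree (root-to-tip
depth 0.5), ~120 kb circular genomes with 18 kb IRs (IRb the exact
reverse complement of IRa, mutated in concert) and a 15 kb SSC, 90 named
genes drawn from real plastid gene pools (a few with introns, one
pseudogene, tRNA names with anticodon suffixes), per-locus substitution
rates — genes 0.001-0.01, spacers and introns 0.005-0.08 expected
substitutions per site root-to-tip, matching the empirical pattern that
non-coding plastome loci diverge several-fold faster than coding ones —
under a K2P-like process (transition:transversion 2:1), and indels at
0.002 events per site with geometric lengths (mean about 3 bp). Planted
ground truth emulates the observations such screens report: seven SSR
groups shared by all species (five homopolymer, three of them
length-variable across species) and five long repeats covering all four
orientation types. An optional SSC inversion reproduces the alternative
genome arrangements seen within real genera.

Three generator choices trade realism for exact truth, and are the main
caveat on what green tests demonstrate. Planted elements sit in dedicated
spacer gaps with immutable 100 bp flanks, so recall can be asserted at
exact coordinates; four immutable 1 bp guard bases at the LSC and SSC
edges stop the constructed IR boundaries from extending by a chance
match, so partition recovery can be asserted exactly; and the ancestral
background is scrubbed of incidental near-threshold SSRs so the planted
manifest is exhaustive and a zero false-positive assertion is meaningful.
Real plastomes offer none of these guarantees: SSRs sit in mutating
context, IR boundaries shift between species, and annotation quality
varies. The simulation validates the machinery — scanners against their
oracles, the statistic against hand counts, rate recovery against planted
rates (Spearman at least 0.9 across loci spanning 0.005-0.15) — not the
biology of any particular genus. Equally, the generator's event logs
replay exactly onto the ancestor, which is what makes the genomes' truth
auditable rather than asserted.

Default problem sizes in the test suite and acceptance script are scaled
to desk hardware: 40-60 kb genomes with 30-45 genes exercise every code
path of the 120 kb defaults at a fraction of the alignment cost, and the
oracle-equivalence sweeps use hundreds of sequences of a few hundred
bases (where the quadratic brute force is exact and fast) with a smaller
number of 0.5-2 kb cases.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout; GenBank's 1-based
  inclusive spans are converted at the boundary, and origin-wrapping
  features keep `end > length`.
* `N` bases: never match in repeat finding or IR detection (even against
  another `N`), split SSR runs, score 0 in alignment, and are not counted
  as substitutions.
* Ties in ranking break deterministically (length, then name), and the
  pipeline is deterministic for a fixed input set and seed; reruns give
  byte-identical outputs.
* Sequences shorter than `min_len` return an empty hit set rather than an
  error; a genome with no inverted duplication gets the degenerate
  all-LSC map; abutting features (end == start) yield no IGS; overlapping
  features log a warning and yield none.
* The homologous-SSR flank test excludes hits whose flanks would run off
  a linear sequence end (with a warning); circular genomes wrap instead.

## Known limitations

Homology is annotation-name-driven; mis-annotated or inconsistently named
genes will fragment loci rather than be rescued by sequence similarity.
The IGS enumeration ignores features nested inside other features'
introns. Repeats spanning the circular origin are not searched. The
progressive supermatrix alignment has no iterative refinement — import a
proper multiple alignment for distant taxa. Compound SSRs are not
modelled. The planted-element and boundary-guard conventions above mean
the simulator slightly understates the ambiguity of real data.
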