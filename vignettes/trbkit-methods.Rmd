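---
title: "Methods: annotating and validating duplicated T cell receptor beta loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and validating duplicated T cell receptor beta loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trbkit)
```

## The problem

Salmonids carry the imprint of a lineage-specific whole-genome duplication
(roughly 94 million years old). In Atlantic salmon this left two complete,
paralogous T cell receptor beta (TRB) regions on different chromosomes, each
organized as *dual* V–D–J–C transcriptional units in opposite (head-to-head)
orientations, plus an unplaced scaffold that behaves like a haplotype of the
first region. Characterizing such loci requires four coupled analyses:

1. **Germline mining** — find every V, D, J and C segment in genomic
   sequence by similarity to a seed library, classify V genes into
   subgroups, call pseudogenes, and apply a coherent naming scheme across
   the two transcriptional orientations.
2. **Phylogenetic verification** — confirm segment families with
   neighbor-joining trees and bootstrap support.
3. **Expressed support** — process paired-end amplicon reads into unique
   collapsed sequences with read counts, keep open reading frames, match
   them to germline genes at 100% identity, and mark genes with expressed
   support as functional.
4. **Junction decomposition** — split each expressed CDR3 into templated
   (V, D, J) and non-templated (N) parts, with explicit ambiguity sets when
   sequence-identical germline genes cannot be distinguished.

`trbkit` implements all four stages plus a ground-truthed simulator, so the
entire workflow can be exercised and validated end-to-end without any
external data.

## The synthetic study system

The simulator (`sim_config()`, `simulate_locus()`, `simulate_amplicons()`)
is a first-class, tested component. Its **defaults are the study
conditions** against which the package validates itself:

* A V-gene census of 119 genes across three regions — 51 on the first
  chromosome region, 49 on the duplicated region, 19 on the scaffold — with
  18 pseudogenes of which 12 sit in the duplicated region. The defaults
  plant these counts subgroup by subgroup (`sim_config()$v_plan`).
* Paralogous constant domains diverged at **exactly one third of codons**
  (each selected codon is replaced by a codon for a different amino acid),
  giving 67.06% amino-acid identity — the rapid-diversification regime that
  distinguishes these paralogues from the 82–90% identity typical of other
  duplicated genes. The two constant copies *within* a region are
  identical; the first region's constant gene has three exons, the
  duplicated region's four.
* A single 12 nt diversity core, byte-identical in every unit of every
  region.
* J arrays with inverted sequence-identical duplicates (four identical
  forward/reverse pairs in one region, five in the other) plus one tandem
  duplication that creates a three-member identity class — the
  configuration that makes J assignment ambiguous by construction.
* A scaffold whose V genes are partly byte-identical copies of
  first-region genes (default: half), reproducing the multi-gene 100%
  identity sets seen in expressed data.
* 26 of the 49 duplicated-region V genes carry expressed support; amplicons
  are recombined with geometric(0.4) exonuclease trims (capped at 6 nt),
  non-templated insertions uniform on 0–10 nt, 250 bp paired-end reads and
  a default per-base error rate of 0.001.

Divergence is applied as per-site substitution with a 2:1 transition bias
and **no indels**: coordinate truth then stays exact, which is what makes
the "exact recovery" round-trip tests meaningful. Substitutions that would
create an in-frame stop codon are reverted; pseudogene stops are planted
explicitly, never by accident.

Two deliberate constructions keep the leader-exon ground truth decidable:
intergenic spacers are scrubbed of start codons on both strands, and leader
introns are built as `GT` + {A,C,T} + `AG`, so they contain no internal
splice donors and stop codons appear almost immediately in any reading
frame. The planted 48 nt leader is then the unique longest ATG-initiated,
codon-aligned, stop-free exon in the search window. Real intergenic DNA is
not ATG-free; what passing leader tests show is that the enumeration and
splice logic are correct, not that leader finding is unambiguous in real
genomes. Leader exons are modelled codon-aligned (length divisible by 3); a
real leader exon may carry a split codon.

### What the simulator does not emulate

Indels between paralogues, PCR chimeras, sequencer-specific error profiles,
PhiX spike-in, allelic variation beyond the scaffold haplotype, and
recombination signal sequences. Tests passing on this material show the
pipeline's logic is correct under a substitution-dominated model; they do
not certify performance on real assemblies with structural variation.

## Germline mining

`find_candidates()` is a k-mer seeded banded aligner: 11-mer matches
between seed and contig (both strands) vote for diagonals; a supported
diagonal (≥ 2 hits) defines a window into which the full seed is aligned
globally (match +1, mismatch −1, gap open −4, gap extend −1). V and C hits
require 70% identity and 60% seed coverage; J hits, being short, require
80% identity; the 12 nt D core is located by exact scan only. Overlapping
hits of the same type keep the best-scoring interval, and per-exon constant
hits are chained into multi-exon segments. These thresholds are set to
recover paralogues at the 67–90% identity regime without drowning in
noise; an 11-mer survives 10% per-site divergence with high probability
across a 280 nt gene, which is what bounds the advertised "≥ 95% recovery
at ≤ 10% divergence".

Coordinates are 0-based half-open on the forward strand, with strand stored
separately (BED/GFF-friendly); GFF3 export converts to 1-based.

**Subgroup clustering** (`cluster_subgroups()`) is single-linkage on
pairwise *global* nucleotide identity at ≥ 75% — the IMGT subgroup rule,
with ties at exactly 0.75 counted as within-subgroup. Two identity measures
coexist deliberately: `pairwise_identity()` uses free end gaps (so a
fragment versus a full gene is judged only over the region covered — right
for expressed-sequence and constant-domain comparisons), while
`global_identity()` penalizes end gaps (a locally similar core must not
pull two diverged genes into one subgroup; with free end gaps, two
unrelated sequences can score a perfect tiny overlap). Clusters containing
a subgroup-tagged seed inherit the seed's number; novel clusters take the
next free numbers in order of first appearance. `pairwise_identity()`
orders its arguments canonically before aligning, because alignment
tie-breaking is role-dependent; this makes the measure exactly symmetric.

**Functionality** uses internal stop codons as the sole pseudogene
criterion: `P` iff the defined reading frame contains one; frameshift-only
defects are not called `P`. `F` is assigned only downstream, from expressed support.
A consequence worth knowing: leader recovery requires a stop-free splice
into the V frame, so pseudogenes usually report no leader — consistent
with leader sequences being found for functional genes and only some
pseudogenes.

**Naming** numbers each transcriptional unit separately in its V→D→J→C
direction, forward unit first, inserting `R` for the reverse unit,
with per-subgroup ordinals for V genes, `_P` extensions for pseudogenes
and `S`-ordinals on the unplaced scaffold (e.g. `Scf.TRBV3S1`). Unit
membership follows strand except for a V gene whose flanking V genes both
belong to the opposite orientation — such a translocated gene is assigned
to the surrounding unit, and the simulator plants one such gene per
chromosomal region to keep this rule exercised.

## Phylogenetics

Distances: Poisson-corrected amino-acid distance (`d = −ln(1−p)`),
p-distance, JC69 and K80, all under pairwise deletion of ambiguous
positions. Saturated pairs are capped at 10 substitutions/site with a
warning rather than returned infinite, keeping neighbor joining runnable.
`nj_tree()` is the Saitou–Nei algorithm with the standard Q criterion;
ties join the lowest-index pair, and negative branch lengths are clamped to
zero with the deficit moved to the sibling edge. On additive matrices the
tree reproduces the input exactly (a property the test suite checks on
hundreds of random additive matrices, alongside a topology cross-check
against an independent implementation). `bootstrap_support()` resamples
columns with replacement and counts, for each internal bipartition of the
full-data tree, the fraction of replicate trees containing it; bipartitions
are canonicalized against the alphabetically first taxon so counts are
stable across replicate tip orderings. Tree input is pre-aligned by
contract; the simulator's equal-length, indel-free genes satisfy it
directly. The composite-likelihood nucleotide distance used in some
published figures is approximated by JC69/K80; topology-level agreement,
not branch lengths, is the reproduction target.

## Amplicon repertoire

The read-processing chain mirrors a standard amplicon pipeline:
3′ quality trimming (default Q20, minimum length 50), adapter read-through
removal by mate overlap, IUPAC-aware primer demultiplexing (default
≤ 1 mismatch in the gene-specific part; a read matching two primers equally
goes to `undetermined` — ambiguity is never guessed), FLASH-style overlap
merging (minimum overlap 10, maximum mismatch density 0.25, disagreements
resolved towards the higher-quality base), and exact-sequence collapsing
with `{primer}_{rank}-{count}` identifiers. Merging evaluates every insert
hypothesis at once via per-base cross-correlation, choosing minimal
mismatch density then longest overlap.

ORF filtering anchors the reading frame at the constant-gene prefix and
requires the anchored frame to be stop-free through the read — an
out-of-frame V–J join fails this almost surely because the shifted frame
reads stops within the V region.

Germline assignment requires **100% identity over the covered portion**,
excluding the primer-binding prefix (primer sequence can mask true
variation): a germline V is called when the read matches it exactly from
the primer end to within 15 nt of the gene's 3′ end (junction trimming
allowance). All byte-identical germline genes are reported as one
ambiguity set. Reads matching no V are `novel` — with sequencing errors on,
a realistic fraction of reads lands there, as real data does through
haplotypic variation. A gene becomes `F` when an ORF-bearing collapsed
sequence with ≥ 20 reads (the reporting threshold) includes it in its call
set; a pseudogene matched by bona fide transcripts is reported as a status
conflict instead of silently flipped.

## Junction decomposition

`decompose_junction()` maximizes total templated nucleotides: V prefix
match + J suffix match (ending at the constant anchor) + D-core substring
of ≥ 4 nt. Ties break towards the longest V match, then J, then the
leftmost D placement. The search is exhaustive with a provable bound:
trimming the V or J anchor by more than the D-core length (12 nt) can gain
at most the core length back, so scanning that window below the maximal
anchors covers every decomposition — the test suite verifies equality with
a naive full enumeration on over a thousand simulated reads. Below 4 nt a
D match is indistinguishable from chance and the middle is reported as one
undifferentiated N region. P-nucleotides are not modelled separately; they
fold into the N regions.

Because the decomposition is maximum-parsimony, non-templated bases that
*coincidentally* extend a templated segment are absorbed into it: recovered
N lengths are a lower bound on the truth, and on simulated reads roughly
half the decompositions shorten the N regions by a base or two. The
reconstruction invariant — parts re-concatenate to the observed read — is
asserted on every record. J calls are equivalence classes of identical
germline J sequences (`j_identity_classes()`), and `tally_j_usage()` sums
read support per (V, J-class) without resolving ambiguity.

## Numerical and design choices

* **Frame-neutral N lengths.** Expressed transcripts are resampled until
  in-frame and stop-free (spleen cDNA is dominated by productive
  rearrangements). N-insertion lengths are drawn once per clonotype and
  kept; the frame constraint is satisfied by resampling trims and junction
  content, so the N-length marginals stay exactly uniform — a property the
  suite verifies by chi-square at α = 0.01 on > 5000 draws. Trim
  distributions are mildly frame-conditioned as a result.
* **Expressed-set round trip.** Scaffold genes byte-identical to expressed
  first-region genes are marked `F` too — indistinguishability is a fact of
  the data, so the round-trip test compares the `F` set to the *identity
  closure* of the planted expressed set.
* **Problem sizes.** The validation suite runs the full census-scale
  simulation (119 V genes, ~150 kb over three contigs, ~4000 read pairs),
  200 random additive matrices for NJ, 100 clustering instances of up to 30
  sequences against a brute-force closure oracle, 1000 junction
  decompositions against exhaustive search, and a 100,000-read
  demultiplex/collapse count-conservation check. These sizes make every
  property statistically meaningful while keeping a full run in minutes.
* **Region spans.** How the published region boundaries were delimited is
  not reproducible from sequence alone; the census, not the span, is the
  object this package reproduces. Spans are reported as first-to-last
  segment extent.
* **The scaffold** is treated as an independent region labelled `Scf`;
  whether it is a haplotype or an extension of the first region is left
  open, exactly as the expressed-identity evidence leaves it.

## Known limitations

Candidate mining assumes substitution-dominated divergence; genes split by
assembly gaps or large indels would be missed or fragmented. The
constant-gene chainer assumes exons of one gene lie within 2 kb. Germline
assignment is exact-match only by design — it will not call a gene from a
read with even one error in the covered portion (such reads surface as
`novel`). Repertoire diversity statistics, clonal lineage inference and
RSS modelling are out of scope.
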