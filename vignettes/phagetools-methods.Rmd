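---
title: "Methods and design notes for phagetools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for phagetools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagetools)
library(dplyr)
```

phagetools is a toolkit for building a catalogue of viral genomes from bulk
metagenome assemblies: deciding which contigs are viral, assessing how
complete each viral genome is, detecting stop-codon reassignment, collapsing
genomes into species / genus / family groups, assigning taxonomy and hosts,
and summarising phylogenetic diversity. This vignette explains the methods
and the design decisions behind them, in the order a pipeline would run.

## Viral contig classification

A contig is classified from four signatures:

1. **Viral protein content** — the number of proteins whose best HMM hit
   (bit score, e-value < 1e-10) lies in a viral protein-family database.
2. **Microbial protein content** — the same count against microbial
   families. Viral contigs should have few.
3. **Nucleotide signature score** — a score in [0, 1] from any k-mer-based
   scorer. The scorer is a pluggable input (`nt_scores` table): phagetools
   does not model nucleotide composition itself.
4. **Strand switch rate** — strand switches between adjacent genes divided
   by gene count. Phage genomes are transcribed in long co-oriented runs,
   so low values indicate viruses; 0 or 1 genes give rate 0.

Thresholds on these signatures form *clauses* (all set thresholds must
hold; boundaries are inclusive) and up to five clauses per fragment-length
class are combined by disjunction. Rule sets are data, not code: the
shipped `default_ruleset()` is a plausible starting point, and
`grid_search_cutoffs()` re-derives cutoffs on any labelled benchmark by
exhaustively scoring every combination of candidate thresholds with

\[ \mathrm{score} = \mathrm{TPR} - 50 \times \mathrm{FPR}, \]

the true-positive rate penalised heavily for false positives because bulk
metagenomes are dominated by non-viral sequence. Grid-search ties break
lexicographically on the threshold tuple so selected clauses are
reproducible. Contigs are assigned to the largest benchmark length class
(1, 2, 5, 10, 20, 50, 100 kb) not exceeding their length; contigs under
1 kb are rejected — they carry too little signal for any clause.

Equal top bit scores across the two HMM databases resolve to *viral*: the
pipeline is tuned for sensitivity, with specificity enforced downstream by
the 50× FPR penalty.

## Genome quality control

**Terminal repeats.** A direct terminal repeat (DTR; prefix equals suffix)
indicates a circular or circularly permuted genome; an inverted terminal
repeat (ITR; prefix equals the reverse complement of the suffix) marks
some linear genomes. Matching is exact, N never matches, and lengths are
scanned downward from `min(length/2, 5000)` so the longest repeat is
reported; 20 bp is the detection floor. When both kinds occur, the DTR is
preferred (it is by far the commoner closure evidence). Exact matching is
a deliberate simplification — assembly consensus errors inside a true
repeat will hide it — and the 5 kb scan ceiling bounds worst-case cost.

**Large repeats.** Contigs in which exactly repeated seeds (≥ 100 bp,
either strand) span — by interval union — strictly more than 30% of the
length are flagged as likely assembly artefacts.

**Provirus trimming** extracts an externally predicted viral region
(1-based inclusive coordinates) and suffixes the record id so provenance
survives. Boundary prediction itself is out of scope.

**Quality tiers.** Completeness estimation is consumed, not computed.
Tiers: `complete` (closure evidence — DTR, ITR or provirus boundaries on
both ends — *and* completeness > 90%), `high` (> 90% without closure),
`medium` (50–90%, both ends inclusive), `low` (< 50%), `undetermined`
(no estimate). The 50% lower bound of `medium` is inclusive; the catalogue
selection filter is therefore "≥ 50%" in this implementation.

**rRNA screen.** A contig is flagged as cellular contamination when any
16S/18S hit covers ≥ 70% of its model with e-value < 1e-5.

## Alternative genetic codes

Some gut phages reassign a stop codon (TGA → code 4/25, TAG → code 15,
TAA → code 90) so standard-code gene calls truncate at the recoded codon.
Screening is restricted to contigs > 10 kb with GC < 50% — reassignment is
concentrated in AT-rich phages, and short contigs carry too little coding
signal. For each candidate code the gene caller's per-gene coding scores
are summed per contig; an alternative code is called only when its total
is both the maximum and at least 10% above the standard code's total
(compared against code 11 specifically, not the runner-up; a small
relative epsilon keeps an exact 10% margin from being lost to floating
point). The call is invariant to rescaling all totals.

The gene caller is pluggable. The shipped `orf_gene_calls()` scorer is
deliberately naive — ORFs are stop-free stretches in six frames, scored by
length in codons (minimum 30) — adequate for engineered test genomes, not
for real data, where a probabilistic caller should be adapted in.

## Species-level clustering (vOTUs)

Pairwise relatedness uses two statistics computed from local alignments:
ANI (length-weighted mean percent identity across alignments) and AF (the
percentage of the *shorter* genome covered by the union of alignment
intervals, coordinates merged before dividing). Alignments below 90%
identity are ignored. Genomes are first dereplicated at 100% identity over
100% of the shorter sequence (exact duplicate or substring, reverse
complement included by default), then clustered greedily: sort by length,
take the longest unassigned genome as centroid, assign everything within
95% ANI and 85% AF of it, repeat. Sorting first (ties by id) makes the
outcome invariant to input order; members are never reassigned to a later
centroid. These thresholds are configurable — the species partition is
known to be somewhat sensitive to them.

The built-in aligner (`align_pair()`) exists so the package runs with no
external search tool: shared 13-mers seed diagonals, each diagonal's match
profile is segmented into high-scoring un-gapped runs (match +1, mismatch
−1, X-drop 20, minimum segment score 25), and terminal mismatches are
trimmed exactly as a score-maximising local aligner would. It handles
substitution-level divergence well and indel-rich divergence poorly (each
indel shifts the diagonal; fragments on nearby diagonals are reported as
separate alignments, which is adequate for ANI/AF but undercalls long
gapped alignments). At catalogue scale an external all-vs-all search
should be used and its 12-column hit tables fed in verbatim; the package's
contribution is the ANI/AF arithmetic and the clustering, which are the
same either way. Validation compares the built-in path against a full
dynamic-programming local aligner on random pairs up to 2 kb (agreement
within 0.5 ANI points over 50 pairs) and against planted substitution
rates of 1/5/10% at 10 kb (medians within 1 point over 20 pairs each).

## Genus- and family-level clustering

Only the longest genome per vOTU enters. For each genome pair, shared
genes are best *bidirectional* protein hits (mutual best by bit score,
e-value < 1e-5) — the paper-level definition is looser ("shared genes"),
and mutual-best is the standard, conservative reading. AAI is their
unweighted mean identity; gene sharing is the pair count over the smaller
gene complement (symmetric, robust to fragmentation). Edges are filtered
at rank-specific floors — family: AAI ≥ 20% and sharing ≥ 10%; genus:
AAI ≥ 50% and sharing ≥ 20% — and weighted by `aai × sharing / 100`, a
choice the upstream description leaves open; both the floors and the
weighting are configurable.

Markov clustering is implemented in-package (no MCL implementation ships
with the environment's R stack): self-loops at each node's maximum
incident weight, column normalisation, then alternating expansion (matrix
squaring) and inflation (entrywise power, re-normalisation, pruning of
entries < 1e-5) until the maximum entrywise change falls below 1e-6 or
100 iterations, whichever first (non-convergence returns the last iterate
with a warning). Clusters are read from the attractors of the converged
flow, overlapping attractor sets merged, fully pruned nodes becoming
singletons. Inflation 2.0 (genus) and 1.2 (family) follow standard
granularity practice for these ranks. Cluster quality against reference
labels is summarised by homogeneity (mean cluster purity) and cohesion
(mean taxon concentration).

## Consensus taxonomy

Per protein, the taxonomy of the top reference hit is transferred at each
rank; when the top hit lacks a rank, the first lower hit within 25% of the
top bit score (i.e. ≥ 0.75×) supplies it. An unannotated top hit still
anchors that window. Per genome, ranks are evaluated from genus upward;
the genome is annotated at the most specific rank where the modal taxon
holds > 70% of the bit-score-weighted votes among proteins annotated at
that rank (unannotated proteins are excluded from the denominator) *and*
the rank's evidence minimum holds — family: ≥ 2 annotated proteins with
identity > 30%; genus: ≥ 3 annotated proteins with mean identity > 40%.
More general ranks are inherited from the winning lineage. Modal ties
break toward the lexicographically smaller taxon, with a warning.

## Host prediction

Two evidence types connect viruses to host genomes. **CRISPR spacers**:
a spacer links its host to a virus when it aligns (either strand) over at
least 95% of its length with at most one combined mismatch-plus-gap. The
matcher enumerates end-clips within the coverage allowance and scans all
window positions with vectorised mismatch and single-indel checks, so it
is exhaustive: validation demands exact equality with a brute-force
edit-distance oracle over 200 seeded plantings. An internal deletion
reduces aligned spacer coverage by one base more than the edit count
implies; the implementation charges it only against the edit budget, a
documented simplification. **Genome matches**: local alignments of at
least 1 kb at ≥ 96% identity between (decontaminated) host contigs and
viral genomes. Host contigs whose annotated host-classified fraction is
below 50% are removed first, so mis-binned viral contigs inside
metagenome-assembled host genomes cannot create self-links; contigs
without the annotation are retained with a warning (conservative).
Overlapping CRISPR arrays from different detectors are merged by interval
union with exact-duplicate spacers collapsed.

Per virus, connections vote with equal weight (spacer and genome-match
evidence count the same — relative weighting is exposed but defaults to
equality) and the host lineage is assigned at the most specific rank with
> 70% agreement.

## Phylogenetic utilities

Marker alignments are trimmed to columns with *less than* 50% gaps, then
concatenated in fixed marker order with all-gap blocks for missing
markers. Genomes stay only with ≥ 3 markers and data at > 5% of columns.
Tree inference itself is external; the package midpoint-roots trees
(via the longest tip-to-tip path) and computes phylogenetic diversity of
a tip subset as the sum of branch lengths over branches with at least one
subset tip among their descendants, on the rooted tree — this makes
PD(all tips) equal the total branch length, and is validated against an
independent union-of-root-to-tip-paths computation. Whether PD should be
computed on the rooted or unrooted tree is genuinely open; the rooted
reading was chosen and is stated here.

Core-genome SNP matrices represent members of one vOTU in the reference
coordinates of its longest genome (gap and N are missing data; indels are
ignored — SNPs are substitutions only). Variant positions require
coverage by ≥ 50% of genomes, then genomes require data at ≥ 50% of the
retained positions, applied in that order.

## Synthetic data: what it does and does not show

Every input class has a seeded generator, byte-identical for a fixed seed
(`withr::with_seed`; the global RNG is never touched):

- `sim_genome_pair()` — i.i.d. substitutions at a stated rate, so expected
  ANI is known. No indels, no rearrangements.
- `sim_votu_clusters()` — cluster ancestors at 25% divergence from a
  shared root, members at 2% within clusters; member lengths are staggered
  so the expected centroid is deterministic.
- `sim_mock_benchmark()` — labelled fragments at the seven benchmark
  lengths, 2,000 per class per length by default. It emits the
  *classifier's inputs* (gene strand layouts, per-protein hit labels,
  nucleotide scores drawn from class-separated Beta distributions), not
  nucleotide sequence: every downstream computation consumes features, so
  simulating sequence would only add an untested layer. Hit-label rates
  (60% of genes labelled in-class) and switch probabilities (0.05 viral,
  0.45 host) were chosen once as plausible class separations.
- `sim_provirus()`, `sim_spacer_plantings()`, `sim_recoded_genome()`,
  `sim_toy_tree()` — planted constructions with the truth returned
  alongside. The spacer generator verifies its own claim that a ≥ 2-edit
  planting is truly ≥ 2 edits from everywhere in the genome (in rare
  repetitive contexts two substitutions can collapse into one indel) and
  resamples when it is not. The recoded-genome generator interleaves an
  18-codon cassette whose five non-coding frames each contain stops under
  every genetic code, so the naive ORF scorer sees signal only in the
  intended frame.

Passing on these fixtures demonstrates the *logic* — thresholds, tie
breaks, aggregation arithmetic, oracle agreement — not performance on
real data, which depends on the external HMM databases, gene callers and
search tools the package deliberately treats as pluggable inputs.

## Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses: 50
random pairs ≤ 2 kb against the dynamic-programming oracle; 20 pairs of
10 kb per planted divergence; 20 seeds of the 3 × 5 planted cluster
layout at 5 kb; 20 clique-union and 20 random graphs for Markov
clustering; 200 spacer plantings on 800 bp genomes; 50 recoded replicates
of 12 kb per code; benchmarks of 200 fragments per class at two lengths;
and 50 random trees for the diversity oracle. These sizes give stable
pass/fail behaviour at desk scale; all are parameters, not limits.

## Known limitations

- The built-in aligner is substitution-oriented and capped at ~100 kb per
  sequence; use an external search at scale or for indel-rich pairs.
- The naive ORF scorer is for testing the code-detection logic only.
- Greedy vOTU clustering computes centroid-member ANI on demand, which is
  quadratic in the worst case; precomputed hit tables avoid this.
- Consensus taxonomy assumes reference lineages are internally consistent
  (prefix-consistent); it does not reconcile conflicting references.
- Markov clustering is dense-matrix; graphs far beyond ~2,000 nodes
  should go through an external sparse implementation.
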