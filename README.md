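# phagetools

Tools for cataloguing bacteriophage and other viral genomes assembled from
bulk metagenomes. Most DNA in a stool metagenome is microbial; the viruses
hiding in the assembly have to be recognised, quality-controlled, and
organised into taxonomic units before any ecology can be done with them.
phagetools implements that pipeline end to end as a set of composable,
tibble-in / tibble-out R functions:

- **Classification** — four viral signatures per contig (viral protein-family
  hits, microbial protein-family hits, a pluggable nucleotide-signature
  score, and the strand switch rate), combined by disjunctive threshold
  clauses per fragment-length class, with a benchmark harness that
  grid-searches cutoffs by `score = TPR − 50 × FPR`.
- **Quality control** — direct/inverted terminal repeat detection (≥ 20 bp),
  provirus flank trimming, rejection of contigs with > 30% repeat span,
  completeness tiers (complete / high / medium / low / undetermined), and a
  16S/18S rRNA contamination screen.
- **Alternative genetic codes** — detection of stop-codon reassignment
  (TGA → code 4/25, TAG → 15, TAA → 90) by comparing summed coding-potential
  scores across codes, with a ≥ 10% margin over the standard code.
- **Species clustering** — pairwise ANI (length-weighted identity over local
  alignments) and AF (alignment fraction of the shorter genome, intervals
  merged), 100%/100% dereplication, and greedy centroid clustering into
  vOTUs at 95% ANI / 85% AF. A built-in k-mer seeded local aligner makes
  this runnable without external search tools.
- **Genus/family clustering** — AAI and gene sharing from best-bidirectional
  protein hits, rank-specific edge floors (genus: 50%/20%; family:
  20%/10%), and in-package Markov clustering (inflation 2.0 / 1.2).
- **Consensus taxonomy** — per-protein transfer from top reference hits with
  a 25% bit-score fallback window, then bit-score-weighted voting per
  genome at the most specific rank with > 70% agreement, subject to
  rank-specific evidence minimums.
- **Host prediction** — CRISPR spacer matching (≤ 1 mismatch or gap over
  ≥ 95% of the spacer, both strands), ≥ 1 kb / ≥ 96% genome matches,
  host-contig decontamination, array merging, and > 70% host-lineage
  consensus.
- **Phylogenetics** — marker-alignment trimming (< 50% gap columns),
  concatenation with gap fill, genome inclusion filters (≥ 3 markers,
  > 5% columns), midpoint rooting, phylogenetic diversity of genome
  subsets, and core-SNP matrices for strain trees.
- **Synthetic data** — seeded generators for every input class (diverged
  genome pairs, planted proviruses and spacers, recoded genomes, mock
  benchmarks, toy trees), so the whole pipeline is testable offline.

External heavy lifting (HMM searches, gene calling, all-vs-all search at
catalogue scale, completeness estimation, tree inference) is consumed
through standard tabular formats, not reimplemented; see the methods
vignette (`vignettes/phagetools-methods.Rmd`) for the full design notes.

## Worked example

Cluster a planted set of 15 genomes (3 species, 5 members each, 2%
within-species divergence) into vOTUs:

```r
library(phagetools)

sim <- sim_votu_clusters(n_clusters = 3, members_per_cluster = 5,
                         length = 5000, within_divergence = 0.02, seed = 11)
genomes  <- dereplicate_genomes(sim$contigs)
clusters <- cluster_votus(genomes)
clusters
#> 15 genomes in 3 vOTUs (ANI >= 95, AF >= 85)
glance(clusters)
#> # A tibble: 1 × 4
#>   n_genomes n_votus largest n_singletons
#>       <int>   <int>   <int>        <int>
#> 1        15       3       5            0
head(tidy(clusters), 3)
#> # A tibble: 3 × 4
#>   id    votu      representative is_representative
#>   <chr> <chr>     <chr>          <lgl>
#> 1 c1_m1 vOTU_0001 c1_m1          TRUE
#> 2 c2_m1 vOTU_0002 c2_m1          TRUE
#> 3 c3_m1 vOTU_0003 c3_m1          TRUE
```

The three planted species come back as exactly three vOTUs of five, each
represented by its longest member. The underlying pairwise statistic is
ANI/AF; on a 10 kb pair with 5% planted substitutions:

```r
p <- sim_genome_pair(10000, 0.05, seed = 7)
sequence_ani(p$contigs$sequence[1], p$contigs$sequence[2])
#> # A tibble: 1 × 3
#>     ani af_shorter n_alignments
#>   <dbl>      <dbl>        <int>
#> 1  94.9        100            1
```

ANI 94.9 against an expected 95.0 — the pair falls just below the species
threshold, as 5% divergence should. Cutoff selection for the classifier
runs the same way on a labelled benchmark:

```r
bm <- sim_mock_benchmark(n_per_class = 200, lengths_kb = c(5, 20), seed = 3)
gs <- grid_search_cutoffs(bm$features, bm$truth,
        grids = list(min_viral_hits = c(NA, 1, 3, 5),
                     max_microbial_hits = c(NA, 0, 1),
                     min_nt_score = c(NA, 0.5, 0.9),
                     max_strand_switch_rate = c(NA, 0.2)),
        classes_kb = c(5, 20))
gs
#> Viral-detection benchmark: 71 cutoff combinations searched
#>  length_class best_score
#>             5       95.5
#>            20       99.0
```

`tidy(gs)` lists the top clauses per length class with their TPR/FPR, and
`as_ruleset(gs)` turns them into the rule set `evaluate_ruleset()` applies
to new contigs. `autoplot()` methods exist for benchmark, vOTU and MCL
results.

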