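# Independent oracles used across the suite. These deliberately take the
# slow, obvious route so they stay independent of the implementation paths
# they check.

# ANI of the single best local alignment under full dynamic programming
# (match +1 / mismatch -1, affine gaps), via Biostrings.
dp_oracle_ani <- function(seq_a, seq_b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  al <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "local",
                                      substitutionMatrix = sm,
                                      gapOpening = 10, gapExtension = 2)
  Biostrings::pid(al)
}

# brute-force spacer matching: every clip split within the coverage
# allowance, every window, full Levenshtein distance via adist, both strands
bruteforce_spacer_hit <- function(spacer, genome, min_coverage = 0.95,
                                  max_edits = 1) {
  L <- nchar(spacer)
  clip_budget <- floor((1 - min_coverage) * L)
  for (strand_seq in c(genome, phagetools::revcomp(genome))) {
    n <- nchar(strand_seq)
    for (a in 0:clip_budget) {
      for (b in 0:(clip_budget - a)) {
        core <- substr(spacer, 1 + a, L - b)
        Lc <- nchar(core)
        for (w in (Lc - max_edits):(Lc + max_edits)) {
          if (w < 1 || w > n) next
          starts <- seq_len(n - w + 1)
          wins <- substring(strand_seq, starts, starts + w - 1)
          if (any(utils::adist(core, wins) <= max_edits)) return(TRUE)
        }
      }
    }
  }
  FALSE
}

# phylogenetic diversity as the union of root-to-tip path edges
pd_path_union_oracle <- function(tree, tips) {
  if (length(tips) == 0) return(0)
  root <- length(tree$tip.label) + 1
  edges <- c()
  for (tp in match(tips, tree$tip.label)) {
    path_nodes <- ape::nodepath(tree, from = root, to = tp)
    for (k in seq_len(length(path_nodes) - 1)) {
      e <- which(tree$edge[, 1] == path_nodes[k] &
                   tree$edge[, 2] == path_nodes[k + 1])
      edges <- c(edges, e)
    }
  }
  sum(tree$edge.length[unique(edges)])
}

# exhaustive maximiser over a cutoff grid, independent of grid_search_cutoffs
bruteforce_best_score <- function(features, truth, grids, fpr_weight = 50) {
  combos <- expand.grid(v = grids$min_viral_hits, m = grids$max_microbial_hits,
                        s = grids$min_nt_score,
                        r = grids$max_strand_switch_rate)
  combos <- combos[rowSums(!is.na(combos)) > 0, , drop = FALSE]
  tr <- truth$viral[match(features$contig_id, truth$contig_id)]
  best <- -Inf
  for (i in seq_len(nrow(combos))) {
    pred <- rep(TRUE, nrow(features))
    if (!is.na(combos$v[i])) pred <- pred & features$n_viral_hits >= combos$v[i]
    if (!is.na(combos$m[i])) {
      pred <- pred & features$n_microbial_hits <= combos$m[i]
    }
    if (!is.na(combos$s[i])) pred <- pred & features$nt_score >= combos$s[i]
    if (!is.na(combos$r[i])) {
      pred <- pred & features$strand_switch_rate <= combos$r[i]
    }
    tpr <- 100 * sum(pred & tr) / sum(tr)
    fpr <- 100 * sum(pred & !tr) / sum(!tr)
    best <- max(best, tpr - fpr_weight * fpr)
  }
  best
}
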