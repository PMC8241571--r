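#' Simulate a genome pair of known divergence
#'
#' The second genome is the first with i.i.d. substitutions at the given
#' per-base rate (each substituted base changes to a different base), so
#' the expected ANI of the pair is `100 * (1 - divergence)`. Deterministic
#' for a fixed seed.
#'
#' @param length Genome length (bp).
#' @param divergence Substitution rate in \[0, 0.3).
#' @param seed Integer seed.
#' @param gc GC content of the ancestral genome.
#' @return List with `contigs` (two-row contig tibble, ids `a` and `b`)
#'   and `n_mutations` (true substitution count).
#' @export
sim_genome_pair <- function(length, divergence, seed, gc = 0.5) {
  stopifnot(divergence >= 0, divergence < 0.3)
  withr::with_seed(seed, {
    a <- random_dna(length, gc = gc)
    chars <- seq_chars(a)
    mut <- which(runif(length) < divergence)
    for (i in mut) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
    b <- paste(chars, collapse = "")
    list(contigs = contig_tbl(c("a", "b"), c(a, b)),
         n_mutations = length(mut))
  })
}

#' Simulate a labelled viral-detection benchmark
#'
#' Emulates the mock fragment benchmark used to tune the classifier:
#' equal numbers of viral-like and host-like fragments at each fragment
#' length. Viral-like fragments carry long same-strand gene runs, mostly
#' viral top-hit labels and high nucleotide-signature scores; host-like
#' fragments carry frequently switching strands, microbial labels and low
#' scores. The generator emits the classifier's inputs (gene strand
#' layout, per-protein hit labels, nucleotide scores) plus truth labels
#' and the assembled feature table; nucleotide sequences themselves are
#' not simulated because every downstream computation consumes features.
#'
#' @param n_per_class Fragments per class (viral / host) per length.
#' @param lengths_kb Fragment lengths in kb.
#' @param seed Integer seed.
#' @param viral_hit_rate,host_hit_rate Probability that a gene receives a
#'   viral (resp. microbial) top-hit label in its own class.
#' @param viral_switch_prob,host_switch_prob Per-gene probability of a
#'   strand switch.
#' @return List with `features` (tibble as [contig_features()]) and
#'   `truth` (tibble `contig_id`, `viral`).
#' @export
sim_mock_benchmark <- function(n_per_class = 2000,
                               lengths_kb = c(1, 2, 5, 10, 20, 50, 100),
                               seed = 1,
                               viral_hit_rate = 0.6, host_hit_rate = 0.6,
                               viral_switch_prob = 0.05,
                               host_switch_prob = 0.45) {
  withr::with_seed(seed, {
    one_fragment <- function(id, len_bp, viral) {
      n_genes <- max(1L, stats::rpois(1, len_bp / 1000))
      switch_prob <- if (viral) viral_switch_prob else host_switch_prob
      switches <- runif(n_genes - 1) < switch_prob
      if (viral) {
        nv <- rbinom(1, n_genes, viral_hit_rate)
        nm <- rbinom(1, n_genes - nv, 0.05)
        nt <- stats::rbeta(1, 8, 2)
      } else {
        nm <- rbinom(1, n_genes, host_hit_rate)
        nv <- rbinom(1, n_genes - nm, 0.05)
        nt <- stats::rbeta(1, 2, 8)
      }
      tibble(contig_id = id, length = len_bp, n_genes = n_genes,
             n_viral_hits = nv, n_microbial_hits = nm,
             nt_score = nt, strand_switch_rate = sum(switches) / n_genes,
             viral_truth = viral)
    }
    rows <- list()
    for (lk in lengths_kb) {
      for (cls in c(TRUE, FALSE)) {
        tag <- if (cls) "viral" else "host"
        for (i in seq_len(n_per_class)) {
          id <- sprintf("%s_%dkb_%04d", tag, lk, i)
          rows[[length(rows) + 1]] <- one_fragment(id, lk * 1000, cls)
        }
      }
    }
    all <- bind_rows(rows)
    list(features = all %>% select(-"viral_truth"),
         truth = all %>% select("contig_id", viral = "viral_truth"))
  })
}

#' Simulate a provirus contig with known boundaries
#'
#' A viral genome (optionally carrying a direct terminal repeat) is
#' embedded in host sequence; the true viral boundaries are returned so
#' trimming and repeat detection can be verified exactly.
#'
#' @param host_len Total flanking host sequence (bp), split around the
#'   virus.
#' @param virus_len Viral genome length (bp).
#' @param dtr_len Direct terminal repeat length on the viral part (0 for
#'   none).
#' @param seed Integer seed.
#' @return List with `contig` (one-row contig tibble), `viral_start`,
#'   `viral_end`, `virus` (the planted viral sequence).
#' @export
sim_provirus <- function(host_len, virus_len, dtr_len = 0, seed = 1) {
  stopifnot(virus_len > 2 * dtr_len + 2)
  withr::with_seed(seed, {
    core <- random_dna(virus_len - 2 * dtr_len)
    virus <- if (dtr_len > 0) {
      r <- random_dna(dtr_len)
      paste0(r, core, r)
    } else core
    left_len <- host_len %/% 2
    right_len <- host_len - left_len
    left <- if (left_len > 0) random_dna(left_len) else ""
    right <- if (right_len > 0) random_dna(right_len) else ""
    contig <- contig_tbl("provirus_contig", paste0(left, virus, right))
    list(contig = contig, viral_start = left_len + 1,
         viral_end = left_len + virus_len, virus = virus)
  })
}

#' Plant CRISPR spacers in a viral genome
#'
#' Draws spacers from the viral genome, applies the requested number of
#' substitutions to each, and randomly assigns half to the reverse
#' strand, returning both the spacer table and the expected-hit truth
#' (hits are expected for at most one edit).
#'
#' @param virus One-row contig tibble.
#' @param n Number of spacers.
#' @param mismatches Substitutions applied to each spacer.
#' @param seed Integer seed.
#' @param spacer_len Spacer length (bp).
#' @return List with `spacers` (tibble `spacer_id`, `host_genome_id`,
#'   `sequence`, `strand`, `origin_start`) and `expect_hit` (logical).
#' @export
sim_spacer_plantings <- function(virus, n, mismatches = 0, seed = 1,
                                 spacer_len = 32) {
  glen <- nchar(virus$sequence)
  stopifnot(glen > spacer_len + 2)
  withr::with_seed(seed, {
    starts <- sample(glen - spacer_len + 1, n, replace = TRUE)
    seqs <- substring(virus$sequence, starts, starts + spacer_len - 1)
    seqs <- vapply(seqs, function(s) {
      if (mismatches == 0) return(s)
      mutate_once <- function() {
        chars <- seq_chars(s)
        pos <- sample(2:(spacer_len - 1), mismatches)  # internal edits
        for (p in pos) {
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        }
        paste(chars, collapse = "")
      }
      out <- mutate_once()
      # substitutions in repetitive context can collapse to a single indel;
      # resample so the emitted truth (>=2 edits -> no hit) really holds
      if (mismatches >= 2) {
        for (try in 1:50) {
          if (min_edit_to_genome(out, virus$sequence) >= 2) break
          out <- mutate_once()
        }
      }
      out
    }, character(1), USE.NAMES = FALSE)
    rev_strand <- runif(n) < 0.5
    seqs[rev_strand] <- revcomp(seqs[rev_strand])
    list(
      spacers = tibble(
        spacer_id = sprintf("sp%03d", seq_len(n)),
        host_genome_id = sprintf("host%03d", seq_len(n)),
        sequence = seqs,
        strand = ifelse(rev_strand, "-", "+"),
        origin_start = starts
      ),
      expect_hit = mismatches <= 1
    )
  })
}

# 18 safe in-frame codons whose five non-coding frames (the two shifted
# forward frames and all three reverse frames) each contain both a TAA-type
# and a TGA-type stop codon, i.e. a stop under every genetic-code class.
# Interleaving this cassette through simulated genes caps off-frame open
# reading frames below any sensible ORF-length cutoff for every code, so a
# naive length-based coding score only responds to the intended reading
# frame.
STOP_CASSETTE <- c("TTA", "TCA",          # reverse in-phase stops
                   "CTA", "AAT",          # +1 frame TAA
                   "ATG", "ACT",          # +1 frame TGA
                   "AAT", "AAC",          # +2 frame TAA
                   "ACT", "GAC",          # +2 frame TGA
                   "ATT", "AAC",          # reverse +2 phase TAA
                   "ATC", "ACT",          # reverse +2 phase TGA
                   "AAT", "TAT",          # reverse +1 phase TAA
                   "AAT", "CAT")          # reverse +1 phase TGA

# minimum Levenshtein distance from any end-clipped form of `pattern`
# (clip budget per the 95% coverage rule) to any genome window, either
# strand; exhaustive via utils::adist, independent of the matcher
min_edit_to_genome <- function(pattern, genome, min_coverage = 0.95) {
  L <- nchar(pattern)
  clip_budget <- floor((1 - min_coverage) * L)
  best <- Inf
  for (g in c(genome, revcomp(genome))) {
    n <- nchar(g)
    for (a in 0:clip_budget) {
      for (b in 0:(clip_budget - a)) {
        core <- substr(pattern, 1 + a, L - b)
        Lc <- nchar(core)
        for (w in (Lc - 1):(Lc + 1)) {
          if (w < 1 || w > n) next
          st <- seq_len(n - w + 1)
          d <- utils::adist(core, substring(g, st, st + w - 1))
          best <- min(best, min(d))
        }
      }
    }
  }
  best
}

#' Simulate a genome using a recoded stop codon
#'
#' Builds a genome of long genes whose in-frame codons are stop-free under
#' the genome's own genetic code. For an alternative code the reassigned
#' stop codon is planted in frame once per ~23 codons, so gene calls under
#' any other code truncate below the ORF-length cutoff and the total
#' coding potential collapses relative to the true code; for code 11 no
#' such codon is planted and all codes score the gene identically. A
#' stop cassette interleaved through every gene terminates the five
#' non-coding frames under every code, and intergenic spacers carry
#' in-frame stops on both strands. The construction keeps GC content
#' around 30%, inside the screening eligibility window.
#'
#' @param length Approximate genome length (bp).
#' @param code Genetic code of the genome (11, 4, 15 or 90).
#' @param seed Integer seed.
#' @param gene_units Cassette+filler units per gene (one recoded codon per
#'   unit).
#' @return A one-row contig tibble.
#' @export
sim_recoded_genome <- function(length, code = 11, seed = 1,
                               gene_units = 10) {
  recoded <- setdiff(c("TAA", "TAG", "TGA"), code_stop_codons(code))
  safe <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA")
  )
  unit_codons <- length(STOP_CASSETTE) + 5
  gene_bp <- 3 * unit_codons * gene_units
  withr::with_seed(seed, {
    n_genes <- max(1, length %/% (gene_bp + 18))
    parts <- character(0)
    for (g in seq_len(n_genes)) {
      codons <- unlist(purrr::map(seq_len(gene_units), function(u) {
        filler <- sample(safe, 4, replace = TRUE)
        slot <- if (length(recoded) > 0) recoded[1] else
          sample(safe, 1)
        c(STOP_CASSETTE, filler[1:2], slot, filler[3:4])
      }))
      spacer <- "TAATAGTGATTATCACTA"  # in-frame stops, both strands
      parts <- c(parts, paste(codons, collapse = ""), spacer)
    }
    contig_tbl(paste0("recoded_", code), paste(parts, collapse = ""))
  })
}

#' Simulate a random tree with branch lengths
#'
#' @param n_tips Number of tips.
#' @param seed Integer seed.
#' @return An [ape::phylo] tree with tip labels `t1..tn` and uniform
#'   random branch lengths.
#' @export
sim_toy_tree <- function(n_tips, seed = 1) {
  withr::with_seed(seed, ape::rtree(n_tips))
}

#' Simulate planted vOTU cluster structure
#'
#' Derives `n_clusters` cluster ancestors from a shared root genome at the
#' between-cluster divergence (so clusters sit far below the species ANI
#' threshold), then derives `members_per_cluster` genomes from each
#' ancestor at the within-cluster divergence (well above it). Members get
#' distinct lengths by trimming a few terminal bases, making the expected
#' centroid (the longest member) deterministic.
#'
#' @param n_clusters Number of planted clusters.
#' @param members_per_cluster Genomes per cluster.
#' @param length Ancestor length (bp).
#' @param within_divergence Substitution rate within a cluster.
#' @param between_divergence Substitution rate from the shared root to
#'   each cluster ancestor.
#' @param seed Integer seed.
#' @return List with `contigs` and `truth` (tibble `id`,
#'   `true_cluster`).
#' @export
sim_votu_clusters <- function(n_clusters = 3, members_per_cluster = 5,
                              length = 5000, within_divergence = 0.02,
                              between_divergence = 0.25, seed = 1) {
  withr::with_seed(seed, {
    mutate_seq <- function(s, rate) {
      chars <- seq_chars(s)
      mut <- which(runif(nchar(s)) < rate)
      for (i in mut) {
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
      }
      paste(chars, collapse = "")
    }
    root <- random_dna(length)
    rows <- list()
    for (cl in seq_len(n_clusters)) {
      anc <- mutate_seq(root, between_divergence)
      for (m in seq_len(members_per_cluster)) {
        s <- mutate_seq(anc, within_divergence)
        s <- substr(s, 1, length - (m - 1) * 10)  # distinct lengths
        rows[[length(rows) + 1]] <- tibble(
          id = sprintf("c%d_m%d", cl, m), sequence = s,
          true_cluster = sprintf("planted_%d", cl)
        )
      }
    }
    all <- bind_rows(rows)
    list(contigs = contig_tbl(all$id, all$sequence),
         truth = all %>% select("id", "true_cluster"))
  })
}
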