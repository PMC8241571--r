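#' Amino-acid identity and gene sharing between two genomes
#'
#' Shared genes are best bidirectional hits: protein pairs that are each
#' other's highest-bit-score match after the e-value filter. AAI is the
#' unweighted mean percent identity over those pairs; the shared fraction
#' is the pair count divided by the smaller gene complement, which keeps
#' the measure symmetric and robust to genome fragmentation.
#'
#' @param protein_hits Hit tibble between the two genomes' proteins, with
#'   hits in both directions (`query_id`/`target_id` are protein ids).
#' @param proteins_a,proteins_b Character vectors of protein ids belonging
#'   to genome a and genome b.
#' @param max_evalue Hits at or above this e-value are discarded.
#' @return A one-row tibble `aai`, `shared_fraction`, `n_shared`, or a
#'   zero-row tibble when no gene is shared (no edge).
#' @export
compute_aai <- function(protein_hits, proteins_a, proteins_b,
                        max_evalue = 1e-5) {
  if (length(proteins_a) == 0 || length(proteins_b) == 0) {
    abort("both genomes must have at least one gene")
  }
  none <- tibble(aai = numeric(), shared_fraction = numeric(),
                 n_shared = integer())
  hits <- protein_hits %>% filter(.data$evalue < max_evalue)
  ab <- hits %>%
    filter(.data$query_id %in% proteins_a, .data$target_id %in% proteins_b)
  ba <- hits %>%
    filter(.data$query_id %in% proteins_b, .data$target_id %in% proteins_a)
  if (nrow(ab) == 0 || nrow(ba) == 0) return(none)
  best <- function(h) {
    h %>%
      arrange(.data$query_id, -.data$bitscore, .data$target_id) %>%
      group_by(.data$query_id) %>%
      slice_head(n = 1) %>%
      ungroup()
  }
  best_ab <- best(ab)
  best_ba <- best(ba)
  shared <- inner_join(
    best_ab %>% select(a = "query_id", b = "target_id", "pident"),
    best_ba %>% select(b = "query_id", a = "target_id"),
    by = c("a", "b")
  )
  if (nrow(shared) == 0) return(none)
  tibble(
    aai = mean(shared$pident),
    shared_fraction = 100 * nrow(shared) /
      min(length(proteins_a), length(proteins_b)),
    n_shared = nrow(shared)
  )
}

#' Build the rank-specific AAI/gene-sharing graph
#'
#' Genus-level clustering demands closer relatives (at least 50% AAI and
#' 20% gene sharing) than family-level clustering (20% AAI, 10% sharing);
#' edges failing either floor are removed. The retained edge weight is
#' `aai * shared_fraction / 100`, combining both relatedness axes.
#'
#' @param pairs Tibble `genome_a`, `genome_b`, `aai`, `shared_fraction`.
#' @param rank `"genus"` or `"family"`.
#' @param min_aai,min_shared Override the rank's default floors
#'   (percent, inclusive survival: edges with values below are dropped).
#' @return A tibble `from`, `to`, `weight` of surviving edges.
#' @export
build_rank_graph <- function(pairs, rank = c("genus", "family"),
                             min_aai = NULL, min_shared = NULL) {
  rank <- match.arg(rank)
  defaults <- default_config()$aai[[rank]]
  min_aai <- min_aai %||% defaults$min_aai
  min_shared <- min_shared %||% defaults$min_shared
  out <- pairs %>%
    filter(.data$aai >= min_aai, .data$shared_fraction >= min_shared) %>%
    mutate(weight = .data$aai * .data$shared_fraction / 100) %>%
    select(from = "genome_a", to = "genome_b", "weight")
  log_filter("aai", paste0(rank, "-rank edges surviving floors"),
             nrow(pairs), nrow(out))
  out
}

#' Agreement between clusters and reference taxon labels
#'
#' Homogeneity is the mean, over clusters, of the fraction of labelled
#' members carrying the cluster's most common taxon; cohesion is the mean,
#' over taxa, of the fraction of a taxon's genomes placed in its most
#' common cluster. Unlabelled genomes are ignored.
#'
#' @param membership Tibble `id`, `cluster`.
#' @param reference_labels Tibble `id`, `taxon` (partial labelling allowed).
#' @return A one-row tibble `homogeneity`, `cohesion` (percent).
#' @export
cluster_homogeneity <- function(membership, reference_labels) {
  lab <- inner_join(membership, reference_labels, by = "id") %>%
    filter(!is.na(.data$taxon))
  if (nrow(lab) == 0) abort("no labelled genomes in the clustering")
  homog <- lab %>%
    count(.data$cluster, .data$taxon) %>%
    group_by(.data$cluster) %>%
    summarise(frac = max(.data$n) / sum(.data$n), .groups = "drop")
  cohes <- lab %>%
    count(.data$taxon, .data$cluster) %>%
    group_by(.data$taxon) %>%
    summarise(frac = max(.data$n) / sum(.data$n), .groups = "drop")
  tibble(homogeneity = 100 * mean(homog$frac),
         cohesion = 100 * mean(cohes$frac))
}
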