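VIRUS_RANKS <- c("baltimore", "order", "family", "genus")   # general -> specific
HOST_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Transfer reference taxonomy to proteins from ranked hits
#'
#' Each protein takes, at every rank, the taxon of its top (highest
#' bit-score) reference hit. When the top hit is unannotated at a rank,
#' the first subsequent hit whose bit-score is at least 75% of the top
#' hit's (i.e. within 25%) and that carries the rank supplies it; if none
#' does, the rank stays unassigned. The supplying hit's bit-score and
#' percent identity travel with the rank so the genome-level consensus can
#' weight by them.
#'
#' @param hits Hit tibble for the proteins of one or more query genomes
#'   (pre-filtered for query/subject coverage and e-value), with columns
#'   `query_id`, `target_id`, `pident`, `bitscore`.
#' @param ref_taxonomy Tibble `target_id` plus one column per rank in
#'   `ranks` (NA = unannotated).
#' @param ranks Rank ladder, most general first.
#' @param next_hit_fraction Bit-score floor for the fallback hit, as a
#'   fraction of the top hit's bit-score.
#' @return A long tibble `protein_id`, `rank`, `taxon`, `bitscore`,
#'   `pident`, one row per assigned (protein, rank).
#' @export
transfer_protein_taxonomy <- function(hits, ref_taxonomy,
                                      ranks = VIRUS_RANKS,
                                      next_hit_fraction = 0.75) {
  stopifnot(all(ranks %in% names(ref_taxonomy)))
  if (nrow(hits) == 0) {
    return(tibble(protein_id = character(), rank = character(),
                  taxon = character(), bitscore = numeric(),
                  pident = numeric()))
  }
  # left join so references absent from the taxonomy table still anchor the
  # top bit-score used by the 25% fallback window
  annotated <- hits %>%
    left_join(ref_taxonomy, by = "target_id") %>%
    arrange(.data$query_id, -.data$bitscore, .data$target_id)
  annotated %>%
    group_by(protein_id = .data$query_id) %>%
    dplyr::group_modify(function(h, key) {
      top_bits <- h$bitscore[1]
      purrr::map(ranks, function(rk) {
        ok <- !is.na(h[[rk]]) &
          h$bitscore >= next_hit_fraction * top_bits
        if (!any(ok)) return(NULL)
        i <- which(ok)[1]
        tibble(rank = rk, taxon = h[[rk]][i],
               bitscore = h$bitscore[i], pident = h$pident[i])
      }) %>% bind_rows()
    }) %>%
    ungroup()
}

#' Bit-score-weighted consensus taxonomy of a genome
#'
#' Per-protein annotations are aggregated rank by rank, from most specific
#' to most general. At each rank the modal taxon's bit-score-weighted
#' share among proteins annotated at that rank is computed; the genome is
#' assigned at the most specific rank whose share exceeds 70% and that
#' meets the rank's minimum-evidence rule (family: at least two annotated
#' proteins with identity above 30%; genus: at least three annotated
#' proteins whose mean identity exceeds 40%). More general ranks are then
#' filled from the winning taxon's lineage. Ties in the modal taxon break
#' toward the lexicographically smaller name, with a warning.
#'
#' @param calls Long tibble from [transfer_protein_taxonomy()] for one
#'   genome.
#' @param ranks Rank ladder, most general first.
#' @param min_agreement Weighted-share threshold (strict >).
#' @param config Taxonomy section of [default_config()] (rank minimums).
#' @return A one-row tibble with one column per rank (NA where
#'   unassigned) plus `assigned_rank` and `agreement` (the winning share,
#'   in \[0, 1\]).
#' @export
consensus_taxonomy <- function(calls, ranks = VIRUS_RANKS,
                               min_agreement = 0.70,
                               config = default_config()$taxonomy) {
  empty <- as_tibble(setNames(as.list(rep(NA_character_, length(ranks))),
                              ranks))
  empty$assigned_rank <- NA_character_
  empty$agreement <- NA_real_
  if (is.null(calls) || nrow(calls) == 0) return(empty)
  for (rk in rev(ranks)) {   # most specific first
    at_rank <- calls %>% filter(.data$rank == rk, !is.na(.data$taxon))
    if (nrow(at_rank) == 0) next
    votes <- at_rank %>%
      group_by(.data$taxon) %>%
      summarise(w = sum(.data$bitscore), .groups = "drop") %>%
      arrange(-.data$w, .data$taxon)
    if (nrow(votes) > 1 && votes$w[1] == votes$w[2]) {
      warn(sprintf("tie at rank %s broken toward '%s'", rk, votes$taxon[1]))
    }
    share <- votes$w[1] / sum(votes$w)
    if (share <= min_agreement) next
    if (!rank_minimum_met(rk, at_rank, config)) next
    # winning assignment: inherit more-general ranks from the lineage of
    # the winning taxon's calls
    winner <- votes$taxon[1]
    winner_proteins <- at_rank$protein_id[at_rank$taxon == winner]
    out <- empty
    out[[rk]] <- winner
    more_general <- ranks[seq_len(match(rk, ranks) - 1)]
    for (g in more_general) {
      gcalls <- calls %>%
        filter(.data$rank == g, .data$protein_id %in% winner_proteins,
               !is.na(.data$taxon))
      if (nrow(gcalls) > 0) {
        gv <- gcalls %>% group_by(.data$taxon) %>%
          summarise(w = sum(.data$bitscore), .groups = "drop") %>%
          arrange(-.data$w, .data$taxon)
        out[[g]] <- gv$taxon[1]
      }
    }
    out$assigned_rank <- rk
    out$agreement <- share
    return(out)
  }
  empty
}

rank_minimum_met <- function(rank, at_rank, config) {
  if (rank == "family") {
    sum(at_rank$pident > config$family_min_identity) >=
      config$family_min_proteins
  } else if (rank == "genus") {
    nrow(at_rank) >= config$genus_min_proteins &&
      mean(at_rank$pident) > config$genus_min_mean_identity
  } else {
    TRUE
  }
}

#' Consensus taxonomy for many genomes at once
#'
#' @param calls Long tibble from [transfer_protein_taxonomy()] with an
#'   additional `genome_id` column.
#' @inheritParams consensus_taxonomy
#' @return A tibble with one row per genome.
#' @export
consensus_taxonomy_all <- function(calls, ranks = VIRUS_RANKS,
                                   min_agreement = 0.70,
                                   config = default_config()$taxonomy) {
  calls %>%
    group_by(.data$genome_id) %>%
    dplyr::group_modify(~ consensus_taxonomy(.x, ranks, min_agreement,
                                             config)) %>%
    ungroup()
}
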