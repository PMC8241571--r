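#' Strand switch rate of a contig's gene calls
#'
#' Viral genomes tend to encode long runs of genes on one strand, so the
#' rate of strand switches between adjacent genes separates viral from
#' microbial contigs. The rate is the number of adjacent gene pairs on
#' opposite strands divided by the number of genes; contigs with zero or
#' one gene score 0.
#'
#' @param genes Gene tibble for a single contig, sorted by `start`
#'   (as produced by [read_gene_table()]).
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' g <- tibble::tibble(contig_id = "c", start = c(1, 100, 200, 300),
#'                     end = c(90, 190, 290, 390),
#'                     strand = c("+", "-", "+", "-"))
#' strand_switch_rate(g)  # 3 switches / 4 genes
strand_switch_rate <- function(genes) {
  n <- nrow(genes)
  if (n <= 1) return(0)
  if (length(unique(genes$contig_id)) > 1) {
    abort("strand_switch_rate expects genes from a single contig")
  }
  if (is.unsorted(genes$start)) {
    abort("genes must be sorted by start coordinate")
  }
  ssr_vec(genes$strand)
}

# switch rate from an ordered strand vector
ssr_vec <- function(strand) {
  n <- length(strand)
  if (n <= 1) return(0)
  sum(strand[-n] != strand[-1]) / n
}

#' Classify proteins by their top HMM hit
#'
#' Each protein is labelled by the database (viral or microbial protein
#' families) containing its highest-bit-score hit, after discarding hits
#' with e-value at or above the cutoff. Proteins with no surviving hit are
#' labelled `"none"`. Equal top bit-scores across the two databases resolve
#' to viral: the pipeline is tuned for viral sensitivity, with false
#' positives controlled downstream by the heavily FPR-penalised
#' benchmark score.
#'
#' @param hits Hit tibble with at least `query_id`, `bitscore`, `evalue`
#'   and a `db` column with values `"viral"` or `"microbial"`.
#' @param max_evalue Hits at or above this e-value are discarded
#'   (strict `<` retains).
#' @return A tibble with one row per protein: `protein_id`, `label`.
#' @export
classify_protein_hits <- function(hits, max_evalue = 1e-10) {
  stopifnot(all(c("query_id", "bitscore", "evalue", "db") %in% names(hits)))
  if (!all(hits$db %in% c("viral", "microbial"))) {
    abort("hit db must be 'viral' or 'microbial'")
  }
  kept <- hits %>% filter(.data$evalue < max_evalue)
  log_filter("classify", "hmm hits below e-value cutoff", nrow(hits), nrow(kept))
  kept %>%
    mutate(.pref = ifelse(.data$db == "viral", 0L, 1L)) %>%
    arrange(.data$query_id, -.data$bitscore, .data$.pref) %>%
    group_by(protein_id = .data$query_id) %>%
    summarise(label = first(.data$db), .groups = "drop")
}

#' Assemble the four-signature feature vector for contigs
#'
#' Aggregates, per contig, the counts of proteins whose top hit is viral or
#' microbial, the pluggable nucleotide-signature score, and the strand
#' switch rate, into the feature set consumed by [evaluate_ruleset()].
#'
#' @param contigs Contig tibble (`id`, `length` at minimum).
#' @param genes Gene tibble covering the contigs (may omit contigs with no
#'   genes).
#' @param protein_labels Tibble `protein_id`, `label` from
#'   [classify_protein_hits()]; protein ids follow the
#'   `<contig_id>_<gene_index>` convention.
#' @param nt_scores Tibble `contig_id`, `nt_score` with scores in \[0, 1\]
#'   from any nucleotide-signature scorer; missing contigs score 0.
#' @return A tibble with columns `contig_id`, `length`, `n_genes`,
#'   `n_viral_hits`, `n_microbial_hits`, `nt_score`, `strand_switch_rate`.
#' @export
contig_features <- function(contigs, genes, protein_labels, nt_scores) {
  if (nrow(nt_scores) > 0 &&
      any(nt_scores$nt_score < 0 | nt_scores$nt_score > 1)) {
    abort("nt_score must lie in [0, 1]")
  }
  gene_stats <- genes %>%
    mutate(protein_id = paste0(.data$contig_id, "_", .data$gene_index)) %>%
    left_join(protein_labels, by = "protein_id") %>%
    arrange(.data$contig_id, .data$start) %>%
    group_by(.data$contig_id) %>%
    summarise(
      n_genes = n(),
      n_viral_hits = sum(.data$label == "viral", na.rm = TRUE),
      n_microbial_hits = sum(.data$label == "microbial", na.rm = TRUE),
      strand_switch_rate = ssr_vec(.data$strand),
      .groups = "drop"
    )
  contigs %>%
    select(contig_id = "id", "length") %>%
    left_join(gene_stats, by = "contig_id") %>%
    left_join(nt_scores, by = "contig_id") %>%
    mutate(
      n_genes = dplyr::coalesce(.data$n_genes, 0L),
      n_viral_hits = dplyr::coalesce(.data$n_viral_hits, 0L),
      n_microbial_hits = dplyr::coalesce(.data$n_microbial_hits, 0L),
      strand_switch_rate = dplyr::coalesce(.data$strand_switch_rate, 0),
      nt_score = dplyr::coalesce(.data$nt_score, 0)
    )
}

#' A plausible default rule set
#'
#' Disjunctive threshold clauses per benchmark length class. The pipeline
#' treats rule sets as data: these defaults favour contigs with several
#' viral protein hits, few microbial hits, a high nucleotide-signature
#' score, or long same-strand gene runs, with stricter demands on short
#' fragments. Re-derive cutoffs for any benchmark with
#' [grid_search_cutoffs()].
#'
#' @return A rule-set tibble (see [evaluate_ruleset()] for the format).
#' @export
default_ruleset <- function() {
  short <- tibble(clause = 1:3,
                  min_viral_hits = c(2L, 1L, NA),
                  max_microbial_hits = c(NA, 0L, 0L),
                  min_nt_score = c(NA, 0.9, 0.95),
                  max_strand_switch_rate = c(NA, NA, 0.1))
  long <- tibble(clause = 1:3,
                 min_viral_hits = c(5L, 2L, NA),
                 max_microbial_hits = c(NA, 1L, 2L),
                 min_nt_score = c(NA, 0.9, 0.95),
                 max_strand_switch_rate = c(NA, NA, 0.05))
  bind_rows(
    purrr::map(c(1, 2, 5), ~ mutate(short, length_class = .x, .before = 1)),
    purrr::map(c(10, 20, 50, 100), ~ mutate(long, length_class = .x, .before = 1))
  )
}

validate_ruleset <- function(ruleset) {
  req <- c("length_class", "clause", "min_viral_hits", "max_microbial_hits",
           "min_nt_score", "max_strand_switch_rate")
  stopifnot(all(req %in% names(ruleset)))
  thr <- ruleset[, c("min_viral_hits", "max_microbial_hits",
                     "min_nt_score", "max_strand_switch_rate")]
  if (any(rowSums(!is.na(thr)) == 0)) {
    abort("every rule clause must set at least one threshold")
  }
  n_per <- table(ruleset$length_class)
  if (any(n_per > 5)) abort("at most 5 clauses per length class")
  invisible(ruleset)
}

#' Benchmark length class of a contig
#'
#' Contigs are assigned the largest benchmark fragment length (kb) not
#' exceeding their own length; contigs shorter than the smallest class are
#' rejected with `NA`.
#'
#' @param length Integer vector of contig lengths in bases.
#' @param classes_kb Benchmark fragment lengths in kb.
#' @return Numeric vector of length classes in kb (`NA` below the smallest).
#' @export
length_class <- function(length, classes_kb = c(1, 2, 5, 10, 20, 50, 100)) {
  classes <- sort(classes_kb) * 1000
  idx <- findInterval(length, classes)
  out <- ifelse(idx == 0, NA_real_, classes[pmax(idx, 1)] / 1000)
  out
}

#' Apply a disjunctive rule set to contig features
#'
#' A contig is called viral when all thresholds set by any single clause of
#' its length class are satisfied. Boundaries are inclusive (`>=` for
#' minimums, `<=` for maximums). Contigs shorter than the smallest length
#' class are called non-viral and flagged.
#'
#' @param features Feature tibble from [contig_features()].
#' @param ruleset Rule-set tibble with columns `length_class`, `clause`,
#'   `min_viral_hits`, `max_microbial_hits`, `min_nt_score`,
#'   `max_strand_switch_rate` (NA = threshold unset).
#' @return `features` with added columns `length_class` and `viral`
#'   (logical).
#' @export
evaluate_ruleset <- function(features, ruleset) {
  validate_ruleset(ruleset)
  features$length_class <- length_class(features$length,
                                        sort(unique(ruleset$length_class)))
  viral <- rep(FALSE, nrow(features))
  for (i in seq_len(nrow(ruleset))) {
    cl <- ruleset[i, ]
    ok <- features$length_class == cl$length_class & !is.na(features$length_class)
    if (!is.na(cl$min_viral_hits)) {
      ok <- ok & features$n_viral_hits >= cl$min_viral_hits
    }
    if (!is.na(cl$max_microbial_hits)) {
      ok <- ok & features$n_microbial_hits <= cl$max_microbial_hits
    }
    if (!is.na(cl$min_nt_score)) {
      ok <- ok & features$nt_score >= cl$min_nt_score
    }
    if (!is.na(cl$max_strand_switch_rate)) {
      ok <- ok & features$strand_switch_rate <= cl$max_strand_switch_rate
    }
    viral <- viral | ok
  }
  features$viral <- viral
  features
}
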