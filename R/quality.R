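#' Detect direct or inverted terminal repeats
#'
#' Complete phage genomes assembled from circular templates carry a direct
#' terminal repeat (DTR: prefix equals suffix), while some linear genomes
#' carry an inverted terminal repeat (ITR: prefix equals the reverse
#' complement of the suffix). Repeat lengths are scanned downward from
#' `min(floor(length/2), max_len)` so the longest exact repeat of each kind
#' is found; matching is exact and N never matches. When both kinds reach
#' `min_len`, the DTR is reported.
#'
#' @param sequence A single nucleotide string.
#' @param min_len Minimum repeat length in bp.
#' @param max_len Upper bound on the repeat search.
#' @return A one-row tibble `kind` (`"DTR"`/`"ITR"`), `repeat_length`,
#'   `repeat_sequence`, or a zero-row tibble when no repeat reaches
#'   `min_len`.
#' @export
detect_terminal_repeats <- function(sequence, min_len = 20, max_len = 5000) {
  n <- nchar(sequence)
  hi <- min(n %/% 2, max_len)
  none <- tibble(kind = character(), repeat_length = integer(),
                 repeat_sequence = character())
  if (hi < min_len) return(none)
  prefix <- substr(sequence, 1, hi)
  suffix <- substr(sequence, n - hi + 1, n)
  rc_suffix <- revcomp(suffix)
  best <- function(a, b) {
    # longest L in [min_len, hi] with a[1..L] == tail(b, L), N never matching
    for (L in hi:min_len) {
      pa <- substr(a, 1, L)
      pb <- substr(b, nchar(b) - L + 1, nchar(b))
      if (pa == pb && !grepl("N", pa, fixed = TRUE)) return(L)
    }
    0L
  }
  dtr <- best(prefix, suffix)
  if (dtr >= min_len) {
    return(tibble(kind = "DTR", repeat_length = as.integer(dtr),
                  repeat_sequence = substr(sequence, 1, dtr)))
  }
  # ITR: prefix equals revcomp(suffix); compare prefix against the tail of
  # rc_suffix reversed appropriately -- revcomp of the last L bases equals
  # the first L bases of rc_suffix
  itr <- 0L
  for (L in hi:min_len) {
    pa <- substr(sequence, 1, L)
    pb <- substr(rc_suffix, 1, L)
    if (pa == pb && !grepl("N", pa, fixed = TRUE)) { itr <- L; break }
  }
  if (itr >= min_len) {
    return(tibble(kind = "ITR", repeat_length = as.integer(itr),
                  repeat_sequence = substr(sequence, 1, itr)))
  }
  none
}

#' Flag contigs dominated by large internal repeats
#'
#' Assembly artefacts sometimes produce contigs that are mostly tandem or
#' interspersed copies of the same block. The flag is raised when the union
#' of occurrence intervals of exactly repeated seeds (forward or reverse
#' complement) spans strictly more than `max_span` of the contig length.
#'
#' @param sequence A single nucleotide string.
#' @param seed_len Exact seed length (bp) used in the self-comparison.
#' @param max_span Span fraction above which the flag is raised (strict >).
#' @return Logical.
#' @export
large_repeat_flag <- function(sequence, seed_len = 100, max_span = 0.30) {
  n <- nchar(sequence)
  if (n < 2 * seed_len) return(FALSE)
  starts <- seq_len(n - seed_len + 1)
  kmers <- substring(sequence, starts, starts + seed_len - 1)
  rc <- revcomp(sequence)
  kmers_rc <- substring(rc, starts, starts + seed_len - 1)
  # a seed is repeated if its sequence occurs >1 time forward, or occurs on
  # the reverse complement strand as well
  fwd_counts <- table(kmers)
  repeated <- fwd_counts[kmers] > 1 | kmers %in% kmers_rc
  if (!any(repeated)) return(FALSE)
  iv <- cbind(starts[repeated], starts[repeated] + seed_len - 1)
  span <- merge_intervals(iv)
  span / n > max_span
}

#' Trim a provirus to its viral region
#'
#' Integrated proviruses are flanked by host chromosome; given externally
#' predicted viral boundaries this extracts the inclusive subsequence and
#' suffixes the id so provenance is visible.
#'
#' @param contig One-row contig tibble (`id`, `sequence`).
#' @param viral_start,viral_end 1-based inclusive boundaries of the viral
#'   region.
#' @return A one-row contig tibble with `provirus = TRUE`; the id gains a
#'   `|provirus_<start>_<end>` suffix unless the full range was requested.
#' @export
trim_provirus <- function(contig, viral_start, viral_end) {
  stopifnot(nrow(contig) == 1)
  len <- nchar(contig$sequence)
  if (viral_start < 1 || viral_end > len || viral_start > viral_end) {
    abort(sprintf("provirus boundaries (%d, %d) out of range for length %d",
                  viral_start, viral_end, len))
  }
  full <- viral_start == 1 && viral_end == len
  id <- if (full) contig$id else {
    paste0(sub("\\|provirus_\\d+_\\d+$", "", contig$id),
           "|provirus_", viral_start, "_", viral_end)
  }
  out <- contig_tbl(id, substr(contig$sequence, viral_start, viral_end))
  out$provirus <- TRUE
  out
}

#' Assign a genome-completeness quality tier
#'
#' Tiers follow the catalogue partition: `complete` needs closed-genome
#' evidence (terminal repeat or provirus boundaries) plus estimated
#' completeness above 90%; `high` is >90% without closure evidence;
#' `medium` is 50-90% (both ends inclusive); `low` is below 50%;
#' genomes without an estimate are `undetermined`.
#'
#' @param completeness Numeric vector of completeness percentages in
#'   \[0, 100\], `NA` when undetermined.
#' @param complete_evidence Character vector of closure evidence per genome:
#'   one of `"DTR"`, `"ITR"`, `"provirus_boundaries"`, `"none"`.
#' @return Character vector of tiers.
#' @export
assign_quality_tier <- function(completeness,
                                complete_evidence = "none") {
  stopifnot(all(is.na(completeness) |
                  (completeness >= 0 & completeness <= 100)))
  evidence <- rep_len(complete_evidence, length(completeness))
  ok_ev <- evidence %in% c("DTR", "ITR", "provirus_boundaries")
  dplyr::case_when(
    is.na(completeness) ~ "undetermined",
    completeness > 90 & ok_ev ~ "complete",
    completeness > 90 ~ "high",
    completeness >= 50 ~ "medium",
    TRUE ~ "low"
  )
}

#' Screen contigs for ribosomal RNA contamination
#'
#' Viral genomes do not encode 16S/18S rRNA; a confident rRNA hit marks a
#' contig as cellular contamination. A contig is contaminated when any hit
#' covers at least `min_coverage` of its rRNA model and has e-value below
#' `max_evalue`.
#'
#' @param hits Hit tibble (contig vs rRNA models) with `query_id`,
#'   `target_id`, `sstart`, `send`, `evalue`.
#' @param model_lengths Named numeric vector: rRNA model id -> model length.
#' @return Tibble `contig_id`, `contaminated` for every contig appearing in
#'   `hits`.
#' @export
rrna_contamination <- function(hits, model_lengths,
                               min_coverage = 0.70, max_evalue = 1e-5) {
  if (nrow(hits) == 0) {
    return(tibble(contig_id = character(), contaminated = logical()))
  }
  if (!all(hits$target_id %in% names(model_lengths))) {
    missing <- setdiff(unique(hits$target_id), names(model_lengths))
    abort(paste0("missing model length for: ", paste(missing, collapse = ", ")))
  }
  hits %>%
    mutate(
      coverage = (abs(.data$send - .data$sstart) + 1) /
        model_lengths[.data$target_id]
    ) %>%
    group_by(contig_id = .data$query_id) %>%
    summarise(contaminated = any(.data$coverage >= min_coverage &
                                   .data$evalue < max_evalue),
              .groups = "drop")
}

#' Quality-control a set of viral contigs
#'
#' Convenience wrapper: detects terminal repeats, flags large repeats,
#' joins externally estimated completeness, and assigns tiers.
#'
#' @param contigs Contig tibble.
#' @param completeness Tibble `contig_id`, `completeness` (percent, `NA`
#'   allowed), optional `provirus` logical for provirus-boundary evidence.
#' @return A tibble with one row per contig: repeat evidence, large-repeat
#'   flag, completeness and tier.
#' @export
qc_genomes <- function(contigs, completeness) {
  reps <- purrr::map(contigs$sequence, detect_terminal_repeats)
  evidence <- purrr::map_chr(reps, ~ if (nrow(.x) == 0) "none" else .x$kind)
  rep_len_bp <- purrr::map_int(reps, ~ if (nrow(.x) == 0) NA_integer_
                               else .x$repeat_length)
  out <- contigs %>%
    select(contig_id = "id", "length") %>%
    mutate(
      repeat_kind = ifelse(evidence == "none", NA_character_, evidence),
      repeat_length = rep_len_bp,
      large_repeat = purrr::map_lgl(contigs$sequence, large_repeat_flag)
    ) %>%
    left_join(completeness, by = "contig_id")
  if ("provirus" %in% names(out)) {
    evidence[is.na(out$repeat_kind) & !is.na(out$provirus) & out$provirus] <-
      "provirus_boundaries"
  }
  out$tier <- assign_quality_tier(out$completeness, evidence)
  n_flag <- sum(out$large_repeat)
  log_filter("qc", "large-repeat contigs flagged", nrow(out),
             nrow(out) - n_flag)
  out
}
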