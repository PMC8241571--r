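#' Merge CRISPR arrays predicted by multiple detectors
#'
#' Different array detectors report overlapping predictions of the same
#' locus; arrays on the same contig whose intervals overlap are merged
#' into one (interval union), and their spacer sets are unioned with exact
#' duplicate spacer sequences collapsed.
#'
#' @param arrays Tibble `array_id`, `host_genome_id`, `contig_id`,
#'   `start`, `end`, `source_tool`.
#' @param spacers Tibble `array_id`, `sequence` (plus any extra columns).
#' @return List with `arrays` (merged intervals, comma-joined source
#'   tools) and `spacers` (deduplicated, re-keyed to merged array ids).
#' @export
merge_crispr_arrays <- function(arrays, spacers) {
  merged <- arrays %>%
    arrange(.data$contig_id, .data$start, .data$end) %>%
    group_by(.data$host_genome_id, .data$contig_id) %>%
    mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                 default = -Inf) + 1)) %>%
    ungroup()
  out_arrays <- merged %>%
    group_by(.data$host_genome_id, .data$contig_id, .data$grp) %>%
    summarise(
      merged_array_id = paste0(first(.data$contig_id), "_arr",
                               dplyr::cur_group_id()),
      start = min(.data$start), end = max(.data$end),
      source_tool = paste(sort(unique(.data$source_tool)), collapse = ","),
      member_ids = list(.data$array_id),
      .groups = "drop"
    )
  key <- out_arrays %>%
    select("merged_array_id", "member_ids") %>%
    tidyr::unnest_longer("member_ids", values_to = "array_id")
  out_spacers <- spacers %>%
    inner_join(key, by = "array_id") %>%
    distinct(.data$merged_array_id, .data$sequence, .keep_all = TRUE) %>%
    select(-"array_id") %>%
    rename(array_id = "merged_array_id")
  log_filter("host", "arrays after merging", nrow(arrays), nrow(out_arrays))
  list(arrays = out_arrays %>% select(-"member_ids", -"grp"),
       spacers = out_spacers)
}

#' Match CRISPR spacers against viral genomes
#'
#' A spacer links its host genome to a virus when it aligns to the viral
#' genome (either strand) over at least `min_coverage` of its length with
#' at most `max_edits` combined mismatches plus indels. End-clipping up to
#' the coverage allowance and a single internal edit are both searched
#' exhaustively with vectorised scans, so results match a brute-force
#' edit-distance oracle.
#'
#' @param spacers Tibble `spacer_id`, `host_genome_id`, `sequence`.
#' @param viruses Contig tibble of viral genomes.
#' @param min_coverage Minimum fraction of the spacer that must align.
#' @param max_edits Combined mismatch + gap budget (0 or 1 supported).
#' @return Connection tibble: `virus_id`, `host_genome_id`, `spacer_id`,
#'   `evidence = "spacer"`, `strand`, `start`, `end`, `edits`.
#' @export
match_spacers <- function(spacers, viruses, min_coverage = 0.95,
                          max_edits = 1) {
  stopifnot(max_edits %in% c(0, 1))
  out <- list()
  for (v in seq_len(nrow(viruses))) {
    g_fwd <- viruses$sequence[v]
    g_rev <- revcomp(g_fwd)
    glen <- nchar(g_fwd)
    for (s in seq_len(nrow(spacers))) {
      sp <- spacers$sequence[s]
      L <- nchar(sp)
      clip_budget <- floor((1 - min_coverage) * L)
      hit <- NULL
      for (strand in c("+", "-")) {
        g <- if (strand == "+") g_fwd else g_rev
        m <- scan_approx(sp, g, clip_budget, max_edits)
        if (!is.null(m)) {
          if (strand == "-") {
            tmp <- m
            m$start <- glen - tmp$end + 1
            m$end <- glen - tmp$start + 1
          }
          m$strand <- strand
          if (is.null(hit) || m$edits < hit$edits) hit <- m
        }
      }
      if (!is.null(hit)) {
        out[[length(out) + 1]] <- tibble(
          virus_id = viruses$id[v],
          host_genome_id = spacers$host_genome_id[s],
          spacer_id = spacers$spacer_id[s],
          evidence = "spacer", strand = hit$strand,
          start = hit$start, end = hit$end, edits = hit$edits
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(virus_id = character(), host_genome_id = character(),
                  spacer_id = character(), evidence = character(),
                  strand = character(), start = integer(), end = integer(),
                  edits = integer()))
  }
  bind_rows(out)
}

# best approximate occurrence of pattern in text with <= max_edits
# (substitution or single indel) after clipping at most clip_budget bases
# from the pattern ends; returns list(start, end, edits) or NULL
scan_approx <- function(pattern, text, clip_budget, max_edits) {
  best <- NULL
  consider <- function(start, end, edits) {
    if (is.null(best) || edits < best$edits) {
      best <<- list(start = start, end = end, edits = edits)
    }
  }
  L <- nchar(pattern)
  for (a in 0:clip_budget) {
    for (b in 0:(clip_budget - a)) {
      core <- substr(pattern, 1 + a, L - b)
      Lc <- nchar(core)
      if (Lc < 1) next
      # substitutions only
      mm <- window_mismatches(core, text)
      ok <- which(mm <= max_edits)
      for (p in ok) consider(p, p + Lc - 1, mm[p])
      if (max_edits >= 1 && (is.null(best) || best$edits > 1)) {
        # one deletion from the core (window length Lc - 1)
        del <- one_indel_match(core, text, indel = "del")
        for (p in del) consider(p, p + Lc - 2, 1L)
        # one insertion into the core (window length Lc + 1)
        ins <- one_indel_match(core, text, indel = "ins")
        for (p in ins) consider(p, p + Lc, 1L)
      }
      if (!is.null(best) && best$edits == 0) return(best)
    }
  }
  best
}

# vector of mismatch counts of pattern against every window of text
window_mismatches <- function(pattern, text) {
  Lc <- nchar(pattern)
  n <- nchar(text)
  if (n < Lc) return(integer(0))
  pc <- seq_chars(pattern)
  tc <- seq_chars(text)
  n_win <- n - Lc + 1
  mm <- integer(n_win)
  for (j in seq_len(Lc)) {
    mm <- mm + (tc[j:(j + n_win - 1)] != pc[j])
  }
  mm
}

# windows of text matching pattern with exactly one indel: positions p such
# that pattern aligns to text[p .. p+Lw-1] with one gap and no mismatches
one_indel_match <- function(pattern, text, indel = c("del", "ins")) {
  indel <- match.arg(indel)
  pc <- seq_chars(pattern)
  tc <- seq_chars(text)
  Lc <- length(pc)
  Lw <- if (indel == "del") Lc - 1 else Lc + 1
  n <- length(tc)
  if (Lw < 1 || n < Lw) return(integer(0))
  n_win <- n - Lw + 1
  # pref[p] = longest k with pattern[1..k] == text[p..p+k-1]
  # suff[p] = longest k with pattern ending == window ending
  shorter <- min(Lc, Lw)
  # pref_len[p]: longest run of leading positions where the pattern matches
  # the window starting at p; suff_len likewise from the window's end.
  # Computed as row sums of cumulative ANDs, one vectorised pass per column.
  pref_run <- rep(TRUE, n_win); suff_run <- rep(TRUE, n_win)
  pref_len <- integer(n_win); suff_len <- integer(n_win)
  off <- 0:(n_win - 1)
  for (j in seq_len(shorter)) {
    pref_run <- pref_run & (tc[off + j] == pc[j])
    suff_run <- suff_run & (tc[off + (Lw - j + 1)] == pc[Lc - j + 1])
    pref_len <- pref_len + pref_run
    suff_len <- suff_len + suff_run
    if (!any(pref_run) && !any(suff_run)) break
  }
  # a single indel alignment exists iff a split point is covered:
  # pref_len + suff_len >= shorter (gap placed between the matched ends)
  which(pref_len + suff_len >= shorter)
}

#' Genome-sequence matches between host contigs and viruses
#'
#' Prophages and recently integrated elements leave long high-identity
#' matches between host contigs and viral genomes; matches of at least
#' `min_length` bases at `min_identity` percent identity or better become
#' host-virus connections.
#'
#' @param host_contigs Contig tibble with a `host_genome_id` column
#'   (decontaminated, see [decontaminate_host_contigs()]).
#' @param viruses Contig tibble of viral genomes.
#' @param min_length Minimum alignment length (bp).
#' @param min_identity Minimum percent identity.
#' @param ... Passed to [align_pair()].
#' @return Connection tibble: `virus_id`, `host_genome_id`,
#'   `host_contig_id`, `evidence = "genome_match"`, `length`, `pident`.
#' @export
genome_matches <- function(host_contigs, viruses, min_length = 1000,
                           min_identity = 96, ...) {
  out <- list()
  for (h in seq_len(nrow(host_contigs))) {
    for (v in seq_len(nrow(viruses))) {
      hits <- align_pair(viruses$sequence[v], host_contigs$sequence[h],
                         min_length = min_length, min_pident = min_identity,
                         ...)
      hits <- hits %>%
        filter(.data$length >= min_length, .data$pident >= min_identity)
      if (nrow(hits) > 0) {
        out[[length(out) + 1]] <- tibble(
          virus_id = viruses$id[v],
          host_genome_id = host_contigs$host_genome_id[h],
          host_contig_id = host_contigs$id[h],
          evidence = "genome_match",
          length = max(hits$length),
          pident = hits$pident[which.max(hits$length)]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(virus_id = character(), host_genome_id = character(),
                  host_contig_id = character(), evidence = character(),
                  length = integer(), pident = numeric()))
  }
  bind_rows(out)
}

#' Remove virus-dominated contigs from host genomes
#'
#' Metagenome-assembled host genomes sometimes bin viral contigs; a contig
#' whose host-classified region covers less than half its length is
#' removed before genome matching so such contigs cannot create spurious
#' host-virus links. Contigs lacking the annotation are retained with a
#' warning (conservative).
#'
#' @param host_contigs Contig tibble with a `host_fraction` column (the
#'   fraction of the contig classified as host; `NA` allowed).
#' @param min_host_fraction Retention threshold (inclusive).
#' @return The retained subset.
#' @export
decontaminate_host_contigs <- function(host_contigs,
                                       min_host_fraction = 0.50) {
  if (!"host_fraction" %in% names(host_contigs)) {
    abort("host_contigs must carry a host_fraction column")
  }
  missing <- is.na(host_contigs$host_fraction)
  if (any(missing)) {
    warn(sprintf("%d contig(s) lack host_fraction; retained conservatively",
                 sum(missing)))
  }
  keep <- missing | host_contigs$host_fraction >= min_host_fraction
  log_filter("host", "contigs surviving decontamination",
             nrow(host_contigs), sum(keep))
  host_contigs[keep, ]
}

#' Consensus host taxonomy for a virus
#'
#' Each connection contributes its host genome's lineage with equal
#' weight; the virus is assigned at the lowest (most specific) host rank
#' where more than `min_agreement` of connections agree, inheriting the
#' more general ranks of the winning lineage.
#'
#' @param connections Connection tibble for one virus (`host_genome_id`).
#' @param host_lineages Tibble `host_genome_id` plus the host rank columns
#'   (`domain` ... `species`).
#' @param ranks Host rank ladder, most general first.
#' @param min_agreement Agreement threshold (strict >).
#' @return A one-row tibble as [consensus_taxonomy()], with `n_connections`.
#' @export
host_consensus <- function(connections, host_lineages, ranks = HOST_RANKS,
                           min_agreement = 0.70) {
  empty <- as_tibble(setNames(as.list(rep(NA_character_, length(ranks))),
                              ranks))
  empty$assigned_rank <- NA_character_
  empty$agreement <- NA_real_
  empty$n_connections <- nrow(connections)
  if (nrow(connections) == 0) return(empty)
  lin <- connections %>%
    left_join(host_lineages, by = "host_genome_id")
  # unit-weight calls: reuse the bit-score-weighted consensus machinery
  calls <- purrr::map(ranks, function(rk) {
    tibble(protein_id = paste0("conn", seq_len(nrow(lin))),
           rank = rk, taxon = lin[[rk]], bitscore = 1, pident = 100)
  }) %>% bind_rows() %>% filter(!is.na(.data$taxon))
  host_cfg <- list(family_min_proteins = 0, family_min_identity = 0,
                   genus_min_proteins = 0, genus_min_mean_identity = 0)
  out <- consensus_taxonomy(calls, ranks = ranks,
                            min_agreement = min_agreement,
                            config = host_cfg)
  out$n_connections <- nrow(connections)
  out
}
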