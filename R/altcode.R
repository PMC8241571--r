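# stop codons per genetic code class: 11 standard; 4 = TGA recoded
# (covers code 25 as well); 15 = TAG recoded; 90 = TAA recoded
CODE_STOPS <- list(
  `11` = c("TAA", "TAG", "TGA"),
  `4`  = c("TAA", "TAG"),
  `15` = c("TAA", "TGA"),
  `90` = c("TAG", "TGA")
)

#' Stop codons of a genetic-code class
#'
#' @param code One of 11 (standard), 4 (TGA recoded; also covers 25),
#'   15 (TAG recoded), 90 (TAA recoded).
#' @return Character vector of stop codons.
#' @export
code_stop_codons <- function(code) {
  key <- as.character(code)
  if (!key %in% names(CODE_STOPS)) {
    abort(paste0("unknown genetic code: ", code))
  }
  CODE_STOPS[[key]]
}

#' Eligibility for alternative-genetic-code screening
#'
#' Screening is restricted to contigs longer than 10 kb with GC content
#' below 50%: stop-codon reassignment is concentrated in low-GC phages,
#' and short contigs give too little coding signal to call a code reliably.
#'
#' @param contigs Contig tibble (`length`, `gc`).
#' @param min_length Strict lower bound on length (bp).
#' @param max_gc Strict upper bound on GC fraction.
#' @return Logical vector.
#' @export
altcode_eligible <- function(contigs, min_length = 10000, max_gc = 0.50) {
  contigs$length > min_length & contigs$gc < max_gc
}

#' Total coding-potential score of one contig under one code
#'
#' @param genes Gene tibble (one contig, one genetic code) with
#'   `coding_score`.
#' @return The arithmetic sum (0 for no genes).
#' @export
sum_coding_scores <- function(genes) {
  if (nrow(genes) == 0) return(0)
  sum(genes$coding_score)
}

#' Call the genetic code of a contig from per-code coding totals
#'
#' An alternative code is called only when its total coding-potential
#' score is the maximum over all evaluated codes and at least 10% greater
#' than the standard code's total; otherwise the standard code (11) is
#' returned. The call is invariant to positive rescaling of all totals.
#'
#' @param scores Tibble `code`, `total_coding_score` for one contig; the
#'   code 11 entry is mandatory.
#' @param margin Required ratio over the standard code (`>=`).
#' @return The called code (integer).
#' @export
#' @examples
#' detect_genetic_code(tibble::tibble(code = c(11, 15),
#'                                    total_coding_score = c(100, 111)))
detect_genetic_code <- function(scores, margin = 1.10) {
  if (!11 %in% scores$code) {
    abort("scores must include the standard code (11)")
  }
  std <- scores$total_coding_score[scores$code == 11][1]
  alt <- scores %>% filter(.data$code != 11) %>%
    arrange(-.data$total_coding_score, .data$code)
  if (nrow(alt) == 0) return(11L)
  top <- alt[1, ]
  # small relative slack so an exact 10% margin is not lost to floating point
  eps <- 1e-9 * max(1, abs(std))
  if (top$total_coding_score >= margin * std - eps &&
      top$total_coding_score >= max(scores$total_coding_score) - eps) {
    return(as.integer(top$code))
  }
  11L
}

#' Naive ORF-based gene calls and coding scores
#'
#' A deliberately simple stand-in for an external gene caller, used so the
#' alternative-code machinery is testable without one: open reading
#' frames are stop-free stretches in all six frames under the requested
#' code's stop set, and each ORF of at least `min_codons` codons becomes a
#' gene whose coding-potential score is its length in codons. Recoding a
#' stop codon lengthens ORFs that contain it in frame, which is exactly
#' the signal [detect_genetic_code()] consumes.
#'
#' @param contig One-row contig tibble.
#' @param code Genetic-code class (see [code_stop_codons()]).
#' @param min_codons Minimum ORF length in codons.
#' @return A gene tibble (`contig_id`, `gene_index`, `start`, `end`,
#'   `strand`, `coding_score`, `genetic_code`, `protein`).
#' @export
orf_gene_calls <- function(contig, code = 11, min_codons = 30) {
  stopifnot(nrow(contig) == 1)
  stops <- code_stop_codons(code)
  seqs <- c(`+` = contig$sequence, `-` = revcomp(contig$sequence))
  len <- nchar(contig$sequence)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- seqs[[strand]]
    for (frame in 0:2) {
      n_codons <- (nchar(s) - frame) %/% 3
      if (n_codons < 1) next
      starts <- frame + 1 + 3 * (0:(n_codons - 1))
      codons <- substring(s, starts, starts + 2)
      is_stop <- codons %in% stops
      r <- rle(!is_stop)
      ends_idx <- cumsum(r$lengths)
      starts_idx <- ends_idx - r$lengths + 1
      keep <- r$values & r$lengths >= min_codons
      for (i in which(keep)) {
        c0 <- starts[starts_idx[i]]
        c1 <- starts[ends_idx[i]] + 2
        if (strand == "+") {
          g_start <- c0; g_end <- c1
        } else {
          g_start <- len - c1 + 1; g_end <- len - c0 + 1
        }
        rows[[length(rows) + 1]] <- tibble(
          contig_id = contig$id, start = g_start, end = g_end,
          strand = strand, coding_score = r$lengths[i],
          genetic_code = as.integer(code), protein = NA_character_
        )
      }
    }
  }
  if (length(rows) == 0) return(empty_gene_tbl())
  bind_rows(rows) %>%
    arrange(.data$start, .data$end) %>%
    mutate(gene_index = row_number()) %>%
    select("contig_id", "gene_index", "start", "end", "strand",
           "coding_score", "genetic_code", "protein")
}

#' Screen contigs for alternative genetic codes
#'
#' Runs the pluggable gene caller under the standard and the three
#' recoded stop-codon classes on every eligible contig and calls the code
#' by total coding potential. Ineligible contigs are reported as code 11
#' with `eligible = FALSE`.
#'
#' @param contigs Contig tibble.
#' @param gene_caller Function `(contig, code)` returning a gene tibble
#'   with `coding_score`; defaults to [orf_gene_calls()].
#' @param codes Codes to evaluate alongside 11.
#' @param margin Margin over the standard code.
#' @param min_length,max_gc Eligibility bounds.
#' @return Tibble `contig_id`, `eligible`, `code`, plus one
#'   `score_<code>` column per evaluated code.
#' @export
screen_genetic_codes <- function(contigs, gene_caller = orf_gene_calls,
                                 codes = c(4, 15, 90), margin = 1.10,
                                 min_length = 10000, max_gc = 0.50) {
  eligible <- altcode_eligible(contigs, min_length, max_gc)
  all_codes <- c(11, codes)
  purrr::map(seq_len(nrow(contigs)), function(i) {
    row <- tibble(contig_id = contigs$id[i], eligible = eligible[i])
    if (!eligible[i]) {
      row$code <- 11L
      return(row)
    }
    totals <- purrr::map_dbl(all_codes, function(cd) {
      sum_coding_scores(gene_caller(contigs[i, ], cd))
    })
    scores <- tibble(code = all_codes, total_coding_score = totals)
    row$code <- detect_genetic_code(scores, margin)
    for (j in seq_along(all_codes)) {
      row[[paste0("score_", all_codes[j])]] <- totals[j]
    }
    row
  }) %>% bind_rows()
}
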