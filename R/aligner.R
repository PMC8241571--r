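#' Total bases covered by a union of intervals
#'
#' Intervals are 1-based inclusive; overlapping or bookended intervals are
#' merged before summing, matching how alignment coordinates are merged
#' when computing alignment fractions.
#'
#' @param intervals Two-column matrix or data frame of (start, end) pairs.
#' @return Total covered bases (integer-valued numeric).
#' @export
#' @examples
#' merge_intervals(rbind(c(1, 500), c(400, 900)))  # 900
merge_intervals <- function(intervals) {
  iv <- as.matrix(intervals)
  if (nrow(iv) == 0) return(0)
  stopifnot(ncol(iv) == 2, all(iv[, 1] <= iv[, 2]))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  total <- 0
  cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= cur_e + 1) {
        cur_e <- max(cur_e, iv[i, 2])
      } else {
        total <- total + (cur_e - cur_s + 1)
        cur_s <- iv[i, 1]; cur_e <- iv[i, 2]
      }
    }
  }
  unname(total + (cur_e - cur_s + 1))
}

#' Built-in k-mer seeded local aligner
#'
#' A light-weight stand-in for an external all-versus-all nucleotide search,
#' sufficient for genome pairs up to ~100 kb. Shared k-mers seed diagonals;
#' on each seeded diagonal the un-gapped match profile is segmented into
#' high-scoring local alignments (match +1, mismatch -`mismatch_penalty`,
#' X-drop `xdrop`), so terminal mismatches are trimmed exactly as a
#' score-maximising local aligner would. Both strands of the target are
#' searched; N never matches. Alignments below `min_pident` percent
#' identity or shorter than `min_length` are dropped, mirroring the
#' identity pre-filter applied before ANI computation.
#'
#' @param seq_a,seq_b Nucleotide strings (query and target).
#' @param k Seed length.
#' @param min_seg_score Minimum segment score to report.
#' @param min_length Minimum alignment length to report.
#' @param min_pident Minimum percent identity to report.
#' @param mismatch_penalty Penalty per mismatch.
#' @param xdrop Score drop triggering segment termination.
#' @param both_strands Also search the reverse complement of `seq_b`.
#' @param max_seed_hits Ignore seeds whose k-mer occurs more often than this
#'   in the target (repeat masking).
#' @return A hit tibble in the 12-column format of [read_hit_table()]
#'   (query = `seq_a`, target = `seq_b`), with `s_orient`.
#' @export
align_pair <- function(seq_a, seq_b, k = 13, min_seg_score = 25,
                       min_length = 100, min_pident = 90,
                       mismatch_penalty = 1, xdrop = 20,
                       both_strands = TRUE, max_seed_hits = 20) {
  na <- nchar(seq_a); nb <- nchar(seq_b)
  if (na < k || nb < k) return(empty_hit_tbl())
  a_chars <- seq_chars(seq_a)
  hits <- diagonal_hits(seq_a, a_chars, seq_b, "+", k, min_seg_score,
                        min_length, min_pident, mismatch_penalty, xdrop,
                        max_seed_hits)
  if (both_strands) {
    rc <- revcomp(seq_b)
    rhits <- diagonal_hits(seq_a, a_chars, rc, "-", k, min_seg_score,
                           min_length, min_pident, mismatch_penalty, xdrop,
                           max_seed_hits)
    if (nrow(rhits) > 0) {
      # map reverse-strand coordinates back to the forward target
      s1 <- nb - rhits$send + 1
      s2 <- nb - rhits$sstart + 1
      rhits$sstart <- s1
      rhits$send <- s2
      hits <- bind_rows(hits, rhits)
    }
  }
  hits
}

# seed + extend on one strand of the target; returns hit rows
diagonal_hits <- function(seq_a, a_chars, seq_b, orient, k, min_seg_score,
                          min_length, min_pident, mismatch_penalty, xdrop,
                          max_seed_hits) {
  na <- length(a_chars); nb <- nchar(seq_b)
  b_chars <- seq_chars(seq_b)
  qstarts <- seq_len(na - k + 1)
  tstarts <- seq_len(nb - k + 1)
  kmers_a <- substring(seq_a, qstarts, qstarts + k - 1)
  kmers_b <- substring(seq_b, tstarts, tstarts + k - 1)
  pos_by_kmer <- split(tstarts, kmers_b)
  counts <- lengths(pos_by_kmer)
  pos_by_kmer <- pos_by_kmer[counts <= max_seed_hits]
  matches <- pos_by_kmer[kmers_a]
  has <- !vapply(matches, is.null, logical(1))
  if (!any(has)) return(empty_hit_tbl())
  qpos <- rep(qstarts[has], lengths(matches[has]))
  tpos <- unlist(matches[has], use.names = FALSE)
  diags <- unique(qpos - tpos)

  rows <- vector("list", length(diags))
  ri <- 0
  for (d in diags) {
    # overlap of the two sequences on diagonal d (q = t + d)
    q0 <- max(1L, 1L + d); q1 <- min(na, nb + d)
    if (q1 - q0 + 1 < min_length) next
    qa <- a_chars[q0:q1]
    qb <- b_chars[(q0 - d):(q1 - d)]
    mv <- qa == qb & qa != "N" & qb != "N"
    segs <- score_segments(mv, mismatch_penalty, xdrop, min_seg_score)
    if (nrow(segs) == 0) next
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, 1]; e <- segs[i, 2]
      len <- e - s + 1
      nmatch <- sum(mv[s:e])
      pident <- 100 * nmatch / len
      if (len < min_length || pident < min_pident) next
      ri <- ri + 1
      rows[[ri]] <- tibble(
        query_id = "query", target_id = "target",
        pident = pident, length = as.integer(len),
        mismatch = as.integer(len - nmatch), gapopen = 0L,
        qstart = as.integer(q0 + s - 1), qend = as.integer(q0 + e - 1),
        sstart = as.integer(q0 + s - 1 - d), send = as.integer(q0 + e - 1 - d),
        evalue = 0, bitscore = as.numeric(nmatch - mismatch_penalty *
                                            (len - nmatch)),
        s_orient = orient
      )
    }
  }
  if (ri == 0) return(empty_hit_tbl())
  bind_rows(rows[seq_len(ri)])
}

# one-pass X-drop segmentation of a logical match vector into
# high-scoring un-gapped segments; returns matrix of (start, end)
score_segments <- function(mv, mismatch_penalty, xdrop, min_seg_score) {
  s <- ifelse(mv, 1, -mismatch_penalty)
  n <- length(s)
  segs <- list()
  cur <- 0; best <- 0; seg_start <- 1L; best_end <- 0L
  flush <- function() {
    if (best >= min_seg_score && best_end >= seg_start) {
      segs[[length(segs) + 1L]] <<- c(seg_start, best_end)
    }
  }
  i <- 1L
  while (i <= n) {
    cur <- cur + s[i]
    if (cur > best) { best <- cur; best_end <- i }
    if (cur <= 0 || cur < best - xdrop) {
      flush()
      cur <- 0; best <- 0; best_end <- 0L; seg_start <- i + 1L
    }
    i <- i + 1L
  }
  flush()
  if (length(segs) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  out <- do.call(rbind, segs)
  # trim leading mismatches (segments always end on a match by construction)
  for (j in seq_len(nrow(out))) {
    while (!mv[out[j, 1]]) out[j, 1] <- out[j, 1] + 1L
  }
  out
}

#' Pairwise ANI and alignment fraction from local alignments
#'
#' ANI is the length-weighted mean percent identity across local
#' alignments; the alignment fraction (AF) is the percentage of the
#' shorter genome covered by the union of alignment intervals (coordinates
#' merged before dividing). Pairs with no qualifying alignment yield no
#' row ("no edge").
#'
#' @param alignments Hit tibble between one genome pair (query = a,
#'   target = b), e.g. from [align_pair()] or an external search.
#' @param len_q,len_t Genome lengths of query and target.
#' @param min_pident Alignments below this identity are ignored.
#' @return A one-row tibble `ani`, `af_shorter`, `n_alignments`, or a
#'   zero-row tibble when no alignment qualifies.
#' @export
pairwise_ani <- function(alignments, len_q, len_t, min_pident = 90) {
  al <- alignments %>% filter(.data$pident >= min_pident)
  if (nrow(al) == 0) {
    return(tibble(ani = numeric(), af_shorter = numeric(),
                  n_alignments = integer()))
  }
  ani <- sum(al$pident * al$length) / sum(al$length)
  if (len_q <= len_t) {
    iv <- cbind(al$qstart, al$qend)
  } else {
    iv <- cbind(al$sstart, al$send)
  }
  af <- 100 * merge_intervals(iv) / min(len_q, len_t)
  tibble(ani = ani, af_shorter = min(af, 100), n_alignments = nrow(al))
}

#' ANI/AF between two sequences via the built-in aligner
#'
#' Convenience wrapper chaining [align_pair()] and [pairwise_ani()].
#'
#' @inheritParams align_pair
#' @param min_pident Identity pre-filter on local alignments.
#' @param ... Passed to [align_pair()].
#' @return As [pairwise_ani()].
#' @export
sequence_ani <- function(seq_a, seq_b, min_pident = 90, ...) {
  hits <- align_pair(seq_a, seq_b, min_pident = min_pident, ...)
  pairwise_ani(hits, nchar(seq_a), nchar(seq_b), min_pident = min_pident)
}
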