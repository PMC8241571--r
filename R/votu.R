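#' Dereplicate genomes at 100% identity over the full shorter sequence
#'
#' Removes any sequence that is an exact duplicate or an exact substring of
#' a longer retained sequence (optionally also on the reverse-complement
#' strand, since assemblers emit either orientation). Among identical
#' sequences the lexicographically smallest id is retained.
#'
#' @param contigs Contig tibble.
#' @param revcomp_too Also treat reverse-complement containment as
#'   redundancy.
#' @return The retained subset of `contigs`, in decreasing length order.
#' @export
dereplicate_genomes <- function(contigs, revcomp_too = TRUE) {
  ord <- order(-contigs$length, contigs$id)
  x <- contigs[ord, ]
  keep <- logical(nrow(x))
  kept_seqs <- character(0)
  for (i in seq_len(nrow(x))) {
    s <- x$sequence[i]
    redundant <- any(stringr::str_detect(kept_seqs, stringr::fixed(s)))
    if (!redundant && revcomp_too) {
      redundant <- any(stringr::str_detect(kept_seqs,
                                           stringr::fixed(revcomp(s))))
    }
    if (!redundant) {
      keep[i] <- TRUE
      kept_seqs <- c(kept_seqs, s)
    }
  }
  log_filter("votu", "dereplicated at 100/100", nrow(x), sum(keep))
  x[keep, ]
}

#' Greedy centroid clustering into species-level vOTUs
#'
#' Genomes are sorted by decreasing length (ties by id); the longest
#' unassigned genome seeds a cluster and every unassigned genome within
#' `min_ani` ANI and `min_af` alignment fraction of that centroid joins it;
#' this repeats until all genomes are assigned. Sorting first makes the
#' result invariant to input order. Members are never reassigned to a
#' later, closer centroid.
#'
#' @param contigs Contig tibble (dereplicated).
#' @param ani_source Either `NULL` (compute ANI on demand with
#'   [sequence_ani()]), or a precomputed tibble with columns `query_id`,
#'   `target_id`, `ani`, `af_shorter` covering both orientations of each
#'   pair that has an edge.
#' @param min_ani,min_af Cluster admission thresholds (percent, inclusive).
#' @param ... Passed to [sequence_ani()] when computing on demand.
#' @return An object of class `votu_clusters`: list with `membership`
#'   (tibble `id`, `votu`, `representative`, `is_representative`) and the
#'   thresholds used.
#' @export
cluster_votus <- function(contigs, ani_source = NULL, min_ani = 95,
                          min_af = 85, ...) {
  x <- contigs[order(-contigs$length, contigs$id), ]
  n <- nrow(x)
  assigned <- rep(NA_integer_, n)
  lookup <- if (is.null(ani_source)) {
    function(i, j) sequence_ani(x$sequence[i], x$sequence[j], ...)
  } else {
    function(i, j) {
      hit <- ani_source %>%
        filter((.data$query_id == x$id[i] & .data$target_id == x$id[j]) |
                 (.data$query_id == x$id[j] & .data$target_id == x$id[i]))
      if (nrow(hit) == 0) tibble(ani = numeric(), af_shorter = numeric())
      else tibble(ani = max(hit$ani), af_shorter = max(hit$af_shorter))
    }
  }
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    cluster_id <- cluster_id + 1L
    assigned[i] <- cluster_id
    todo <- which(is.na(assigned))
    for (j in todo) {
      rel <- lookup(j, i)
      if (nrow(rel) == 1 && rel$ani >= min_ani && rel$af_shorter >= min_af) {
        assigned[j] <- cluster_id
      }
    }
  }
  reps <- x$id[match(seq_len(max(assigned)), assigned)]
  membership <- tibble(
    id = x$id,
    votu = paste0("vOTU_", sprintf("%04d", assigned)),
    representative = reps[assigned],
    is_representative = x$id == reps[assigned]
  )
  structure(list(membership = membership, min_ani = min_ani,
                 min_af = min_af),
            class = "votu_clusters")
}

#' @export
print.votu_clusters <- function(x, ...) {
  cat(sprintf("%d genomes in %d vOTUs (ANI >= %s, AF >= %s)\n",
              nrow(x$membership), length(unique(x$membership$votu)),
              x$min_ani, x$min_af))
  invisible(x)
}

#' Tidy vOTU membership
#'
#' @param x A `votu_clusters` object.
#' @param ... Unused.
#' @return The membership tibble.
#' @method tidy votu_clusters
#' @export
tidy.votu_clusters <- function(x, ...) x$membership

#' One-row summary of a vOTU clustering
#'
#' @param x A `votu_clusters` object.
#' @param ... Unused.
#' @return Tibble with genome count, cluster count, largest cluster size
#'   and singleton count.
#' @method glance votu_clusters
#' @export
glance.votu_clusters <- function(x, ...) {
  sizes <- table(x$membership$votu)
  tibble(n_genomes = nrow(x$membership), n_votus = length(sizes),
         largest = max(sizes), n_singletons = sum(sizes == 1))
}
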