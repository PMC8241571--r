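#' Trim alignment columns by gap fraction
#'
#' Columns in which at least `max_gap_fraction` of sequences are gaps are
#' removed (i.e. positions with less than 50% gaps are retained at the
#' default), matching the trimming applied to marker alignments before
#' concatenation.
#'
#' @param alignment Named character vector (id -> aligned sequence, equal
#'   lengths; gap = `-`).
#' @param max_gap_fraction Columns with gap fraction `>=` this are removed.
#' @return The trimmed alignment (named character vector); retained column
#'   indices are attached as attribute `"kept"`.
#' @export
trim_alignment_columns <- function(alignment, max_gap_fraction = 0.5) {
  if (length(alignment) == 0) abort("empty alignment")
  widths <- unique(nchar(alignment))
  if (length(widths) != 1) abort("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac < max_gap_fraction
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  out <- setNames(out, names(alignment))
  attr(out, "kept") <- which(keep)
  out
}

#' Concatenate marker alignments into a supermatrix
#'
#' Markers are concatenated in list order; genomes missing a marker
#' receive an all-gap block of that marker's width, so every row has the
#' same total length.
#'
#' @param markers Named list of alignments (each a named character vector,
#'   id -> aligned sequence), individually trimmed.
#' @param genome_ids Genomes to include (rows of the supermatrix).
#' @return List with `alignment` (named character vector),
#'   `marker_counts` (tibble `genome_id`, `n_markers`) and
#'   `marker_widths`.
#' @export
concatenate_markers <- function(markers, genome_ids) {
  if (length(genome_ids) == 0) abort("empty genome set")
  widths <- purrr::map_int(markers, ~ unique(nchar(.x))[1])
  rows <- purrr::map_chr(genome_ids, function(g) {
    paste(purrr::imap_chr(markers, function(aln, m) {
      if (g %in% names(aln)) aln[[g]] else strrep("-", widths[[m]])
    }), collapse = "")
  })
  counts <- purrr::map_int(genome_ids, function(g) {
    sum(purrr::map_lgl(markers, ~ g %in% names(.x)))
  })
  list(alignment = setNames(rows, genome_ids),
       marker_counts = tibble(genome_id = genome_ids, n_markers = counts),
       marker_widths = widths)
}

#' Filter genomes from a concatenated alignment
#'
#' Genomes enter the phylogeny only with at least `min_markers` markers
#' and data (non-gap characters) at more than `min_col_fraction` of
#' alignment columns.
#'
#' @param concat Result of [concatenate_markers()].
#' @param min_markers Minimum marker count (inclusive).
#' @param min_col_fraction Non-gap column fraction (strict >).
#' @return Character vector of retained genome ids.
#' @export
filter_concat_genomes <- function(concat, min_markers = 3,
                                  min_col_fraction = 0.05) {
  aln <- concat$alignment
  width <- unique(nchar(aln))[1]
  nongap <- 1 - stringr::str_count(aln, stringr::fixed("-")) / width
  ok <- concat$marker_counts$n_markers >= min_markers &
    nongap > min_col_fraction
  log_filter("phylo", "genomes surviving marker/column filters",
             length(aln), sum(ok))
  concat$marker_counts$genome_id[ok]
}

#' Phylogenetic diversity of a tip subset
#'
#' The sum of branch lengths of all branches with at least one subset tip
#' among their descendants on the rooted tree; with all tips selected this
#' equals the tree's total branch length.
#'
#' @param tree An [ape::phylo] tree with branch lengths (rooted; root with
#'   [midpoint_root_tree()] first if needed).
#' @param tip_subset Character vector of tip labels (subset of the tree's
#'   tips).
#' @return The branch-length sum (0 for an empty subset).
#' @export
phylogenetic_diversity <- function(tree, tip_subset) {
  if (length(tip_subset) == 0) return(0)
  if (!all(tip_subset %in% tree$tip.label)) {
    abort("tip_subset must be a subset of the tree's tips")
  }
  n_tip <- length(tree$tip.label)
  sel <- match(tip_subset, tree$tip.label)
  # mark every node with a selected descendant, tips upward
  has_sel <- logical(n_tip + tree$Nnode)
  has_sel[sel] <- TRUE
  edges <- tree$edge[order(tree$edge[, 2]), , drop = FALSE]
  # process edges child-first in reverse depth order: repeat sweeps until
  # stable (trees are small; a postorder would be one pass)
  repeat {
    prop <- has_sel[tree$edge[, 2]] & !has_sel[tree$edge[, 1]]
    if (!any(prop)) break
    has_sel[tree$edge[prop, 1]] <- TRUE
  }
  sum(tree$edge.length[has_sel[tree$edge[, 2]]])
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path.
#'
#' @param tree An [ape::phylo] tree with branch lengths and at least two
#'   tips.
#' @return The rooted tree.
#' @export
midpoint_root_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 2)
  if (sum(tree$edge.length) <= 0) abort("tree has zero total branch length")
  phangorn::midpoint(tree)
}

#' Core-genome SNP matrix for one species cluster
#'
#' Member genomes are represented in the coordinates of the cluster's
#' longest genome (the reference): each row is a reference-length string
#' in which `-` or `N` marks positions the genome does not cover.
#' Variant positions are called where at least `min_site_coverage` of
#' genomes have data and more than one allele is observed (substitutions
#' only); genomes with data at fewer than `min_genome_data` of the
#' retained positions are then dropped, in that order.
#'
#' @param aligned Named character vector: genome id -> reference-aligned
#'   sequence, all of reference length.
#' @param min_site_coverage Fraction of genomes that must cover a position
#'   (inclusive).
#' @param min_genome_data Fraction of retained positions a genome must
#'   cover (inclusive).
#' @return List with `matrix` (character matrix genomes x positions,
#'   `NA` = missing), `positions` (reference coordinates) and `genomes`.
#' @export
core_snp_matrix <- function(aligned, min_site_coverage = 0.5,
                            min_genome_data = 0.5) {
  if (length(aligned) < 2) abort("need at least two genomes")
  widths <- unique(nchar(aligned))
  if (length(widths) != 1) abort("sequences must share reference coordinates")
  m <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  rownames(m) <- names(aligned)
  m[m %in% c("-", "N")] <- NA
  covered <- colMeans(!is.na(m)) >= min_site_coverage
  n_allele <- apply(m, 2, function(col) length(unique(stats::na.omit(col))))
  variant <- covered & n_allele >= 2
  positions <- which(variant)
  snp <- m[, variant, drop = FALSE]
  if (length(positions) > 0) {
    genome_ok <- rowMeans(!is.na(snp)) >= min_genome_data
  } else {
    genome_ok <- rep(TRUE, nrow(m))
  }
  log_filter("phylo", "genomes surviving SNP data filter",
             nrow(m), sum(genome_ok))
  list(matrix = snp[genome_ok, , drop = FALSE],
       positions = positions,
       genomes = rownames(m)[genome_ok])
}
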