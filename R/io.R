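#' Read a nucleotide or protein FASTA file into a contig table
#'
#' Wraps [Biostrings::readBStringSet()] and returns one row per record with
#' derived length and GC columns, preserving file order. Duplicate record ids
#' and empty sequences are errors: every downstream stage keys on unique
#' contig ids.
#'
#' @param path Path to a FASTA file.
#' @param type `"DNA"` (default) or `"AA"`; GC is only computed for DNA.
#' @return A tibble with columns `id`, `sequence`, `length`, `gc`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence for id(s): ",
                 paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  contig_tbl(ids, seqs, compute_gc = type == "DNA")
}

#' Build a contig table from ids and sequences
#'
#' @param id Character vector of unique record ids.
#' @param sequence Character vector of sequences, same length as `id`.
#' @param compute_gc Compute the `gc` column (DNA only).
#' @return A tibble with columns `id`, `sequence`, `length`, `gc`.
#' @export
contig_tbl <- function(id, sequence, compute_gc = TRUE) {
  stopifnot(length(id) == length(sequence), !anyDuplicated(id),
            all(nchar(sequence) >= 1))
  tibble(
    id = as.character(id),
    sequence = toupper(as.character(sequence)),
    length = nchar(sequence),
    gc = if (compute_gc) gc_content(sequence) else NA_real_
  )
}

#' Write a contig table to FASTA
#'
#' @param contigs A tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 80L) {
  stopifnot(all(c("id", "sequence") %in% names(contigs)))
  set <- Biostrings::BStringSet(setNames(contigs$sequence, contigs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a gene-call table
#'
#' Reads the tab-separated gene dialect used throughout the package: columns
#' `contig`, `caller`, `feature`, `start`, `end`, `coding_score`, `strand`,
#' `frame`, `attributes`. Coordinates are 1-based inclusive. Genes are
#' returned grouped by contig and sorted by start, with a 1-based
#' `gene_index` assigned within each contig. The `attributes` column may
#' carry `genetic_code=<int>` and `protein=<aa string>` key=value pairs
#' separated by `;`.
#'
#' @param path Path to a tab-separated gene table (may have `#` comments).
#' @return A tibble with columns `contig_id`, `gene_index`, `start`, `end`,
#'   `strand`, `coding_score`, `genetic_code`, `protein`.
#' @export
read_gene_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_gene_tbl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    abort(sprintf("malformed gene table: expected 9 columns, got %d at line %d",
                  nf[which(nf != 9)[1]], which(nf != 9)[1]))
  }
  m <- do.call(rbind, fields)
  attr_get <- function(attrs, key) {
    val <- stringr::str_match(attrs, paste0("(?:^|;)\\s*", key, "=([^;]*)"))[, 2]
    val
  }
  genes <- tibble(
    contig_id = m[, 1],
    start = as.integer(m[, 4]),
    end = as.integer(m[, 5]),
    coding_score = as.numeric(m[, 6]),
    strand = m[, 7],
    genetic_code = as.integer(attr_get(m[, 9], "genetic_code") %||% NA),
    protein = attr_get(m[, 9], "protein")
  )
  genes$genetic_code[is.na(genes$genetic_code)] <- 11L
  if (any(bad <- !(genes$strand %in% c("+", "-")))) {
    abort(sprintf("unknown strand symbol '%s' at line %d",
                  genes$strand[which(bad)[1]], which(bad)[1]))
  }
  if (any(bad <- genes$start > genes$end)) {
    abort(sprintf("start > end at line %d", which(bad)[1]))
  }
  genes %>%
    arrange(.data$contig_id, .data$start, .data$end) %>%
    group_by(.data$contig_id) %>%
    mutate(gene_index = row_number()) %>%
    ungroup() %>%
    select("contig_id", "gene_index", "start", "end", "strand",
           "coding_score", "genetic_code", "protein")
}

empty_gene_tbl <- function() {
  tibble(contig_id = character(), gene_index = integer(),
         start = integer(), end = integer(), strand = character(),
         coding_score = numeric(), genetic_code = integer(),
         protein = character())
}

#' Write a gene-call table
#'
#' Inverse of [read_gene_table()] up to column ordering.
#'
#' @param genes A gene tibble as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  attrs <- paste0("genetic_code=", genes$genetic_code,
                  ifelse(is.na(genes$protein), "",
                         paste0(";protein=", genes$protein)))
  lines <- paste(genes$contig_id, "phagetools", "CDS", genes$start, genes$end,
                 genes$coding_score, genes$strand, "0", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a 12-column tabular alignment hit table
#'
#' The standard tabular search format: query, target, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bit score. Reverse-strand subject alignments (sstart > send) are
#' normalised on load to `sstart <= send` with `s_orient = "-"`.
#'
#' @param path Path to a tab-separated 12-column file.
#' @return A tibble with the twelve standard columns (named `query_id`,
#'   `target_id`, `pident`, `length`, `mismatch`, `gapopen`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`) plus `s_orient`.
#' @export
read_hit_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_hit_tbl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    abort(sprintf("malformed hit table: expected 12 columns, got %d at line %d",
                  nf[which(nf != 12)[1]], which(nf != 12)[1]))
  }
  m <- do.call(rbind, fields)
  hits <- tibble(
    query_id = m[, 1], target_id = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  )
  if (any(bad <- hits$qstart > hits$qend)) {
    abort(sprintf("qstart > qend at line %d", which(bad)[1]))
  }
  normalise_hit_strand(hits)
}

normalise_hit_strand <- function(hits) {
  flip <- hits$sstart > hits$send
  hits$s_orient <- ifelse(flip, "-", "+")
  tmp <- hits$sstart[flip]
  hits$sstart[flip] <- hits$send[flip]
  hits$send[flip] <- tmp
  hits
}

empty_hit_tbl <- function() {
  tibble(query_id = character(), target_id = character(),
         pident = numeric(), length = integer(), mismatch = integer(),
         gapopen = integer(), qstart = integer(), qend = integer(),
         sstart = integer(), send = integer(), evalue = numeric(),
         bitscore = numeric(), s_orient = character())
}

#' Write a hit table in 12-column tabular format
#'
#' Reverse-orientation rows (`s_orient == "-"`) are written with
#' sstart > send, matching the raw search-tool convention.
#'
#' @param hits A hit tibble as returned by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  s1 <- ifelse(hits$s_orient %||% "+" == "-", hits$send, hits$sstart)
  s2 <- ifelse(hits$s_orient %||% "+" == "-", hits$sstart, hits$send)
  lines <- paste(hits$query_id, hits$target_id, hits$pident, hits$length,
                 hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
                 s1, s2, format(hits$evalue), hits$bitscore, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
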