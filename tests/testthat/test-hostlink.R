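test_that("overlapping CRISPR arrays merge with spacer deduplication", {
  arrays <- tibble::tibble(
    array_id = c("crt_1", "pilercr_1", "crt_2"),
    host_genome_id = "h1", contig_id = c("ctg1", "ctg1", "ctg1"),
    start = c(100, 450, 2000), end = c(500, 900, 2400),
    source_tool = c("crt", "pilercr", "crt")
  )
  spacers <- tibble::tibble(
    array_id = c("crt_1", "crt_1", "pilercr_1", "crt_2"),
    sequence = c("ACGTACGTACGTACGTACGT", "TTTTGGGGCCCCAAAATTTT",
                 "ACGTACGTACGTACGTACGT", "GGGGCCCCTTTTAAAAGGGG")
  )
  merged <- merge_crispr_arrays(arrays, spacers)
  expect_equal(nrow(merged$arrays), 2)
  first <- dplyr::filter(merged$arrays, start == 100)
  expect_equal(first$end, 900)
  expect_equal(first$source_tool, "crt,pilercr")
  in_first <- dplyr::filter(merged$spacers,
                            array_id == first$merged_array_id)
  expect_equal(nrow(in_first), 2)   # shared spacer collapsed
  expect_equal(nrow(merged$spacers), 3)
})

test_that("spacer matches tolerate one edit over 95% coverage", {
  virus <- contig_tbl("v1", random_dna(3000, seed = 111))
  for (mm in 0:2) {
    pl <- sim_spacer_plantings(virus, n = 12, mismatches = mm,
                               seed = 500 + mm)
    conn <- match_spacers(pl$spacers, virus)
    if (mm <= 1) {
      expect_equal(nrow(conn), 12)
      expect_equal(sort(unique(conn$edits)), mm)
    } else {
      expect_equal(nrow(conn), 0)
    }
  }
})

test_that("spacer matching is strand-symmetric", {
  virus <- contig_tbl("v1", random_dna(2000, seed = 131))
  sp <- substr(virus$sequence, 501, 532)
  fwd <- tibble::tibble(spacer_id = "s1", host_genome_id = "h1",
                        sequence = sp)
  rev <- dplyr::mutate(fwd, sequence = revcomp(sp))
  c_fwd <- match_spacers(fwd, virus)
  c_rev <- match_spacers(rev, virus)
  expect_equal(nrow(c_fwd), 1)
  expect_equal(nrow(c_rev), 1)
  expect_equal(c_fwd$start, c_rev$start)
  expect_equal(c_fwd$end, c_rev$end)
})

test_that("single indels are accepted within the edit budget", {
  virus <- contig_tbl("v1", random_dna(2000, seed = 141))
  sp <- substr(virus$sequence, 801, 832)
  chars <- strsplit(sp, "")[[1]]
  with_del <- paste(chars[-16], collapse = "")          # spacer lost a base
  with_ins <- paste(c(chars[1:16], "A", chars[17:32]), collapse = "")
  two_edit <- paste(c(chars[1:10], "A", chars[11:20], "C", chars[21:32]),
                    collapse = "")
  tb <- function(s) tibble::tibble(spacer_id = "s", host_genome_id = "h",
                                   sequence = s)
  expect_equal(nrow(match_spacers(tb(with_del), virus)), 1)
  expect_equal(nrow(match_spacers(tb(with_ins), virus)), 1)
  expect_equal(nrow(match_spacers(tb(two_edit), virus)), 0)
})

test_that("spacer matcher agrees with the brute-force edit-distance oracle", {
  withr::with_seed(61, {
    for (i in 1:12) {
      virus <- contig_tbl("v", random_dna(800))
      mm <- sample(0:2, 1)
      pl <- sim_spacer_plantings(virus, n = 1, mismatches = mm, seed = i)
      got <- nrow(match_spacers(pl$spacers, virus)) > 0
      oracle <- bruteforce_spacer_hit(pl$spacers$sequence[1],
                                      virus$sequence)
      expect_equal(got, oracle)
    }
  })
})

test_that("genome matches require 1 kb at 96% identity", {
  withr::with_seed(71, {
    virus <- contig_tbl("v1", random_dna(5000))
    host_bg <- random_dna(4000)
  })
  mk_host <- function(insert) {
    tibble::tibble(id = "hc1", host_genome_id = "h1",
                   sequence = paste0(substr(host_bg, 1, 2000), insert,
                                     substr(host_bg, 2001, 4000)))
  }
  long_exact <- mk_host(substr(virus$sequence, 1001, 2200))   # 1.2 kb
  conn <- genome_matches(long_exact, virus)
  expect_equal(nrow(conn), 1)
  expect_equal(conn$evidence, "genome_match")
  expect_gte(conn$length, 1000)
  short_exact <- mk_host(substr(virus$sequence, 1001, 1900))  # 0.9 kb
  expect_equal(nrow(genome_matches(short_exact, virus)), 0)
  # a 1.5 kb insert with a substitution every 20 bp sits at exactly 95%
  # identity in every window, below the 96% floor
  seg <- substr(virus$sequence, 2001, 3500)
  chars <- strsplit(seg, "")[[1]]
  at <- seq(10, 1500, by = 20)
  chars[at] <- chartr("ACGT", "TGCA", chars[at])
  expect_equal(nrow(genome_matches(mk_host(paste(chars, collapse = "")),
                                   virus)), 0)
})

test_that("host decontamination keeps contigs at or above half host content", {
  hc <- tibble::tibble(
    id = c("c1", "c2", "c3", "c4"), host_genome_id = "h",
    sequence = "ACGT", host_fraction = c(0.40, 0.80, 0.50, NA)
  )
  kept <- suppressWarnings(decontaminate_host_contigs(hc))
  expect_setequal(kept$id, c("c2", "c3", "c4"))
  expect_warning(decontaminate_host_contigs(hc), "host_fraction")
  expect_error(decontaminate_host_contigs(hc[, 1:3]), "host_fraction")
})

host_lineages <- tibble::tibble(
  host_genome_id = c("h1", "h2", "h3", "h4"),
  domain = "Bacteria", phylum = "Bacteroidota", class = "Bacteroidia",
  order = "Bacteroidales", family = "Bacteroidaceae",
  genus = c("Bacteroides", "Bacteroides", "Bacteroides", "Phocaeicola"),
  species = c("B. uniformis", "B. uniformis", "B. uniformis", "P. dorei")
)

test_that("host consensus picks the lowest rank above 70% agreement", {
  conns <- tibble::tibble(virus_id = "v",
                          host_genome_id = c("h1", "h2", "h3", "h4"))
  out <- host_consensus(conns, host_lineages)
  expect_equal(out$assigned_rank, "species")   # 3/4 = 75% > 70%
  expect_equal(out$species, "B. uniformis")
  expect_equal(out$genus, "Bacteroides")

  unanimous <- host_consensus(conns[1:3, ], host_lineages)
  expect_equal(unanimous$species, "B. uniformis")
  expect_equal(unanimous$agreement, 1)

  split <- tibble::tibble(virus_id = "v",
                          host_genome_id = c("h1", "h1", "h4", "h4"))
  out_split <- suppressWarnings(host_consensus(split, host_lineages))
  expect_true(is.na(out_split$genus))          # 50/50 at genus and species
  expect_equal(out_split$assigned_rank, "family")
  expect_equal(out_split$family, "Bacteroidaceae")

  none <- host_consensus(conns[0, ], host_lineages)
  expect_true(is.na(none$assigned_rank))
  expect_equal(none$n_connections, 0)
})
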