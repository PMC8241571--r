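test_that("column trimming removes positions with half or more gaps", {
  aln <- c(g1 = "AC-DE", g2 = "AC-DE", g3 = "A--DE", g4 = "AC-D-")
  # column 3 is all gaps; column 2 has 1/4 gaps; column 5 has 1/4
  trimmed <- trim_alignment_columns(aln)
  expect_equal(unname(trimmed["g1"]), "ACDE")
  expect_equal(attr(trimmed, "kept"), c(1, 2, 4, 5))

  half <- c(g1 = "A-", g2 = "A-", g3 = "AC", g4 = "AC")
  # 50% gaps: removed (retain only positions with *less* than 50%)
  expect_equal(unname(trim_alignment_columns(half)["g1"]), "A")

  clean <- c(g1 = "ACDE", g2 = "ACDE")
  expect_equal(unname(trim_alignment_columns(clean)["g2"]), "ACDE")
  expect_error(trim_alignment_columns(character(0)), "empty")
})

test_that("marker concatenation pads missing markers with gap blocks", {
  markers <- list(
    m1 = c(gA = strrep("A", 10), gB = strrep("C", 10)),
    m2 = c(gA = strrep("D", 20)),
    m3 = c(gA = strrep("E", 30), gB = strrep("F", 30))
  )
  cc <- concatenate_markers(markers, c("gA", "gB"))
  expect_equal(nchar(cc$alignment[["gA"]]), 60)
  expect_equal(substr(cc$alignment[["gB"]], 11, 30), strrep("-", 20))
  expect_equal(substr(cc$alignment[["gB"]], 31, 60), strrep("F", 30))
  expect_equal(cc$marker_counts$n_markers, c(3L, 2L))
  expect_error(concatenate_markers(markers, character(0)), "empty")
})

test_that("genome filters demand three markers and 5% of columns", {
  # 100-column supermatrix built from three markers
  mk <- function(width, fill, genomes) {
    setNames(purrr::map_chr(genomes, ~ strrep(fill, width)), genomes)
  }
  markers <- list(
    m1 = mk(8, "A", c("keep", "few_markers", "sparse")),
    m2 = mk(46, "-", c("keep", "few_markers")),  # all-gap rows: still "present"
    m3 = mk(46, "C", c("keep", "sparse"))
  )
  markers$m2[["keep"]] <- strrep("D", 46)
  markers$m3[["sparse"]] <- paste0("CC", strrep("-", 44))
  cc <- concatenate_markers(markers, c("keep", "few_markers", "sparse"))
  kept <- filter_concat_genomes(cc)
  # keep: 3 markers, 100% data; few_markers: 2 markers; sparse: 2 markers
  expect_equal(kept, "keep")
  # marker count at exactly 3 with >5% columns passes
  expect_true("keep" %in%
                filter_concat_genomes(cc, min_markers = 2,
                                      min_col_fraction = 0.05))
  # data at exactly 5% of columns fails the strict threshold
  markers2 <- list(m1 = c(g = strrep("A", 5), h = strrep("A", 5)),
                   m2 = c(g = strrep("C", 95), h = strrep("-", 95)),
                   m3 = c(g = strrep("D", 10), h = strrep("D", 10)))
  cc2 <- concatenate_markers(markers2, c("g", "h"))
  # h has data at 15/110 columns > 5%: kept; then tighten the fraction
  expect_true("h" %in% filter_concat_genomes(cc2, min_markers = 3))
  expect_false("h" %in% filter_concat_genomes(cc2, min_markers = 3,
                                              min_col_fraction = 15 / 110))
})

test_that("phylogenetic diversity sums represented branches", {
  # balanced quartet with unit branches: two sister tips span 3 branches
  quartet <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  expect_equal(phylogenetic_diversity(quartet, c("t1", "t2")), 3)
  expect_equal(phylogenetic_diversity(quartet, c("t1", "t3")), 4)
  expect_equal(phylogenetic_diversity(quartet, quartet$tip.label),
               sum(quartet$edge.length))
  expect_equal(phylogenetic_diversity(quartet, character(0)), 0)
  expect_error(phylogenetic_diversity(quartet, "t9"), "subset")
})

test_that("diversity equals the root-to-tip path-union oracle", {
  withr::with_seed(47, {
    for (i in 1:15) {
      tree <- sim_toy_tree(sample(4:20, 1), seed = i)
      tips <- sample(tree$tip.label, sample(seq_along(tree$tip.label), 1))
      expect_equal(phylogenetic_diversity(tree, tips),
                   pd_path_union_oracle(tree, tips), tolerance = 1e-10)
    }
  })
})

test_that("diversity is monotone in the tip subset", {
  tree <- sim_toy_tree(12, seed = 5)
  withr::with_seed(6, {
    tips <- sample(tree$tip.label)
  })
  pd <- vapply(seq_along(tips), function(k) {
    phylogenetic_diversity(tree, tips[1:k])
  }, numeric(1))
  expect_true(all(diff(pd) >= 0))
  expect_equal(pd[length(pd)], sum(tree$edge.length))
})

test_that("midpoint rooting centres the longest tip-to-tip path", {
  two <- ape::read.tree(text = "(a:2,b:4);")
  rooted <- midpoint_root_tree(two)
  depths <- ape::node.depth.edgelength(rooted)
  expect_equal(unname(depths[1:2]), c(3, 3))

  quartet <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  rq <- midpoint_root_tree(quartet)
  dq <- ape::node.depth.edgelength(rq)
  expect_true(all(abs(dq[1:4] - 2) < 1e-10))

  # idempotence on random trees
  for (i in 1:5) {
    tree <- sim_toy_tree(8, seed = 70 + i)
    r1 <- midpoint_root_tree(tree)
    r2 <- midpoint_root_tree(r1)
    expect_equal(sort(ape::node.depth.edgelength(r1)[1:8]),
                 sort(ape::node.depth.edgelength(r2)[1:8]),
                 tolerance = 1e-10)
  }
})

test_that("core SNP matrices apply coverage then genome-data filters", {
  aligned <- c(
    ref  = "ACGTACGTAC",
    g2   = "ACGTACGAAC",   # one substitution at position 8
    g3   = "ACGAACGT--",   # substitution at 4, misses 9-10
    g4   = "NNNNNNGTAC"    # covers only 7-10
  )
  snp <- core_snp_matrix(aligned)
  # positions 4 and 8 vary among covered genomes
  expect_equal(snp$positions, c(4, 8))
  expect_setequal(snp$genomes, c("ref", "g2", "g3", "g4"))
  expect_equal(unname(snp$matrix["g3", 1]), "A")
  expect_true(is.na(snp$matrix["g4", 1]))

  # a genome below 50% data at variant positions is dropped
  aligned2 <- c(ref = "ACGTACGTAC", g2 = "TCGAACGAAC",
                g5 = "T---------")
  snp2 <- core_snp_matrix(aligned2)
  expect_false("g5" %in% snp2$genomes)

  ident <- c(a = "ACGT", b = "ACGT", c = "ACGT")
  expect_equal(length(core_snp_matrix(ident)$positions), 0)
  expect_error(core_snp_matrix(c(a = "ACGT")), "two genomes")
})
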