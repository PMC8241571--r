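make_hits <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(purrr::map(rows, function(r) {
    tibble::tibble(query_id = r[[1]], target_id = r[[2]],
                   pident = as.numeric(r[[3]]),
                   bitscore = as.numeric(r[[4]]), evalue = 1e-10)
  }))
}

test_that("AAI averages best bidirectional hit identities", {
  hits <- make_hits(
    list("a1", "b1", 50, 100), list("b1", "a1", 50, 100),
    list("a2", "b2", 70, 120), list("b2", "a2", 70, 120)
  )
  r <- compute_aai(hits, paste0("a", 1:4), paste0("b", 1:3))
  expect_equal(r$aai, 60)
  expect_equal(r$n_shared, 2)
  expect_equal(r$shared_fraction, 100 * 2 / 3)  # smaller gene count

  # identical proteomes
  ident <- dplyr::bind_rows(purrr::map(1:10, function(i) make_hits(
    list(paste0("a", i), paste0("b", i), 100, 200),
    list(paste0("b", i), paste0("a", i), 100, 200))))
  ri <- compute_aai(ident, paste0("a", 1:10), paste0("b", 1:10))
  expect_equal(ri$aai, 100)
  expect_equal(ri$shared_fraction, 100)

  # one-way hits are not shared genes
  oneway <- make_hits(list("a1", "b1", 80, 100))
  expect_equal(nrow(compute_aai(oneway, "a1", "b1")), 0)
  # the e-value floor removes weak pairs entirely
  weak <- dplyr::mutate(hits, evalue = 1e-4)
  expect_equal(nrow(compute_aai(weak, paste0("a", 1:4), paste0("b", 1:3))), 0)
  expect_error(compute_aai(hits, character(0), "b1"), "gene")
})

test_that("rank graphs apply the family and genus edge floors", {
  pairs <- tibble::tibble(
    genome_a = c("g1", "g1", "g2"), genome_b = c("g2", "g3", "g3"),
    aai = c(45, 55, 80), shared_fraction = c(25, 8, 60)
  )
  fam <- build_rank_graph(pairs, "family")
  gen <- build_rank_graph(pairs, "genus")
  expect_setequal(paste(fam$from, fam$to),
                  c("g1 g2", "g2 g3"))      # (55, 8) fails 10% sharing
  expect_setequal(paste(gen$from, gen$to), "g2 g3")
  expect_equal(fam$weight[fam$from == "g2"], 80 * 60 / 100)
  # genus edges are always a subset of family edges
  withr::with_seed(2, {
    rnd <- tibble::tibble(
      genome_a = sprintf("x%02d", 1:40),
      genome_b = sprintf("y%02d", 1:40),
      aai = runif(40, 0, 100), shared_fraction = runif(40, 0, 100)
    )
  })
  fam_r <- build_rank_graph(rnd, "family")
  gen_r <- build_rank_graph(rnd, "genus")
  expect_true(all(paste(gen_r$from, gen_r$to) %in%
                    paste(fam_r$from, fam_r$to)))
})

clique_edges <- function(ids, weight = 1) {
  g <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  g <- g[g$from < g$to, ]
  g$weight <- weight
  tibble::as_tibble(g)
}

test_that("MCL recovers connected components of clique unions", {
  skip_if_not_installed("igraph")
  withr::with_seed(19, {
    for (rep in 1:8) {
      n_cliques <- sample(2:4, 1)
      edges <- dplyr::bind_rows(purrr::map(seq_len(n_cliques), function(k) {
        clique_edges(sprintf("c%d_n%d", k, seq_len(sample(3:6, 1))))
      }))
      for (infl in c(1.2, 2.0)) {
        part <- tidy(mcl_cluster(edges, inflation = infl))
        ig <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
        comp <- igraph::components(ig)$membership
        comp <- tibble::tibble(id = names(comp), comp = unname(comp))
        j <- dplyr::inner_join(part, comp, by = "id")
        tab <- table(j$cluster, j$comp)
        expect_true(all(rowSums(tab > 0) == 1))
        expect_true(all(colSums(tab > 0) == 1))
      }
    }
  })
})

test_that("MCL splits weakly bridged cliques at genus inflation", {
  edges <- dplyr::bind_rows(
    clique_edges(paste0("a", 1:5)), clique_edges(paste0("b", 1:5)),
    tibble::tibble(from = "a1", to = "b1", weight = 0.01)
  )
  part <- mcl_cluster(edges, inflation = 2.0)
  memb <- tidy(part)
  expect_equal(length(unique(memb$cluster)), 2)
  expect_equal(length(unique(memb$cluster[grepl("^a", memb$id)])), 1)
  expect_true(part$converged)
})

test_that("single nodes and isolated nodes form singletons", {
  only <- mcl_cluster(tibble::tibble(from = character(), to = character(),
                                     weight = numeric()),
                      nodes = "solo")
  expect_equal(tidy(only)$cluster, "cluster_1")
  with_iso <- mcl_cluster(clique_edges(c("a", "b", "c")),
                          nodes = c("a", "b", "c", "island"))
  m <- tidy(with_iso)
  expect_equal(length(unique(m$cluster)), 2)
  expect_false(m$cluster[m$id == "island"] %in%
                 m$cluster[m$id != "island"])
})

test_that("cluster counts do not decrease with inflation", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      n <- sample(8:14, 1)
      ids <- sprintf("n%02d", seq_len(n))
      all_pairs <- expand.grid(from = ids, to = ids,
                               stringsAsFactors = FALSE)
      all_pairs <- all_pairs[all_pairs$from < all_pairs$to, ]
      keep <- runif(nrow(all_pairs)) < 0.35
      edges <- tibble::as_tibble(all_pairs[keep, ])
      edges$weight <- runif(nrow(edges), 0.2, 1)
      counts <- vapply(c(1.2, 1.6, 2.0), function(infl) {
        length(unique(tidy(
          mcl_cluster(edges, inflation = infl, nodes = ids))$cluster))
      }, numeric(1))
      expect_true(all(diff(counts) >= 0))
    }
  })
})

test_that("homogeneity and cohesion match hand counts", {
  memb <- tibble::tibble(id = c("g1", "g2", "g3"), cluster = "c1")
  labs <- tibble::tibble(id = c("g1", "g2", "g3"), taxon = c("A", "A", "B"))
  r <- cluster_homogeneity(memb, labs)
  expect_equal(r$homogeneity, 100 * 2 / 3, tolerance = 1e-9)

  perfect <- cluster_homogeneity(
    tibble::tibble(id = letters[1:4], cluster = rep(c("c1", "c2"), each = 2)),
    tibble::tibble(id = letters[1:4], taxon = rep(c("A", "B"), each = 2))
  )
  expect_equal(perfect$homogeneity, 100)
  expect_equal(perfect$cohesion, 100)

  split <- cluster_homogeneity(
    tibble::tibble(id = letters[1:4], cluster = c("c1", "c1", "c2", "c2")),
    tibble::tibble(id = letters[1:4], taxon = "A")
  )
  expect_equal(split$cohesion, 50)
  expect_error(cluster_homogeneity(memb,
                                   tibble::tibble(id = "zz", taxon = "A")),
               "labelled")
})
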