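test_that("terminal repeats are found exactly, with the 20 bp floor", {
  withr::with_seed(21, {
    r25 <- random_dna(25); core <- random_dna(4000)
    dtr <- paste0(r25, core, r25)
    res <- detect_terminal_repeats(dtr)
    expect_equal(res$kind, "DTR")
    expect_equal(res$repeat_length, 25)
    expect_equal(res$repeat_sequence, r25)

    r19 <- random_dna(19)
    expect_equal(nrow(detect_terminal_repeats(paste0(r19, core, r19))), 0)
    r20 <- random_dna(20)
    expect_equal(detect_terminal_repeats(paste0(r20, core, r20))$repeat_length,
                 20)

    r30 <- random_dna(30)
    itr <- paste0(r30, core, revcomp(r30))
    res_itr <- detect_terminal_repeats(itr)
    expect_equal(res_itr$kind, "ITR")
    expect_equal(res_itr$repeat_length, 30)

    # N bases never count as matching
    rn <- paste0(substr(r25, 1, 10), "N", substr(r25, 12, 25))
    expect_equal(nrow(detect_terminal_repeats(paste0(rn, core, rn))), 0)
  })
})

test_that("terminal repeat detection is reverse-complement invariant", {
  withr::with_seed(33, {
    for (i in 1:5) {
      r <- random_dna(sample(20:60, 1)); core <- random_dna(1500)
      s_dtr <- paste0(r, core, r)
      expect_equal(detect_terminal_repeats(revcomp(s_dtr))$repeat_length,
                   detect_terminal_repeats(s_dtr)$repeat_length)
      s_itr <- paste0(r, core, revcomp(r))
      expect_equal(detect_terminal_repeats(revcomp(s_itr))$repeat_length,
                   detect_terminal_repeats(s_itr)$repeat_length)
    }
  })
})

test_that("large-repeat flag is raised strictly above 30% span", {
  withr::with_seed(55, {
    filler <- random_dna(10000)
    block <- function(b) random_dna(b, seed = 1234)
    with_span <- function(b) {
      # two disjoint copies of a b-bp block inside a 10 kb contig
      paste0(substr(filler, 1, 2000), block(b),
             substr(filler, 2001, 2000 + 10000 - 2 * b - 2000),
             block(b))
    }
    expect_true(large_repeat_flag(with_span(3500)))    # 70% span
    expect_false(large_repeat_flag(with_span(1500)))   # exactly 30%
    expect_true(large_repeat_flag(with_span(1505)))    # 30.1%
    expect_false(large_repeat_flag(filler))            # no repeat
    small <- paste0(substr(filler, 1, 4900), block(100),
                    substr(filler, 5001, 9900), block(100))
    expect_false(large_repeat_flag(small))             # 2% span
  })
})

test_that("provirus trimming extracts the inclusive subsequence", {
  pv <- sim_provirus(host_len = 10000, virus_len = 15000, seed = 77)
  trimmed <- trim_provirus(pv$contig, pv$viral_start, pv$viral_end)
  expect_equal(nchar(trimmed$sequence), 15000)
  expect_equal(trimmed$sequence, pv$virus)
  expect_true(trimmed$provirus)
  expect_match(trimmed$id, "provirus_5001_20000")

  full <- trim_provirus(pv$contig, 1, nchar(pv$contig$sequence))
  expect_equal(full$sequence, pv$contig$sequence)
  expect_equal(full$id, pv$contig$id)
  # full-range trimming is idempotent
  again <- trim_provirus(full, 1, nchar(full$sequence))
  expect_equal(again$sequence, full$sequence)

  expect_error(trim_provirus(pv$contig, 5001,
                             nchar(pv$contig$sequence) + 1), "out of range")
})

test_that("provirus fixtures with terminal repeats round-trip", {
  pv <- sim_provirus(host_len = 8000, virus_len = 6000, dtr_len = 25,
                     seed = 91)
  trimmed <- trim_provirus(pv$contig, pv$viral_start, pv$viral_end)
  res <- detect_terminal_repeats(trimmed$sequence)
  expect_equal(res$kind, "DTR")
  expect_equal(res$repeat_length, 25)
  pv0 <- sim_provirus(host_len = 8000, virus_len = 6000, dtr_len = 0,
                      seed = 91)
  t0 <- trim_provirus(pv0$contig, pv0$viral_start, pv0$viral_end)
  expect_equal(nrow(detect_terminal_repeats(t0$sequence)), 0)
})

test_that("quality tiers partition completeness with closure evidence", {
  expect_equal(assign_quality_tier(95, "DTR"), "complete")
  expect_equal(assign_quality_tier(95, "provirus_boundaries"), "complete")
  expect_equal(assign_quality_tier(95, "none"), "high")
  expect_equal(assign_quality_tier(90, "DTR"), "medium")  # needs > 90
  expect_equal(assign_quality_tier(50, "none"), "medium")
  expect_equal(assign_quality_tier(49.9, "none"), "low")
  expect_equal(assign_quality_tier(NA, "DTR"), "undetermined")
  # totality: every completeness/evidence pair maps to exactly one tier
  grid <- expand.grid(comp = c(NA, 0, 25, 50, 75, 90, 90.1, 100),
                      ev = c("DTR", "ITR", "provirus_boundaries", "none"),
                      stringsAsFactors = FALSE)
  tiers <- assign_quality_tier(grid$comp, grid$ev)
  expect_true(all(tiers %in% c("complete", "high", "medium", "low",
                               "undetermined")))
  expect_equal(length(tiers), nrow(grid))
})

test_that("rRNA screening applies coverage and e-value jointly", {
  model_lengths <- c(ssu16 = 1500)
  hit <- function(cov, ev) {
    tibble::tibble(query_id = "c1", target_id = "ssu16",
                   sstart = 1, send = round(cov * 1500), evalue = ev)
  }
  expect_true(rrna_contamination(hit(0.72, 1e-6), model_lengths)$contaminated)
  expect_false(rrna_contamination(hit(0.60, 1e-9), model_lengths)$contaminated)
  expect_false(rrna_contamination(hit(0.90, 1e-3), model_lengths)$contaminated)
  expect_error(rrna_contamination(hit(0.9, 1e-9), c(other = 100)),
               "ssu16")
})

test_that("qc_genomes summarises repeats, completeness and tiers", {
  withr::with_seed(13, {
    r <- random_dna(30)
    closed <- paste0(r, random_dna(3000), r)
    open <- random_dna(3000)
  })
  contigs <- contig_tbl(c("closed", "open"), c(closed, open))
  comp <- tibble::tibble(contig_id = c("closed", "open"),
                         completeness = c(98, 72))
  q <- qc_genomes(contigs, comp)
  expect_equal(q$tier[q$contig_id == "closed"], "complete")
  expect_equal(q$repeat_kind[q$contig_id == "closed"], "DTR")
  expect_equal(q$tier[q$contig_id == "open"], "medium")
  expect_false(any(q$large_repeat))
})
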