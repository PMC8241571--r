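#' Classification metrics for a labelled benchmark
#'
#' True-positive rate (percentage of truly viral contigs called viral),
#' false-positive rate (percentage of truly non-viral contigs called viral)
#' and the weighted benchmark score `TPR - fpr_weight * FPR`. The heavy
#' default FPR weight reflects that bulk metagenomes are mostly non-viral,
#' so even a small FPR swamps the catalogue with false positives.
#'
#' @param predictions Tibble `contig_id`, `viral` (logical predictions).
#' @param truth Tibble `contig_id`, `viral` (logical truth); must cover the
#'   same ids and contain at least one viral and one non-viral contig.
#' @param fpr_weight Weight on FPR in the score.
#' @return A one-row tibble with `tpr`, `fpr` (percent) and `score`.
#' @export
#' @examples
#' p <- tibble::tibble(contig_id = c("a", "b"), viral = c(TRUE, FALSE))
#' compute_metrics(p, p)  # perfect: TPR 100, FPR 0, score 100
compute_metrics <- function(predictions, truth, fpr_weight = 50) {
  if (!setequal(predictions$contig_id, truth$contig_id)) {
    abort("predictions and truth must cover the same contig ids")
  }
  joined <- inner_join(predictions, truth, by = "contig_id",
                       suffix = c("_pred", "_true"))
  n_pos <- sum(joined$viral_true)
  n_neg <- sum(!joined$viral_true)
  if (n_pos == 0 || n_neg == 0) {
    abort("truth must contain at least one viral and one non-viral contig")
  }
  tpr <- 100 * sum(joined$viral_pred & joined$viral_true) / n_pos
  fpr <- 100 * sum(joined$viral_pred & !joined$viral_true) / n_neg
  tibble(tpr = tpr, fpr = fpr, score = tpr - fpr_weight * fpr)
}

#' Grid-search signature cutoffs against a labelled benchmark
#'
#' Exhaustively evaluates the Cartesian product of candidate thresholds for
#' the four viral signatures against a benchmark of labelled fragments,
#' separately for each fragment length class, and retains the top scoring
#' combinations by `TPR - fpr_weight * FPR`. Ties are broken
#' lexicographically on the threshold tuple so results are reproducible.
#' `NA` in a candidate list means "signature unused" in that combination.
#'
#' @param features Feature tibble from [contig_features()] (or a synthetic
#'   benchmark), one row per fragment.
#' @param truth Tibble `contig_id`, `viral` with the true labels.
#' @param grids Named list of candidate threshold vectors:
#'   `min_viral_hits`, `max_microbial_hits`, `min_nt_score`,
#'   `max_strand_switch_rate`. Each may include `NA`.
#' @param classes_kb Fragment length classes (kb) to search.
#' @param top_n Number of clauses retained per length class.
#' @param fpr_weight Weight on FPR in the score.
#' @return An object of class `viral_benchmark`: a list with `clauses`
#'   (the selected rule set with per-clause `tpr`, `fpr`, `score`) and
#'   `n_combinations`.
#' @export
grid_search_cutoffs <- function(features, truth, grids,
                                classes_kb = c(1, 2, 5, 10, 20, 50, 100),
                                top_n = 5, fpr_weight = 50) {
  stopifnot(all(lengths(grids) > 0))
  req <- c("min_viral_hits", "max_microbial_hits", "min_nt_score",
           "max_strand_switch_rate")
  stopifnot(setequal(names(grids), req))
  combos <- tidyr::expand_grid(
    min_viral_hits = grids$min_viral_hits,
    max_microbial_hits = grids$max_microbial_hits,
    min_nt_score = grids$min_nt_score,
    max_strand_switch_rate = grids$max_strand_switch_rate
  )
  combos <- combos[rowSums(!is.na(combos)) > 0, , drop = FALSE]
  features$length_class <- length_class(features$length, classes_kb)
  truth <- truth[match(features$contig_id, truth$contig_id), ]

  out <- purrr::map(sort(unique(stats::na.omit(features$length_class))),
                    function(lc) {
    f <- features[!is.na(features$length_class) & features$length_class == lc, ]
    tr <- truth[match(f$contig_id, truth$contig_id), ]
    n_pos <- sum(tr$viral); n_neg <- sum(!tr$viral)
    res <- purrr::pmap(combos, function(min_viral_hits, max_microbial_hits,
                                        min_nt_score, max_strand_switch_rate) {
      pred <- rep(TRUE, nrow(f))
      if (!is.na(min_viral_hits)) pred <- pred & f$n_viral_hits >= min_viral_hits
      if (!is.na(max_microbial_hits)) {
        pred <- pred & f$n_microbial_hits <= max_microbial_hits
      }
      if (!is.na(min_nt_score)) pred <- pred & f$nt_score >= min_nt_score
      if (!is.na(max_strand_switch_rate)) {
        pred <- pred & f$strand_switch_rate <= max_strand_switch_rate
      }
      tpr <- 100 * sum(pred & tr$viral) / n_pos
      fpr <- 100 * sum(pred & !tr$viral) / n_neg
      c(tpr = tpr, fpr = fpr)
    })
    res <- do.call(rbind, res)
    scored <- combos
    scored$tpr <- res[, "tpr"]
    scored$fpr <- res[, "fpr"]
    scored$score <- scored$tpr - fpr_weight * scored$fpr
    scored %>%
      arrange(-.data$score, .data$min_viral_hits, .data$max_microbial_hits,
              .data$min_nt_score, .data$max_strand_switch_rate) %>%
      slice_head(n = top_n) %>%
      mutate(length_class = lc, clause = row_number(), .before = 1)
  })
  structure(
    list(clauses = bind_rows(out), n_combinations = nrow(combos),
         fpr_weight = fpr_weight),
    class = "viral_benchmark"
  )
}

#' @export
print.viral_benchmark <- function(x, ...) {
  cat("Viral-detection benchmark:", x$n_combinations,
      "cutoff combinations searched\n")
  best <- x$clauses %>% group_by(.data$length_class) %>%
    summarise(best_score = max(.data$score), .groups = "drop")
  print(as.data.frame(best), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the selected clauses of a benchmark grid search
#'
#' @param x A `viral_benchmark` object.
#' @param ... Unused.
#' @return The clause tibble with per-clause `tpr`, `fpr` and `score`.
#' @method tidy viral_benchmark
#' @export
tidy.viral_benchmark <- function(x, ...) x$clauses

#' One-row summary of a benchmark grid search
#'
#' @param x A `viral_benchmark` object.
#' @param ... Unused.
#' @return A one-row tibble: combinations searched, number of length
#'   classes, and the best score over all classes.
#' @method glance viral_benchmark
#' @export
glance.viral_benchmark <- function(x, ...) {
  tibble(n_combinations = x$n_combinations,
         n_length_classes = length(unique(x$clauses$length_class)),
         best_score = max(x$clauses$score))
}

#' Extract the selected clauses as a rule set
#'
#' Converts a `viral_benchmark` result into the rule-set format accepted by
#' [evaluate_ruleset()].
#'
#' @param benchmark A `viral_benchmark` object.
#' @param top_n Clauses kept per length class.
#' @return A rule-set tibble.
#' @export
as_ruleset <- function(benchmark, top_n = 5) {
  stopifnot(inherits(benchmark, "viral_benchmark"))
  benchmark$clauses %>%
    group_by(.data$length_class) %>%
    slice_head(n = top_n) %>%
    ungroup() %>%
    select("length_class", "clause", "min_viral_hits", "max_microbial_hits",
           "min_nt_score", "max_strand_switch_rate")
}
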