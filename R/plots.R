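#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot benchmark scores across fragment lengths
#'
#' One point per selected clause: TPR, FPR-penalised score by fragment
#' length class, with the best clause per class highlighted.
#'
#' @param object A `viral_benchmark` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot viral_benchmark
#' @export
autoplot.viral_benchmark <- function(object, ...) {
  cl <- object$clauses %>%
    group_by(.data$length_class) %>%
    mutate(best = .data$score == max(.data$score)) %>%
    ungroup()
  ggplot2::ggplot(cl, ggplot2::aes(x = factor(.data$length_class),
                                   y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey50"),
                                 guide = "none") +
    ggplot2::labs(x = "fragment length class (kb)",
                  y = expression(score == TPR - 50 %*% FPR),
                  title = "Selected cutoff clauses by fragment length") +
    ggplot2::theme_minimal()
}

#' Plot vOTU size distribution
#'
#' @param object A `votu_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot votu_clusters
#' @export
autoplot.votu_clusters <- function(object, ...) {
  sizes <- object$membership %>% count(.data$votu, name = "size")
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar(fill = "#0072B2") +
    ggplot2::labs(x = "genomes per vOTU", y = "vOTUs",
                  title = sprintf("vOTU sizes (ANI ≥ %s%%, AF ≥ %s%%)",
                                  object$min_ani, object$min_af)) +
    ggplot2::theme_minimal()
}

#' Plot MCL cluster sizes
#'
#' @param object An `mcl_partition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcl_partition
#' @export
autoplot.mcl_partition <- function(object, ...) {
  sizes <- object$membership %>% count(.data$cluster, name = "size")
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar(fill = "#009E73") +
    ggplot2::labs(x = "genomes per cluster", y = "clusters",
                  title = sprintf("MCL clusters at inflation %.1f",
                                  object$inflation)) +
    ggplot2::theme_minimal()
}

#' Bar chart of genome quality tiers
#'
#' @param quality Quality tibble from [qc_genomes()].
#' @return A ggplot object.
#' @export
plot_quality_tiers <- function(quality) {
  tiers <- c("complete", "high", "medium", "low", "undetermined")
  q <- quality %>% mutate(tier = factor(.data$tier, levels = tiers))
  ggplot2::ggplot(q, ggplot2::aes(x = .data$tier)) +
    ggplot2::geom_bar(fill = "#CC79A7") +
    ggplot2::labs(x = "quality tier", y = "genomes",
                  title = "Genome completeness tiers") +
    ggplot2::theme_minimal()
}
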