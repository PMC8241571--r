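#' Markov clustering of a weighted undirected graph
#'
#' Standard Markov clustering: the edge-weight matrix gains self-loops and
#' is column-normalised into a stochastic flow matrix, then expansion
#' (matrix squaring) and inflation (entrywise power followed by
#' renormalisation, with small entries pruned) alternate until the matrix
#' stops changing. Clusters are read off the attractors of the converged
#' flow: each row with mass defines a cluster of the columns it attracts,
#' and overlapping attractor sets are merged. The inflation factor sets
#' granularity - higher inflation gives more, smaller clusters - with 2.0
#' used for genus-level and 1.2 for family-level genome graphs.
#'
#' @param edges Tibble `from`, `to`, `weight` (undirected; one row per
#'   edge). Isolated nodes can be supplied via `nodes`.
#' @param inflation Inflation exponent (> 1).
#' @param nodes Optional character vector of all node ids (to include
#'   isolated nodes as singletons).
#' @param prune Entries below this are zeroed after each inflation.
#' @param max_iter Iteration cap; non-convergence returns the final
#'   iterate's clusters with a warning.
#' @param tol Convergence tolerance on the max entrywise change.
#' @param self_loop_weight Weight of the added self-loops; the
#'   conventional choice is the node's maximum incident weight, `NULL`
#'   selects that.
#' @return An object of class `mcl_partition`: list with `membership`
#'   (tibble `id`, `cluster`), `n_iterations`, `converged`, `inflation`.
#' @export
mcl_cluster <- function(edges, inflation = 2.0, nodes = NULL, prune = 1e-5,
                        max_iter = 100, tol = 1e-6,
                        self_loop_weight = NULL) {
  stopifnot(inflation > 1)
  ids <- sort(unique(c(edges$from, edges$to, nodes)))
  n <- length(ids)
  if (n == 0) abort("empty graph")
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges) > 0) {
    i <- match(edges$from, ids); j <- match(edges$to, ids)
    M[cbind(i, j)] <- edges$weight
    M[cbind(j, i)] <- edges$weight
  }
  loops <- if (is.null(self_loop_weight)) {
    w <- apply(M, 2, max)
    ifelse(w > 0, w, 1)
  } else rep(self_loop_weight, n)
  diag(M) <- loops
  normalise <- function(m) sweep(m, 2, colSums(m), "/")
  M <- normalise(M)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    M_new <- M %*% M              # expansion
    M_new <- M_new^inflation      # inflation
    M_new[M_new < prune] <- 0
    M_new <- normalise(M_new)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("MCL did not converge in %d iterations; returning last iterate",
                 max_iter))
  }
  # attractor interpretation: rows with any appreciable mass define
  # clusters; overlapping clusters are merged
  thresh <- sqrt(.Machine$double.eps)
  cluster_of <- rep(NA_integer_, n)
  next_id <- 0L
  for (r in seq_len(n)) {
    members <- which(M[r, ] > thresh)
    if (length(members) == 0) next
    existing <- unique(stats::na.omit(cluster_of[members]))
    if (length(existing) == 0) {
      next_id <- next_id + 1L
      cluster_of[members] <- next_id
    } else {
      keep <- min(existing)
      cluster_of[members] <- keep
      cluster_of[cluster_of %in% existing] <- keep
    }
  }
  for (r in which(is.na(cluster_of))) {  # fully pruned nodes -> singletons
    next_id <- next_id + 1L
    cluster_of[r] <- next_id
  }
  # renumber clusters by first appearance for determinism
  cluster_of <- match(cluster_of, unique(cluster_of))
  structure(
    list(membership = tibble(id = ids,
                             cluster = paste0("cluster_", cluster_of)),
         n_iterations = iter, converged = converged, inflation = inflation),
    class = "mcl_partition"
  )
}

#' @export
print.mcl_partition <- function(x, ...) {
  cat(sprintf("MCL partition: %d nodes, %d clusters (inflation %.1f, %d iterations%s)\n",
              nrow(x$membership), length(unique(x$membership$cluster)),
              x$inflation, x$n_iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Tidy an MCL partition
#'
#' @param x An `mcl_partition` object.
#' @param ... Unused.
#' @return The membership tibble (`id`, `cluster`).
#' @method tidy mcl_partition
#' @export
tidy.mcl_partition <- function(x, ...) x$membership

#' One-row summary of an MCL partition
#'
#' @param x An `mcl_partition` object.
#' @param ... Unused.
#' @return Tibble with node/cluster counts, convergence and inflation.
#' @method glance mcl_partition
#' @export
glance.mcl_partition <- function(x, ...) {
  sizes <- table(x$membership$cluster)
  tibble(n_nodes = nrow(x$membership), n_clusters = length(sizes),
         largest = max(sizes), converged = x$converged,
         inflation = x$inflation, n_iterations = x$n_iterations)
}
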