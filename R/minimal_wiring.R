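#' Absolute minimally wired baseline network (AM)
#'
#' Keeps the node layout of `net` and links exactly the `E` spatially
#' closest node pairs, where `E` is the source network's edge count. By
#' construction no other simple graph with `E` edges on the same nodes has a
#' smaller total Euclidean wiring length. The result is unweighted (all
#' weights 1); distance ties are broken deterministically by lexicographic
#' (node-table order) pair ordering.
#'
#' @param net Source [spatial_network()] with n >= 2 nodes and E >= 1 edges.
#' @param n_edges Optional override of the edge count.
#' @return A [spatial_network()].
#' @export
absolute_minimal <- function(net, n_edges = NULL) {
  E <- if (is.null(n_edges)) nrow(net$edges) else n_edges
  n <- nrow(net$nodes)
  if (E < 1) stop("source network must have at least one edge", call. = FALSE)
  if (E > n * (n - 1) / 2) stop("edge count exceeds n(n-1)/2", call. = FALSE)
  sp <- sorted_pairs(net)
  take <- sp[seq_len(E), , drop = FALSE]
  spatial_network(net$nodes,
                  tibble::tibble(from = net$nodes$id[take$i],
                                 to = net$nodes$id[take$j], weight = 1))
}

#' Degree-preserving minimally wired baseline network (DPM)
#'
#' Greedy construction: walk the list of all node pairs ordered from
#' shortest to longest and add a connection only while both endpoints are
#' still below their degrees in the source network. Per-node degrees never
#' exceed the source degrees; the final edge count can fall slightly short
#' of the source's because some residual degree may become unplaceable.
#' Output is unweighted (all weights 1).
#'
#' @param net Source [spatial_network()].
#' @return A [spatial_network()].
#' @export
degree_preserving_minimal <- function(net) {
  sp <- sorted_pairs(net)
  cap <- node_degrees(net)
  deg <- integer(length(cap))
  keep <- logical(nrow(sp))
  i <- sp$i
  j <- sp$j
  for (p in seq_len(nrow(sp))) {
    a <- i[p]; b <- j[p]
    if (deg[a] < cap[a] && deg[b] < cap[b]) {
      keep[p] <- TRUE
      deg[a] <- deg[a] + 1L
      deg[b] <- deg[b] + 1L
    }
  }
  spatial_network(net$nodes,
                  tibble::tibble(from = net$nodes$id[i[keep]],
                                 to = net$nodes$id[j[keep]], weight = 1))
}

# all unordered node pairs sorted by Euclidean distance, ties broken by
# lexicographic (node-table order) pair index
sorted_pairs <- function(net) {
  n <- nrow(net$nodes)
  xyz <- node_coords(net)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                       xyz[pairs[, 2], , drop = FALSE])^2))
  ord <- order(d, pairs[, 1], pairs[, 2])
  tibble::tibble(i = pairs[ord, 1], j = pairs[ord, 2], distance = d[ord])
}
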