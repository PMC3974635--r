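#' Build a spatially embedded weighted network from node and edge tables
#'
#' A `spatial_network` is an undirected simple graph whose nodes carry 3-D
#' positions (in mm) and optional hemisphere / anatomical-structure labels,
#' and whose edges carry positive real weights (connection strengths).
#' Connection lengths are never stored: they are always recomputed on demand
#' as Euclidean distances between endpoint coordinates.
#'
#' @param nodes A data frame with columns `id`, `x`, `y`, `z` and optionally
#'   `hemisphere` and `structure`.
#' @param edges A data frame with columns `from` (or `source`), `to` (or
#'   `target`) and `weight`. Duplicate rows describing the same unordered
#'   pair are collapsed when their weights agree and rejected otherwise.
#' @return An object of class `spatial_network`: a list with tibbles `nodes`
#'   and `edges`. Edges are stored canonically with `from` preceding `to` in
#'   node-table order.
#' @export
#' @examples
#' nodes <- data.frame(id = c("a", "b", "c"),
#'                     x = c(0, 1, 2), y = 0, z = 0)
#' edges <- data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1)
#' net <- spatial_network(nodes, edges)
#' connection_density(net)
spatial_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (!all(c("id", "x", "y", "z") %in% names(nodes))) {
    stop("node table must have columns id, x, y, z", call. = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  coords <- as.matrix(nodes[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("node coordinates must be finite", call. = FALSE)
  if (!"hemisphere" %in% names(nodes)) nodes$hemisphere <- NA_character_
  if (!"structure" %in% names(nodes)) nodes$structure <- NA_character_
  nodes <- nodes[, c("id", "x", "y", "z", "hemisphere", "structure")]

  nm <- names(edges)
  nm[nm == "source"] <- "from"
  nm[nm == "target"] <- "to"
  names(edges) <- nm
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = double())
  }
  if (!all(c("from", "to", "weight") %in% names(edges))) {
    stop("edge table must have columns from/source, to/target, weight",
         call. = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!is.numeric(edges$weight) || anyNA(edges$weight)) {
    stop("edge weights must be numeric", call. = FALSE)
  }
  i <- match(edges$from, nodes$id)
  j <- match(edges$to, nodes$id)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(edges$from[is.na(i)], edges$to[is.na(j)]))
    stop("unknown endpoint id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(i == j)) stop("self-loop edge(s) not allowed", call. = FALSE)
  if (any(edges$weight <= 0)) stop("edge weights must be > 0", call. = FALSE)

  # canonical orientation, then collapse symmetric duplicates
  flip <- i > j
  ii <- ifelse(flip, j, i)
  jj <- ifelse(flip, i, j)
  key <- paste(ii, jj)
  if (anyDuplicated(key)) {
    w_by_key <- split(edges$weight, key)
    conflicting <- vapply(w_by_key, function(w) {
      diff(range(w)) > 1e-12 * max(abs(w))
    }, logical(1))
    if (any(conflicting)) {
      stop("duplicate edge rows with conflicting weights", call. = FALSE)
    }
    keep <- !duplicated(key)
    ii <- ii[keep]; jj <- jj[keep]
    edges <- edges[keep, ]
  }
  ord <- order(ii, jj)
  edges <- tibble::tibble(from = nodes$id[ii][ord], to = nodes$id[jj][ord],
                          weight = edges$weight[ord])
  structure(list(nodes = nodes, edges = edges), class = "spatial_network")
}

#' @export
print.spatial_network <- function(x, ...) {
  cat(sprintf("<spatial_network: %d nodes, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0 && nrow(x$nodes) >= 2) {
    len <- edge_lengths(x)
    cat(sprintf("  density %.2f%%, mean edge length %.2f mm, total weight %.4g\n",
                100 * connection_density(x), mean(len), sum(x$edges$weight)))
  }
  invisible(x)
}

#' Read a spatial network from node and edge TSV files
#'
#' The node table is tab-separated with header
#' `id  x  y  z [hemisphere] [structure]`; the edge table has header
#' `source  target  weight` (or `from`/`to`). Symmetric duplicate edge rows
#' are collapsed when their weights agree.
#'
#' @param node_path,edge_path Paths to the two TSV files.
#' @return A [spatial_network()].
#' @export
read_network <- function(node_path, edge_path) {
  nodes <- readr::read_tsv(node_path, show_col_types = FALSE,
                           progress = FALSE)
  edges <- readr::read_tsv(edge_path, show_col_types = FALSE,
                           progress = FALSE)
  spatial_network(nodes, edges)
}

#' Write a spatial network to node and edge TSV files
#'
#' Inverse of [read_network()]: `read_network()` on the written files
#' reproduces the network (weights to full double precision).
#'
#' @param net A [spatial_network()].
#' @param node_path,edge_path Output paths.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, node_path, edge_path) {
  stopifnot(inherits(net, "spatial_network"))
  nodes <- net$nodes
  if (all(is.na(nodes$structure))) nodes$structure <- NULL
  if (all(is.na(nodes$hemisphere))) nodes$hemisphere <- NULL
  readr::write_tsv(nodes, node_path, progress = FALSE)
  edges <- net$edges
  names(edges) <- c("source", "target", "weight")
  readr::write_tsv(edges, edge_path, progress = FALSE)
  invisible(net)
}

#' Read a spatial network from a dense connectivity matrix
#'
#' The matrix must be square and symmetric (to `tol`) with a zero diagonal;
#' every nonzero entry becomes an undirected weighted edge. Row/column order
#' follows the node table.
#'
#' @param matrix_path Path to a delimited text file holding the matrix.
#' @param node_path Path to the matching node TSV (see [read_network()]).
#' @param delim Field delimiter in the matrix file.
#' @param header Does the matrix file carry a header row?
#' @param tol Absolute tolerance for the symmetry check.
#' @return A [spatial_network()].
#' @export
read_matrix <- function(matrix_path, node_path, delim = "\t",
                        header = FALSE, tol = 1e-9) {
  nodes <- readr::read_tsv(node_path, show_col_types = FALSE,
                           progress = FALSE)
  m <- as.matrix(utils::read.table(matrix_path, sep = delim, header = header))
  dimnames(m) <- NULL
  matrix_network(m, nodes, tol = tol)
}

#' Build a spatial network from an in-memory connectivity matrix
#'
#' @param m Square symmetric numeric matrix with zero diagonal.
#' @param nodes Node data frame (see [spatial_network()]); row order of `m`
#'   must follow `nodes`.
#' @param tol Symmetry tolerance.
#' @return A [spatial_network()].
#' @export
matrix_network <- function(m, nodes, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("connectivity matrix must be square", call. = FALSE)
  }
  nodes <- tibble::as_tibble(nodes)
  if (nrow(nodes) != nrow(m)) {
    stop("node table and matrix dimensions disagree", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop("connectivity matrix is asymmetric beyond tolerance", call. = FALSE)
  }
  if (any(diag(m) != 0)) {
    stop("connectivity matrix must have a zero diagonal", call. = FALSE)
  }
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("connectivity matrix has no nonzero off-diagonal entries",
            call. = FALSE)
  }
  ids <- as.character(nodes$id)
  edges <- tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]],
                          weight = m[idx])
  spatial_network(nodes, edges)
}

#' Dense connectivity matrix of a network
#'
#' @param net A [spatial_network()].
#' @param weighted If `FALSE`, return the binary adjacency matrix.
#' @return A symmetric numeric matrix ordered as the node table.
#' @export
adjacency_matrix <- function(net, weighted = TRUE) {
  n <- nrow(net$nodes)
  m <- matrix(0, n, n, dimnames = list(net$nodes$id, net$nodes$id))
  ei <- edge_indices(net)
  if (nrow(ei) > 0) {
    w <- if (weighted) net$edges$weight else 1
    m[ei] <- w
    m[ei[, 2:1, drop = FALSE]] <- w
  }
  m
}

# edge endpoints as a 2-column integer index matrix (node-table order)
edge_indices <- function(net) {
  cbind(match(net$edges$from, net$nodes$id),
        match(net$edges$to, net$nodes$id))
}

node_coords <- function(net) {
  as.matrix(net$nodes[, c("x", "y", "z")])
}

#' Euclidean lengths of all edges
#'
#' @param net A [spatial_network()].
#' @return Numeric vector aligned with `net$edges`, in the coordinate unit
#'   (mm).
#' @export
edge_lengths <- function(net) {
  ei <- edge_indices(net)
  xyz <- node_coords(net)
  sqrt(rowSums((xyz[ei[, 1], , drop = FALSE] -
                  xyz[ei[, 2], , drop = FALSE])^2))
}

#' Per-node degree, strength and total connection length
#'
#' `node_degrees()` counts connections per node, `node_strengths()` sums
#' connection weights, and `node_total_lengths()` sums the Euclidean lengths
#' of each node's connections (the per-region wiring that the spatial
#' surrogate constraint caps).
#'
#' @param net A [spatial_network()].
#' @return Named numeric vector over all nodes (zeros for isolated nodes).
#' @export
node_degrees <- function(net) {
  tabulate_over_edges(net, rep(1, nrow(net$edges)))
}

#' @rdname node_degrees
#' @export
node_strengths <- function(net) {
  tabulate_over_edges(net, net$edges$weight)
}

#' @rdname node_degrees
#' @export
node_total_lengths <- function(net) {
  tabulate_over_edges(net, edge_lengths(net))
}

tabulate_over_edges <- function(net, val) {
  n <- nrow(net$nodes)
  ei <- edge_indices(net)
  out <- numeric(n)
  if (nrow(ei) > 0) {
    s <- rowsum(c(val, val), c(ei[, 1], ei[, 2]))
    out[as.integer(rownames(s))] <- s[, 1]
  }
  names(out) <- net$nodes$id
  out
}

#' Total wiring length of a network
#'
#' Sum of Euclidean edge lengths, the wiring-cost proxy that the reduced
#' surrogates minimise.
#'
#' @param net A [spatial_network()].
#' @return Total length in mm.
#' @export
total_wiring_length <- function(net) sum(edge_lengths(net))

#' Connection density
#'
#' Fraction of realised node pairs, `E / (n (n - 1) / 2)`.
#'
#' @param net A [spatial_network()] with at least two nodes.
#' @return A fraction in `[0, 1]`.
#' @export
connection_density <- function(net) {
  n <- nrow(net$nodes)
  if (n < 2) stop("density needs at least two nodes", call. = FALSE)
  nrow(net$edges) / (n * (n - 1) / 2)
}

#' Aggregate a network to a lower-resolution parcellation
#'
#' Each group of nodes collapses to a single node at the unweighted centroid
#' of its members. The weight of an aggregated edge is the sum of the weights
#' of all member-pair connections crossing the two groups; intra-group
#' connections are discarded.
#'
#' @param net A [spatial_network()].
#' @param grouping A data frame with columns `id` and `group` mapping every
#'   node to exactly one group.
#' @return A [spatial_network()] on the groups.
#' @export
aggregate_to_groups <- function(net, grouping) {
  grouping <- tibble::as_tibble(grouping)
  stopifnot(all(c("id", "group") %in% names(grouping)))
  grouping$id <- as.character(grouping$id)
  grouping$group <- as.character(grouping$group)
  g <- grouping$group[match(net$nodes$id, grouping$id)]
  if (anyNA(g)) {
    stop("grouping is missing node(s): ",
         paste(utils::head(net$nodes$id[is.na(g)], 5), collapse = ", "),
         call. = FALSE)
  }
  nodes <- net$nodes |>
    dplyr::mutate(group = g) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                     hemisphere = if (dplyr::n_distinct(.data$hemisphere) == 1)
                       .data$hemisphere[1] else NA_character_,
                     .groups = "drop") |>
    dplyr::rename(id = "group")
  gf <- g[match(net$edges$from, net$nodes$id)]
  gt <- g[match(net$edges$to, net$nodes$id)]
  keep <- gf != gt
  edges <- tibble::tibble(
    from = pmin(gf[keep], gt[keep]),
    to = pmax(gf[keep], gt[keep]),
    weight = net$edges$weight[keep]
  ) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  spatial_network(nodes, edges)
}

#' Induced subnetwork on a node subset
#'
#' Keeps the listed nodes with their coordinates and labels, and every edge
#' whose two endpoints are both in the subset.
#'
#' @param net A [spatial_network()].
#' @param node_subset Character vector of node ids (for example all nodes of
#'   one hemisphere).
#' @return A [spatial_network()].
#' @export
extract_subnetwork <- function(net, node_subset) {
  node_subset <- as.character(node_subset)
  unknown <- setdiff(node_subset, net$nodes$id)
  if (length(unknown) > 0) {
    stop("unknown node id(s): ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  nodes <- net$nodes[net$nodes$id %in% node_subset, ]
  keep <- net$edges$from %in% node_subset & net$edges$to %in% node_subset
  spatial_network(nodes, net$edges[keep, ])
}

#' Convert to an igraph graph
#'
#' Vertices keep the node-table order and carry `name`, coordinates and
#' labels; edges carry `weight`.
#'
#' @param net A [spatial_network()].
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  ei <- edge_indices(net)
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  g <- igraph::add_edges(g, t(ei))
  igraph::V(g)$name <- net$nodes$id
  igraph::E(g)$weight <- net$edges$weight
  g
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a spatial network into an edge tibble
#'
#' @param x A [spatial_network()].
#' @param ... Unused.
#' @return A tibble with one row per edge: endpoints, weight and Euclidean
#'   length.
#' @method tidy spatial_network
#' @export
tidy.spatial_network <- function(x, ...) {
  tibble::tibble(from = x$edges$from, to = x$edges$to,
                 weight = x$edges$weight, length = edge_lengths(x))
}

#' One-row summary of a spatial network
#'
#' @param x A [spatial_network()].
#' @param ... Unused.
#' @return A one-row tibble: node and edge counts, density, total weight,
#'   mean edge length and total wiring length.
#' @method glance spatial_network
#' @export
glance.spatial_network <- function(x, ...) {
  len <- edge_lengths(x)
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    density = if (nrow(x$nodes) >= 2) connection_density(x) else NA_real_,
    total_weight = sum(x$edges$weight),
    mean_edge_length = if (length(len)) mean(len) else NA_real_,
    total_wiring_length = sum(len)
  )
}
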