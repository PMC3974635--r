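#' Create a module partition object
#'
#' @param net The [spatial_network()] the partition belongs to.
#' @param membership Module labels over the nodes: either a vector aligned
#'   with the node table or a named vector keyed by node id.
#' @param method Free-text provenance tag.
#' @return A `module_partition`: list with `assignment` (tibble: id,
#'   module), `q` (weighted modularity of the partition), `n_modules` and
#'   `module_sizes`.
#' @export
module_partition <- function(net, membership, method = "manual") {
  ids <- net$nodes$id
  if (!is.null(names(membership))) {
    if (!setequal(names(membership), ids)) {
      stop("membership names do not cover the node set", call. = FALSE)
    }
    membership <- membership[ids]
  }
  if (length(membership) != length(ids) || anyNA(membership)) {
    stop("membership must cover every node exactly once", call. = FALSE)
  }
  membership <- as.integer(factor(membership))
  p <- structure(list(
    assignment = tibble::tibble(id = ids, module = membership),
    n_modules = max(membership),
    module_sizes = tabulate(membership),
    method = method
  ), class = "module_partition")
  p$q <- modularity_q(net, p)
  p
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition: %d modules over %d nodes, Q = %.4f (%s)>\n",
              x$n_modules, nrow(x$assignment), x$q, x$method))
  invisible(x)
}

#' Tidy a module partition
#'
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return The node-to-module assignment tibble.
#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) x$assignment

#' One-row summary of a module partition
#'
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return A one-row tibble with Q, module count and size range.
#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(q = x$q, n_modules = x$n_modules,
                 min_module_size = min(x$module_sizes),
                 max_module_size = max(x$module_sizes))
}

partition_membership <- function(partition, ids) {
  if (inherits(partition, "module_partition")) {
    m <- partition$assignment$module[match(ids, partition$assignment$id)]
  } else if (!is.null(names(partition))) {
    m <- partition[ids]
  } else {
    m <- partition
  }
  if (length(m) != length(ids) || anyNA(m)) {
    stop("partition does not cover the node set", call. = FALSE)
  }
  as.integer(factor(m))
}

#' Weighted Newman modularity of a partition
#'
#' `Q = (1 / 2W) * sum_ij (w_ij - k_i k_j / (2W)) delta(m_i, m_j)` with `W`
#' the total edge weight and `k_i` the node strengths: the within-module
#' weight minus its expectation under the strength-preserving null model.
#' `Q` lies in `[-1, 1]` and is 0 for the one-module partition.
#'
#' @param net A [spatial_network()].
#' @param partition A `module_partition`, a named membership vector, or a
#'   membership vector aligned with the node table.
#' @return The modularity index.
#' @export
modularity_q <- function(net, partition) {
  m <- partition_membership(partition, net$nodes$id)
  w_total <- sum(net$edges$weight)
  if (w_total == 0) return(0)
  ei <- edge_indices(net)
  internal <- m[ei[, 1]] == m[ei[, 2]]
  strength <- node_strengths(net)
  a_u <- rowsum(strength, m)[, 1] / (2 * w_total)
  sum(net$edges$weight[internal]) / w_total - sum(a_u^2)
}

# modularity matrix B_ij = w_ij - k_i k_j / (2W)
modularity_matrix <- function(net) {
  a <- adjacency_matrix(net, weighted = TRUE)
  k <- node_strengths(net)
  w2 <- sum(k)
  a - outer(k, k) / w2
}

#' Newman spectral module detection
#'
#' Recursive bipartitioning by the sign of the leading eigenvector of the
#' (weighted, for subgraphs generalised) modularity matrix. Starting from
#' the connected components, each module is split in two along the leading
#' eigenvector of its generalised modularity matrix
#' `B(g)_ij = B_ij - delta_ij sum_{k in g} B_ik`; the split is kept only if
#' it increases the global modularity Q, and the algorithm stops when no
#' further split yields an increase. Eigenvector sign is canonicalised and
#' zero entries go to the positive block, so the result is deterministic.
#'
#' @param net A [spatial_network()].
#' @param fine_tune Apply Kernighan-Lin style single-node refinement after
#'   each accepted split (off by default).
#' @return A `module_partition` (method `"newman_spectral"`).
#' @export
spectral_partition <- function(net, fine_tune = FALSE) {
  n <- nrow(net$nodes)
  b <- modularity_matrix(net)
  w2 <- sum(node_strengths(net))
  membership <- integer(n)
  comp <- igraph::components(as_igraph(net))$membership
  next_label <- 0L

  split_group <- function(g) {
    # returns list of index groups forming final modules within g
    if (length(g) < 2) return(list(g))
    bg <- b[g, g, drop = FALSE]
    diag(bg) <- diag(bg) - rowSums(bg)
    es <- eigen(bg, symmetric = TRUE)
    u <- es$vectors[, 1]
    if (es$values[1] <= 1e-12) return(list(g))
    # canonical sign: make the first entry of largest magnitude positive
    lead <- which.max(abs(u))
    if (u[lead] < 0) u <- -u
    s <- ifelse(u >= 0, 1, -1)
    if (fine_tune) s <- kl_refine(bg, s)
    dq <- drop(t(s) %*% bg %*% s) / (2 * w2)
    if (dq <= 1e-12 || all(s == s[1])) return(list(g))
    c(split_group(g[s > 0]), split_group(g[s < 0]))
  }

  for (cc in sort(unique(comp))) {
    groups <- split_group(which(comp == cc))
    for (gr in groups) {
      next_label <- next_label + 1L
      membership[gr] <- next_label
    }
  }
  module_partition(net, membership, method = "newman_spectral")
}

# single-node sign flips that improve s' B s, repeated to convergence
kl_refine <- function(bg, s) {
  repeat {
    gains <- drop(-4 * s * (bg %*% s)) + 4 * diag(bg)
    best <- which.max(gains)
    if (gains[best] <= 1e-12) return(s)
    s[best] <- -s[best]
  }
}

#' Scaled inclusivity of a reference partition across an ensemble
#'
#' For a reference partition C and each ensemble partition S, the
#' module-by-module similarity is
#' `X(p, q) = |S_p intersect C_q|^2 / (|S_p| * |C_q|)`, 0 for disjoint
#' modules and 1 for identical ones. Each node's scaled inclusivity in one
#' ensemble member is `X(p(node), q(node))` for the two modules containing
#' it; the per-node SI is the mean over members. High SI means the node's
#' reference module is consistently recovered in the ensemble.
#'
#' @param reference A `module_partition` (or membership vector) on the
#'   common node set.
#' @param ensemble_partitions List of partitions on the same node set.
#' @param net Optional network supplying the node id order when membership
#'   vectors are unnamed.
#' @return A tibble with columns `id`, `si_mean`, `si_sd`.
#' @export
scaled_inclusivity <- function(reference, ensemble_partitions, net = NULL) {
  ids <- if (inherits(reference, "module_partition")) {
    reference$assignment$id
  } else if (!is.null(net)) net$nodes$id else names(reference)
  if (is.null(ids)) stop("cannot determine the node id set", call. = FALSE)
  ref <- partition_membership(reference, ids)
  ref_sizes <- tabulate(ref)
  per_member <- purrr::map(ensemble_partitions, function(p) {
    m <- partition_membership(p, ids)
    m_sizes <- tabulate(m)
    counts <- table(factor(m, seq_len(max(m))), factor(ref, seq_len(max(ref))))
    x <- counts^2 / outer(m_sizes, ref_sizes)
    x[cbind(m, ref)]
  })
  si <- do.call(cbind, per_member)
  tibble::tibble(id = ids,
                 si_mean = rowMeans(si),
                 si_sd = apply(si, 1, stats::sd))
}

#' Co-assignment frequency matrix of an ensemble of partitions
#'
#' @param ensemble_partitions Non-empty list of partitions on a common node
#'   set (each a `module_partition` or membership vector).
#' @param net Optional network supplying node ids for unnamed vectors.
#' @return A symmetric node-by-node matrix in `[0, 1]`: the fraction of
#'   partitions placing the two nodes in the same module (diagonal 1).
#' @export
module_correspondence <- function(ensemble_partitions, net = NULL) {
  if (length(ensemble_partitions) == 0) {
    stop("need at least one partition", call. = FALSE)
  }
  first <- ensemble_partitions[[1]]
  ids <- if (inherits(first, "module_partition")) first$assignment$id
    else if (!is.null(net)) net$nodes$id else names(first)
  acc <- 0
  for (p in ensemble_partitions) {
    m <- partition_membership(p, ids)
    acc <- acc + outer(m, m, "==")
  }
  out <- acc / length(ensemble_partitions)
  dimnames(out) <- list(ids, ids)
  out
}

#' Intra- and inter-module connection statistics
#'
#' @param net A [spatial_network()].
#' @param partition A partition of `net` (see [modularity_q()]).
#' @return A one-row tibble: fraction of edges internal to modules, mean
#'   within-module connection density, mean between-module pair density,
#'   and the global density.
#' @export
module_connection_stats <- function(net, partition) {
  m <- partition_membership(partition, net$nodes$id)
  ei <- edge_indices(net)
  internal <- m[ei[, 1]] == m[ei[, 2]]
  sizes <- tabulate(m)
  n_mod <- length(sizes)
  intra_possible <- sizes * (sizes - 1) / 2
  intra_edges <- vapply(seq_len(n_mod), function(u) {
    sum(internal & m[ei[, 1]] == u)
  }, numeric(1))
  intra_density <- mean(intra_edges[intra_possible > 0] /
                          intra_possible[intra_possible > 0])
  inter_density <- NA_real_
  if (n_mod >= 2) {
    pairs <- utils::combn(n_mod, 2)
    dens <- apply(pairs, 2, function(uv) {
      cross <- sum((m[ei[, 1]] == uv[1] & m[ei[, 2]] == uv[2]) |
                     (m[ei[, 1]] == uv[2] & m[ei[, 2]] == uv[1]))
      cross / (sizes[uv[1]] * sizes[uv[2]])
    })
    inter_density <- mean(dens)
  }
  tibble::tibble(
    intra_edge_fraction = if (nrow(net$edges)) mean(internal) else NA_real_,
    mean_intra_density = intra_density,
    mean_inter_density = inter_density,
    global_density = connection_density(net)
  )
}
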