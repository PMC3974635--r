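edge_keys <- function(net) paste(net$edges$from, net$edges$to)

check_same_nodes <- function(netA, netB) {
  if (!identical(sort(netA$nodes$id), sort(netB$nodes$id))) {
    stop("networks are not defined on the same node set", call. = FALSE)
  }
}

#' Binary similarity quotient between two networks
#'
#' Overlap of the two edge sets as the quotient of their intersection and
#' union: 1 when the edge sets are identical, 0 when they are disjoint.
#' This intersection-over-union form follows the modified Sorensen quotient
#' used for surrogate validation; set `classical = TRUE` for the classical
#' Sorensen form `2|A intersect B| / (|A| + |B|)`.
#'
#' @param netA,netB Two [spatial_network()]s on the same node set.
#' @param classical Use the classical Sorensen normalisation instead of
#'   intersection-over-union.
#' @return A quotient in `[0, 1]`.
#' @export
similarity_binary <- function(netA, netB, classical = FALSE) {
  check_same_nodes(netA, netB)
  a <- edge_keys(netA)
  b <- edge_keys(netB)
  if (length(a) == 0 && length(b) == 0) return(1)
  n_int <- length(intersect(a, b))
  if (classical) return(2 * n_int / (length(a) + length(b)))
  n_int / length(union(a, b))
}

#' Weighted similarity quotient between two networks
#'
#' Weighted analogue of [similarity_binary()]: shared connections contribute
#' their consistent overlap `min(C_ij, S_ij)` to the numerator, while the
#' union mass in the denominator counts `max(C_ij, S_ij)` for shared
#' connections and the full weight of unshared ones. Equals the binary
#' quotient whenever all weights are equal, is 1 iff the two weighted edge
#' sets are identical, and 0 iff they are disjoint.
#'
#' @inheritParams similarity_binary
#' @param classical Use a Sorensen-style normalisation
#'   `2 sum(min) / (sum(C) + sum(S))` instead.
#' @return A quotient in `[0, 1]`.
#' @export
similarity_weighted <- function(netA, netB, classical = FALSE) {
  check_same_nodes(netA, netB)
  a <- edge_keys(netA)
  b <- edge_keys(netB)
  if (length(a) == 0 && length(b) == 0) return(1)
  wa <- stats::setNames(netA$edges$weight, a)
  wb <- stats::setNames(netB$edges$weight, b)
  shared <- intersect(a, b)
  num <- sum(pmin(wa[shared], wb[shared]))
  if (classical) return(2 * num / (sum(wa) + sum(wb)))
  den <- sum(pmax(wa[shared], wb[shared])) +
    sum(wa[setdiff(a, shared)]) + sum(wb[setdiff(b, shared)])
  if (den == 0) return(1)
  num / den
}

#' Greedily pair original with rewired neighbours by spatial proximity
#'
#' Computes all cross distances between the two node lists, sorts them
#' ascending, and admits a pair iff neither member is already paired.
#' Distance ties are resolved by lexicographic (original id, rewired id)
#' order so the pairing is deterministic. The result approximates (but does
#' not guarantee) the minimum-total-distance assignment.
#'
#' @param original,rewired Character vectors of node ids (a region's
#'   neighbour sets in the source and in the surrogate network).
#' @param coords Numeric matrix of 3-D positions with node ids as row
#'   names, or a [spatial_network()] from which it is taken.
#' @return A tibble with columns `original`, `rewired`, `distance`;
#'   `min(length(original), length(rewired))` rows (empty inputs give an
#'   empty pairing).
#' @export
greedy_pairing <- function(original, rewired, coords) {
  if (inherits(coords, "spatial_network")) {
    xyz <- node_coords(coords)
    rownames(xyz) <- coords$nodes$id
    coords <- xyz
  }
  nl <- length(original)
  nm <- length(rewired)
  if (nl == 0 || nm == 0) {
    return(tibble::tibble(original = character(), rewired = character(),
                          distance = double()))
  }
  li <- rep(seq_len(nl), each = nm)
  mi <- rep(seq_len(nm), times = nl)
  d <- unname(sqrt(rowSums((coords[original[li], , drop = FALSE] -
                              coords[rewired[mi], , drop = FALSE])^2)))
  ord <- order(d, original[li], rewired[mi])
  used_l <- logical(nl)
  used_m <- logical(nm)
  sel <- integer(min(nl, nm))
  k <- 0L
  for (p in ord) {
    if (!used_l[li[p]] && !used_m[mi[p]]) {
      used_l[li[p]] <- TRUE
      used_m[mi[p]] <- TRUE
      k <- k + 1L
      sel[k] <- p
      if (k == length(sel)) break
    }
  }
  sel <- sel[seq_len(k)]
  tibble::tibble(original = original[li[sel]], rewired = rewired[mi[sel]],
                 distance = d[sel])
}

#' Relative spatial displacement between a network and a surrogate
#'
#' For each region r, pairs r's neighbours in the source network with its
#' neighbours in the surrogate via [greedy_pairing()], and averages the
#' paired displacement `d(original, rewired)` normalised by the original
#' connection length `d(r, original)`. The global displacement D is the
#' mean of the per-region averages; D = 0 iff the two networks are
#' identical. Pairs whose original neighbour coincides spatially with r
#' (zero-length original connection) are excluded with a warning.
#'
#' @param source,surrogate Two [spatial_network()]s on the same node set
#'   (degree-preserving surrogates give equal neighbour-list sizes, but the
#'   measure is defined for any pair: each region pairs
#'   `min(|original|, |rewired|)` neighbours).
#' @param rewired_only Exclude pairs with zero displacement (connections
#'   shared by the two networks), measuring the displacement of the
#'   replaced connections only.
#' @return A list with `global` (mean over regions) and `per_region` (a
#'   tibble: id, displacement, n_pairs).
#' @export
spatial_displacement <- function(source, surrogate, rewired_only = FALSE) {
  check_same_nodes(source, surrogate)
  xyz <- node_coords(source)
  rownames(xyz) <- source$nodes$id
  nb_a <- neighbour_sets(source)
  nb_b <- neighbour_sets(surrogate)
  warned <- FALSE
  rows <- purrr::map(source$nodes$id, function(r) {
    L <- nb_a[[r]]
    M <- nb_b[[r]]
    if (length(L) == 0 || length(M) == 0) return(NULL)
    pr <- greedy_pairing(L, M, xyz)
    d_orig <- sqrt(rowSums((xyz[pr$original, , drop = FALSE] -
                              matrix(xyz[r, ], nrow(pr), 3, byrow = TRUE))^2))
    zero <- d_orig == 0
    if (any(zero) && !warned) {
      warning("excluded pairing(s) with zero-length original connection",
              call. = FALSE)
      warned <<- TRUE
    }
    ratio <- pr$distance[!zero] / d_orig[!zero]
    if (rewired_only) ratio <- ratio[ratio > 0]
    tibble::tibble(id = r,
                   displacement = if (length(ratio)) mean(ratio) else NA_real_,
                   n_pairs = length(ratio))
  })
  per_region <- dplyr::bind_rows(rows)
  list(global = mean(per_region$displacement, na.rm = TRUE),
       per_region = per_region)
}

neighbour_sets <- function(net) {
  n <- nrow(net$nodes)
  ei <- edge_indices(net)
  out <- split(net$nodes$id[c(ei[, 2], ei[, 1])],
               factor(c(ei[, 1], ei[, 2]), levels = seq_len(n)))
  names(out) <- net$nodes$id
  out
}

#' Shared-connection analysis of a surrogate ensemble
#'
#' Determines the connections present in every member of an ensemble (the
#' ensemble's 'skeleton'), how many of those are also cortical/source
#' connections, and the mean pairwise binary and weighted similarity
#' quotients within the ensemble.
#'
#' @param source The source [spatial_network()].
#' @param ensemble A `surrogate_ensemble` or a list of networks on the same
#'   node set.
#' @return A one-row tibble: `shared_fraction` (edges shared by all members
#'   / member edge count), `shared_in_source_fraction` (fraction of those
#'   also present in the source), `mean_intra_qs_binary`,
#'   `mean_intra_qs_weighted`.
#' @export
shared_connection_analysis <- function(source, ensemble) {
  members <- if (inherits(ensemble, "surrogate_ensemble")) ensemble$members else ensemble
  if (length(members) == 0) stop("ensemble is empty", call. = FALSE)
  keys <- purrr::map(members, edge_keys)
  shared <- purrr::reduce(keys, intersect)
  shared_fraction <- length(shared) / length(keys[[1]])
  in_source <- if (length(shared) == 0) NA_real_ else {
    mean(shared %in% edge_keys(source))
  }
  qsb <- qsw <- numeric(0)
  if (length(members) >= 2) {
    pairs <- utils::combn(length(members), 2)
    qsb <- qsw <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      qsb[p] <- similarity_binary(members[[pairs[1, p]]], members[[pairs[2, p]]])
      qsw[p] <- similarity_weighted(members[[pairs[1, p]]], members[[pairs[2, p]]])
    }
  }
  tibble::tibble(shared_fraction = shared_fraction,
                 shared_in_source_fraction = in_source,
                 mean_intra_qs_binary = if (length(qsb)) mean(qsb) else NA_real_,
                 mean_intra_qs_weighted = if (length(qsw)) mean(qsw) else NA_real_)
}
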