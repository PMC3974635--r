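#' Global efficiency of a weighted network
#'
#' Mean inverse weighted shortest-path length over node pairs. Path cost
#' along an edge is the reciprocal of its weight, so strong connections are
#' short; unreachable pairs contribute zero, which makes the measure well
#' defined on networks with multiple components.
#'
#' @param net A [spatial_network()] with n >= 2 nodes.
#' @return A list with `global` (mean of the per-node efficiencies) and
#'   `per_node` (named vector; node i's efficiency is the mean of `1/d_ij`
#'   over all other nodes j).
#' @export
global_efficiency <- function(net) {
  n <- nrow(net$nodes)
  if (n < 2) stop("efficiency needs at least two nodes", call. = FALSE)
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  per_node <- rowSums(inv) / (n - 1)
  names(per_node) <- net$nodes$id
  list(global = mean(per_node), per_node = per_node)
}

#' Onnela weighted clustering coefficient
#'
#' Per node i the geometric-mean triangle intensity
#' `t_i = 1/2 * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)` with weights normalised
#' by the network-wide maximum (`w' = w / max(w)`), giving
#' `C_i = 2 t_i / (k_i (k_i - 1))`; nodes with degree < 2 have `C_i = 0`.
#' On a network with all weights equal this reduces to the binary fraction
#' of closed triangles.
#'
#' @param net A [spatial_network()].
#' @return A list with `global` (mean over all nodes) and `per_node`.
#' @export
weighted_clustering <- function(net) {
  n <- nrow(net$nodes)
  per_node <- stats::setNames(numeric(n), net$nodes$id)
  if (nrow(net$edges) > 0) {
    a <- adjacency_matrix(net, weighted = TRUE)
    w3 <- (a / max(a))^(1 / 3)
    t_i <- diag(w3 %*% w3 %*% w3) / 2
    k <- node_degrees(net)
    ok <- k >= 2
    per_node[ok] <- 2 * t_i[ok] / (k[ok] * (k[ok] - 1))
  }
  list(global = mean(per_node), per_node = per_node)
}

#' Small-world index against a random-surrogate reference
#'
#' `SW = (C / C_rnd) * (E / E_rnd)`: the product of the clustering and
#' efficiency ratios of a network relative to the mean values of its random
#' surrogate ensemble. A network evaluated against its own values gives
#' SW = 1 exactly, so random surrogates have SW = 1 by definition.
#'
#' @param net_c,net_e Clustering coefficient and global efficiency of the
#'   network.
#' @param rnd_c_mean,rnd_e_mean Random-ensemble means (must be > 0).
#' @return The small-world index.
#' @export
small_world_index <- function(net_c, net_e, rnd_c_mean, rnd_e_mean) {
  if (rnd_c_mean <= 0 || rnd_e_mean <= 0) {
    stop("reference values must be positive", call. = FALSE)
  }
  (net_c / rnd_c_mean) * (net_e / rnd_e_mean)
}

#' Degree-to-clustering hierarchy curve
#'
#' Bins nodes by degree and reports each bin's mean clustering coefficient
#' normalised by the global mean clustering. A declining curve (high-degree
#' nodes less clustered than average) is the signature of hierarchical
#' organisation: hubs connect otherwise segregated neighbourhoods. The
#' node-level Spearman correlation between degree and clustering is
#' returned as a scalar indicator (negative = hierarchical).
#'
#' @param net A non-empty [spatial_network()].
#' @param bin_width Degree bin width (>= 1).
#' @return A `hierarchy_curve` object: list with `curve` (tibble: bin_lo,
#'   bin_hi, mean_clustering_norm, n_nodes), `spearman_rho`, and
#'   `global_clustering`.
#' @export
hierarchy_curve <- function(net, bin_width = 5) {
  if (nrow(net$nodes) == 0) stop("empty network", call. = FALSE)
  if (bin_width < 1) stop("bin_width must be >= 1", call. = FALSE)
  k <- node_degrees(net)
  cl <- weighted_clustering(net)
  c_i <- cl$per_node
  lo <- floor(min(k) / bin_width) * bin_width
  breaks <- seq(lo, max(k) + bin_width, by = bin_width)
  bin <- cut(k, breaks = breaks, right = FALSE)
  curve <- tibble::tibble(k = k, c = c_i, bin = bin) |>
    dplyr::group_by(.data$bin, .drop = TRUE) |>
    dplyr::summarise(mean_clustering = mean(.data$c), n_nodes = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(
      bin_lo = breaks[as.integer(.data$bin)],
      bin_hi = breaks[as.integer(.data$bin) + 1],
      mean_clustering_norm = .data$mean_clustering / cl$global
    ) |>
    dplyr::select("bin_lo", "bin_hi", "mean_clustering_norm", "n_nodes")
  rho <- if (stats::sd(k) == 0 || stats::sd(c_i) == 0) NA_real_ else {
    stats::cor(k, c_i, method = "spearman")
  }
  structure(list(curve = curve, spearman_rho = rho,
                 global_clustering = cl$global),
            class = "hierarchy_curve")
}

#' Degree assortativity coefficient
#'
#' Pearson-type correlation of the degrees at the two ends of each edge
#' (Newman's edge-based form, symmetrised over the unordered endpoints).
#' Positive values indicate that nodes attach to nodes of similar degree;
#' `r` lies in `[-1, 1]`.
#'
#' @param net A [spatial_network()] with at least 2 edges.
#' @return The coefficient, or `NA` (with a warning) when all endpoint
#'   degrees are equal and the correlation is undefined.
#' @export
degree_assortativity <- function(net) {
  if (nrow(net$edges) < 2) stop("need at least two edges", call. = FALSE)
  k <- node_degrees(net)
  ei <- edge_indices(net)
  je <- k[ei[, 1]]
  ke <- k[ei[, 2]]
  mid <- mean((je + ke) / 2)
  num <- mean(je * ke) - mid^2
  den <- mean((je^2 + ke^2) / 2) - mid^2
  if (den <= 0) {
    warning("degree assortativity undefined: no degree variance over edges",
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' K-core / s-core decomposition by iterative peeling
#'
#' For a threshold t, the core is the maximal subgraph in which every node
#' keeps at least t connections (`k_core`) or at least summed connection
#' strength t towards the rest of the core (`s_core`), found by repeatedly
#' deleting nodes below the threshold. The decomposition sweeps the exact
#' collapse thresholds (the attained intra-core degrees/strengths, so no
#' grid artefacts arise from the continuous strength values), records the
#' core size at each, and returns the innermost (last non-empty) core.
#'
#' @param net A [spatial_network()].
#' @param kind `"k_core"` or `"s_core"`.
#' @return A list with `profile` (tibble: threshold, size - the core is the
#'   recorded node set for all thresholds up to the next collapse point)
#'   and `core` (a [core_structure()] for the innermost core; its
#'   `threshold` is the largest value at which the core is still
#'   non-empty).
#' @export
core_decomposition <- function(net, kind = c("k_core", "s_core")) {
  kind <- match.arg(kind)
  a <- adjacency_matrix(net, weighted = kind == "s_core")
  n <- nrow(a)
  alive <- rep(TRUE, n)
  vals <- rowSums(a)  # intra-core degree/strength, updated incrementally
  thresholds <- sizes <- numeric(0)
  last_members <- integer()
  last_thr <- NA_real_
  while (any(alive)) {
    # refresh from scratch at each collapse point: the incremental updates
    # below are fast for the cascade but accumulate rounding drift
    vals[alive] <- rowSums(a[alive, alive, drop = FALSE])
    m <- min(vals[alive])
    thresholds <- c(thresholds, m)
    sizes <- c(sizes, sum(alive))
    last_members <- which(alive)
    last_thr <- m
    # peel at any threshold just above m: drop nodes at <= m, then cascade
    repeat {
      drop <- alive & vals <= m + 1e-12
      if (!any(drop)) break
      alive[drop] <- FALSE
      if (!any(alive)) break
      vals <- vals - rowSums(a[, drop, drop = FALSE])
    }
  }
  profile <- list(tibble::tibble(threshold = thresholds, size = sizes))
  core <- core_structure(net, net$nodes$id[last_members], threshold = last_thr,
                         kind = kind)
  structure(list(profile = dplyr::bind_rows(profile), core = core,
                 kind = kind),
            class = "core_decomposition")
}

#' Describe a node set as a core with its connection statistics
#'
#' @param net A [spatial_network()].
#' @param members Character vector of member node ids.
#' @param threshold The defining threshold (s, k, or degree cut-off).
#' @param kind `"k_core"`, `"s_core"` or `"rich_club"`.
#' @return A `core_structure`: list with the member set, threshold, kind,
#'   number of internal edges, internal connection density, and
#'   `external_reach` (number of non-member nodes directly connected to the
#'   core).
#' @export
core_structure <- function(net, members, threshold = NA_real_,
                           kind = "k_core") {
  members <- as.character(members)
  inside_from <- net$edges$from %in% members
  inside_to <- net$edges$to %in% members
  internal <- inside_from & inside_to
  sz <- length(members)
  touched <- unique(c(net$edges$to[inside_from & !inside_to],
                      net$edges$from[inside_to & !inside_from]))
  structure(list(
    members = members, threshold = threshold, kind = kind,
    internal_edges = sum(internal),
    internal_density = if (sz >= 2) sum(internal) / (sz * (sz - 1) / 2) else NA_real_,
    external_reach = length(touched)
  ), class = "core_structure")
}

#' @export
print.core_structure <- function(x, ...) {
  cat(sprintf("<core_structure [%s]: %d members, threshold %.4g>\n",
              x$kind, length(x$members), x$threshold))
  cat(sprintf("  internal edges %d (density %.3f), reaches %d outside nodes\n",
              x$internal_edges, x$internal_density, x$external_reach))
  invisible(x)
}

#' Weighted rich-club density profile
#'
#' For each degree threshold k, takes the club `N_>k` of nodes with degree
#' strictly above k and computes
#' `phi_w(k) = W_>k / sum of the E_max strongest edge weights in the whole
#' network`, where `W_>k` is the total weight among club members and
#' `E_max = |N_>k| (|N_>k| - 1) / 2`. The measure is 1 only when the club
#' is fully interconnected by exactly the globally strongest connections,
#' and on binary networks it reduces to the classical rich-club k-density.
#' Thresholds whose club is too large (`E_max > E`, denominator undefined)
#' or smaller than two nodes are excluded with a reason.
#'
#' @param net A weighted simple [spatial_network()].
#' @return A `rich_club` object: list with `profile` (tibble: k, club_size,
#'   e_max, phi_w, valid, reason), `k_min` (smallest valid threshold) and
#'   `max_club_size` (largest x with `x (x - 1) / 2 <= E`; clubs above this
#'   size cannot be assessed).
#' @export
weighted_rich_club <- function(net) {
  k <- node_degrees(net)
  E <- nrow(net$edges)
  if (E == 0) stop("rich-club assessment needs at least one edge", call. = FALSE)
  w_sorted <- sort(net$edges$weight, decreasing = TRUE)
  cum_top <- cumsum(w_sorted)
  ei <- edge_indices(net)
  ks <- 0:(max(k) - 1)
  rows <- purrr::map(ks, function(kk) {
    club <- k > kk
    sz <- sum(club)
    emax <- sz * (sz - 1) / 2
    if (sz < 2) {
      return(tibble::tibble(k = kk, club_size = sz, e_max = emax,
                            phi_w = NA_real_, valid = FALSE,
                            reason = "club smaller than two nodes"))
    }
    if (emax > E) {
      return(tibble::tibble(k = kk, club_size = sz, e_max = emax,
                            phi_w = NA_real_, valid = FALSE,
                            reason = "denominator undefined: E_max exceeds E"))
    }
    internal <- club[ei[, 1]] & club[ei[, 2]]
    tibble::tibble(k = kk, club_size = sz, e_max = emax,
                   phi_w = sum(net$edges$weight[internal]) / cum_top[emax],
                   valid = TRUE, reason = NA_character_)
  })
  profile <- dplyr::bind_rows(rows)
  valid_k <- profile$k[profile$valid]
  structure(list(profile = profile,
                 k_min = if (length(valid_k)) min(valid_k) else NA_real_,
                 max_club_size = max_assessable_club(E)),
            class = "rich_club")
}

#' Largest fully interconnectable club size
#'
#' The largest integer x such that `x (x - 1) / 2 <= E`: a club of more
#' than this many nodes cannot be fully interconnected by the E existing
#' edges, so its weighted rich-club density is undefined.
#'
#' @param E Number of edges in the network.
#' @return An integer club size.
#' @export
max_assessable_club <- function(E) {
  x <- floor((1 + sqrt(1 + 8 * E)) / 2)
  while (x * (x - 1) / 2 > E) x <- x - 1
  as.integer(x)
}

#' Rich club of a fixed size with its weighted density
#'
#' Takes the `size` highest-degree nodes (ties broken by node-table order)
#' and evaluates the weighted rich-club density of that club: total
#' internal weight over the sum of the `size (size - 1) / 2` strongest edge
#' weights in the network.
#'
#' @param net A [spatial_network()].
#' @param size Club size (with `size (size - 1) / 2 <= E`).
#' @return A [core_structure()] of kind `"rich_club"` with an extra
#'   `phi_w` element; `threshold` is the lowest member degree.
#' @export
rich_club_core <- function(net, size) {
  E <- nrow(net$edges)
  if (size * (size - 1) / 2 > E) {
    stop("club of this size cannot be assessed (E_max exceeds E)",
         call. = FALSE)
  }
  k <- node_degrees(net)
  ord <- order(-k, seq_along(k))
  members <- net$nodes$id[ord[seq_len(size)]]
  cs <- core_structure(net, members, threshold = min(k[ord[seq_len(size)]]),
                       kind = "rich_club")
  inside <- net$edges$from %in% members & net$edges$to %in% members
  emax <- size * (size - 1) / 2
  top <- sort(net$edges$weight, decreasing = TRUE)[seq_len(emax)]
  cs$phi_w <- sum(net$edges$weight[inside]) / sum(top)
  cs
}

#' Wiring-length statistics of a network
#'
#' Summarises the Euclidean connection lengths: mean and standard deviation
#' over edges, total wiring, per-region totals, and - when hemisphere
#' labels are present - the fraction of inter-hemispheric connections and
#' their mean length. Against a reference network on the same nodes it also
#' reports the mean per-region percentage change in total connection length
#' and a Wilcoxon rank-sum test of the two per-region distributions.
#'
#' @param net A [spatial_network()] with coordinates.
#' @param reference Optional reference [spatial_network()] (e.g. the source
#'   of a surrogate).
#' @return A list with `summary` (one-row tibble) and `per_region`
#'   (tibble: id, total_length, and vs-reference change when given).
#' @export
wiring_statistics <- function(net, reference = NULL) {
  len <- edge_lengths(net)
  per_tot <- node_total_lengths(net)
  hemi <- net$nodes$hemisphere[match(net$edges$from, net$nodes$id)] !=
    net$nodes$hemisphere[match(net$edges$to, net$nodes$id)]
  have_hemi <- !all(is.na(net$nodes$hemisphere))
  summary <- tibble::tibble(
    n_edges = length(len),
    mean_length = mean(len),
    sd_length = stats::sd(len),
    total_length = sum(len),
    interhemispheric_fraction = if (have_hemi) mean(hemi) else NA_real_,
    mean_interhemispheric_length = if (have_hemi && any(hemi))
      mean(len[hemi]) else NA_real_
  )
  per_region <- tibble::tibble(id = names(per_tot), total_length = per_tot)
  if (!is.null(reference)) {
    check_same_nodes(net, reference)
    ref_tot <- node_total_lengths(reference)[names(per_tot)]
    pct <- 100 * (per_tot - ref_tot) / ref_tot
    pct[ref_tot == 0] <- NA_real_
    per_region$reference_total <- ref_tot
    per_region$pct_change <- pct
    wt <- suppressWarnings(stats::wilcox.test(per_tot, ref_tot,
                                              exact = FALSE))
    summary$mean_pct_change <- mean(pct, na.rm = TRUE)
    summary$sd_pct_change <- stats::sd(pct, na.rm = TRUE)
    # identical distributions with full ties degenerate to 0/0; report 1
    summary$ranksum_p <- if (is.finite(wt$p.value)) wt$p.value else 1
  }
  list(summary = summary, per_region = per_region)
}

#' Overlap and connection statistics of two cores
#'
#' @param core_a,core_b [core_structure()]s from the same network.
#' @param net The network both cores live in.
#' @return A one-row tibble: overlap fraction `|A intersect B| / |A|`, and
#'   each core's size, internal edge count, internal density and external
#'   reach.
#' @export
core_overlap <- function(core_a, core_b, net) {
  inter <- length(intersect(core_a$members, core_b$members))
  tibble::tibble(
    overlap = inter / length(core_a$members),
    n_shared = inter,
    size_a = length(core_a$members),
    size_b = length(core_b$members),
    internal_edges_a = core_a$internal_edges,
    internal_edges_b = core_b$internal_edges,
    internal_density_a = core_a$internal_density,
    internal_density_b = core_b$internal_density,
    external_reach_a = core_a$external_reach,
    external_reach_b = core_b$external_reach
  )
}
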