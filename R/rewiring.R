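#' Configuration for surrogate generation by constrained edge rewiring
#'
#' All three surrogate types preserve the node set, coordinates, edge count
#' and exact degree sequence of the source network; they differ only in the
#' wiring-length constraint applied to each proposed edge swap:
#' \describe{
#'   \item{random}{no spatial constraint: every valid swap is accepted.}
#'   \item{spatial}{a swap is accepted only if afterwards the total Euclidean
#'     connection length of each of the four touched regions does not exceed
#'     that region's total in the source network.}
#'   \item{reduced}{a swap is accepted only if it shortens the wiring; see
#'     `reduced_mode`.}
#' }
#'
#' @param surrogate_type `"random"`, `"spatial"` or `"reduced"`.
#' @param swaps_per_edge Average number of rewirings per connection before
#'   stopping. Defaults to 20 for random/spatial surrogates and 1 for the
#'   much more constrained reduced surrogates, whose acceptance rate decays
#'   as fewer length-reducing swaps remain.
#' @param max_attempts_factor Consecutive rejected proposals allowed per
#'   required swap before a member is declared saturated.
#' @param reduced_mode `"per_region_strict"` (each of the four touched
#'   regions' totals strictly decreases; the literal per-region reading) or
#'   `"total_length"` (the summed length of the two new edges is strictly
#'   smaller than that of the two removed ones). Both modes make the total
#'   network wiring length strictly decrease with every accepted swap.
#' @param seed Integer base seed; member `i` of an ensemble uses `seed + i`.
#' @return A `rewiring_config` list.
#' @export
rewiring_config <- function(surrogate_type = c("random", "spatial", "reduced"),
                            swaps_per_edge = NULL,
                            max_attempts_factor = 1000,
                            reduced_mode = c("per_region_strict", "total_length"),
                            seed = 1) {
  surrogate_type <- match.arg(surrogate_type)
  reduced_mode <- match.arg(reduced_mode)
  if (is.null(swaps_per_edge)) {
    swaps_per_edge <- if (surrogate_type == "reduced") 1 else 20
  }
  if (swaps_per_edge <= 0) stop("swaps_per_edge must be > 0", call. = FALSE)
  if (max_attempts_factor < 1) stop("max_attempts_factor must be >= 1", call. = FALSE)
  structure(list(surrogate_type = surrogate_type,
                 swaps_per_edge = swaps_per_edge,
                 max_attempts_factor = max_attempts_factor,
                 reduced_mode = reduced_mode, seed = seed),
            class = "rewiring_config")
}

#' Number of swaps required to rewire each connection F times on average
#'
#' Each accepted swap rewires two connections, so rewiring each of the
#' `n_edges` connections `swaps_per_edge` times on average takes
#' `floor(swaps_per_edge * n_edges / 2)` swaps.
#'
#' @param n_edges Number of connections (>= 2).
#' @param swaps_per_edge Average rewirings per connection.
#' @return Integer swap count.
#' @export
#' @examples
#' required_swaps(17865, 20) # 178650
#' required_swaps(17865, 1)  # 8932
required_swaps <- function(n_edges, swaps_per_edge) {
  if (n_edges < 2) stop("need at least two edges to swap", call. = FALSE)
  floor(swaps_per_edge * n_edges / 2)
}

#' Propose a degree-preserving replacement of two edges
#'
#' Draws two distinct edges (r1, r2) and (r3, r4) uniformly at random and
#' proposes replacing them by (r1, r3) and (r2, r4). The proposal is marked
#' invalid if it would create a self-connection or a parallel link. The
#' replacement edges inherit the weights of the removed edges:
#' (r1, r3) takes w(r1, r2) and (r2, r4) takes w(r3, r4).
#'
#' @param net A [spatial_network()] with at least two edges.
#' @return A list with elements `edge_rows` (the two sampled rows of
#'   `net$edges`), `removed`, `added` (two-row tibbles with endpoints and
#'   carried weights) and `valid`.
#' @export
propose_swap <- function(net) {
  E <- nrow(net$edges)
  if (E < 2) stop("need at least two edges to propose a swap", call. = FALSE)
  es <- sample.int(E, 2)
  swap_candidate(net, es[1], es[2])
}

# deterministic core of propose_swap, also used by tests
swap_candidate <- function(net, e1, e2) {
  r1 <- net$edges$from[e1]; r2 <- net$edges$to[e1]
  r3 <- net$edges$from[e2]; r4 <- net$edges$to[e2]
  added <- tibble::tibble(from = c(r1, r2), to = c(r3, r4),
                          weight = net$edges$weight[c(e1, e2)])
  removed <- net$edges[c(e1, e2), ]
  valid <- r1 != r3 && r2 != r4 &&
    !has_edge(net, r1, r3) && !has_edge(net, r2, r4)
  list(edge_rows = c(e1, e2), removed = removed, added = added, valid = valid)
}

has_edge <- function(net, a, b) {
  any((net$edges$from == a & net$edges$to == b) |
        (net$edges$from == b & net$edges$to == a))
}

#' Decide whether a proposed swap satisfies the wiring-length constraint
#'
#' Implements the three acceptance rules described in [rewiring_config()].
#' The spatial rule compares the post-swap per-region totals of the four
#' touched regions against their totals in the *source* network (not the
#' current rewired state), so per-region wiring can never drift above its
#' original value over any number of swaps.
#'
#' @param source_net The original network whose per-region totals cap the
#'   spatial surrogates.
#' @param current_net The network in its current rewired state.
#' @param candidate A valid proposal from [propose_swap()].
#' @param config A [rewiring_config()].
#' @return `TRUE` to accept the swap.
#' @export
accept_swap <- function(source_net, current_net, candidate, config) {
  stopifnot(inherits(config, "rewiring_config"))
  if (config$surrogate_type == "random") return(TRUE)
  xyz <- node_coords(current_net)
  rownames(xyz) <- current_net$nodes$id
  d <- function(a, b) sqrt(sum((xyz[a, ] - xyz[b, ])^2))
  r1 <- candidate$removed$from[1]; r2 <- candidate$removed$to[1]
  r3 <- candidate$removed$from[2]; r4 <- candidate$removed$to[2]
  d12 <- d(r1, r2); d34 <- d(r3, r4); d13 <- d(r1, r3); d24 <- d(r2, r4)
  if (config$surrogate_type == "reduced") {
    if (config$reduced_mode == "per_region_strict") {
      return(d13 < d12 && d24 < d12 && d13 < d34 && d24 < d34)
    }
    return(d13 + d24 < d12 + d34)
  }
  # spatial: per-region totals capped at the source network's totals
  tot <- node_total_lengths(current_net)
  src <- node_total_lengths(source_net)
  delta <- c(d13 - d12, d24 - d12, d13 - d34, d24 - d34)
  regions <- c(r1, r2, r3, r4)
  all(tot[regions] + delta <= src[regions] + 1e-9)
}

#' Generate an ensemble of rewired surrogate networks
#'
#' Each member starts from the source network and repeats propose/accept
#' swap steps (see [propose_swap()] and [accept_swap()]) until
#' [required_swaps()] have been accepted, or until
#' `max_attempts_factor * required_swaps` consecutive proposals have been
#' rejected (reduced surrogates saturate as length-reducing swaps run out;
#' saturation is recorded in the provenance, not an error). The inner loop
#' runs in compiled code; member `i` seeds R's RNG with `config$seed + i`,
#' so members are independent and the ensemble is reproducible regardless
#' of generation order.
#'
#' @param net Source [spatial_network()] (simple, >= 2 edges).
#' @param config A [rewiring_config()].
#' @param n_members Number of surrogate networks.
#' @return A `surrogate_ensemble`: list with `members` (list of
#'   [spatial_network()]), `config`, `source`, and a `provenance` tibble
#'   (member, seed, accepted and attempted swap counts, saturation flag).
#' @export
generate_ensemble <- function(net, config, n_members = 20) {
  stopifnot(inherits(net, "spatial_network"), inherits(config, "rewiring_config"))
  E <- nrow(net$edges)
  req <- required_swaps(E, config$swaps_per_edge)
  type_code <- match(config$surrogate_type, c("random", "spatial", "reduced")) - 1L
  mode_code <- match(config$reduced_mode, c("per_region_strict", "total_length")) - 1L
  slack <- if (config$surrogate_type == "spatial") 1e-9 else 1e-12
  ei <- edge_indices(net)
  xyz <- node_coords(net)
  members <- vector("list", n_members)
  prov <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    member_seed <- config$seed + m
    set.seed(member_seed)
    res <- rewire_engine_cpp(ei - 1L, net$edges$weight, xyz, type_code,
                             mode_code, req,
                             config$max_attempts_factor * req, slack)
    new_ei <- res$edges + 1L
    edges <- tibble::tibble(from = net$nodes$id[new_ei[, 1]],
                            to = net$nodes$id[new_ei[, 2]],
                            weight = res$weights)
    members[[m]] <- spatial_network(net$nodes, edges)
    prov[[m]] <- tibble::tibble(member = m, seed = member_seed,
                                required = req, accepted = res$accepted,
                                attempted = res$attempted,
                                saturated = res$saturated)
  }
  structure(list(members = members, config = config, source = net,
                 provenance = dplyr::bind_rows(prov)),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble: %d %s members of a %d-node network>\n",
              length(x$members), x$config$surrogate_type,
              nrow(x$source$nodes)))
  cat(sprintf("  accepted swaps per member: %s (required %d)\n",
              paste(range(x$provenance$accepted), collapse = "-"),
              x$provenance$required[1]))
  invisible(x)
}

#' Tidy a surrogate ensemble into per-member summaries
#'
#' @param x A `surrogate_ensemble`.
#' @param ... Unused.
#' @return The provenance tibble extended with each member's mean edge
#'   length and total wiring length.
#' @method tidy surrogate_ensemble
#' @export
tidy.surrogate_ensemble <- function(x, ...) {
  stats <- purrr::map_dfr(x$members, function(m) {
    len <- edge_lengths(m)
    tibble::tibble(mean_edge_length = mean(len), total_wiring_length = sum(len))
  })
  dplyr::bind_cols(x$provenance, stats)
}

#' One-row summary of a surrogate ensemble
#'
#' @param x A `surrogate_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: type, member count, mean accepted swaps,
#'   saturation count, mean member wiring length and the source network's.
#' @method glance surrogate_ensemble
#' @export
glance.surrogate_ensemble <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    surrogate_type = x$config$surrogate_type,
    n_members = length(x$members),
    mean_accepted = mean(td$accepted),
    n_saturated = sum(td$saturated),
    mean_total_wiring = mean(td$total_wiring_length),
    source_total_wiring = total_wiring_length(x$source)
  )
}
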