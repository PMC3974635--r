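# small deterministic networks used across test files

# n collinear points on the x axis at the given positions
collinear_net <- function(xs, edges, ids = letters[seq_along(xs)]) {
  nodes <- data.frame(id = ids, x = xs, y = 0, z = 0)
  spatial_network(nodes, edges)
}

# Erdos-Renyi-style random weighted network with random coordinates
random_net <- function(n, p = 0.3, seed = 1, weights = TRUE) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  nodes <- data.frame(id = ids, x = stats::runif(n, 0, 10),
                      y = stats::runif(n, 0, 10), z = stats::runif(n, 0, 10))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  w <- if (weights) stats::runif(nrow(pairs), 0.1, 2) else rep(1, nrow(pairs))
  spatial_network(nodes, data.frame(from = ids[pairs[, 1]],
                                    to = ids[pairs[, 2]], weight = w))
}

complete_net <- function(n, weight = 1) {
  ids <- letters[seq_len(n)]
  nodes <- data.frame(id = ids, x = cos(2 * pi * seq_len(n) / n),
                      y = sin(2 * pi * seq_len(n) / n), z = 0)
  pairs <- utils::combn(n, 2)
  spatial_network(nodes, data.frame(from = ids[pairs[1, ]],
                                    to = ids[pairs[2, ]], weight = weight))
}

# hub node connected to every vertex of m otherwise disjoint triangles
hub_and_cliques_net <- function(m = 3) {
  ids <- c("hub", paste0("t", rep(seq_len(m), each = 3), letters[1:3]))
  ang <- 2 * pi * seq_len(m) / m
  nodes <- data.frame(
    id = ids,
    x = c(0, rep(10 * cos(ang), each = 3) + rep(c(0, 1, 0.5), m)),
    y = c(0, rep(10 * sin(ang), each = 3) + rep(c(0, 0, 1), m)),
    z = 0
  )
  tri <- do.call(rbind, lapply(seq_len(m), function(i) {
    v <- paste0("t", i, letters[1:3])
    rbind(data.frame(from = v[c(1, 1, 2)], to = v[c(2, 3, 3)]),
          data.frame(from = "hub", to = v))
  }))
  tri$weight <- 1
  spatial_network(nodes, tri)
}
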