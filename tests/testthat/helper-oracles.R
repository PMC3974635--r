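# independent brute-force oracles, deliberately written along different
# routes than the package implementations

# all-pairs shortest paths by Floyd-Warshall on costs 1/weight
oracle_efficiency <- function(net) {
  n <- nrow(net$nodes)
  a <- adjacency_matrix(net, weighted = TRUE)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1 / a[a > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  inv <- 1 / d
  diag(inv) <- 0
  mean(rowSums(inv) / (n - 1))
}

# Onnela clustering by explicit triangle enumeration
oracle_clustering <- function(net) {
  a <- adjacency_matrix(net, weighted = TRUE)
  w <- a / max(a)
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (j in nb) for (h in nb) {
      if (j != h && a[j, h] > 0) {
        t_i <- t_i + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    ci[i] <- (t_i / 2) * 2 / (k * (k - 1))
  }
  list(global = mean(ci), per_node = ci)
}

# assortativity as the Pearson correlation of endpoint degrees over the
# edge list listed in both directions
oracle_assortativity <- function(net) {
  k <- node_degrees(net)
  ei <- cbind(match(net$edges$from, net$nodes$id),
              match(net$edges$to, net$nodes$id))
  x <- c(k[ei[, 1]], k[ei[, 2]])
  y <- c(k[ei[, 2]], k[ei[, 1]])
  stats::cor(x, y)
}

# modularity by the explicit double sum over all node pairs
oracle_modularity <- function(net, membership) {
  a <- adjacency_matrix(net, weighted = TRUE)
  k <- rowSums(a)
  w2 <- sum(k)
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j]) {
      q <- q + a[i, j] - k[i] * k[j] / w2
    }
  }
  unname(q / w2)
}

# weighted rich-club phi at one degree threshold by direct summation
oracle_rich_club_k <- function(net, kk) {
  k <- node_degrees(net)
  members <- net$nodes$id[k > kk]
  sz <- length(members)
  emax <- sz * (sz - 1) / 2
  if (sz < 2 || emax > nrow(net$edges)) return(NA_real_)
  w_in <- 0
  for (e in seq_len(nrow(net$edges))) {
    if (net$edges$from[e] %in% members && net$edges$to[e] %in% members) {
      w_in <- w_in + net$edges$weight[e]
    }
  }
  w_in / sum(sort(net$edges$weight, decreasing = TRUE)[seq_len(emax)])
}

# core at a single fixed threshold by naive repeated scanning
oracle_core_at <- function(net, thr, weighted) {
  a <- adjacency_matrix(net, weighted = weighted)
  keep <- rep(TRUE, nrow(a))
  repeat {
    v <- rowSums(a[keep, keep, drop = FALSE])
    bad <- v < thr
    if (!any(bad)) break
    keep[keep][bad] <- FALSE
    if (!any(keep)) break
  }
  net$nodes$id[keep]
}

# all set partitions of n labelled items as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0)
  out
}

# exhaustive-search optimal modularity over all partitions (tiny n only)
oracle_best_q <- function(net) {
  n <- nrow(net$nodes)
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- modularity_q(net, p)
    if (q > best) best <- q
  }
  best
}

skewness <- function(x) mean(((x - mean(x)) / stats::sd(x))^3)

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  nn <- ch2(sum(tab))
  (sij - si * sj / nn) / ((si + sj) / 2 - si * sj / nn)
}
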