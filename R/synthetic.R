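#' Specification for a synthetic spatially embedded network
#'
#' Describes the generator used throughout the package's tests and examples:
#' nodes laid out in 3-D space, edges sampled with a distance-decay
#' preference for short connections (the dominant statistical feature of
#' cortical connectivity), and i.i.d. positive weights.
#'
#' @param n_nodes Number of nodes (>= 4).
#' @param target_edges Exact number of edges to place.
#' @param geometry `"sphere_surface"` (uniform on a sphere of `radius` mm,
#'   emulating a cortical spheroid) or `"box"` (uniform in a cube of side
#'   `2 * radius`).
#' @param radius Geometry scale in mm.
#' @param decay_scale Distance-decay scale lambda in mm: a candidate pair at
#'   distance d is sampled with probability proportional to `exp(-d / lambda)`.
#' @param weight_model `"lognormal"` or `"exponential"`.
#' @param weight_params Parameters of the weight distribution
#'   (`meanlog`/`sdlog` or `rate`).
#' @param n_modules Number of planted spatial clusters; 0 places nodes
#'   directly on the geometry. With modules, cluster centres sit on the
#'   geometry and members scatter around them with Gaussian noise
#'   (`module_sd` mm), so distance decay concentrates edges within clusters.
#' @param module_sd Within-cluster scatter in mm.
#' @param propensity_sd Degree-heterogeneity control: each node draws a
#'   log-normal connection propensity `a_i` with `sdlog = propensity_sd`,
#'   and a pair's sampling weight becomes `a_i a_j exp(-d / lambda)`. Zero
#'   (the default) gives a purely geometric model; positive values skew the
#'   degree distribution to the right, towards the exponential-like degree
#'   distributions of cortical networks.
#' @param seed Integer seed; the whole network is reproducible from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_nodes, target_edges,
                       geometry = c("sphere_surface", "box"),
                       radius = 70, decay_scale = 15,
                       weight_model = c("lognormal", "exponential"),
                       weight_params = list(meanlog = 0, sdlog = 1),
                       n_modules = 0, module_sd = 8,
                       propensity_sd = 0, seed = 1) {
  geometry <- match.arg(geometry)
  weight_model <- match.arg(weight_model)
  if (n_nodes < 4) stop("n_nodes must be >= 4", call. = FALSE)
  if (decay_scale <= 0) stop("decay_scale must be > 0", call. = FALSE)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (target_edges > max_edges) {
    stop("target_edges exceeds n(n-1)/2", call. = FALSE)
  }
  if (radius <= 0) stop("degenerate geometry: radius must be > 0", call. = FALSE)
  structure(list(n_nodes = n_nodes, target_edges = target_edges,
                 geometry = geometry, radius = radius,
                 decay_scale = decay_scale, weight_model = weight_model,
                 weight_params = weight_params, n_modules = n_modules,
                 module_sd = module_sd, propensity_sd = propensity_sd,
                 seed = seed),
            class = "synth_spec")
}

# deterministic, well-separated points on the sphere (Fibonacci lattice),
# used for planted module centres so clusters cannot collide by chance
fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(r * cos(phi), r * sin(phi), z)
}

sample_geometry <- function(n, geometry, radius) {
  if (geometry == "sphere_surface") {
    # uniform on the sphere surface via normalised Gaussians
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    radius * v / sqrt(rowSums(v^2))
  } else {
    matrix(stats::runif(3 * n, -radius, radius), ncol = 3)
  }
}

#' Generate a synthetic spatially embedded network
#'
#' Places nodes according to the spec's geometry, then samples exactly
#' `target_edges` distinct node pairs without replacement with probability
#' proportional to `exp(-d / decay_scale)` (d the pair's Euclidean
#' distance), and finally draws i.i.d. weights from the weight model. All
#' randomness derives from `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return A [spatial_network()] with node ids `n001`, `n002`, ...
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    code
  }
  withr_seed({
    n <- spec$n_nodes
    if (spec$n_modules > 0) {
      centres <- if (spec$geometry == "sphere_surface") {
        fibonacci_sphere(spec$n_modules, spec$radius)
      } else {
        sample_geometry(spec$n_modules, spec$geometry, spec$radius)
      }
      member <- rep_len(seq_len(spec$n_modules), n)
      xyz <- centres[member, , drop = FALSE] +
        matrix(stats::rnorm(3 * n, sd = spec$module_sd), ncol = 3)
    } else {
      xyz <- sample_geometry(n, spec$geometry, spec$radius)
    }
    ids <- sprintf("n%0*d", nchar(n), seq_len(n))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                         xyz[pairs[, 2], , drop = FALSE])^2))
    # exact weighted sampling without replacement over all candidate pairs
    # (exponential-keys method; O(n log n) rather than sample.int's O(n k));
    # subtracting min(d) only rescales the probabilities but avoids underflow
    p <- exp(-(d - min(d)) / spec$decay_scale)
    if (spec$propensity_sd > 0) {
      a <- stats::rlnorm(n, sdlog = spec$propensity_sd)
      p <- p * a[pairs[, 1]] * a[pairs[, 2]]
    }
    take <- order(stats::rexp(length(d)) / p)[seq_len(spec$target_edges)]
    w <- switch(spec$weight_model,
      lognormal = stats::rlnorm(length(take),
                                meanlog = spec$weight_params$meanlog,
                                sdlog = spec$weight_params$sdlog),
      exponential = stats::rexp(length(take), rate = spec$weight_params$rate)
    )
    nodes <- tibble::tibble(id = ids, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            hemisphere = ifelse(xyz[, 1] < 0, "left", "right"))
    edges <- tibble::tibble(from = ids[pairs[take, 1]],
                            to = ids[pairs[take, 2]], weight = w)
    spatial_network(nodes, edges)
  })
}

#' Cortical-like test network
#'
#' A fixed-parameter [generate_network()] call used throughout the test
#' suite and examples: 500 nodes uniform on a 70 mm sphere surface, 8900
#' edges with an 8 mm distance-decay scale and moderate degree
#' heterogeneity (both calibrated once so the mean edge length falls in the
#' 25-30 mm range typical of cortical connectivity and the degree
#' distribution is right-skewed), log-normal weights.
#'
#' @param seed Integer seed.
#' @return A [spatial_network()].
#' @export
cortical_like_fixture <- function(seed = 0) {
  generate_network(synth_spec(
    n_nodes = 500, target_edges = 8900, geometry = "sphere_surface",
    radius = 70, decay_scale = 8,
    weight_model = "lognormal", weight_params = list(meanlog = 0, sdlog = 1),
    propensity_sd = 0.6, seed = seed
  ))
}

#' Synthetic network with planted spatial modules
#'
#' Four (by default) well-separated spatial clusters with small scatter and a
#' short decay scale, so almost all connections fall within clusters. Used to
#' test planted-partition recovery by spectral module detection.
#'
#' @param seed Integer seed.
#' @param n_nodes,target_edges,n_modules Generator parameters.
#' @return A list with the network (`net`) and the planted assignment
#'   (`membership`, integer vector over nodes).
#' @export
planted_module_fixture <- function(seed = 0, n_nodes = 120,
                                   target_edges = 960, n_modules = 4) {
  spec <- synth_spec(n_nodes = n_nodes, target_edges = target_edges,
                     geometry = "sphere_surface", radius = 50,
                     decay_scale = 6, n_modules = n_modules, module_sd = 6,
                     seed = seed)
  net <- generate_network(spec)
  list(net = net,
       membership = rep_len(seq_len(n_modules), n_nodes))
}
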