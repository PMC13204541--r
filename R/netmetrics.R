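# Weighted graph-theory measures, brain-connectivity-toolbox conventions.
#
# Conventions, each isolated in one function so alternates can be swapped:
# Onnela geometric-mean clustering; shortest-path lengths with edge length
# 1/weight; characteristic path length over reachable ordered pairs; local
# efficiency as the global efficiency of each node's neighbor-induced
# subgraph; strength-based weighted assortativity; degree-based rich club on
# the binarized graph; small-worldness against degree-preserving
# Maslov-Sneppen rewired surrogates with weights shuffled onto the rewired
# topology. Statistically undefined values (0/0 transitivity, zero-variance
# assortativity, rich club with fewer than two members) are NA so cohort
# tables stay rectangular; structural impossibilities raise errors.

.as_weights <- function(g) {
  w <- if (inherits(g, "graph_view")) g$weights else g
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (any(w < 0) || any(w > 1)) stop("weights must be in [0, 1]")
  diag(w) <- 0
  w
}

#' Edge density
#'
#' Fraction of region pairs that are connected: the number of nonzero
#' upper-triangle entries over `N(N-1)/2`.
#'
#' @param g A `graph_view` or weight matrix.
#' @return Density in `[0, 1]`.
#' @export
net_density <- function(g) {
  w <- .as_weights(g)
  n <- nrow(w)
  if (n < 2L) stop("density needs at least 2 nodes")
  sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}

# Onnela triangle intensity around each node: diag((W^(1/3))^3).
.onnela_cycles <- function(w) {
  w3 <- w^(1 / 3)
  diag(w3 %*% w3 %*% w3)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per node, the geometric-mean intensity of triangles around it divided by
#' the number of connected neighbor pairs: `C_i = sum_(j,h) (w_ij w_ih
#' w_jh)^(1/3) / (k_i (k_i - 1))`, with `C_i = 0` for degree below 2. The
#' mean is over all nodes, zeros included.
#'
#' @param g A `graph_view` or weight matrix with entries in `[0, 1]`.
#' @return List with `per_node` and `mean`.
#' @export
net_clustering <- function(g) {
  w <- .as_weights(g)
  k <- rowSums(w > 0)
  cyc <- .onnela_cycles(w)
  ci <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  list(per_node = as.numeric(ci), mean = mean(ci))
}

#' Weighted transitivity
#'
#' Global ratio form of the clustering sum: total Onnela triangle intensity
#' over the total number of connected neighbor pairs. `NA` when no node has
#' degree at least 2 (the 0/0 case).
#'
#' @inheritParams net_clustering
#' @return Scalar, or `NA` when undefined.
#' @export
net_transitivity <- function(g) {
  w <- .as_weights(g)
  k <- rowSums(w > 0)
  denom <- sum(k * (k - 1))
  if (denom == 0) return(NA_real_)
  sum(.onnela_cycles(w)) / denom
}

# Shortest-path distance matrix with edge lengths 1/weight; Inf where
# unreachable. Vectorized Floyd-Warshall: O(N^3) but with N <= 72 this
# beats per-call graph-object construction by a wide margin.
.sp_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  pos <- w > 0
  d[pos] <- 1 / w[pos]
  diag(d) <- 0
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], "+")
    upd <- via < d
    d[upd] <- via[upd]
  }
  d
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered reachable node pairs, with edge
#' length the inverse weight. Unreachable pairs are excluded with a warning.
#'
#' @inheritParams net_clustering
#' @return Mean distance (edge-length units).
#' @export
net_path_length <- function(g) {
  w <- .as_weights(g)
  d <- .sp_distances(w)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  if (!any(reach)) stop("no connected node pair: path length undefined")
  if (!all(reach)) warning("graph is disconnected; unreachable pairs excluded")
  mean(off[reach])
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over ordered node pairs, with
#' `1/Inf = 0` for unreachable pairs, so disconnection is handled naturally.
#'
#' @inheritParams net_clustering
#' @return Efficiency in `[0, 1]`.
#' @export
net_global_efficiency <- function(g) {
  w <- .as_weights(g)
  if (nrow(w) < 2L) stop("efficiency needs at least 2 nodes")
  d <- .sp_distances(w)
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Local efficiency
#'
#' Per node, the global efficiency of the weighted subgraph induced on its
#' neighbors; 0 for degree below 2 (neighbors can never exchange
#' information around a missing hub).
#'
#' @inheritParams net_clustering
#' @return List with `per_node` and `mean`.
#' @export
net_local_efficiency <- function(g) {
  w <- .as_weights(g)
  n <- nrow(w)
  ei <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) >= 2L) {
      ei[i] <- net_global_efficiency(w[nb, nb, drop = FALSE])
    }
  }
  list(per_node = ei, mean = mean(ei))
}

#' Strength assortativity
#'
#' Pearson correlation of endpoint strengths (weighted degrees) over the
#' edge list, each undirected edge contributing both orientations. `NA`
#' when the endpoint strengths have zero variance (e.g. a regular graph).
#'
#' @inheritParams net_clustering
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
net_assortativity <- function(g) {
  w <- .as_weights(g)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) < 2L) stop("assortativity needs at least 2 edges")
  s <- rowSums(w)
  x <- c(s[idx[, 1]], s[idx[, 2]])
  y <- c(s[idx[, 2]], s[idx[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Rich-club coefficient
#'
#' On the binarized graph, the edge density among nodes whose degree
#' exceeds `k`: `phi(k) = 2 E_>k / (N_>k (N_>k - 1))`. `NA` when fewer than
#' two nodes survive the degree cut.
#'
#' @inheritParams net_clustering
#' @param k Degree level (scalar or vector).
#' @return Numeric vector of coefficients, one per `k`.
#' @export
net_rich_club <- function(g, k = 0L) {
  w <- .as_weights(g)
  a <- w > 0
  deg <- rowSums(a)
  vapply(k, function(kk) {
    keep <- deg > kk
    nk <- sum(keep)
    if (nk < 2L) return(NA_real_)
    sub <- a[keep, keep]
    sum(sub[upper.tri(sub)]) / (nk * (nk - 1) / 2)
  }, numeric(1))
}

# Maslov-Sneppen degree-preserving rewiring of an undirected edge list.
# `attempts` random double-edge swaps are proposed; swaps creating self-loops
# or duplicate edges are rejected. Returns the rewired edge list.
.ms_rewire <- function(edges, n, attempts) {
  m <- nrow(edges)
  if (m < 2L) return(edges)
  ei <- edges[, 1]
  ej <- edges[, 2]
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  # Presampled proposals and scalar linear indexing keep the loop lean.
  ea <- sample.int(m, attempts, replace = TRUE)
  eb <- sample.int(m, attempts, replace = TRUE)
  flip <- stats::runif(attempts) < 0.5
  for (it in seq_len(attempts)) {
    a <- ea[it]
    b <- eb[it]
    if (a == b) next
    x1 <- ei[a]; y1 <- ej[a]
    x2 <- ei[b]; y2 <- ej[b]
    # Randomly chosen swap orientation.
    if (flip[it]) { tmp <- x2; x2 <- y2; y2 <- tmp }
    if (x1 == y2 || x2 == y1) next
    if (adj[x1 + (y2 - 1L) * n] || adj[x2 + (y1 - 1L) * n]) next
    adj[x1 + (y1 - 1L) * n] <- adj[y1 + (x1 - 1L) * n] <- FALSE
    adj[x2 + (y2 - 1L) * n] <- adj[y2 + (x2 - 1L) * n] <- FALSE
    adj[x1 + (y2 - 1L) * n] <- adj[y2 + (x1 - 1L) * n] <- TRUE
    adj[x2 + (y1 - 1L) * n] <- adj[y1 + (x2 - 1L) * n] <- TRUE
    ei[a] <- x1; ej[a] <- y2
    ei[b] <- x2; ej[b] <- y1
  }
  cbind(ei, ej, deparse.level = 0)
}

#' Small-worldness against degree-preserving rewired nulls
#'
#' Computes `sigma = (C / C_rand) / (L / L_rand)` where `C` is the mean
#' Onnela clustering coefficient, `L` the characteristic path length, and
#' `C_rand`, `L_rand` are means over `n_null` surrogates produced by
#' Maslov-Sneppen double-edge swaps (degree sequence preserved) with the
#' original weight multiset shuffled onto the rewired topology. `sigma > 1`
#' indicates small-world organization. Deterministic given the seed.
#'
#' @inheritParams net_clustering
#' @param n_null Number of null surrogates (default 100).
#' @param swaps_per_edge Swap attempts per edge in each surrogate.
#' @param seed Integer seed for the null ensemble.
#' @return List: `sigma`, `c_ratio`, `l_ratio`, observed `clustering` and
#'   `path_length`, null means/sds, and the null configuration.
#' @export
small_worldness <- function(g, n_null = 100L, swaps_per_edge = 10L,
                            seed = 1L) {
  w <- .as_weights(g)
  if (n_null < 1L) stop("n_null must be at least 1")
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) < 1L) stop("empty graph: small-worldness undefined")
  weights <- w[idx]
  c_obs <- net_clustering(w)$mean
  l_obs <- suppressWarnings(net_path_length(w))

  c_null <- numeric(n_null)
  l_null <- numeric(n_null)
  set.seed(seed)
  attempts <- swaps_per_edge * nrow(idx)
  for (b in seq_len(n_null)) {
    e <- .ms_rewire(idx, n, attempts)
    wb <- matrix(0, n, n)
    wb[e] <- weights[sample.int(length(weights))]
    wb <- pmax(wb, t(wb))
    c_null[b] <- net_clustering(wb)$mean
    l_null[b] <- suppressWarnings(net_path_length(wb))
  }
  c_ratio <- c_obs / mean(c_null)
  l_ratio <- l_obs / mean(l_null)
  list(sigma = c_ratio / l_ratio,
       c_ratio = c_ratio, l_ratio = l_ratio,
       clustering = c_obs, path_length = l_obs,
       null_clustering_mean = mean(c_null), null_clustering_sd = stats::sd(c_null),
       null_path_length_mean = mean(l_null), null_path_length_sd = stats::sd(l_null),
       null_config = list(n_null = n_null, swaps_per_edge = swaps_per_edge,
                          seed = seed))
}

#' All network measures of one view
#'
#' Convenience wrapper evaluating the full metric set on a weight view.
#' Small-worldness is optional because it is the only stochastic (null-model)
#' measure.
#'
#' @inheritParams net_clustering
#' @param rich_club_k Degree level for the reported rich-club coefficient.
#' @param sigma Also compute [small_worldness()]?
#' @param n_null,swaps_per_edge,seed Null-model configuration for sigma.
#' @return One-row data frame of metric values (NA where undefined).
#' @export
network_metrics <- function(g, rich_club_k = 2L, sigma = FALSE,
                            n_null = 100L, swaps_per_edge = 10L, seed = 1L) {
  w <- .as_weights(g)
  res <- data.frame(
    density = net_density(w),
    clustering = net_clustering(w)$mean,
    transitivity = net_transitivity(w),
    path_length = tryCatch(suppressWarnings(net_path_length(w)),
                           error = function(e) NA_real_),
    global_efficiency = net_global_efficiency(w),
    local_efficiency = net_local_efficiency(w)$mean,
    assortativity = tryCatch(net_assortativity(w),
                             error = function(e) NA_real_),
    rich_club = net_rich_club(w, rich_club_k)
  )
  if (sigma) {
    res$sigma <- small_worldness(w, n_null = n_null,
                                 swaps_per_edge = swaps_per_edge,
                                 seed = seed)$sigma
  }
  res
}

#' Ring lattice with random shortcuts
#'
#' A Watts-Strogatz-style benchmark graph: each node is joined to its `k/2`
#' nearest neighbors on each side of a ring, then a fraction `p` of edges is
#' rewired to random shortcuts (degree of the detached endpoint preserved is
#' not enforced; this is the classic rewiring construction). Unit weights.
#'
#' @param n Nodes.
#' @param k Even lattice degree.
#' @param p Fraction of edges rewired to shortcuts.
#' @param seed Integer seed.
#' @return A `graph_view`.
#' @export
ring_lattice_graph <- function(n = 36L, k = 4L, p = 0.1, seed = 1L) {
  if (k %% 2L != 0L || k >= n) stop("k must be even and below n")
  w <- matrix(0, n, n)
  for (d in seq_len(k %/% 2L)) {
    i <- seq_len(n)
    j <- ((i - 1L + d) %% n) + 1L
    w[cbind(i, j)] <- 1
    w[cbind(j, i)] <- 1
  }
  set.seed(seed)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  rew <- which(stats::runif(nrow(idx)) < p)
  for (e in rew) {
    i <- idx[e, 1]
    free <- which(w[i, ] == 0 & seq_len(n) != i)
    if (length(free) == 0L) next
    j_new <- free[sample.int(length(free), 1L)]
    j_old <- idx[e, 2]
    w[i, j_old] <- w[j_old, i] <- 0
    w[i, j_new] <- w[j_new, i] <- 1
  }
  rownames(w) <- colnames(w) <- sprintf("n%02d", seq_len(n))
  graph_view(w, provenance = "whole")
}
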