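# Independent brute-force oracles for the graph measures. Deliberately
# naive (triple loops, exhaustive enumeration) and written against the
# definitions, not against the package code paths.

# Shortest-path distances with edge length 1/weight via repeated relaxation
# (Bellman-Ford style over all node triples, order-independent).
bf_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (d[i, k] + d[k, j] < d[i, j]) {
        d[i, j] <- d[i, k] + d[k, j]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  d
}

bf_path_length <- function(w) {
  d <- bf_distances(w)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

bf_global_efficiency <- function(w) {
  d <- bf_distances(w)
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

bf_clustering <- function(w) {
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        s <- s + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    ci[i] <- s / (k * (k - 1))
  }
  ci
}

bf_transitivity <- function(w) {
  n <- nrow(w)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    den <- den + k * (k - 1)
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        num <- num + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
  }
  if (den == 0) NA_real_ else num / den
}

bf_local_efficiency <- function(w) {
  n <- nrow(w)
  ei <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    ei[i] <- bf_global_efficiency(w[nb, nb, drop = FALSE])
  }
  ei
}

bf_assortativity <- function(w) {
  s <- rowSums(w)
  x <- c()
  y <- c()
  n <- nrow(w)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (w[i, j] > 0) {
      x <- c(x, s[i], s[j])
      y <- c(y, s[j], s[i])
    }
  }
  if (length(x) == 0 || sd(x) == 0) return(NA_real_)
  cor(x, y)
}

bf_rich_club <- function(w, k) {
  deg <- rowSums(w > 0)
  keep <- which(deg > k)
  if (length(keep) < 2) return(NA_real_)
  e <- 0
  for (a in seq_along(keep)) for (b in seq_along(keep)) {
    if (a < b && w[keep[a], keep[b]] > 0) e <- e + 1
  }
  2 * e / (length(keep) * (length(keep) - 1))
}

# Random symmetric weighted graph in [0, 1] with zero diagonal.
random_weight_matrix <- function(n, p = 0.5, unit = FALSE) {
  w <- matrix(0, n, n)
  idx <- which(upper.tri(w))
  on <- idx[stats::runif(length(idx)) < p]
  w[on] <- if (unit) 1 else stats::runif(length(on), 0.05, 1)
  pmax(w, t(w))
}
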