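# Brute-force graph-metric oracles, independent of the package's
# compiled core: Floyd-Warshall distances, per-node triangle
# enumeration, adjacency-power shortest-path counting for betweenness.
# Deliberately O(N^3)-or-worse; meant for N <= 12.

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- sum(a[nb, nb]) / 2
    cc[v] <- 2 * tri / (k * (k - 1))
  }
  cc
}

oracle_global_efficiency <- function(a) {
  d <- oracle_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (nrow(a) * (nrow(a) - 1))
}

oracle_char_path <- function(a) {
  d <- oracle_distances(a)
  comp <- oracle_components(a)
  big <- which(comp == which.max(tabulate(comp)))
  if (length(big) < 2) return(NA_real_)
  db <- d[big, big]
  mean(db[upper.tri(db)])
}

oracle_components <- function(a) {
  n <- nrow(a)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    front <- s
    comp[s] <- cur
    while (length(front) > 0) {
      nxt <- unique(unlist(lapply(front, function(v) which(a[v, ] > 0))))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      front <- nxt
    }
  }
  comp
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  vals <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] > 0)
    if (length(nb) < 2) next
    vals[v] <- oracle_global_efficiency(a[nb, nb, drop = FALSE])
  }
  mean(vals)
}

oracle_nodal_efficiency <- function(a) {
  d <- oracle_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  rowSums(inv) / (nrow(a) - 1)
}

oracle_assortativity <- function(a) {
  ij <- which(a > 0 & upper.tri(a), arr.ind = TRUE)
  deg <- rowSums(a)
  # each undirected edge contributes both orientations
  x <- c(deg[ij[, 1]], deg[ij[, 2]])
  y <- c(deg[ij[, 2]], deg[ij[, 1]])
  suppressWarnings(stats::cor(x, y))
}

# Betweenness via minimal-length walk counting: the number of walks of
# length d(s,t) from s to t equals the number of shortest s-t paths, so
# sigma_st comes from powers of the adjacency matrix.
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  maxd <- max(d[is.finite(d)])
  pow <- vector("list", maxd + 1L)
  pow[[1L]] <- diag(n)  # A^0
  for (k in seq_len(maxd)) pow[[k + 1L]] <- pow[[k]] %*% a
  sigma <- function(s, t) {
    if (!is.finite(d[s, t])) return(0)
    pow[[d[s, t] + 1L]][s, t]
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t]) || d[s, t] == 0) next
      st <- sigma(s, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + sigma(s, v) * sigma(v, t) / st
        }
      }
    }
  }
  bc
}

graph_from_adj <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

adj_from_graph <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

random_adjacency <- function(n, p) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.numeric(stats::runif(length(up)) < p)
  a + t(a)
}
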