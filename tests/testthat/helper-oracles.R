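# Independent oracles and small random fixtures used across the suite.

# Exhaustive minimum-length simple path between s and t (branch-and-bound
# enumeration; independent of the package's Dijkstra).
enumerate_shortest <- function(adj, s, t) {
  n <- nrow(adj)
  best <- Inf
  rec <- function(u, visited, len) {
    if (u == t) {
      if (len < best) best <<- len
      return(invisible())
    }
    for (v in which(adj[u, ] > 0)) {
      if (!visited[v] && len + adj[u, v] < best) {
        visited[v] <- TRUE
        rec(v, visited, len + adj[u, v])
        visited[v] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  rec(s, visited, 0)
  best
}

# Random connected weighted structural matrix on n nodes.
random_sc <- function(n, p = 0.45, seed = 1, wmin = 10, wmax = 100) {
  set.seed(seed)
  repeat {
    m <- matrix(0, n, n)
    up <- which(upper.tri(m))
    on <- up[runif(length(up)) < p]
    m[on] <- runif(length(on), wmin, wmax)
    m <- m + t(m)
    # connectivity via matrix powers of the adjacency indicator
    a <- (m > 0) * 1
    reach <- diag(n)
    for (k in seq_len(n)) reach <- (reach %*% (a + diag(n)) > 0) * 1
    if (all(reach > 0)) return(m)
  }
}

# Random symmetric positive MI matrix (bits) with entropy-like diagonal.
random_fc_matrix <- function(n, seed = 1, lo = 0.05, hi = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  m[up] <- runif(length(up), lo, hi)
  m <- m + t(m)
  diag(m) <- 2
  m
}

# Product-form PBS oracle, straight from the definition.
pbs_product_oracle <- function(path, mi, sc_lengths) {
  n <- nrow(mi)
  w <- vapply(seq_len(n), function(i) {
    nb <- which(sc_lengths[i, ] > 0 & seq_len(n) != i)
    sum(mi[i, nb])
  }, 0)
  pr <- 1
  for (k in seq_len(length(path) - 1)) {
    pr <- pr * mi[path[k], path[k + 1]] / w[path[k]]
  }
  -log2(pr)
}

# PPS re-summation oracle: (m+1) * anchor - sum over post-source nodes.
pps_resum_oracle <- function(path, mi) {
  s <- path[1]
  rest <- path[-1]
  length(rest) * mi[s, rest[1]] - sum(mi[s, rest])
}

# Chain structural connectome of n nodes with given hop lengths (mm).
chain_sc <- function(n, hop_mm = 20) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- hop_mm
  structural_connectome(m, paste0("K", seq_len(n)))
}
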