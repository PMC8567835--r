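lex_less <- function(a, b) {
  # TRUE if integer sequence a precedes b lexicographically
  k <- min(length(a), length(b))
  if (k > 0) {
    d <- a[seq_len(k)] - b[seq_len(k)]
    nz <- which(d != 0)
    if (length(nz)) return(d[nz[1]] < 0)
  }
  length(a) < length(b)
}

path_better <- function(nd, nh, npath, dist, hops, path) {
  # composite order: total mm length, then hop count, then lexicographic
  # node-index sequence; all comparisons exact
  if (nd != dist) return(nd < dist)
  if (nh != hops) return(nh < hops)
  lex_less(npath, path)
}

dijkstra_from <- function(adj, source) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  hops <- rep(Inf, n)
  paths <- vector("list", n)
  dist[source] <- 0
  hops[source] <- 0
  paths[[source]] <- source
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    dmin <- min(dist[cand])
    cand <- cand[dist[cand] == dmin]
    if (length(cand) > 1) {
      cand <- cand[hops[cand] == min(hops[cand])]
      if (length(cand) > 1) {
        u <- cand[1]
        for (v in cand[-1]) if (lex_less(paths[[v]], paths[[u]])) u <- v
        cand <- u
      }
    }
    u <- cand[1]
    visited[u] <- TRUE
    for (v in which(adj[u, ] > 0)) {
      if (visited[v]) next
      nd <- dist[u] + adj[u, v]
      nh <- hops[u] + 1
      if (nd > dist[v]) next
      npath <- c(paths[[u]], v)
      if (path_better(nd, nh, npath, dist[v], hops[v], paths[[v]])) {
        dist[v] <- nd
        hops[v] <- nh
        paths[[v]] <- npath
      }
    }
  }
  list(dist = dist, hops = hops, paths = paths)
}

#' All-pairs shortest paths on the fiber-length structural connectome
#'
#' Computes, for every ordered pair of regions, the minimum-total-length
#' node sequence on the structural connectome, minimizing millimeter fiber
#' lengths directly (no inverse transform). Ties are broken
#' deterministically: among equal-length paths the one with fewer hops
#' wins, then the lexicographically smallest node-index sequence. Each
#' unordered pair is resolved once from its lower-index endpoint and the
#' opposite orientation is the exact reversal, so
#' `path(s, t) == rev(path(t, s))` always holds.
#'
#' @param sc A [structural_connectome()].
#' @return A tibble with one row per ordered pair (diagonal excluded):
#'   columns `source`, `target` (integer indices), `source_region`,
#'   `target_region`, `connected` (logical), `hops` (integer, `NA` when
#'   disconnected), `length_mm` (total path length, `NA` when
#'   disconnected), and `path` (list column of integer node-index
#'   sequences, `NULL` when disconnected). The region-id vector is attached
#'   as attribute `region_ids`.
#' @examples
#' sc <- toy_fixture()$sc
#' shortest_paths(sc)
#' @export
shortest_paths <- function(sc) {
  if (!inherits(sc, "structural_connectome")) {
    abort("`sc` must be a structural_connectome.")
  }
  adj <- sc$lengths
  n <- nrow(adj)
  if (n < 2) abort("need at least 2 regions.")
  dist <- matrix(NA_real_, n, n)
  hop <- matrix(NA_integer_, n, n)
  pth <- vector("list", n * n)
  dim(pth) <- c(n, n)
  for (s in seq_len(n - 1)) {
    res <- dijkstra_from(adj, s)
    for (t in (s + 1):n) {
      if (is.finite(res$dist[t])) {
        dist[s, t] <- dist[t, s] <- res$dist[t]
        hop[s, t] <- hop[t, s] <- as.integer(res$hops[t])
        pth[[s, t]] <- res$paths[[t]]
        pth[[t, s]] <- rev(res$paths[[t]])
      }
    }
  }
  idx <- which(row(dist) != col(dist), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  src <- idx[, 1]
  tgt <- idx[, 2]
  out <- tibble(
    source = as.integer(src),
    target = as.integer(tgt),
    source_region = sc$region_ids[src],
    target_region = sc$region_ids[tgt],
    connected = !is.na(dist[idx]),
    hops = hop[idx],
    length_mm = dist[idx],
    path = pth[idx]
  )
  attr(out, "region_ids") <- sc$region_ids
  out
}

resolve_region <- function(x, region_ids, what = "region") {
  if (is.character(x)) {
    i <- match(x, region_ids)
    if (is.na(i)) abort(sprintf("unknown %s: %s", what, x))
    return(i)
  }
  i <- as.integer(x)
  if (is.na(i) || i < 1 || i > length(region_ids)) {
    abort(sprintf("%s index out of range: %s", what, x))
  }
  i
}

get_path_row <- function(paths, s, t) {
  region_ids <- attr(paths, "region_ids")
  si <- resolve_region(s, region_ids, "source")
  ti <- resolve_region(t, region_ids, "target")
  row <- paths[paths$source == si & paths$target == ti, ]
  if (!nrow(row)) abort(sprintf("no path record for pair (%s, %s).", s, t))
  row
}

#' Extract a shortest-path node sequence, optionally dropping an endpoint
#'
#' Returns the node sequence of the geodesic between `s` and `t`: the full
#' sequence (source, intermediates, target), the sequence without the
#' source (used by the path processing score) or without the target (used
#' by the path broadcasting strength).
#'
#' @param paths Output of [shortest_paths()].
#' @param s,t Source and target, as region name or index.
#' @param variant One of `"full"`, `"drop_source"`, `"drop_target"`.
#' @param as Return `"index"` (integer) or `"region"` (character) ids.
#' @return Integer or character vector of nodes along the path.
#' @export
path_view <- function(paths, s, t,
                      variant = c("full", "drop_source", "drop_target"),
                      as = c("index", "region")) {
  variant <- match.arg(variant)
  as <- match.arg(as)
  row <- get_path_row(paths, s, t)
  if (!row$connected) {
    abort(sprintf("pair (%s, %s) is structurally disconnected.", s, t))
  }
  p <- row$path[[1]]
  p <- switch(variant,
    full = p,
    drop_source = p[-1],
    drop_target = p[-length(p)]
  )
  if (as == "region") attr(paths, "region_ids")[p] else p
}
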