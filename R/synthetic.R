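#' Analytic mutual information of a bivariate Gaussian
#'
#' For a correlation `rho`, `MI = -1/2 * log2(1 - rho^2)` bits. This is the
#' ground truth the synthetic Gaussian generator provides for testing MI
#' estimators.
#'
#' @param rho Correlation(s) in (-1, 1).
#' @return MI in bits.
#' @export
gaussian_mi <- function(rho) {
  if (any(abs(rho) >= 1)) abort("`rho` must lie strictly inside (-1, 1).")
  -0.5 * log2(1 - rho^2)
}

#' Exact mutual information of a binned bivariate Gaussian
#'
#' Computes the mutual information that remains after discretizing a
#' bivariate standard Gaussian with a [binning_scheme()] (outer bins
#' clipped to infinity, matching [discretize_timeseries()]). Cell
#' probabilities are obtained by one-dimensional numerical integration of
#' the conditional Gaussian, so this is an oracle independent of the
#' histogram estimator: it is the quantity [pairwise_mi()] converges to as
#' T grows. The gap between this value and [gaussian_mi()] is the
#' quantization bias of the binning, which no sample size removes.
#'
#' @param rho Correlation in (-1, 1).
#' @param scheme A [binning_scheme()].
#' @return MI of the discretized pair, in bits.
#' @export
binned_gaussian_mi <- function(rho, scheme = binning_scheme()) {
  if (abs(rho) >= 1) abort("`rho` must lie strictly inside (-1, 1).")
  b <- scheme$n_bins
  edges <- scheme$range[1] + scheme$bin_width * seq(0, b)
  edges[b + 1] <- min(edges[b + 1], scheme$range[2])
  lo <- edges[-(b + 1)]
  hi <- edges[-1]
  lo[1] <- -Inf
  hi[b] <- Inf
  if (rho == 0) {
    px <- stats::pnorm(hi) - stats::pnorm(lo)
    return(0 * sum(px))  # independent: exactly zero MI
  }
  sdc <- sqrt(1 - rho^2)
  p <- matrix(0, b, b)
  for (i in seq_len(b)) {
    for (j in seq_len(b)) {
      f <- function(x) {
        stats::dnorm(x) *
          (stats::pnorm((hi[j] - rho * x) / sdc) -
             stats::pnorm((lo[j] - rho * x) / sdc))
      }
      p[i, j] <- stats::integrate(f, lo[i], hi[i],
                                  rel.tol = 1e-10, abs.tol = 1e-12)$value
    }
  }
  p <- p / sum(p)
  px <- rowSums(p)
  py <- colSums(p)
  entropy_bits(px) + entropy_bits(py) - entropy_bits(as.vector(p))
}

components_of <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[u]) next
      comp[u] <- cur
      stack <- c(stack, which(adj[u, ] > 0 & comp == 0L))
    }
  }
  comp
}

#' Synthetic spatially embedded structural connectome
#'
#' Places `n_regions` nodes uniformly at random in a cubic box and connects
#' every pair within `radius`, with edge weight equal to the Euclidean
#' distance (interpreted as fiber length in millimeters). Euclidean weights
#' satisfy the triangle inequality, so structurally adjacent pairs are
#' their own geodesics, which makes hand verification easy; set
#' `length_noise_sd > 0` to add lognormal-style tortuosity noise to the
#' lengths and exercise multi-edge geodesics between adjacent nodes.
#'
#' Randomness uses base R's Mersenne-Twister via `set.seed(seed)`; the seed
#' fully determines the output. If the sampled graph is disconnected the
#' placement is retried (with a warning) up to `max_tries` times.
#'
#' @param n_regions Number of regions (>= 3).
#' @param radius Connection radius in mm (default 60).
#' @param box Side of the cubic box in mm (default 100).
#' @param dim Embedding dimension (default 3).
#' @param seed Integer seed.
#' @param length_noise_sd SD of multiplicative Gaussian noise on the log
#'   lengths (default 0, i.e. exact Euclidean distances).
#' @param max_tries Placement retries before giving up (default 20).
#' @return A [structural_connectome()]; node coordinates are attached as
#'   attribute `coords`.
#' @export
synth_structural <- function(n_regions, radius = 60, box = 100, dim = 3,
                             seed = 1, length_noise_sd = 0, max_tries = 20) {
  if (n_regions < 3) abort("need n_regions >= 3.")
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    coords <- matrix(stats::runif(n_regions * dim, 0, box), n_regions, dim)
    d <- as.matrix(stats::dist(coords))
    adj <- d
    adj[d > radius] <- 0
    diag(adj) <- 0
    if (length_noise_sd > 0) {
      noise <- matrix(exp(rnorm(n_regions^2, 0, length_noise_sd)),
                      n_regions, n_regions)
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      adj <- adj * noise
      diag(adj) <- 0
    }
    if (max(components_of(adj)) == 1L) {
      sc <- structural_connectome(adj, sprintf("R%03d", seq_len(n_regions)))
      attr(sc, "coords") <- coords
      return(sc)
    }
    warn(sprintf(
      "synthetic structural graph disconnected (try %d/%d); resampling placement.",
      try, max_tries
    ))
  }
  abort(paste(
    "could not generate a connected structural graph;",
    "increase `radius` or reduce `n_regions` relative to `box`."
  ))
}

#' Synthetic Gaussian regional time series with prescribed correlation
#'
#' Draws `n_timepoints` samples from a zero-mean multivariate Gaussian
#' with the given correlation matrix (Cholesky factorization; base R
#' Mersenne-Twister RNG under `set.seed(seed)`). Because pairwise MI of a
#' Gaussian is `-1/2 log2(1 - rho^2)`, the generated series carry an
#' analytically known MI ground truth.
#'
#' @param corr N x N positive-semidefinite correlation matrix.
#' @param n_timepoints Number of samples T.
#' @param seed Integer seed.
#' @param region_ids Optional region names (default `R001..`).
#' @return N x T numeric matrix with region-id rownames.
#' @export
synth_gaussian_timeseries <- function(corr, n_timepoints, seed = 1,
                                      region_ids = NULL) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (ncol(corr) != n || max(abs(corr - t(corr))) > 1e-9) {
    abort("`corr` must be a symmetric square matrix.")
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf(
      "`corr` is not positive semidefinite: smallest eigenvalue %.3g.",
      min(ev)
    ))
  }
  l <- chol(corr + diag(1e-10, n))
  set.seed(seed)
  z <- matrix(rnorm(n * n_timepoints), n, n_timepoints)
  x <- t(l) %*% z
  if (is.null(region_ids)) region_ids <- sprintf("R%03d", seq_len(n))
  rownames(x) <- region_ids
  x
}

#' Synthetic Gaussian Markov-chain time series (telephone-game relay)
#'
#' Builds an N-node first-order chain: node 1 is white Gaussian noise and
#' node j+1 = `hop_rho` * node j + sqrt(1 - hop_rho^2) * fresh noise, so
#' every node has unit variance and `corr(node 1, node j) = hop_rho^(j-1)`.
#' The chain is Markov, hence the data processing inequality holds:
#' MI(node 1; node j) is nonincreasing in j, which makes this the natural
#' fixture for relay-communication behavior (PPS of chain paths should not
#' be spuriously negative).
#'
#' @param n_nodes Chain length (>= 2).
#' @param hop_rho Per-hop correlation, |hop_rho| < 1.
#' @param n_timepoints Number of samples T.
#' @param seed Integer seed.
#' @return N x T matrix with rownames `K1..KN` (K1 is the source).
#' @export
synth_markov_chain <- function(n_nodes, hop_rho, n_timepoints, seed = 1) {
  if (n_nodes < 2) abort("need n_nodes >= 2.")
  if (abs(hop_rho) >= 1) abort("|hop_rho| must be < 1.")
  set.seed(seed)
  x <- matrix(0, n_nodes, n_timepoints)
  x[1, ] <- rnorm(n_timepoints)
  for (j in seq_len(n_nodes - 1)) {
    x[j + 1, ] <- hop_rho * x[j, ] +
      sqrt(1 - hop_rho^2) * rnorm(n_timepoints)
  }
  rownames(x) <- paste0("K", seq_len(n_nodes))
  x
}

#' Five-region toy fixture with a hand-computed answer sheet
#'
#' A fixed 5-region instance (regions A..E) small enough that every
#' quantity can be verified by hand. Structural edges (mm): A-B 10, B-C
#' 10, C-E 10, A-D 25, D-E 25, B-D 15. The MI matrix is given directly
#' (bits), with entropy 2 on the diagonal. The geodesic A->E is
#' (A, B, C, E), 30 mm. The answer sheet records, as exact arithmetic
#' from these constants: `pps_a_e = 0.9` bits
#' (= (0.8-0.8) + (0.8-0.5) + (0.8-0.2)); nodal strengths
#' `w = c(A=1.2, B=2.0, C=1.6, D=1.3, E=1.3)`;
#' `pbs_raw_a_e = -log2((0.8/1.2) * (0.9/2.0) * (0.7/1.6))` bits and
#' `pbs_a_e = pbs_raw_a_e / 30` bits/mm.
#'
#' @return List with `sc`, `fc`, `parcellation`, and `answers` (named list
#'   of the hand-computed values above, plus `path_a_e` and
#'   `length_a_e`).
#' @export
toy_fixture <- function() {
  ids <- c("A", "B", "C", "D", "E")
  sc <- matrix(0, 5, 5, dimnames = list(ids, ids))
  edges <- rbind(
    c(1, 2, 10), c(2, 3, 10), c(3, 5, 10),
    c(1, 4, 25), c(4, 5, 25), c(2, 4, 15)
  )
  sc[edges[, 1:2]] <- edges[, 3]
  sc[edges[, 2:1]] <- edges[, 3]
  mi <- matrix(0, 5, 5, dimnames = list(ids, ids))
  vals <- rbind(
    c(1, 2, 0.8), c(1, 3, 0.5), c(1, 4, 0.4), c(1, 5, 0.2),
    c(2, 3, 0.9), c(2, 4, 0.3), c(2, 5, 0.4),
    c(3, 4, 0.2), c(3, 5, 0.7), c(4, 5, 0.6)
  )
  mi[vals[, 1:2]] <- vals[, 3]
  mi[vals[, 2:1]] <- vals[, 3]
  diag(mi) <- 2
  parc <- tibble(
    region = ids,
    network = c("Default", "Default", "Default", "Visual", "Visual"),
    hemisphere = c("L", "L", "L", "R", "R")
  )
  answers <- list(
    path_a_e = c(1L, 2L, 3L, 5L),
    length_a_e = 30,
    pps_a_e = (0.8 - 0.8) + (0.8 - 0.5) + (0.8 - 0.2),
    w = c(A = 0.8 + 0.4, B = 0.8 + 0.9 + 0.3, C = 0.9 + 0.7,
          D = 0.4 + 0.3 + 0.6, E = 0.7 + 0.6),
    pbs_raw_a_e = -log2((0.8 / 1.2) * (0.9 / 2.0) * (0.7 / 1.6)),
    pbs_a_e = -log2((0.8 / 1.2) * (0.9 / 2.0) * (0.7 / 1.6)) / 30
  )
  list(
    sc = structural_connectome(sc, ids),
    fc = functional_connectome(mi, ids),
    parcellation = parc,
    answers = answers
  )
}
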