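test_that("2-edge chains reduce to MI(S,K1) - MI(S,T), both signs", {
  mi <- matrix(2, 3, 3)
  mi[1, 2] <- mi[2, 1] <- 0.8
  mi[1, 3] <- mi[3, 1] <- 0.3
  mi[2, 3] <- mi[3, 2] <- 0.5
  fc <- functional_connectome(mi, c("S", "X", "T"))
  expect_equal(compute_pps(c(1, 2, 3), fc), 0.5)

  mi[1, 3] <- mi[3, 1] <- 0.9  # MI(S,T) > MI(S,K1): negative score
  fc2 <- functional_connectome(mi, c("S", "X", "T"))
  expect_equal(compute_pps(c(1, 2, 3), fc2), 0.8 - 0.9)
  expect_lt(compute_pps(c(1, 2, 3), fc2), 0)
})

test_that("PPS equals the (m+1)*anchor re-summation oracle on longer chains", {
  for (s in 1:100) {
    mi <- random_fc_matrix(6, seed = 900 + s)
    fc <- functional_connectome(mi)
    path <- sample(6, sample(3:6, 1))
    expect_equal(compute_pps(path, fc), pps_resum_oracle(path, mi),
                 tolerance = 1e-12)
  }
})

test_that("PPS on every 2-edge geodesic matches the anchor-cancellation identity", {
  for (s in 1:20) {
    adj <- random_sc(7, seed = 700 + s)
    sc <- structural_connectome(adj)
    fc <- functional_connectome(random_fc_matrix(7, seed = 7000 + s))
    tab <- add_pps(shortest_paths(sc), fc)
    two <- tab[!is.na(tab$hops) & tab$hops == 2, ]
    for (k in seq_len(nrow(two))) {
      p <- two$path[[k]]
      expect_equal(two$pps[k], fc$mi[p[1], p[2]] - fc$mi[p[1], p[3]],
                   tolerance = 1e-12)
    }
  }
})

test_that("PPS is invariant to adding a constant to all MI(S, .) values", {
  mi <- random_fc_matrix(6, seed = 42)
  fc <- functional_connectome(mi)
  path <- c(2L, 4L, 1L, 6L)
  mi2 <- mi
  mi2[2, -2] <- mi2[2, -2] + 0.35
  mi2[-2, 2] <- mi2[-2, 2] + 0.35
  fc2 <- functional_connectome(mi2)
  expect_equal(compute_pps(path, fc2), compute_pps(path, fc),
               tolerance = 1e-12)
})

test_that("PPS is undefined on single-edge paths and nonsymmetric in general", {
  fx <- toy_fixture()
  expect_error(compute_pps(c(1, 2), fx$fc), "single-edge")
  tab <- add_pps(shortest_paths(fx$sc), fx$fc)
  m <- pps_matrix(tab, fx$fc)
  # undefined where direct / diagonal
  expect_true(is.na(m["A", "B"]))
  expect_true(is.na(m["A", "A"]))
  # A->E anchored at MI(A,B); E->A anchored at MI(E,C): different scores
  expect_false(isTRUE(all.equal(m["A", "E"], m["E", "A"])))
  # matrix agrees with per-pair calls
  for (k in which(!is.na(tab$pps))) {
    expect_identical(m[tab$source[k], tab$target[k]],
                     compute_pps(tab$path[[k]], fx$fc))
  }
})

test_that("telescoping mode collapses to anchor minus target MI", {
  mi <- random_fc_matrix(5, seed = 17)
  fc <- functional_connectome(mi)
  path <- c(1L, 3L, 4L, 5L)
  expect_equal(compute_pps(path, fc, mode = "telescoping"),
               mi[1, 3] - mi[1, 5], tolerance = 1e-14)
  # both readings coincide on 2-edge paths
  expect_equal(compute_pps(c(1, 3, 5), fc, mode = "telescoping"),
               compute_pps(c(1, 3, 5), fc))
})

make_pps_table <- function(vals) {
  tibble::tibble(
    source = 1L, target = 2L,
    source_region = "A", target_region = "B",
    connected = TRUE, hops = 2L, length_mm = 10,
    path = list(c(1L, 3L, 2L)), pps = vals
  )
}

dmn_parc <- tibble::tibble(region = c("A", "B"),
                           network = "Default", hemisphere = "L")

test_that("boundary estimation recovers order statistics of the reference distribution", {
  set.seed(99)
  tab <- make_pps_table(stats::runif(1e4))
  b <- estimate_boundaries(tab, dmn_parc)
  expect_equal(b$lower, 0.05, tolerance = 0.01)
  expect_equal(b$upper, 0.95, tolerance = 0.01)
})

test_that("boundary estimation rejects degenerate and undersized inputs", {
  expect_error(estimate_boundaries(make_pps_table(rep(0.3, 100)), dmn_parc),
               "degenerate")
  expect_error(estimate_boundaries(make_pps_table(stats::runif(10)), dmn_parc),
               "20")
  expect_error(estimate_boundaries(make_pps_table(stats::runif(50)), dmn_parc,
                                   network = "Limbic"),
               "not present")
})

test_that("default boundaries are the published relay interval", {
  b <- regime_boundaries()
  expect_identical(b$lower, -0.04)
  expect_identical(b$upper, 0.07)
  expect_error(regime_boundaries(1, 1), "lower < upper")
})

test_that("regimes follow the boundary rules, closed at the endpoints", {
  fx <- toy_fixture()
  tab <- add_pps(shortest_paths(fx$sc), fx$fc)
  probe <- function(v) {
    t2 <- tab
    t2$pps[!is.na(t2$pps)] <- v
    as.character(classify_regimes(t2)$regime[!is.na(t2$pps)][1])
  }
  expect_equal(probe(-0.10), "absent")
  expect_equal(probe(0.00), "relay")
  expect_equal(probe(0.50), "transducted")
  expect_equal(probe(-0.04), "relay")  # closed lower endpoint
  expect_equal(probe(0.07), "relay")   # closed upper endpoint
  cl <- classify_regimes(tab)
  expect_true(all(cl$regime[cl$hops == 1] == "direct", na.rm = TRUE))
})

test_that("regime labels partition all ordered pairs", {
  m <- matrix(0, 6, 6)
  m[1, 2] <- m[2, 1] <- 5
  m[2, 3] <- m[3, 2] <- 5
  m[4, 5] <- m[5, 4] <- 5  # {4,5} and isolated 6 exercise 'disconnected'
  sc <- structural_connectome(m)
  fc <- functional_connectome(random_fc_matrix(6, seed = 3))
  cl <- classify_regimes(add_pps(shortest_paths(sc), fc))
  n <- 6
  expect_equal(sum(table(cl$regime)) + n, n^2)
  expect_false(anyNA(cl$regime))
})

test_that("near-lossless Gaussian relay chains are not classified absent", {
  n_nodes <- 4
  sc <- chain_sc(n_nodes)
  frac <- vapply(1:20, function(s) {
    ts <- synth_markov_chain(n_nodes, hop_rho = 0.99, n_timepoints = 5000,
                             seed = 2000 + s)
    fc <- mi_connectome(ts)
    cl <- classify_regimes(add_pps(shortest_paths(sc), fc))
    multi <- cl$regime[cl$hops >= 2 & !is.na(cl$hops)]
    mean(multi %in% c("relay", "transducted"))
  }, 0)
  expect_gte(mean(frac), 0.9)
})
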