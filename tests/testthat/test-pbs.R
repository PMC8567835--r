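test_that("structural strength masks functionally coupled but unconnected pairs", {
  # node 1 has structural neighbors 2 and 3 (MI .5, .25); MI(1,4) = .99 has
  # no structural edge and must not contribute
  scm <- matrix(0, 4, 4)
  scm[1, 2] <- scm[2, 1] <- 10
  scm[1, 3] <- scm[3, 1] <- 10
  scm[2, 3] <- scm[3, 2] <- 10
  sc <- structural_connectome(scm)
  mi <- matrix(0.1, 4, 4)
  mi[1, 2] <- mi[2, 1] <- 0.5
  mi[1, 3] <- mi[3, 1] <- 0.25
  mi[1, 4] <- mi[4, 1] <- 0.99
  diag(mi) <- 2
  fc <- functional_connectome(mi)
  w <- structural_strength(fc, sc)
  expect_equal(w$strength[1], 0.75)
  expect_equal(w$strength[4], 0)  # structurally isolated node
  # W_i >= MI(i, j) for every structural neighbor j
  expect_true(all(w$strength[1] >= c(0.5, 0.25)))
})

test_that("with a complete structural graph the mask changes nothing", {
  mi <- random_fc_matrix(5, seed = 8)
  full <- matrix(30, 5, 5); diag(full) <- 0
  w <- structural_strength(functional_connectome(mi),
                           structural_connectome(full))
  expect_equal(w$strength, rowSums(mi) - diag(mi), ignore_attr = TRUE)
})

test_that("PBS arithmetic matches the printed product form on a 2-edge path", {
  # edge MIs {1.0, 0.5}, W_S = W_K1 = 2, |path| = 10 mm:
  # raw = -log2(0.5 * 0.25) = 3 bits, normalized 0.3 bits/mm
  mi <- matrix(0.4, 3, 3)
  mi[1, 2] <- mi[2, 1] <- 1.0
  mi[2, 3] <- mi[3, 2] <- 0.5
  diag(mi) <- 2
  fc <- functional_connectome(mi)
  v <- compute_pbs(c(1, 2, 3), fc, strengths = c(2, 2, 2), length_mm = 10)
  expect_equal(v[["raw"]], 3)
  expect_equal(v[["per_mm"]], 0.3)
})

test_that("a direct path whose edge MI exhausts the sender strength has zero PBS", {
  mi <- matrix(0, 2, 2)
  mi[1, 2] <- mi[2, 1] <- 0.7
  diag(mi) <- 2
  fc <- functional_connectome(mi)
  v <- compute_pbs(c(1, 2), fc, strengths = c(0.7, 0.7), length_mm = 12)
  expect_equal(v[["raw"]], 0)
})

test_that("raw PBS equals the independent product-form oracle on random fixtures", {
  for (s in 1:100) {
    adj <- random_sc(6, seed = 1500 + s)
    mi <- random_fc_matrix(6, seed = 2500 + s)
    sc <- structural_connectome(adj)
    fc <- functional_connectome(mi)
    paths <- shortest_paths(sc)
    k <- sample(which(paths$connected), 1)
    p <- paths$path[[k]]
    v <- compute_pbs(p, fc, sc)
    expect_equal(v[["raw"]], pbs_product_oracle(p, mi, adj),
                 tolerance = 1e-10)
  }
})

test_that("raw PBS is nonnegative and additive over hops", {
  adj <- random_sc(7, seed = 61)
  mi <- random_fc_matrix(7, seed = 62)
  sc <- structural_connectome(adj)
  fc <- functional_connectome(mi)
  w <- structural_strength(fc, sc)$strength
  tab <- add_pbs(shortest_paths(sc), fc, sc)
  expect_true(all(tab$pbs_raw[tab$connected] >= 0))
  for (k in which(tab$hops >= 2)) {
    p <- tab$path[[k]]
    hops_sum <- sum(vapply(seq_len(length(p) - 1), function(i) {
      compute_pbs(p[i:(i + 1)], fc, strengths = w, length_mm = 1)[["raw"]]
    }, 0))
    expect_equal(tab$pbs_raw[k], hops_sum, tolerance = 1e-10)
  }
})

test_that("scaling the structural lengths rescales only the normalized PBS", {
  adj <- random_sc(6, seed = 71)
  mi <- random_fc_matrix(6, seed = 72)
  fc <- functional_connectome(mi)
  t1 <- add_pbs(shortest_paths(structural_connectome(adj)), fc,
                structural_connectome(adj))
  t2 <- add_pbs(shortest_paths(structural_connectome(2 * adj)), fc,
                structural_connectome(2 * adj))
  expect_equal(t2$pbs_raw, t1$pbs_raw, tolerance = 1e-12)
  expect_equal(t2$pbs, t1$pbs / 2, tolerance = 1e-12)
})

test_that("the classical incoming-edge-exclusion variant shrinks the denominator", {
  fx <- toy_fixture()
  p <- c(1L, 2L, 3L, 5L)
  v_default <- compute_pbs(p, fx$fc, fx$sc)
  v_classic <- compute_pbs(p, fx$fc, fx$sc, exclude_incoming = TRUE)
  # smaller denominators at intermediate nodes => larger ratios => lower PBS
  expect_lt(v_classic[["raw"]], v_default[["raw"]])
  # manual evaluation of the classical form
  w <- fx$answers$w
  manual <- -log2((0.8 / w["A"]) * (0.9 / (w["B"] - 0.8)) *
                    (0.7 / (w["C"] - 0.9)))
  expect_equal(v_classic[["raw"]], unname(manual), tolerance = 1e-12)
})

test_that("zero-MI path edges yield an infinite-PBS marker and a warning", {
  scm <- matrix(0, 3, 3)
  scm[1, 2] <- scm[2, 1] <- 10
  scm[2, 3] <- scm[3, 2] <- 10
  sc <- structural_connectome(scm)
  mi <- matrix(0, 3, 3)
  mi[2, 3] <- mi[3, 2] <- 0.5
  diag(mi) <- 2
  fc <- functional_connectome(mi)
  expect_warning(tab <- add_pbs(shortest_paths(sc), fc, sc), "zero-MI")
  expect_true(is.infinite(tab$pbs_raw[tab$source == 1 & tab$target == 2]))
  cl <- classify_regimes(add_pps(shortest_paths(sc), fc))
  cl <- suppressWarnings(add_pbs(cl, fc, sc))
  bs <- broadcast_strengths(cl, "direct")
  expect_true(all(is.finite(bs$wbs)))
  expect_gt(attr(bs, "n_excluded"), 0)
})

test_that("nodal broadcasting strengths are masked row/column sums with exact symmetric average", {
  adj <- random_sc(7, seed = 81)
  mi <- random_fc_matrix(7, seed = 82)
  sc <- structural_connectome(adj)
  fc <- functional_connectome(mi)
  scored <- add_pbs(classify_regimes(add_pps(shortest_paths(sc), fc)), fc, sc)
  pm <- pbs_matrix(scored)
  for (r in c("direct", "relay", "transducted")) {
    bs <- broadcast_strengths(scored, r)
    mask <- matrix(FALSE, 7, 7)
    sel <- !is.na(scored$regime) & scored$regime == r & is.finite(scored$pbs)
    mask[cbind(scored$source[sel], scored$target[sel])] <- TRUE
    pm0 <- ifelse(mask, pm, 0)
    expect_equal(bs$wbs_sender, rowSums(pm0), ignore_attr = TRUE)
    expect_equal(bs$wbs_receiver, colSums(pm0), ignore_attr = TRUE)
    expect_identical(bs$wbs, (bs$wbs_sender + bs$wbs_receiver) / 2)
  }
  expect_error(broadcast_strengths(scored, "absent"), "arg")
})

test_that("a single scored pair contributes only to its endpoints", {
  tab <- tibble::tibble(
    source = 1L, target = 3L, source_region = "a", target_region = "c",
    connected = TRUE, hops = 1L, length_mm = 10, path = list(c(1L, 3L)),
    pps = NA_real_,
    regime = factor("direct",
                    levels = c("direct", "absent", "relay", "transducted",
                               "disconnected")),
    pbs_raw = 4, pbs = 0.4
  )
  attr(tab, "region_ids") <- c("a", "b", "c")
  bs <- broadcast_strengths(tab, "direct")
  expect_equal(bs$wbs_sender, c(0.4, 0, 0))
  expect_equal(bs$wbs_receiver, c(0, 0, 0.4))
})

test_that("top_regions ranks by symmetric WBS with index tie-breaks", {
  bs <- tibble::tibble(
    region_index = 1:4, region = letters[1:4],
    wbs_sender = c(1, 3, 1, 3), wbs_receiver = c(1, 3, 1, 3),
    wbs = c(1, 3, 1, 3), regime = "relay"
  )
  class(bs) <- c("broadcast_strengths", class(bs))
  top <- top_regions(bs, 3)
  expect_equal(top$region, c("b", "d", "a"))
  all_eq <- bs; all_eq$wbs <- 1
  expect_equal(top_regions(all_eq, 2)$region, c("a", "b"))
  expect_error(top_regions(bs, 9), "exceeds")
})

test_that("a planted star hub with unspecific routing ranks first", {
  # hub 1 connects to 5 leaves with equal edge MI: every edge leaving the
  # hub carries only 1/5 of its strength (high broadcasting), while each
  # leaf's single edge carries all of its strength (raw PBS 0)
  n <- 6
  scm <- matrix(0, n, n)
  scm[1, 2:n] <- scm[2:n, 1] <- 10
  mi <- matrix(0.1, n, n)
  mi[1, ] <- mi[, 1] <- 0.5
  diag(mi) <- 2
  sc <- structural_connectome(scm)
  fc <- functional_connectome(mi)
  scored <- add_pbs(classify_regimes(add_pps(shortest_paths(sc), fc)), fc, sc)
  bs <- broadcast_strengths(scored, "direct")
  expect_equal(top_regions(bs, 1)$region_index, 1L)
  expect_true(all(bs$wbs[1] > bs$wbs[-1]))
})
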