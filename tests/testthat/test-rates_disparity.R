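# single-regime map with all branch time in one state
single_regime_map <- function(tree, state = "S") {
  tr <- ape::reorder.phylo(tree, "postorder")
  segs <- lapply(tr$edge.length, function(t_b)
    data.frame(state = state, duration = t_b))
  structure(list(tree = tr, segments = segs,
                 tip_states = setNames(rep(state, ape::Ntip(tr)), tr$tip.label),
                 node_states = rep(state, ape::Ntip(tr) + tr$Nnode),
                 states = state, map_id = "single", seed = NULL),
            class = "regime_map")
}

test_that("single-regime univariate rate equals the GLS ML estimator", {
  tr <- fixture_tree(24, seed = 121)
  y <- simulate_bm_on_tree(tr, diag(2.5, 1), seed = 122)
  rr <- regime_bm_rates(y, single_regime_map(tr))
  # oracle: sigma2 = (y - mu)' C^-1 (y - mu) / n with the GLS mean
  C <- ape::vcv(tr)
  Ci <- solve(C)
  yv <- y[rownames(C), 1]
  mu <- sum(Ci %*% yv) / sum(Ci)
  s2 <- as.numeric(t(yv - mu) %*% Ci %*% (yv - mu)) / length(yv)
  expect_equal(unname(rr$mean[["S"]]), s2, tolerance = 1e-6)
})

test_that("star phylogeny reduces to cross-species variance over tip depth", {
  n <- 20
  star <- ape::stree(n, "star")
  star$edge.length <- rep(2, n)
  star$tip.label <- sprintf("sp%03d", 1:n)
  set.seed(123)
  Y <- matrix(rnorm(n * 3), n, 3, dimnames = list(star$tip.label, NULL))
  rr <- regime_bm_rates(Y, single_regime_map(star))
  expected <- mean(apply(Y, 2, function(v) sum((v - mean(v))^2) / n)) / 2
  expect_equal(unname(rr$mean[["S"]]), expected, tolerance = 1e-8)
})

test_that("two-regime scalar ratio and scale equivariance hold", {
  set.seed(125)
  ratios <- vapply(1:6, function(i) {
    spec <- simulation_spec(n_species = 48, n_specimens = 48,
                            regime_states = c("A", "B"),
                            regime_scalars = c(A = 1, B = 4), regime_q = 1)
    sim <- simulate_study(spec, seed = 130 + i)
    rr <- regime_bm_rates(sim$truth$species_shapes, sim$truth$regime_map)
    rr$mean[["B"]] / rr$mean[["A"]]
  }, 0)
  expect_gt(mean(ratios), 2.5)
  expect_lt(mean(ratios), 6)
  # scaling traits by c multiplies every rate by c^2
  spec <- simulation_spec(n_species = 16, n_specimens = 16,
                          regime_states = c("A", "B"),
                          regime_scalars = c(A = 1, B = 4))
  sim <- simulate_study(spec, seed = 137)
  r1 <- regime_bm_rates(sim$truth$species_shapes, sim$truth$regime_map)
  r2 <- regime_bm_rates(sim$truth$species_shapes * 3, sim$truth$regime_map)
  expect_equal(unname(r2$mean), unname(r1$mean) * 9, tolerance = 1e-5)
})

test_that("fold changes reproduce simple ratios and guard the degenerate case", {
  expect_equal(rate_fold_changes(c(a = 2, b = 2))$fold_change, 1)
  expect_error(rate_fold_changes(c(a = 1)), "at least 2")
  expect_error(rate_fold_changes(c(a = 1, b = 0)), "zero rate")
  fc <- rate_fold_changes(c(x = 6e-7, y = 3e-7, z = 2e-7))
  expect_equal(fc$fold_change[fc$reference == "y"], 2)
  expect_equal(fc$fold_change[fc$reference == "z"], 3)
})

test_that("per-landmark rates decompose the scalar rate and flag planted signal", {
  sch <- landmark_scheme(4L)
  tr <- fixture_tree(32, seed = 141)
  # landmark 2 (coordinates 4:6) evolves 10x faster
  rates_true <- rep(1, 12); rates_true[4:6] <- 10
  hits <- 0
  for (i in 1:20) {
    Y <- simulate_bm_on_tree(tr, diag(rates_true), seed = 150 + i)
    rr <- regime_bm_rates(Y, single_regime_map(tr))
    plr <- per_landmark_rates(rr, sch)
    # decomposition identity: per-landmark rates sum to 3p x scalar rate
    expect_equal(sum(plr[, "S"]), 12 * unname(rr$mean[["S"]]), tolerance = 1e-6)
    hits <- hits + (which.max(plr[, "S"]) == 2)
  }
  expect_gte(hits / 20, 0.9)
  # isotropic simulation: per-landmark rates are exchangeable
  Yi <- simulate_bm_on_tree(tr, diag(1, 12), seed = 177)
  pli <- per_landmark_rates(regime_bm_rates(Yi, single_regime_map(tr)), sch)
  expect_lt(max(pli) / min(pli), 6) # no systematic ordering at n = 32
})

test_that("group disparity equals the direct mean-squared-deviation formula", {
  set.seed(161)
  Y <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(paste0("s", 1:30), NULL))
  g <- setNames(rep(c("a", "b", "c"), each = 10), rownames(Y))
  gd <- group_disparity(Y, g, n_boot = 30, seed = 1)
  for (grp in c("a", "b", "c")) {
    M <- Y[g == grp, ]
    oracle <- mean(rowSums(sweep(M, 2, colMeans(M))^2))
    expect_equal(unname(gd$pv[[grp]]), oracle, tolerance = 1e-10)
  }
  # identical shapes: zero disparity; singletons excluded from tests
  Y2 <- rbind(Y, s31 = Y[1, ], s32 = Y[1, ], s33 = Y[1, ], lone = rnorm(8))
  g2 <- c(g, s31 = "d", s32 = "d", s33 = "d", lone = "e")
  expect_warning(gd2 <- group_disparity(Y2, g2, n_boot = 30, seed = 2),
                 "single member")
  expect_equal(unname(gd2$pv[["d"]]), 0)
  expect_equal(unname(gd2$pv[["e"]]), 0)
  expect_true(all(is.na(gd2$pairwise_p[, "e"])))
  # adjusted p-values never fall below raw ones
  ok <- gd$pairwise_p >= gd$pairwise_p_raw - 1e-12
  expect_true(all(ok[!is.na(ok)]))
  # rotation invariance of the metric
  Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  gd3 <- group_disparity(Y %*% Q, g, n_boot = 5, seed = 3)
  expect_equal(gd3$pv, gd$pv, tolerance = 1e-10)
})

test_that("bootstrap disparity distribution is centred near the point estimate", {
  set.seed(163)
  Y <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(paste0("s", 1:40), NULL))
  g <- setNames(rep("one", 40), rownames(Y))
  gd <- group_disparity(Y, g, n_boot = 4000, seed = 9)
  # resampling n of n with replacement biases PV by about (n-1)/n
  expect_equal(mean(gd$boot[, "one"]), gd$pv[["one"]] * 39 / 40,
               tolerance = 0.02)
})

test_that("DTT is normalised, calibrated under BM, and detects early bursts", {
  tr <- fixture_tree(24, seed = 171)
  Y <- simulate_bm_on_tree(tr, diag(1, 8), seed = 172)
  d <- dtt(Y, tr, n_sim = 100, seed = 3)
  expect_equal(d$observed[1], 1, tolerance = 1e-9)
  expect_error(dtt(Y[1:3, ], ape::rtree(3)), "4 tips|ultrametric")
  nontree <- ape::rtree(10)
  expect_error(dtt(simulate_bm_on_tree(ape::compute.brlen(nontree), diag(1, 2)),
                   nontree), "ultrametric")
  # calibration: BM data inside the envelope at >= 90% of grid points
  inside_ok <- 0
  eb_low <- 0
  for (i in 1:15) {
    tri <- fixture_tree(24, seed = 180 + i)
    Yb <- simulate_bm_on_tree(tri, diag(1, 8), seed = 300 + i)
    db <- dtt(Yb, tri, n_sim = 60, seed = i)
    inside_ok <- inside_ok + (mean(db$observed >= db$lo & db$observed <= db$hi) >= 0.9)
    Ye <- simulate_bm_on_tree(tri, diag(1, 8), model = "EB", eb_rate = -4,
                              seed = 400 + i)
    de <- dtt(Ye, tri, n_sim = 60, seed = i)
    late <- de$time > 0.5
    eb_low <- eb_low + (mean(de$observed[late] < de$sim_mean[late]) > 0.5)
  }
  expect_gte(inside_ok / 15, 0.75)
  expect_gte(eb_low / 15, 0.8)
})
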