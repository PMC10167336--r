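test_that("pruning likelihood matches closed form on a two-tip tree", {
  t2 <- ape::read.tree(text = "(a:0.7,b:1.3);")
  q <- 0.4
  Q <- build_Q(q, c("A", "B"), "ER")
  ll <- mk_loglik(t2, c(a = "A", b = "A"), Q, root_prior = "equal")
  # closed form: sum over the root state of P(root)(P_t1[r,A] P_t2[r,A])
  P1 <- as.matrix(Matrix::expm(Q * 0.7)); P2 <- as.matrix(Matrix::expm(Q * 1.3))
  hand <- log(0.5 * (P1["A", "A"] * P2["A", "A"] + P1["B", "A"] * P2["B", "A"]))
  expect_equal(ll, hand, tolerance = 1e-10)
  # q -> 0 with identical tips: logLik -> log(prior of that state)
  Q0 <- build_Q(1e-10, c("A", "B"), "ER")
  expect_equal(mk_loglik(t2, c(a = "A", b = "A"), Q0, "equal"), log(0.5),
               tolerance = 1e-6)
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(101)
  states <- c("A", "B", "C")
  for (rep in 1:5) {
    ntip <- sample(3:6, 1)
    tr <- ape::rtree(ntip)
    tr$tip.label <- letters[seq_len(ntip)]
    rates <- runif(6, 0.1, 1.5)
    Q <- build_Q(rates, states, "ARD")
    tips <- setNames(sample(states, ntip, TRUE), tr$tip.label)
    if (length(unique(tips)) < 2) tips[1] <- setdiff(states, tips)[1]
    expect_equal(mk_loglik(tr, tips, Q, "equal"),
                 mk_brute(tr, tips, Q, "equal"), tolerance = 1e-8)
  }
})

test_that("Mk model fitting recovers ER and respects AIC accounting", {
  set.seed(103)
  tr <- fixture_tree(80, seed = 103)
  tr$edge.length <- tr$edge.length * 3
  wins <- 0
  for (i in 1:8) {
    map <- morphoclade:::sim_regimes(tr, c("A", "B"), 0.5)
    tips <- map$tip_states
    if (length(unique(tips)) < 2) next
    fer <- fit_mk(tr, tips, "ER")
    fard <- fit_mk(tr, tips, "ARD")
    wins <- wins + (fer$AIC <= fard$AIC)
    # the optimum is at least as good as the generating parameters
    expect_gte(fer$logLik + 1e-8,
               mk_loglik(tr, tips, build_Q(0.5, fer$states, "ER")))
  }
  expect_gt(wins / 8, 0.5)
  # AIC bookkeeping: ER 1 free rate, SYM s(s-1)/2, ARD s(s-1)
  f <- fit_mk(fixture_tree(12, seed = 1),
              setNames(rep(c("A", "B"), 6), sprintf("sp%03d", 1:12)), "ER")
  expect_equal(f$AIC, 2 * 1 - 2 * f$logLik)
})

test_that("Mk fit matches phytools on a fixed dataset", {
  skip_if_not_installed("phytools")
  tr <- fixture_tree(40, seed = 105)
  set.seed(105)
  map <- morphoclade:::sim_regimes(tr, c("A", "B"), 1.2)
  tips <- map$tip_states
  ours <- fit_mk(tr, tips, "ER", root_prior = "equal")
  theirs <- phytools::fitMk(tr, tips, model = "ER", pi = "equal")
  expect_equal(ours$logLik, as.numeric(stats::logLik(theirs)), tolerance = 1e-3)
  expect_equal(ours$rates[[1]], theirs$rates[[1]], tolerance = 0.02)
})

test_that("marginal ancestral states obey limits and symmetry", {
  tr <- fixture_tree(8, seed = 107)
  states <- c("A", "B")
  tipsA <- setNames(rep("A", 8), tr$tip.label)
  Q0 <- build_Q(1e-9, states, "ER")
  m0 <- marginal_ancestral_states(tr, tipsA, Q0)
  expect_true(all(m0[, "A"] > 1 - 1e-6))
  expect_equal(unname(rowSums(m0)), rep(1, nrow(m0)))
  # symmetric tree + mirrored tip data: root exactly (0.5, 0.5)
  ts <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  Q <- build_Q(0.3, states, "ER")
  ms <- marginal_ancestral_states(ts, c(a = "A", b = "A", c = "B", d = "B"), Q,
                                  root_prior = "equal")
  expect_equal(unname(ms["5", ]), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("marginal probabilities agree with stochastic-map frequencies", {
  tr <- fixture_tree(10, seed = 109)
  tr$edge.length <- tr$edge.length * 2
  set.seed(109)
  map_true <- morphoclade:::sim_regimes(tr, c("A", "B"), 0.8)
  tips <- map_true$tip_states
  Q <- build_Q(0.8, c("A", "B"), "ER")
  marg <- marginal_ancestral_states(tr, tips, Q, root_prior = "equal")
  maps <- simmap(tr, tips, Q, n_maps = 1500, seed = 11, root_prior = "equal")
  # empirical node-state frequencies across maps
  node_ids <- as.integer(rownames(marg))
  freq <- matrix(0, length(node_ids), 2, dimnames = dimnames(marg))
  for (mp in maps) {
    st <- mp$node_states[node_ids]
    freq[, "A"] <- freq[, "A"] + (st == "A")
  }
  freq[, "A"] <- freq[, "A"] / length(maps)
  freq[, "B"] <- 1 - freq[, "A"]
  mc_se <- sqrt(marg * (1 - marg) / length(maps)) + 1e-4
  expect_true(all(abs(freq - marg) < 4 * mc_se))
})

test_that("stochastic maps satisfy their structural invariants", {
  tr <- fixture_tree(12, seed = 111)
  set.seed(111)
  map_true <- morphoclade:::sim_regimes(tr, c("A", "B", "C"), 1)
  tips <- map_true$tip_states
  Q <- fit_mk(tr, tips, "ER")$Q
  maps <- simmap(tr, tips, Q, n_maps = 20, seed = 5)
  for (mp in maps) {
    et <- vapply(mp$segments, function(s) sum(s$duration), 0)
    expect_equal(et, mp$tree$edge.length, tolerance = 1e-9)
    expect_equal(mp$tip_states[names(tips)], tips)
    for (s in mp$segments)
      if (nrow(s) > 1) expect_true(all(s$state[-1] != s$state[-nrow(s)]))
  }
  # determinism: same seed, same maps
  maps2 <- simmap(tr, tips, Q, n_maps = 20, seed = 5)
  expect_identical(maps, maps2)
  # q -> 0 with a uniform tip state: no changes anywhere
  Q0 <- build_Q(1e-9, c("A", "B"), "ER")
  m0 <- simmap(tr, setNames(rep("A", 12), tr$tip.label), Q0, n_maps = 3, seed = 2)
  expect_true(all(vapply(m0[[1]]$segments, nrow, 0L) == 1L))
})

test_that("substitution counts on a free branch match the Poisson expectation", {
  # two states, rate q: expected changes over time t with free endpoints ~ q t
  q <- 0.7; t_b <- 2
  tr <- ape::read.tree(text = sprintf("(a:%f,b:0.0001);", t_b))
  Q <- build_Q(q, c("A", "B"), "ER")
  set.seed(113)
  nch <- vapply(1:2500, function(i) {
    # tip states drawn from the forward process, histories resampled by the
    # conditional bridge: unconditionally, changes are Poisson(q t)
    truth <- morphoclade:::sim_regimes(tr, c("A", "B"), q)
    mp <- simmap(tr, truth$tip_states, Q, n_maps = 1, seed = i,
                 root_prior = "equal")[[1]]
    k <- which(mp$tree$edge.length > 1)
    nrow(mp$segments[[k]]) - 1
  }, 0)
  expect_equal(mean(nch), q * t_b, tolerance = 0.1)
})

test_that("AIC ranking is invariant to state relabelling", {
  tr <- fixture_tree(40, seed = 115)
  set.seed(115)
  map_true <- morphoclade:::sim_regimes(tr, c("A", "B"), 1)
  tips <- map_true$tip_states
  relab <- c(A = "Z", B = "Y")[tips]
  names(relab) <- names(tips)
  for (st in c("ER", "ARD")) {
    f1 <- fit_mk(tr, tips, st)
    f2 <- fit_mk(tr, relab, st)
    expect_equal(f1$AIC, f2$AIC, tolerance = 1e-4)
  }
})

test_that("regime maps round-trip losslessly through JSON", {
  tr <- fixture_tree(8, seed = 117)
  set.seed(117)
  map_true <- morphoclade:::sim_regimes(tr, c("A", "B"), 1)
  Q <- build_Q(1, c("A", "B"), "ER")
  maps <- simmap(tr, map_true$tip_states, Q, n_maps = 3, seed = 4)
  f <- tempfile(fileext = ".json")
  write_regime_maps(maps, f)
  back <- read_regime_maps(f)
  for (i in seq_along(maps)) {
    expect_equal(back[[i]]$tip_states, maps[[i]]$tip_states)
    expect_equal(back[[i]]$states, maps[[i]]$states)
    for (k in seq_along(maps[[i]]$segments))
      expect_equal(back[[i]]$segments[[k]], maps[[i]]$segments[[k]],
                   tolerance = 1e-12)
    # edge regime times reproduce exactly
    expect_equal(regime_edge_times(back[[i]]), regime_edge_times(maps[[i]]),
                 tolerance = 1e-12)
  }
})
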