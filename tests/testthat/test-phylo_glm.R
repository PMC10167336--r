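test_that("mvgls with lambda = 0 and vanishing penalty matches OLS", {
  set.seed(41)
  n <- 60; p <- 4
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- sprintf("sp%03d", 1:n)
  X <- cbind(1, rnorm(n))
  rownames(X) <- star$tip.label
  B_true <- matrix(c(1, -2, 0.5, 3, 0, 1, 2, -1), 2, 4)
  Y <- X %*% B_true + matrix(rnorm(n * p, sd = 0.3), n, p)
  rownames(Y) <- star$tip.label
  fit <- mvgls_fit(Y, X, star, model = "BM", penalty_grid = 1e-8)
  B_ols <- solve(crossprod(X), crossprod(X, Y)) # normal-equations oracle
  expect_equal(unname(fit$B), unname(B_ols), tolerance = 1e-6)
})

test_that("mvgls recovers coefficients and lambda near 1 under BM", {
  tr <- fixture_tree(64, seed = 43)
  set.seed(43)
  X <- cbind(1, rnorm(64))
  rownames(X) <- tr$tip.label
  B_true <- matrix(c(0, 2, 1, -1, 0.5, 0), 2, 3)
  E <- simulate_bm_on_tree(tr, diag(0.5, 3), seed = 44)
  Y <- X %*% B_true + E[rownames(X), ]
  fit <- mvgls_fit(Y, X, tr, model = "lambda")
  expect_gt(fit$par, 0.8) # lambda-hat near 1
  expect_equal(unname(fit$B[2, ]), unname(B_true[2, ]), tolerance = 0.35)
  # degenerate response path warns but returns
  Yc <- matrix(1, 64, 3, dimnames = list(tr$tip.label, NULL))
  expect_warning(mvgls_fit(Yc, NULL, tr, model = "BM"), "identical across species")
})

test_that("GIC model selection recovers the generating trait model", {
  # EB-simulated data select EB in the majority of replicates
  eb_wins <- 0; bm_ok <- 0
  for (i in 1:20) {
    tr <- fixture_tree(64, seed = 50 + i)
    Yeb <- simulate_bm_on_tree(tr, diag(1, 4), model = "EB", eb_rate = -2,
                               seed = 900 + i)
    sel <- model_selection_gic(Yeb, tr)
    eb_wins <- eb_wins + (names(sel)[1] == "EB")
    Ybm <- simulate_bm_on_tree(tr, diag(1, 4), seed = 950 + i)
    selb <- model_selection_gic(Ybm, tr, models = c("BM", "EB"))
    tab <- attr(selb, "table")
    r_hat <- tab$par[tab$model == "EB"]
    bm_ok <- bm_ok + (abs(r_hat) < 0.5 &&
                        tab$GIC[tab$model == "BM"] <= tab$GIC[tab$model == "EB"] + 1e-6)
  }
  expect_gt(eb_wins / 20, 0.5)
  expect_gt(bm_ok / 20, 0.5) # EB nests BM: r-hat ~ 0 and BM typically wins on GIC
})

test_that("model ranking is invariant to global branch-length rescaling", {
  tr <- fixture_tree(32, seed = 61)
  Y <- simulate_bm_on_tree(tr, diag(1, 3), seed = 62)
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 10
  r1 <- attr(model_selection_gic(Y, tr), "table")$model
  r2 <- attr(model_selection_gic(Y, tr2), "table")$model
  expect_equal(r1, r2)
})

test_that("pMANOVA matches classical Wilks on a star tree", {
  set.seed(71)
  n <- 40; p <- 3
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- sprintf("sp%03d", 1:n)
  g <- factor(rep(c("x", "y"), each = n / 2))
  Y <- matrix(rnorm(n * p), n, p)
  Y[g == "y", ] <- Y[g == "y", ] + 1.5 # planted mean shift
  rownames(Y) <- star$tip.label
  dat <- data.frame(g = g, row.names = star$tip.label)
  tab <- manova_type2(Y, dat, "g", star, model = "BM", n_perm = 199, seed = 1)
  # closed-form Wilks via the classical MANOVA decomposition
  fitm <- stats::manova(Y ~ g)
  lam_cls <- summary(fitm, test = "Wilks")$stats["g", "Wilks"]
  expect_equal(tab$Wilks[1], unname(lam_cls), tolerance = 1e-6)
  expect_lt(tab$p_perm[1], 0.01)
})

test_that("pMANOVA permutation p-values are uniform under the null", {
  tr <- fixture_tree(24, seed = 73)
  set.seed(73)
  ps <- vapply(1:200, function(i) {
    Y <- simulate_bm_on_tree(tr, diag(1, 3), seed = 2000 + i)
    g <- factor(sample(rep(c("u", "v"), each = 12)))
    dat <- data.frame(g = g, row.names = tr$tip.label)
    manova_type2(Y, dat, "g", tr, model = "BM", n_perm = 49,
                 seed = i)$p_perm[1]
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("type-II tables do not depend on term order", {
  tr <- fixture_tree(32, seed = 75)
  set.seed(75)
  Y <- simulate_bm_on_tree(tr, diag(1, 3), seed = 76)
  dat <- data.frame(g = factor(sample(c("a", "b"), 32, TRUE)),
                    cs = rnorm(32), row.names = tr$tip.label)
  t1 <- manova_type2(Y, dat, c("cs", "g"), tr, model = "BM", n_perm = 49, seed = 3)
  t2 <- manova_type2(Y, dat, c("g", "cs"), tr, model = "BM", n_perm = 49, seed = 3)
  expect_equal(t1[match(t2$term, t1$term), "Wilks"], t2$Wilks, tolerance = 1e-10)
})

test_that("ancestral states match closed forms and the GLS matrix oracle", {
  # two tips, equal branches: root is the midpoint
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(unname(ancestral_states_continuous(c(a = 0, b = 4), t2)[1, ]), 2)
  # branches 1 and 3: weights proportional to 1/branch, so the closer tip
  # dominates: (0*1 + 4/3) / (4/3) = 1
  t3 <- ape::read.tree(text = "(a:1,b:3);")
  expect_equal(unname(ancestral_states_continuous(c(a = 0, b = 4), t3)[1, ]), 1)
  # 16-tip tree equals the explicit GLS construction from the tree covariance
  tr <- fixture_tree(16, seed = 77)
  y <- simulate_bm_on_tree(tr, diag(1, 2), seed = 78)
  anc <- ancestral_states_continuous(y, tr)
  # oracle: ML ancestral state at node v = Cov(v, tips) C^-1 centered + GLS mean
  C <- ape::vcv(tr)
  h <- morphoclade:::node_heights(tr)
  n <- 16
  Ci <- solve(C)
  ones <- rep(1, n)
  a_hat <- colSums(Ci %*% y[rownames(C), ]) / sum(Ci)
  M <- ape::mrca(tr, full = TRUE)
  for (v in c(n + 1, n + 5, n + 15)) {
    cov_v <- h[M[v, 1:n]] # shared height of node v with each tip
    pred <- a_hat + t(cov_v) %*% Ci %*%
      sweep(y[rownames(C), ], 2, a_hat)
    expect_equal(unname(anc[as.character(v), ]), as.vector(pred),
                 tolerance = 1e-8)
  }
})

test_that("phylogenetic whitening decorrelates BM residuals", {
  tr <- fixture_tree(24, seed = 79)
  C <- ape::vcv(tr)
  L <- chol(C)
  set.seed(79)
  acc <- matrix(0, 24, 24)
  reps <- 200
  for (i in 1:reps) {
    y <- simulate_bm_on_tree(tr, diag(1, 1), seed = 3000 + i)
    z <- backsolve(L, y[rownames(C), , drop = FALSE], transpose = TRUE)
    acc <- acc + tcrossprod(z)
  }
  emp <- acc / reps
  off <- emp[upper.tri(emp)]
  expect_lt(mean(abs(off)), 0.12) # -> 0 with more replicates
  expect_equal(mean(diag(emp)), 1, tolerance = 0.15)
})
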