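test_that("centroid size matches the closed form and is scale-equivariant", {
  X <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(centroid_size(X), sqrt(2))
  Y <- random_config(10, seed = 3)
  # brute-force oracle: root of summed squared deviations from the centroid
  cen <- colMeans(Y)
  expect_equal(centroid_size(Y), sqrt(sum((t(t(Y) - cen))^2)))
  expect_equal(centroid_size(3 * Y), 3 * centroid_size(Y))
  expect_equal(centroid_size(matrix(1, 5, 3)), 0)
})

test_that("GPA removes similarity transforms exactly", {
  X <- random_config(12, seed = 5)
  # a 90-degree rotation + translation + scale of the same configuration
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Y <- sweep(X %*% R90 * 2.5, 2, c(3, -1, 7), `+`)
  al <- gpa(list(a = X, b = Y))
  d <- sqrt(sum((al$coords$a - al$coords$b)^2))
  expect_lt(d, 1e-9)
  expect_equal(al$coords$a, al$consensus, tolerance = 1e-9)
  # identical configs: zero distance, consensus equals the config
  al2 <- gpa(list(a = X, b = X))
  expect_lt(sum((al2$coords$a - al2$coords$b)^2), 1e-18)
})

test_that("GPA matches a brute-force grid search on planar triangles", {
  # 2-D-embedded triangles: optimal alignment is a rotation angle + known
  # centering/scaling, so a fine grid over the angle is an oracle
  set.seed(11)
  tris <- lapply(1:3, function(i) cbind(matrix(rnorm(6), 3, 2), 0))
  norm1 <- function(X) {
    X <- sweep(X, 2, colMeans(X))
    X / centroid_size(X)
  }
  tris_n <- lapply(tris, norm1)
  rot <- function(X, th, flip = FALSE) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    Xp <- X[, 1:2]
    if (flip) Xp[, 1] <- -Xp[, 1] # a 3-D rotation can mirror a planar shape
    cbind(Xp %*% R, 0)
  }
  # oracle: iterate grid-search alignment to the running consensus
  Xs <- tris_n
  for (pass in 1:50) {
    cons <- Reduce(`+`, Xs) / 3
    Xs <- lapply(Xs, function(X) {
      ths <- seq(0, 2 * pi, length.out = 5000)
      cand <- expand.grid(th = ths, flip = c(FALSE, TRUE))
      errs <- mapply(function(th, fl) sum((rot(X, th, fl) - cons)^2),
                     cand$th, cand$flip)
      best <- which.min(errs)
      rot(X, cand$th[best], cand$flip[best])
    })
  }
  cons_oracle <- Reduce(`+`, Xs) / 3
  crit_oracle <- sum(vapply(Xs, function(X) sum((X - cons_oracle)^2), 0))
  al <- gpa(setNames(tris, c("a", "b", "c")))
  crit <- tail(al$criterion, 1)
  expect_equal(crit, crit_oracle, tolerance = 1e-5)
})

test_that("GPA criterion is non-increasing and invariant to input transforms", {
  sim <- fixture_study(n_species = 6, n_specimens = 9)
  al <- gpa(sim$specimens)
  expect_true(all(diff(al$criterion) <= 1e-12))
  # random similarity transforms of the inputs do not change the result
  coords2 <- lapply(seq_along(sim$specimens$coords), function(i)
    similarity_jitter(sim$specimens$coords[[i]], seed = i))
  names(coords2) <- names(sim$specimens$coords)
  al2 <- gpa(specimen_table(coords2, sim$specimens$species, sim$specimens$scheme))
  d <- sum((as_shape_matrix(al) - as_shape_matrix(al2))^2)
  expect_lt(d, 1e-10)
})

test_that("sliding moves only semilandmarks and never raises bending energy", {
  sch <- landmark_scheme(2L, curves = list(c(1L, 3:7, 2L)))
  # straight 5-interior-point curve between fixed endpoints
  cons <- cbind(seq(0, 1, length.out = 7)[c(1, 7, 2:6)], 0, 0)
  cons <- cons + cbind(0, 0.05 * sin(seq_len(7)), 0) # mild reference bend
  set.seed(8)
  jit <- cons
  jit[3:7, 1] <- jit[3:7, 1] + rnorm(5, 0, 0.04) # jitter along the curve
  jit[3:7, 2] <- jit[3:7, 2] + rnorm(5, 0, 0.02)
  be0 <- morphoclade:::bending_energy(cons, jit)
  slid <- slide_semilandmarks(list(s = jit), cons, sch)$s
  be1 <- morphoclade:::bending_energy(cons, slid)
  expect_lte(be1, be0 + 1e-12)
  # fixed landmarks untouched
  expect_equal(slid[1:2, ], jit[1:2, ])
  # oracle: dense 1-D grid search along each tangent cannot do much better
  dirs <- morphoclade:::sliding_directions(cons, sch)
  Be <- morphoclade:::bending_energy_matrix(cons)
  grid_best <- jit
  for (pass in 1:3) for (i in 3:7) {
    u <- dirs[[i]][, 1]
    ts <- seq(-0.1, 0.1, length.out = 801)
    evals <- vapply(ts, function(tv) {
      cand <- grid_best
      cand[i, ] <- cand[i, ] + tv * u
      morphoclade:::bending_energy(cons, cand, Be)
    }, 0)
    tv <- ts[which.min(evals)]
    grid_best[i, ] <- grid_best[i, ] + tv * u
  }
  be_grid <- morphoclade:::bending_energy(cons, grid_best)
  expect_lte(be1, be_grid + 1e-6)
  # specimen equal to the consensus does not move
  same <- slide_semilandmarks(list(s = cons), cons, sch)$s
  expect_equal(same, cons, tolerance = 1e-9)
})

test_that("species averaging is the arithmetic mean and keeps singletons", {
  sch <- landmark_scheme(5L)
  M <- random_config(5, seed = 2)
  d <- random_config(5, seed = 3) * 0.01
  coords <- list(a1 = M + d, a2 = M - d, b1 = M)
  al <- list(coords = lapply(coords, function(x) {
               x <- sweep(x, 2, colMeans(x)); x / centroid_size(x)
             }),
             cs = c(a1 = 1, a2 = 1, b1 = 2),
             consensus = M, scheme = sch,
             species = c(a1 = "A", a2 = "A", b1 = "B"))
  class(al) <- "aligned_sample"
  sp <- average_by_species(al)
  expect_equal(nrow(sp$shapes), 2)
  expect_equal(sp$shapes["A", ],
               (morphoclade:::flatten_config(al$coords$a1) +
                morphoclade:::flatten_config(al$coords$a2)) / 2)
  expect_equal(sp$shapes["B", ], morphoclade:::flatten_config(al$coords$b1))
  expect_equal(unname(sp$mean_log_cs["B"]), log(2))
})

test_that("noise-free single-specimen study recovers species shapes through GPA", {
  spec <- simulation_spec(n_species = 8, n_specimens = 8, noise_sd = 0)
  sim <- simulate_study(spec, seed = 13)
  al <- gpa(sim$specimens)
  sh <- average_by_species(al)
  # truth, put through the same normalisation
  truth <- t(apply(sim$truth$species_shapes, 1, function(v) {
    x <- morphoclade:::unflatten_config(v)
    x <- sweep(x, 2, colMeans(x))
    morphoclade:::flatten_config(x / centroid_size(x))
  }))
  # align the consensus frames before comparing
  for (s in rownames(truth)) {
    A <- morphoclade:::unflatten_config(sh$shapes[s, ])
    B <- morphoclade:::unflatten_config(truth[s, ])
    R <- morphoclade:::procrustes_rotation(B, A)
    expect_lt(sqrt(sum((B %*% R - A)^2)), 1e-6)
  }
})
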