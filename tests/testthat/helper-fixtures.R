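# Shared fixtures, generated in code.

# tiny 4-landmark scheme with one 3-point curve (1 sliding interior point)
tiny_scheme <- function() {
  landmark_scheme(3L, curves = list(c(1L, 4L, 2L)))
}

random_config <- function(p = 10, seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(p * 3, sd = sd), p, 3)
}

# small ultrametric pure-birth tree with unit height
fixture_tree <- function(n = 16, seed = 1) {
  set.seed(seed)
  tr <- ape::rphylo(n, 1, 0)
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

# small complete study used by several module tests
fixture_study <- function(n_species = 12, n_specimens = 18, seed = 42, ...) {
  spec <- simulation_spec(n_species = n_species, n_specimens = n_specimens, ...)
  simulate_study(spec, seed = seed)
}

# apply a random similarity transform (rotation det +1, scale, translation)
similarity_jitter <- function(X, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(X %*% R * exp(rnorm(1, 0, 0.5)), 2, rnorm(3, 0, 3), `+`)
}

# brute-force Mk likelihood: sum over all ancestral state assignments
# (equal root prior); exact oracle for the pruning algorithm on tiny trees
mk_brute <- function(tree, tip_states, Q, root_prior = "equal") {
  states <- rownames(Q)
  s <- length(states)
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tr); m <- tr$Nnode
  tipv <- match(tip_states[tr$tip.label], states)
  Pm <- lapply(seq_len(nrow(tr$edge)), function(k)
    as.matrix(Matrix::expm(Q * tr$edge.length[k])))
  combos <- as.matrix(expand.grid(rep(list(seq_len(s)), m)))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    assign_all <- c(tipv, combos[r, ])
    lik <- 1
    for (k in seq_len(nrow(tr$edge)))
      lik <- lik * Pm[[k]][assign_all[tr$edge[k, 1]], assign_all[tr$edge[k, 2]]]
    total <- total + (1 / s) * lik
  }
  log(total)
}
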