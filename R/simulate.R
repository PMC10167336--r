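#' Template jaw-like landmark configuration
#'
#' 100 landmarks sampled on a bent half-tube (a jaw-ramus analogue): 6
#' fixed anchors at the ends and articulation analogues, 3 curves of 17
#' interior sliding points, and 43 surface semilandmarks on the tube wall,
#' matching [default_jaw_scheme()].
#' @param scheme a [landmark_scheme()] (the default jaw scheme).
#' @return p x 3 matrix.
#' @export
template_jaw <- function(scheme = default_jaw_scheme()) {
  # ramus midline: a quarter arc in the xy plane
  arc <- function(t) cbind(cos(t * pi / 2), sin(t * pi / 2), 0)
  radius <- 0.12
  X <- matrix(0, scheme$p, 3)
  # fixed landmarks
  X[1, ] <- arc(0) + c(0, 0, radius)          # anterior symphysis
  X[2, ] <- arc(1) + c(0, 0, -radius)         # articular condyle
  X[3, ] <- arc(1) + c(0, 0, radius)          # coronoid analogue
  X[4, ] <- arc(0.1) + c(0, 0, radius * 0.5)  # dental groove anterior
  X[5, ] <- arc(0.9) + c(0, 0, radius * 0.5)  # dental groove posterior
  X[6, ] <- arc(0.5) + c(0, 0, -radius)       # ventral angle
  # curves: interpolate along the arc with role-specific tube offsets
  fill_curve <- function(idx, z_off, r_scale = 1) {
    tt <- seq(0, 1, length.out = length(idx) + 2)[-c(1, length(idx) + 2)]
    X[idx, ] <<- arc(tt) * r_scale + cbind(0, 0, rep(z_off, length(idx)))
  }
  fill_curve(6 + 1:17, -radius)           # lower margin
  fill_curve(23 + 1:17, radius)           # upper margin
  fill_curve(40 + 1:17, radius * 0.5, 0.97) # dental groove (slightly inset)
  # surface: points wrapped around the half tube
  ns <- length(scheme$surface)
  tt <- seq(0.05, 0.95, length.out = ns)
  phi <- seq(0, pi, length.out = ns)[order((seq_len(ns) * 7) %% ns)]
  X[scheme$surface, ] <- arc(tt) * (1 + 0.02 * cos(phi)) +
    cbind(0, 0, radius * 0.8 * cos(phi)) + cbind(0.01 * sin(phi), 0, 0)
  X
}

#' Specification for a synthetic landmark study
#'
#' Bundles the generator parameters: study size, tree model, regime (Mk)
#' process, trait model and rates, specimen noise and diet guild structure.
#' Defaults mirror a 90-species / 145-specimen design with four habitat
#' regimes on a unit-height pure-birth tree.
#'
#' @param n_species number of species.
#' @param n_specimens total specimens (>= n_species; the surplus is
#'   assigned round-robin).
#' @param scheme landmark scheme.
#' @param template base shape.
#' @param regime_states regime labels (habitat categories).
#' @param regime_q Mk rate for regimes (ER).
#' @param regime_scalars named per-regime BM rate multipliers.
#' @param trait_model `"BM"` or `"EB"`.
#' @param eb_rate EB decay rate r (<= 0) on the unit-height tree.
#' @param shape_sd per-coordinate Brownian SD accumulated over unit time.
#' @param noise_sd digitisation noise SD (in template units).
#' @param n_guilds planted diet guilds.
#' @param diet_categories prey category names.
#' @param guild_concentration Dirichlet concentration of the focal
#'   category per guild (larger = tighter guilds).
#' @param n_trees number of trees in the returned set (first is the
#'   generating tree; the rest are branch-length jitters emulating
#'   phylogenetic uncertainty).
#' @export
simulation_spec <- function(n_species = 90, n_specimens = 145,
                            scheme = default_jaw_scheme(),
                            template = template_jaw(scheme),
                            regime_states = habitat_levels(),
                            regime_q = 0.5,
                            regime_scalars = c(reef = 1, shelf = 1,
                                               pelagic = 1, `deep-sea` = 4),
                            trait_model = c("BM", "EB"), eb_rate = -2,
                            shape_sd = 0.05, noise_sd = 0.005,
                            n_guilds = 8,
                            diet_categories = c("FISH", "CEPH", "CR", "GEN",
                                                "BP", "MOLL", "INV", "ZOO"),
                            guild_concentration = 12,
                            n_trees = 1) {
  trait_model <- match.arg(trait_model)
  stopifnot(n_specimens >= n_species, noise_sd >= 0, shape_sd > 0,
            all(regime_scalars > 0), n_guilds <= length(diet_categories))
  structure(list(n_species = n_species, n_specimens = n_specimens,
                 scheme = scheme, template = template,
                 regime_states = regime_states, regime_q = regime_q,
                 regime_scalars = regime_scalars, trait_model = trait_model,
                 eb_rate = eb_rate, shape_sd = shape_sd, noise_sd = noise_sd,
                 n_guilds = n_guilds, diet_categories = diet_categories,
                 guild_concentration = guild_concentration,
                 n_trees = n_trees),
            class = "simulation_spec")
}

# Pure-birth tree scaled to unit height.
sim_tree <- function(n) {
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr$edge.length <- tr$edge.length / tree_height(tr)
  tr
}

# Simulate an Mk (ER) regime history along the tree; returns a regime_map.
sim_regimes <- function(tree, states, q) {
  s <- length(states)
  Q <- build_Q(q, states, "ER")
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tr)
  node_state <- integer(n + tr$Nnode)
  node_state[n + 1L] <- sample.int(s, 1)
  segments <- vector("list", nrow(tr$edge))
  for (k in rev(seq_len(nrow(tr$edge)))) { # preorder
    a <- node_state[tr$edge[k, 1]]
    t_b <- tr$edge.length[k]
    cur <- a; left <- t_b
    st <- integer(); dur <- numeric()
    repeat {
      wait <- stats::rexp(1, -Q[cur, cur])
      if (wait >= left) {
        st <- c(st, cur); dur <- c(dur, left)
        break
      }
      st <- c(st, cur); dur <- c(dur, wait)
      left <- left - wait
      probs <- Q[cur, ]; probs[cur] <- 0
      cur <- sample.int(s, 1, prob = probs)
    }
    node_state[tr$edge[k, 2]] <- cur
    segments[[k]] <- data.frame(state = states[st], duration = dur)
  }
  structure(list(tree = tr, segments = segments,
                 tip_states = setNames(states[node_state[seq_len(n)]], tr$tip.label),
                 node_states = states[node_state], states = states,
                 map_id = "true", seed = NULL),
            class = "regime_map")
}

#' Simulate multivariate Brownian / early-burst data on a tree
#'
#' Draws tip values from the exact multivariate normal implied by the
#' (regime-scaled, model-transformed) tree covariance: rows covary as the
#' tree dictates, columns as `trait_cov`.
#'
#' @param tree ape `phylo` (or a `regime_map` when `regime_scalars` are
#'   used).
#' @param trait_cov p x p positive-definite trait covariance (a scalar is
#'   taken as isotropic variance).
#' @param regime_scalars optional named per-regime rate multipliers
#'   (requires `tree` to be a `regime_map`).
#' @param model `"BM"` or `"EB"`.
#' @param eb_rate EB decay rate (<= 0).
#' @param root root state (vector of length p, default 0).
#' @param seed RNG seed.
#' @return species x p matrix with tip rownames.
#' @export
simulate_bm_on_tree <- function(tree, trait_cov, regime_scalars = NULL,
                                model = c("BM", "EB"), eb_rate = -2,
                                root = NULL, seed = NULL) {
  model <- match.arg(model)
  if (inherits(tree, "regime_map")) {
    map <- tree
    Ck <- regime_vcv(map)
    if (is.null(regime_scalars)) regime_scalars <- setNames(rep(1, length(Ck)), names(Ck))
    C <- Reduce(`+`, Map(`*`, as.list(regime_scalars[names(Ck)]), Ck))
    tips <- map$tree$tip.label
  } else {
    tree <- check_tree(tree)
    C <- ape::vcv(tree)
    tips <- tree$tip.label
  }
  if (model == "EB") C <- transform_vcv(C, "EB", eb_rate)
  if (length(trait_cov) == 1) trait_cov <- diag(as.numeric(trait_cov), 1)
  trait_cov <- as.matrix(trait_cov)
  p <- ncol(trait_cov)
  ev <- eigen(trait_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= -1e-10 * max(ev)) stopf("trait covariance is not positive definite")
  n <- nrow(C)
  root <- root %||% rep(0, p)
  if (max(diag(C)) < 1e-14) {
    Y <- matrix(root, n, p, byrow = TRUE)
  } else {
    Lc <- t(chol_safe(C + diag(1e-12 * max(diag(C)), n), "tree"))
    Lr <- t(chol_safe(trait_cov + diag(1e-12 * max(diag(trait_cov)), p), "trait"))
    Z <- with_seed(seed, matrix(stats::rnorm(n * p), n, p))
    Y <- sweep(Lc %*% Z %*% t(Lr), 2, root, `+`)
  }
  rownames(Y) <- tips
  Y
}

random_similarity_transform <- function(X) {
  # random rotation (det +1), scale, translation
  M <- matrix(stats::rnorm(9), 3, 3)
  qrM <- qr(M)
  R <- qr.Q(qrM)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  s <- exp(stats::rnorm(1, 0, 0.3))
  tr <- stats::rnorm(3, 0, 2)
  sweep(X %*% R * s, 2, tr, `+`)
}

#' Simulate a complete landmark study
#'
#' Generates the full synthetic study the pipeline consumes: a unit-height
#' pure-birth tree, a regime (habitat) history under an Mk process, species
#' shapes as the template plus multivariate BM/EB displacements with
#' regime-specific rate scalars, specimens as species shapes plus isotropic
#' digitisation noise under random similarity transforms (so GPA has work
#' to do), trophic levels, and Dirichlet diet compositions with planted
#' guilds. All ground-truth parameters are returned for recovery tests;
#' the output is a pure function of `seed`.
#'
#' @param spec a [simulation_spec()].
#' @param seed master seed.
#' @return list: `specimens` (a `specimen_table`), `ecology`
#'   (`ecology_table`), `trees` (`multiPhylo`), `truth` (tree, regime map,
#'   species shapes, guilds, parameters).
#' @export
simulate_study <- function(spec = simulation_spec(), seed = 1) {
  with_seed(derive_seed(seed, "study"), {
    n <- spec$n_species
    tree <- sim_tree(n)
    map <- sim_regimes(tree, spec$regime_states, spec$regime_q)
    tmpl <- flatten_config(spec$template)
    # isotropic BM displacement across all 3p coordinates
    P3 <- length(tmpl)
    dispM <- simulate_bm_on_tree(map, trait_cov = diag(spec$shape_sd^2, P3),
                                 regime_scalars = spec$regime_scalars,
                                 model = spec$trait_model, eb_rate = spec$eb_rate)
    shapes <- sweep(dispM, 2, tmpl, `+`)
    rownames(shapes) <- map$tree$tip.label
    # specimens: distribute the surplus round-robin
    counts <- rep(1L, n)
    extra <- spec$n_specimens - n
    if (extra > 0) counts[seq_len(extra) %% n + 1L] <- counts[seq_len(extra) %% n + 1L] + 1L
    coords <- list(); species <- character()
    for (i in seq_len(n)) {
      sp_id <- map$tree$tip.label[i]
      base <- unflatten_config(shapes[sp_id, ])
      for (j in seq_len(counts[i])) {
        id <- sprintf("%s_ind%02d", sp_id, j)
        noisy <- base + matrix(stats::rnorm(length(base), 0, spec$noise_sd),
                               nrow(base), 3)
        coords[[id]] <- random_similarity_transform(noisy)
        species[id] <- sp_id
      }
    }
    specimens <- specimen_table(coords, species, spec$scheme)
    # ecology: habitat from the regime tip states; trophic level uniform;
    # diets from planted Dirichlet guilds
    guild_id <- sample(rep_len(seq_len(spec$n_guilds), n))
    ncat <- length(spec$diet_categories)
    diet <- t(vapply(guild_id, function(g) {
      alpha <- rep(1, ncat)
      alpha[(g - 1) %% ncat + 1] <- spec$guild_concentration
      gam <- stats::rgamma(ncat, alpha)
      gam / sum(gam)
    }, numeric(ncat)))
    colnames(diet) <- spec$diet_categories
    TR <- round(stats::runif(n, 3.2, 4.6), 2)
    eco <- data.frame(species = map$tree$tip.label,
                      order = paste0("order", 1 + (guild_id %% 3)),
                      trophic_level = TR,
                      stringsAsFactors = FALSE)
    regimes <- unname(map$tip_states[map$tree$tip.label])
    # custom regime labels go in their own column; the habitat column keeps
    # its fixed four-level vocabulary
    if (all(spec$regime_states %in% habitat_levels())) eco$habitat <- regimes
    else eco$regime <- regimes
    eco <- cbind(eco, setNames(as.data.frame(diet),
                               paste0("diet_", spec$diet_categories)))
    ecology <- as_ecology(eco)
    trees <- structure(c(list(tree), lapply(seq_len(max(0, spec$n_trees - 1)),
      function(i) {
        tr <- tree
        tr$edge.length <- tr$edge.length *
          exp(stats::rnorm(length(tr$edge.length), 0, 0.1))
        tr$edge.length <- tr$edge.length / tree_height(tr)
        tr
      })), class = "multiPhylo")
    list(specimens = specimens, ecology = ecology, trees = trees,
         truth = list(tree = tree, regime_map = map, species_shapes = shapes,
                      guilds = setNames(guild_id, map$tree$tip.label),
                      spec = spec, seed = seed))
  })
}
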