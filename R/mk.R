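# Build an Mk rate matrix from free rates under a structural constraint.
# ER: one rate; SYM: s(s-1)/2 rates (upper triangle, mirrored); ARD:
# s(s-1) rates (row-major off-diagonals). Rows sum to zero.
build_Q <- function(rates, states, structure = c("ER", "SYM", "ARD")) {
  structure <- match.arg(structure)
  s <- length(states)
  Q <- matrix(0, s, s, dimnames = list(states, states))
  if (structure == "ER") {
    Q[] <- rates[1]
  } else if (structure == "SYM") {
    k <- 0
    for (i in 1:(s - 1)) for (j in (i + 1):s) {
      k <- k + 1
      Q[i, j] <- Q[j, i] <- rates[k]
    }
  } else {
    k <- 0
    for (i in 1:s) for (j in 1:s) {
      if (i == j) next
      k <- k + 1
      Q[i, j] <- rates[k]
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

n_free_rates <- function(structure, s) {
  switch(structure, ER = 1L, SYM = as.integer(s * (s - 1) / 2),
         ARD = as.integer(s * (s - 1)))
}

check_Q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stopf("Q must be square")
  off <- Q; diag(off) <- 0
  if (any(off < -1e-12)) stopf("Q off-diagonals must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-8 * max(abs(Q), 1)))
    stopf("Q rows must sum to 0")
  Q
}

# Transition probability matrix exp(Q t) via a cached eigendecomposition,
# with a scaling-and-squaring fallback (Matrix::expm) for defective Q.
mk_eigen <- function(Q) {
  eg <- eigen(Q)
  Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
  # condition check: a near-defective eigenbasis falls back to expm
  ok <- !is.null(Vi) && all(is.finite(Vi)) &&
    max(abs(Vi)) < 1e12
  list(values = eg$values, vectors = eg$vectors, inv = Vi, ok = ok, Q = Q)
}

mk_Pmat_cached <- function(eg, t) {
  s <- nrow(eg$Q)
  if (t == 0) return(diag(s))
  P <- NULL
  if (eg$ok)
    P <- Re(eg$vectors %*% (exp(eg$values * t) * eg$inv))
  if (is.null(P) || any(!is.finite(P)) || max(abs(rowSums(P) - 1)) > 1e-6)
    P <- as.matrix(Matrix::expm(eg$Q * t))
  P[P < 0] <- 0
  P / rowSums(P)
}

mk_Pmat <- function(Q, t) mk_Pmat_cached(mk_eigen(Q), t)

# Tip partial likelihoods: observed state -> indicator row; NA -> all ones.
tip_partials <- function(tip_states, states) {
  n <- length(tip_states)
  Lp <- matrix(0, n, length(states))
  for (i in seq_len(n)) {
    if (is.na(tip_states[i])) Lp[i, ] <- 1
    else Lp[i, match(as.character(tip_states[i]), states)] <- 1
  }
  if (anyNA(Lp)) stopf("tip state not in the declared state set")
  Lp
}

# One pruning pass; returns per-node partial likelihoods, per-node log
# scalers, and per-edge transition matrices (postorder edge order).
mk_prune <- function(tree, tip_states, Q, states) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tr); m <- tr$Nnode; s <- length(states)
  part <- matrix(0, n + m, s)
  part[seq_len(n), ] <- tip_partials(tip_states[tr$tip.label], states)
  scaler <- numeric(n + m)
  started <- logical(n + m)
  started[seq_len(n)] <- TRUE
  Pmats <- vector("list", nrow(tr$edge))
  eg <- mk_eigen(Q)
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    P <- mk_Pmat_cached(eg, tr$edge.length[k])
    Pmats[[k]] <- P
    msg <- as.vector(P %*% part[ch, ])
    if (!started[par]) {
      part[par, ] <- msg
      started[par] <- TRUE
    } else part[par, ] <- part[par, ] * msg
    scaler[par] <- scaler[par] + scaler[ch]
    mx <- max(part[par, ])
    if (mx <= 0) stopf("zero likelihood: data impossible under Q")
    part[par, ] <- part[par, ] / mx
    scaler[par] <- scaler[par] + log(mx)
  }
  list(tree = tr, part = part, scaler = scaler, Pmats = Pmats)
}

root_prior_weights <- function(root_partial, prior = c("fitzjohn", "equal", "stationary"), Q = NULL) {
  prior <- match.arg(prior)
  s <- length(root_partial)
  switch(prior,
    equal = rep(1 / s, s),
    fitzjohn = {
      tot <- sum(root_partial)
      if (tot <= 0) rep(1 / s, s) else root_partial / tot
    },
    stationary = {
      v <- Re(eigen(t(Q))$vectors[, which.min(abs(Re(eigen(t(Q))$values)))])
      v <- abs(v); v / sum(v)
    })
}

#' Mk-model log-likelihood
#'
#' Felsenstein pruning with per-branch transition matrices `exp(Q t)`.
#' Missing tip states (NA) enter as all-ones partials.
#'
#' @param tree ape `phylo`.
#' @param tip_states named character/factor vector over tips.
#' @param Q rate matrix with state dimnames (rows sum to 0).
#' @param root_prior `"fitzjohn"` (state-conditional weighting), `"equal"`,
#'   or `"stationary"`.
#' @return log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "fitzjohn") {
  tree <- check_tree(tree)
  check_Q(Q)
  states <- rownames(Q) %||% as.character(seq_len(nrow(Q)))
  pr <- mk_prune(tree, tip_states, Q, states)
  root <- ape::Ntip(pr$tree) + 1L
  w <- root_prior_weights(pr$part[root, ], root_prior, Q)
  log(sum(w * pr$part[root, ])) + pr$scaler[root]
}

#' Fit an Mk model of discrete character evolution
#'
#' Bounded maximisation of the pruning likelihood over log-parameterised
#' free rates: Brent's method for a single rate, quasi-Newton from three
#' starting points otherwise. AIC = 2k - 2 logLik with k the free-rate
#' count (ER 1, SYM s(s-1)/2, ARD s(s-1)).
#'
#' @param tree ape `phylo`.
#' @param tip_states named vector of observed states.
#' @param structure `"ER"`, `"SYM"` or `"ARD"`.
#' @param root_prior see [mk_loglik()].
#' @return an `mk_fit`: `Q`, `rates`, `structure`, `logLik`, `AIC`,
#'   `states`, `root_prior`.
#' @export
fit_mk <- function(tree, tip_states, structure = c("ER", "SYM", "ARD"),
                   root_prior = "fitzjohn") {
  structure <- match.arg(structure)
  tree <- check_tree(tree)
  states <- sort(unique(as.character(stats::na.omit(tip_states))))
  if (length(states) < 2) {
    warnf("only one state observed: rate is driven to the lower bound")
    states <- c(states, paste0(states, "_unobserved"))
  }
  k <- n_free_rates(structure, length(states))
  nll <- function(logr) {
    Q <- build_Q(exp(logr), states, structure)
    -mk_loglik(tree, tip_states, Q, root_prior)
  }
  tl <- sum(tree$edge.length)
  nchg <- max(1, length(states) - 1)
  starts <- list(rep(log(nchg / tl), k),
                 rep(log(0.1), k),
                 rep(log(2 / tl), k))
  lo <- log(1e-8); hi <- log(1e4)
  best <- NULL
  if (k == 1) {
    # one free rate: Brent's method is robust to the flat likelihood
    # plateau near the bounds where quasi-Newton steps stall
    op <- stats::optim(starts[[1]], nll, method = "Brent", lower = lo,
                       upper = hi)
    best <- op
  } else {
    for (st in starts) {
      op <- tryCatch(
        stats::optim(st, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(factr = 1e10, maxit = 200)),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
  }
  if (is.null(best)) stopf("Mk optimisation failed for all starts")
  if (any(best$par > hi - 1e-3))
    warnf("rate(s) at the upper bound: likelihood surface is saturated")
  Q <- build_Q(exp(best$par), states, structure)
  ll <- -best$value
  structure(list(Q = Q, rates = exp(best$par), structure = structure,
                 logLik = ll, AIC = 2 * k - 2 * ll, states = states,
                 root_prior = root_prior),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk fit [%s, %d states]: logLik = %.3f, AIC = %.3f\n",
              x$structure, length(x$states), x$logLik, x$AIC))
  invisible(x)
}

#' Marginal ancestral state probabilities
#'
#' Posterior probability of each state at every internal node under a
#' fitted Q, by the standard two-pass (tipward/rootward message) algorithm;
#' rows sum to 1.
#'
#' @inheritParams mk_loglik
#' @return matrix (internal nodes x states), rows named by ape node number.
#' @export
marginal_ancestral_states <- function(tree, tip_states, Q,
                                      root_prior = "fitzjohn") {
  tree <- check_tree(tree)
  check_Q(Q)
  states <- rownames(Q) %||% as.character(seq_len(nrow(Q)))
  pr <- mk_prune(tree, tip_states, Q, states)
  tr <- pr$tree
  n <- ape::Ntip(tr); m <- tr$Nnode; s <- length(states)
  root <- n + 1L
  # rootward ("up") messages per node
  up <- matrix(1, n + m, s)
  up[root, ] <- root_prior_weights(pr$part[root, ], root_prior, Q)
  edges <- tr$edge
  kid_edges <- split(seq_len(nrow(edges)), edges[, 1])
  # preorder: reverse postorder edge order visits parents before children
  for (k in rev(seq_len(nrow(edges)))) {
    par <- edges[k, 1]; ch <- edges[k, 2]
    sibs <- setdiff(kid_edges[[as.character(par)]], k)
    msg <- up[par, ]
    for (j in sibs) msg <- msg * as.vector(pr$Pmats[[j]] %*% pr$part[edges[j, 2], ])
    up[ch, ] <- as.vector(msg %*% pr$Pmats[[k]])
    mx <- max(up[ch, ])
    if (mx > 0) up[ch, ] <- up[ch, ] / mx
  }
  marg <- pr$part * up
  marg <- marg / rowSums(marg)
  out <- marg[(n + 1):(n + m), , drop = FALSE]
  rownames(out) <- as.character((n + 1):(n + m))
  colnames(out) <- states
  out
}

# Sample the number of jumps and intermediate states of a uniformised
# Markov bridge from state a to state b over time t.
sample_bridge <- function(a, b, t, Q, B, mu, Pab, max_jumps = 1000) {
  s <- nrow(Q)
  # P(N = j | a -> b) ~ dpois(j, mu t) * B^j[a, b] / Pab
  Bpow <- vector("list", max_jumps + 1)
  Bpow[[1]] <- diag(s)
  u <- stats::runif(1)
  cum <- 0
  nj <- NA
  for (j in 0:max_jumps) {
    if (j > 0) Bpow[[j + 1]] <- Bpow[[j]] %*% B
    pj <- stats::dpois(j, mu * t) * Bpow[[j + 1]][a, b] / Pab
    cum <- cum + pj
    if (u <= cum) { nj <- j; break }
  }
  if (is.na(nj)) nj <- max_jumps
  if (nj == 0) return(list(states = a, times = numeric())) # a == b here
  path <- integer(nj + 1)
  path[1] <- a; path[nj + 1] <- b
  if (nj > 1) {
    for (step in 1:(nj - 1)) {
      prev <- path[step]
      wts <- B[prev, ] * Bpow[[nj - step + 1]][, b]
      path[step + 1] <- sample.int(s, 1, prob = wts)
    }
  }
  times <- sort(stats::runif(nj, 0, t))
  # drop virtual (self) jumps
  keep <- which(diff(path) != 0)
  list(states = c(a, path[keep + 1]), times = times[keep])
}

#' Stochastic character mapping
#'
#' Samples full character histories conditional on the tip data and Q:
#' joint node states from their conditional distribution (rootward pass of
#' sampled states), then substitution histories along each branch by
#' uniformisation, conditional on the branch's endpoint states.
#'
#' @inheritParams mk_loglik
#' @param n_maps number of maps. When `trees` is a list (`multiPhylo`),
#'   maps are drawn round-robin across trees, one per tree by default.
#' @param seed RNG seed; map `i` is reproducible from `(seed, i)`.
#' @return list of `regime_map` objects: `tree`, per-edge `segments`
#'   (list of data.frames with `state`, `duration`), `tip_states`,
#'   `node_states`, `map_id`, `seed`.
#' @export
simmap <- function(tree, tip_states, Q, n_maps = 1, seed = NULL,
                   root_prior = "fitzjohn") {
  trees <- if (inherits(tree, "multiPhylo")) tree else list(tree)
  check_Q(Q)
  states <- rownames(Q) %||% as.character(seq_len(nrow(Q)))
  maps <- vector("list", n_maps)
  for (i in seq_len(n_maps)) {
    tr <- check_tree(trees[[(i - 1) %% length(trees) + 1]])
    maps[[i]] <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "simmap", i),
                           simmap_one(tr, tip_states, Q, states, root_prior, i, seed))
  }
  maps
}

simmap_one <- function(tree, tip_states, Q, states, root_prior, map_id, seed) {
  pr <- mk_prune(tree, tip_states, Q, states)
  tr <- pr$tree
  n <- ape::Ntip(tr); m <- tr$Nnode; s <- length(states)
  root <- n + 1L
  node_state <- integer(n + m)
  w <- root_prior_weights(pr$part[root, ], root_prior, Q) * pr$part[root, ]
  node_state[root] <- sample.int(s, 1, prob = w)
  edges <- tr$edge
  mu <- max(-diag(Q)) * 1.05 + 1e-12
  B <- diag(s) + Q / mu
  segments <- vector("list", nrow(edges))
  for (k in rev(seq_len(nrow(edges)))) { # preorder
    par <- edges[k, 1]; ch <- edges[k, 2]
    P <- pr$Pmats[[k]]
    a <- node_state[par]
    wts <- P[a, ] * pr$part[ch, ]
    if (sum(wts) <= 0) stopf("impossible endpoint conditioning in simmap")
    b <- sample.int(s, 1, prob = wts)
    node_state[ch] <- b
    t_b <- tr$edge.length[k]
    if (t_b == 0) {
      segments[[k]] <- data.frame(state = states[b], duration = 0)
      next
    }
    br <- sample_bridge(a, b, t_b, Q, B, mu, P[a, b])
    bounds <- c(0, br$times, t_b)
    segments[[k]] <- data.frame(state = states[br$states],
                                duration = diff(bounds))
  }
  structure(list(tree = tr, segments = segments,
                 tip_states = setNames(states[node_state[seq_len(n)]], tr$tip.label),
                 node_states = states[node_state],
                 states = states, map_id = map_id, seed = seed),
            class = "regime_map")
}

#' @export
print.regime_map <- function(x, ...) {
  nchanges <- sum(vapply(x$segments, nrow, 0L) - 1L)
  cat(sprintf("regime map %s: %d states, %d changes\n",
              x$map_id %||% "?", length(x$states), nchanges))
  invisible(x)
}

#' Per-edge time spent in each regime
#' @param map a `regime_map`.
#' @return edges x states matrix of durations (postorder edge order of
#'   `map$tree`).
#' @export
regime_edge_times <- function(map) {
  out <- matrix(0, length(map$segments), length(map$states),
                dimnames = list(NULL, map$states))
  for (k in seq_along(map$segments)) {
    seg <- map$segments[[k]]
    for (r in seq_len(nrow(seg)))
      out[k, seg$state[r]] <- out[k, seg$state[r]] + seg$duration[r]
  }
  out
}

#' Serialise stochastic character maps
#'
#' Writes a list of regime maps to JSON (tree as embedded Newick, per-edge
#' segment tables, tip states, seed); [read_regime_maps()] restores them
#' losslessly.
#' @param maps list of `regime_map`s from [simmap()].
#' @param path output JSON file.
#' @export
write_regime_maps <- function(maps, path) {
  if (inherits(maps, "regime_map")) maps <- list(maps)
  payload <- lapply(maps, function(mp) {
    list(newick = ape::write.tree(mp$tree),
         states = mp$states,
         tip_states = as.list(mp$tip_states),
         node_states = mp$node_states,
         map_id = mp$map_id,
         seed = mp$seed,
         segments = lapply(mp$segments, function(s)
           list(state = s$state, duration = s$duration)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read stochastic character maps written by [write_regime_maps()]
#' @param path JSON file.
#' @return list of `regime_map`s.
#' @export
read_regime_maps <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(mp) {
    tr <- ape::read.tree(text = mp$newick)
    segs <- lapply(mp$segments, function(s)
      data.frame(state = unlist(s$state), duration = unlist(s$duration),
                 stringsAsFactors = FALSE))
    structure(list(tree = tr, segments = segs,
                   tip_states = unlist(mp$tip_states),
                   node_states = unlist(mp$node_states),
                   states = unlist(mp$states),
                   map_id = mp$map_id, seed = mp$seed),
              class = "regime_map")
  })
}
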