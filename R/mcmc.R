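# REML Brownian log-likelihood of axis scores on a tree whose branch b has
# effective length scale_b * t_b, with per-axis rates. Axes are treated as
# independent (they are orthogonal ordination scores).
axes_loglik <- function(arr, Y, edge_scale, rates) {
  bm_reml_loglik_cpp(arr$parent, arr$child, arr$el * edge_scale,
                     arr$ntip, Y, rates)
}

#' Reversible-jump MCMC for branch-specific evolutionary rate shifts
#'
#' Models the retained ordination axes as Brownian motion on a tree whose
#' branch b has effective length `r_b * t_b`, where `r_b = 1` unless a rate
#' shift is active on that branch. Reversible jump adds, removes, and
#' updates shifts; per-axis global rates are updated by random-walk
#' Metropolis. Priors: branch scalars log-uniform on 1e-3..1e3; shift
#' count geometric (p = 0.5); global rates log-uniform on a wide support.
#' The REML (contrast) likelihood is used, so no root state is sampled.
#'
#' @param axis_scores species x k matrix of ordination scores (rownames =
#'   species).
#' @param tree ape `phylo` with positive branch lengths.
#' @param iterations,burn_in,thinning chain controls (desk-scale defaults;
#'   increase for production runs).
#' @param n_chains independent chains (different seeds).
#' @param seed master seed; chain c is reproducible from `(seed, c)`.
#' @param prior_only switch the likelihood off (prior recovery checks).
#' @return an `rjmcmc_result`: `traces` (list per chain of data.frames
#'   with logLik, n_shifts, global rates), `branch_scalars` (posterior
#'   mean per branch, edge order of the postorder tree), `scalar_samples`,
#'   `tree`.
#' @export
rjmcmc_variable_rates <- function(axis_scores, tree, iterations = 2e5,
                                  burn_in = floor(iterations / 4),
                                  thinning = 20, n_chains = 2, seed = 1,
                                  prior_only = FALSE) {
  if (iterations <= 0 || thinning <= 0) stopf("iterations and thinning must be positive")
  Y <- as.matrix(axis_scores)
  keep <- apply(Y, 2, stats::sd) > 0
  if (!all(keep)) {
    warnf("dropping %d zero-variance axis/axes", sum(!keep))
    Y <- Y[, keep, drop = FALSE]
  }
  if (!ncol(Y)) stopf("no informative axes")
  tree <- check_tree(tree)
  if (any(tree$edge.length <= 0)) stopf("branch lengths must be positive")
  arr <- tree_arrays(tree)
  Y <- Y[arr$tip.label, , drop = FALSE]
  k <- ncol(Y); nb <- length(arr$el)

  lp_scalar <- function(r) ifelse(r >= 1e-3 & r <= 1e3, -log(r) - log(log(1e6)), -Inf)
  lp_count <- function(m) m * log(0.5) + log(0.5) # geometric(0.5) on 0,1,2,...
  lp_rate <- function(s2) ifelse(s2 >= 1e-10 & s2 <= 1e10, -log(s2), -Inf)

  chains <- vector("list", n_chains)
  scalar_sum <- matrix(0, 0, nb)
  all_scalar_samples <- list()
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- with_seed(derive_seed(seed, "rjmcmc", ch), {
      rates <- apply(Y, 2, function(y) {
        p <- ape::pic(y, arr$tree); mean(p^2)
      })
      shifts <- numeric(0) # named by branch index
      scale_vec <- rep(1, nb)
      ll <- if (prior_only) 0 else axes_loglik(arr, Y, scale_vec, rates)
      lp <- sum(lp_rate(rates)) + lp_count(0)
      n_keep <- floor((iterations - burn_in) / thinning)
      trace <- data.frame(iter = integer(n_keep), logLik = numeric(n_keep),
                          n_shifts = integer(n_keep))
      rate_trace <- matrix(NA_real_, n_keep, k)
      scalar_samp <- matrix(1, n_keep, nb)
      kept <- 0L
      for (it in seq_len(iterations)) {
        move <- sample.int(5, 1)
        if (move == 1) { # update a global rate
          j <- sample.int(k, 1)
          prop <- rates; prop[j] <- prop[j] * exp(stats::rnorm(1, 0, 0.3))
          ll_p <- if (prior_only) 0 else axes_loglik(arr, Y, scale_vec, prop)
          lpr_p <- sum(lp_rate(prop)) + lp_count(length(shifts)) +
            sum(lp_scalar(shifts))
          lpr_c <- sum(lp_rate(rates)) + lp_count(length(shifts)) +
            sum(lp_scalar(shifts))
          # log-scale walk: Jacobian term log(prop/current)
          if (log(stats::runif(1)) < ll_p - ll + lpr_p - lpr_c +
              log(prop[j] / rates[j])) {
            rates <- prop; ll <- ll_p
          }
        } else if (move == 2 && length(shifts)) { # update a shift scalar
          j <- sample.int(length(shifts), 1)
          prop <- shifts
          prop[j] <- prop[j] * exp(stats::rnorm(1, 0, 0.4))
          sv <- scale_vec
          sv[as.integer(names(prop)[j])] <- prop[j]
          ll_p <- if (prior_only) 0 else axes_loglik(arr, Y, sv, rates)
          if (log(stats::runif(1)) < ll_p - ll +
              lp_scalar(prop[j]) - lp_scalar(shifts[j]) +
              log(prop[j] / shifts[j])) {
            shifts <- prop; scale_vec <- sv; ll <- ll_p
          }
        } else if (move == 3) { # birth
          free <- setdiff(seq_len(nb), as.integer(names(shifts)))
          if (length(free)) {
            b <- free[sample.int(length(free), 1)]
            r_new <- exp(stats::runif(1, log(1e-3), log(1e3))) # draw from prior
            sv <- scale_vec; sv[b] <- r_new
            ll_p <- if (prior_only) 0 else axes_loglik(arr, Y, sv, rates)
            m <- length(shifts)
            # scalar proposed from its prior and the uniform-over-subsets
            # placement prior cancel all dimension-matching terms except
            # the shift-count prior ratio
            lacc <- ll_p - ll + (lp_count(m + 1) - lp_count(m))
            if (log(stats::runif(1)) < lacc) {
              shifts <- c(shifts, setNames(r_new, b))
              scale_vec <- sv; ll <- ll_p
            }
          }
        } else if (move == 4 && length(shifts)) { # death
          j <- sample.int(length(shifts), 1)
          b <- as.integer(names(shifts)[j])
          sv <- scale_vec; sv[b] <- 1
          ll_p <- if (prior_only) 0 else axes_loglik(arr, Y, sv, rates)
          m <- length(shifts)
          lacc <- ll_p - ll + (lp_count(m - 1) - lp_count(m))
          if (log(stats::runif(1)) < lacc) {
            shifts <- shifts[-j]; scale_vec <- sv; ll <- ll_p
          }
        } else if (move == 5 && length(shifts)) {
          # relocate a shift to a random free branch (symmetric proposal)
          j <- sample.int(length(shifts), 1)
          b_old <- as.integer(names(shifts)[j])
          free <- setdiff(seq_len(nb), as.integer(names(shifts)))
          if (length(free)) {
            b_new <- free[sample.int(length(free), 1)]
            sv <- scale_vec
            sv[b_old] <- 1
            sv[b_new] <- shifts[j]
            ll_p <- if (prior_only) 0 else axes_loglik(arr, Y, sv, rates)
            if (log(stats::runif(1)) < ll_p - ll) {
              names(shifts)[j] <- b_new
              scale_vec <- sv; ll <- ll_p
            }
          }
        }
        if (it > burn_in && (it - burn_in) %% thinning == 0) {
          kept <- kept + 1L
          trace$iter[kept] <- it
          trace$logLik[kept] <- ll
          trace$n_shifts[kept] <- length(shifts)
          rate_trace[kept, ] <- rates
          scalar_samp[kept, ] <- scale_vec
        }
      }
      colnames(rate_trace) <- paste0("rate_axis", seq_len(k))
      list(trace = cbind(trace, rate_trace), scalars = scalar_samp)
    })
  }
  scalar_samples <- do.call(rbind, lapply(chains, `[[`, "scalars"))
  structure(list(traces = lapply(chains, `[[`, "trace"),
                 branch_scalars = colMeans(scalar_samples),
                 scalar_samples = scalar_samples,
                 tree = arr$tree, seed = seed,
                 settings = list(iterations = iterations, burn_in = burn_in,
                                 thinning = thinning, n_chains = n_chains)),
            class = "rjmcmc_result")
}

#' @export
print.rjmcmc_result <- function(x, ...) {
  ns <- unlist(lapply(x$traces, function(tr) tr$n_shifts))
  cat(sprintf("rjMCMC: %d chains x %d samples; median shift count %d; max branch scalar %.3g\n",
              length(x$traces), nrow(x$traces[[1]]), stats::median(ns),
              max(x$branch_scalars)))
  invisible(x)
}

#' Posterior of regime-specific rates under a regime-partitioned BM model
#'
#' MCMC over per-regime rate scalars: axis j evolves by BM with tip
#' covariance `w_j * sum_k sigma2_k C_k(map)`, where the per-axis weights
#' w_j (first axis fixed at 1) absorb axis scale and the sigma2_k carry the
#' regime signal. Log-uniform priors throughout; REML (contrast)
#' likelihood. Each chain conditions on one stochastic map drawn from the
#' supplied pool by seed, so pooled samples integrate over map uncertainty.
#'
#' @param axis_scores species x k score matrix.
#' @param regime_maps list of `regime_map`s; the map identity is itself a
#'   sampled variable with a uniform prior over the pool, so the posterior
#'   integrates over stochastic-mapping uncertainty.
#' @param iterations,burn_in,thinning,n_chains chain controls.
#' @param seed master seed.
#' @param prior_only likelihood off (prior recovery).
#' @return a `regime_posterior`: `samples` (pooled data.frame of sigma2_k),
#'   `traces` (per chain), `p_greater` (matrix P(sigma_A > sigma_B)),
#'   `overlap` (pairwise overlap proportion; < 0.05 deemed distinct).
#' @export
regime_rate_posterior <- function(axis_scores, regime_maps, iterations = 2e4,
                                  burn_in = floor(iterations / 10),
                                  thinning = 10, n_chains = 2, seed = 1,
                                  prior_only = FALSE) {
  if (iterations <= 0 || thinning <= 0) stopf("iterations and thinning must be positive")
  if (inherits(regime_maps, "regime_map")) regime_maps <- list(regime_maps)
  Y0 <- as.matrix(axis_scores)
  states <- regime_maps[[1]]$states
  K <- length(states)
  k_ax <- ncol(Y0)
  lp_rate <- function(s2) ifelse(s2 >= 1e-10 & s2 <= 1e10, -log(s2), -Inf)
  # precompute pruning arrays and per-edge regime times for every map
  prep <- lapply(regime_maps, function(map) {
    arr <- tree_arrays(map$tree)
    list(arr = arr,
         et = regime_edge_times(map)[match_edges(arr$tree, map$tree), , drop = FALSE],
         Y = Y0[arr$tip.label, , drop = FALSE])
  })
  n_maps <- length(prep)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- with_seed(derive_seed(seed, "regmcmc", ch), {
      mi <- sample.int(n_maps, 1)
      loglik <- function(sig, w, mi) {
        if (prior_only) return(0)
        pp <- prep[[mi]]
        el_eff <- as.vector(pp$et %*% sig)
        sum(vapply(seq_len(k_ax), function(j) {
          bm_reml_loglik_cpp(pp$arr$parent, pp$arr$child, el_eff * w[j],
                             pp$arr$ntip, pp$Y[, j, drop = FALSE], 1)
        }, 0))
      }
      sig <- setNames(rep(mean(apply(prep[[mi]]$Y, 2, function(y)
        mean(ape::pic(y, prep[[mi]]$arr$tree)^2))), K), states)
      w <- rep(1, k_ax)
      ll <- loglik(sig, w, mi)
      n_keep <- floor((iterations - burn_in) / thinning)
      samp <- matrix(NA_real_, n_keep, K, dimnames = list(NULL, states))
      kept <- 0L
      for (it in seq_len(iterations)) {
        # update one regime rate
        j <- sample.int(K, 1)
        prop <- sig; prop[j] <- prop[j] * exp(stats::rnorm(1, 0, 0.4))
        ll_p <- loglik(prop, w, mi)
        if (log(stats::runif(1)) < ll_p - ll + lp_rate(prop[j]) -
            lp_rate(sig[j]) + log(prop[j] / sig[j])) {
          sig <- prop; ll <- ll_p
        }
        # update one axis weight (axis 1 fixed)
        if (k_ax > 1) {
          a <- sample(2:k_ax, 1)
          wp <- w; wp[a] <- wp[a] * exp(stats::rnorm(1, 0, 0.3))
          ll_p <- loglik(sig, wp, mi)
          if (log(stats::runif(1)) < ll_p - ll + lp_rate(wp[a]) -
              lp_rate(w[a]) + log(wp[a] / w[a])) {
            w <- wp; ll <- ll_p
          }
        }
        # switch stochastic map (uniform prior over the pool)
        if (n_maps > 1) {
          mj <- sample.int(n_maps, 1)
          if (mj != mi) {
            ll_p <- loglik(sig, w, mj)
            if (log(stats::runif(1)) < ll_p - ll) {
              mi <- mj; ll <- ll_p
            }
          }
        }
        if (it > burn_in && (it - burn_in) %% thinning == 0) {
          kept <- kept + 1L
          samp[kept, ] <- sig
        }
      }
      samp
    })
  }
  pooled <- do.call(rbind, chains)
  p_greater <- overlap <- matrix(NA_real_, K, K, dimnames = list(states, states))
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (a == b) next
    p_greater[a, b] <- mean(pooled[, a] > pooled[, b])
    overlap[a, b] <- distribution_overlap(log(pooled[, a]), log(pooled[, b]))
  }
  structure(list(samples = as.data.frame(pooled), traces = chains,
                 p_greater = p_greater, overlap = overlap, seed = seed),
            class = "regime_posterior")
}

# Proportion of shared density mass between two samples (histogram
# intersection on a common grid).
distribution_overlap <- function(x, y, nbins = 50) {
  rng <- range(c(x, y))
  brk <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = nbins + 1)
  hx <- graphics::hist(x, breaks = brk, plot = FALSE)$counts / length(x)
  hy <- graphics::hist(y, breaks = brk, plot = FALSE)$counts / length(y)
  sum(pmin(hx, hy))
}

# Match edges of a reordered copy back to the original edge order.
match_edges <- function(reordered, original) {
  key <- function(E) paste(E[, 1], E[, 2])
  match(key(reordered$edge), key(original$edge))
}

#' MCMC convergence diagnostics
#'
#' Rank-normalised across-chain potential scale reduction (R-hat, floored
#' at 1; requires >= 2 chains) and autocorrelation-based effective sample
#' size (Geyer initial monotone sequence) per parameter. Thresholds:
#' R-hat < 1.1 and ESS > 200.
#'
#' @param traces list of per-chain data.frames/matrices with identical
#'   numeric columns.
#' @param rhat_threshold,ess_threshold pass/fail thresholds.
#' @return a `convergence_report` data.frame: parameter, rhat, ess, pass.
#' @export
convergence <- function(traces, rhat_threshold = 1.1, ess_threshold = 200) {
  if (is.data.frame(traces) || is.matrix(traces)) traces <- list(traces)
  traces <- lapply(traces, function(tr) as.matrix(as.data.frame(tr)))
  params <- colnames(traces[[1]])
  params <- params[params != "iter"]
  if (nrow(traces[[1]]) < 50) stopf("need at least 50 samples per chain")
  single <- length(traces) < 2
  if (single) warnf("single chain: R-hat unavailable, reporting ESS only")
  out <- do.call(rbind, lapply(params, function(pp) {
    draws <- vapply(traces, function(tr) tr[, pp], numeric(nrow(traces[[1]])))
    rhat <- if (single) NA_real_ else rhat_rank(draws)
    ess <- sum(apply(draws, 2, ess_geyer))
    data.frame(parameter = pp, rhat = rhat, ess = ess,
               pass = (single || rhat < rhat_threshold) & ess > ess_threshold)
  }))
  class(out) <- c("convergence_report", "data.frame")
  out
}

# Rank-normalised across-chain R-hat (non-split so that identical chains
# give exactly 1), floored at 1.
rhat_rank <- function(draws) {
  nm <- length(draws)
  z <- matrix(stats::qnorm((rank(draws) - 0.5) / nm), nrow(draws), ncol(draws))
  n <- nrow(z); m <- ncol(z)
  mu <- colMeans(z)
  B <- n * stats::var(mu)
  W <- mean(apply(z, 2, stats::var))
  if (B < 1e-14) return(1)
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

# Geyer initial-monotone-sequence ESS for one chain.
ess_geyer <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2, 1000), plot = FALSE)$acf[-1]
  # sum consecutive pairs while positive and decreasing
  npair <- floor(length(rho) / 2)
  gam <- rho[2 * seq_len(npair) - 1] + rho[2 * seq_len(npair)]
  s <- 0
  prev <- Inf
  for (g in gam) {
    g <- min(g, prev)
    if (g <= 0) break
    s <- s + g
    prev <- g
  }
  n / (1 + 2 * s)
}
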