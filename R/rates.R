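# Regime-specific shared-path-length matrices C_k: C_k[i, j] is the time
# spent in regime k along the path from the root to mrca(i, j);
# sum_k C_k equals the Brownian tip covariance of the tree.
regime_vcv <- function(map) {
  tr <- map$tree
  n <- ape::Ntip(tr)
  et <- regime_edge_times(map)
  K <- ncol(et)
  acc <- matrix(0, n + tr$Nnode, K) # per-node regime time from root
  edges <- tr$edge
  for (k in rev(seq_len(nrow(edges)))) # preorder
    acc[edges[k, 2], ] <- acc[edges[k, 1], ] + et[k, ]
  M <- ape::mrca(tr)
  Ck <- lapply(seq_len(K), function(j) {
    Cj <- matrix(acc[M, j], n, n, dimnames = list(tr$tip.label, tr$tip.label))
    diag(Cj) <- acc[seq_len(n), j]
    Cj
  })
  names(Ck) <- colnames(et)
  Ck
}

# Per-axis profiled variances under V(s) = sum_k s_k C_k: the d-th value is
# v_d = (z_d - 1 a_d)' V^-1 (z_d - 1 a_d) / n with a_d the GLS mean.
regime_profile_vars <- function(s, Ck, Z) {
  n <- nrow(Z)
  if (any(!is.finite(s)) || any(s <= 0)) return(NULL)
  V <- Reduce(`+`, Map(`*`, as.list(s), Ck))
  if (any(!is.finite(V))) return(NULL)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  ones <- matrix(1, n, 1)
  w1 <- whiten(L, ones); wZ <- whiten(L, Z)
  if (any(!is.finite(wZ)) || sum(w1^2) < 1e-300) return(NULL)
  a <- gls_mean(Z, w1, wZ)
  W <- wZ - w1 %*% a
  list(v = pmax(colSums(W^2) / n, 1e-300), logdetV = logdet_chol(L))
}

# Profiled log-likelihood for the axis scores Z (full column rank) under
# V(s), treating axes as independent with per-axis variances profiled out.
# Trait correlation is carried by the fixed principal-axis rotation;
# profiling a full trait covariance jointly with the regime scalars is
# unbounded when n is small relative to p, the diagonal profile is not.
regime_profile_loglik <- function(s, Ck, Z) {
  pv <- regime_profile_vars(s, Ck, Z)
  if (is.null(pv)) return(-Inf)
  n <- nrow(Z); r <- ncol(Z)
  -0.5 * (r * pv$logdetV + n * sum(log(pv$v)) + n * r * (1 + log(2 * pi)))
}

#' Regime-specific Brownian-motion rates for multivariate shape data
#'
#' For each stochastic character map, maximises the Brownian likelihood in
#' which the expected species covariance is `sum_k sigma2_k C_k` (a common
#' trait correlation structure with regime-specific scalars), where `C_k`
#' holds the shared branch length spent in regime k. The reported scalar
#' rate per regime is the mean across trait dimensions of that regime's
#' rate-matrix diagonal; summaries aggregate over maps.
#'
#' @param species_shapes species x 3p matrix (or `species_shapes` object).
#' @param regime_maps list of `regime_map`s sharing the species set.
#' @return a `regime_rates`: `rates` (maps x regimes scalar rates),
#'   `mean`, `sd` (per regime across maps), `per_trait` (list of regime x
#'   trait rate diagonals averaged over maps), `unstable` (regimes
#'   occupying < 1% of tree length in some map).
#' @export
regime_bm_rates <- function(species_shapes, regime_maps) {
  Y0 <- as_shape_matrix(species_shapes)
  if (inherits(regime_maps, "regime_map")) regime_maps <- list(regime_maps)
  states <- regime_maps[[1]]$states
  K <- length(states)
  p_full <- ncol(Y0)
  # fixed principal-axis rotation of the shape data carries the common
  # trait correlation structure; the per-map fit estimates per-axis
  # variances and regime scalars
  cen <- colMeans(Y0)
  sv <- svd(sweep(Y0, 2, cen))
  rk <- sum(sv$d > max(sv$d) * 1e-10)
  Vb <- sv$v[, seq_len(rk), drop = FALSE]
  Z0 <- sweep(Y0, 2, cen) %*% Vb
  rownames(Z0) <- rownames(Y0)
  rates <- matrix(NA_real_, length(regime_maps), K,
                  dimnames = list(NULL, states))
  per_trait_acc <- matrix(0, K, p_full, dimnames = list(states, NULL))
  unstable <- character()
  for (mi in seq_along(regime_maps)) {
    map <- regime_maps[[mi]]
    if (!setequal(rownames(Y0), map$tree$tip.label))
      stopf("map %d does not share the species set of the shape matrix", mi)
    Z <- Z0[map$tree$tip.label, , drop = FALSE]
    Ck <- regime_vcv(map)
    frac <- colSums(regime_edge_times(map)) / sum(map$tree$edge.length)
    thin <- names(frac)[frac < 0.01]
    if (length(thin)) unstable <- union(unstable, thin)
    present <- names(frac)[frac > 0]
    Ck_use <- Ck[present]
    # optimise relative scalars with the first present regime fixed at 1
    nfree <- length(present) - 1
    obj <- function(lf) {
      lf <- pmin(pmax(lf, -20), 20)
      -regime_profile_loglik(c(1, exp(lf)), Ck_use, Z)
    }
    if (nfree > 0) {
      op <- stats::optim(rep(0, nfree), obj,
                         method = if (nfree == 1) "Brent" else "Nelder-Mead",
                         lower = if (nfree == 1) -15 else -Inf,
                         upper = if (nfree == 1) 15 else Inf,
                         control = list(maxit = 500))
      s_rel <- c(1, exp(pmin(pmax(op$par, -20), 20)))
    } else s_rel <- 1
    names(s_rel) <- present
    pv <- regime_profile_vars(s_rel, Ck_use, Z)
    # rate-matrix diagonal in the original coordinate basis for regime 1
    diagR <- as.vector(Vb^2 %*% pv$v)
    for (st in present) {
      rates[mi, st] <- s_rel[[st]] * sum(pv$v) / p_full
      per_trait_acc[st, ] <- per_trait_acc[st, ] + s_rel[[st]] * diagR
    }
  }
  per_trait <- per_trait_acc / length(regime_maps)
  structure(list(rates = rates,
                 mean = colMeans(rates, na.rm = TRUE),
                 sd = apply(rates, 2, stats::sd, na.rm = TRUE),
                 per_trait = per_trait,
                 unstable = unstable),
            class = "regime_rates")
}

#' @export
print.regime_rates <- function(x, ...) {
  cat("regime BM rates (mean over maps):\n")
  print(signif(x$mean, 6))
  if (length(x$unstable))
    cat(" unstable (regime < 1% of tree length):",
        paste(x$unstable, collapse = ", "), "\n")
  invisible(x)
}

#' Fold changes between regime rates
#'
#' fold(A, reference) = sigma2_A / sigma2_reference, rounded to 3 decimals
#' for reporting.
#' @param rates named numeric vector of per-regime rates, or a
#'   `regime_rates` (its `mean` is used).
#' @param reference regime name (default: the regime with the largest
#'   rate is the numerator against each other regime).
#' @return data.frame `regime`, `reference`, `fold_change`.
#' @export
rate_fold_changes <- function(rates, reference = NULL) {
  if (inherits(rates, "regime_rates")) rates <- rates$mean
  if (length(rates) < 2) stopf("need at least 2 regimes")
  if (any(rates == 0)) stopf("zero rate: fold change undefined")
  ref <- reference %||% names(which.max(rates))
  out <- data.frame(regime = ref, reference = names(rates),
                    fold_change = round(rates[[ref]] / unname(rates), 3),
                    row.names = NULL)
  out[out$reference != ref, , drop = FALSE]
}

#' Per-landmark evolutionary rates
#'
#' Aggregates the regime rate-matrix diagonal per landmark (the sum of its
#' three coordinate rates), for heat-map display on the consensus shape.
#' The per-landmark rates of a regime sum to 3p x its scalar rate.
#' @param rates a `regime_rates` from [regime_bm_rates()].
#' @param scheme the [landmark_scheme()] (gives p).
#' @return landmark x regime matrix.
#' @export
per_landmark_rates <- function(rates, scheme) {
  pt <- rates$per_trait
  p <- scheme$p
  if (ncol(pt) != 3 * p) stopf("trait count %d is not 3 x p = %d", ncol(pt), 3 * p)
  lm_idx <- rep(seq_len(p), each = 3)
  out <- t(apply(pt, 1, function(v) tapply(v, lm_idx, sum)))
  t(out) # landmark x regime
}

#' Morphological disparity (Procrustes variance) by group
#'
#' PV_g = sum over coordinates of within-group variances = mean squared
#' deviation from the group mean shape (divisor n). Groups are compared by
#' two-sided Wilcoxon rank-sum tests on within-group bootstrap
#' distributions (resampling species with replacement), Bonferroni-adjusted
#' over the number of pairs.
#'
#' @param species_shapes species x q matrix (rownames = species).
#' @param grouping named character/factor over species.
#' @param n_boot bootstrap replicates per group.
#' @param seed RNG seed.
#' @return a `disparity_result`: `pv` (per group), `boot` (n_boot x group
#'   matrix), `pairwise_p` (Bonferroni-adjusted), `pairwise_p_raw`,
#'   `excluded` (singleton groups).
#' @export
group_disparity <- function(species_shapes, grouping, n_boot = 100, seed = NULL) {
  Y <- as_shape_matrix(species_shapes)
  grouping <- grouping[rownames(Y)]
  if (anyNA(grouping)) stopf("every species needs a group")
  groups <- sort(unique(as.character(grouping)))
  pv_of <- function(M) {
    if (nrow(M) < 2) return(0)
    mu <- colMeans(M)
    sum(sweep(M, 2, mu)^2) / nrow(M)
  }
  pv <- setNames(vapply(groups, function(g)
    pv_of(Y[grouping == g, , drop = FALSE]), 0), groups)
  singletons <- groups[table(factor(grouping, groups)) < 2]
  if (length(singletons))
    warnf("group(s) with a single member have PV = 0 and are excluded from tests: %s",
          paste(singletons, collapse = ", "))
  testable <- setdiff(groups, singletons)
  boot <- with_seed(seed, {
    sapply(groups, function(g) {
      M <- Y[grouping == g, , drop = FALSE]
      vapply(seq_len(n_boot), function(b)
        pv_of(M[sample.int(nrow(M), replace = TRUE), , drop = FALSE]), 0)
    })
  })
  pairs_ <- if (length(testable) >= 2) utils::combn(testable, 2) else NULL
  praw <- padj <- matrix(NA_real_, length(groups), length(groups),
                         dimnames = list(groups, groups))
  if (!is.null(pairs_)) {
    pvec <- apply(pairs_, 2, function(pr)
      suppressWarnings(stats::wilcox.test(boot[, pr[1]], boot[, pr[2]])$p.value))
    pvec_adj <- pmin(1, pvec * ncol(pairs_)) # Bonferroni
    for (j in seq_len(ncol(pairs_))) {
      a <- pairs_[1, j]; b <- pairs_[2, j]
      praw[a, b] <- praw[b, a] <- pvec[j]
      padj[a, b] <- padj[b, a] <- pvec_adj[j]
    }
  }
  structure(list(pv = pv, boot = boot, pairwise_p = padj,
                 pairwise_p_raw = praw, excluded = singletons,
                 n_boot = n_boot),
            class = "disparity_result")
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("Procrustes variance by group:\n")
  print(signif(x$pv, 4))
  invisible(x)
}

#' Disparity through time with a Brownian-motion envelope
#'
#' At each internal-node relative height, the mean Procrustes variance of
#' the subclades whose stem crosses that time, normalised by the disparity
#' of the full sample (so the value at relative time 0 is 1); singleton
#' lineages contribute 0. The null envelope is built from `n_sim`
#' multivariate BM simulations rate-matched to the data (contrast
#' covariance), with per-time 2.5/97.5 percentiles, and an area-between-
#' curves statistic (observed minus simulation mean, integrated over
#' relative time; the MDI analogue).
#'
#' @param species_shapes species x q matrix.
#' @param tree ultrametric ape `phylo` (>= 4 tips).
#' @param n_sim BM simulations for the envelope.
#' @param seed RNG seed.
#' @return a `dtt_curve`: `time` (relative), `observed`, `lo`, `hi`,
#'   `sim_mean`, `mdi`.
#' @export
dtt <- function(species_shapes, tree, n_sim = 1000, seed = NULL) {
  Y <- as_shape_matrix(species_shapes)
  tree <- check_tree(tree)
  if (ape::Ntip(tree) < 4) stopf("DTT needs at least 4 tips")
  if (!is_ultrametric(tree))
    stopf("DTT needs an ultrametric tree; time-calibrate or chronos() it first")
  Y <- Y[tree$tip.label, , drop = FALSE]
  obs <- dtt_curve(Y, tree)
  R <- contrast_rate_matrix(Y, tree)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(b) {
      Yb <- simulate_bm_on_tree(tree, R)
      dtt_curve(Yb, tree)$disparity
    }, numeric(length(obs$disparity)))
  })
  lo <- apply(sims, 1, stats::quantile, 0.025)
  hi <- apply(sims, 1, stats::quantile, 0.975)
  sim_mean <- rowMeans(sims)
  tgrid <- obs$time
  wts <- diff(c(tgrid, 1))
  mdi <- sum((obs$disparity - sim_mean) * wts)
  structure(list(time = tgrid, observed = obs$disparity, lo = lo, hi = hi,
                 sim_mean = sim_mean, mdi = mdi, n_sim = n_sim),
            class = "dtt_curve")
}

# Observed mean relative subclade disparity at each internal-node height.
dtt_curve <- function(Y, tree) {
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  H <- max(h[seq_len(n)])
  int_nodes <- (n + 1):(n + tree$Nnode)
  times <- sort(unique(h[int_nodes])) / H
  pv_of <- function(M) {
    if (nrow(M) < 2) return(0)
    mu <- colMeans(M)
    sum(sweep(M, 2, mu)^2) / nrow(M)
  }
  total <- pv_of(Y)
  tips_below <- tips_under_nodes(tree)
  edges <- tree$edge
  disp <- vapply(times, function(tt) {
    if (tt <= 1e-12) return(1) # at the root the single lineage is the clade
    # lineages present just before the divergence at time tt
    t_abs <- tt * H - 1e-9 * H
    crossing <- which(h[edges[, 1]] <= t_abs & h[edges[, 2]] > t_abs)
    if (!length(crossing)) return(0)
    vals <- vapply(crossing, function(k) {
      ch <- edges[k, 2]
      tipset <- if (ch <= n) ch else tips_below[[ch - n]]
      pv_of(Y[tipset, , drop = FALSE])
    }, 0)
    mean(vals) / total
  }, 0)
  list(time = times, disparity = disp)
}

tips_under_nodes <- function(tree) {
  n <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  below[(n + 1):(n + tr$Nnode)]
}

# REML trait covariance from phylogenetically independent contrasts.
contrast_rate_matrix <- function(Y, tree) {
  pics <- apply(Y, 2, function(y) ape::pic(y, tree))
  crossprod(as.matrix(pics)) / nrow(pics)
}

#' Plot a DTT curve
#' @param x a `dtt_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dtt_curve <- function(x, ...) {
  graphics::plot(x$time, x$observed, type = "l", lwd = 2,
                 xlab = "relative time", ylab = "mean subclade disparity",
                 ylim = range(c(x$observed, x$lo, x$hi)), ...)
  graphics::polygon(c(x$time, rev(x$time)), c(x$lo, rev(x$hi)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(x$time, x$sim_mean, lty = 2)
  graphics::lines(x$time, x$observed, lwd = 2)
  invisible(x)
}
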