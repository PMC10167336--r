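#' Principal component analysis of shape data
#'
#' SVD of the column-centered matrix; axes ordered by decreasing
#' eigenvalue, with the sign convention that each axis's
#' largest-magnitude loading is positive.
#'
#' @param shape_matrix n x q numeric matrix (rows = specimens or species),
#'   or a `species_shapes` object.
#' @return an `ordination`: `scores`, `loadings`, `eigenvalues`,
#'   `percent` (variance explained per axis, sums to 100), `center`,
#'   `kind = "pca"`.
#' @export
shape_pca <- function(shape_matrix) {
  Y <- as_shape_matrix(shape_matrix)
  if (nrow(Y) < 3) stopf("PCA needs at least 3 rows")
  cen <- colMeans(Y)
  Yc <- sweep(Y, 2, cen)
  s <- svd(Yc)
  k <- sum(s$d > max(s$d) * 1e-12)
  if (k == 0) {
    warnf("constant matrix: all eigenvalues are zero")
    k <- 1
  }
  eig <- s$d^2 / (nrow(Y) - 1)
  V <- s$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  scores <- Yc %*% V
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = V, eigenvalues = eig[seq_len(k)],
                 percent = 100 * eig[seq_len(k)] / sum(eig),
                 center = cen, kind = "pca"),
            class = "ordination")
}

as_shape_matrix <- function(x) {
  if (inherits(x, "species_shapes")) x$shapes
  else if (inherits(x, "aligned_sample"))
    t(vapply(x$coords, flatten_config, numeric(3 * nrow(x$consensus))))
  else as.matrix(x)
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d axes; axis 1 explains %.2f%% of variance\n",
              toupper(x$kind), ncol(x$scores), x$percent[1]))
  invisible(x)
}

#' Phylogenetically aligned component analysis
#'
#' Centers the data on the GLS (phylogenetic) mean and extracts axes from
#' the eigen-decomposition of the cross-product of the data with its
#' projection through the tip covariance of the tree (the "aligned"
#' flavour of PaCA), so leading axes maximise variation aligned with
#' phylogenetic signal. Percent explained is relative to total data
#' variance and so need not decrease monotonically nor reach 100 on the
#' first axes.
#'
#' @param shape_matrix species x q matrix with rownames = species ids.
#' @param tree an ape `phylo`; tips must match the rownames.
#' @return an `ordination` with `kind = "papca"`.
#' @export
papca <- function(shape_matrix, tree) {
  Y <- as_shape_matrix(shape_matrix)
  tree <- check_tree(tree)
  if (is.null(rownames(Y))) stopf("shape matrix needs species rownames")
  if (!setequal(rownames(Y), tree$tip.label))
    stopf("species do not match tree tips")
  Y <- Y[tree$tip.label, , drop = FALSE]
  C <- ape::vcv(tree)
  L <- chol_safe(C, "tree")
  ones <- matrix(1, nrow(Y), 1)
  w1 <- whiten(L, ones); wY <- whiten(L, Y)
  a <- gls_mean(Y, w1, wY)
  Yc <- sweep(Y, 2, as.vector(a))
  M <- crossprod(Yc, C %*% Yc)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  k <- sum(e$values > max(e$values) * 1e-12)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  scores <- Yc %*% V
  total_var <- sum(apply(Yc, 2, function(v) sum(v^2))) / (nrow(Y) - 1)
  axis_var <- apply(scores, 2, function(v) sum(v^2)) / (nrow(Y) - 1)
  colnames(scores) <- colnames(V) <- paste0("PaPC", seq_len(k))
  structure(list(scores = scores, loadings = V, eigenvalues = e$values[seq_len(k)],
                 percent = 100 * axis_var / total_var,
                 center = as.vector(a), kind = "papca"),
            class = "ordination")
}

#' Multivariate phylogenetic signal (Kmult)
#'
#' Multivariate generalisation of Blomberg's K: the ratio of the observed
#' mean squared deviation from the phylogenetic mean in ordinary versus
#' phylogenetically whitened space, scaled by its Brownian-motion
#' expectation under the tree covariance. K = 1 for data evolving by BM on
#' the tree; K < 1 indicates less signal than BM. Significance is assessed
#' by permuting species across tips.
#'
#' @param shape_matrix species x q matrix, rownames = species ids (a single
#'   column gives univariate Blomberg's K).
#' @param tree ape `phylo`.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return a `signal_result`: `K`, `p_value`, `n_perm`, `perm_K`.
#' @export
kmult <- function(shape_matrix, tree, n_perm = 999, seed = NULL) {
  Y <- as_shape_matrix(shape_matrix)
  tree <- check_tree(tree)
  if (nrow(Y) < 4) stopf("Kmult needs at least 4 species")
  if (!setequal(rownames(Y), tree$tip.label)) stopf("species do not match tree tips")
  Y <- Y[tree$tip.label, , drop = FALSE]
  n <- nrow(Y)
  C <- ape::vcv(tree)
  Ci <- solve(C)
  ones <- matrix(1, n, 1)
  denom_expect <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  k_stat <- function(Y) {
    a <- (crossprod(ones, Ci %*% Y)) / sum(Ci)
    E <- sweep(Y, 2, as.vector(a))
    num <- sum(E^2)
    den <- sum(E * (Ci %*% E))
    (num / den) / denom_expect
  }
  K_obs <- k_stat(Y)
  perm_K <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    k_stat(Y[sample.int(n), , drop = FALSE])
  }, 0))
  p <- (sum(perm_K >= K_obs) + 1) / (n_perm + 1)
  structure(list(K = K_obs, p_value = p, n_perm = n_perm, perm_K = perm_K),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Kmult = %.4f, p = %.4g (%d permutations)\n",
              x$K, x$p_value, x$n_perm))
  invisible(x)
}

#' Number of meaningful ordination axes
#'
#' Sequential log-likelihood ratio (Bartlett-type) test on the eigenvalue
#' spectrum: returns the smallest k such that the remaining eigenvalues
#' are statistically homogeneous (isotropic residual) at `alpha`, i.e. the
#' axes up to k each significantly improve the eigenvalue-structure
#' likelihood. Deterministic.
#'
#' @param ordination an `ordination` (or a numeric eigenvalue vector).
#' @param n_samples number of rows the ordination was computed from.
#' @param alpha test level.
#' @return integer count >= 1.
#' @export
meaningful_pcs <- function(ordination, n_samples, alpha = 0.05) {
  ev <- if (inherits(ordination, "ordination")) ordination$eigenvalues
        else as.numeric(ordination)
  ev <- ev[ev > max(ev) * 1e-12]
  m <- length(ev)
  if (m < 2) return(1L)
  for (k in 0:(m - 2)) {
    rest <- ev[(k + 1):m]
    r <- length(rest)
    # Bartlett-corrected likelihood-ratio statistic for homogeneity of the
    # trailing r eigenvalues
    stat <- (n_samples - 1 - k - (2 * r + 1 + 2 / r) / 6) *
      (r * log(mean(rest)) - sum(log(rest)))
    df <- (r + 2) * (r - 1) / 2
    if (stats::pchisq(stat, df, lower.tail = FALSE) > alpha)
      return(max(1L, k))
  }
  as.integer(m - 1)
}

#' Functional proxies from aligned jaw configurations
#'
#' Mechanical advantage (MA) = in-lever / out-lever, with the out-lever the
#' distance from the articular-condyle landmark to the anterior symphysis
#' landmark, and the in-lever the distance from the condyle to the centroid
#' of the adductor-insertion surface landmarks. Symphysis depth is the
#' distance between two symphysis-margin landmarks. All landmark indices
#' are configurable; on unit-centroid-size aligned shapes both proxies are
#' scale-invariant.
#'
#' @param aligned an `aligned_sample` or named list of p x 3 matrices.
#' @param condyle,symphysis landmark indices.
#' @param insertion indices of the adductor-insertion landmarks (centroid
#'   used as the in-lever endpoint).
#' @param symphysis_pair two indices spanning the symphysis depth.
#' @return data.frame with `ma` and `symphysis_depth` per configuration.
#' @export
functional_proxies <- function(aligned, condyle = 2L, symphysis = 1L,
                               insertion = NULL, symphysis_pair = c(1L, 3L)) {
  coords <- if (inherits(aligned, "aligned_sample")) aligned$coords else aligned
  scheme <- if (inherits(aligned, "aligned_sample")) aligned$scheme else NULL
  if (is.null(insertion)) {
    insertion <- if (!is.null(scheme) && length(scheme$surface))
      scheme$surface else seq_len(nrow(coords[[1]]))
  }
  res <- t(vapply(coords, function(x) {
    out_lever <- sqrt(sum((x[condyle, ] - x[symphysis, ])^2))
    ins <- colMeans(x[insertion, , drop = FALSE])
    in_lever <- sqrt(sum((x[condyle, ] - ins)^2))
    depth <- sqrt(sum((x[symphysis_pair[1], ] - x[symphysis_pair[2], ])^2))
    c(ma = in_lever / out_lever, symphysis_depth = depth)
  }, numeric(2)))
  data.frame(res)
}

#' Correlate a functional proxy with an ordination axis
#'
#' Pearson correlation with a two-sided p-value from the t distribution.
#' @param proxy numeric vector (named, matched to score rownames when both
#'   are named).
#' @param ordination an `ordination`.
#' @param axis axis number.
#' @return list with `r`, `p_value`, `n`.
#' @export
functional_correlations <- function(proxy, ordination, axis = 1) {
  scores <- ordination$scores[, axis]
  if (!is.null(names(proxy)) && !is.null(rownames(ordination$scores)))
    proxy <- proxy[rownames(ordination$scores)]
  if (stats::sd(proxy) == 0 || stats::sd(scores) == 0)
    stopf("zero variance in proxy or scores: correlation undefined")
  ct <- stats::cor.test(proxy, scores)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(proxy))
}

#' Phylomorphospace plot
#'
#' Scatter of tip scores on two ordination axes with maximum-likelihood
#' ancestral estimates projected on the same axes and connected by the tree
#' edges.
#' @param ordination an `ordination` computed on species means.
#' @param tree ape `phylo` matching the score rownames.
#' @param axes two axis indices.
#' @param col point colours (named by species or in score row order).
#' @param ... passed to [graphics::plot()].
#' @export
phylomorphospace_plot <- function(ordination, tree, axes = c(1, 2),
                                  col = "black", ...) {
  sc <- ordination$scores[tree$tip.label, axes, drop = FALSE]
  anc <- ancestral_states_continuous(sc, tree)
  all_xy <- rbind(sc, anc)
  graphics::plot(all_xy[, 1], all_xy[, 2], type = "n",
                 xlab = colnames(sc)[1], ylab = colnames(sc)[2], ...)
  n <- ape::Ntip(tree)
  node_xy <- rbind(sc, anc)
  for (k in seq_len(nrow(tree$edge))) {
    e <- tree$edge[k, ]
    graphics::segments(node_xy[e[1], 1], node_xy[e[1], 2],
                       node_xy[e[2], 1], node_xy[e[2], 2], col = "grey60")
  }
  graphics::points(sc[, 1], sc[, 2], pch = 19, col = col)
  invisible(node_xy)
}
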