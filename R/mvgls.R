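# Model-specific transforms of the Brownian tip covariance C.
# lambda: off-diagonals scaled by lambda; EB: accumulated variance
# (exp(r t) - 1)/r elementwise on shared heights; OU: stationary transform
# on an ultrametric tree.
transform_vcv <- function(C, model, par) {
  switch(model,
    BM = C,
    lambda = {
      Cl <- par * C
      diag(Cl) <- diag(C)
      Cl
    },
    EB = {
      if (abs(par) < 1e-10) C else (exp(par * C) - 1) / par
    },
    OU = {
      if (par < 1e-10) return(C)
      Tmax <- max(diag(C))
      (1 / (2 * par)) * exp(-2 * par * (Tmax - C)) * (1 - exp(-2 * par * C))
    },
    stopf("unknown model '%s'", model))
}

model_par_bounds <- function(model, tree_height = 1) {
  switch(model,
    BM = c(0, 0),
    lambda = c(0, 1),
    EB = c(-20 / tree_height, 0),
    OU = c(0, 50 / tree_height))
}

#' Multivariate phylogenetic linear model by penalized likelihood
#'
#' Fits Y = X B + E with matrix-normal errors whose row covariance is a
#' model-transformed tree covariance (Pagel's lambda, BM, early burst, or
#' OU) and whose trait covariance is estimated by ridge-regularised maximum
#' likelihood, shrinking the sample covariance of the whitened residuals
#' toward its diagonal. The shrinkage weight is chosen by leave-one-out
#' cross-validated likelihood over a log-spaced grid (with a rank-one
#' downdate approximation; coefficients are held fixed across folds), which
#' permits n < p. The model parameter (lambda, r, or alpha) is optimised by
#' bounded one-dimensional search of the cross-validated objective.
#'
#' @param Y species x p response matrix, rownames = species ids.
#' @param X design matrix (species x q) including the intercept, or `NULL`
#'   for an intercept-only fit.
#' @param tree ape `phylo`.
#' @param model one of `"lambda"`, `"BM"`, `"EB"`, `"OU"`.
#' @param penalty_grid shrinkage weights in (0, 1]; default 10 log-spaced
#'   points.
#' @return an `mvgls_fit`: `B`, `Sigma`, `model`, `par` (lambda/r/alpha),
#'   `penalty`, `logLik`, `GIC`, plus whitened residuals.
#' @export
mvgls_fit <- function(Y, X = NULL, tree, model = c("lambda", "BM", "EB", "OU"),
                      penalty_grid = 10^seq(-4, 0, length.out = 10)) {
  model <- match.arg(model)
  if (!length(penalty_grid)) stopf("penalty grid is empty")
  Y <- as_shape_matrix(Y)
  tree <- check_tree(tree)
  if (!setequal(rownames(Y), tree$tip.label)) stopf("Y rows do not match tree tips")
  Y <- Y[tree$tip.label, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(tree$tip.label, "(Intercept)"))
  else X <- as.matrix(X)[tree$tip.label, , drop = FALSE]
  C <- ape::vcv(tree)
  if (max(abs(Y - Y[rep(1, n), ])) < 1e-14)
    warnf("response is identical across species: trait covariance is degenerate")

  eval_par <- function(par) {
    Cm <- transform_vcv(C, model, par)
    L <- chol_safe(Cm, "tree")
    Z <- whiten(L, Y); Xw <- whiten(L, X)
    qrX <- qr(Xw)
    B <- qr.coef(qrX, Z)
    B[is.na(B)] <- 0
    R <- Z - Xw %*% B
    S <- crossprod(R) / n
    Dg <- diag(diag(S), p)
    # Jacobian of the whitening transform: without it the CV score is not
    # comparable across model parameters (lambda, r, alpha)
    jac <- 0.5 * p * logdet_chol(L)
    best <- list(score = Inf, h = NA)
    for (h in penalty_grid) {
      Sig <- (1 - h) * S + h * Dg
      ih <- tryCatch(solve(Sig), error = function(e) NULL)
      if (is.null(ih)) next
      ld <- determinant(Sig, logarithm = TRUE)$modulus
      cst <- (1 - h) / (n - 1)
      score <- 0
      ok <- TRUE
      for (i in seq_len(n)) {
        r_i <- R[i, ]
        ir <- ih %*% r_i
        g <- cst * sum(r_i * ir)
        if (g >= 1) { ok <- FALSE; break }  # downdate not PD
        ld_i <- ld + log(1 - g)
        quad_i <- sum(r_i * ir) + cst * sum(r_i * ir)^2 / (1 - g)
        score <- score + 0.5 * (ld_i + quad_i + p * log(2 * pi))
      }
      if (ok && score + jac < best$score) best <- list(score = score + jac, h = h)
    }
    if (!is.finite(best$score)) stopf("no admissible penalty in the grid")
    Sig <- (1 - best$h) * S + best$h * Dg
    ldC <- logdet_chol(L)
    ldS <- determinant(Sig, logarithm = TRUE)$modulus
    quad <- sum(diag(solve(Sig, crossprod(R))))
    ll <- -0.5 * (n * p * log(2 * pi) + p * ldC + n * ldS + quad)
    list(score = best$score, h = best$h, B = B, Sigma = Sig, logLik = as.numeric(ll),
         R = R, L = L, par = par, qrX = qrX)
  }

  bounds <- model_par_bounds(model, tree_height(tree))
  fit <- if (model == "BM") eval_par(0)
  else {
    opt <- stats::optimize(function(par) eval_par(par)$score,
                           interval = bounds, tol = 1e-4)
    eval_par(opt$minimum)
  }
  q <- ncol(X)
  df <- q * p + p + (1 - fit$h) * p * (p - 1) / 2 + (model != "BM")
  gic <- -2 * fit$logLik + 2 * df
  structure(list(B = fit$B, Sigma = fit$Sigma, model = model, par = fit$par,
                 penalty = fit$h, logLik = fit$logLik, GIC = gic, df = df,
                 residuals = fit$R, L = fit$L, X = X, Y = Y, tree = tree,
                 cv_score = fit$score),
            class = "mvgls_fit")
}

#' @export
print.mvgls_fit <- function(x, ...) {
  parname <- switch(x$model, lambda = "lambda", EB = "r", OU = "alpha", BM = "")
  cat(sprintf("mvgls fit [%s%s]: logLik = %.2f, GIC = %.2f, penalty = %.3g\n",
              x$model,
              if (nzchar(parname)) sprintf(", %s = %.4g", parname, x$par) else "",
              x$logLik, x$GIC, x$penalty))
  invisible(x)
}

#' Trait-evolution model selection by GIC
#'
#' Fits each candidate model with [mvgls_fit()] (intercept-only design) and
#' ranks them by the generalized information criterion (-2 logLik plus a
#' bias-correction term for the penalized covariance estimate).
#' @param Y species x p matrix.
#' @param tree ape `phylo` (>= 8 species).
#' @param models candidate models.
#' @return list of fits sorted ascending by GIC; attribute `table` is a
#'   data.frame of logLik/GIC per model.
#' @export
model_selection_gic <- function(Y, tree, models = c("BM", "EB", "OU")) {
  Y <- as_shape_matrix(Y)
  if (nrow(Y) < 8) stopf("model selection needs at least 8 species")
  fits <- list()
  for (m in models) {
    fits[[m]] <- tryCatch(mvgls_fit(Y, NULL, tree, model = m),
                          error = function(e) {
                            warnf("model %s failed: %s", m, conditionMessage(e))
                            NULL
                          })
  }
  fits <- Filter(Negate(is.null), fits)
  ord <- order(vapply(fits, function(f) f$GIC, 0))
  fits <- fits[ord]
  attr(fits, "table") <- data.frame(
    model = names(fits),
    par = vapply(fits, function(f) f$par, 0),
    logLik = vapply(fits, function(f) f$logLik, 0),
    GIC = vapply(fits, function(f) f$GIC, 0),
    row.names = NULL)
  fits
}

# Wilks' lambda from error and hypothesis cross-product matrices, computed
# in a common full-rank basis so n < p is handled.
wilks_lambda <- function(E, H, rank_basis) {
  Eb <- crossprod(rank_basis, E %*% rank_basis)
  Hb <- crossprod(rank_basis, H %*% rank_basis)
  lam <- tryCatch({
    ev <- Re(eigen(solve(Eb, Hb), only.values = TRUE)$values)
    prod(1 / (1 + pmax(ev, 0)))
  }, error = function(e) NA_real_)
  lam
}

rao_F <- function(lambda, p, q_h, df_e) {
  # Rao's F approximation for Wilks' lambda
  s <- sqrt((p^2 * q_h^2 - 4) / (p^2 + q_h^2 - 5))
  if (!is.finite(s) || s == 0) s <- 1
  df1 <- p * q_h
  df2 <- s * (df_e - (p - q_h + 1) / 2) - (p * q_h - 2) / 2
  Fv <- ((1 - lambda^(1 / s)) / lambda^(1 / s)) * df2 / df1
  list(F = Fv, df1 = df1, df2 = df2)
}

#' Phylogenetic MANOVA / MANCOVA (type II, permutation tests)
#'
#' Fits a multivariate phylogenetic linear model (via [mvgls_fit()], with
#' Pagel's lambda by default) and tests each term with Wilks' lambda
#' computed from the generalized sums of squares in the phylogenetically
#' whitened space. Terms are assessed type-II style: each term is compared
#' against the model containing all other terms of equal or lower order
#' that do not involve it. Significance is by Freedman-Lane permutation of
#' reduced-model residuals in the whitened space.
#'
#' @param Y species x p response matrix, rownames = species.
#' @param data data.frame of predictors (factors and/or numeric), rownames
#'   = species.
#' @param terms character vector of model terms, e.g.
#'   `c("logCS", "habitat", "logCS:habitat")`.
#' @param tree ape `phylo`.
#' @param model covariance model passed to [mvgls_fit()].
#' @param n_perm permutations per term.
#' @param seed RNG seed.
#' @return a `manova_table` data.frame: term, Wilks, F, Z (permutation
#'   effect size), p_perm; attribute `lambda` is the fitted model
#'   parameter.
#' @export
manova_type2 <- function(Y, data, terms, tree, model = "lambda",
                         n_perm = 999, seed = NULL) {
  Y <- as_shape_matrix(Y)
  tree <- check_tree(tree)
  Y <- Y[tree$tip.label, , drop = FALSE]
  data <- data[tree$tip.label, , drop = FALSE]
  n <- nrow(Y)
  for (v in names(data)) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]])) {
      tab <- table(data[[v]])
      if (length(tab) < 2 && v %in% unlist(strsplit(terms, ":")))
        stopf("factor '%s' has a single level", v)
      if (any(tab < 2)) warnf("factor '%s' has level(s) with < 2 species", v)
    }
  }
  full_formula <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  full_fit <- mvgls_fit(Y, stats::model.matrix(full_formula, data), tree, model = model)
  L <- full_fit$L
  Z <- whiten(L, Y)

  mm_for <- function(tms) {
    if (!length(tms)) matrix(1, n, 1)
    else stats::model.matrix(stats::as.formula(paste("~", paste(tms, collapse = " + "))), data)
  }
  resid_cp <- function(Xw, Zresp) {
    qrX <- qr(Xw)
    R <- Zresp - Xw %*% qr.coef(qrX, Zresp)
    R[is.na(R)] <- 0
    R
  }
  order_of <- function(t) length(strsplit(t, ":")[[1]])
  involves <- function(t, v) v %in% strsplit(t, ":")[[1]]

  rows <- list()
  set <- with_seed(seed, {
    lapply(terms, function(tm) {
      # type II: reduced model excludes tm and any term containing its factors
      # at equal or higher order
      others <- setdiff(terms, tm)
      keep <- others[!vapply(others, function(o) {
        all(strsplit(tm, ":")[[1]] %in% strsplit(o, ":")[[1]])
      }, TRUE)]
      X_red <- whiten(L, mm_for(keep))
      X_full <- whiten(L, mm_for(c(keep, tm)))
      R_red <- resid_cp(X_red, Z)
      R_full <- resid_cp(X_full, Z)
      E <- crossprod(R_full)
      H <- crossprod(R_red) - E
      q_h <- qr(X_full)$rank - qr(X_red)$rank
      basis <- svd(R_red, nu = 0)$v[, seq_len(min(n - qr(X_full)$rank, ncol(Y))), drop = FALSE]
      lam_obs <- wilks_lambda(E, H, basis)
      fit_red <- X_red %*% qr.coef(qr(X_red), Z)
      fit_red[is.na(fit_red)] <- 0
      perm_lam <- vapply(seq_len(n_perm), function(b) {
        Zb <- fit_red + R_red[sample.int(n), , drop = FALSE]
        Rf <- resid_cp(X_full, Zb)
        Rr <- resid_cp(X_red, Zb)
        Eb <- crossprod(Rf)
        Hb <- crossprod(Rr) - Eb
        wilks_lambda(Eb, Hb, basis)
      }, 0)
      p_perm <- (sum(perm_lam <= lam_obs, na.rm = TRUE) + 1) / (n_perm + 1)
      lw <- -log(pmax(perm_lam, 1e-300))
      Zscore <- (-log(max(lam_obs, 1e-300)) - mean(lw)) / max(stats::sd(lw), 1e-12)
      rF <- rao_F(lam_obs, ncol(basis), q_h, n - qr(X_full)$rank)
      data.frame(term = tm, Wilks = lam_obs, F = rF$F, Z = Zscore,
                 p_perm = p_perm, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, set)
  attr(out, "lambda") <- full_fit$par
  attr(out, "model") <- model
  attr(out, "n_perm") <- n_perm
  class(out) <- c("manova_table", "data.frame")
  out
}

#' Maximum-likelihood ancestral states for continuous traits
#'
#' Brownian-motion ML reconstruction at every internal node, obtained as
#' the solution of the weighted (1/branch-length) tree Laplacian system --
#' equivalent to the GLS solution built from the full tree covariance. The
#' root of a two-tip tree is the branch-length-inverse-weighted average of
#' the tips.
#'
#' @param Y species x p matrix (or vector) with rownames/names = species.
#' @param tree ape `phylo`.
#' @return matrix of internal-node states (rows named by node number,
#'   root first per ape convention).
#' @export
ancestral_states_continuous <- function(Y, tree) {
  tree <- check_tree(tree)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1, dimnames = list(names(Y), NULL))
  Y <- as_shape_matrix(Y)
  Y <- Y[tree$tip.label, , drop = FALSE]
  n <- ape::Ntip(tree); m <- tree$Nnode
  el <- tree$edge.length
  if (any(el <= 0)) {
    warnf("zero-length branch(es): weights capped")
    el <- pmax(el, 1e-8 * max(el))
  }
  w <- 1 / el
  # weighted Laplacian over all nodes, partitioned into tips / internals
  A <- matrix(0, n + m, n + m)
  for (k in seq_len(nrow(tree$edge))) {
    i <- tree$edge[k, 1]; j <- tree$edge[k, 2]
    A[i, j] <- A[i, j] + w[k]; A[j, i] <- A[j, i] + w[k]
  }
  Dg <- diag(rowSums(A))
  Lap <- Dg - A
  int <- (n + 1):(n + m)
  tipid <- seq_len(n)
  anc <- solve(Lap[int, int, drop = FALSE],
               -Lap[int, tipid, drop = FALSE] %*% Y)
  rownames(anc) <- as.character(int)
  anc
}
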