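#' @useDynLib morphoclade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var cor sd optim optimize rnorm runif rexp quantile
#'   setNames pchisq pf pt p.adjust wilcox.test cor.test cutree hclust
#'   as.dist cophenetic prcomp rmultinom rgamma qnorm qbeta acf aggregate
#' @importFrom utils head tail read.csv write.csv
NULL

#' Derive a child RNG seed from a master seed
#'
#' Deterministically hashes the master seed together with any number of
#' labels into an integer below 2^31, so one pipeline seed can drive many
#' independent random stages reproducibly.
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the stage.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483587L
  as.integer(h + 1L)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Flatten a p x 3 configuration to a length-3p row (x1,y1,z1,x2,...).
flatten_config <- function(x) as.vector(t(x))
unflatten_config <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# Checks that a tree is rooted, binary-or-multifurcating with non-negative
# branch lengths and returns it in postorder ("pruningwise" ape order).
check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("expected an ape 'phylo' tree")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch lengths are not allowed")
  # exactly one node with no incoming edge (covers star trees and
  # multifurcating roots, which ape::is.rooted rejects)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1) stopf("tree must have exactly one root")
  tree
}

# Height above the root of every node (tips + internals).
node_heights <- function(tree) {
  tree <- check_tree(tree)
  n <- ape::Ntip(tree)
  h <- numeric(n + tree$Nnode)
  pre <- ape::reorder.phylo(tree, "postorder")
  # walk edges parent-before-child: reverse postorder
  ed <- pre$edge[rev(seq_len(nrow(pre$edge))), , drop = FALSE]
  el <- pre$edge.length[rev(seq_len(nrow(pre$edge)))]
  for (k in seq_len(nrow(ed))) h[ed[k, 2]] <- h[ed[k, 1]] + el[k]
  h
}

tree_height <- function(tree) max(node_heights(tree)[seq_len(ape::Ntip(tree))])

is_ultrametric <- function(tree, tol = 1e-6) {
  h <- node_heights(tree)[seq_len(ape::Ntip(tree))]
  diff(range(h)) < tol * max(h, 1)
}

# Postorder edge table + contrasts-ready arrays for the C++ pruning code.
tree_arrays <- function(tree) {
  tr <- ape::reorder.phylo(check_tree(tree), "postorder")
  list(parent = tr$edge[, 1] - 1L, child = tr$edge[, 2] - 1L,
       el = tr$edge.length, ntip = ape::Ntip(tr),
       nnode = tr$Nnode, tip.label = tr$tip.label, tree = tr)
}

# log|V| and V^{-1} helpers via Cholesky, with informative failure.
chol_safe <- function(V, what = "covariance") {
  out <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(out)) {
    out <- tryCatch(chol(V + diag(1e-10 * mean(diag(V)), nrow(V))),
                    error = function(e) NULL)
    if (is.null(out)) stopf("singular %s matrix", what)
  }
  out
}

logdet_chol <- function(L) 2 * sum(log(diag(L)))

# GLS (phylogenetic) mean of the rows of Y under tip covariance V = L'L.
gls_mean <- function(Y, Linv_t_ones, Linv_t_Y) {
  # a = (1' V^-1 1)^-1 1' V^-1 Y computed from whitened quantities
  crossprod(Linv_t_ones, Linv_t_Y) / sum(Linv_t_ones^2)
}

whiten <- function(L, X) backsolve(L, X, transpose = TRUE)
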