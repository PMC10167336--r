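#' Centroid size of a landmark configuration
#'
#' CS = sqrt(sum of squared distances of landmarks from their centroid),
#' the standard geometric-morphometric size measure. Scale-equivariant:
#' `centroid_size(c * X) == c * centroid_size(X)`.
#' @param config p x 3 (or p x k) numeric matrix.
#' @return non-negative scalar; 0 when all landmarks coincide.
#' @export
centroid_size <- function(config) {
  if (!is.matrix(config) || nrow(config) < 2)
    stopf("configuration must be a matrix with p >= 2 landmarks")
  if (!all(is.finite(config))) stopf("non-finite coordinates")
  cen <- colMeans(config)
  sqrt(sum(sweep(config, 2, cen)^2))
}

center_config <- function(x) sweep(x, 2, colMeans(x))

# Optimal rotation of X onto target (both centered): SVD solution with the
# determinant forced to +1 unless reflections are allowed.
procrustes_rotation <- function(X, target, allow_reflection = FALSE) {
  s <- svd(crossprod(X, target))
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes alignment
#'
#' Iteratively removes translation, scale and rotation (partial Procrustes:
#' configurations are scaled to unit centroid size, rotations exclude
#' reflections by default), optionally interleaving bending-energy sliding
#' of semilandmarks against the current consensus. The alignment criterion
#' (summed squared distance to the consensus) is non-increasing across
#' iterations.
#'
#' @param specimens a `specimen_table`, or a named list of p x 3 matrices.
#' @param scheme a [landmark_scheme()]; required when `slide = TRUE`.
#' @param slide slide curve/surface semilandmarks to minimise thin-plate
#'   spline bending energy relative to the consensus?
#' @param n_slide_passes sliding passes interleaved with re-alignment.
#' @param max_iter,tol alignment iteration controls.
#' @param allow_reflection permit improper rotations.
#' @return an `aligned_sample`: `coords` (named list, unit centroid size,
#'   centered), `cs` (original centroid sizes), `consensus` (mean shape),
#'   `criterion` (per-iteration summed squared distance), `scheme`.
#' @export
gpa <- function(specimens, scheme = NULL, slide = FALSE, n_slide_passes = 3,
                max_iter = 100, tol = 1e-8, allow_reflection = FALSE) {
  if (inherits(specimens, "specimen_table")) {
    scheme <- scheme %||% specimens$scheme
    species <- specimens$species
    configs <- specimens$coords
  } else {
    configs <- specimens
    species <- NULL
  }
  if (length(configs) < 2) stopf("GPA needs at least 2 specimens")
  if (slide && is.null(scheme)) stopf("sliding requires a landmark scheme")
  cs <- vapply(configs, centroid_size, 0)
  for (id in names(configs)) {
    if (cs[[id]] == 0) stopf("specimen '%s' has all landmarks coincident", id)
    x <- configs[[id]]
    if (qr(center_config(x))$rank < 2)
      stopf("specimen '%s' is degenerate (rank < 2)", id)
  }
  X <- lapply(names(configs), function(id) center_config(configs[[id]]) / cs[[id]])
  names(X) <- names(configs)

  align_pass <- function(X, crit_log) {
    consensus <- Reduce(`+`, X) / length(X)
    crit <- sum(vapply(X, function(x) sum((x - consensus)^2), 0))
    crit_log <- c(crit_log, crit)
    for (it in seq_len(max_iter)) {
      X <- lapply(X, function(x) x %*% procrustes_rotation(x, consensus, allow_reflection))
      consensus <- Reduce(`+`, X) / length(X)
      new_crit <- sum(vapply(X, function(x) sum((x - consensus)^2), 0))
      crit_log <- c(crit_log, new_crit)
      if (crit - new_crit < tol) break
      crit <- new_crit
    }
    if (it == max_iter && crit - new_crit >= tol)
      warnf("GPA did not converge in %d iterations; returning best iterate", max_iter)
    list(X = X, consensus = consensus, crit_log = crit_log)
  }

  res <- align_pass(X, numeric())
  if (slide) {
    for (pass in seq_len(n_slide_passes)) {
      res$X <- slide_semilandmarks(res$X, res$consensus, scheme)
      res$X <- lapply(res$X, function(x) {
        x <- center_config(x)
        x / centroid_size(x)
      })
      res <- align_pass(res$X, res$crit_log)
    }
  }
  # standardise the arbitrary global orientation: rotate the whole sample
  # so the consensus lies along its principal axes (det +1, signs fixed by
  # the largest-magnitude coordinate), making results invariant to the
  # orientation of the inputs
  Rstd <- eigen(crossprod(res$consensus), symmetric = TRUE)$vectors
  for (j in 1:3) {
    cj <- res$consensus %*% Rstd[, j]
    if (cj[which.max(abs(cj))] < 0) Rstd[, j] <- -Rstd[, j]
  }
  if (det(Rstd) < 0) Rstd[, 3] <- -Rstd[, 3]
  res$X <- lapply(res$X, function(x) x %*% Rstd)
  res$consensus <- res$consensus %*% Rstd
  structure(list(coords = res$X, cs = cs, consensus = res$consensus,
                 criterion = res$crit_log, scheme = scheme, species = species),
            class = "aligned_sample")
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat(sprintf("aligned sample: %d specimens, p = %d, final criterion %.3g\n",
              length(x$coords), nrow(x$consensus), tail(x$criterion, 1)))
  invisible(x)
}

# Thin-plate spline bending-energy matrix from a 3-D reference
# configuration. Kernel U(r) = -r (3-D); the bending-energy matrix is the
# upper-left p x p block of the inverse of the bordered system.
bending_energy_matrix <- function(reference, reg = 0) {
  p <- nrow(reference)
  D <- as.matrix(stats::dist(reference))
  K <- -D
  # affine block from the reference's non-degenerate principal coordinates,
  # so planar or collinear references are handled without singularity
  cen <- sweep(reference, 2, colMeans(reference))
  sv <- svd(cen)
  keep <- sv$d > max(sv$d, 1e-300) * 1e-8
  P <- cbind(1, cen %*% sv$v[, keep, drop = FALSE])
  q <- ncol(P)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, q, q)))
  Li <- tryCatch(solve(L), error = function(e) NULL)
  if (is.null(Li)) {
    warnf("singular bending-energy system; regularising")
    Li <- solve(L + diag(1e-8 * max(D), nrow(L)))
  }
  Be <- Li[seq_len(p), seq_len(p), drop = FALSE]
  (Be + t(Be)) / 2
}

# Tangent directions for sliding landmarks, estimated on the reference
# (consensus) shape. Curves: central differences of polyline neighbours
# (one-sided at interior points adjacent to endpoints). Surfaces: the two
# leading principal directions of the 6 nearest reference neighbours.
sliding_directions <- function(reference, scheme) {
  dirs <- vector("list", scheme$p)
  for (cv in scheme$curves) {
    for (j in 2:(length(cv) - 1)) {
      tang <- reference[cv[j + 1], ] - reference[cv[j - 1], ]
      nt <- sqrt(sum(tang^2))
      if (nt < 1e-12) tang <- c(1, 0, 0) else tang <- tang / nt
      dirs[[cv[j]]] <- matrix(tang, ncol = 1)
    }
  }
  if (length(scheme$surface)) {
    D <- as.matrix(stats::dist(reference))
    for (i in scheme$surface) {
      nb <- order(D[i, ])[2:7]
      loc <- sweep(reference[nb, , drop = FALSE], 2, reference[i, ])
      pcs <- svd(loc)$v[, 1:2, drop = FALSE]
      dirs[[i]] <- pcs
    }
  }
  dirs
}

#' Slide semilandmarks against a reference shape
#'
#' Moves curve semilandmarks along their tangent direction and surface
#' semilandmarks within their tangent plane so as to minimise the
#' thin-plate-spline bending energy of the deformation from the reference
#' (consensus) to each specimen. Fixed landmarks never move, and because
#' the move is the exact minimiser of a positive semi-definite quadratic,
#' bending energy never increases.
#'
#' @param configs named list of p x 3 matrices (aligned to the reference).
#' @param consensus reference p x 3 configuration.
#' @param scheme a [landmark_scheme()].
#' @return the updated list of configurations.
#' @export
slide_semilandmarks <- function(configs, consensus, scheme) {
  Be <- bending_energy_matrix(consensus)
  dirs <- sliding_directions(consensus, scheme)
  slid_idx <- which(!vapply(dirs, is.null, TRUE))
  if (!length(slid_idx)) return(configs)
  ndof <- sum(vapply(dirs[slid_idx], ncol, 0L))
  p <- scheme$p
  # U[, j]: displacement field of dof j, one p-vector per coordinate axis
  U <- array(0, c(p, ndof, 3))
  dof <- 0L
  for (i in slid_idx) {
    for (k in seq_len(ncol(dirs[[i]]))) {
      dof <- dof + 1L
      U[i, dof, ] <- dirs[[i]][, k]
    }
  }
  A <- matrix(0, ndof, ndof)
  for (d in 1:3) A <- A + crossprod(U[, , d], Be %*% U[, , d])
  A <- A + diag(1e-10 * max(abs(A), 1), ndof)
  lapply(configs, function(X) {
    b <- numeric(ndof)
    for (d in 1:3) b <- b + crossprod(U[, , d], Be %*% (X[, d] - consensus[, d]))
    t_hat <- -solve(A, b)
    for (d in 1:3) X[, d] <- X[, d] + U[, , d] %*% t_hat
    X
  })
}

# Bending energy of the deformation from `reference` to `target`.
bending_energy <- function(reference, target, Be = NULL) {
  if (is.null(Be)) Be <- bending_energy_matrix(reference)
  sum(vapply(1:3, function(d) {
    v <- target[, d] - reference[, d]
    drop(crossprod(v, Be %*% v))
  }, 0))
}

#' Average aligned shapes by species
#'
#' @param aligned an `aligned_sample` from [gpa()].
#' @param mapping named character vector specimen -> species; defaults to
#'   the mapping carried by the specimen table.
#' @return a `species_shapes` list: `shapes` (species x 3p matrix),
#'   `mean_log_cs` (per-species mean log centroid size), `scheme`.
#' @export
average_by_species <- function(aligned, mapping = NULL) {
  mapping <- mapping %||% aligned$species
  if (is.null(mapping)) stopf("no specimen-to-species mapping available")
  mapping <- mapping[names(aligned$coords)]
  if (anyNA(mapping)) stopf("every specimen must map to a species")
  sp <- sort(unique(unname(mapping)))
  p3 <- 3 * nrow(aligned$consensus)
  shapes <- matrix(NA_real_, length(sp), p3, dimnames = list(sp, NULL))
  mlcs <- setNames(numeric(length(sp)), sp)
  for (s in sp) {
    ids <- names(mapping)[mapping == s]
    mat <- t(vapply(aligned$coords[ids], flatten_config, numeric(p3)))
    shapes[s, ] <- colMeans(mat)
    mlcs[s] <- mean(log(aligned$cs[ids]))
  }
  structure(list(shapes = shapes, mean_log_cs = mlcs, scheme = aligned$scheme),
            class = "species_shapes")
}

#' @export
print.species_shapes <- function(x, ...) {
  cat(sprintf("species shape matrix: %d species x %d coordinates\n",
              nrow(x$shapes), ncol(x$shapes)))
  invisible(x)
}
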