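#' Define a landmark scheme
#'
#' A landmark scheme declares the role of every landmark in a configuration:
#' fixed anatomical landmarks, curve semilandmarks (ordered open polylines
#' whose interior points slide along their tangent), and surface
#' semilandmarks (which slide within their local tangent plane). Curve
#' polylines may start and end on fixed landmarks; those endpoints keep
#' their fixed role and every index appears in exactly one role.
#'
#' @param n_fixed number of fixed landmarks; by convention these occupy
#'   indices `1:n_fixed`.
#' @param curves list of integer vectors, each an ordered open polyline of
#'   landmark indices with at least 3 points. Interior points must not be
#'   fixed landmarks.
#' @param surface integer vector of surface semilandmark indices.
#' @return an object of class `landmark_scheme` with elements `n_fixed`,
#'   `curves`, `surface`, `p` (total landmarks) and per-index `role`.
#' @export
landmark_scheme <- function(n_fixed, curves = list(), surface = integer()) {
  n_fixed <- as.integer(n_fixed)
  if (n_fixed < 0) stopf("n_fixed must be >= 0")
  curves <- lapply(curves, as.integer)
  surface <- as.integer(surface)
  for (cv in curves) {
    if (length(cv) < 3) stopf("every curve needs >= 3 points (interior points slide)")
  }
  interior <- unlist(lapply(curves, function(cv) cv[-c(1, length(cv))]))
  if (anyDuplicated(c(interior, surface)))
    stopf("a landmark index appears in more than one sliding role")
  if (any(interior <= n_fixed))
    stopf("curve interior points cannot be fixed landmarks")
  if (any(surface <= n_fixed))
    stopf("surface semilandmarks cannot be fixed landmarks")
  p <- n_fixed + length(interior) + length(surface)
  idx <- sort(c(seq_len(n_fixed), interior, surface))
  if (!identical(idx, seq_len(p)))
    stopf("landmark indices must cover 1..p exactly once across roles")
  role <- rep("fixed", p)
  role[interior] <- "curve"
  role[surface] <- "surface"
  structure(list(n_fixed = n_fixed, curves = curves, surface = surface,
                 p = p, role = role),
            class = "landmark_scheme")
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat(sprintf("landmark scheme: p = %d (%d fixed, %d curve, %d surface; %d curves)\n",
              x$p, x$n_fixed, sum(x$role == "curve"), sum(x$role == "surface"),
              length(x$curves)))
  invisible(x)
}

#' Default synthetic jaw scheme
#'
#' 100 landmarks: 6 fixed anchors, 3 curves of 17 interior sliding points
#' each (51 curve semilandmarks) and 43 surface semilandmarks, mirroring a
#' typical lower-jaw digitisation design.
#' @return a [landmark_scheme()]
#' @export
default_jaw_scheme <- function() {
  # fixed: 1 anterior symphysis, 2 condyle, 3 coronoid analogue,
  # 4 dental-groove anterior, 5 dental-groove posterior, 6 ventral angle
  c1 <- c(1L, 6L + 1:17, 2L)    # lower margin: symphysis -> condyle
  c2 <- c(1L, 23L + 1:17, 3L)   # upper margin: symphysis -> coronoid
  c3 <- c(4L, 40L + 1:17, 5L)   # dental groove
  landmark_scheme(6L, curves = list(c1, c2, c3), surface = 57L + 1:43)
}
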