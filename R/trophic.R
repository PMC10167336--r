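#' Bray-Curtis dissimilarity between diet compositions
#'
#' D_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk); symmetric, zero
#' diagonal, within 0..1 for non-negative data. Delegates to
#' [vegan::vegdist()].
#' @param diet_matrix species x prey-category matrix, non-negative with at
#'   least one positive entry per row.
#' @return a `dist` object.
#' @export
bray_curtis <- function(diet_matrix) {
  diet_matrix <- as.matrix(diet_matrix)
  if (any(diet_matrix < 0)) stopf("diet proportions must be non-negative")
  zero <- rowSums(diet_matrix) == 0
  if (any(zero))
    stopf("all-zero diet row(s): %s",
          paste(rownames(diet_matrix)[zero] %||% which(zero), collapse = ", "))
  vegan::vegdist(diet_matrix, method = "bray")
}

#' UPGMA (average-linkage) clustering
#'
#' @param distance a `dist` or symmetric matrix with zero diagonal.
#' @return an `hclust` dendrogram (heights are non-decreasing along
#'   merges).
#' @export
upgma <- function(distance) {
  d <- stats::as.dist(distance)
  if (anyNA(d)) stopf("NaN/NA distances are not allowed")
  stats::hclust(d, method = "average")
}

#' Assign feeding guilds by cutting a diet dendrogram
#'
#' Cuts a UPGMA dendrogram of Bray-Curtis diet dissimilarities into k
#' guilds. With `exclude_monospecific`, species whose diet has a single
#' non-zero prey category are removed before clustering and labelled by
#' that sole category.
#'
#' @param diet_matrix species x prey proportion matrix.
#' @param k number of guilds cut from the dendrogram.
#' @param exclude_monospecific remove single-category diets first?
#' @return a `guild_assignment`: `guilds` (named character), `dendrogram`
#'   (`hclust`), `k`, `excluded` (monospecific species and their labels).
#' @export
assign_guilds <- function(diet_matrix, k, exclude_monospecific = FALSE) {
  diet_matrix <- as.matrix(diet_matrix)
  if (k < 1) stopf("k must be >= 1")
  excluded <- character()
  if (exclude_monospecific) {
    mono <- rowSums(diet_matrix > 0) == 1
    if (any(mono)) {
      excluded <- setNames(
        colnames(diet_matrix)[apply(diet_matrix[mono, , drop = FALSE], 1, which.max)],
        rownames(diet_matrix)[mono])
      diet_matrix <- diet_matrix[!mono, , drop = FALSE]
    }
  }
  if (k > nrow(diet_matrix))
    stopf("k = %d exceeds the %d clustered species", k, nrow(diet_matrix))
  dend <- upgma(bray_curtis(diet_matrix))
  cl <- stats::cutree(dend, k = k)
  guilds <- setNames(paste0("G", cl), names(cl))
  structure(list(guilds = c(guilds, excluded), dendrogram = dend, k = k,
                 excluded = excluded),
            class = "guild_assignment")
}

#' @export
print.guild_assignment <- function(x, ...) {
  cat(sprintf("guild assignment: %d species in %d guilds (%d monospecific excluded)\n",
              length(x$guilds), length(unique(x$guilds)), length(x$excluded)))
  invisible(x)
}

#' Automatic guild count from the largest dendrogram height gap
#' @param dendrogram an `hclust`.
#' @return integer k.
#' @export
guild_count_by_gap <- function(dendrogram) {
  h <- sort(dendrogram$height, decreasing = TRUE)
  if (length(h) < 2) return(1L)
  gaps <- -diff(h)
  as.integer(which.max(gaps) + 1L)
}

#' Categorise trophic level values
#'
#' TR <= 3.8 -> low-level predator (LP); 3.8 < TR <= 4.2 -> mesopredator
#' (MP); TR > 4.2 -> top predator (TP). The boundary value 4.2 defaults to
#' MP (`boundary = "MP"`); boundary cases are flagged via the
#' `boundary_flag` attribute because published usage is inconsistent
#' exactly at 4.2.
#'
#' @param TR numeric vector of trophic level values (roughly between 2 and 5).
#' @param boundary `"MP"` (default) or `"TP"`: category of TR == 4.2.
#' @return character vector in {LP, MP, TP} with attribute
#'   `boundary_flag` marking values exactly at a category boundary.
#' @export
trophic_category <- function(TR, boundary = c("MP", "TP")) {
  boundary <- match.arg(boundary)
  if (any(!is.finite(TR))) stopf("trophic level must be finite")
  if (any(TR < 2 | TR > 5.5)) warnf("trophic level outside [2, 5.5]")
  hi <- if (boundary == "MP") 4.2 else 4.2 - 1e-9
  out <- ifelse(TR <= 3.8, "LP", ifelse(TR <= hi, "MP", "TP"))
  attr(out, "boundary_flag") <- TR %in% c(3.8, 4.2)
  out
}

#' Export a dendrogram as Newick with heights
#' @param dendrogram an `hclust`.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  ape::write.tree(ape::as.phylo(dendrogram), file = path)
  invisible(path)
}
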