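#' Join specimens, ecology and trees into a validated study object
#'
#' Cross-references the three data sources by species id, reporting (not
#' erroring on) species present in one source but absent in another. The
#' result is the single object downstream stages consume.
#'
#' @param specimens a `specimen_table` from [read_landmarks()].
#' @param ecology an `ecology_table` from [read_ecology()], or `NULL`.
#' @param trees an ape `phylo` or `multiPhylo` (all trees must share one tip
#'   set), or `NULL`.
#' @return a `morpho_study`: specimens, ecology, trees, and a `report` list
#'   with `species_without_tree`, `tips_without_specimens`,
#'   `species_without_ecology`.
#' @export
join_metadata <- function(specimens, ecology = NULL, trees = NULL) {
  sp <- sort(unique(stats::na.omit(unname(specimens$species))))
  if (!length(sp)) stopf("no specimen has a species assignment")
  if (inherits(trees, "phylo")) trees <- c(structure(list(trees), class = "multiPhylo"))
  report <- list(species_without_tree = character(),
                 tips_without_specimens = character(),
                 species_without_ecology = character())
  if (!is.null(trees)) {
    tips <- trees[[1]]$tip.label
    for (tr in trees) {
      check_tree(tr)
      if (!setequal(tr$tip.label, tips))
        stopf("trees in the set do not share one tip set")
    }
    report$species_without_tree <- setdiff(sp, tips)
    report$tips_without_specimens <- setdiff(tips, sp)
  }
  if (!is.null(ecology)) {
    report$species_without_ecology <- setdiff(sp, ecology$species)
  }
  structure(list(specimens = specimens, ecology = ecology, trees = trees,
                 species = sp, report = report),
            class = "morpho_study")
}

#' @export
print.morpho_study <- function(x, ...) {
  cat(sprintf("morpho study: %d specimens / %d species; %d trees; ecology: %s\n",
              length(x$specimens$coords), length(x$species),
              if (is.null(x$trees)) 0 else length(x$trees),
              if (is.null(x$ecology)) "none" else "present"))
  r <- x$report
  if (length(r$species_without_tree))
    cat(" species missing from trees:", paste(r$species_without_tree, collapse = ", "), "\n")
  if (length(r$tips_without_specimens))
    cat(" tree tips without specimens:", paste(r$tips_without_specimens, collapse = ", "), "\n")
  if (length(r$species_without_ecology))
    cat(" species without ecology:", paste(r$species_without_ecology, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a study
#'
#' `"has_diet"` keeps species with diet proportion rows; `"in_tree"` keeps
#' species present in the tree tip set. Specimens, ecology rows and tree
#' tips are pruned consistently.
#' @param study a `morpho_study`.
#' @param subset `"has_diet"` or `"in_tree"`, or a character vector of
#'   species ids.
#' @export
subset_study <- function(study, subset) {
  keep <- if (identical(subset, "has_diet")) {
    if (is.null(study$ecology) || is.null(attr(study$ecology, "diet")))
      stopf("study has no diet data")
    intersect(study$species, rownames(attr(study$ecology, "diet")))
  } else if (identical(subset, "in_tree")) {
    if (is.null(study$trees)) stopf("study has no trees")
    intersect(study$species, study$trees[[1]]$tip.label)
  } else as.character(subset)
  spec_keep <- names(study$specimens$species)[study$specimens$species %in% keep]
  specimens <- specimen_table(study$specimens$coords[spec_keep],
                              study$specimens$species[spec_keep],
                              study$specimens$scheme)
  ecology <- study$ecology
  if (!is.null(ecology)) {
    diet <- attr(ecology, "diet")
    ecology <- ecology[ecology$species %in% keep, , drop = FALSE]
    if (!is.null(diet)) diet <- diet[rownames(diet) %in% keep, , drop = FALSE]
    attr(ecology, "diet") <- diet
    class(ecology) <- c("ecology_table", "data.frame")
  }
  trees <- study$trees
  if (!is.null(trees)) {
    trees <- structure(lapply(trees, function(tr) {
      drop <- setdiff(tr$tip.label, keep)
      if (length(drop)) ape::drop.tip(tr, drop) else tr
    }), class = "multiPhylo")
  }
  join_metadata(specimens, ecology, trees)
}

#' Write a JSON run manifest
#'
#' Records the stage name, RNG seed, parameter set and input digests so a
#' pipeline run can be reproduced.
#' @param path output JSON path.
#' @param stage stage name.
#' @param seed integer seed used by the stage.
#' @param params named list of stage parameters.
#' @param inputs named character vector of input file paths (digested by
#'   size + first bytes).
#' @export
write_manifest <- function(path, stage, seed = NULL, params = list(),
                           inputs = character()) {
  digest1 <- function(f) {
    if (!file.exists(f)) return("missing")
    info <- file.info(f)
    head_bytes <- readBin(f, "raw", n = min(4096, info$size))
    sprintf("size=%d;sum=%d", info$size, sum(as.integer(head_bytes)) %% 1e9)
  }
  manifest <- list(stage = stage,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed, params = params,
                   inputs = lapply(stats::setNames(as.list(inputs), names(inputs) %||% inputs), digest1))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Write aligned coordinates, centroid sizes and consensus as flat CSV
#' @param aligned an `aligned_sample` from [gpa()].
#' @param dir output directory (created if absent).
#' @export
write_aligned_csv <- function(aligned, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coords <- t(vapply(aligned$coords, flatten_config,
                     numeric(3 * nrow(aligned$consensus))))
  utils::write.csv(coords, file.path(dir, "aligned_coordinates.csv"))
  utils::write.csv(data.frame(specimen = names(aligned$cs), cs = aligned$cs),
                   file.path(dir, "centroid_sizes.csv"), row.names = FALSE)
  utils::write.csv(aligned$consensus, file.path(dir, "consensus.csv"),
                   row.names = FALSE)
  invisible(dir)
}
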