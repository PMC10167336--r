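#' Read 3-D landmark configurations
#'
#' Supported dialects:
#' * `csv` — long format with columns `specimen, species, landmark, x, y, z`
#'   (`species` optional, `landmark` 1-based);
#' * `tps` — `LM3=p` blocks with one `x y z` row per landmark, specimen ids
#'   from `ID=` lines;
#' * `pts` — one specimen per file, one `index x y z` row per landmark
#'   (pass a character vector of paths, one per specimen).
#'
#' @param path file path (or vector of paths for `pts`).
#' @param format one of `"csv"`, `"tps"`, `"pts"`.
#' @param scheme a [landmark_scheme()]; every specimen must carry exactly
#'   `scheme$p` landmarks.
#' @return a `specimen_table`: list with `coords` (named list of p x 3
#'   matrices), `species` (named character, may contain `NA`), `scheme`.
#' @export
read_landmarks <- function(path, format = c("csv", "tps", "pts"), scheme) {
  format <- match.arg(format)
  specs <- switch(format,
    csv = read_landmarks_csv(path),
    tps = read_landmarks_tps(path),
    pts = read_landmarks_pts(path))
  for (id in names(specs$coords)) {
    x <- specs$coords[[id]]
    if (nrow(x) != scheme$p)
      stopf("specimen '%s' has %d landmarks but the scheme declares %d",
            id, nrow(x), scheme$p)
    if (!all(is.finite(x)))
      stopf("specimen '%s' has non-finite coordinates", id)
  }
  specimen_table(specs$coords, specs$species, scheme)
}

#' Construct a specimen table in memory
#' @param coords named list of p x 3 numeric matrices (names = specimen ids).
#' @param species named character vector mapping specimen id to species id.
#' @param scheme a [landmark_scheme()].
#' @export
specimen_table <- function(coords, species, scheme) {
  if (is.null(names(coords))) stopf("specimen coordinates must be named")
  species <- species[names(coords)]
  names(species) <- names(coords)
  structure(list(coords = coords, species = species, scheme = scheme),
            class = "specimen_table")
}

#' @export
print.specimen_table <- function(x, ...) {
  cat(sprintf("specimen table: %d specimens, %d species, p = %d\n",
              length(x$coords), length(unique(stats::na.omit(x$species))),
              x$scheme$p))
  invisible(x)
}

read_landmarks_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "landmark", "x", "y", "z")
  if (!all(need %in% names(d)))
    stopf("landmark CSV must have columns %s", paste(need, collapse = ", "))
  for (col in c("x", "y", "z")) {
    if (!is.numeric(d[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[col]]))))[1]
      stopf("non-numeric '%s' value at data line %d", col, bad)
    }
  }
  ids <- unique(d$specimen)
  coords <- lapply(ids, function(id) {
    sub <- d[d$specimen == id, ]
    sub <- sub[order(sub$landmark), ]
    if (!identical(as.integer(sub$landmark), seq_len(nrow(sub))))
      stopf("specimen '%s': landmark indices must be 1..p without gaps", id)
    m <- as.matrix(sub[, c("x", "y", "z")])
    dimnames(m) <- NULL
    m
  })
  names(coords) <- ids
  species <- if ("species" %in% names(d)) {
    vapply(ids, function(id) as.character(d$species[d$specimen == id][1]), "")
  } else setNames(rep(NA_character_, length(ids)), ids)
  names(species) <- ids
  list(coords = coords, species = species)
}

read_landmarks_tps <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  starts <- grep("^LM3?=", lines, ignore.case = TRUE)
  if (!length(starts)) stopf("no LM/LM3 blocks found in %s", path)
  coords <- list(); species <- character()
  for (b in seq_along(starts)) {
    i <- starts[b]
    p <- as.integer(sub("^LM3?=", "", lines[i], ignore.case = TRUE))
    end <- if (b < length(starts)) starts[b + 1] - 1 else length(lines)
    block <- lines[(i + 1):end]
    rows <- block[grepl("^[-+0-9.eE]", block)]
    if (length(rows) < p)
      stopf("TPS block %d declares LM3=%d but has %d coordinate rows (line %d)",
            b, p, length(rows), i)
    mat <- t(vapply(rows[seq_len(p)], function(r) {
      v <- suppressWarnings(as.numeric(strsplit(r, "[ \t]+")[[1]]))
      if (length(v) != 3 || any(is.na(v)))
        stopf("TPS block %d: malformed coordinate row '%s'", b, r)
      v
    }, numeric(3)))
    rownames(mat) <- NULL
    idline <- grep("^ID=", block, value = TRUE, ignore.case = TRUE)
    id <- if (length(idline)) sub("^ID=", "", idline[1], ignore.case = TRUE)
          else sprintf("specimen_%03d", b)
    coords[[id]] <- mat
    species[id] <- NA_character_
  }
  list(coords = coords, species = species)
}

read_landmarks_pts <- function(paths) {
  coords <- list(); species <- character()
  for (path in paths) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    lines <- grep("^[0-9]", trimws(readLines(path)), value = TRUE)
    mat <- t(vapply(lines, function(r) {
      v <- suppressWarnings(as.numeric(strsplit(r, "[ \t]+")[[1]]))
      if (length(v) != 4 || any(is.na(v)))
        stopf("pts file %s: malformed row '%s'", path, r)
      v[2:4]
    }, numeric(3)))
    rownames(mat) <- NULL
    id <- sub("\\.pts$", "", basename(path))
    coords[[id]] <- mat
    species[id] <- NA_character_
  }
  list(coords = coords, species = species)
}

#' Write landmark configurations
#'
#' Inverse of [read_landmarks()] for the `csv` and `tps` dialects; CSV
#' round-trips bit-exactly (coordinates are printed with full precision).
#' @param specimens a `specimen_table`.
#' @param path output file.
#' @param format `"csv"` or `"tps"`.
#' @export
write_landmarks <- function(specimens, path, format = c("csv", "tps")) {
  format <- match.arg(format)
  if (format == "csv") {
    rows <- lapply(names(specimens$coords), function(id) {
      x <- specimens$coords[[id]]
      data.frame(specimen = id,
                 species = specimens$species[[id]],
                 landmark = seq_len(nrow(x)),
                 x = x[, 1], y = x[, 2], z = x[, 3],
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("specimen,species,landmark,x,y,z", con)
    writeLines(sprintf("%s,%s,%d,%.17g,%.17g,%.17g",
                       d$specimen, d$species, d$landmark, d$x, d$y, d$z), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (id in names(specimens$coords)) {
      x <- specimens$coords[[id]]
      writeLines(sprintf("LM3=%d", nrow(x)), con)
      writeLines(sprintf("%.17g %.17g %.17g", x[, 1], x[, 2], x[, 3]), con)
      writeLines(sprintf("ID=%s", id), con)
    }
  }
  invisible(path)
}

#' Read a species ecology table
#'
#' CSV/TSV with columns `species, order, habitat, trophic_level` and
#' optionally one column per prey category (prefix `diet_`). Diet rows are
#' renormalised to sum to 1; habitat must be one of reef, shelf, pelagic,
#' deep-sea when present.
#' @param path file path; separator inferred from extension.
#' @return data.frame of class `ecology_table`; attribute `diet` holds the
#'   species x prey-category proportion matrix (rows may be missing).
#' @export
read_ecology <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  as_ecology(d)
}

#' Coerce a data.frame to an ecology table
#' @param d data.frame with `species`, `order`, `habitat`, `trophic_level`
#'   and optional `diet_*` proportion columns.
#' @export
as_ecology <- function(d) {
  if (!"species" %in% names(d)) stopf("ecology table needs a 'species' column")
  dup <- unique(d$species[duplicated(d$species)])
  if (length(dup))
    stopf("duplicate species in ecology table: %s", paste(dup, collapse = ", "))
  if ("habitat" %in% names(d)) {
    ok <- is.na(d$habitat) | d$habitat %in% habitat_levels()
    if (!all(ok))
      stopf("unknown habitat value(s): %s",
            paste(unique(d$habitat[!ok]), collapse = ", "))
  }
  dietcols <- grep("^diet_", names(d), value = TRUE)
  diet <- NULL
  if (length(dietcols)) {
    diet <- as.matrix(d[, dietcols, drop = FALSE])
    colnames(diet) <- sub("^diet_", "", dietcols)
    rownames(diet) <- d$species
    has <- rowSums(is.na(diet)) == 0 & rowSums(diet, na.rm = TRUE) > 0
    diet[has, ] <- diet[has, , drop = FALSE] / rowSums(diet[has, , drop = FALSE])
    diet <- diet[has, , drop = FALSE]
    if (any(diet < 0)) stopf("negative diet proportions")
  }
  structure(d, diet = diet, class = c("ecology_table", "data.frame"))
}

#' @export
habitat_levels <- function() c("reef", "shelf", "pelagic", "deep-sea")
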