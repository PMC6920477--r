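#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene symbols. Members
#'   are uppercased and de-duplicated; empty sets are rejected.
#' @param source description of where the collection came from.
#' @return An object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, source = "user") {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a fully named list of gene vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty))
    stop("empty gene set(s): ", paste(empty, collapse = ", "))
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets (source:", x$source, ")\n")
  sizes <- lengths(x$sets)
  cat("set sizes:", min(sizes), "-", max(sizes),
      "(median", stats::median(sizes), ")\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' \code{name}, \code{description}, then member gene symbols. Duplicate
#' members within a set are collapsed. Gene symbols are uppercased to
#' match the conventional casing of curated collections.
#'
#' @param path path to the GMT file.
#' @param exclude character vector of set names to drop after reading
#'   (e.g. a heme-metabolism set confounded by globin transcripts on
#'   blood arrays).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, exclude = character()) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parsed) < 3)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", bad[1]))
  nm <- vapply(parsed, `[[`, character(1), 1L)
  sets <- lapply(parsed, function(f) f[-(1:2)])
  names(sets) <- nm
  coll <- gene_set_collection(sets, source = path)
  if (length(exclude)) {
    keep <- setdiff(names(coll$sets), exclude)
    coll$sets <- coll$sets[keep]
  }
  coll
}

#' Write gene sets to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(
    names(collection$sets),
    function(nm) paste(c(nm, collection$source, collection$sets[[nm]]),
                       collapse = "\t"),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' The packaged circadian gene panel
#'
#' The union of canonical clock genes (ordered by signal-to-noise ratio
#' for predicting circadian rhythmicity: PER1, NR1D2, PER3, NR1D1, PER2,
#' ARNTL, NPAS2, CLOCK, CRY2, CRY1) and the top predictor genes of
#' circadian rhythmicity in human blood (DDIT4, CLEC4E, FKBP5, DAAM2,
#' TPST1, IL13RA1, SMAP2, HNRNPDL, FOSL2, PER1, FLT3, CDC42EP2, TMEM88,
#' NR1D2, RBM3). PER1 and NR1D2 appear on both lists, so the union holds
#' 23 unique symbols.
#'
#' @param which one of \code{"union"} (default), \code{"clock"} or
#'   \code{"blood"}.
#' @return Character vector of gene symbols.
#' @export
circadian_panel <- function(which = c("union", "clock", "blood")) {
  which <- match.arg(which)
  clock <- c("PER1", "NR1D2", "PER3", "NR1D1", "PER2",
             "ARNTL", "NPAS2", "CLOCK", "CRY2", "CRY1")
  blood <- c("DDIT4", "CLEC4E", "FKBP5", "DAAM2", "TPST1",
             "IL13RA1", "SMAP2", "HNRNPDL", "FOSL2", "PER1",
             "FLT3", "CDC42EP2", "TMEM88", "NR1D2", "RBM3")
  switch(which,
         clock = clock,
         blood = unique(blood),
         union = unique(c(clock, blood)))
}

#' Read a gene panel from a plain-text file
#'
#' @param path file with one gene symbol per line; blank lines and lines
#'   starting with \code{#} are ignored.
#' @return Character vector of unique uppercased symbols.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(toupper(x))
}
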