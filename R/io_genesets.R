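#' Construct a gene-set collection
#'
#' Named sets of gene symbols (pathway term -> members). Symbols are
#' upper-cased and de-duplicated within each set; the collection's universe
#' is the union of all members (the annotated-universe convention used as
#' the default enrichment background).
#'
#' @param sets named list of character vectors; every set must be non-empty.
#' @param descriptions optional character vector of per-set descriptions.
#' @return A `gene_set_collection` (named list) with attributes `universe`
#'   and `universe_size`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), length(sets) > 0L)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene_set_collection: sets must be named", call. = FALSE)
  sets <- lapply(sets, function(s) unique(toupper(as.character(s))))
  if (any(lengths(sets) == 0L))
    stop("gene_set_collection: empty set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "),
         call. = FALSE)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            universe = universe, universe_size = length(universe),
            class = "gene_set_collection")
}

#' Read a gene-set collection from a GMT file
#'
#' GMT format: one set per line, tab-separated `name`, `description`,
#' then members. Lines with fewer than 3 fields are a format error reported
#' with their line number.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_gene_sets: empty GMT file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("read_gene_sets: malformed GMT line ", bad[1L],
         " (fewer than 3 tab-separated fields)", call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    warning("read_gene_sets: duplicate set name(s) - first occurrence kept")
    keep <- !duplicated(nm)
    fields <- fields[keep]; nm <- nm[keep]
  }
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- nm
  gene_set_collection(sets, descriptions = vapply(fields, `[[`, "", 2L))
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @export
write_gene_sets <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    d <- desc[[nm]]; if (is.null(d) || is.na(d)) d <- ""
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x), "sets,",
      attr(x, "universe_size"), "unique genes\n")
  invisible(x)
}
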