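#' Construct an identifier map
#'
#' Pairs of (source_id, target_id) labelled with namespaces, e.g.
#' ENST -> ENSG or ENSG -> symbol. Lookup order is file/row order, which
#' makes one-to-many resolution deterministic.
#'
#' @param source_id,target_id character vectors of equal length.
#' @param source_ns,target_ns namespace labels (scalars or vectors).
#' @return An `id_map` data frame with columns
#'   `source_ns, source_id, target_ns, target_id`.
#' @export
id_map <- function(source_id, target_id, source_ns, target_ns) {
  stopifnot(length(source_id) == length(target_id))
  out <- data.frame(source_ns = as.character(source_ns),
                    source_id = as.character(source_id),
                    target_ns = as.character(target_ns),
                    target_id = as.character(target_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("id_map", "data.frame")
  out
}

#' Read / write a 2-column identifier-map TSV
#'
#' The header row carries the namespace labels (e.g. `ENST<TAB>ENSG`).
#'
#' @param path file path.
#' @return `read_id_map`: an [id_map()].
#' @export
read_id_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("read_id_map: expected 2 columns", call. = FALSE)
  id_map(df[[1L]], df[[2L]], names(df)[1L], names(df)[2L])
}

#' @rdname read_id_map
#' @param idmap an [id_map()] restricted to one namespace pair.
#' @export
write_id_map <- function(idmap, path) {
  stopifnot(inherits(idmap, "id_map"))
  ns <- unique(idmap[, c("source_ns", "target_ns")])
  if (nrow(ns) != 1L)
    stop("write_id_map: map holds more than one namespace pair", call. = FALSE)
  df <- stats::setNames(idmap[, c("source_id", "target_id")],
                        c(ns$source_ns, ns$target_ns))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map identifiers between namespaces
#'
#' Each input ID takes the first matching target in map order (one-to-many
#' mappings resolved deterministically); duplicate targets in the result are
#' collapsed to the first occurrence, mirroring automatic replicate removal
#' after ENST to ENSG conversion. Unmapped IDs are reported, never silently
#' dropped.
#'
#' @param ids character vector.
#' @param idmap an [id_map()].
#' @param from_ns,to_ns namespaces to map between; must exist in `idmap`.
#' @param collapse collapse duplicate targets (default `TRUE`).
#' @return A list with `mapped` (targets, duplicates collapsed when
#'   `collapse`), `unmapped` (input IDs without a target), `n_collapsed`
#'   (duplicates removed), and `mapped_all` (positionally aligned targets,
#'   `NA` where unmapped).
#' @export
map_identifiers <- function(ids, idmap, from_ns, to_ns, collapse = TRUE) {
  stopifnot(inherits(idmap, "id_map"))
  if (!from_ns %in% idmap$source_ns)
    stop("map_identifiers: unknown source namespace '", from_ns, "'",
         call. = FALSE)
  if (!to_ns %in% idmap$target_ns)
    stop("map_identifiers: unknown target namespace '", to_ns, "'",
         call. = FALSE)
  pairs <- idmap[idmap$source_ns == from_ns & idmap$target_ns == to_ns, ]
  idx <- match(ids, pairs$source_id)   # first occurrence in map order
  mapped_all <- pairs$target_id[idx]
  unmapped <- ids[is.na(idx)]
  mapped <- mapped_all[!is.na(mapped_all)]
  n_collapsed <- 0L
  if (collapse) {
    dup <- duplicated(mapped)
    n_collapsed <- sum(dup)
    mapped <- mapped[!dup]
  }
  list(mapped = mapped, unmapped = unmapped, n_collapsed = n_collapsed,
       mapped_all = mapped_all)
}
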