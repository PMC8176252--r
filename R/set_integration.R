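#' Detectable genes under a TPM threshold
#'
#' A gene is detectable when its TPM is at or above `threshold` (the
#' boundary value itself is detectable). Scope `"per-sample"` returns one
#' gene set per sample, `"any-sample"` the union (the dataset-level
#' convention), `"all-samples"` the genes detectable in every sample.
#'
#' @param m an [expression_matrix()] in TPM.
#' @param threshold detectability threshold in TPM (default 0.1).
#' @param scope `"any-sample"`, `"per-sample"` or `"all-samples"`.
#' @return Character vector of gene IDs, or a named list of them for
#'   `"per-sample"`.
#' @export
detectable_genes <- function(m, threshold = 0.1,
                             scope = c("any-sample", "per-sample", "all-samples")) {
  scope <- match.arg(scope)
  if (expr_unit(m) != "TPM")
    stop("detectable_genes: unit is '", expr_unit(m), "', expected 'TPM'",
         call. = FALSE)
  x <- unclass(m) >= threshold
  switch(scope,
         "per-sample" = lapply(stats::setNames(colnames(m), colnames(m)),
                               function(s) rownames(m)[x[, s]]),
         "any-sample" = rownames(m)[rowSums(x) > 0L],
         "all-samples" = rownames(m)[rowSums(x) == ncol(m)])
}

#' Partition 2-4 labelled sets into Venn regions
#'
#' Every non-empty label combination becomes a region holding the elements
#' that belong to exactly those sets. Regions are ordered deterministically:
#' single sets first (input order), then pairs, triples, etc. Region sizes
#' sum to the size of the union.
#'
#' @param sets named list of 2-4 character vectors.
#' @return A `set_partition`: `labels`, `regions` (named list of members,
#'   keys like `"A&B"`), `sizes`, `universe`.
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets))
  if (length(sets) < 2L || length(sets) > 4L)
    stop("venn_partition: between 2 and 4 sets are supported", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets)))
    stop("venn_partition: sets must have unique non-empty labels", call. = FALSE)
  labels <- names(sets)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  key <- apply(membership, 1L, function(b) paste(labels[b], collapse = "&"))
  region_names <- unlist(lapply(seq_along(labels), function(s)
    apply(utils::combn(labels, s), 2L, paste, collapse = "&")))
  regions <- lapply(stats::setNames(region_names, region_names),
                    function(rn) universe[key == rn])
  structure(list(labels = labels, regions = regions,
                 sizes = lengths(regions), universe = universe),
            class = "set_partition")
}

#' @export
print.set_partition <- function(x, ...) {
  cat("set_partition over", length(x$labels), "sets; |union| =",
      length(x$universe), "\n")
  print(x$sizes)
  invisible(x)
}

#' Write a set partition as TSV
#'
#' Columns: region label, size, semicolon-joined members.
#'
#' @param partition a [venn_partition()] result.
#' @param path output file.
#' @export
write_set_partition <- function(partition, path) {
  df <- data.frame(region = names(partition$regions),
                   size = unname(partition$sizes),
                   members = vapply(partition$regions, paste, "",
                                    collapse = ";"),
                   stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Partition genes by mutation and transcription status
#'
#' Splits genes into mutated-and-transcribed (candidate functional mutant
#' proteins), mutated-but-untranscribed (likely passenger mutations) and
#' transcribed-but-unmutated.
#'
#' @param mutated,transcribed character vectors of gene symbols.
#' @return List with `mutated_transcribed`, `mutated_untranscribed`,
#'   `transcribed_unmutated` (sorted, upper-cased).
#' @export
mutated_transcribed_partition <- function(mutated, transcribed) {
  m <- unique(toupper(as.character(mutated)))
  t_ <- unique(toupper(as.character(transcribed)))
  list(mutated_transcribed = sort(intersect(m, t_)),
       mutated_untranscribed = sort(setdiff(m, t_)),
       transcribed_unmutated = sort(setdiff(t_, m)))
}

#' Resolve trans-species protein ambiguity in a PDX proteome
#'
#' A patient-derived xenograft is a chimera: the same peptide pool is
#' searched against the human and the mouse database, and proteins
#' identified in both lists cannot be assigned a species - they are
#' "Possibly of Murine Origin" (PMO). Matching is case-insensitive symbol
#' equality, optionally preceded by an explicit mouse-to-human orthology map
#' for renamed orthologues (Trp53 vs TP53 style).
#'
#' @param human_list,murine_list character vectors of protein/gene symbols.
#' @param orthology_map optional named character vector or 2-column data
#'   frame mapping murine symbols to human symbols.
#' @return A `pmo_partition`: `human_only`, `murine_only`, `pmo` (all in
#'   human symbol space) and `ambiguity_fraction` = |pmo| / |human list|.
#' @export
identify_pmo <- function(human_list, murine_list, orthology_map = NULL) {
  if (!length(human_list) || !length(murine_list))
    stop("identify_pmo: both lists must be non-empty", call. = FALSE)
  h <- unique(toupper(as.character(human_list)))
  m <- unique(toupper(as.character(murine_list)))
  if (!is.null(orthology_map)) {
    if (is.data.frame(orthology_map))
      orthology_map <- stats::setNames(as.character(orthology_map[[2L]]),
                                       as.character(orthology_map[[1L]]))
    names(orthology_map) <- toupper(names(orthology_map))
    orthology_map <- toupper(orthology_map)
    hit <- m %in% names(orthology_map)
    m[hit] <- unname(orthology_map[m[hit]])
    m <- unique(m)
  }
  pmo <- sort(intersect(h, m))
  structure(list(human_only = sort(setdiff(h, pmo)),
                 murine_only = sort(setdiff(m, pmo)),
                 pmo = pmo,
                 ambiguity_fraction = length(pmo) / length(h)),
            class = "pmo_partition")
}

#' @export
print.pmo_partition <- function(x, ...) {
  cat(sprintf("pmo_partition: %d human-only, %d murine-only, %d PMO (%.1f%% of human list)\n",
              length(x$human_only), length(x$murine_only), length(x$pmo),
              100 * x$ambiguity_fraction))
  invisible(x)
}

#' Low-count prefilter for read-count matrices
#'
#' Flags transcript counts below `min_reads` and excludes a transcript when
#' strictly more than `max_flag_fraction` of its samples are flagged
#' (flagged in exactly 75% of samples is retained under the defaults).
#' Surviving rows are unchanged. This is the screening step applied before
#' differential-expression fitting; the DE fit itself is out of scope.
#'
#' @param counts an [expression_matrix()] with unit `"counts"`.
#' @param min_reads flag counts strictly below this (default 10).
#' @param max_flag_fraction exclusion threshold on the flagged fraction
#'   (default 0.75, exclusive).
#' @return Filtered [expression_matrix()] with attribute `removed` (the
#'   excluded transcript IDs).
#' @export
count_prefilter <- function(counts, min_reads = 10, max_flag_fraction = 0.75) {
  if (expr_unit(counts) != "counts")
    stop("count_prefilter: unit is '", expr_unit(counts),
         "', expected 'counts'", call. = FALSE)
  flagged_fraction <- rowMeans(unclass(counts) < min_reads)
  keep <- flagged_fraction <= max_flag_fraction
  out <- expression_matrix(unclass(counts)[keep, , drop = FALSE],
                           unit = "counts")
  attr(out, "removed") <- rownames(counts)[!keep]
  out
}

#' Threshold a differential-expression results table
#'
#' Generic post-filter on an externally fitted DE table: keeps entries with
#' adjusted p below `alpha` and |log2 fold-change| above `lfc`.
#'
#' @param de data frame with columns `padj` and `log2FoldChange`.
#' @param alpha adjusted-p threshold (default 0.005, exclusive).
#' @param lfc absolute log2 fold-change threshold (default 1, exclusive).
#' @return The filtered data frame.
#' @export
filter_de_results <- function(de, alpha = 0.005, lfc = 1) {
  stopifnot(is.data.frame(de), all(c("padj", "log2FoldChange") %in% names(de)))
  keep <- !is.na(de$padj) & de$padj < alpha & abs(de$log2FoldChange) > lfc
  out <- de[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
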