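# Recognised header spellings for each canonical MAF-lite field.  Firebrowse
# ("Mutation_Packager_Calls") and CCLE exports use the TCGA names; the
# package's own writer uses the canonical lower-case names.
.maf_column_aliases <- list(
  sample_id              = c("sample_id", "Tumor_Sample_Barcode", "Sample", "sample"),
  gene_symbol            = c("gene_symbol", "Hugo_Symbol", "Gene", "gene"),
  gene_id                = c("gene_id", "Ensembl_Gene_Id", "Gene_Id"),
  variant_classification = c("variant_classification", "Variant_Classification"),
  variant_type           = c("variant_type", "Variant_Type"),
  protein_change         = c("protein_change", "Protein_Change", "HGVSp_Short",
                             "amino_acid_change")
)

.maf_fields <- names(.maf_column_aliases)

#' Construct a mutation table
#'
#' One somatic variant call per row. `sample_id`, `gene_symbol` and
#' `variant_classification` are mandatory; `gene_id`, `variant_type` and
#' `protein_change` may be `NA`. Gene symbols are upper-cased so that
#' matching within one species is case-insensitive.
#'
#' @param df data frame with (a subset of) the canonical columns
#'   `sample_id`, `gene_symbol`, `gene_id`, `variant_classification`,
#'   `variant_type`, `protein_change`.
#' @return A `mutation_table` (a data frame).
#' @export
mutation_table <- function(df) {
  stopifnot(is.data.frame(df))
  for (f in c("sample_id", "gene_symbol", "variant_classification")) {
    if (!f %in% names(df))
      stop("mutation_table: missing required column '", f, "'", call. = FALSE)
  }
  opt <- function(field) {
    x <- if (field %in% names(df)) as.character(df[[field]])
         else rep(NA_character_, nrow(df))
    x[!is.na(x) & !nzchar(x)] <- NA_character_   # blank TSV fields are NA
    x
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
    sample_id              = as.character(df$sample_id),
    gene_symbol            = toupper(as.character(df$gene_symbol)),
    gene_id                = opt("gene_id"),
    variant_classification = as.character(df$variant_classification),
    variant_type           = opt("variant_type"),
    protein_change         = opt("protein_change")
  )
  if (nrow(out) > 0L &&
      (anyNA(out$sample_id) || any(!nzchar(out$sample_id)) ||
       anyNA(out$gene_symbol) || any(!nzchar(out$gene_symbol))))
    stop("mutation_table: sample_id and gene_symbol must be non-empty",
         call. = FALSE)
  class(out) <- c("mutation_table", "data.frame")
  out
}

.resolve_maf_columns <- function(header, need_sample = TRUE) {
  resolved <- lapply(.maf_column_aliases, function(al) {
    hit <- al[al %in% header]
    if (length(hit)) hit[[1L]] else NA_character_
  })
  mandatory <- c("gene_symbol", "variant_classification",
                 if (need_sample) "sample_id")
  for (f in mandatory) {
    if (is.na(resolved[[f]]))
      stop("MAF format error: missing required column '", f,
           "' (accepted spellings: ",
           paste(.maf_column_aliases[[f]], collapse = ", "), ")",
           call. = FALSE)
  }
  resolved
}

.read_maf_file <- function(path, need_sample = TRUE, sample_id = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  cols <- .resolve_maf_columns(names(raw), need_sample = need_sample)
  df <- data.frame(stringsAsFactors = FALSE, row.names = NULL,
                   gene_symbol = raw[[cols$gene_symbol]],
                   variant_classification = raw[[cols$variant_classification]])
  df$sample_id <- if (!is.null(sample_id)) sample_id else raw[[cols$sample_id]]
  for (f in c("gene_id", "variant_type", "protein_change"))
    if (!is.na(cols[[f]])) df[[f]] <- raw[[cols[[f]]]]
  df
}

#' Read somatic mutation calls in MAF-lite format
#'
#' Two dialects are supported: `"single-file"` (one TSV holding all samples,
#' with a sample column) and `"per-sample-directory"` (a directory of
#' per-sample files, Firebrowse Mutation_Packager_Calls style, where the
#' sample ID is the file-name stem). Column aliases for TCGA/CCLE exports
#' are recognised automatically. Classification tokens not covered by
#' `scheme` are retained and counted in the ingestion log (attribute
#' `ingest_log`).
#'
#' @param path file (single-file dialect) or directory
#'   (per-sample-directory dialect).
#' @param dialect `"single-file"` or `"per-sample-directory"`.
#' @param scheme a [variant_class_scheme()] used only to flag unknown
#'   classification tokens at ingestion.
#' @return A [mutation_table()] with an `ingest_log` attribute
#'   (`n_records`, `n_unknown_class`, `unknown_tokens`, `files`).
#' @export
read_maf <- function(path,
                     dialect = c("single-file", "per-sample-directory"),
                     scheme = default_variant_scheme()) {
  dialect <- match.arg(dialect)
  if (dialect == "single-file") {
    if (!file.exists(path)) stop("read_maf: no such file: ", path, call. = FALSE)
    files <- path
    dfs <- list(.read_maf_file(path, need_sample = TRUE))
  } else {
    if (!dir.exists(path)) stop("read_maf: no such directory: ", path, call. = FALSE)
    files <- sort(list.files(path, pattern = "\\.(maf|tsv|txt)$",
                             full.names = TRUE))
    if (!length(files))
      stop("read_maf: no .maf/.tsv/.txt files in ", path, call. = FALSE)
    dfs <- lapply(files, function(f)
      .read_maf_file(f, need_sample = FALSE,
                     sample_id = tools::file_path_sans_ext(basename(f))))
  }
  df <- do.call(rbind, dfs)
  if (is.null(df) || nrow(df) == 0L) {
    warning("read_maf: no records in ", path)
    df <- data.frame(sample_id = character(), gene_symbol = character(),
                     variant_classification = character())
  }
  tab <- mutation_table(df)
  known <- unlist(unclass(scheme)[c("non_silent_tokens", "silent_tokens",
                                    "excluded_tokens")], use.names = FALSE)
  unknown <- setdiff(unique(tab$variant_classification), known)
  attr(tab, "ingest_log") <- list(
    n_records = nrow(tab),
    n_unknown_class = sum(tab$variant_classification %in% unknown),
    unknown_tokens = unknown,
    files = files)
  tab
}

#' Write a mutation table as MAF-lite TSV
#'
#' Writes the canonical lower-case column names, which [read_maf()] accepts,
#' so write-then-read round-trips the logical content.
#'
#' @param table a [mutation_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_maf <- function(table, path) {
  stopifnot(inherits(table, "mutation_table"))
  utils::write.table(as.data.frame(table)[, .maf_fields], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write one-symbol-per-line text lists
#'
#' Used for protein identification lists and plain gene sets. Blank lines
#' and surrounding whitespace are dropped; case is preserved (normalisation
#' happens at matching time).
#'
#' @param path file path.
#' @return `read_symbol_list`: character vector.
#' @export
read_symbol_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' @rdname read_symbol_list
#' @param symbols character vector to write.
#' @export
write_symbol_list <- function(symbols, path) {
  writeLines(as.character(symbols), path)
  invisible(path)
}

#' Restrict a dataset to a protein-coding gene universe
#'
#' Entries whose gene identifier (optionally mapped through `idmap` first)
#' is found in `coding_ids` survive; the number removed is recorded in the
#' `n_removed` attribute. Matching is case-insensitive. An empty
#' intersection yields an empty result with a warning, not an error.
#'
#' @param x a [mutation_table()] or [expression_matrix()].
#' @param coding_ids non-empty character vector of allowed identifiers.
#' @param idmap optional [id_map()] applied to the entry identifiers before
#'   filtering.
#' @param from_ns,to_ns namespaces for `idmap` (required when it is given).
#' @param by for mutation tables: which column identifies the gene
#'   (`"gene_symbol"` or `"gene_id"`).
#' @return Object of the same type, filtered.
#' @export
filter_protein_coding <- function(x, coding_ids, idmap = NULL,
                                  from_ns = NULL, to_ns = NULL, ...) {
  UseMethod("filter_protein_coding")
}

.pc_keep <- function(ids, coding_ids, idmap, from_ns, to_ns) {
  if (!length(coding_ids)) stop("filter_protein_coding: empty coding_ids",
                                call. = FALSE)
  key <- ids
  if (!is.null(idmap)) {
    res <- map_identifiers(ids, idmap, from_ns, to_ns, collapse = FALSE)
    key <- res$mapped_all          # positionally aligned, NA where unmapped
  }
  keep <- !is.na(key) & toupper(key) %in% toupper(coding_ids)
  if (!any(keep) && length(ids))
    warning("filter_protein_coding: empty intersection with coding universe")
  keep
}

#' @rdname filter_protein_coding
#' @export
filter_protein_coding.mutation_table <- function(x, coding_ids, idmap = NULL,
                                                 from_ns = NULL, to_ns = NULL,
                                                 by = c("gene_symbol", "gene_id"),
                                                 ...) {
  by <- match.arg(by)
  keep <- .pc_keep(x[[by]], coding_ids, idmap, from_ns, to_ns)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(x)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' @rdname filter_protein_coding
#' @export
filter_protein_coding.expression_matrix <- function(x, coding_ids,
                                                    idmap = NULL,
                                                    from_ns = NULL,
                                                    to_ns = NULL, ...) {
  keep <- .pc_keep(rownames(x), coding_ids, idmap, from_ns, to_ns)
  out <- expression_matrix(unclass(x)[keep, , drop = FALSE], unit = expr_unit(x))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' @rdname filter_protein_coding
#' @export
filter_protein_coding.default <- function(x, coding_ids, idmap = NULL,
                                          from_ns = NULL, to_ns = NULL, ...) {
  keep <- .pc_keep(as.character(x), coding_ids, idmap, from_ns, to_ns)
  out <- x[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}
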