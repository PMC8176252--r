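.expr_units <- c("TPM", "scaled_estimate", "counts")

#' Construct a gene-by-sample expression matrix
#'
#' A numeric genes x samples matrix with a declared unit. Values must be
#' non-negative and finite; gene identifiers (rownames) must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames.
#' @param unit one of `"TPM"`, `"scaled_estimate"` (RSEM within-sample
#'   proportion; TPM / 1e6), `"counts"`.
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(values, unit = c("TPM", "scaled_estimate", "counts")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("expression_matrix: gene names are required", call. = FALSE)
  if (ncol(values) > 0L && is.null(colnames(values)))
    stop("expression_matrix: sample names are required", call. = FALSE)
  if (nrow(values) == 0L && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("expression_matrix: duplicate gene identifiers", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression_matrix: values must be finite and >= 0", call. = FALSE)
  structure(values, unit = unit,
            class = c("expression_matrix", "matrix", "array"))
}

#' Declared unit of an expression matrix
#' @param m an [expression_matrix()].
#' @return The unit string.
#' @export
expr_unit <- function(m) {
  u <- attr(m, "unit")
  if (is.null(u)) stop("not an expression_matrix: no unit attribute",
                       call. = FALSE)
  u
}

#' Read / write an expression matrix TSV
#'
#' Genes in rows, samples in columns, first column the gene identifier.
#' Duplicate gene rows keep the first occurrence (with a warning), matching
#' the automatic replicate-removal convention used for ID conversion.
#'
#' @param path file path.
#' @param unit declared unit of the stored values.
#' @return `read_expression_matrix`: an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, unit = c("TPM", "scaled_estimate", "counts")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  dup <- duplicated(ids)
  if (any(dup)) {
    warning("read_expression_matrix: ", sum(dup),
            " duplicate gene identifier(s) dropped (first occurrence kept)")
    df <- df[!dup, , drop = FALSE]
    ids <- ids[!dup]
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  expression_matrix(m, unit = unit)
}

#' @rdname read_expression_matrix
#' @param m an [expression_matrix()] to write.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert RSEM scaled_estimate values to TPM
#'
#' TPM is the scaled_estimate (a within-sample transcript proportion)
#' multiplied by 10^6.
#'
#' @param m an [expression_matrix()] with unit `"scaled_estimate"`.
#' @return An [expression_matrix()] in TPM.
#' @export
convert_scaled_estimate_to_tpm <- function(m) {
  if (expr_unit(m) != "scaled_estimate")
    stop("convert_scaled_estimate_to_tpm: unit is '", expr_unit(m),
         "', expected 'scaled_estimate'", call. = FALSE)
  expression_matrix(unclass(m) * 1e6, unit = "TPM")
}
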