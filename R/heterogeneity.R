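#' Matching dissimilarity between two Boolean vectors
#'
#' The fraction of positions at which the vectors disagree. 0 means
#' identical profiles, 1 complementary profiles. Double absence (both
#' `FALSE`) counts as agreement, which is why very sparse mutation profiles
#' score as similar under this metric.
#'
#' @param u,v logical (or 0/1 numeric) vectors of equal positive length.
#' @return A number in \[0, 1\].
#' @export
matching_dissimilarity <- function(u, v) {
  if (length(u) != length(v))
    stop("matching_dissimilarity: length mismatch (", length(u), " vs ",
         length(v), ")", call. = FALSE)
  if (length(u) == 0L)
    stop("matching_dissimilarity: zero-length vectors", call. = FALSE)
  u <- as.logical(u); v <- as.logical(v)
  if (anyNA(u) || anyNA(v))
    stop("matching_dissimilarity: NA values", call. = FALSE)
  mean(u != v)
}

#' Correlation distance between two real vectors
#'
#' One minus the Pearson correlation,
#' `1 - ((u - mean(u)) . (v - mean(v))) / (||u - mean(u)|| ||v - mean(v)||)`,
#' ranging over \[0, 2\]: 0 for positively affine-related vectors, 1 for
#' uncorrelated ones, 2 for perfect anti-correlation. Constant vectors have
#' no defined correlation and raise an error.
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return A number in \[0, 2\].
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v))
    stop("correlation_distance: length mismatch", call. = FALSE)
  if (length(u) < 2L)
    stop("correlation_distance: need length >= 2", call. = FALSE)
  uc <- u - mean(u)
  vc <- v - mean(v)
  nu <- sqrt(sum(uc^2))
  nv <- sqrt(sum(vc^2))
  if (nu == 0 || nv == 0)
    stop("correlation_distance: zero-variance (degenerate) vector",
         call. = FALSE)
  1 - sum(uc * vc) / (nu * nv)
}

#' Construct a labelled dissimilarity matrix
#'
#' @param values symmetric numeric matrix with sample dimnames; `NA` rows
#'   mark degenerate samples.
#' @param metric `"matching"` or `"correlation_distance"`.
#' @param degenerate sample IDs excluded as degenerate.
#' @return A `dissimilarity_matrix` with a `summary` attribute (min, max,
#'   mean over the strict upper triangle of finite entries).
#' @export
dissimilarity_matrix <- function(values,
                                 metric = c("matching", "correlation_distance"),
                                 degenerate = character()) {
  metric <- match.arg(metric)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  m <- structure(values, metric = metric, degenerate = degenerate,
                 class = c("dissimilarity_matrix", "matrix", "array"))
  attr(m, "summary") <- summarize_matrix(m)
  m
}

#' Pairwise dissimilarity over a cohort
#'
#' Applies [matching_dissimilarity()] over all sample pairs of a
#' [build_profiles()] matrix, or [correlation_distance()] over all sample
#' pairs (columns) of a TPM [expression_matrix()]. Zero-variance expression
#' samples are degenerate: their rows/columns are `NA`, they are listed in
#' the `degenerate` attribute and excluded from the summary.
#'
#' @param data a `mutation_profile_matrix` (samples x genes, metric
#'   `"matching"`) or an [expression_matrix()] (genes x samples, metric
#'   `"correlation_distance"`).
#' @param metric optional; must be compatible with the data kind.
#' @param log2_transform for expression data, compare `log2(TPM + 1)`
#'   instead of raw TPM (default `FALSE`).
#' @return A [dissimilarity_matrix()].
#' @export
pairwise_matrix <- function(data, metric = NULL, log2_transform = FALSE) {
  if (inherits(data, "mutation_profile_matrix")) {
    if (!is.null(metric) && metric != "matching")
      stop("pairwise_matrix: Boolean profiles support only the matching metric",
           call. = FALSE)
    if (nrow(data) < 2L) stop("pairwise_matrix: need >= 2 samples", call. = FALSE)
    x <- unclass(data)
    storage.mode(x) <- "double"
    G <- ncol(x)
    if (G == 0L) stop("pairwise_matrix: empty gene universe", call. = FALSE)
    d <- (x %*% t(1 - x) + (1 - x) %*% t(x)) / G
    d <- (d + t(d)) / 2          # kill round-off asymmetry
    dimnames(d) <- list(rownames(data), rownames(data))
    return(dissimilarity_matrix(d, "matching"))
  }
  if (inherits(data, "expression_matrix")) {
    if (!is.null(metric) && metric != "correlation_distance")
      stop("pairwise_matrix: expression data support only correlation_distance",
           call. = FALSE)
    if (ncol(data) < 2L) stop("pairwise_matrix: need >= 2 samples", call. = FALSE)
    x <- unclass(data)
    if (log2_transform) x <- log2(x + 1)
    cs <- apply(x, 2L, stats::sd)
    degenerate <- colnames(x)[cs == 0]
    xc <- sweep(x, 2L, colMeans(x))
    nrm <- sqrt(colSums(xc^2))
    nrm[nrm == 0] <- NA_real_
    xn <- sweep(xc, 2L, nrm, "/")
    d <- 1 - crossprod(xn)
    d <- (d + t(d)) / 2
    diag(d)[!colnames(x) %in% degenerate] <- 0
    dimnames(d) <- list(colnames(x), colnames(x))
    return(dissimilarity_matrix(d, "correlation_distance",
                                degenerate = degenerate))
  }
  stop("pairwise_matrix: unsupported input type", call. = FALSE)
}

#' Summarise a dissimilarity matrix
#'
#' Minimum, maximum and mean over the strict upper triangle (the diagonal is
#' never included); `NA` entries from degenerate samples are dropped.
#'
#' @param m a square [dissimilarity_matrix()] (or plain symmetric matrix).
#' @return List with `min`, `max`, `mean`, `n_pairs`.
#' @export
summarize_matrix <- function(m) {
  m <- as.matrix(m)
  ut <- m[upper.tri(m)]
  ut <- ut[is.finite(ut)]
  if (!length(ut))
    stop("summarize_matrix: no usable off-diagonal entries", call. = FALSE)
  list(min = min(ut), max = max(ut), mean = mean(ut), n_pairs = length(ut))
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("dissimilarity_matrix [%s]: %d samples; off-diagonal range %.3g-%.3g, mean %.3g\n",
              attr(x, "metric"), nrow(x), s$min, s$max, s$mean))
  if (length(attr(x, "degenerate")))
    cat("degenerate samples:", paste(attr(x, "degenerate"), collapse = ", "), "\n")
  invisible(x)
}

#' Write a dissimilarity matrix as TSV
#'
#' @param m a [dissimilarity_matrix()].
#' @param path output file (header row/first column are sample IDs).
#' @export
write_dissimilarity_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.matrix(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
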