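.check_contingency <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals)))
    stop("enrichment: table cells must be non-negative integers", call. = FALSE)
  if (n > N || K > N || k > min(n, K) || k < max(0, n + K - N))
    stop("enrichment: inconsistent contingency table (k=", k, ", n=", n,
         ", K=", K, ", N=", N, ")", call. = FALSE)
}

#' One-sided Fisher exact test for over-representation
#'
#' Hypergeometric upper tail `P(X >= k)` for drawing `k` annotated genes in
#' a list of `n`, given `K` annotated genes in a universe of `N`.
#'
#' @param k list hits; `n` list size; `K` term size; `N` universe size.
#' @param n,K,N see `k`.
#' @return p-value in (0, 1].
#' @export
fisher_exact_enrichment <- function(k, n, K, N) {
  .check_contingency(k, n, K, N)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score (jackknifed Fisher exact test)
#'
#' The one-sided Fisher exact p-value recomputed with one list hit removed
#' (`k - 1` against the same margins), a conservative penalty that nullifies
#' single-gene support: `k <= 1` scores exactly 1. Always >= the unpenalised
#' Fisher p-value.
#'
#' @inheritParams fisher_exact_enrichment
#' @return p-value in (0, 1].
#' @export
ease_score <- function(k, n, K, N) {
  .check_contingency(k, n, K, N)
  if (k <= 1) return(1)
  stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation with the EASE score
#'
#' Scores every term of `collection` against `query` with both the EASE and
#' the plain one-sided Fisher exact p-value, plus fold enrichment
#' `(k/n)/(K/N)` and a Benjamini-Hochberg column (informational only; the
#' reporting filter uses the raw EASE p). Query genes outside the
#' collection's universe are dropped with a warning. Reported rows satisfy
#' `ease_p <= ease_cutoff` and `k >= min_count`, ranked by ascending EASE p
#' with ties broken by term name.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param universe_size background size `N`; defaults to the collection's
#'   unique-gene count (annotated-universe convention).
#' @param ease_cutoff report terms with EASE p at or below this (default 0.1).
#' @param min_count minimum list hits per reported term (default 2).
#' @return An `enrichment_result`: list with `full` and `reported` data
#'   frames (`term, k, n, K, N, ease_p, fisher_p, bh_q, fold_enrichment,
#'   genes`) and the thresholds used.
#' @export
enrich <- function(query, collection, universe_size = NULL,
                   ease_cutoff = 0.1, min_count = 2) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(toupper(as.character(query)))
  if (!length(query)) {
    warning("enrich: empty query")
    empty <- data.frame(term = character(), k = integer(), n = integer(),
                        K = integer(), N = integer(), ease_p = numeric(),
                        fisher_p = numeric(), bh_q = numeric(),
                        fold_enrichment = numeric(), genes = character(),
                        stringsAsFactors = FALSE)
    return(structure(list(full = empty, reported = empty,
                          ease_cutoff = ease_cutoff, min_count = min_count),
                     class = "enrichment_result"))
  }
  universe <- attr(collection, "universe")
  out_of_universe <- setdiff(query, universe)
  if (length(out_of_universe))
    warning("enrich: ", length(out_of_universe),
            " query gene(s) outside the collection universe were dropped")
  query <- intersect(query, universe)
  N <- if (is.null(universe_size)) attr(collection, "universe_size")
       else as.integer(universe_size)
  n <- length(query)
  rows <- lapply(names(collection), function(term) {
    members <- collection[[term]]
    hits <- intersect(query, members)
    k <- length(hits)
    K <- length(members)
    data.frame(term = term, k = k, n = n, K = K, N = N,
               ease_p = ease_score(k, n, K, N),
               fisher_p = fisher_exact_enrichment(k, n, K, N),
               fold_enrichment = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_,
               genes = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  full <- do.call(rbind, rows)
  full$bh_q <- stats::p.adjust(full$ease_p, method = "BH")
  full <- full[order(full$ease_p, full$term),
               c("term", "k", "n", "K", "N", "ease_p", "fisher_p", "bh_q",
                 "fold_enrichment", "genes")]
  rownames(full) <- NULL
  reported <- full[full$ease_p <= ease_cutoff & full$k >= min_count, ,
                   drop = FALSE]
  rownames(reported) <- NULL
  structure(list(full = full, reported = reported,
                 ease_cutoff = ease_cutoff, min_count = min_count),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d/%d terms pass EASE <= %g and count >= %d\n",
              nrow(x$reported), nrow(x$full), x$ease_cutoff, x$min_count))
  if (nrow(x$reported))
    print(utils::head(x$reported[, c("term", "k", "K", "ease_p",
                                     "fold_enrichment")], 10L))
  invisible(x)
}

#' Write an enrichment table as TSV
#'
#' @param result an `enrichment_result` from [enrich()].
#' @param path output file.
#' @param which write the `"full"` or `"reported"` table.
#' @export
write_enrichment <- function(result, path, which = c("full", "reported")) {
  which <- match.arg(which)
  utils::write.table(result[[which]], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
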