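#' Variant classification scheme
#'
#' Partitions MAF variant-classification tokens into non-silent (protein
#' altering), silent (synonymous) and excluded (non-coding) groups. Tokens
#' seen in data but absent from all three groups are labelled `unknown`.
#'
#' @param non_silent_tokens,silent_tokens,excluded_tokens disjoint character
#'   vectors of classification tokens.
#' @return A `variant_class_scheme`.
#' @export
variant_class_scheme <- function(non_silent_tokens, silent_tokens,
                                 excluded_tokens = character()) {
  all_tok <- c(non_silent_tokens, silent_tokens, excluded_tokens)
  if (anyDuplicated(all_tok))
    stop("variant_class_scheme: token groups must be disjoint", call. = FALSE)
  structure(list(non_silent_tokens = as.character(non_silent_tokens),
                 silent_tokens = as.character(silent_tokens),
                 excluded_tokens = as.character(excluded_tokens)),
            class = "variant_class_scheme")
}

#' Default MAF classification scheme
#'
#' Standard MAF conventions: the non-silent group covers missense, nonsense,
#' nonstop, frameshift and in-frame indels, splice-site and
#' translation-start-site changes; `Silent` is synonymous; UTR/flank/intron/
#' RNA/IGR records are excluded from coding analyses.
#'
#' @return A [variant_class_scheme()].
#' @export
default_variant_scheme <- function() {
  variant_class_scheme(
    non_silent_tokens = c("Missense_Mutation", "Nonsense_Mutation",
                          "Nonstop_Mutation", "Frame_Shift_Del",
                          "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
                          "Splice_Site", "Translation_Start_Site"),
    silent_tokens = "Silent",
    excluded_tokens = c("3'UTR", "5'UTR", "Intron", "RNA", "IGR",
                        "3'Flank", "5'Flank"))
}

#' Read a classification scheme from YAML
#'
#' Expects top-level keys `non_silent`, `silent`, `excluded` (each a list of
#' tokens), so users can match a cohort's exact convention.
#'
#' @param path YAML file.
#' @return A [variant_class_scheme()].
#' @export
read_variant_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  variant_class_scheme(unlist(y$non_silent), unlist(y$silent),
                       unlist(y$excluded))
}

#' Classify variant-classification tokens
#'
#' @param token character vector of classification tokens.
#' @param scheme a [variant_class_scheme()].
#' @return Character vector over
#'   `c("silent", "non_silent", "excluded", "unknown")`.
#' @export
classify_variant <- function(token, scheme = default_variant_scheme()) {
  stopifnot(inherits(scheme, "variant_class_scheme"))
  out <- rep("unknown", length(token))
  out[token %in% scheme$non_silent_tokens] <- "non_silent"
  out[token %in% scheme$silent_tokens] <- "silent"
  out[token %in% scheme$excluded_tokens] <- "excluded"
  out
}

#' Build Boolean mutation profiles
#'
#' Encodes each sample as a Boolean vector over a fixed, lexicographically
#' ordered gene universe: `TRUE` iff the sample carries at least one
#' non-silent mutation in that gene (multiple hits collapse to one). The
#' universe defaults to the union of all non-silently mutated genes in the
#' cohort; a caller-supplied universe (e.g. all protein-coding genes) is
#' honoured, with mutated genes outside it dropped with a warning.
#'
#' @param table a [mutation_table()].
#' @param scheme a [variant_class_scheme()].
#' @param universe optional character vector of gene symbols.
#' @return A logical samples x genes `mutation_profile_matrix`.
#' @export
build_profiles <- function(table, scheme = default_variant_scheme(),
                           universe = NULL) {
  stopifnot(inherits(table, "mutation_table"), nrow(table) > 0L)
  samples <- unique(table$sample_id)
  lab <- classify_variant(table$variant_classification, scheme)
  ns <- table[lab == "non_silent", c("sample_id", "gene_symbol")]
  mutated <- sort(unique(ns$gene_symbol))
  if (is.null(universe)) {
    universe <- mutated
  } else {
    universe <- sort(unique(toupper(as.character(universe))))
    missing <- setdiff(mutated, universe)
    if (length(missing))
      warning("build_profiles: ", length(missing),
              " mutated gene(s) outside the supplied universe were dropped")
    ns <- ns[ns$gene_symbol %in% universe, , drop = FALSE]
  }
  m <- matrix(FALSE, nrow = length(samples), ncol = length(universe),
              dimnames = list(samples, universe))
  if (nrow(ns))
    m[cbind(match(ns$sample_id, samples), match(ns$gene_symbol, universe))] <- TRUE
  structure(m, class = c("mutation_profile_matrix", "matrix", "array"))
}

#' Per-sample mutation-count statistics
#'
#' Counts, per sample, the genes carrying silent and non-silent mutations
#' (default) or the raw mutation events (`unit = "events"`), the non-silent
#' genes private to that sample within the cohort, and the derived ratios.
#'
#' @param table a [mutation_table()].
#' @param scheme a [variant_class_scheme()].
#' @param unit count mutated genes (collapsed per sample) or raw events.
#' @return A `sample_mutation_counts` data frame with columns `sample_id`,
#'   `n_silent`, `n_non_silent`, `n_unique_non_silent`, `ratio_non_silent`
#'   (= non-silent / (silent + non-silent)) and `ratio_unique_non_silent`
#'   (= unique / non-silent). Uniqueness is always gene-based.
#' @export
count_mutations <- function(table, scheme = default_variant_scheme(),
                            unit = c("genes", "events")) {
  stopifnot(inherits(table, "mutation_table"), nrow(table) > 0L)
  unit <- match.arg(unit)
  samples <- unique(table$sample_id)
  if (length(samples) == 1L)
    warning("count_mutations: single-sample cohort - all its genes are unique")
  lab <- classify_variant(table$variant_classification, scheme)
  gene_sets <- function(which_lab)
    lapply(samples, function(s) {
      sel <- table$sample_id == s & lab == which_lab
      unique(table$gene_symbol[sel])
    })
  ns_sets <- gene_sets("non_silent")
  si_sets <- gene_sets("silent")
  count_of <- function(which_lab, sets) {
    if (unit == "genes") lengths(sets)
    else vapply(samples, function(s)
      sum(table$sample_id == s & lab == which_lab), 0L)
  }
  n_ns <- count_of("non_silent", ns_sets)
  n_si <- count_of("silent", si_sets)
  # gene counts across the rest of the cohort, for privacy
  tab_ns <- table(unlist(ns_sets, use.names = FALSE))
  n_uni <- vapply(ns_sets, function(g)
    sum(tab_ns[g] == 1L), 0L)
  out <- data.frame(sample_id = samples,
                    n_silent = as.integer(n_si),
                    n_non_silent = as.integer(n_ns),
                    n_unique_non_silent = as.integer(n_uni),
                    stringsAsFactors = FALSE)
  out$ratio_non_silent <- ifelse(out$n_silent + out$n_non_silent > 0,
                                 out$n_non_silent / (out$n_silent + out$n_non_silent),
                                 NA_real_)
  out$ratio_unique_non_silent <- ifelse(out$n_non_silent > 0,
                                        out$n_unique_non_silent / out$n_non_silent,
                                        NA_real_)
  class(out) <- c("sample_mutation_counts", "data.frame")
  out
}

#' Silent vs non-silent gene-count regression
#'
#' Ordinary least squares of non-silent counts (y) on silent counts (x),
#' with the Pearson correlation; used to check whether silent and
#' non-silent mutation loads track each other across samples.
#'
#' @param counts a [count_mutations()] result with >= 3 samples.
#' @return A `regression_result`: `slope`, `intercept`, `r`, `r_squared`.
#' @export
silent_nonsilent_regression <- function(counts) {
  stopifnot(inherits(counts, "data.frame"), nrow(counts) >= 3L)
  x <- counts$n_silent
  y <- counts$n_non_silent
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("silent_nonsilent_regression: zero variance, correlation undefined",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = r, r_squared = r^2),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g   R = %.4f, R^2 = %.4f\n",
              x$slope, x$intercept, x$r, x$r_squared))
  invisible(x)
}

#' Catalogue the non-silent variant spectrum of one gene
#'
#' Distinct variants are keyed on the protein-change string (records lacking
#' one are keyed on a synthetic `(classification|variant_type)` label), with
#' per-variant distinct-sample and raw record counts, ranked by sample count
#' with lexicographic tie-breaking, plus the partition of distinct variants
#' over the classification tokens.
#'
#' @param table a [mutation_table()] for the whole cohort.
#' @param gene gene symbol (case-insensitive).
#' @param scheme a [variant_class_scheme()]; only non-silent records qualify.
#' @return A `variant_catalog`: `gene_symbol`, `variants` (data frame
#'   `protein_change`, `classification`, `n_samples`, `n_records`),
#'   `class_partition` (distinct variants per class), `n_samples_mutated`,
#'   `fraction_samples_mutated`, `n_cohort_samples`.
#' @export
variant_catalog <- function(table, gene, scheme = default_variant_scheme()) {
  stopifnot(inherits(table, "mutation_table"))
  gene <- toupper(gene)
  n_cohort <- length(unique(table$sample_id))
  lab <- classify_variant(table$variant_classification, scheme)
  sub <- table[table$gene_symbol == gene & lab == "non_silent", , drop = FALSE]
  if (nrow(sub) == 0L) {
    variants <- data.frame(protein_change = character(),
                           classification = character(),
                           n_samples = integer(), n_records = integer(),
                           stringsAsFactors = FALSE)
    return(structure(list(gene_symbol = gene, variants = variants,
                          class_partition = integer(0),
                          n_samples_mutated = 0L,
                          fraction_samples_mutated = 0,
                          n_cohort_samples = n_cohort),
                     class = "variant_catalog"))
  }
  key <- sub$protein_change
  no_pc <- is.na(key) | !nzchar(key)
  key[no_pc] <- sprintf("(%s|%s)", sub$variant_classification[no_pc],
                        ifelse(is.na(sub$variant_type[no_pc]), "NA",
                               sub$variant_type[no_pc]))
  agg <- split(seq_len(nrow(sub)), key)
  variants <- data.frame(
    protein_change = names(agg),
    classification = vapply(agg, function(i) sub$variant_classification[i[1L]], ""),
    n_samples = vapply(agg, function(i) length(unique(sub$sample_id[i])), 0L),
    n_records = lengths(agg),
    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-variants$n_samples, variants$protein_change)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  n_mut <- length(unique(sub$sample_id))
  structure(list(gene_symbol = gene, variants = variants,
                 class_partition = table(variants$classification),
                 n_samples_mutated = n_mut,
                 fraction_samples_mutated = n_mut / n_cohort,
                 n_cohort_samples = n_cohort),
            class = "variant_catalog")
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat(sprintf("variant_catalog %s: %d distinct variant(s), mutated in %d/%d samples (%.1f%%)\n",
              x$gene_symbol, nrow(x$variants), x$n_samples_mutated,
              x$n_cohort_samples, 100 * x$fraction_samples_mutated))
  print(utils::head(x$variants, 10L))
  invisible(x)
}

#' Variants shared between two catalogues of the same gene
#'
#' @param cat_a,cat_b [variant_catalog()] objects for the same gene.
#' @return Sorted character vector of shared protein-change labels.
#' @export
shared_variants <- function(cat_a, cat_b) {
  stopifnot(inherits(cat_a, "variant_catalog"),
            inherits(cat_b, "variant_catalog"))
  if (!identical(cat_a$gene_symbol, cat_b$gene_symbol))
    stop("shared_variants: catalogs describe different genes (",
         cat_a$gene_symbol, " vs ", cat_b$gene_symbol, ")", call. = FALSE)
  sort(intersect(cat_a$variants$protein_change, cat_b$variants$protein_change))
}
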