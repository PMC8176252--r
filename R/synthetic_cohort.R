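# Seeding discipline: every generator expands one cohort-level seed into
# per-sample substreams as seed + sample counter (expression streams offset
# by a fixed constant), so adding samples never perturbs earlier samples and
# a fixed seed yields byte-identical files. Consequence: two cohorts whose
# seeds differ by less than n_samples share sample substreams - space cohort
# seeds by more than the sample count when independence matters.

.check_prob <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("invalid ", what, ": must be a probability in [0, 1]", call. = FALSE)
}

#' Default hotspot variant spectrum for the obligate gene
#'
#' Six named protein-change labels spanning the five non-silent variant
#' classes seen in recurrently mutated tumor-suppressor spectra (missense,
#' nonsense, frameshift deletion, splice site, in-frame deletion), with the
#' missense hotspot p.R248Q as the most frequent variant. Labels are plain
#' strings; no sequence-level meaning is attached.
#'
#' @return Data frame with `protein_change`, `classification`, `weight`
#'   (weights sum to 1).
#' @export
default_hotspot_spectrum <- function() {
  data.frame(
    protein_change = c("p.R248Q", "p.R175H", "p.E343*", "p.P152fs",
                       "p.T125_splice", "p.I255del"),
    classification = c("Missense_Mutation", "Missense_Mutation",
                       "Nonsense_Mutation", "Frame_Shift_Del",
                       "Splice_Site", "In_Frame_Del"),
    weight = c(0.30, 0.20, 0.15, 0.15, 0.10, 0.10),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic mutation cohort
#'
#' The generative model: a gene universe of `n_genes` symbols, the first
#' `n_backbone` of which form a shared backbone mutated in each sample with
#' probability `p_backbone`; the remaining genes acquire private non-silent
#' mutations with probability `p_private`. Silent mutations arise
#' independently per gene at `silent_odds` times the mean non-silent rate.
#' A per-sample log-normal burden multiplier (`burden_sd` on the log scale)
#' scales the private and silent rates so silent and non-silent loads
#' correlate across samples, as they do in real cohorts. An optional
#' obligate gene (TP53-like) is mutated in `obligate_fraction` of samples
#' with a variant drawn from a weighted hotspot spectrum.
#'
#' @param n_samples,n_genes cohort and universe sizes.
#' @param n_backbone number of backbone genes (<= `n_genes`).
#' @param p_backbone,p_private per-sample, per-gene mutation probabilities.
#' @param silent_odds expected silent events per non-silent event.
#' @param burden_sd log-scale SD of the per-sample burden multiplier.
#' @param obligate_gene symbol of the obligate gene, or `NULL` for none.
#' @param obligate_fraction probability each sample mutates the obligate gene.
#' @param hotspot_spectrum data frame as in [default_hotspot_spectrum()].
#' @param nonsilent_class_weights named weights over non-silent
#'   classification tokens for ordinary (non-obligate) mutations.
#' @param sample_prefix prefix for generated sample IDs.
#' @param seed integer cohort seed.
#' @return A `mutation_cohort_spec` list.
#' @export
mutation_cohort_spec <- function(n_samples, n_genes, n_backbone,
                                 p_backbone, p_private,
                                 silent_odds = 1 / 3, burden_sd = 0,
                                 obligate_gene = "TP53",
                                 obligate_fraction = 1,
                                 hotspot_spectrum = default_hotspot_spectrum(),
                                 nonsilent_class_weights = c(
                                   Missense_Mutation = 0.70,
                                   Nonsense_Mutation = 0.10,
                                   Frame_Shift_Del = 0.08,
                                   Splice_Site = 0.07,
                                   In_Frame_Del = 0.05),
                                 sample_prefix = "S", seed = 1L) {
  stopifnot(n_samples >= 1L, n_genes >= 1L, n_backbone >= 0L,
            n_backbone <= n_genes, silent_odds >= 0, burden_sd >= 0)
  .check_prob(p_backbone, "p_backbone")
  .check_prob(p_private, "p_private")
  .check_prob(obligate_fraction, "obligate_fraction")
  if (!is.null(obligate_gene)) {
    stopifnot(is.data.frame(hotspot_spectrum),
              all(c("protein_change", "classification", "weight") %in%
                    names(hotspot_spectrum)))
    if (abs(sum(hotspot_spectrum$weight) - 1) > 1e-8)
      stop("mutation_cohort_spec: hotspot spectrum weights must sum to 1",
           call. = FALSE)
  }
  if (abs(sum(nonsilent_class_weights) - 1) > 1e-8)
    stop("mutation_cohort_spec: class weights must sum to 1", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_backbone = as.integer(n_backbone),
                 p_backbone = p_backbone, p_private = p_private,
                 silent_odds = silent_odds, burden_sd = burden_sd,
                 obligate_gene = obligate_gene,
                 obligate_fraction = obligate_fraction,
                 hotspot_spectrum = hotspot_spectrum,
                 nonsilent_class_weights = nonsilent_class_weights,
                 sample_prefix = sample_prefix, seed = as.integer(seed)),
            class = "mutation_cohort_spec")
}

#' Preset cohort specifications
#'
#' `cell_line_cohort_spec()` emulates a dense, cell-line-like cohort: 12
#' samples, a large heavily shared mutation backbone (1500 of 5000 genes at
#' probability 0.8) plus moderate private mutation (0.02), the obligate gene
#' mutated in every sample, and a silent:non-silent odds of 1:3 (expected
#' non-silent ratio about 0.75 and mean pairwise matching dissimilarity
#' about 0.23). `patient_cohort_spec()` emulates a sparse, patient-like
#' cohort: 80 samples, a small weakly shared backbone (300 of 8500 at 0.3),
#' rarer private mutation (0.012), the obligate gene in 90% of samples and
#' more burden dispersion (expected mean matching dissimilarity about 0.06).
#'
#' @param seed integer cohort seed.
#' @param ... overrides passed to [mutation_cohort_spec()].
#' @return A `mutation_cohort_spec`.
#' @export
cell_line_cohort_spec <- function(seed = 1L, ...) {
  args <- list(n_samples = 12L, n_genes = 5000L, n_backbone = 1500L,
               p_backbone = 0.8, p_private = 0.02, silent_odds = 1 / 3,
               burden_sd = 0.3, obligate_fraction = 1,
               sample_prefix = "CL", seed = seed)
  do.call(mutation_cohort_spec, utils::modifyList(args, list(...)))
}

#' @rdname cell_line_cohort_spec
#' @export
patient_cohort_spec <- function(seed = 1L, ...) {
  args <- list(n_samples = 80L, n_genes = 8500L, n_backbone = 300L,
               p_backbone = 0.3, p_private = 0.012, silent_odds = 0.25,
               burden_sd = 0.5, obligate_fraction = 0.9,
               sample_prefix = "PT", seed = seed)
  do.call(mutation_cohort_spec, utils::modifyList(args, list(...)))
}

.class_to_type <- function(classification) {
  ifelse(grepl("Del$", classification), "DEL",
         ifelse(grepl("Ins$", classification), "INS", "SNP"))
}

#' Simulate a somatic mutation cohort
#'
#' Draws a MAF-lite [mutation_table()] from a [mutation_cohort_spec()] and
#' returns it with a truth record holding every planted quantity, so
#' downstream expected values can be computed without re-reading files.
#' Deterministic under a fixed seed.
#'
#' @param spec a [mutation_cohort_spec()].
#' @return List with `table` (a [mutation_table()]) and `truth`:
#'   `gene_universe`, per-sample `nonsilent_genes` / `silent_genes`
#'   (obligate gene included in the non-silent sets), `obligate` (data frame
#'   sample / protein_change / classification), `variant_counts` (planted
#'   per-variant sample counts) and `spec`.
#' @export
simulate_mutation_cohort <- function(spec) {
  stopifnot(inherits(spec, "mutation_cohort_spec"))
  G <- spec$n_genes
  genes <- toupper(sprintf("GENE%05d", seq_len(G)))
  p_gene <- rep(spec$p_private, G)
  if (spec$n_backbone > 0L) p_gene[seq_len(spec$n_backbone)] <- spec$p_backbone
  mean_ns_rate <- mean(p_gene)
  p_silent <- spec$silent_odds * mean_ns_rate
  samples <- sprintf("%s%02d", spec$sample_prefix, seq_len(spec$n_samples))
  cls <- names(spec$nonsilent_class_weights)
  recs <- vector("list", spec$n_samples)
  ns_sets <- si_sets <- vector("list", spec$n_samples)
  ob_rows <- list()
  for (i in seq_len(spec$n_samples)) {
    set.seed(spec$seed + i)
    burden <- exp(stats::rnorm(1L, 0, spec$burden_sd))
    p_ns_i <- p_gene
    priv <- seq_len(G) > spec$n_backbone
    p_ns_i[priv] <- pmin(1, p_gene[priv] * burden)
    ns_hit <- stats::runif(G) < p_ns_i
    si_hit <- stats::runif(G) < pmin(1, p_silent * burden)
    ns_genes <- genes[ns_hit]
    si_genes <- genes[si_hit]
    parts <- list()
    if (length(ns_genes))
      parts$ns <- data.frame(
        sample_id = samples[i], gene_symbol = ns_genes,
        variant_classification = sample(cls, length(ns_genes), replace = TRUE,
                                        prob = spec$nonsilent_class_weights),
        protein_change = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(spec$obligate_gene) &&
        stats::runif(1L) < spec$obligate_fraction) {
      vi <- sample.int(nrow(spec$hotspot_spectrum), 1L,
                       prob = spec$hotspot_spectrum$weight)
      parts$ob <- data.frame(
        sample_id = samples[i],
        gene_symbol = toupper(spec$obligate_gene),
        variant_classification = spec$hotspot_spectrum$classification[vi],
        protein_change = spec$hotspot_spectrum$protein_change[vi],
        stringsAsFactors = FALSE)
      ob_rows[[length(ob_rows) + 1L]] <- parts$ob
      ns_genes <- c(ns_genes, toupper(spec$obligate_gene))
    }
    if (length(si_genes))
      parts$si <- data.frame(
        sample_id = samples[i], gene_symbol = si_genes,
        variant_classification = "Silent",
        protein_change = NA_character_, stringsAsFactors = FALSE)
    recs[[i]] <- do.call(rbind, parts)
    ns_sets[[i]] <- ns_genes
    si_sets[[i]] <- si_genes
  }
  df <- do.call(rbind, recs)
  if (is.null(df))
    stop("simulate_mutation_cohort: spec generated no mutations", call. = FALSE)
  df$variant_type <- .class_to_type(df$variant_classification)
  df$variant_type[df$variant_classification == "Silent"] <- "SNP"
  tab <- mutation_table(df)
  obligate <- if (length(ob_rows)) {
    ob <- do.call(rbind, ob_rows)
    data.frame(sample_id = ob$sample_id, protein_change = ob$protein_change,
               classification = ob$variant_classification,
               stringsAsFactors = FALSE)
  } else data.frame(sample_id = character(), protein_change = character(),
                    classification = character(), stringsAsFactors = FALSE)
  variant_counts <- if (nrow(obligate))
    table(obligate$protein_change) else table(character())
  names(ns_sets) <- names(si_sets) <- samples
  list(table = tab,
       truth = list(gene_universe = genes, sample_ids = samples,
                    nonsilent_genes = ns_sets, silent_genes = si_sets,
                    obligate = obligate, variant_counts = variant_counts,
                    spec = spec))
}

#' Specify a synthetic expression cohort
#'
#' Log-normal TPM values with a single-common-factor correlation structure:
#' `log2 x[g, s] = mu + sd * (sqrt(rho) z[g] + sqrt(1 - rho) e[g, s])`,
#' where `z` is a gene profile shared by all samples and `e` is
#' sample-specific noise, so `rho` is the expected inter-sample correlation
#' of log-expression (0 = independent samples, near 1 = near-duplicate
#' profiles). `dropout_prob` zeroes entries independently, emulating
#' undetectable transcripts. `log2_mean`/`log2_sd` are scalars by default;
#' per-gene vectors are accepted, but a varying mean profile is itself
#' shared and adds baseline correlation on top of `rho`.
#'
#' @param n_samples,n_genes dimensions.
#' @param log2_mean,log2_sd location and scale of log2 expression.
#' @param rho common-factor loading in \[0, 1).
#' @param dropout_prob per-entry zeroing probability.
#' @param sample_prefix prefix for sample IDs.
#' @param seed integer cohort seed.
#' @return An `expression_cohort_spec` list.
#' @export
expression_cohort_spec <- function(n_samples, n_genes, log2_mean = 3,
                                   log2_sd = 2, rho = 0, dropout_prob = 0,
                                   sample_prefix = "S", seed = 1L) {
  stopifnot(n_samples >= 1L, n_genes >= 2L, all(log2_sd > 0))
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("expression_cohort_spec: rho must be in [0, 1)", call. = FALSE)
  .check_prob(dropout_prob, "dropout_prob")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 log2_mean = log2_mean, log2_sd = log2_sd, rho = rho,
                 dropout_prob = dropout_prob, sample_prefix = sample_prefix,
                 seed = as.integer(seed)),
            class = "expression_cohort_spec")
}

#' Preset expression cohorts
#'
#' Cell-line-like transcriptomes are tightly related (`rho = 0.95`, 10
#' samples), patient tumors more dispersed (`rho = 0.8`, 80 samples) and
#' normal tissue tight again (`rho = 0.9`, 11 samples); all use 2000 genes,
#' log2 mean 3, sd 2 and 20% dropout.
#'
#' @param seed integer cohort seed.
#' @param ... overrides passed to [expression_cohort_spec()].
#' @return An `expression_cohort_spec`.
#' @export
cell_line_expression_spec <- function(seed = 1L, ...) {
  args <- list(n_samples = 10L, n_genes = 2000L, rho = 0.95,
               dropout_prob = 0.2, sample_prefix = "CL", seed = seed)
  do.call(expression_cohort_spec, utils::modifyList(args, list(...)))
}

#' @rdname cell_line_expression_spec
#' @export
patient_expression_spec <- function(seed = 1L, ...) {
  args <- list(n_samples = 80L, n_genes = 2000L, rho = 0.8,
               dropout_prob = 0.2, sample_prefix = "PT", seed = seed)
  do.call(expression_cohort_spec, utils::modifyList(args, list(...)))
}

#' @rdname cell_line_expression_spec
#' @export
normal_expression_spec <- function(seed = 1L, ...) {
  args <- list(n_samples = 11L, n_genes = 2000L, rho = 0.9,
               dropout_prob = 0.2, sample_prefix = "NM", seed = seed)
  do.call(expression_cohort_spec, utils::modifyList(args, list(...)))
}

#' Simulate an expression cohort
#'
#' @param spec an [expression_cohort_spec()].
#' @return List with `matrix` (a TPM [expression_matrix()]) and `truth`
#'   (`rho`, the shared gene factor `z`, `spec`).
#' @export
simulate_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "expression_cohort_spec"))
  G <- spec$n_genes
  set.seed(spec$seed)
  z <- stats::rnorm(G)
  samples <- sprintf("%s%02d", spec$sample_prefix, seq_len(spec$n_samples))
  genes <- toupper(sprintf("GENE%05d", seq_len(G)))
  vals <- matrix(0, nrow = G, ncol = spec$n_samples,
                 dimnames = list(genes, samples))
  for (i in seq_len(spec$n_samples)) {
    set.seed(spec$seed + 100000L + i)
    e <- stats::rnorm(G)
    lg <- spec$log2_mean + spec$log2_sd *
      (sqrt(spec$rho) * z + sqrt(1 - spec$rho) * e)
    x <- 2^lg
    if (spec$dropout_prob > 0)
      x[stats::runif(G) < spec$dropout_prob] <- 0
    vals[, i] <- x
  }
  list(matrix = expression_matrix(vals, unit = "TPM"),
       truth = list(rho = spec$rho, z = z, spec = spec))
}

#' Specify / simulate a bi-species PDX proteome
#'
#' Generates a human and a murine protein identification list with a planted
#' shared-homology fraction: `round(shared_fraction * n_human)` symbols
#' appear in both lists (the murine copies in mouse-style title case), the
#' rest are species-specific. [identify_pmo()] on the output recovers
#' `shared_fraction` exactly.
#'
#' @param n_human,n_mouse list sizes.
#' @param shared_fraction fraction of the human list shared with the mouse
#'   list; `round(shared_fraction * n_human)` must not exceed `n_mouse`.
#' @param seed integer seed.
#' @return `bispecies_spec`: a spec list. `simulate_bispecies_proteome`:
#'   list with `human`, `mouse` (character vectors) and `truth`
#'   (`shared_symbols`, `shared_fraction`, `spec`).
#' @export
bispecies_spec <- function(n_human = 5290L, n_mouse = 4285L,
                           shared_fraction = 0.75, seed = 1L) {
  stopifnot(n_human >= 1L, n_mouse >= 1L)
  .check_prob(shared_fraction, "shared_fraction")
  n_shared <- round(shared_fraction * n_human)
  if (n_shared > n_mouse)
    stop("bispecies_spec: shared_fraction * n_human exceeds n_mouse",
         call. = FALSE)
  structure(list(n_human = as.integer(n_human), n_mouse = as.integer(n_mouse),
                 shared_fraction = shared_fraction,
                 n_shared = as.integer(n_shared), seed = as.integer(seed)),
            class = "bispecies_spec")
}

#' @rdname bispecies_spec
#' @param spec a `bispecies_spec`.
#' @export
simulate_bispecies_proteome <- function(spec) {
  stopifnot(inherits(spec, "bispecies_spec"))
  set.seed(spec$seed)
  n_sh <- spec$n_shared
  shared <- sprintf("SHP%05d", seq_len(n_sh))
  human <- c(shared, sprintf("HSP%05d", seq_len(spec$n_human - n_sh)))
  mouse_only <- sprintf("MSP%05d", seq_len(spec$n_mouse - n_sh))
  title_case <- function(s) paste0(substr(s, 1, 1),
                                   tolower(substring(s, 2)))
  mouse <- c(title_case(shared), title_case(mouse_only))
  list(human = sample(human), mouse = sample(mouse),
       truth = list(shared_symbols = shared,
                    shared_fraction = n_sh / spec$n_human, spec = spec))
}

#' Simulate a gene-set collection
#'
#' Draws `n_sets` random sets from a gene universe (GMT-style fixture for
#' the enrichment stage), optionally appending planted sets.
#'
#' @param universe character vector of gene symbols.
#' @param n_sets number of random sets.
#' @param size_range inclusive range of set sizes.
#' @param planted optional named list of gene vectors appended as-is.
#' @param seed integer seed.
#' @return A [gene_set_collection()].
#' @export
simulate_gene_sets <- function(universe, n_sets = 40L, size_range = c(15L, 80L),
                               planted = list(), seed = 1L) {
  stopifnot(length(universe) >= max(size_range), n_sets >= 1L)
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample(seq(size_range[1L], size_range[2L]), 1L)))
  names(sets) <- sprintf("PATHWAY_%03d", seq_len(n_sets))
  gene_set_collection(c(sets, planted))
}
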