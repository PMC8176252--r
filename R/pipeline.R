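#' Default pipeline configuration
#'
#' Builds the configuration for a full synthetic run: cell-line-like and
#' patient-like mutation cohorts, three expression cohorts (cell lines,
#' patients, normal tissue), a bi-species PDX proteome and a simulated
#' gene-set collection, plus the analysis thresholds (TPM detectability 0.1,
#' EASE cutoff 0.1, minimum term count 2, read-count prefilter 10 reads /
#' 75% of samples).
#'
#' @param seed integer master seed; stage seeds are derived as small fixed
#'   offsets from it.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  structure(list(
    simulate = TRUE,
    seed = seed,
    specs = list(
      mutation = list(cell_lines = cell_line_cohort_spec(seed = seed),
                      patients = patient_cohort_spec(seed = seed + 1000L)),
      expression = list(cell_lines = cell_line_expression_spec(seed = seed + 2000L),
                        patients = patient_expression_spec(seed = seed + 3000L),
                        normal = normal_expression_spec(seed = seed + 4000L)),
      bispecies = bispecies_spec(seed = seed + 5000L),
      gene_sets = list(n_sets = 40L, size_range = c(15L, 80L),
                       seed = seed + 6000L)),
    datasets = list(),
    obligate_gene = "TP53",
    thresholds = list(tpm_detect = 0.1, ease_cutoff = 0.1, min_count = 2,
                      min_reads = 10, max_flag_fraction = 0.75),
    log2_expression_distance = FALSE),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override the defaults of [default_pipeline_config()];
#' `datasets` may name input paths per role (`cell_lines`, `patients`,
#' `normal`, `pdx_human`, `pdx_mouse`, `gene_sets`) for runs on real data,
#' in which case set `simulate: false`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = if (!is.null(y$seed)) y$seed else 1L)
  for (key in setdiff(names(y), "seed")) {
    if (key == "thresholds") {
      cfg$thresholds <- utils::modifyList(cfg$thresholds, y$thresholds)
    } else cfg[[key]] <- y[[key]]
  }
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.pipe_log <- function(...) message("[escchet] ", ...)

#' Run the full heterogeneity pipeline
#'
#' Executes the stages in dependency order - ingest (or simulate), variant
#' classification, Boolean profiles, pairwise dissimilarities, mutation
#' counts and the silent/non-silent regression, per-gene variant catalogues
#' and cross-cohort shared variants, detectability and multi-set partitions,
#' PMO resolution, and EASE enrichment - writing every result table under
#' `output_dir` together with a machine-readable manifest
#' (`manifest.json`: inputs, thresholds, seeds, package version and MD5
#' checksums of every output). Stages whose input role is absent are skipped
#' with a logged reason; the run continues.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()],
#'   [read_pipeline_config()]).
#' @param output_dir directory to create/write into.
#' @param figures also render figures via [render_figures()].
#' @return Invisibly, the result bundle: a list of in-memory objects
#'   (`mutation`, `expression`, `profiles`, `dissimilarity`, `counts`,
#'   `regression`, `catalogs`, `shared_variants`, `detectable`, `venn`,
#'   `mutated_transcribed`, `pmo`, `enrichment`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir, figures = FALSE) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  dir.create(file.path(output_dir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(output_dir, "tables"), showWarnings = FALSE)
  th <- config$thresholds
  scheme <- default_variant_scheme()
  bundle <- list(config = config)
  written <- character()
  skipped <- character()
  tpath <- function(...) file.path(output_dir, "tables", paste0(..., ".tsv"))
  note <- function(p) { written[[length(written) + 1L]] <<- p; p }

  # ---- stage: ingest / simulate -------------------------------------------
  mutation <- list(); expression <- list(); truth <- list()
  pdx <- list(); collection <- NULL
  if (isTRUE(config$simulate)) {
    .pipe_log("simulating synthetic input bundle (seed ", config$seed, ")")
    for (role in names(config$specs$mutation)) {
      sim <- simulate_mutation_cohort(config$specs$mutation[[role]])
      mutation[[role]] <- sim$table
      truth[[role]] <- sim$truth
      note(write_maf(sim$table,
                     file.path(output_dir, "inputs", paste0(role, ".maf"))))
    }
    for (role in names(config$specs$expression)) {
      sim <- simulate_expression_cohort(config$specs$expression[[role]])
      expression[[role]] <- sim$matrix
      note(write_expression_matrix(sim$matrix,
        file.path(output_dir, "inputs", paste0("expression_", role, ".tsv"))))
    }
    bi <- simulate_bispecies_proteome(config$specs$bispecies)
    pdx <- bi[c("human", "mouse")]
    note(write_symbol_list(pdx$human,
                           file.path(output_dir, "inputs", "pdx_human.txt")))
    note(write_symbol_list(pdx$mouse,
                           file.path(output_dir, "inputs", "pdx_mouse.txt")))
    gs <- config$specs$gene_sets
    universe <- truth[[1L]]$gene_universe
    planted <- list()
    if (length(mutation)) {
      # plant one pathway inside the first cohort's mutated genes so the
      # enrichment stage has signal at desk scale
      lab <- classify_variant(mutation[[1L]]$variant_classification, scheme)
      mut_genes <- unique(mutation[[1L]]$gene_symbol[lab == "non_silent"])
      set.seed(gs$seed + 1L)
      planted <- list(PLANTED_PATHWAY =
                        sample(mut_genes, min(40L, length(mut_genes))))
    }
    collection <- simulate_gene_sets(universe, n_sets = gs$n_sets,
                                     size_range = gs$size_range,
                                     planted = planted, seed = gs$seed)
    note(write_gene_sets(collection,
                         file.path(output_dir, "inputs", "gene_sets.gmt")))
  } else {
    ds <- config$datasets
    for (role in c("cell_lines", "patients")) {
      if (!is.null(ds[[role]])) {
        dialect <- if (dir.exists(ds[[role]])) "per-sample-directory"
                   else "single-file"
        mutation[[role]] <- read_maf(ds[[role]], dialect = dialect,
                                     scheme = scheme)
      }
    }
    for (role in c("cell_lines", "patients", "normal")) {
      key <- paste0("expression_", role)
      if (!is.null(ds[[key]]))
        expression[[role]] <- read_expression_matrix(ds[[key]], unit = "TPM")
    }
    if (!is.null(ds$pdx_human) && !is.null(ds$pdx_mouse))
      pdx <- list(human = read_symbol_list(ds$pdx_human),
                  mouse = read_symbol_list(ds$pdx_mouse))
    if (!is.null(ds$gene_sets)) collection <- read_gene_sets(ds$gene_sets)
  }
  if (!length(mutation) && !length(expression))
    stop("run_pipeline: no dataset roles available", call. = FALSE)
  bundle$mutation <- mutation
  bundle$expression <- expression
  bundle$truth <- truth

  # ---- stage: profiles, dissimilarity, counts, catalogues -----------------
  bundle$profiles <- list(); bundle$dissimilarity <- list()
  bundle$counts <- list(); bundle$regression <- list()
  bundle$catalogs <- list()
  for (role in names(mutation)) {
    tab <- mutation[[role]]
    prof <- build_profiles(tab, scheme)
    bundle$profiles[[role]] <- prof
    dfp <- data.frame(sample_id = rownames(prof),
                      1L * unclass(prof), check.names = FALSE)
    note(.write_tsv(dfp, tpath("mutation_profiles_", role)))
    if (nrow(prof) >= 2L) {
      dm <- pairwise_matrix(prof)
      bundle$dissimilarity[[paste0("matching_", role)]] <- dm
      note(write_dissimilarity_matrix(dm, tpath("matching_dissimilarity_", role)))
    } else {
      skipped[[length(skipped) + 1L]] <-
        paste0("matching_", role, ": fewer than 2 samples")
      .pipe_log("skipping matching dissimilarity for ", role,
                " (fewer than 2 samples)")
    }
    cnt <- count_mutations(tab, scheme)
    bundle$counts[[role]] <- cnt
    note(.write_tsv(as.data.frame(cnt), tpath("mutation_counts_", role)))
    if (nrow(cnt) >= 3L && stats::var(cnt$n_silent) > 0 &&
        stats::var(cnt$n_non_silent) > 0)
      bundle$regression[[role]] <- silent_nonsilent_regression(cnt)
    if (!is.null(config$obligate_gene)) {
      cat_g <- variant_catalog(tab, config$obligate_gene, scheme)
      bundle$catalogs[[role]] <- cat_g
      note(.write_tsv(cat_g$variants, tpath("variant_catalog_",
                                            tolower(config$obligate_gene),
                                            "_", role)))
    }
  }
  if (length(bundle$catalogs) >= 2L) {
    sv <- shared_variants(bundle$catalogs[[1L]], bundle$catalogs[[2L]])
    bundle$shared_variants <- sv
    note(write_symbol_list(sv, file.path(output_dir, "tables",
                                         "shared_variants.txt")))
  }

  # ---- stage: expression distances and detectability ----------------------
  bundle$detectable <- list()
  for (role in names(expression)) {
    m <- expression[[role]]
    if (ncol(m) >= 2L) {
      dm <- pairwise_matrix(m, log2_transform = config$log2_expression_distance)
      bundle$dissimilarity[[paste0("correlation_", role)]] <- dm
      note(write_dissimilarity_matrix(dm, tpath("correlation_distance_", role)))
    } else {
      skipped[[length(skipped) + 1L]] <-
        paste0("correlation_", role, ": fewer than 2 samples")
    }
    det <- detectable_genes(m, threshold = th$tpm_detect, scope = "any-sample")
    bundle$detectable[[role]] <- det
    note(write_symbol_list(det, file.path(output_dir, "tables",
                                          paste0("detectable_", role, ".txt"))))
  }

  # ---- stage: set integration ---------------------------------------------
  overlap_sets <- bundle$detectable
  if (length(pdx)) overlap_sets$pdx <- pdx$human
  if (length(overlap_sets) >= 2L) {
    vp <- venn_partition(overlap_sets[seq_len(min(4L, length(overlap_sets)))])
    bundle$venn <- vp
    note(write_set_partition(vp, tpath("venn_partition")))
  } else {
    skipped[[length(skipped) + 1L]] <- "venn: fewer than 2 gene sets"
    .pipe_log("skipping multi-set overlap (fewer than 2 sets)")
  }
  if (length(mutation) && length(expression)) {
    role_m <- names(mutation)[1L]
    role_e <- if (role_m %in% names(expression)) role_m
              else names(expression)[1L]
    lab <- classify_variant(mutation[[role_m]]$variant_classification, scheme)
    mut_genes <- unique(mutation[[role_m]]$gene_symbol[lab == "non_silent"])
    mtp <- mutated_transcribed_partition(mut_genes,
                                         bundle$detectable[[role_e]])
    bundle$mutated_transcribed <- mtp
    note(.write_tsv(data.frame(partition = names(mtp), size = lengths(mtp)),
                    tpath("mutated_transcribed_", role_m)))
  }
  if (length(pdx) == 2L) {
    pmo <- identify_pmo(pdx$human, pdx$mouse)
    bundle$pmo <- pmo
    note(.write_tsv(data.frame(
      partition = c("human_only", "murine_only", "pmo"),
      size = c(length(pmo$human_only), length(pmo$murine_only),
               length(pmo$pmo))), tpath("pmo_partition")))
  } else {
    skipped[[length(skipped) + 1L]] <- "pmo: PDX protein lists absent"
    .pipe_log("skipping PMO stage (PDX protein lists absent)")
  }

  # ---- stage: enrichment ----------------------------------------------------
  if (!is.null(collection) && length(mutation)) {
    role <- names(mutation)[1L]
    lab <- classify_variant(mutation[[role]]$variant_classification, scheme)
    query <- unique(mutation[[role]]$gene_symbol[lab == "non_silent"])
    enr <- suppressWarnings(
      enrich(query, collection, ease_cutoff = th$ease_cutoff,
             min_count = th$min_count))
    bundle$enrichment <- enr
    note(write_enrichment(enr, tpath("enrichment_full"), which = "full"))
    note(write_enrichment(enr, tpath("enrichment_reported"),
                          which = "reported"))
  } else {
    skipped[[length(skipped) + 1L]] <- "enrichment: gene sets or mutations absent"
    .pipe_log("skipping enrichment (gene-set collection or mutations absent)")
  }

  # ---- summary and manifest -------------------------------------------------
  summ <- list()
  for (nm in names(bundle$dissimilarity))
    summ[[nm]] <- attr(bundle$dissimilarity[[nm]], "summary")[c("min", "max", "mean")]
  for (nm in names(bundle$regression))
    summ[[paste0("regression_", nm)]] <-
      unclass(bundle$regression[[nm]])[c("slope", "intercept", "r", "r_squared")]
  if (!is.null(bundle$pmo))
    summ$pmo_ambiguity_fraction <- bundle$pmo$ambiguity_fraction
  for (nm in names(bundle$catalogs))
    summ[[paste0("n_variants_", nm)]] <- nrow(bundle$catalogs[[nm]]$variants)
  summary_path <- file.path(output_dir, "summary.json")
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  note(summary_path)
  bundle$summary <- summ

  rel <- sort(vapply(written, function(p)
    sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", output_dir), "/?"),
        "", p), ""))
  sums <- tools::md5sum(file.path(output_dir, rel))
  manifest <- list(package = "escchet",
                   version = as.character(utils::packageVersion("escchet")),
                   seed = config$seed,
                   thresholds = th,
                   simulate = isTRUE(config$simulate),
                   stages_skipped = unlist(skipped),
                   files = stats::setNames(unname(sums), rel))
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  bundle$manifest <- manifest
  .pipe_log("pipeline complete: ", length(rel), " output files in ", output_dir)
  if (figures) render_figures(output_dir)
  invisible(bundle)
}
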