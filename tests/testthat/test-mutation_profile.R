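toy_table <- function(df) mutation_table(df)

test_that("classify_variant maps tokens through the scheme deterministically", {
  sch <- default_variant_scheme()
  expect_equal(classify_variant("Missense_Mutation", sch), "non_silent")
  expect_equal(classify_variant("Silent", sch), "silent")
  expect_equal(classify_variant("3'UTR", sch), "excluded")
  expect_equal(classify_variant("Made_Up", sch), "unknown")
  expect_equal(classify_variant(c("Silent", "Splice_Site"), sch),
               c("silent", "non_silent"))
})

test_that("classification schemes require disjoint token groups and read from YAML", {
  expect_error(variant_class_scheme("Silent", "Silent"), "disjoint")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("non_silent: [Missense_Mutation]", "silent: [Silent]",
               "excluded: [Intron]"), path)
  sch <- read_variant_scheme(path)
  expect_equal(classify_variant("Intron", sch), "excluded")
})

test_that("build_profiles encodes Boolean vectors over a lexicographic universe", {
  tab <- toy_table(data.frame(
    sample_id = c("s1", "s1", "s2", "s2"),
    gene_symbol = c("A", "B", "B", "C"),
    variant_classification = "Missense_Mutation"))
  prof <- build_profiles(tab)
  expect_equal(dimnames(prof), list(c("s1", "s2"), c("A", "B", "C")))
  expect_equal(unclass(prof),
               matrix(c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE), 2,
                      dimnames = list(c("s1", "s2"), c("A", "B", "C"))))
  # multiple hits in one gene collapse to a single TRUE
  tab2 <- toy_table(data.frame(sample_id = "s1", gene_symbol = "A",
                               variant_classification =
                                 rep("Missense_Mutation", 3)))
  expect_equal(sum(build_profiles(tab2)), 1)
  # a supplied universe missing a mutated gene drops it with a warning
  expect_warning(p3 <- build_profiles(tab, universe = c("A", "B")), "dropped")
  expect_equal(colnames(p3), c("A", "B"))
})

test_that("profile row sums equal per-sample non-silent gene counts", {
  sim <- simulate_mutation_cohort(mutation_cohort_spec(
    n_samples = 6, n_genes = 300, n_backbone = 50, p_backbone = 0.6,
    p_private = 0.05, silent_odds = 0.4, seed = 7))
  prof <- build_profiles(sim$table)
  cnt <- count_mutations(sim$table)
  expect_equal(unname(rowSums(prof)[cnt$sample_id]), cnt$n_non_silent)
})

test_that("count_mutations computes unique counts and ratios", {
  tab <- toy_table(data.frame(
    sample_id = c("s1", "s1", "s2", "s2"),
    gene_symbol = c("A", "B", "B", "C"),
    variant_classification = "Missense_Mutation"))
  cnt <- count_mutations(tab)
  expect_equal(cnt$n_unique_non_silent, c(1L, 1L))
  expect_equal(cnt$ratio_unique_non_silent, c(0.5, 0.5))
  # identical samples have zero unique genes
  tab2 <- toy_table(data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                               gene_symbol = rep(c("A", "B"), 2),
                               variant_classification = "Missense_Mutation"))
  expect_equal(count_mutations(tab2)$n_unique_non_silent, c(0L, 0L))
  # single-sample cohorts warn and call every gene unique
  tab3 <- toy_table(data.frame(sample_id = "s1", gene_symbol = c("A", "B"),
                               variant_classification = "Missense_Mutation"))
  expect_warning(cnt3 <- count_mutations(tab3), "single-sample")
  expect_equal(cnt3$n_unique_non_silent, 2L)
})

test_that("event-unit counting differs from gene-unit counting for multi-hit genes", {
  tab <- toy_table(data.frame(sample_id = "s1", gene_symbol = c("A", "A", "B"),
                              variant_classification = "Missense_Mutation"))
  genes <- suppressWarnings(count_mutations(tab, unit = "genes"))
  events <- suppressWarnings(count_mutations(tab, unit = "events"))
  expect_equal(genes$n_non_silent, 2L)
  expect_equal(events$n_non_silent, 3L)
})

test_that("silent/non-silent regression recovers exact and simulated relations", {
  mk <- function(x, y) structure(data.frame(sample_id = seq_along(x),
                                            n_silent = x, n_non_silent = y),
                                 class = c("sample_mutation_counts",
                                           "data.frame"))
  reg <- silent_nonsilent_regression(mk(1:3, c(2, 4, 6)))
  expect_equal(reg$slope, 2)
  expect_equal(reg$intercept, 0)
  expect_equal(reg$r, 1)
  expect_equal(reg$r_squared, 1)
  expect_equal(silent_nonsilent_regression(mk(1:5, 10 - (1:5)))$r, -1)
  expect_error(silent_nonsilent_regression(mk(rep(2, 4), 1:4)), "variance")
  # simulation oracle: bivariate normal with rho = 0.9, n = 200
  set.seed(11)
  x <- rnorm(200)
  y <- 0.9 * x + sqrt(1 - 0.9^2) * rnorm(200)
  r <- silent_nonsilent_regression(mk(x, y))$r
  se <- sqrt((1 - 0.9^2)^2 / 200)   # asymptotic SE of Pearson r
  expect_lt(abs(r - 0.9), 3 * se)
  # invariance to sample ordering
  perm <- sample(200)
  expect_equal(silent_nonsilent_regression(mk(x[perm], y[perm]))$r, r)
})

test_that("variant_catalog ranks distinct variants and partitions classes", {
  tab <- toy_table(data.frame(
    sample_id = c("s1", "s2", "s3", "s3"),
    gene_symbol = "TP53",
    variant_classification = "Missense_Mutation",
    protein_change = c("p.R248Q", "p.R248Q", "p.R175H", "p.R248Q")))
  cat_ <- variant_catalog(tab, "TP53")
  expect_equal(nrow(cat_$variants), 2L)
  expect_equal(cat_$variants$protein_change[1], "p.R248Q")
  expect_equal(cat_$variants$n_samples, c(3L, 1L))
  expect_equal(cat_$variants$n_records, c(3L, 1L))
  expect_equal(cat_$n_samples_mutated, 3L)
  expect_equal(cat_$fraction_samples_mutated, 1)
  # per-variant record counts sum to the number of qualifying records
  expect_equal(sum(cat_$variants$n_records), 4L)
  # absent gene yields an empty catalog
  empty <- variant_catalog(tab, "EGFR")
  expect_equal(nrow(empty$variants), 0L)
  expect_equal(empty$fraction_samples_mutated, 0)
  # missing protein_change falls back to a synthetic label
  tab2 <- toy_table(data.frame(sample_id = "s1", gene_symbol = "TP53",
                               variant_classification = "Splice_Site",
                               variant_type = "SNP"))
  expect_equal(variant_catalog(tab2, "TP53")$variants$protein_change,
               "(Splice_Site|SNP)")
  # ties broken lexicographically
  tab3 <- toy_table(data.frame(sample_id = c("s1", "s2"), gene_symbol = "TP53",
                               variant_classification = "Missense_Mutation",
                               protein_change = c("p.B", "p.A")))
  expect_equal(variant_catalog(tab3, "TP53")$variants$protein_change,
               c("p.A", "p.B"))
})

test_that("shared_variants intersects catalogs of the same gene only", {
  mk <- function(samples, pcs) variant_catalog(toy_table(data.frame(
    sample_id = samples, gene_symbol = "TP53",
    variant_classification = "Missense_Mutation", protein_change = pcs)),
    "TP53")
  a <- mk(c("s1", "s2", "s3"), c("p.R248Q", "p.H179R", "p.X1"))
  b <- mk(c("t1", "t2", "t3"), c("p.R248Q", "p.H179R", "p.Y1"))
  expect_setequal(shared_variants(a, b), c("p.R248Q", "p.H179R"))
  # disjoint catalogs share nothing; subset catalogs share themselves
  d <- mk("t1", "p.Z9")
  expect_equal(shared_variants(a, d), character(0))
  sub <- mk(c("u1", "u2"), c("p.R248Q", "p.H179R"))
  expect_setequal(shared_variants(sub, a), sub$variants$protein_change)
  other <- variant_catalog(toy_table(data.frame(
    sample_id = "s1", gene_symbol = "EGFR",
    variant_classification = "Missense_Mutation", protein_change = "p.L858R")),
    "EGFR")
  expect_error(shared_variants(a, other), "different genes")
})
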