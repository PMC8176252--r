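test_that("generators are deterministic: fixed seeds give byte-identical files", {
  spec <- mutation_cohort_spec(n_samples = 5, n_genes = 150, n_backbone = 30,
                               p_backbone = 0.7, p_private = 0.05,
                               burden_sd = 0.4, seed = 19)
  f1 <- withr::local_tempfile(fileext = ".maf")
  f2 <- withr::local_tempfile(fileext = ".maf")
  write_maf(simulate_mutation_cohort(spec)$table, f1)
  write_maf(simulate_mutation_cohort(spec)$table, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  e1 <- simulate_expression_cohort(expression_cohort_spec(4, 100, rho = 0.5,
                                                          seed = 19))
  e2 <- simulate_expression_cohort(expression_cohort_spec(4, 100, rho = 0.5,
                                                          seed = 19))
  expect_identical(e1$matrix, e2$matrix)
  # adding samples never perturbs earlier samples (per-sample substreams)
  e3 <- simulate_expression_cohort(expression_cohort_spec(6, 100, rho = 0.5,
                                                          seed = 19))
  expect_identical(unclass(e1$matrix)[, 1:4], unclass(e3$matrix)[, 1:4])
})

test_that("degenerate mutation specs produce the forced cohorts", {
  # p_backbone = 1, p_private = 0: all samples identical, dissimilarity 0
  sim <- simulate_mutation_cohort(mutation_cohort_spec(
    n_samples = 4, n_genes = 100, n_backbone = 20, p_backbone = 1,
    p_private = 0, silent_odds = 0, obligate_gene = NULL, seed = 2))
  prof <- build_profiles(sim$table)
  dm <- pairwise_matrix(prof)
  expect_equal(max(unclass(dm)), 0)
  # obligate fraction 1 puts the gene in 100% of samples
  sim2 <- simulate_mutation_cohort(mutation_cohort_spec(
    n_samples = 10, n_genes = 100, n_backbone = 0, p_backbone = 0,
    p_private = 0.1, obligate_fraction = 1, seed = 2))
  cat_ <- variant_catalog(sim2$table, "TP53")
  expect_equal(cat_$fraction_samples_mutated, 1)
  expect_error(mutation_cohort_spec(2, 10, 0, p_backbone = 1.5, p_private = 0),
               "probability")
})

test_that("truth records reproduce every downstream quantity without re-reading files", {
  spec <- mutation_cohort_spec(n_samples = 8, n_genes = 400, n_backbone = 80,
                               p_backbone = 0.6, p_private = 0.04,
                               silent_odds = 0.3, burden_sd = 0.3, seed = 31)
  sim <- simulate_mutation_cohort(spec)
  prof <- build_profiles(sim$table)
  for (s in sim$truth$sample_ids)
    expect_setequal(colnames(prof)[prof[s, ]], sim$truth$nonsilent_genes[[s]])
  cnt <- count_mutations(sim$table)
  expect_equal(cnt$n_silent,
               unname(lengths(sim$truth$silent_genes[cnt$sample_id])))
  cat_ <- variant_catalog(sim$table, "TP53")
  planted <- sort(names(sim$truth$variant_counts))
  expect_equal(sort(cat_$variants$protein_change), planted)
  expect_equal(cat_$variants$n_samples[order(cat_$variants$protein_change)],
               unname(as.integer(sim$truth$variant_counts[planted])))
})

test_that("planted private-gene fraction is recovered by the unique-mutation ratio", {
  # iid Bernoulli(q) genes: P(private | mutated) = (1-q)^(n-1)
  q <- 0.05; n <- 12
  sims <- lapply(1:8, function(s) simulate_mutation_cohort(
    mutation_cohort_spec(n_samples = n, n_genes = 1500, n_backbone = 0,
                         p_backbone = 0, p_private = q, silent_odds = 0,
                         obligate_gene = NULL, seed = 100 + 50 * s)))
  ratios <- vapply(sims, function(sim)
    mean(count_mutations(sim$table)$ratio_unique_non_silent), 0)
  expected <- (1 - q)^(n - 1)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - expected), 3 * se + 1e-3)
})

test_that("expression generator honours the common-factor correlation model", {
  # rho = 0: independent samples, mean correlation distance near 1
  e0 <- simulate_expression_cohort(expression_cohort_spec(
    n_samples = 12, n_genes = 3000, rho = 0, seed = 41))
  s0 <- attr(pairwise_matrix(e0$matrix), "summary")
  expect_lt(abs(s0$mean - 1), 3 / sqrt(3000) * 3)
  # duplicated profiles (the rho -> 1 limit) are at distance 0
  one <- simulate_expression_cohort(expression_cohort_spec(
    n_samples = 1, n_genes = 100, rho = 0, seed = 41))$matrix
  dup <- expression_matrix(cbind(s1 = unclass(one)[, 1], s2 = unclass(one)[, 1],
                                 s3 = unclass(one)[, 1]), unit = "TPM")
  expect_lt(max(abs(unclass(pairwise_matrix(dup)))), 1e-12)
  # higher rho gives stochastically smaller distances
  hi <- simulate_expression_cohort(expression_cohort_spec(
    n_samples = 8, n_genes = 500, rho = 0.9, seed = 42))
  lo <- simulate_expression_cohort(expression_cohort_spec(
    n_samples = 8, n_genes = 500, rho = 0.1, seed = 42))
  expect_lt(attr(pairwise_matrix(hi$matrix), "summary")$mean,
            attr(pairwise_matrix(lo$matrix), "summary")$mean)
  expect_error(expression_cohort_spec(4, 100, rho = 1), "rho")
  expect_error(expression_cohort_spec(4, 100, log2_sd = 0), "log2_sd")
})

test_that("bi-species generator plants the shared fraction exactly", {
  d <- simulate_bispecies_proteome(bispecies_spec(100, 100, 0, seed = 5))
  expect_equal(identify_pmo(d$human, d$mouse)$pmo, character(0))
  s <- simulate_bispecies_proteome(bispecies_spec(1000, 900, 0.75, seed = 5))
  res <- identify_pmo(s$human, s$mouse)
  expect_equal(length(res$pmo), 750L)
  expect_equal(res$ambiguity_fraction, 0.75)
  expect_setequal(res$pmo, s$truth$shared_symbols)
  expect_error(bispecies_spec(1000, 500, 0.75), "exceeds n_mouse")
})

test_that("simulated gene-set collections are valid and plantable", {
  u <- sprintf("G%04d", 1:500)
  col <- simulate_gene_sets(u, n_sets = 10, size_range = c(5, 20),
                            planted = list(MARKER = u[1:8]), seed = 3)
  expect_s3_class(col, "gene_set_collection")
  expect_equal(length(col), 11L)
  expect_setequal(col$MARKER, u[1:8])
  expect_true(all(lengths(col) >= 5 | names(col) == "MARKER"))
})
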