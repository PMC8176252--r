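test_that("detectability uses an inclusive TPM threshold in every scope", {
  vals <- matrix(c(0.1, 0.05, 0, 0.09, 0.2, 0), 3,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m <- expression_matrix(vals, unit = "TPM")
  expect_true("g1" %in% detectable_genes(m))           # exactly 0.1 detectable
  expect_false("g3" %in% detectable_genes(m))          # all-zero never
  expect_setequal(detectable_genes(m, scope = "any-sample"), c("g1", "g2"))
  expect_equal(detectable_genes(m, scope = "all-samples"), character(0))
  per <- detectable_genes(m, scope = "per-sample")
  expect_equal(per$s1, "g1")          # s1: g1 at the 0.1 boundary only
  expect_equal(per$s2, "g2")          # s2: g1 sits below at 0.09
  # union of per-sample sets equals the any-sample set
  expect_setequal(unique(unlist(per)), detectable_genes(m, scope = "any-sample"))
  counts <- expression_matrix(vals, unit = "counts")
  expect_error(detectable_genes(counts), "unit")
})

test_that("venn partitions enumerate every region and conserve sizes", {
  vp <- venn_partition(list(A = c(1, 2), B = c(2, 3)))
  expect_equal(vp$regions$A, "1")
  expect_equal(vp$regions$B, "3")
  expect_equal(vp$regions$`A&B`, "2")
  # identical sets collapse into the single shared region
  vp2 <- venn_partition(list(X = letters[1:3], Y = letters[1:3]))
  expect_equal(vp2$sizes[["X&Y"]], 3L)
  expect_equal(vp2$sizes[["X"]], 0L)
  expect_error(venn_partition(list(a = 1)), "between 2 and 4")
  expect_error(venn_partition(setNames(as.list(1:5), letters[1:5])),
               "between 2 and 4")
  # conservation on random 2-4 set instances, against per-element brute force
  set.seed(14)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    sets <- setNames(lapply(seq_len(k), function(i)
      sample(1:60, sample(5:40, 1))), LETTERS[seq_len(k)])
    vp <- venn_partition(sets)
    expect_equal(sum(vp$sizes), length(vp$universe))
    for (lbl in vp$labels) {
      in_regions <- sum(vp$sizes[grepl(paste0("(^|&)", lbl, "(&|$)"),
                                       names(vp$sizes))])
      expect_equal(in_regions, length(unique(sets[[lbl]])))
    }
    # brute force: each element lands in exactly the region of its memberships
    for (el in as.character(vp$universe)) {
      memb <- paste(vp$labels[vapply(sets, function(s)
        el %in% as.character(s), TRUE)], collapse = "&")
      expect_true(el %in% vp$regions[[memb]])
    }
  }
})

test_that("mutated x transcribed partition conserves the mutated set", {
  p <- mutated_transcribed_partition(c("A", "B"), c("B", "C"))
  expect_equal(p$mutated_transcribed, "B")
  expect_equal(p$mutated_untranscribed, "A")
  expect_equal(p$transcribed_unmutated, "C")
  d <- mutated_transcribed_partition(c("A", "B"), c("X", "Y"))
  expect_equal(d$mutated_transcribed, character(0))
  expect_setequal(d$mutated_untranscribed, c("A", "B"))
  set.seed(3)
  mut <- sample(letters, 10)
  tx <- sample(letters, 12)
  pp <- mutated_transcribed_partition(mut, tx)
  expect_equal(length(pp$mutated_transcribed) + length(pp$mutated_untranscribed),
               length(unique(toupper(mut))))
})

test_that("PMO resolution matches case-insensitively with optional orthology map", {
  res <- identify_pmo(c("TP53", "ALB"), c("Trp53", "Gapdh"),
                      orthology_map = c(TRP53 = "TP53"))
  expect_equal(res$pmo, "TP53")
  expect_equal(res$human_only, "ALB")
  expect_equal(res$murine_only, "GAPDH")
  expect_equal(res$ambiguity_fraction, 0.5)
  # disjoint lists
  d <- identify_pmo(c("A", "B"), c("C", "D"))
  expect_equal(d$pmo, character(0))
  expect_equal(d$ambiguity_fraction, 0)
  # |pmo| is the same computed from either side
  set.seed(8)
  h <- sample(sprintf("P%03d", 1:200), 80)
  m <- sample(sprintf("P%03d", 1:200), 90)
  expect_equal(length(identify_pmo(h, m)$pmo), length(identify_pmo(m, h)$pmo))
  expect_error(identify_pmo(character(0), "X"), "non-empty")
})

test_that("count prefilter applies the strict >75%-flagged exclusion rule", {
  # 10 transcripts x 4 samples with a hand-enumerated flag pattern
  vals <- rbind(
    t1 = c(50, 50, 50, 50),   # 0 flagged -> keep
    t2 = c(5, 50, 50, 50),    # 1/4       -> keep
    t3 = c(5, 5, 50, 50),     # 2/4       -> keep
    t4 = c(5, 5, 5, 50),      # 3/4 = 75% -> keep (boundary)
    t5 = c(5, 5, 5, 5),       # 4/4       -> excluded
    t6 = c(9, 9, 9, 10),      # 3/4       -> keep (10 reads not flagged)
    t7 = c(0, 0, 0, 0),       # 4/4       -> excluded
    t8 = c(10, 10, 10, 10),   # 0 flagged -> keep
    t9 = c(9, 9, 9, 9),       # 4/4       -> excluded
    t10 = c(100, 0, 0, 0))    # 3/4       -> keep
  colnames(vals) <- paste0("s", 1:4)
  m <- expression_matrix(vals, unit = "counts")
  filt <- count_prefilter(m)
  expect_setequal(rownames(filt), c("t1", "t2", "t3", "t4", "t6", "t8", "t10"))
  expect_setequal(attr(filt, "removed"), c("t5", "t7", "t9"))
  # survivors unchanged
  expect_equal(unclass(filt)["t4", ], vals["t4", ])
  expect_error(count_prefilter(expression_matrix(vals, unit = "TPM")), "unit")
  # monotone: raising min_reads never enlarges the survivor set
  set.seed(4)
  rv <- matrix(rpois(200, 12), 20,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  rm_ <- expression_matrix(rv, unit = "counts")
  prev <- rownames(count_prefilter(rm_, min_reads = 5))
  for (mr in c(10, 15, 20)) {
    cur <- rownames(count_prefilter(rm_, min_reads = mr))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("DE post-filter keeps strong, significant entries only", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2FoldChange = c(2, 0.5, -3, 2),
                   padj = c(0.001, 0.001, 0.004, 0.2))
  kept <- filter_de_results(de)
  expect_setequal(kept$gene, c("a", "c"))
})
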