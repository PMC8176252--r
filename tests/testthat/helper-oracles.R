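# Independent oracles, deliberately coded differently from the package
# implementations they check.

# position-by-position disagreement count
oracle_matching <- function(u, v) {
  n <- length(u)
  disagree <- 0L
  for (i in seq_len(n)) if (u[i] != v[i]) disagree <- disagree + 1L
  disagree / n
}

# two-pass Pearson correlation distance
oracle_correlation_distance <- function(u, v) {
  mu <- sum(u) / length(u)
  mv <- sum(v) / length(v)
  num <- 0; du <- 0; dv <- 0
  for (i in seq_along(u)) {
    num <- num + (u[i] - mu) * (v[i] - mv)
    du <- du + (u[i] - mu)^2
    dv <- dv + (v[i] - mv)^2
  }
  1 - num / (sqrt(du) * sqrt(dv))
}

# brute-force hypergeometric upper tail P(X >= k) as a combinatorial sum
oracle_hyper_tail <- function(k, n, K, N) {
  xs <- max(0, n + K - N):min(n, K)
  xs <- xs[xs >= k]
  if (!length(xs)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# toy MAF writer with TCGA-style headers
write_toy_maf <- function(path, df) {
  names(df)[names(df) == "gene_symbol"] <- "Hugo_Symbol"
  names(df)[names(df) == "variant_classification"] <- "Variant_Classification"
  names(df)[names(df) == "sample_id"] <- "Tumor_Sample_Barcode"
  names(df)[names(df) == "protein_change"] <- "Protein_Change"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_expression <- function(values, unit = "TPM") {
  expression_matrix(values, unit = unit)
}
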