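---
title: "Quantifying multi-omics tumor heterogeneity with escchet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-omics tumor heterogeneity with escchet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escchet)
```

## The problem

Esophageal squamous cell carcinoma (ESCC) cohorts are heterogeneous at every
molecular level: cell lines, patient tumors, normal tissue and
patient-derived xenografts (PDX) disagree on which genes are mutated, which
are expressed, and - in the chimeric PDX setting - even which species a
protein came from. `escchet` quantifies that heterogeneity with a small set
of statistics and makes the whole analysis reproducible at desk scale
through a synthetic-cohort generator, so every stage can be tested without
access to the original repositories.

## Models and statistics

### Boolean mutation profiles and matching dissimilarity

Each sample is encoded as a Boolean vector over a fixed gene universe:
position $g$ is 1 iff the sample carries at least one *non-silent* mutation
in gene $g$ (missense, nonsense, nonstop, frameshift or in-frame indel,
splice-site, or translation-start change under the default scheme; see
`default_variant_scheme()`). Two samples $u, v$ are compared with the
matching dissimilarity

$$ d_M(u, v) \;=\; \frac{1}{G}\sum_{i=1}^{G} \mathbf{1}[u_i \neq v_i], $$

the fraction of disagreeing positions. Double absence counts as agreement,
so sparse profiles (typical of patient cohorts) score as similar regardless
of *which* genes are mutated - a known property of the metric, and the
reason dense cell-line cohorts show *higher* matching dissimilarity than
sparse patient cohorts even when patients share fewer mutations. For two
independent Bernoulli($q$) profiles the expectation is $2q(1-q)$, which the
test suite uses as a closed-form oracle. The default universe is the union
of non-silently mutated genes in the cohort; pass `universe=` to
`build_profiles()` to fix it externally (required whenever expectations are
computed against a declared gene panel, and when comparing cohorts side by
side).

### Correlation distance on transcriptomes

Expression heterogeneity avoids the sparse-vector caveat by comparing TPM
vectors with the correlation distance

$$ d_C(u, v) \;=\; 1 - \frac{(u-\bar u)\cdot(v-\bar v)}
   {\lVert u-\bar u\rVert\,\lVert v-\bar v\rVert} \in [0, 2]. $$

Raw TPM is used by default (`log2_transform = TRUE` switches to
$\log_2(\mathrm{TPM}+1)$); the full common gene panel of the matrix is used
for every pair, zeros included, so distances are comparable across pairs.
Constant (zero-variance) samples have no defined correlation: they are
reported as degenerate, their rows are `NA`, and they are excluded from the
off-diagonal summary rather than imputed. All matrix summaries
(`summarize_matrix()`) are over the strict upper triangle; the diagonal is
never included (a diagonal-inclusive mean would be smaller by a factor
$\binom{n}{2}/\binom{n+1}{2}$ and is not what heatmap ranges describe).

### Variant catalogues

`variant_catalog()` enumerates the distinct non-silent variants of one gene
(keyed on the protein-change string, e.g. `p.R248Q`; records without one
fall back to a `(classification|variant_type)` label), with per-variant
distinct-sample counts, a partition over classification tokens, and the
fraction of cohort samples mutated. Ranking is by sample count with
lexicographic tie-breaks, so output order is deterministic. Variants with
identical positions but different substitutions (p.R175G vs p.R175H) are
distinct entries by construction.

### Set integration and PMO resolution

Detectability uses the inclusive rule TPM $\geq$ 0.1. `venn_partition()`
computes all $2^k - 1$ regions for 2-4 labelled sets; region sizes always
sum to the union size. For PDX proteomes, `identify_pmo()` intersects the
human-database and mouse-database identification lists (case-insensitive
symbols, optionally through an explicit mouse-to-human orthology map):
proteins found in both are *Possibly of Murine Origin* and the
`ambiguity_fraction` is $|\mathrm{PMO}| / |\mathrm{human\ list}|$. The
read-count prefilter flags counts $< 10$ and excludes a transcript only
when *strictly more than* 75% of its samples are flagged - flagged in
exactly 75% is retained. Downstream differential-expression fitting is
deliberately out of scope; `filter_de_results()` only thresholds an
externally fitted table (padj $< 0.005$, $|\log_2 FC| > 1$).

### EASE-score enrichment

Over-representation of a query gene list in a collection of gene sets uses
the one-sided Fisher exact (hypergeometric upper-tail) p-value and its
conservative jackknifed form, the EASE score: the same tail recomputed with
one hit removed ($k \to k-1$ against unchanged margins), so a term
supported by a single gene scores exactly 1. Reported terms satisfy EASE
$p \leq 0.1$ *and* hit count $\geq 2$; both filters independently exclude
single-gene terms. The background universe defaults to the collection's
own annotated gene count (the DAVID convention), overridable via
`universe_size`. No multiple-testing correction is applied to the filter; a
Benjamini-Hochberg column is emitted for information only.

## The synthetic-cohort generator

The generators exist so that every pipeline stage has inputs with known
ground truth. What they emulate, and what they do not:

* **Mutation cohorts** (`simulate_mutation_cohort()`): per-gene independent
  Bernoulli mutation with a shared backbone (first $B$ genes at probability
  $p_b$) and private tail ($p_p$), a per-sample log-normal burden multiplier
  (`burden_sd`) that makes silent and non-silent loads correlate across
  samples, independent per-gene silent mutations at `silent_odds` times the
  mean non-silent rate, and an obligate TP53-like gene mutated in a target
  fraction of samples with a weighted six-variant hotspot spectrum spanning
  the five non-silent classes (`default_hotspot_spectrum()`; the labels are
  plain strings chosen so each of the five classes is represented). There is
  no sequence simulation, no mutational signatures, no gene-gene dependence
  beyond the backbone.
* **Expression cohorts** (`simulate_expression_cohort()`): single common
  factor on the log scale,
  $\log_2 x_{gs} = \mu + \sigma(\sqrt{\rho}\, z_g + \sqrt{1-\rho}\,
  e_{gs})$, plus independent dropout zeros. $\rho$ is the expected
  inter-sample log-scale correlation; $\rho = 0$ gives mean correlation
  distance near 1, duplicated profiles give 0. Means and SDs are constant
  across genes by default: a varying gene-mean profile is itself shared
  between samples and would add baseline correlation on top of $\rho$
  (per-gene vectors are accepted for users who want that). No count noise,
  no library-size variation, no gene-gene covariance structure.
* **Bi-species proteomes** (`simulate_bispecies_proteome()`): a planted
  shared fraction $s$; `identify_pmo()` recovers
  $\mathrm{round}(s \cdot n_\mathrm{human}) / n_\mathrm{human}$ exactly.

Passing tests on these inputs demonstrates the *statistical machinery* -
metric definitions, filters, bookkeeping, determinism - not biological
realism: real cohorts have correlated mutation processes, batch effects and
count noise that the generators deliberately omit.

**Seeding.** Every generator expands one cohort seed into per-sample
substreams as `seed + sample index`, so a fixed seed yields byte-identical
files and appending samples never perturbs earlier ones. The flip side is
that cohorts whose seeds differ by less than the sample count share
substreams; independent replicates should space their seeds accordingly
(the pipeline spaces its stage seeds by 1000).

## Default study conditions

The default pipeline bundle fixes the synthetic conditions once, scaled to
the cohort sizes of the emulated study:

| condition | cell-line-like | patient-like | normal |
|---|---|---|---|
| mutation samples / genes | 12 / 5000 | 80 / 8500 | - |
| backbone size @ probability | 1500 @ 0.8 | 300 @ 0.3 | - |
| private mutation probability | 0.02 | 0.012 | - |
| silent:non-silent odds; burden SD | 1/3; 0.3 | 0.25; 0.5 | - |
| obligate-gene fraction | 1.0 | 0.9 | - |
| expression samples / genes | 10 / 2000 | 80 / 2000 | 11 / 2000 |
| common-factor $\rho$; dropout | 0.95; 0.2 | 0.80; 0.2 | 0.90; 0.2 |
| PDX lists (human / mouse; shared fraction) | 5290 / 4285; 0.75 | (one pair per bundle) | - |

The dense backbone makes the expected mean matching dissimilarity about
0.23 for the cell-line-like cohort versus about 0.06 for the sparse
patient-like cohort, the expected non-silent ratios about 0.75 and 0.80,
and the obligate gene ubiquitous in cell lines - the qualitative regime the
pipeline is meant to reproduce. These sizes also keep the full bundle under
a few seconds of compute.

## Numerical and design choices

* **Correlation distance formula**: the standard $1 - r$ (centered,
  norm-scaled Pearson) reading, the only one consistent with values spanning
  almost the whole $[0, 2]$ range in practice.
* **Counting unit**: per-sample counts are *genes with* silent/non-silent
  mutations by default (matching the Boolean-profile machinery); raw event
  counting is available via `unit = "events"` in `count_mutations()`. Both
  denominators (with and without excluded classes) are derivable since
  excluded records are never counted in either group.
* **One-to-many ID mappings**: first target in map order wins; duplicates
  collapse to the first occurrence; unmapped IDs are reported, never
  silently dropped. Gene symbols are upper-cased for matching within one
  species. Genes with no mapping are logged and excluded.
* **Unknown classification tokens** are retained, labelled `unknown`, and
  counted in the ingestion log; they participate in neither the silent nor
  the non-silent group.
* **Degenerate inputs**: zero-variance samples error in the scalar distance
  and are reported-and-excluded in the matrix builder; empty coding-gene
  intersections warn and return empty results; single-sample cohorts warn
  that every gene is private.
* **EASE jackknife** holds the margins fixed and decrements only the hit
  cell, the published convention for the score; `k <= 1` returns exactly 1.
* **Tie-breaks**: lexicographic everywhere (variant ranking, enrichment
  ties, region ordering by combination size then input order), so all
  outputs are deterministic and diffable.
* **Manifest**: `run_pipeline()` writes relative paths and MD5 checksums of
  every output plus seeds and thresholds; reruns with the same config are
  bit-identical, which the test suite verifies.

## Limitations

* The matching dissimilarity depends on the declared universe; comparing
  cohorts under different universes is not meaningful. The pipeline uses
  each cohort's own mutated-gene union (as heatmaps of a single cohort do);
  cross-cohort comparisons in the tests fix a shared universe explicitly.
* Raw-TPM correlation is dominated by high-expression genes; use the log2
  mode when that is a concern.
* Symbol-equality PMO matching understates ambiguity for renamed
  orthologues unless an explicit orthology map is supplied.
* The enrichment stage assumes the collection's universe is the analysis
  background; with a custom `universe_size`, hits outside the collection
  are still dropped from the query.
* The generators' independence assumptions make Monte-Carlo standard errors
  honest but real-data effect sizes (e.g. dissimilarity means) are emulated
  only qualitatively.
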