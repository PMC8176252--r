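.placeholder_figure <- function(path, msg) {
  grDevices::png(path, width = 600, height = 400)
  graphics::plot.new()
  graphics::text(0.5, 0.5, msg)
  grDevices::dev.off()
  path
}

.read_dissim_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Render figures from a pipeline output directory
#'
#' Produces, for whichever tables exist: dissimilarity heatmaps (colour
#' scale anchored at the off-diagonal min/max), the silent vs non-silent
#' scatter with fitted line and printed R/R-squared, stacked per-sample
#' mutation-count bars, a Venn-region size chart and a top-terms enrichment
#' bar chart. Heatmaps for single-sample cohorts are refused with a logged
#' notice; empty tables yield a placeholder figure.
#'
#' @param output_dir a directory written by [run_pipeline()].
#' @param figures_dir where to put the PNGs (default
#'   `output_dir/figures`).
#' @return Invisibly, the paths of the figures written.
#' @export
render_figures <- function(output_dir,
                           figures_dir = file.path(output_dir, "figures")) {
  dir.create(figures_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- file.path(output_dir, "tables")
  out <- character()
  emit <- function(p) out[[length(out) + 1L]] <<- p

  for (f in list.files(tables, pattern = "^(matching_dissimilarity|correlation_distance)_.*\\.tsv$")) {
    m <- .read_dissim_tsv(file.path(tables, f))
    stem <- tools::file_path_sans_ext(f)
    dest <- file.path(figures_dir, paste0("heatmap_", stem, ".png"))
    if (nrow(m) < 2L) {
      .pipe_log("refusing heatmap for ", stem, ": single-sample matrix")
      next
    }
    s <- summarize_matrix(m)
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       breaks = seq(s$min, max(s$max, s$min + 1e-12),
                                    length.out = 101),
                       main = sprintf("%s (range %.3g-%.3g, mean %.3g)",
                                      stem, s$min, s$max, s$mean),
                       filename = dest, silent = TRUE)
    emit(dest)
  }

  for (f in list.files(tables, pattern = "^mutation_counts_.*\\.tsv$")) {
    cnt <- utils::read.delim(file.path(tables, f))
    stem <- tools::file_path_sans_ext(f)
    dest <- file.path(figures_dir, paste0("scatter_", stem, ".png"))
    if (nrow(cnt) == 0L) { emit(.placeholder_figure(dest, "no data")); next }
    if (nrow(cnt) >= 3L && stats::var(cnt$n_silent) > 0 &&
        stats::var(cnt$n_non_silent) > 0) {
      reg <- silent_nonsilent_regression(cnt)
      grDevices::png(dest, width = 600, height = 600)
      graphics::plot(cnt$n_silent, cnt$n_non_silent,
                     xlab = "genes with silent mutations",
                     ylab = "genes with non-silent mutations",
                     main = sprintf("%s: y = %.3gx + %.3g, R = %.3f, R^2 = %.3f",
                                    stem, reg$slope, reg$intercept,
                                    reg$r, reg$r_squared),
                     pch = 19)
      graphics::abline(reg$intercept, reg$slope, col = "red")
      grDevices::dev.off()
      emit(dest)
    }
    dest2 <- file.path(figures_dir, paste0("bars_", stem, ".png"))
    grDevices::png(dest2, width = max(600, 12 * nrow(cnt)), height = 500)
    graphics::barplot(t(as.matrix(cnt[, c("n_silent", "n_non_silent")])),
                      names.arg = cnt$sample_id, las = 2,
                      col = c("grey70", "firebrick"),
                      legend.text = c("silent", "non-silent"),
                      main = stem, border = NA)
    grDevices::dev.off()
    emit(dest2)
  }

  vp <- file.path(tables, "venn_partition.tsv")
  if (file.exists(vp)) {
    df <- utils::read.delim(vp)
    dest <- file.path(figures_dir, "venn_regions.png")
    if (nrow(df) == 0L) {
      emit(.placeholder_figure(dest, "no overlap regions"))
    } else {
      grDevices::png(dest, width = max(600, 45 * nrow(df)), height = 500)
      graphics::par(mar = c(10, 4, 3, 1))
      graphics::barplot(df$size, names.arg = df$region, las = 2,
                        ylab = "genes", main = "multi-set overlap regions")
      grDevices::dev.off()
      emit(dest)
    }
  }

  ef <- file.path(tables, "enrichment_reported.tsv")
  if (file.exists(ef)) {
    df <- utils::read.delim(ef)
    dest <- file.path(figures_dir, "enrichment_top.png")
    if (nrow(df) == 0L) {
      emit(.placeholder_figure(dest, "no enriched terms"))
    } else {
      top <- utils::head(df, 10L)
      grDevices::png(dest, width = 700, height = 500)
      graphics::par(mar = c(5, 14, 3, 1))
      graphics::barplot(rev(-log10(top$ease_p)), names.arg = rev(top$term),
                        horiz = TRUE, las = 1, xlab = "-log10 EASE p",
                        main = "top enriched terms")
      grDevices::dev.off()
      emit(dest)
    }
  }
  .pipe_log("rendered ", length(out), " figure(s) in ", figures_dir)
  invisible(out)
}
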