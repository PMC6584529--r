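#' Hierarchically cluster populations from an overlap matrix
#'
#' Agglomerative clustering on the dissimilarity d(i, j) = 1 - overlap(i, j)
#' with average linkage (UPGMA) by default. Populations are presented in
#' code order, which fixes tie-breaking deterministically.
#'
#' @param matrix an `overlap_matrix`.
#' @param linkage linkage criterion passed to [stats::hclust()] (default
#'   `"average"`).
#' @return Object of class `population_dendrogram`: list with `merge`,
#'   `height`, `order`, `labels` and the underlying `hclust` object.
#' @export
cluster_populations <- function(matrix, linkage = "average") {
  vals <- unclass(matrix)
  if (nrow(vals) < 2) stop("need at least 2 populations")
  if (max(abs(vals - t(vals))) > 1e-9) {
    stop("overlap matrix is not symmetric within tolerance 1e-9")
  }
  ord <- order(rownames(vals))
  vals <- vals[ord, ord]
  d <- stats::as.dist(1 - vals)
  hc <- stats::hclust(d, method = linkage)
  structure(list(merge = hc$merge, height = hc$height,
                 order = hc$order, labels = hc$labels, hclust = hc,
                 linkage = linkage, level = attr(matrix, "level")),
            class = "population_dendrogram")
}

#' @export
print.population_dendrogram <- function(x, ...) {
  cat("population_dendrogram (level:", x$level %||% "?", "; linkage:",
      x$linkage, ")\n")
  cat("  leaf order:", paste(x$labels[x$order], collapse = " "), "\n")
  cat("  merge heights:", paste(round(x$height, 4), collapse = " "), "\n")
  invisible(x)
}

open_figure_device <- function(path_stub) {
  if (isTRUE(unname(capabilities("png")))) {
    path <- paste0(path_stub, ".png")
    grDevices::png(path, width = 1200, height = 900, res = 150)
  } else {
    path <- paste0(path_stub, ".pdf")
    grDevices::pdf(path, width = 8, height = 6)
  }
  path
}

plot_heatmap <- function(matrix, dendro, path_stub) {
  path <- open_figure_device(path_stub)
  on.exit(grDevices::dev.off())
  vals <- unclass(matrix)
  ord <- dendro$order
  labs <- dendro$labels
  vals <- vals[labs, labs][ord, ord]
  pal <- grDevices::colorRampPalette(c("white", "#b22222"))(64)
  graphics::par(mar = c(5, 5, 3, 1))
  graphics::image(seq_len(nrow(vals)), seq_len(ncol(vals)),
                  t(vals[rev(seq_len(nrow(vals))), ]),
                  col = pal, zlim = c(0, 1), axes = FALSE, xlab = "",
                  ylab = "",
                  main = paste0("overlap (", attr(matrix, "level"), ")"))
  graphics::axis(1, seq_len(ncol(vals)), colnames(vals), las = 2)
  graphics::axis(2, seq_len(nrow(vals)), rev(rownames(vals)), las = 2)
  path
}

plot_overlap_function <- function(observed, null, path_stub) {
  path <- open_figure_device(path_stub)
  on.exit(grDevices::dev.off())
  l <- seq_len(observed$k)
  graphics::par(mar = c(5, 5, 3, 1))
  graphics::plot(l, observed$values, type = "b", pch = 19, ylim = c(0, 1),
                 xlab = "number of populations (l)",
                 ylab = "cumulative overlap f(l)",
                 main = paste0("cumulative overlap (", observed$level, ")"))
  if (!is.null(null)) {
    graphics::polygon(c(l, rev(l)),
                      c(null$summary$min, rev(null$summary$max)),
                      col = grDevices::adjustcolor("grey", 0.5), border = NA)
    graphics::lines(l, null$summary$mean, lty = 2, col = "grey30")
    graphics::lines(l, observed$values, type = "b", pch = 19)
  }
  path
}

plot_subtype_bars <- function(counts, path_stub) {
  path <- open_figure_device(path_stub)
  on.exit(grDevices::dev.off())
  mat <- t(as.matrix(counts[, c("secretion_deficiency", "insulin_resistance",
                                "both", "other")]))
  colnames(mat) <- counts$population
  graphics::par(mar = c(5, 5, 3, 1))
  graphics::barplot(mat, col = c("gold", "steelblue", "seagreen", "grey80"),
                    legend.text = rownames(mat),
                    xlab = "population", ylab = "genes",
                    main = paste0("subtype stratification (",
                                  attr(counts, "granularity"), ")"))
  path
}

write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(population = rownames(matrix),
                   as.data.frame(unclass(matrix)), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write the consolidated run report
#'
#' For every computed level writes the overlap matrix and cumulative overlap
#' function as TSV, the clustered heatmap and the overlap-function figure
#' with the permutation min/max band and mean line, plus the significance
#' table, optional subtype stacked bars, and a JSON manifest recording the
#' configuration, seed and any levels dropped along the way.
#'
#' @param results named list, level -> list with elements `matrix`
#'   (`overlap_matrix`), `cumulative` (`cumulative_overlap`), and optionally
#'   `null` (`permutation_null`) and `significance`.
#' @param out_dir output directory (created if needed).
#' @param subtype_counts optional named list of `subtype_counts` tables (by
#'   granularity).
#' @param config optional configuration list echoed into the manifest.
#' @param dropped_populations optional character vector of population codes
#'   excluded from function/network levels.
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
render_report <- function(results, out_dir, subtype_counts = NULL,
                          config = NULL, dropped_populations = NULL) {
  if (length(results) == 0) stop("no computed levels to report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gwasoverlap")),
    generated = "run report",
    levels = names(results),
    dropped_populations = dropped_populations %||% character(0),
    config = config %||% list(),
    files = list())
  all_levels <- c("snp", "ld", "gene", "function", "network")
  manifest$missing_levels <- setdiff(all_levels, names(results))
  sig_rows <- list()
  for (level in names(results)) {
    res <- results[[level]]
    files <- list()
    if (!is.null(res$matrix)) {
      files$matrix_tsv <- write_matrix_tsv(
        res$matrix, file.path(out_dir, paste0("overlap_matrix_", level,
                                              ".tsv")))
      dendro <- cluster_populations(res$matrix)
      files$heatmap <- plot_heatmap(res$matrix, dendro,
                                    file.path(out_dir,
                                              paste0("heatmap_", level)))
      files$leaf_order <- paste(dendro$labels[dendro$order], collapse = ",")
    }
    if (!is.null(res$cumulative)) {
      cum_df <- data.frame(l = seq_len(res$cumulative$k),
                           f = res$cumulative$values)
      p <- file.path(out_dir, paste0("cumulative_overlap_", level, ".tsv"))
      write.table(cum_df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      files$cumulative_tsv <- p
      files$function_plot <- plot_overlap_function(
        res$cumulative, res$null,
        file.path(out_dir, paste0("overlap_function_", level)))
    }
    if (!is.null(res$null)) {
      p <- file.path(out_dir, paste0("null_summary_", level, ".tsv"))
      write.table(cbind(level = level, res$null$summary), p, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      files$null_tsv <- p
    }
    if (!is.null(res$significance)) {
      sig_rows[[level]] <- cbind(level = level,
                                 as.data.frame(res$significance))
    }
    manifest$files[[level]] <- files
  }
  if (length(sig_rows) > 0) {
    sig <- do.call(rbind, sig_rows)
    rownames(sig) <- NULL
    p <- file.path(out_dir, "significance.tsv")
    write.table(sig, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$files$significance <- p
  }
  if (!is.null(subtype_counts)) {
    for (gran in names(subtype_counts)) {
      p <- file.path(out_dir, paste0("subtype_counts_", gran, ".tsv"))
      write.table(subtype_counts[[gran]], p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      manifest$files[[paste0("subtype_", gran)]] <-
        list(tsv = p,
             figure = plot_subtype_bars(
               subtype_counts[[gran]],
               file.path(out_dir, paste0("subtype_bars_", gran))))
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
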