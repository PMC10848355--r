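# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a DE result (drops the class attributes)
#' @param x A `boom_de` table.
#' @param ... Unused.
#' @return Plain tibble.
#' @export
tidy.boom_de <- function(x, ...) as_tibble(unclass(x)[
  c("feature", "base_mean", "log2fc", "p", "p_adj", "direction", "method")])

#' One-line summary of a DE result
#' @param x A `boom_de` table.
#' @param ... Unused.
#' @return One-row tibble: contrast, method, alpha, up/down/total counts.
#' @export
glance.boom_de <- function(x, ...) {
  cnt <- count_de_directions(x)
  tibble(contrast = paste(attr(x, "contrast"), collapse = " vs "),
         method = x$method[1], alpha = attr(x, "alpha")) |>
    dplyr::bind_cols(cnt)
}

#' Tidy a consensus DEG set
#' @param x A `consensus_degs` object.
#' @param ... Unused.
#' @return Tibble with feature, direction.
#' @export
tidy.consensus_degs <- function(x, ...) {
  bind_rows(tibble(feature = x$up, direction = "up"),
            tibble(feature = x$down, direction = "down")) |>
    arrange(.data$feature)
}

#' Tidy bookkeeping categories
#' @param x A `delta_bookkeeping` object.
#' @param ... Unused.
#' @return Tibble with feature, category.
#' @export
tidy.delta_bookkeeping <- function(x, ...) {
  bind_rows(tibble(feature = x$normalized, category = "normalized"),
            tibble(feature = x$persistent, category = "persistent"),
            tibble(feature = x$de_novo, category = "de_novo")) |>
    arrange(.data$feature)
}

#' Tidy a classifier set (provenance table)
#' @param x A `classifier_set`.
#' @param ... Unused.
#' @return Tibble with feature, provenance.
#' @export
tidy.classifier_set <- function(x, ...) x$provenance

#' @export
glance.classifier_set <- function(x, ...) {
  tibble(contrast = x$contrast, n_classifier = length(x$features),
         n_pca_only = sum(x$provenance$provenance == "pca_only"),
         n_de_only = sum(x$provenance$provenance == "de_only"))
}

#' Tidy term clusters
#' @param x A `term_clusters` object.
#' @param ... Unused.
#' @return Membership tibble with the cluster representative attached.
#' @export
tidy.term_clusters <- function(x, ...) {
  x$membership |> mutate(representative = x$representatives[.data$cluster])
}

#' Tidy target clusters
#' @param x A `target_clusters` object.
#' @param ... Unused.
#' @return Membership tibble (cluster 0 = flat rows).
#' @export
tidy.target_clusters <- function(x, ...) x$membership

#' PCA score plot
#' @param object A `boom_pca`.
#' @param ... Unused.
#' @return A ggplot of the first two score dimensions, colored by group
#'   when groups are known.
#' @export
autoplot.boom_pca <- function(object, ...) {
  d <- tidy(object)
  ev <- object$explained_variance
  p <- if ("group" %in% names(d)) {
    ggplot(d, aes(.data$PC1, .data$PC2, colour = .data$group))
  } else {
    ggplot(d, aes(.data$PC1, .data$PC2))
  }
  p + geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * ev[2])) +
    theme_minimal()
}

#' Volcano plot of a DE result
#' @param object A `boom_de` table.
#' @param ... Unused.
#' @return A ggplot of log2FC vs -log10 adjusted p, colored by direction.
#' @export
autoplot.boom_de <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(.data$log2fc, -log10(.data$p_adj), colour = .data$direction)) +
    geom_point(alpha = 0.6) +
    labs(x = "log2 fold change", y = "-log10 adjusted p") +
    theme_minimal()
}

#' Volcano plot with the significance curve
#' @param object A `boom_dep` table.
#' @param ... Unused.
#' @return A ggplot with the significance-curve boundary overlaid.
#' @export
autoplot.boom_dep <- function(object, ...) {
  curve <- attr(object, "curve")
  fc <- seq(curve["fc_min"] + 0.01, max(abs(object$log2fc), 2) + 1, by = 0.01)
  thr <- -log10(curve["alpha"]) + curve["curvature"] / (fc - curve["fc_min"])
  boundary <- bind_rows(tibble(log2fc = fc, y = thr),
                        tibble(log2fc = -fc, y = thr))
  ggplot(as_tibble(object),
         aes(.data$log2fc, -log10(.data$p_adj))) +
    geom_point(aes(colour = .data$consistent), alpha = 0.6) +
    geom_line(data = boundary, aes(.data$log2fc, .data$y, group = sign(.data$log2fc)),
              linetype = "dashed", colour = "grey40") +
    labs(x = "log2 fold change", y = "-log10 adjusted p") +
    theme_minimal()
}

#' Tile plot of term clusters (treemap layout table)
#' @param treemap The `treemap` tibble from [display_tables()].
#' @return A ggplot bar layout: one bar per cluster, segments per term
#'   sized by term gene count.
#' @export
plot_term_clusters <- function(treemap) {
  ggplot(treemap, aes(factor(.data$cluster), .data$tile_size,
                      fill = .data$representative, group = .data$term)) +
    geom_col(colour = "white") +
    labs(x = "cluster", y = "term size (genes)") +
    theme_minimal()
}

#' Trajectory plot of TF target clusters
#' @param report The tibble from [cluster_trajectory_report()].
#' @return A ggplot of per-cluster mean log2FC across contrasts.
#' @export
plot_cluster_trajectories <- function(report) {
  long <- report |>
    pivot_longer(dplyr::starts_with("mean_"), names_to = "contrast",
                 values_to = "mean_log2fc") |>
    mutate(contrast = sub("^mean_", "", .data$contrast))
  ggplot(long, aes(.data$contrast, .data$mean_log2fc,
                   group = factor(.data$cluster), colour = factor(.data$cluster))) +
    geom_point() + geom_line() +
    labs(colour = "cluster", y = "mean log2 fold change") +
    theme_minimal()
}
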