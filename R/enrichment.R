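# Hypergeometric over-representation, redundancy pruning at similarity 0.7,
# binary-cut clustering of the similarity matrix, and the layout tables
# behind treemap / word-cloud / ridge displays.

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test per term: with N universe genes,
#' K of them annotated to the term, and a query of n genes hitting k of the
#' term's genes, p = P(X >= k). Terms are retained at raw p < `p_max`
#' (no multiplicity adjustment, matching the study's threshold); a BH column
#' is included for transparency.
#'
#' @param query Character vector of genes of interest (must lie in universe).
#' @param universe Character vector, the gene universe (all detected genes).
#' @param dag An [ontology_dag()] carrying the annotations.
#' @param p_max Raw-p retention threshold. Default 0.1.
#' @param lfc Optional named log2-fold-change vector used to annotate each
#'   term with the mean log2fc of its hit genes.
#' @return Tibble of class `boom_enrichment`: `term`, `name`, `k`, `K`, `n`,
#'   `N`, `p`, `p_adj`, `genes` (list column of hits), `mean_log2fc`.
#' @export
ora <- function(query, universe, dag, p_max = 0.1, lfc = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  universe <- unique(universe)
  if (!length(universe)) abort("empty universe")
  query <- unique(query)
  if (length(setdiff(query, universe))) abort("query genes outside the universe")
  if (!length(query)) {
    inform("empty query: no enrichment computed")
    return(structure(tibble(term = character(), name = character(),
                            k = integer(), K = integer(), n = integer(),
                            N = integer(), p = numeric(), p_adj = numeric(),
                            genes = list(), mean_log2fc = numeric()),
                     class = c("boom_enrichment", "tbl_df", "tbl", "data.frame")))
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(dag$terms, function(t) {
    tg <- intersect(dag$annotations[[t]], universe)
    K <- length(tg)
    if (K == 0) return(NULL)
    hits <- intersect(tg, query)
    k <- length(hits)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = t,
           name = if (!is.null(dag$term_names)) unname(dag$term_names[t]) else t,
           k = k, K = K, n = n, N = N, p = p, genes = list(sort(hits)),
           mean_log2fc = if (!is.null(lfc) && k > 0) mean(lfc[hits], na.rm = TRUE)
                         else NA_real_)
  })
  out <- bind_rows(rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out |> filter(.data$k >= 1, .data$p < p_max) |> arrange(.data$p, .data$term)
  structure(out |> select("term", "name", "k", "K", "n", "N", "p", "p_adj",
                          "genes", "mean_log2fc"),
            class = c("boom_enrichment", class(out)))
}

#' Greedy redundancy pruning of enriched terms
#'
#' Walks terms in order of ascending p (ties broken by term id) and keeps a
#' term only if its semantic similarity to every already-kept term is below
#' `threshold`. The result is deterministic and independent of the input
#' row order.
#'
#' @param terms Data frame with columns `term` and `p` (e.g. an [ora()]
#'   result).
#' @param sim Symmetric similarity matrix over (at least) those terms.
#' @param threshold Redundancy threshold. Default 0.7.
#' @return Character vector of retained term ids, in the greedy order.
#' @export
prune_redundant <- function(terms, sim, threshold = 0.7) {
  stopifnot(is.data.frame(terms), all(c("term", "p") %in% names(terms)))
  ord <- terms[order(terms$p, terms$term), ]
  kept <- character(0)
  for (i in seq_len(nrow(ord))) {
    t <- ord$term[i]
    if (!length(kept) || all(sim[t, kept] < threshold)) kept <- c(kept, t)
  }
  kept
}

binary_cut_rec <- function(sim, idx, homogeneity, min_size) {
  if (length(idx) < min_size) return(list(idx))
  block <- sim[idx, idx, drop = FALSE]
  off <- block[upper.tri(block)]
  if (!length(off) || mean(off) >= homogeneity) return(list(idx))
  hc <- hclust(as.dist(1 - block), method = "average")
  split <- cutree(hc, k = 2)
  if (length(unique(split)) < 2) return(list(idx))
  c(binary_cut_rec(sim, idx[split == 1], homogeneity, min_size),
    binary_cut_rec(sim, idx[split == 2], homogeneity, min_size))
}

#' Binary-cut clustering of a semantic similarity matrix
#'
#' Recursively bipartitions the average-linkage dendrogram of 1 - similarity:
#' a node becomes a cluster when the mean off-diagonal similarity of its
#' block reaches the homogeneity cutoff or the block has fewer than
#' `min_size` terms. Representatives are the member term with the smallest p
#' when p-values are supplied.
#'
#' @param sim Symmetric similarity matrix with term ids as dimnames.
#' @param p Optional named p-value vector used to pick representatives.
#' @param homogeneity Mean-similarity cutoff to stop splitting. Default 0.85.
#' @param min_size Blocks smaller than this are never split. Default 3.
#' @return A `term_clusters` object: `membership` tibble (term, cluster),
#'   `clusters` (list of term vectors), `representatives`.
#' @export
binary_cut <- function(sim, p = NULL, homogeneity = 0.85, min_size = 3) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  if (is.null(rownames(sim))) abort("`sim` needs term ids as dimnames")
  if (max(abs(sim - t(sim))) > 1e-8) abort("`sim` must be symmetric")
  terms <- rownames(sim)
  if (length(terms) == 1) {
    groups <- list(terms)
  } else {
    groups <- binary_cut_rec(sim, terms, homogeneity, min_size)
  }
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  membership <- bind_rows(imap(groups, function(g, i) tibble(term = g, cluster = i)))
  reps <- vapply(groups, function(g) {
    if (is.null(p)) g[1] else g[which.min(p[g])]
  }, character(1))
  structure(list(membership = membership, clusters = groups,
                 representatives = reps),
            class = "term_clusters")
}

#' @exportS3Method base::print
print.term_clusters <- function(x, ...) {
  cat(sprintf("<term_clusters> %d terms in %d clusters\n",
              nrow(x$membership), length(x$clusters)))
  invisible(x)
}

#' Layout tables for treemap, word-cloud and ridge displays
#'
#' Converts enrichment results and their semantic clusters into the plain
#' tables a plotting layer needs: treemap tiles (one per term, tile size =
#' term gene count, cluster area = number of member terms), word frequencies
#' (per gene, the number of enriched terms containing it, signed by log2fc),
#' and ridge rows (per-term member log2 fold changes with their mean).
#'
#' @param results A [ora()] result (enriched terms only).
#' @param clusters A [binary_cut()] result over those terms.
#' @param lfc Named log2-fold-change vector for the query genes.
#' @return List of tibbles `treemap`, `words`, `ridge`.
#' @export
display_tables <- function(results, clusters, lfc = NULL) {
  stopifnot(inherits(results, "boom_enrichment"), inherits(clusters, "term_clusters"))
  mem <- clusters$membership
  area <- mem |> group_by(.data$cluster) |> summarise(cluster_area = n())
  treemap <- results |>
    select("term", "name", tile_size = "K", "p") |>
    left_join(mem, by = "term") |>
    left_join(area, by = "cluster") |>
    mutate(representative = clusters$representatives[.data$cluster])

  long <- results |>
    select("term", "genes") |>
    tidyr::unnest_longer("genes", values_to = "gene")
  words <- long |>
    group_by(.data$gene) |>
    summarise(frequency = n(), .groups = "drop") |>
    mutate(sign = if (is.null(lfc)) NA_character_
           else ifelse(lfc[.data$gene] > 0, "up", "down")) |>
    arrange(dplyr::desc(.data$frequency), .data$gene)

  ridge <- long |>
    mutate(log2fc = if (is.null(lfc)) NA_real_ else unname(lfc[.data$gene])) |>
    group_by(.data$term) |>
    mutate(mean_log2fc = mean(.data$log2fc)) |>
    ungroup()

  list(treemap = treemap, words = words, ridge = ridge)
}
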