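# Classifier-gene pipeline: PCA on log2 normalized expression, per-PC
# loading-range selection (top/bottom 20% of the loading span, top six PCs),
# intersection with dual-method consensus DEGs, and projection of samples on
# the resulting signature.

#' Log2 normalized expression from counts
#'
#' @param counts A [count_matrix()].
#' @return Features x samples matrix of log2(normalized count + 1).
#' @export
log_normalized <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  sf <- size_factors(counts)
  log2(sweep(counts$counts, 2, sf, "/") + 1)
}

#' PCA of an expression matrix
#'
#' Samples are observations and features variables; the expression is
#' centered by default and not scaled. Accepts a [count_matrix()] (converted
#' with [log_normalized()]) or a plain features x samples matrix.
#'
#' @param expr A `count_matrix` or numeric features x samples matrix with no
#'   missing values.
#' @param center,scale Passed to [stats::prcomp()]. Defaults: center, no scaling.
#' @param features Optional feature subset to restrict to before PCA.
#' @return A `boom_pca` object: `loadings` (features x PCs, orthonormal
#'   columns), `scores` (samples x PCs), `explained_variance` (fractions,
#'   non-increasing), `groups` when available.
#' @export
pca_expression <- function(expr, center = TRUE, scale = FALSE, features = NULL) {
  groups <- NULL
  if (inherits(expr, "count_matrix")) {
    groups <- expr$groups
    expr <- log_normalized(expr)
  }
  stopifnot(is.matrix(expr))
  if (anyNA(expr)) abort("expression matrix contains missing values")
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(expr))
    if (length(miss)) abort(paste("features absent from expression matrix:",
                                  paste(miss, collapse = ", ")))
    expr <- expr[features, , drop = FALSE]
  }
  if (ncol(expr) < 2) abort("PCA needs >= 2 samples")
  x <- t(expr)
  sds <- apply(x, 2, sd)
  if (all(sds == 0)) abort("constant expression matrix: no variance to decompose")
  if (scale) x <- x[, sds > 0, drop = FALSE]
  fit <- prcomp(x, center = center, scale. = scale)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(loadings = fit$rotation, scores = fit$x,
                 explained_variance = ev, groups = groups),
            class = "boom_pca")
}

#' @exportS3Method base::print
print.boom_pca <- function(x, ...) {
  cat(sprintf("<boom_pca> %d features, %d samples, %d PCs (PC1 %.1f%% var)\n",
              nrow(x$loadings), nrow(x$scores), ncol(x$loadings),
              100 * x$explained_variance[1]))
  invisible(x)
}

#' Tidy PCA sample scores
#' @param x A `boom_pca`.
#' @param ... Unused.
#' @return Tibble with sample, group (if known) and one column per PC score.
#' @export
tidy.boom_pca <- function(x, ...) {
  out <- as_tibble(x$scores, rownames = "sample")
  if (!is.null(x$groups)) out <- out |> mutate(group = unname(x$groups[.data$sample]),
                                               .after = "sample")
  out
}

#' Select features in the top/bottom fraction of each PC's loading range
#'
#' For PC k with loading span [lo, hi], features with loading
#' >= hi - frac * (hi - lo) or <= lo + frac * (hi - lo) are selected
#' (boundaries inclusive); the selection is the union over the first
#' `n_pcs` PCs. A PC with zero loading range selects nothing. If fewer than
#' `n_pcs` PCs are available (few samples), all available PCs are used with
#' a warning.
#'
#' @param loadings A `boom_pca` or a features x PCs loading matrix.
#' @param n_pcs Number of leading PCs to use. Default 6.
#' @param frac Fraction of the loading range at each end. Default 0.2,
#'   must lie in (0, 0.5).
#' @return A `loading_selection` object: `per_pc` (feature sets per PC),
#'   `union`, `n_pcs`, `frac`.
#' @export
select_by_loading_range <- function(loadings, n_pcs = 6, frac = 0.2) {
  if (inherits(loadings, "boom_pca")) loadings <- loadings$loadings
  stopifnot(is.matrix(loadings))
  check_fraction(frac, "frac", lo = 0, hi = 0.5, open = TRUE)
  n_pcs <- check_count(n_pcs, "n_pcs", min = 1L)
  if (n_pcs > ncol(loadings)) {
    warn(sprintf("only %d PCs available; using all of them", ncol(loadings)))
    n_pcs <- ncol(loadings)
  }
  per_pc <- lapply(seq_len(n_pcs), function(k) {
    l <- loadings[, k]
    lo <- min(l); hi <- max(l)
    if (hi == lo) return(character())
    sel <- l >= hi - frac * (hi - lo) | l <= lo + frac * (hi - lo)
    sort(rownames(loadings)[sel])
  })
  names(per_pc) <- colnames(loadings)[seq_len(n_pcs)]
  structure(list(per_pc = per_pc, union = sort(unique(unlist(per_pc)))
                 , n_pcs = n_pcs, frac = frac),
            class = "loading_selection")
}

#' @exportS3Method base::print
print.loading_selection <- function(x, ...) {
  cat(sprintf("<loading_selection> %d features over %d PCs (frac %.2f)\n",
              length(x$union), x$n_pcs, x$frac))
  invisible(x)
}

#' Derive a classifier gene set
#'
#' The classifier is the intersection of the PCA loading-range selection with
#' the dual-method consensus DEGs, ordered lexicographically. Features in only
#' one of the two inputs are kept in the provenance table for transparency.
#'
#' @param selection A [select_by_loading_range()] result.
#' @param consensus_set A [consensus()] result (or character vector of DEGs).
#' @param contrast Optional contrast label carried in the result.
#' @return A `classifier_set`: `features` (the classifier), `provenance`
#'   tibble (feature, provenance in {classifier, pca_only, de_only}),
#'   `contrast`.
#' @export
derive_classifier <- function(selection, consensus_set, contrast = NULL) {
  stopifnot(inherits(selection, "loading_selection"))
  degs <- if (is.character(consensus_set)) sort(consensus_set)
          else sort(c(consensus_set$up, consensus_set$down))
  feats <- sort(intersect(selection$union, degs))
  prov <- bind_rows(
    tibble(feature = feats, provenance = "classifier"),
    tibble(feature = setdiff(selection$union, degs), provenance = "pca_only"),
    tibble(feature = setdiff(degs, selection$union), provenance = "de_only")
  ) |> arrange(.data$feature)
  structure(list(features = feats, provenance = prov,
                 contrast = contrast %||% NA_character_),
            class = "classifier_set")
}

#' @exportS3Method base::print
print.classifier_set <- function(x, ...) {
  cat(sprintf("<classifier_set> %d genes (%s)\n", length(x$features), x$contrast))
  invisible(x)
}

#' Combine classifier signatures
#'
#' Union of several classifier gene sets (e.g. the group classifier and the
#' de-obstruction classifier combined into one panel).
#'
#' @param ... `classifier_set` objects or character vectors.
#' @return Sorted character vector of the union.
#' @export
combine_signatures <- function(...) {
  sets <- lapply(list(...), function(x) {
    if (inherits(x, "classifier_set")) x$features else as.character(x)
  })
  sort(unique(unlist(sets)))
}

#' Project samples on a classifier signature and quantify group separation
#'
#' Runs PCA restricted to the classifier features and computes the mean
#' silhouette width of the sample labels on the first two score dimensions
#' (one if only one PC exists). Silhouette near 1 means clear separation,
#' near 0 no structure.
#'
#' @param expr A `count_matrix` or features x samples expression matrix.
#' @param classifier A `classifier_set` or character vector of features.
#' @param labels Named (by sample) or ordered vector of sample labels; taken
#'   from the count matrix groups when omitted.
#' @return List with `pca` (`boom_pca` on the restricted matrix), `scores`
#'   tibble and `silhouette` (mean width, in [-1, 1]).
#' @export
project_and_separate <- function(expr, classifier, labels = NULL) {
  feats <- if (inherits(classifier, "classifier_set")) classifier$features
           else as.character(classifier)
  if (!length(feats)) abort("empty classifier")
  if (is.null(labels) && inherits(expr, "count_matrix")) labels <- expr$groups
  if (is.null(labels)) abort("`labels` required for a plain matrix")
  pc <- pca_expression(expr, features = feats)
  labels <- if (!is.null(names(labels))) labels[rownames(pc$scores)] else labels
  if (length(unique(labels)) < 2) abort("need >= 2 distinct labels")
  d <- min(2L, ncol(pc$scores))
  s <- cluster::silhouette(as.integer(factor(labels)),
                           dist(pc$scores[, seq_len(d), drop = FALSE]))
  list(pca = pc, scores = tidy(pc) |> mutate(label = unname(labels)),
       silhouette = mean(s[, "sil_width"]))
}
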