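# TF -> target regulon analysis: mapping DEGs onto TF databases, trajectory
# categories across the before/after contrasts, clustering of target log2FC
# profiles (1 - Pearson, average linkage), and per-cluster summaries.

#' Read or validate a TF -> target table
#'
#' @param db Data frame with columns `tf`, `target`, `source`.
#' @return The validated tibble with class `tf_regulon_db`; duplicated
#'   tf-target pairs are kept once per source (provenance preserved).
#' @export
tf_regulon_db <- function(db) {
  stopifnot(is.data.frame(db))
  need <- c("tf", "target", "source")
  miss <- setdiff(need, names(db))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  out <- as_tibble(db) |> distinct(.data$tf, .data$target, .data$source)
  if (!nrow(out)) abort("empty TF database")
  structure(out, class = c("tf_regulon_db", class(out)))
}

regulon_targets <- function(db, tf) {
  sort(unique(db$target[db$tf == tf]))
}

#' Trajectory category from before/after DE indicators
#'
#' Pure function of the per-group DE booleans: `persistent` if the feature is
#' DE before and after surgery in some group; otherwise `normalized_after` if
#' it was DE before in some group (and, by exclusion, in no such group after);
#' otherwise `de_novo` if DE only after; else `unchanged`.
#'
#' @param de_before,de_after Logical vectors, one element per patient group.
#' @return One of "persistent", "normalized_after", "de_novo", "unchanged".
#' @export
tf_category <- function(de_before, de_after) {
  stopifnot(length(de_before) == length(de_after))
  if (any(de_before & de_after)) return("persistent")
  if (any(de_before)) return("normalized_after")
  if (any(de_after)) return("de_novo")
  "unchanged"
}

parse_contrast_names <- function(nms) {
  ok <- grepl("_(before|after)$", nms)
  if (!all(ok)) abort(paste("contrast names must end in _before/_after:",
                            paste(nms[!ok], collapse = ", ")))
  tibble(contrast = nms,
         group = sub("_(before|after)$", "", nms),
         timepoint = sub("^.*_", "", nms))
}

de_flags <- function(x, feature_universe) {
  s <- de_sets(x)
  setNames(feature_universe %in% c(s$up, s$down), feature_universe)
}

lfc_lookup <- function(x, feature_universe) {
  if (inherits(x, "boom_de") || (is.data.frame(x) && all(c("feature", "log2fc") %in% names(x)))) {
    v <- setNames(x$log2fc, x$feature)
    return(unname(v[feature_universe]) |> setNames(feature_universe))
  }
  setNames(rep(NA_real_, length(feature_universe)), feature_universe)
}

#' Regulated transcription factors and their trajectory categories
#'
#' Maps the DE results of the four before/after contrasts onto a TF database
#' and classifies each TF found DE in at least one contrast into persistent /
#' normalized_after / de_novo, based on its per-group before/after DE pattern
#' (see [tf_category()]).
#'
#' @param de_by_contrast Named list of `boom_de` (or `consensus_degs`)
#'   results; names must end in `_before` / `_after` with the patient group
#'   as prefix (e.g. `HP_before`).
#' @param db A [tf_regulon_db()] (TFs are its `tf` column).
#' @param require `"any"` (default) keeps TFs DE in at least one contrast;
#'   `"all"` keeps only TFs DE in every contrast.
#' @return Tibble: `tf`, `category`, one `de_<contrast>` flag and one
#'   `lfc_<contrast>` column per contrast.
#' @export
regulated_tfs <- function(de_by_contrast, db, require = c("any", "all")) {
  require <- match.arg(require)
  db <- tf_regulon_db(db)
  if (!length(de_by_contrast) || is.null(names(de_by_contrast))) {
    abort("`de_by_contrast` must be a named list")
  }
  meta <- parse_contrast_names(names(de_by_contrast))
  tfs <- sort(unique(db$tf))
  flags <- lapply(de_by_contrast, de_flags, feature_universe = tfs)
  lfcs <- lapply(de_by_contrast, lfc_lookup, feature_universe = tfs)

  keep <- if (require == "any") Reduce(`|`, flags) else Reduce(`&`, flags)
  tfs <- tfs[keep]
  if (!length(tfs)) {
    return(tibble(tf = character(), category = character()))
  }
  groups <- unique(meta$group)
  cat <- vapply(tfs, function(tf) {
    before <- vapply(groups, function(g) {
      c <- meta$contrast[meta$group == g & meta$timepoint == "before"]
      if (length(c)) flags[[c]][[tf]] else FALSE
    }, logical(1))
    after <- vapply(groups, function(g) {
      c <- meta$contrast[meta$group == g & meta$timepoint == "after"]
      if (length(c)) flags[[c]][[tf]] else FALSE
    }, logical(1))
    tf_category(before, after)
  }, character(1))

  out <- tibble(tf = tfs, category = unname(cat))
  for (cn in meta$contrast) {
    out[[paste0("de_", cn)]] <- unname(flags[[cn]][tfs])
    out[[paste0("lfc_", cn)]] <- unname(lfcs[[cn]][tfs])
  }
  out
}

#' Log2 fold changes of a TF's targets across contrasts
#'
#' @param tf A TF id present in the database.
#' @param db A [tf_regulon_db()].
#' @param lfc_tables Named list of DE tables (with `feature`, `log2fc`), one
#'   per contrast.
#' @return Matrix targets x contrasts of log2 fold changes; regulon targets
#'   absent from the data are dropped with a message.
#' @export
target_matrix <- function(tf, db, lfc_tables) {
  db <- tf_regulon_db(db)
  if (!tf %in% db$tf) abort(paste("TF not in database:", tf))
  targets <- regulon_targets(db, tf)
  measured <- Reduce(intersect, lapply(lfc_tables, function(t) t$feature))
  keep <- intersect(targets, measured)
  dropped <- setdiff(targets, keep)
  if (length(dropped)) {
    inform(sprintf("%d regulon target(s) not measured; dropped", length(dropped)))
  }
  if (!length(keep)) {
    warn(sprintf("no measured targets for %s", tf))
    return(matrix(numeric(0), 0, length(lfc_tables),
                  dimnames = list(NULL, names(lfc_tables))))
  }
  m <- vapply(lfc_tables, function(t) {
    setNames(t$log2fc, t$feature)[keep]
  }, numeric(length(keep)))
  m <- matrix(m, nrow = length(keep),
              dimnames = list(keep, names(lfc_tables)))
  m
}

#' Cluster target trajectories with 1 - Pearson distance, average linkage
#'
#' Rows (targets) are clustered on their log2FC profiles across the
#' contrasts using agglomerative clustering with distance
#' d(x, y) = 1 - pearson(x, y) and average linkage, cut into `k` clusters.
#' Rows with zero variance (flat profiles, where the correlation is
#' undefined) are set aside in a separate "flat" bucket.
#'
#' @param mat Targets x contrasts numeric matrix (e.g. [target_matrix()]).
#' @param k Number of clusters. Default 5.
#' @return A `target_clusters` object: `membership` tibble (`target`,
#'   `cluster`; flat rows get cluster 0), `tree` (the hclust object), `k`.
#' @export
cluster_targets <- function(mat, k = 5) {
  stopifnot(is.matrix(mat))
  k <- check_count(k, "k", min = 1L)
  rv <- apply(mat, 1, var)
  flat <- rownames(mat)[rv == 0 | is.na(rv)]
  live <- setdiff(rownames(mat), flat)
  if (length(live) < k) abort(sprintf("need >= k = %d rows with variance", k))
  sub <- mat[live, , drop = FALSE]
  d <- as.dist(1 - cor(t(sub)))
  tree <- hclust(d, method = "average")
  cl <- cutree(tree, k = k)
  membership <- bind_rows(
    tibble(target = live, cluster = unname(cl)),
    tibble(target = flat, cluster = 0L)
  ) |> arrange(.data$cluster, .data$target)
  structure(list(membership = membership, tree = tree, k = k),
            class = "target_clusters")
}

#' @exportS3Method base::print
print.target_clusters <- function(x, ...) {
  cat(sprintf("<target_clusters> %d targets in %d clusters\n",
              nrow(x$membership), x$k))
  invisible(x)
}

#' Per-cluster trajectory summary
#'
#' Mean log2FC per contrast for each target cluster plus a `down_after`
#' flag: TRUE when the cluster's mean log2FC drops from before to after
#' surgery in every patient group, the signature of obstruction-driven
#' expression that relaxes after de-obstruction.
#'
#' @param clusters A [cluster_targets()] result.
#' @param mat The matrix the clusters were computed from.
#' @return Tibble: `cluster`, `n_targets`, one `mean_<contrast>` column per
#'   contrast, `down_after`.
#' @export
cluster_trajectory_report <- function(clusters, mat) {
  stopifnot(inherits(clusters, "target_clusters"))
  meta <- parse_contrast_names(colnames(mat))
  mem <- clusters$membership |> filter(.data$cluster > 0)
  out <- lapply(sort(unique(mem$cluster)), function(cl) {
    rows <- mem$target[mem$cluster == cl]
    means <- colMeans(mat[rows, , drop = FALSE])
    down <- vapply(unique(meta$group), function(g) {
      b <- meta$contrast[meta$group == g & meta$timepoint == "before"]
      a <- meta$contrast[meta$group == g & meta$timepoint == "after"]
      if (!length(b) || !length(a)) return(TRUE)
      means[a] < means[b]
    }, logical(1))
    row <- tibble(cluster = cl, n_targets = length(rows))
    for (cn in colnames(mat)) row[[paste0("mean_", cn)]] <- unname(means[cn])
    row$down_after <- all(down)
    row
  })
  bind_rows(out)
}

#' Fisher overlap test between two gene sets
#'
#' Generic two-set overlap test on a shared universe (utility used for
#' regulator-target style overlap questions).
#'
#' @param set1,set2 Character vectors.
#' @param universe Character vector containing both sets.
#' @return Tibble with overlap size, odds ratio and one-sided p
#'   (enrichment alternative).
#' @export
overlap_fisher <- function(set1, set2, universe) {
  universe <- unique(universe)
  set1 <- intersect(unique(set1), universe)
  set2 <- intersect(unique(set2), universe)
  a <- length(intersect(set1, set2))
  b <- length(setdiff(set1, set2))
  c <- length(setdiff(set2, set1))
  d <- length(universe) - a - b - c
  ft <- stats::fisher.test(matrix(c(a, b, c, d), 2), alternative = "greater")
  tibble(overlap = a, n1 = length(set1), n2 = length(set2),
         n_universe = length(universe),
         odds_ratio = unname(ft$estimate), p = ft$p.value)
}
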