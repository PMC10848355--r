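# Negative-binomial differential expression: median-of-ratios normalization,
# two documented NB tests (conditional exact-style and Wald-style), BH
# adjustment at adjusted p < 0.1, dual-method consensus, and before/after
# bookkeeping of DEG sets.

#' Median-of-ratios size factors
#'
#' The reference is the per-gene geometric mean over samples, computed on
#' genes with nonzero counts in every sample; each sample's factor is the
#' median of its count-to-reference ratios, taken on the log scale (so an
#' even number of usable genes averages the middle pair geometrically).
#'
#' @param counts A [count_matrix()] or plain counts matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  k <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (any(colSums(k) == 0)) {
    abort(paste("all-zero sample(s):",
                paste(colnames(k)[colSums(k) == 0], collapse = ", ")))
  }
  use <- rowSums(k == 0) == 0
  if (!any(use)) abort("no gene has nonzero counts in every sample")
  logk <- log(k[use, , drop = FALSE])
  ref <- rowMeans(logk)
  apply(logk, 2, function(x) exp(median(x - ref)))
}

# per-gene method-of-moments NB dispersion from normalized counts,
# pooling within-group variance across the groups of the contrast
mom_dispersion <- function(q, groups) {
  gs <- split(seq_along(groups), groups)
  ss <- 0; df <- 0
  mu <- rowMeans(q)
  for (idx in gs) {
    if (length(idx) < 2) next
    sub <- q[, idx, drop = FALSE]
    dev <- sub - rowMeans(sub)
    ss <- ss + rowSums(dev^2)
    df <- df + length(idx) - 1L
  }
  s2 <- ss / df
  disp <- (s2 - mu) / mu^2
  disp[!is.finite(disp)] <- NA_real_
  list(mean = mu, dispersion = disp)
}

# conditional "exact-style" test: under NB with common dispersion and equal
# effective library sizes, the group-A sum given the total is beta-binomial
# with shape parameters n_A/alpha and n_B/alpha; two-sided p sums outcome
# probabilities <= the observed one, with a mid-p correction for discreteness
nb_exact_p <- function(sA, sB, nA, nB, disp, cap = 1e4) {
  t <- sA + sB
  if (t == 0) return(1)
  if (disp < 1e-8) {
    # Poisson limit: conditional distribution is binomial
    pr <- nA / (nA + nB)
    px <- dbinom(0:t, t, pr)
    obs <- px[sA + 1]
    p <- sum(px[px <= obs * (1 + 1e-12)]) - 0.5 * obs
    return(min(1, max(p, 1e-300)))
  }
  rA <- nA / disp
  rB <- nB / disp
  if (t <= cap) {
    x <- 0:t
    lp <- lchoose(t, x) + lbeta(x + rA, t - x + rB) - lbeta(rA, rB)
    px <- exp(lp - max(lp))
    px <- px / sum(px)
    obs <- px[sA + 1]
    p <- sum(px[px <= obs * (1 + 1e-12)]) - 0.5 * obs
  } else {
    # normal tail approximation of the beta-binomial beyond the enumeration cap
    m <- t * rA / (rA + rB)
    v <- t * rA * rB * (t + rA + rB) / ((rA + rB)^2 * (rA + rB + 1))
    z_lo <- (sA + 0.5 - m) / sqrt(v)
    z_hi <- (sA - 0.5 - m) / sqrt(v)
    p <- 2 * min(pnorm(z_lo), pnorm(z_hi, lower.tail = FALSE))
  }
  min(1, max(p, 1e-300))
}

#' Negative-binomial differential expression test
#'
#' Two documented NB procedures sharing the decision contract of the classic
#' count-based DE tools (log2 fold change of normalized group means, raw and
#' BH-adjusted p, significance at adjusted p < `alpha`):
#'
#' * `nb_exact`: a common dispersion is estimated by method of moments on
#'   normalized counts; per gene, the group sums of normalized pseudo-counts
#'   are compared with a conditional exact-style test (the group-A sum given
#'   the total is beta-binomial under the common-dispersion NB model).
#'   Totals above 10^4 use a normal tail approximation.
#' * `nb_wald`: per-gene moment dispersions are shrunk 50/50 (on the log
#'   scale) toward a log-linear dispersion-mean trend; the Wald ratio of the
#'   log2 fold change to its delta-method standard error is referred to a t
#'   distribution with nA + nB - 2 degrees of freedom.
#'
#' Features with zero counts in all contrast samples are reported with
#' `log2fc = 0`, `p = 1` and excluded from the BH adjustment. Log2 fold
#' changes use a +0.5 pseudo-count on normalized means.
#'
#' @param counts A [count_matrix()].
#' @param contrast Character of length 2, `c(group, reference_group)`; the
#'   log2 fold change is group over reference.
#' @param method `"nb_exact"` or `"nb_wald"`.
#' @param alpha Adjusted-p significance threshold. Default 0.1.
#' @return A tibble of class `boom_de` with columns `feature`, `base_mean`,
#'   `log2fc`, `p`, `p_adj`, `direction` ("up"/"down"/"ns") and `method`.
#' @export
de_test <- function(counts, contrast, method = c("nb_exact", "nb_wald"),
                    alpha = 0.1) {
  stopifnot(inherits(counts, "count_matrix"))
  method <- match.arg(method)
  check_fraction(alpha, "alpha", open = TRUE)
  if (length(contrast) != 2L) abort("`contrast` must be c(group, reference)")
  unknown <- setdiff(contrast, unique(counts$groups))
  if (length(unknown)) abort(paste("unknown group(s):", paste(unknown, collapse = ", ")))
  idxA <- which(counts$groups == contrast[1])
  idxB <- which(counts$groups == contrast[2])
  if (length(idxA) < 2 || length(idxB) < 2) abort("each contrast group needs >= 2 samples")

  k <- counts$counts[, c(idxA, idxB), drop = FALSE]
  grp <- counts$groups[c(idxA, idxB)]
  sf <- size_factors(k)
  q <- sweep(k, 2, sf, "/")
  inA <- grp == contrast[1]
  muA <- rowMeans(q[, inA, drop = FALSE])
  muB <- rowMeans(q[, !inA, drop = FALSE])
  lfc <- log2((muA + 0.5) / (muB + 0.5))
  degenerate <- rowSums(k) == 0
  lfc[degenerate] <- 0

  mom <- mom_dispersion(q, grp)
  nA <- sum(inA); nB <- sum(!inA)

  if (method == "nb_exact") {
    d <- mom$dispersion
    common <- mean(d[!is.na(d) & d > 0], trim = 0.1)
    if (!is.finite(common) || common <= 0) common <- 1e-8
    sAv <- round(rowSums(q[, inA, drop = FALSE]))
    sBv <- round(rowSums(q[, !inA, drop = FALSE]))
    p <- vapply(seq_len(nrow(k)), function(i) {
      if (degenerate[i]) return(1)
      nb_exact_p(sAv[i], sBv[i], nA, nB, common)
    }, numeric(1))
  } else {
    d <- pmax(mom$dispersion, 1e-8)
    # dispersion-mean trend fitted log-linearly on binned moment estimates;
    # bin means keep the negative per-gene estimates, avoiding the upward
    # selection and Jensen biases of fitting on positive estimates directly
    trend <- local({
      br <- unique(quantile(mom$mean, probs = seq(0, 1, length.out = 21)))
      if (length(br) < 3) return(rep(max(median(d, na.rm = TRUE), 1e-8), nrow(k)))
      bin <- cut(mom$mean, br, include.lowest = TRUE)
      bm <- tapply(mom$mean, bin, mean)
      bd <- tapply(mom$dispersion, bin, mean, na.rm = TRUE)
      okb <- !is.na(bd) & bd > 0 & bm > 0
      if (sum(okb) < 3) return(rep(max(median(d, na.rm = TRUE), 1e-8), nrow(k)))
      fit <- stats::lm.fit(cbind(1, log(bm[okb])), log(bd[okb]))
      exp(pmin(cbind(1, log(pmax(mom$mean, 1e-8))) %*% fit$coefficients, 5))
    })
    d[is.na(d)] <- trend[is.na(d)]
    shrunk <- exp(0.5 * log(d) + 0.5 * log(trend))
    vA <- (muA + shrunk * muA^2) / nA
    vB <- (muB + shrunk * muB^2) / nB
    se <- sqrt(vA / (muA + 0.5)^2 + vB / (muB + 0.5)^2) / log(2)
    tstat <- ifelse(se > 0, lfc / se, 0)
    # effective df: per-gene residual df plus an equal contribution from the
    # dispersion trend the estimate is shrunk against (50/50 weighting)
    p <- 2 * pt(-abs(tstat), df = 2 * (nA + nB - 2))
    p[degenerate] <- 1
  }

  p_adj <- rep(1, length(p))
  p_adj[!degenerate] <- bh_adjust(p[!degenerate])
  res <- tibble(
    feature = rownames(k),
    base_mean = (muA + muB) / 2,
    log2fc = unname(lfc),
    p = unname(p),
    p_adj = unname(p_adj),
    direction = ifelse(p_adj < alpha, ifelse(lfc > 0, "up", "down"), "ns"),
    method = method
  )
  structure(res, class = c("boom_de", class(res)),
            contrast = contrast, alpha = alpha)
}

de_sets <- function(x, alpha = NULL) {
  if (inherits(x, "consensus_degs")) {
    return(list(up = x$up, down = x$down, universe = x$universe))
  }
  if (inherits(x, "boom_de")) {
    a <- alpha %||% attr(x, "alpha")
    sig <- x$p_adj < a
    return(list(up = x$feature[sig & x$log2fc > 0],
                down = x$feature[sig & x$log2fc < 0],
                universe = x$feature))
  }
  abort("expected a `boom_de` or `consensus_degs` object")
}

#' Dual-method consensus DEG set
#'
#' A feature is an "up" consensus DEG iff its adjusted p is below `alpha` in
#' both methods and its log2 fold change is positive in both; symmetrically
#' for "down". Features significant with discordant signs are excluded.
#'
#' @param res_a,res_b `boom_de` tables over the same feature universe.
#' @param alpha Adjusted-p threshold. Default 0.1.
#' @return A `consensus_degs` object with elements `up`, `down`, `alpha`,
#'   `universe`.
#' @export
consensus <- function(res_a, res_b, alpha = 0.1) {
  stopifnot(inherits(res_a, "boom_de"), inherits(res_b, "boom_de"))
  check_fraction(alpha, "alpha", open = TRUE)
  if (!setequal(res_a$feature, res_b$feature)) {
    abort("DE results cover different feature universes")
  }
  b <- res_b[match(res_a$feature, res_b$feature), ]
  sig <- res_a$p_adj < alpha & b$p_adj < alpha
  up <- sort(res_a$feature[sig & res_a$log2fc > 0 & b$log2fc > 0])
  down <- sort(res_a$feature[sig & res_a$log2fc < 0 & b$log2fc < 0])
  structure(list(up = up, down = down, alpha = alpha,
                 universe = sort(res_a$feature)),
            class = "consensus_degs")
}

#' @exportS3Method base::print
print.consensus_degs <- function(x, ...) {
  cat(sprintf("<consensus_degs> %d up, %d down (alpha = %g, universe %d)\n",
              length(x$up), length(x$down), x$alpha, length(x$universe)))
  invisible(x)
}

#' Before/after bookkeeping of differential feature sets
#'
#' Partitions DE calls across two states (before and after de-obstruction)
#' into `normalized` (DE before, no longer DE after: returned to control
#' level), `persistent` (DE in both states) and `de_novo` (DE only after).
#' The identities |before| = |normalized| + |persistent| and
#' |after| = |persistent| + |de_novo| hold by construction.
#'
#' @param before,after `consensus_degs` or `boom_de` objects over the same
#'   feature universe, or plain character vectors of significant features.
#' @return A `delta_bookkeeping` object: the three sets, per-direction counts
#'   where direction is available, and the set sizes.
#' @export
bookkeeping <- function(before, after) {
  to_sets <- function(x) {
    if (is.character(x)) list(up = NULL, down = NULL, universe = NULL, all = sort(x))
    else { s <- de_sets(x); c(s, list(all = sort(c(s$up, s$down)))) }
  }
  b <- to_sets(before)
  a <- to_sets(after)
  if (!is.null(b$universe) && !is.null(a$universe) && !setequal(b$universe, a$universe)) {
    abort("before/after results cover different feature universes")
  }
  normalized <- setdiff(b$all, a$all)
  persistent <- intersect(b$all, a$all)
  de_novo <- setdiff(a$all, b$all)
  dir_counts <- NULL
  if (!is.null(b$up)) {
    dir_counts <- tibble(
      category = rep(c("normalized", "persistent", "de_novo"), each = 2),
      direction = rep(c("up", "down"), 3),
      n = c(sum(normalized %in% b$up), sum(normalized %in% b$down),
            sum(persistent %in% b$up), sum(persistent %in% b$down),
            sum(de_novo %in% a$up), sum(de_novo %in% a$down))
    )
  }
  structure(list(normalized = sort(normalized), persistent = sort(persistent),
                 de_novo = sort(de_novo),
                 n_before = length(b$all), n_after = length(a$all),
                 direction_counts = dir_counts),
            class = "delta_bookkeeping")
}

#' @exportS3Method base::print
print.delta_bookkeeping <- function(x, ...) {
  cat(sprintf(paste0("<delta_bookkeeping> before: %d, after: %d | ",
                     "normalized: %d, persistent: %d, de-novo: %d\n"),
              x$n_before, x$n_after, length(x$normalized),
              length(x$persistent), length(x$de_novo)))
  invisible(x)
}

#' Summarize bookkeeping counts
#' @param x A `delta_bookkeeping` object.
#' @param ... Unused.
#' @return One-row tibble with the category counts and the implied totals.
#' @export
glance.delta_bookkeeping <- function(x, ...) {
  tibble(
    n_before = x$n_before, n_after = x$n_after,
    normalized = length(x$normalized), persistent = length(x$persistent),
    de_novo = length(x$de_novo),
    before_identity = length(x$normalized) + length(x$persistent),
    after_identity = length(x$persistent) + length(x$de_novo)
  )
}

#' Count significant features by direction
#'
#' Summarizes a DE/DEP table (or several, stacked with a `contrast` column)
#' into up/down/total counts of significant calls, the form in which the
#' study reports its headline numbers.
#'
#' @param tbl Data frame with a `direction` column ("up"/"down"/"ns"), or a
#'   logical `significant` column together with `log2fc`.
#' @param by Optional grouping column name (e.g. "contrast").
#' @return Tibble with columns `up`, `down`, `total` (plus the grouping
#'   column when `by` is given).
#' @export
count_de_directions <- function(tbl, by = NULL) {
  stopifnot(is.data.frame(tbl))
  t2 <- as_tibble(tbl)
  if (!"direction" %in% names(t2)) {
    if (!all(c("significant", "log2fc") %in% names(t2))) {
      abort("need a `direction` column or `significant` + `log2fc`")
    }
    t2 <- t2 |> mutate(direction = ifelse(!.data$significant, "ns",
                                          ifelse(.data$log2fc > 0, "up", "down")))
  }
  if (!is.null(by)) t2 <- t2 |> group_by(dplyr::across(dplyr::all_of(by)))
  t2 |>
    summarise(up = sum(.data$direction == "up"),
              down = sum(.data$direction == "down"),
              total = .data$up + .data$down, .groups = "drop")
}
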