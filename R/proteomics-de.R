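# Label-free proteomics differential expression: detection filter, two-tier
# imputation of left-censored missing values, empirical-Bayes moderated
# t-test, BH adjustment, significance curves, and a repeated-imputation
# consistency flag.

#' Detection filter for LFQ matrices
#'
#' Retains proteins with at least `min_detect` observed (non-missing) values
#' in at least one group of replicates.
#'
#' @param lfq An [lfq_matrix()].
#' @param min_detect Minimum detections in some group. Default 2.
#' @return A filtered `lfq_matrix`.
#' @export
detection_filter <- function(lfq, min_detect = 2) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  min_detect <- check_count(min_detect, "min_detect", min = 1L)
  obs <- !lfq$mask
  keep <- rep(FALSE, nrow(obs))
  for (g in unique(lfq$groups)) {
    keep <- keep | rowSums(obs[, lfq$groups == g, drop = FALSE]) >= min_detect
  }
  lfq_matrix(lfq$intensity[keep, , drop = FALSE], lfq$groups)
}

#' Gaussian down-shift draws for left-censored imputation
#'
#' Random draws from Normal(mu - shift * sigma, (width * sigma)^2): the
#' distribution used for proteins essentially undetected in a replicate
#' group, reflecting that their abundance sits below the detection limit of
#' the sample's intensity distribution.
#'
#' @param n Number of draws.
#' @param mu,sigma Mean and SD of the sample column's observed intensities.
#' @param shift Down-shift in column SDs. Default 2.5.
#' @param width Width of the imputation distribution in column SDs. Default 0.3.
#' @return Numeric vector of n draws.
#' @export
downshift_draws <- function(n, mu, sigma, shift = 2.5, width = 0.3) {
  rnorm(n, mu - shift * sigma, width * sigma)
}

#' Two-tier imputation of missing LFQ values
#'
#' Tier 1: for any (protein, group) block with at most one observed value,
#' missing entries are drawn from a Gaussian of width `width` x the sample
#' column SD, centred at the column mean minus `shift` x the column SD
#' (column statistics over observed values only). Tier 2: remaining missing
#' entries (blocks with >= 2 observed replicates) are set to the normal
#' maximum-likelihood mean of the block's observed values. Observed entries
#' are never modified.
#'
#' @param lfq An [lfq_matrix()]; every sample column needs >= 3 observed
#'   values to define its statistics.
#' @param seed Integer seed; draws are reproducible.
#' @param shift,width Tier-1 distribution parameters in column SDs.
#'   Defaults 2.5 and 0.3.
#' @return List with `completed` (numeric matrix, no missing values) and
#'   `imputed` (logical matrix marking imputed cells, identical to the
#'   input's missingness mask).
#' @export
impute_lfq <- function(lfq, seed = 1L, shift = 2.5, width = 0.3) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  x <- lfq$intensity
  obs <- !lfq$mask
  nobs_col <- colSums(obs)
  if (any(nobs_col < 3)) {
    abort(paste("sample column(s) with < 3 observed values:",
                paste(colnames(x)[nobs_col < 3], collapse = ", ")))
  }
  col_mu <- vapply(seq_len(ncol(x)), function(j) mean(x[obs[, j], j]), numeric(1))
  col_sd <- vapply(seq_len(ncol(x)), function(j) sd(x[obs[, j], j]), numeric(1))
  completed <- x
  with_seed(seed, {
    for (g in unique(lfq$groups)) {
      jj <- which(lfq$groups == g)
      block_obs <- obs[, jj, drop = FALSE]
      n_in_block <- rowSums(block_obs)
      # tier 1: essentially undetected in this replicate group
      for (j in jj) {
        rows <- which(!obs[, j] & n_in_block <= 1)
        if (length(rows)) {
          completed[rows, j] <- downshift_draws(length(rows), col_mu[j], col_sd[j],
                                                shift, width)
        }
      }
      # tier 2: MLE mean of the observed replicates in the block
      rows <- which(n_in_block >= 2 & n_in_block < length(jj))
      for (i in rows) {
        m <- mean(x[i, jj][block_obs[i, ]])
        miss_j <- jj[!block_obs[i, ]]
        completed[i, miss_j] <- m
      }
    }
  })
  list(completed = completed, imputed = lfq$mask)
}

# Newton solve of trigamma(x) = y, vectorized scalar use
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    delta <- (trigamma(x) - y) / psigamma(x, deriv = 2)
    x <- x - delta
    if (x <= 0) x <- 1e-8
    if (abs(delta) < 1e-10 * x) break
  }
  x
}

#' Empirical-Bayes moderated t-test
#'
#' Per-protein two-group comparison with variance moderation: the pooled
#' within-group variance s_g^2 (d_g = nA + nB - 2 df) is shrunk toward a
#' prior s0^2 with d0 df, giving the posterior
#' s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g). The prior is estimated by
#' moment-matching of log s_g^2 against its scaled log-chi-square model; the
#' moderated statistic t~ = lfc / (s~_g sqrt(1/nA + 1/nB)) is referred to a
#' t distribution on d0 + d_g df. If the log-variances show no excess spread,
#' d0 is infinite and every protein uses the common variance; with d0 = 0 the
#' test reduces to the ordinary per-protein t-test.
#'
#' @param completed Numeric proteins x samples matrix (no missing values),
#'   log2 scale.
#' @param groups Named character vector mapping samples to groups.
#' @param contrast `c(group, reference_group)`.
#' @param d0,s0_sq Optional fixed prior df and variance; estimated from the
#'   data when NULL.
#' @return Tibble with `protein`, `log2fc`, `t`, `df`, `p`, plus the prior
#'   (`d0`, `s0_sq`) as attributes.
#' @export
moderated_t <- function(completed, groups, contrast, d0 = NULL, s0_sq = NULL) {
  stopifnot(is.matrix(completed))
  groups <- groups[colnames(completed)]
  idxA <- which(groups == contrast[1])
  idxB <- which(groups == contrast[2])
  if (length(idxA) < 2 || length(idxB) < 2) abort("each group needs >= 2 samples")
  nA <- length(idxA); nB <- length(idxB)
  A <- completed[, idxA, drop = FALSE]
  B <- completed[, idxB, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums((A - mA)^2); ssB <- rowSums((B - mB)^2)
  dg <- nA + nB - 2
  s2 <- (ssA + ssB) / dg
  if (all(s2 == 0)) abort("zero residual variance for every protein")

  if (is.null(d0) || is.null(s0_sq)) {
    pos <- s2 > 0
    z <- log(s2[pos])
    e <- z - digamma(dg / 2) + log(dg / 2)
    evar <- var(e)
    target <- evar - trigamma(dg / 2)
    if (!is.finite(target) || target <= 0) {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    } else {
      d0 <- 2 * trigamma_inverse(target)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + dg * s2) / (d0 + dg)
  lfc <- mA - mB
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  tstat <- ifelse(se > 0, lfc / se, 0)
  df_total <- d0 + dg
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[se == 0] <- 1
  out <- tibble(protein = rownames(completed), log2fc = unname(lfc),
                t = unname(tstat), df = df_total, p = unname(p))
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Significance curve decision
#'
#' A protein is significant iff |log2fc| exceeds `fc_min` and
#' -log10(p_adj) >= -log10(alpha) + curvature / (|log2fc| - fc_min).
#' The p-threshold tightens near the fold-change cutoff and relaxes to
#' `alpha` at asymptotically high fold changes; with curvature 0 the rule is
#' the rectangular |log2fc| > fc_min and p_adj <= alpha.
#'
#' @param log2fc,p_adj Numeric vectors (p_adj in (0, 1]).
#' @param fc_min Fold-change asymptote (log2). Default 1.
#' @param alpha Adjusted-p asymptote. Default 0.05.
#' @param curvature Nonnegative curve constant. Default 0.5.
#' @return Logical vector.
#' @export
significance_curve <- function(log2fc, p_adj, fc_min = 1, alpha = 0.05,
                               curvature = 0.5) {
  if (curvature < 0) abort("`curvature` must be >= 0")
  afc <- abs(log2fc)
  beyond <- afc > fc_min
  thr <- -log10(alpha) + ifelse(beyond, curvature / (afc - fc_min), Inf)
  beyond & (-log10(p_adj) >= thr)
}

#' Repeated-imputation differential expression with consistency flagging
#'
#' Runs the full per-cycle chain impute -> moderated t -> BH -> significance
#' curve for `n_cycles` imputation cycles (seeds `base_seed + i`). Reported
#' statistics come from the first cycle; the `consistent` flag marks proteins
#' significant in every cycle, separating calls that are robust to the random
#' tier-1 draws from those that depend on them.
#'
#' @param lfq An [lfq_matrix()] (filter applied internally).
#' @param contrast `c(group, reference_group)`.
#' @param n_cycles Number of imputation cycles. Default 20.
#' @param base_seed Seed of the first cycle. Default 1.
#' @param min_detect Detection filter threshold. Default 2.
#' @param fc_min,alpha,curvature Significance-curve parameters.
#' @param shift,width Tier-1 imputation parameters.
#' @return A tibble of class `boom_dep`: `protein`, `log2fc`, `p`, `p_adj`,
#'   `significant`, `consistent`, `n_detected_A`, `n_detected_B`.
#' @export
repeated_imputation_de <- function(lfq, contrast, n_cycles = 20, base_seed = 1L,
                                   min_detect = 2, fc_min = 1, alpha = 0.05,
                                   curvature = 0.5, shift = 2.5, width = 0.3) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  n_cycles <- check_count(n_cycles, "n_cycles", min = 1L)
  flt <- detection_filter(lfq, min_detect)
  keep_samples <- flt$groups %in% contrast
  sub <- lfq_matrix(flt$intensity[, keep_samples, drop = FALSE],
                    flt$groups[keep_samples])
  obs <- !sub$mask
  nA_det <- rowSums(obs[, sub$groups == contrast[1], drop = FALSE])
  nB_det <- rowSums(obs[, sub$groups == contrast[2], drop = FALSE])

  first <- NULL
  consistent <- rep(TRUE, nrow(sub$intensity))
  for (i in seq_len(n_cycles) - 1L) {
    imp <- impute_lfq(sub, seed = base_seed + i, shift = shift, width = width)
    mt <- moderated_t(imp$completed, sub$groups, contrast)
    p_adj <- bh_adjust(mt$p)
    sig <- significance_curve(mt$log2fc, p_adj, fc_min, alpha, curvature)
    consistent <- consistent & sig
    if (i == 0L) first <- mt |> mutate(p_adj = p_adj, significant = sig)
  }
  out <- first |>
    mutate(consistent = consistent,
           n_detected_A = unname(nA_det), n_detected_B = unname(nB_det)) |>
    select("protein", "log2fc", "t", "df", "p", "p_adj",
           "significant", "consistent", "n_detected_A", "n_detected_B")
  structure(out, class = c("boom_dep", class(out)),
            contrast = contrast, n_cycles = n_cycles,
            curve = c(fc_min = fc_min, alpha = alpha, curvature = curvature))
}

#' One-line summary of a DEP table
#' @param x A `boom_dep` table.
#' @param ... Unused.
#' @return One-row tibble: contrast, counts of significant/consistent calls
#'   by direction.
#' @export
glance.boom_dep <- function(x, ...) {
  tibble(
    contrast = paste(attr(x, "contrast"), collapse = " vs "),
    n_proteins = nrow(x),
    up = sum(x$significant & x$log2fc > 0),
    down = sum(x$significant & x$log2fc < 0),
    consistent = sum(x$consistent),
    n_cycles = attr(x, "n_cycles")
  )
}
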