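# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use explicit loops / enumeration and
# never call the functions they check.

# BH adjusted p by its definition: padj_i = min over thresholds t = p_j with
# p_j >= p_i of n * t / #{k : p_k <= t}, capped at 1
bh_brute <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(i) {
    cand <- p[p >= p[i]]
    min(1, min(vapply(cand, function(t) n * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# upper-tail hypergeometric by direct enumeration of the pmf
hyper_enum <- function(k, K, n, N) {
  imax <- min(K, n)
  sum(vapply(k:imax, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

# median-of-ratios size factors with explicit loops; for an even number of
# usable genes the middle pair is averaged geometrically (the convention of
# taking the median on the log-ratio scale)
size_factors_loop <- function(k) {
  use <- which(apply(k, 1, function(r) all(r > 0)))
  ref <- numeric(length(use))
  for (ii in seq_along(use)) ref[ii] <- exp(mean(log(k[use[ii], ])))
  out <- numeric(ncol(k))
  for (j in seq_len(ncol(k))) {
    ratios <- numeric(length(use))
    for (ii in seq_along(use)) ratios[ii] <- k[use[ii], j] / ref[ii]
    ratios <- sort(ratios)
    n <- length(ratios)
    out[j] <- if (n %% 2 == 1) ratios[(n + 1) / 2]
              else sqrt(ratios[n / 2] * ratios[n / 2 + 1])
  }
  setNames(out, colnames(k))
}

# ancestor sets by iterated edge expansion (no recursion sharing with the
# package's topological computation)
ancestors_brute <- function(parents, term) {
  anc <- term
  repeat {
    nxt <- unique(c(anc, unlist(parents[anc])))
    if (length(nxt) == length(anc)) return(nxt)
    anc <- nxt
  }
}

resnik_brute <- function(dag, t1, t2) {
  common <- intersect(ancestors_brute(dag$parents, t1),
                      ancestors_brute(dag$parents, t2))
  ics <- dag$ic[common]
  ics <- ics[!is.na(ics)]
  raw <- if (length(ics)) max(ics) else 0
  mx <- max(dag$ic, na.rm = TRUE)
  if (mx == 0) 0 else raw / mx
}

# loading-range selection by direct per-feature enumeration
select_loading_enum <- function(loadings, n_pcs, frac) {
  sel <- character(0)
  for (k in seq_len(n_pcs)) {
    l <- loadings[, k]
    lo <- min(l); hi <- max(l)
    if (hi == lo) next
    for (f in rownames(loadings)) {
      if (l[f] >= hi - frac * (hi - lo) || l[f] <= lo + frac * (hi - lo)) {
        sel <- c(sel, f)
      }
    }
  }
  sort(unique(sel))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# fabricate a boom_de table with chosen significance calls and signs
make_de <- function(features, sig_features, lfc, method = "nb_wald",
                    alpha = 0.1) {
  p_adj <- ifelse(features %in% sig_features, alpha / 2, 0.9)
  res <- tibble::tibble(
    feature = features, base_mean = 10, log2fc = unname(lfc[features]),
    p = p_adj / 2, p_adj = p_adj,
    direction = ifelse(p_adj < alpha, ifelse(lfc[features] > 0, "up", "down"), "ns"),
    method = method
  )
  structure(res, class = c("boom_de", class(res)),
            contrast = c("x", "y"), alpha = alpha)
}

# tiny hand-built DAG: root with two branches and a shared grandchild
toy_dag <- function() {
  terms <- c("root", "a", "b", "ab", "leaf")
  parents <- list(root = character(0), a = "root", b = "root",
                  ab = c("a", "b"), leaf = "a")
  direct <- list(root = "g0", a = "g1", b = "g2", ab = c("g3", "g4"),
                 leaf = c("g5", "g6", "g7"))
  ontology_dag(terms, parents, direct_annotations = direct)
}
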