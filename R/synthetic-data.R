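# Synthetic-data generators emulating the study design: 6 controls and 3
# patients per pressure group sampled before and after de-obstruction, with
# planted effects recorded as ground truth for parameter-recovery tests.

# run code with a private RNG stream, leaving the caller's stream untouched
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

default_group_sizes <- function() {
  c(control = 6L, HP_before = 3L, HP_after = 3L, MP_before = 3L, MP_after = 3L)
}

check_group_sizes <- function(group_sizes) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    abort("`group_sizes` must be a named vector of group sizes")
  }
  if (any(group_sizes != round(group_sizes)) || any(group_sizes < 1)) {
    abort("`group_sizes` must be positive integers")
  }
  setNames(as.integer(group_sizes), names(group_sizes))
}

reference_group <- function(group_sizes) {
  if ("control" %in% names(group_sizes)) "control" else names(group_sizes)[1]
}

# each planted feature is differential in a random nonempty subset of the
# non-reference groups, so before-only / persistent / de-novo patterns all
# occur when the full 5-group design is generated
plant_effects <- function(feature_ids, n_de, lfc_scale, condition_groups) {
  de_features <- sample(feature_ids, n_de)
  sign <- rep_len(c(1, -1), n_de)[sample.int(max(n_de, 1), n_de)]
  effect <- setNames(numeric(length(feature_ids)), feature_ids)
  effect[de_features] <- sign * lfc_scale
  affected <- matrix(FALSE, length(feature_ids), length(condition_groups),
                     dimnames = list(feature_ids, condition_groups))
  for (f in de_features) {
    k <- sample.int(length(condition_groups), 1)
    affected[f, sample(condition_groups, k)] <- TRUE
  }
  list(effect = effect, affected = affected, de_features = de_features)
}

truth_per_contrast <- function(affected) {
  lapply(setNames(colnames(affected), colnames(affected)),
         function(g) rownames(affected)[affected[, g]])
}

#' Generate a synthetic RNA-seq count matrix with planted group effects
#'
#' Counts are drawn gene-wise from a negative-binomial model
#' `NB(mu * s_j * 2^lfc, 1/dispersion)` with log-normal baseline means,
#' gamma-distributed per-gene dispersions around `dispersion_mean`, and
#' per-sample library-size factors drawn log-normal(0, 0.2). A fraction
#' `frac_de` of genes carries a planted log2 fold change of magnitude
#' `lfc_scale` (sign split 50/50) in a random nonempty subset of the
#' non-reference groups, the reference being `control` when present.
#'
#' @param n_genes Number of genes (>= 10).
#' @param group_sizes Named integer vector of samples per group; defaults to
#'   the study design (6 controls, 3 per patient group and timepoint).
#' @param frac_de Fraction of genes with a planted effect. Default 0.05.
#' @param lfc_scale Magnitude of planted log2 fold changes. Default 2.
#' @param dispersion_mean Mean NB dispersion across genes. Default 0.1.
#' @param dispersion_shape Shape of the gamma distribution of per-gene
#'   dispersions (mean fixed at `dispersion_mean`); `Inf` gives a common
#'   dispersion for every gene. Default 4.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`,
#'   a `synthetic_truth` list carrying `de_features` (per contrast),
#'   `effect_log2fc`, `dispersion`, `size_factors` and `group_sizes`.
#' @export
#' @examples
#' sim <- gen_counts(200, c(A = 3, B = 3), frac_de = 0.1, seed = 1)
#' sim$counts
gen_counts <- function(n_genes,
                       group_sizes = default_group_sizes(),
                       frac_de = 0.05,
                       lfc_scale = 2,
                       dispersion_mean = 0.1,
                       dispersion_shape = 4,
                       seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 10L)
  group_sizes <- check_group_sizes(group_sizes)
  if (any(group_sizes < 2L)) abort("all `group_sizes` must be >= 2 for DE")
  check_fraction(frac_de, "frac_de")
  check_number(lfc_scale, "lfc_scale", min = 0)
  check_number(dispersion_mean, "dispersion_mean", min = 1e-6)

  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- unlist(lapply(names(group_sizes), function(g) {
      paste0(g, "_s", seq_len(group_sizes[[g]]))
    }))
    groups <- setNames(rep(names(group_sizes), group_sizes), samples)

    mu <- rlnorm(n_genes, meanlog = log(100), sdlog = 1)
    dispersion <- if (is.infinite(dispersion_shape)) {
      setNames(rep(dispersion_mean, n_genes), genes)
    } else {
      setNames(dispersion_mean * stats::rgamma(n_genes, shape = dispersion_shape,
                                               rate = dispersion_shape), genes)
    }
    sf <- setNames(rlnorm(length(samples), 0, 0.2), samples)

    ref <- reference_group(group_sizes)
    cond <- setdiff(names(group_sizes), ref)
    pl <- plant_effects(genes, floor(frac_de * n_genes), lfc_scale, cond)

    counts <- matrix(0L, n_genes, length(samples), dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      g <- groups[[j]]
      lfc <- if (g == ref) 0 else pl$effect * pl$affected[, g]
      m <- mu * sf[[j]] * 2^lfc
      counts[, j] <- rnbinom(n_genes, mu = m, size = 1 / dispersion)
    }
    storage.mode(counts) <- "integer"

    truth <- structure(list(
      de_features = truth_per_contrast(pl$affected),
      effect_log2fc = pl$effect,
      dispersion = dispersion,
      baseline_mean = setNames(mu, genes),
      size_factors = sf,
      group_sizes = group_sizes,
      reference = ref
    ), class = "synthetic_truth")
    list(counts = count_matrix(counts, groups), truth = truth)
  })
}

#' Generate synthetic label-free proteomics intensities with MNAR missingness
#'
#' Log2 intensities are normal around per-protein baselines (~N(23, 2) across
#' proteins, replicate SD 0.5) with planted shifts of magnitude `delta` for a
#' fraction `frac_de` of proteins. Each sample column is then left-censored:
#' values below that sample's `censor_quantile` intensity quantile are set
#' missing with probability 0.95, plus a 2% missing-completely-at-random
#' background so that groups with >= 2 observed values (the MLE-imputation
#' branch) are exercised.
#'
#' @param n_proteins Number of proteins.
#' @param group_sizes Named integer vector of samples per group.
#' @param frac_de Fraction of proteins with a planted effect. Default 0.05.
#' @param censor_quantile Per-sample censoring quantile in (0, 1). Default 0.3.
#' @param delta Magnitude of planted log2 shifts. Default 2.
#' @param seed Integer seed.
#' @return List with `lfq` (an [lfq_matrix()]) and `truth` (per-contrast
#'   planted proteins, effects, per-sample censoring thresholds).
#' @export
gen_lfq <- function(n_proteins,
                    group_sizes = default_group_sizes(),
                    frac_de = 0.05,
                    censor_quantile = 0.3,
                    delta = 2,
                    seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins", min = 2L)
  group_sizes <- check_group_sizes(group_sizes)
  check_fraction(censor_quantile, "censor_quantile", open = TRUE)
  check_fraction(frac_de, "frac_de")
  check_number(delta, "delta", min = 0)

  with_seed(seed, {
    prots <- sprintf("p%04d", seq_len(n_proteins))
    samples <- unlist(lapply(names(group_sizes), function(g) {
      paste0(g, "_s", seq_len(group_sizes[[g]]))
    }))
    groups <- setNames(rep(names(group_sizes), group_sizes), samples)

    base <- rnorm(n_proteins, 23, 2)
    ref <- reference_group(group_sizes)
    cond <- setdiff(names(group_sizes), ref)
    pl <- plant_effects(prots, floor(frac_de * n_proteins), delta, cond)

    intensity <- matrix(NA_real_, n_proteins, length(samples),
                        dimnames = list(prots, samples))
    for (j in seq_along(samples)) {
      g <- groups[[j]]
      lfc <- if (g == ref) 0 else pl$effect * pl$affected[, g]
      intensity[, j] <- rnorm(n_proteins, base + lfc, 0.5)
    }

    thresholds <- apply(intensity, 2, quantile, probs = censor_quantile)
    below <- sweep(intensity, 2, thresholds, "<")
    miss <- (below & matrix(runif(length(intensity)) < 0.95, n_proteins)) |
      matrix(runif(length(intensity)) < 0.02, n_proteins)
    intensity[miss] <- NA_real_

    truth <- structure(list(
      de_features = truth_per_contrast(pl$affected),
      effect_log2fc = pl$effect,
      censor_thresholds = thresholds,
      group_sizes = group_sizes,
      reference = ref
    ), class = "synthetic_truth")
    list(lfq = lfq_matrix(intensity, groups), truth = truth)
  })
}

#' Generate a toy rooted ontology DAG with true-path-closed annotations
#'
#' Terms form a rooted DAG of is_a edges (a second parent is added with
#' probability 0.2 where available). Every gene is directly annotated to one
#' random term and annotations are propagated to all ancestors, so the
#' true-path rule holds and the root annotation equals the gene universe.
#'
#' @param n_terms Number of terms (>= 3); the first is the root.
#' @param max_children Maximum direct children per term. Default 4.
#' @param n_genes Size of the annotated gene universe.
#' @param seed Integer seed.
#' @param gene_ids Optional character vector used as the gene universe
#'   (overrides `n_genes`).
#' @return An `ontology_dag` object; see [ontology_dag()].
#' @export
gen_ontology <- function(n_terms, max_children = 4, n_genes = 100, seed = 1L,
                         gene_ids = NULL) {
  n_terms <- check_count(n_terms, "n_terms", min = 3L)
  max_children <- check_count(max_children, "max_children", min = 1L)
  with_seed(seed, {
    terms <- sprintf("T:%04d", seq_len(n_terms))
    genes <- gene_ids %||% sprintf("g%04d", seq_len(n_genes))
    parents <- setNames(vector("list", n_terms), terms)
    n_children <- setNames(integer(n_terms), terms)
    for (i in seq(2L, n_terms)) {
      pool <- terms[seq_len(i - 1L)][n_children[seq_len(i - 1L)] < max_children]
      if (!length(pool)) pool <- terms[seq_len(i - 1L)]
      p1 <- if (length(pool) == 1L) pool else sample(pool, 1)
      ps <- p1
      if (i > 2L && runif(1) < 0.2) {
        extra <- setdiff(terms[seq_len(i - 1L)], p1)
        if (length(extra)) ps <- c(p1, if (length(extra) == 1L) extra else sample(extra, 1))
      }
      parents[[terms[i]]] <- ps
      n_children[ps] <- n_children[ps] + 1L
    }
    direct <- setNames(vector("list", n_terms), terms)
    hit <- sample(terms, length(genes), replace = TRUE)
    for (i in seq_along(genes)) {
      direct[[hit[i]]] <- c(direct[[hit[i]]], genes[i])
    }
    ontology_dag(terms, parents, direct_annotations = direct)
  })
}

#' Generate a synthetic TF -> target regulon database
#'
#' Each transcription factor receives exactly `targets_per_tf` targets; a
#' fraction `overlap` of each regulon is a shared core common to all TFs
#' (planted co-regulation), the rest is TF-specific. Each edge is tagged
#' with a source label emulating the merged public databases.
#'
#' @param n_tfs Number of transcription factors (>= 1).
#' @param targets_per_tf Regulon size.
#' @param overlap Fraction of each regulon shared across all TFs. Default 0.
#' @param seed Integer seed.
#' @param gene_pool Optional character vector to draw TF and target ids from;
#'   when given, the TFs themselves are genes of the pool (as for real TFs,
#'   which are measured in the expression data).
#' @return Tibble with columns `tf`, `target`, `source` (class `tf_regulon_db`).
#' @export
gen_tf_db <- function(n_tfs, targets_per_tf, overlap = 0, seed = 1L,
                      gene_pool = NULL) {
  n_tfs <- check_count(n_tfs, "n_tfs", min = 1L)
  targets_per_tf <- check_count(targets_per_tf, "targets_per_tf", min = 1L)
  check_fraction(overlap, "overlap")
  sources <- c("TRED", "ITFP", "TRRUST", "Marbach")
  with_seed(seed, {
    n_shared <- round(overlap * targets_per_tf)
    n_own <- targets_per_tf - n_shared
    need <- n_shared + n_own * n_tfs + n_tfs
    pool <- gene_pool %||% sprintf("g%04d", seq_len(need))
    if (length(pool) < need) abort("`gene_pool` too small for requested regulons")
    picks <- sample(pool, need)
    tf_ids <- picks[seq_len(n_tfs)]
    picks <- picks[-seq_len(n_tfs)]
    shared <- if (n_shared) picks[seq_len(n_shared)] else character()
    rest <- if (n_shared) picks[-seq_len(n_shared)] else picks
    db <- bind_rows(lapply(seq_len(n_tfs), function(i) {
      own <- rest[seq_len(n_own) + (i - 1L) * n_own]
      tibble(tf = tf_ids[i],
             target = c(shared, own),
             source = sample(sources, targets_per_tf, replace = TRUE))
    }))
    structure(db, class = c("tf_regulon_db", class(db)))
  })
}

# printed per-group PdetQmax (cmH2O) and age (years) summary statistics
urodyn_group_params <- function() {
  tibble(
    group = c("HP", "HP", "MP", "MP"),
    timepoint = c("before", "after", "before", "after"),
    pdet_mean = c(107, 40.6, 55, 22),
    pdet_sd = c(20.4, 5.5, 21.7, 2.64),
    age_mean = c(71, 71, 68, 68),
    age_sd = c(2.6, 2.6, 9, 9),
    qmax_mean = c(6, 15, 8, 14),
    qmax_sd = c(2, 4, 3, 4),
    rv_mean = c(150, 25, 120, 25),
    rv_sd = c(60, 12, 60, 12)
  )
}

#' Generate synthetic urodynamic records
#'
#' PdetQmax is drawn per pressure group and timepoint from normal
#' distributions with the study's group means and SDs (HP before 107 +/- 20.4,
#' HP after 40.6 +/- 5.5, MP before 55 +/- 21.7, MP after 22 +/- 2.64 cmH2O),
#' truncated at 0. Qmax and residual volume come from plausible configured
#' ranges: obstructed flow ~6-8 ml/s improving after surgery, residual volume
#' falling below ~50 ml after de-obstruction. Age is drawn once per patient.
#'
#' @param n_per_group Patients per pressure group (each has a before and an
#'   after record).
#' @param seed Integer seed.
#' @return Tibble of records with columns `patient_id`, `group`, `timepoint`,
#'   `pdet_qmax`, `qmax`, `rv`, `age`.
#' @export
gen_urodynamics <- function(n_per_group = 3, seed = 1L) {
  n_per_group <- check_count(n_per_group, "n_per_group", min = 1L)
  pars <- urodyn_group_params()
  with_seed(seed, {
    out <- lapply(seq_len(nrow(pars)), function(i) {
      p <- pars[i, ]
      tibble(
        patient_id = sprintf("%s%03d", p$group, seq_len(n_per_group)),
        group = p$group,
        timepoint = p$timepoint,
        pdet_qmax = pmax(0, rnorm(n_per_group, p$pdet_mean, p$pdet_sd)),
        qmax = pmax(0, rnorm(n_per_group, p$qmax_mean, p$qmax_sd)),
        rv = pmax(0, rnorm(n_per_group, p$rv_mean, p$rv_sd))
      )
    })
    recs <- bind_rows(out)
    ages <- recs |>
      filter(.data$timepoint == "before") |>
      left_join(pars |> filter(.data$timepoint == "before") |>
                  select("group", "age_mean", "age_sd"), by = "group") |>
      mutate(age = pmax(40, rnorm(n(), .data$age_mean, .data$age_sd))) |>
      select("patient_id", "age")
    recs |> left_join(ages, by = "patient_id")
  })
}
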