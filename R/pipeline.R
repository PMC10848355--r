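# End-to-end orchestration of the study workflow on a file bundle:
# urodynamic grouping -> dual-method RNA DE -> classifier selection ->
# GO enrichment with semantic clustering -> proteomics DE -> TF regulons.

#' Pipeline configuration
#'
#' Collects input paths and the analysis parameters, with defaults equal to
#' the study's printed values: DE alpha 0.1 (BH-adjusted), ORA raw p 0.1,
#' top 6 PCs with a 20% loading-range fraction, imputation down-shift 2.5 x
#' SD and width 0.3 x SD over 20 cycles, significance curve |log2FC| > 1
#' with p 0.05 asymptote, semantic-similarity threshold 0.7 and 5 target
#' clusters.
#'
#' @param counts,samples,lfq,obo,gmt,tf,urodyn Input file paths (counts TSV,
#'   sample metadata TSV, LFQ TSV, OBO subset, GMT annotations, TF TSV,
#'   urodynamics CSV).
#' @param alpha_rna,alpha_ora,n_pcs,loading_frac Analysis parameters.
#' @param impute_shift,impute_width,cycles Imputation parameters.
#' @param fc_min,curve_alpha,curvature Significance-curve parameters.
#' @param sim_threshold,cluster_k Semantic pruning threshold and TF target
#'   cluster count.
#' @param seed Master seed; every stage derives its randomness from it.
#' @return A `run_config` list.
#' @export
run_config <- function(counts, samples, lfq, obo, gmt, tf, urodyn,
                       alpha_rna = 0.1, alpha_ora = 0.1, n_pcs = 6,
                       loading_frac = 0.2, impute_shift = 2.5,
                       impute_width = 0.3, cycles = 20, fc_min = 1,
                       curve_alpha = 0.05, curvature = 0.5,
                       sim_threshold = 0.7, cluster_k = 5, seed = 1L) {
  check_fraction(alpha_rna, "alpha_rna", open = TRUE)
  check_fraction(alpha_ora, "alpha_ora", open = TRUE)
  check_fraction(loading_frac, "loading_frac", lo = 0, hi = 0.5, open = TRUE)
  structure(list(paths = list(counts = counts, samples = samples, lfq = lfq,
                              obo = obo, gmt = gmt, tf = tf, urodyn = urodyn),
                 alpha_rna = alpha_rna, alpha_ora = alpha_ora, n_pcs = n_pcs,
                 loading_frac = loading_frac, impute_shift = impute_shift,
                 impute_width = impute_width, cycles = cycles,
                 fc_min = fc_min, curve_alpha = curve_alpha,
                 curvature = curvature, sim_threshold = sim_threshold,
                 cluster_k = cluster_k, seed = as.integer(seed)),
            class = "run_config")
}

#' Write a complete synthetic input bundle
#'
#' Generates counts, LFQ intensities, ontology + annotations, TF regulons
#' and urodynamic records under one directory, sharing the gene universe, and
#' returns a ready [run_config()] plus the ground truth (also saved as JSON).
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param n_genes,n_proteins,n_terms,n_tfs,targets_per_tf Bundle sizes.
#' @param frac_de,lfc_scale,censor_quantile Generator parameters.
#' @param ... Further arguments passed to [run_config()].
#' @return List with `config`, `truth_rna`, `truth_lfq`.
#' @export
write_synthetic_bundle <- function(dir, seed = 1L, n_genes = 1500,
                                   n_proteins = 400, n_terms = 40,
                                   n_tfs = 8, targets_per_tf = 15,
                                   frac_de = 0.05, lfc_scale = 2,
                                   censor_quantile = 0.3, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  sim <- gen_counts(n_genes, frac_de = frac_de, lfc_scale = lfc_scale,
                    seed = seed)
  genes <- rownames(sim$counts$counts)
  lfq <- gen_lfq(n_proteins, frac_de = frac_de, censor_quantile = censor_quantile,
                 seed = seed + 1L)
  dag <- gen_ontology(n_terms, n_genes = n_genes, seed = seed + 2L,
                      gene_ids = genes)
  db <- gen_tf_db(n_tfs, targets_per_tf, overlap = 0.2, seed = seed + 3L,
                  gene_pool = genes)
  uro <- gen_urodynamics(3, seed = seed + 4L)

  write_counts(sim$counts, p("counts.tsv"))
  write_samples(sim$counts$groups, p("samples.tsv"))
  write_lfq(lfq$lfq, p("lfq.tsv"))
  write_samples(lfq$lfq$groups, p("lfq_samples.tsv"))
  write_obo(dag, p("ontology.obo"))
  write_gmt(dag$direct, p("annotations.gmt"))
  write_tf(db, p("tf.tsv"))
  write_urodyn(uro, p("urodynamics.csv"))
  write_truth(sim$truth, p("truth_rna.json"))
  write_truth(lfq$truth, p("truth_lfq.json"))

  cfg <- run_config(counts = p("counts.tsv"), samples = p("samples.tsv"),
                    lfq = p("lfq.tsv"), obo = p("ontology.obo"),
                    gmt = p("annotations.gmt"), tf = p("tf.tsv"),
                    urodyn = p("urodynamics.csv"), seed = seed, ...)
  list(config = cfg, truth_rna = sim$truth, truth_lfq = lfq$truth)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the study workflow on the configured inputs: urodynamic indices
#' and grouping; dual-method NB differential expression of every
#' patient-group contrast vs control with consensus and before/after
#' bookkeeping; classifier-gene selection (PCA loading range intersected
#' with consensus DEGs) for the HP-vs-MP and HP before-vs-after questions;
#' GO over-representation of the HP-before DEGs with Resnik-similarity
#' pruning and binary-cut clustering; repeated-imputation proteomics DE per
#' contrast; and TF trajectory categorization with target clustering for the
#' most clearly normalized TF. The sample metadata must contain a `control`
#' group plus `<group>_before` / `<group>_after` groups.
#'
#' @param config A [run_config()].
#' @return A `boom_report` list of stage results plus a JSON-ready `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pt <- config$paths
  for (nm in names(pt)) {
    if (!file.exists(pt[[nm]])) abort(sprintf("input `%s` not found: %s", nm, pt[[nm]]))
  }
  counts <- stage("read_counts", read_counts(pt$counts, pt$samples))
  lfq_groups_path <- file.path(dirname(pt$lfq), "lfq_samples.tsv")
  lfq <- stage("read_lfq", read_lfq(pt$lfq, if (file.exists(lfq_groups_path))
    lfq_groups_path else pt$samples))
  dag <- stage("read_ontology", read_obo_dag(pt$obo, pt$gmt))
  db <- stage("read_tf", read_tf(pt$tf))
  uro <- stage("read_urodyn", read_urodyn(pt$urodyn))

  indices <- stage("urodynamics", urodynamic_indices(uro))

  groups <- unique(counts$groups)
  if (!"control" %in% groups) abort("sample metadata must contain a control group")
  contrasts <- setdiff(groups, "control")
  de <- list(); cons <- list()
  for (g in contrasts) {
    de[[g]] <- stage(paste0("de_", g), list(
      nb_exact = de_test(counts, c(g, "control"), "nb_exact", config$alpha_rna),
      nb_wald = de_test(counts, c(g, "control"), "nb_wald", config$alpha_rna)
    ))
    cons[[g]] <- consensus(de[[g]]$nb_exact, de[[g]]$nb_wald, config$alpha_rna)
  }

  meta <- parse_contrast_names(contrasts)
  books <- list()
  for (g in unique(meta$group)) {
    b <- meta$contrast[meta$group == g & meta$timepoint == "before"]
    a <- meta$contrast[meta$group == g & meta$timepoint == "after"]
    if (length(b) && length(a)) {
      books[[g]] <- bookkeeping(cons[[b]], cons[[a]])
    }
  }

  classifiers <- stage("classifiers", {
    out <- list()
    pairs <- list()
    befores <- meta$contrast[meta$timepoint == "before"]
    if (length(befores) >= 2) pairs$group <- c(befores[1], befores[2])
    g1 <- unique(meta$group)[1]
    ba <- c(meta$contrast[meta$group == g1 & meta$timepoint == "before"],
            meta$contrast[meta$group == g1 & meta$timepoint == "after"])
    if (length(ba) == 2) pairs$deobstruction <- ba
    for (nm in names(pairs)) {
      pr <- pairs[[nm]]
      sub_idx <- counts$groups %in% pr
      sub <- count_matrix(counts$counts[, sub_idx, drop = FALSE],
                          counts$groups[sub_idx])
      pc <- pca_expression(sub)
      sel <- suppressWarnings(
        select_by_loading_range(pc, config$n_pcs, config$loading_frac))
      dA <- de_test(sub, pr, "nb_exact", config$alpha_rna)
      dB <- de_test(sub, pr, "nb_wald", config$alpha_rna)
      cn <- consensus(dA, dB, config$alpha_rna)
      out[[nm]] <- derive_classifier(sel, cn, contrast = paste(pr, collapse = ":"))
    }
    out$combined <- do.call(combine_signatures, unname(out))
    if (length(out$combined)) {
      out$projection <- project_and_separate(counts, out$combined)
    }
    out
  })

  enrichment <- stage("enrichment", {
    b <- meta$contrast[meta$timepoint == "before"][1]
    degs <- c(cons[[b]]$up, cons[[b]]$down)
    universe <- rownames(counts$counts)[rowSums(counts$counts) > 0]
    lfcv <- setNames(de[[b]]$nb_wald$log2fc, de[[b]]$nb_wald$feature)
    hits <- ora(intersect(degs, universe), universe, dag,
                p_max = config$alpha_ora, lfc = lfcv)
    res <- list(ora = hits)
    if (nrow(hits) >= 2) {
      sim <- resnik_matrix(dag, hits$term)
      pvec <- setNames(hits$p, hits$term)
      retained <- prune_redundant(hits, sim, config$sim_threshold)
      cl <- binary_cut(sim[retained, retained, drop = FALSE], p = pvec)
      res$retained <- retained
      res$clusters <- cl
      res$tables <- display_tables(
        hits |> filter(.data$term %in% retained), cl, lfc = lfcv)
    }
    res
  })

  proteomics <- stage("proteomics", {
    pg <- unique(lfq$groups)
    out <- list()
    for (g in setdiff(pg, "control")) {
      out[[g]] <- repeated_imputation_de(
        lfq, c(g, "control"), n_cycles = config$cycles,
        base_seed = config$seed + 100L, fc_min = config$fc_min,
        alpha = config$curve_alpha, curvature = config$curvature,
        shift = config$impute_shift, width = config$impute_width)
    }
    out
  })

  tf_res <- stage("tf_regulon", {
    pats <- regulated_tfs(cons[contrasts], db)
    res <- list(patterns = pats)
    lfc_tables <- lapply(de[contrasts], function(x) x$nb_wald)
    pick <- if (any(pats$category == "normalized_after")) {
      pats$tf[pats$category == "normalized_after"][1]
    } else if (nrow(pats)) pats$tf[1] else NA_character_
    if (!is.na(pick)) {
      tm <- suppressMessages(target_matrix(pick, db, lfc_tables))
      k_eff <- min(config$cluster_k, max(1, nrow(tm) - 1))
      if (nrow(tm) > k_eff) {
        cl <- cluster_targets(tm, k_eff)
        res$tf <- pick
        res$target_clusters <- cl
        res$trajectories <- cluster_trajectory_report(cl, tm)
      }
    }
    res
  })

  summary <- list(
    seed = config$seed,
    n_genes = nrow(counts$counts),
    n_proteins = nrow(lfq$intensity),
    deg_counts = lapply(cons, function(x) list(up = length(x$up),
                                               down = length(x$down))),
    bookkeeping = lapply(books, function(b) as.list(glance(b))),
    classifier_sizes = list(
      group = length(classifiers$group$features %||% character()),
      deobstruction = length(classifiers$deobstruction$features %||% character()),
      combined = length(classifiers$combined %||% character())),
    dep_counts = lapply(proteomics, function(x) as.list(glance(x))),
    n_enriched_terms = nrow(enrichment$ora),
    tf_categories = if (nrow(tf_res$patterns))
      as.list(table(tf_res$patterns$category)) else list()
  )

  structure(list(config = config, urodynamics = indices, de = de,
                 consensus = cons, bookkeeping = books,
                 classifiers = classifiers, enrichment = enrichment,
                 proteomics = proteomics, tf = tf_res, summary = summary),
            class = "boom_report")
}

#' @exportS3Method base::print
print.boom_report <- function(x, ...) {
  cat("<boom_report>\n")
  cat(jsonlite::toJSON(x$summary, auto_unbox = TRUE, pretty = TRUE, digits = NA))
  cat("\n")
  invisible(x)
}
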