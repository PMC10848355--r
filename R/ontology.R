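# Rooted is_a DAG with true-path-closed annotations, information content and
# Resnik semantic similarity.

topo_order <- function(terms, parents) {
  # Kahn's algorithm on child -> parent edges; returns parents-before-children
  n_unmet <- vapply(terms, function(t) length(parents[[t]]), integer(1))
  children <- setNames(vector("list", length(terms)), terms)
  for (t in terms) for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  order <- character(0)
  queue <- terms[n_unmet == 0]
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    order <- c(order, t)
    for (c in children[[t]]) {
      n_unmet[c] <- n_unmet[c] - 1L
      if (n_unmet[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(order) != length(terms)) abort("ontology contains a cycle")
  order
}

#' Construct a rooted ontology DAG
#'
#' Builds the container used for over-representation and semantic-similarity
#' analysis from a term list and child -> parent (is_a) edges. Direct
#' annotations are propagated to all ancestors so the true-path rule holds;
#' information content is ic(t) = -log(|genes(t)| / |genes(root)|).
#'
#' @param terms Character vector of term ids.
#' @param parents Named list mapping each term to its parent term(s); the
#'   single term without parents is the root.
#' @param direct_annotations Named list term -> character vector of directly
#'   annotated genes.
#' @param term_names Optional named character vector of human-readable names.
#' @return An `ontology_dag` with elements `terms`, `parents`, `root`,
#'   `annotations` (true-path closed), `ic`, `ancestors`.
#' @export
ontology_dag <- function(terms, parents, direct_annotations = list(),
                         term_names = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) abort("duplicate term ids")
  parents <- parents[terms]
  names(parents) <- terms
  bad <- setdiff(unlist(parents), terms)
  if (length(bad)) abort(paste("unknown parent term(s):", paste(bad, collapse = ", ")))
  ord <- topo_order(terms, parents)
  roots <- terms[vapply(terms, function(t) length(parents[[t]]) == 0, logical(1))]
  if (length(roots) != 1) abort("the DAG must have exactly one root")

  # ancestor closure (including the term itself), parents before children
  ancestors <- setNames(vector("list", length(terms)), terms)
  for (t in ord) {
    anc <- t
    for (p in parents[[t]]) anc <- union(anc, ancestors[[p]])
    ancestors[[t]] <- anc
  }

  # true-path closure: push every directly annotated gene to all ancestors
  ann <- setNames(replicate(length(terms), character(0), simplify = FALSE), terms)
  for (t in terms) {
    g <- unique(direct_annotations[[t]])
    if (!length(g)) next
    for (a in ancestors[[t]]) ann[[a]] <- union(ann[[a]], g)
  }

  n_root <- length(ann[[roots]])
  ic <- vapply(terms, function(t) {
    k <- length(ann[[t]])
    if (k == 0 || n_root == 0) NA_real_ else -log(k / n_root)
  }, numeric(1))

  structure(list(terms = terms, parents = parents, root = roots,
                 annotations = ann, ancestors = ancestors, ic = ic,
                 term_names = term_names,
                 direct = direct_annotations),
            class = "ontology_dag")
}

#' @exportS3Method base::print
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, root %s (%d genes)\n",
              length(x$terms), x$root, length(x$annotations[[x$root]])))
  invisible(x)
}

#' Information content of ontology terms
#'
#' ic(t) = -log(|genes(t)| / |genes(root)|) over the true-path-closed
#' annotations; the root has ic 0 and ic never decreases from parent to
#' child. Terms with no annotated genes have undefined (NA) ic and are
#' excluded from similarity computations.
#'
#' @param dag An [ontology_dag()].
#' @return Named numeric vector of ic values.
#' @export
information_content <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  setNames(dag$ic, dag$terms)
}

#' Resnik semantic similarity between two terms
#'
#' The similarity is the information content of the most informative common
#' ancestor (MICA); a term counts among its own ancestors. When
#' `normalize = TRUE` (default) the value is divided by the maximum ic in
#' the DAG so similarities lie in [0, 1].
#'
#' @param dag An [ontology_dag()].
#' @param t1,t2 Term ids.
#' @param normalize Normalize by the corpus maximum ic. Default TRUE.
#' @return Similarity value (0 when the only common ancestor is the root).
#' @export
resnik <- function(dag, t1, t2, normalize = TRUE) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!t1 %in% dag$terms || !t2 %in% dag$terms) abort("unknown term id")
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  ics <- dag$ic[common]
  ics <- ics[!is.na(ics)]
  raw <- if (length(ics)) max(ics) else 0
  if (!normalize) return(raw)
  mx <- max(dag$ic, na.rm = TRUE)
  if (mx == 0) 0 else raw / mx
}

#' Pairwise Resnik similarity matrix
#'
#' @param dag An [ontology_dag()].
#' @param terms Term ids (default all terms with defined ic).
#' @param normalize Normalize to [0, 1]. Default TRUE.
#' @return Symmetric similarity matrix.
#' @export
resnik_matrix <- function(dag, terms = NULL, normalize = TRUE) {
  stopifnot(inherits(dag, "ontology_dag"))
  terms <- terms %||% dag$terms[!is.na(dag$ic)]
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) for (j in i:n) {
    s <- resnik(dag, terms[i], terms[j], normalize = normalize)
    m[i, j] <- m[j, i] <- s
  }
  m
}
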