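# Readers and writers for the plain-text interchange formats: counts TSV /
# MatrixMarket, proteinGroups-like LFQ TSV, OBO subset, GMT, TF TSV,
# urodynamics CSV and truth JSON. Writers emit exactly what the readers
# consume, so write -> read round-trips are identities.

#' Write / read sample metadata (sample, group)
#' @param groups Named character vector sample -> group.
#' @param path File path.
#' @return `read_samples` returns the named vector.
#' @export
write_samples <- function(groups, path) {
  write.table(data.frame(sample = names(groups), group = unname(groups)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(d))) abort("metadata needs sample, group columns")
  setNames(d$group, d$sample)
}

#' Write / read a counts matrix as TSV
#'
#' Tab-separated, first column `feature`, one column per sample.
#'
#' @param counts A [count_matrix()] (writer) .
#' @param path File path.
#' @param groups Named sample -> group vector, or path to a metadata TSV.
#' @return `read_counts` returns a [count_matrix()].
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  d <- data.frame(feature = rownames(counts$counts), counts$counts,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, groups) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "feature") abort("first column must be `feature`")
  dup <- d$feature[duplicated(d$feature)]
  if (length(dup)) abort(paste("duplicate feature id(s):", paste(unique(dup), collapse = ", ")))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$feature
  storage.mode(m) <- "integer"
  if (is.character(groups)) groups <- read_samples(groups)
  count_matrix(m, groups)
}

#' Write / read a counts matrix as MatrixMarket with name sidecars
#'
#' Writes `<prefix>.mtx` plus `<prefix>.rows` and `<prefix>.cols` (one id
#' per line).
#'
#' @param counts A [count_matrix()].
#' @param prefix Path prefix for the three files.
#' @param groups Named sample -> group vector or metadata TSV path (reader).
#' @return `read_counts_mm` returns a [count_matrix()].
#' @export
write_counts_mm <- function(counts, prefix) {
  stopifnot(inherits(counts, "count_matrix"))
  Matrix::writeMM(Matrix::Matrix(counts$counts, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(counts$counts), paste0(prefix, ".rows"))
  writeLines(colnames(counts$counts), paste0(prefix, ".cols"))
  invisible(prefix)
}

#' @rdname write_counts_mm
#' @export
read_counts_mm <- function(prefix, groups) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".rows"))
  colnames(m) <- readLines(paste0(prefix, ".cols"))
  storage.mode(m) <- "integer"
  if (is.character(groups)) groups <- read_samples(groups)
  count_matrix(m, groups)
}

#' Write / read a proteinGroups-like LFQ table
#'
#' TSV with a `protein` id column and one `LFQ intensity <sample>` column
#' per sample, intensities on the raw scale; zeros and blanks mean missing.
#' Intensities are log2-transformed on load.
#'
#' @param lfq An [lfq_matrix()] (log2 scale; the writer emits 2^x).
#' @param path File path.
#' @param groups Named sample -> group vector or metadata TSV path (reader).
#' @return `read_lfq` returns an [lfq_matrix()].
#' @export
write_lfq <- function(lfq, path) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  raw <- 2^lfq$intensity
  raw[lfq$mask] <- NA
  d <- data.frame(protein = rownames(raw), raw, check.names = FALSE)
  names(d)[-1] <- paste("LFQ intensity", colnames(raw))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_lfq
#' @export
read_lfq <- function(path, groups) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"protein" %in% names(d)) abort("LFQ table needs a `protein` column")
  lfq_cols <- grep("^LFQ intensity ", names(d), value = TRUE)
  if (!length(lfq_cols)) abort("no `LFQ intensity <sample>` columns found")
  m <- as.matrix(d[, lfq_cols, drop = FALSE])
  m[m == 0] <- NA
  m <- log2(m)
  rownames(m) <- d$protein
  colnames(m) <- sub("^LFQ intensity ", "", lfq_cols)
  if (is.character(groups)) groups <- read_samples(groups)
  lfq_matrix(m, groups)
}

#' Write / read an OBO-subset ontology (id, name, is_a only)
#'
#' @param dag An [ontology_dag()].
#' @param path File path.
#' @return `read_obo` returns the term structure (combine with annotations
#'   via [ontology_dag()]); `read_obo_dag` additionally takes a GMT path and
#'   returns a ready `ontology_dag`.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  lines <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    nm <- if (!is.null(dag$term_names)) dag$term_names[[t]] else t
    isa <- unlist(lapply(dag$parents[[t]], function(p) paste0("is_a: ", p)))
    lines <- c(lines, "[Term]", paste0("id: ", t), paste0("name: ", nm), isa, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_obo
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- character(0); parents <- list(); nms <- character(0)
  cur <- NULL
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (l == "[Term]") { cur <- NULL; next }
    if (grepl("^id:", l)) {
      cur <- trimws(sub("^id:", "", l))
      if (cur %in% terms) abort(sprintf("line %d: duplicate term %s", i, cur))
      terms <- c(terms, cur)
      parents[[cur]] <- character(0)
      nms[cur] <- cur
    } else if (grepl("^name:", l)) {
      if (is.null(cur)) abort(sprintf("line %d: name outside a [Term]", i))
      nms[cur] <- trimws(sub("^name:", "", l))
    } else if (grepl("^is_a:", l)) {
      if (is.null(cur)) abort(sprintf("line %d: is_a outside a [Term]", i))
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", l)))
      parents[[cur]] <- c(parents[[cur]], p)
    }
  }
  list(terms = terms, parents = parents, term_names = nms)
}

#' @rdname write_obo
#' @param gmt_path Path to a GMT annotation file of direct annotations.
#' @export
read_obo_dag <- function(path, gmt_path) {
  ob <- read_obo(path)
  ann <- read_gmt(gmt_path)
  ontology_dag(ob$terms, ob$parents, direct_annotations = ann,
               term_names = ob$term_names)
}

#' Write / read GMT gene-set annotations
#'
#' One line per term: id, description, then member genes, tab-separated.
#'
#' @param sets Named list term -> character vector of genes.
#' @param path File path.
#' @return `read_gmt` returns the named list.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(t) {
    paste(c(t, t, sets[[t]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) abort(sprintf("line %d: malformed GMT line", i))
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' Write / read a TF -> target table (TSV: tf, target, source)
#' @param db A [tf_regulon_db()] tibble.
#' @param path File path.
#' @return `read_tf` returns a `tf_regulon_db` tibble.
#' @export
write_tf <- function(db, path) {
  write.table(as.data.frame(db)[, c("tf", "target", "source")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tf
#' @export
read_tf <- function(path) {
  tf_regulon_db(read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read urodynamic records (CSV)
#' @param records Tibble of records (see [gen_urodynamics()]).
#' @param path File path.
#' @return `read_urodyn` returns a tibble.
#' @export
write_urodyn <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_urodyn
#' @export
read_urodyn <- function(path) {
  d <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("patient_id", "timepoint", "pdet_qmax", "qmax")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  d
}

#' Write / read a synthetic-truth object as JSON
#' @param truth A `synthetic_truth` list.
#' @param path File path.
#' @return `read_truth` returns the list (unclassed).
#' @export
write_truth <- function(truth, path) {
  # named atomic vectors become JSON objects, not nameless arrays
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (!is.null(names(x)) && length(x)) as.list(x)
    else x
  }
  jsonlite::write_json(listify(unclass(truth)), path, auto_unbox = TRUE,
                       digits = NA, null = "list")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
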