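#' Count matrix with group metadata
#'
#' Lightweight container for a genes x samples matrix of nonnegative integer
#' read counts plus a sample -> group assignment. Most users will get one from
#' [gen_counts()] or [read_counts()].
#'
#' @param counts Integer matrix, features in rows (rownames required),
#'   samples in columns (colnames required), no negative entries.
#' @param groups Named character vector mapping every sample to a group label.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must be a matrix with row and column names")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be nonnegative integers")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate feature ids")
  miss <- setdiff(colnames(counts), names(groups))
  if (length(miss)) abort(paste("samples without a group:", paste(miss, collapse = ", ")))
  structure(list(counts = counts, groups = groups[colnames(counts)]),
            class = "count_matrix")
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s(%d)", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Label-free proteomics intensity matrix
#'
#' Proteins x samples log2 LFQ intensities with an explicit missingness mask
#' (TRUE = missing). Missing cells hold NA in the intensity matrix.
#'
#' @param intensity Numeric matrix on log2 scale; NA marks missing values.
#' @param groups Named character vector mapping every sample to a group.
#' @return An object of class `lfq_matrix` with elements `intensity`, `mask`,
#'   `groups`.
#' @export
lfq_matrix <- function(intensity, groups) {
  if (!is.matrix(intensity) || is.null(rownames(intensity)) || is.null(colnames(intensity))) {
    abort("`intensity` must be a matrix with row and column names")
  }
  miss <- setdiff(colnames(intensity), names(groups))
  if (length(miss)) abort(paste("samples without a group:", paste(miss, collapse = ", ")))
  mask <- is.na(intensity)
  if (any(!is.finite(intensity[!mask]))) abort("observed intensities must be finite")
  structure(list(intensity = intensity, mask = mask, groups = groups[colnames(intensity)]),
            class = "lfq_matrix")
}

#' @exportS3Method base::print
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("<lfq_matrix> %d proteins x %d samples; %.1f%% missing\n",
              nrow(x$intensity), ncol(x$intensity), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.lfq_matrix <- function(x) dim(x$intensity)

#' Tidy a count matrix into long form
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @return Tibble with columns feature, sample, group, count.
#' @export
tidy.count_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE)) |>
    rlang::set_names(c("feature", "sample", "count")) |>
    mutate(group = unname(x$groups[.data$sample]), .before = "count")
}

#' Tidy an LFQ matrix into long form
#' @param x An `lfq_matrix`.
#' @param ... Unused.
#' @return Tibble with columns protein, sample, group, intensity, missing.
#' @export
tidy.lfq_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$intensity, stringsAsFactors = FALSE)) |>
    rlang::set_names(c("protein", "sample", "intensity")) |>
    mutate(group = unname(x$groups[.data$sample]),
           missing = is.na(.data$intensity))
}
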