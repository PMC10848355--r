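# internal input checkers shared across modules

check_number <- function(x, name, min = -Inf, finite = TRUE) {
  if (!is.numeric(x) || anyNA(x) || (finite && any(!is.finite(x))) || any(x < min)) {
    abort(sprintf("`%s` must be finite numeric >= %s", name, format(min)))
  }
  invisible(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    if (open) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) abort(sprintf("`%s` must lie in %s%s, %s%s", name,
                         if (open) "(" else "[", format(lo), format(hi),
                         if (open) ")" else "]"))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Benjamini-Hochberg, thin wrapper so the adjustment used package-wide is one call
bh_adjust <- function(p) p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a
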