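#' Bladder contractility index
#'
#' BCI = PdetQmax + 5 * Qmax, where PdetQmax is the detrusor pressure at
#' maximal flow (cmH2O) and Qmax the maximal flow rate (ml/s). Higher values
#' indicate a stronger detrusor; values above 150 are conventionally "strong",
#' 100-150 "normal", below 100 "weak".
#'
#' @param pdet_qmax Detrusor pressure at maximal flow, cmH2O (>= 0).
#' @param qmax Maximal flow rate, ml/s (>= 0). Vectorized with `pdet_qmax`.
#' @return Numeric vector of BCI values.
#' @export
#' @examples
#' compute_bci(100, 10) # 150
compute_bci <- function(pdet_qmax, qmax) {
  check_number(pdet_qmax, "pdet_qmax", min = 0)
  check_number(qmax, "qmax", min = 0)
  pdet_qmax + 5 * qmax
}

#' Bladder outlet obstruction index
#'
#' BOOI = PdetQmax - 2 * Qmax. Values below 20 indicate an unobstructed
#' outlet, values above 40 obstruction, the 20-40 band is equivocal
#' (standard pressure-flow nomogram bands; see [classify_obstruction()]).
#'
#' @inheritParams compute_bci
#' @return Numeric vector of BOOI values (may be negative).
#' @export
compute_booi <- function(pdet_qmax, qmax) {
  check_number(pdet_qmax, "pdet_qmax", min = 0)
  check_number(qmax, "qmax", min = 0)
  pdet_qmax - 2 * qmax
}

#' Assign a patient to the high- or medium-pressure group
#'
#' Patients with PdetQmax >= 90 cmH2O form the high-pressure (HP) group;
#' all others the medium-pressure (MP) group. The boundary is inclusive.
#'
#' @param pdet_qmax Detrusor pressure at maximal flow, cmH2O (>= 0).
#' @param cutoff Pressure cutoff, cmH2O. Default 90.
#' @return Character vector, "HP" or "MP".
#' @export
classify_pressure_group <- function(pdet_qmax, cutoff = 90) {
  check_number(pdet_qmax, "pdet_qmax", min = 0)
  ifelse(pdet_qmax >= cutoff, "HP", "MP")
}

#' Classify the obstruction state from BOOI
#'
#' BOOI < 20 is unobstructed (relief of obstruction after surgery),
#' BOOI > 40 obstructed, in between equivocal. The 20/40 bands follow the
#' standard BOOI nomogram and are configurable.
#'
#' @param booi BOOI value(s), finite.
#' @param bands Length-2 numeric, lower and upper band boundary. Default c(20, 40).
#' @return Character vector in {"unobstructed", "equivocal", "obstructed"}.
#' @export
classify_obstruction <- function(booi, bands = c(20, 40)) {
  if (!is.numeric(booi) || anyNA(booi) || any(!is.finite(booi))) {
    abort("`booi` must be finite numeric")
  }
  stopifnot(length(bands) == 2L, bands[1] <= bands[2])
  dplyr::case_when(
    booi < bands[1] ~ "unobstructed",
    booi > bands[2] ~ "obstructed",
    TRUE ~ "equivocal"
  )
}

#' Urodynamic indices for a table of pressure-flow records
#'
#' Takes a data frame of per-patient, per-timepoint urodynamic records and
#' appends the derived indices: BCI, BOOI, pressure group and obstruction
#' class. The input needs columns `pdet_qmax` and `qmax`; `patient_id`,
#' `timepoint`, `rv` and `age` are carried through untouched.
#'
#' @param records Data frame with at least `pdet_qmax` and `qmax` columns.
#' @param hp_cutoff PdetQmax cutoff for the HP group (cmH2O). Default 90.
#' @param booi_bands BOOI nomogram bands. Default c(20, 40).
#' @return A tibble: the input plus `bci`, `booi`, `pressure_group`,
#'   `obstruction_class`.
#' @export
#' @examples
#' tibble::tibble(patient_id = "p1", timepoint = "before",
#'                pdet_qmax = 107, qmax = 6) |> urodynamic_indices()
urodynamic_indices <- function(records, hp_cutoff = 90, booi_bands = c(20, 40)) {
  stopifnot(is.data.frame(records))
  need <- c("pdet_qmax", "qmax")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  as_tibble(records) |>
    mutate(
      bci = compute_bci(.data$pdet_qmax, .data$qmax),
      booi = compute_booi(.data$pdet_qmax, .data$qmax),
      pressure_group = classify_pressure_group(.data$pdet_qmax, cutoff = hp_cutoff),
      obstruction_class = classify_obstruction(.data$booi, bands = booi_bands)
    )
}
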