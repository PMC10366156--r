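#' Strain-time curve for one subject and one strain type
#'
#' Container for a single global strain-time signal across one cardiac
#' cycle: strain in percent (negative values indicate shortening) sampled
#' at strictly increasing times in milliseconds from cycle start.
#'
#' @param subject_id Subject identifier (character scalar).
#' @param strain_type `"GCS"` (global circumferential) or `"GLS"`
#'   (global longitudinal strain).
#' @param morphology Dominant-ventricle morphology, `"SLV"` or `"SRV"`.
#' @param times Numeric vector of sample times in ms, strictly increasing,
#'   first sample at time >= 0. At least 8 samples.
#' @param values Numeric vector of strain values in percent, same length
#'   as `times`, all finite.
#' @param heart_rate Heart rate in beats/min (> 0); the nominal cycle
#'   length is `60000 / heart_rate` ms.
#'
#' @return An object of class `"strain_curve"`: a list with the fields
#'   above.
#' @export
strain_curve <- function(subject_id, strain_type, morphology,
                         times, values, heart_rate) {
  strain_type <- match.arg(strain_type, c("GCS", "GLS"))
  morphology  <- match.arg(morphology, c("SLV", "SRV"))
  times  <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times) < 8)
    stop("a strain curve needs at least 8 samples, got ", length(times),
         call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("non-finite times or strain values in curve for subject ",
         subject_id, call. = FALSE)
  if (times[1] < 0)
    stop("times must start at or after 0", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing (subject ", subject_id, ")",
         call. = FALSE)
  if (!is.finite(heart_rate) || heart_rate <= 0)
    stop("heart_rate must be a positive finite number", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id),
         strain_type = strain_type,
         morphology = morphology,
         times = times,
         values = values,
         heart_rate = as.numeric(heart_rate)),
    class = "strain_curve")
}

#' @export
print.strain_curve <- function(x, ...) {
  cat(sprintf("<strain_curve> %s %s/%s: %d samples over %.0f ms, peak %.2f%%, HR %.0f bpm\n",
              x$subject_id, x$strain_type, x$morphology, length(x$times),
              max(x$times) - min(x$times), min(x$values), x$heart_rate))
  invisible(x)
}

cycle_length_ms <- function(curve) 60000 / curve$heart_rate

#' Temporal normalization of a strain curve to a reference cycle length
#'
#' Adjusts for heart-rate variability by uniformly rescaling the time axis
#' so the subject's cardiac-cycle duration matches the cohort-average
#' cycle period. Strain values are untouched; every sample keeps its
#' relative phase within the cycle.
#'
#' @param curve A [strain_curve()].
#' @param cohort_mean_cycle_ms Reference (stratum-average) cycle length in
#'   ms, > 0.
#'
#' @return A `strain_curve` with `times` multiplied by
#'   `cohort_mean_cycle_ms / (60000 / heart_rate)`.
#' @export
normalize_heart_rate <- function(curve, cohort_mean_cycle_ms) {
  stopifnot(inherits(curve, "strain_curve"))
  if (!is.finite(cohort_mean_cycle_ms) || cohort_mean_cycle_ms <= 0)
    stop("cohort_mean_cycle_ms must be positive", call. = FALSE)
  if (curve$heart_rate <= 0)
    stop("heart_rate must be positive", call. = FALSE)
  scale <- cohort_mean_cycle_ms / cycle_length_ms(curve)
  out <- curve
  out$times <- curve$times * scale
  out
}

#' Resample a strain curve to a fixed number of cardiac phases
#'
#' Linearly interpolates the strain signal at `n_phases` equally spaced
#' phase points spanning the curve's sampled time range (closed interval:
#' the first and last output values coincide with the curve's first and
#' last samples).
#'
#' @param curve A [strain_curve()].
#' @param n_phases Number of output phases (>= 2); default 30.
#'
#' @return Numeric vector of length `n_phases` (strain, percent).
#' @export
resample_to_phases <- function(curve, n_phases = 30) {
  stopifnot(inherits(curve, "strain_curve"))
  if (!is.numeric(n_phases) || n_phases < 2)
    stop("n_phases must be at least 2", call. = FALSE)
  grid <- seq(curve$times[1], curve$times[length(curve$times)],
              length.out = n_phases)
  stats::approx(curve$times, curve$values, xout = grid, method = "linear",
                rule = 2)$y
}

#' Assemble the phase-normalized curve matrix for one analysis stratum
#'
#' Selects the curves of one (strain type, ventricular morphology)
#' stratum, temporally normalizes each to the stratum-average cycle
#' period, resamples each to `n_phases` phases, and stacks them row-wise
#' in input order. One matrix per stratum is the unit on which a shape
#' model is fitted.
#'
#' @param curves List of [strain_curve()] objects (may contain other
#'   strata; those are ignored unless `strict`).
#' @param strain_type,morphology Stratum selectors.
#' @param n_phases Number of phases per row (default 30).
#' @param cohort_mean_cycle_ms Reference cycle length; default `NULL`
#'   computes the mean cycle period (60000 / heart rate) over the selected
#'   curves.
#' @param strict If `TRUE`, curves outside the requested stratum raise an
#'   error instead of being filtered out.
#'
#' @return An object of class `"curve_matrix"`: list with `stratum`
#'   (named character of strain_type, morphology), `subject_ids`, `matrix`
#'   (subjects x phases), `n_phases`, `cohort_mean_cycle_ms` and `empty`
#'   flag.
#' @export
build_curve_matrix <- function(curves, strain_type, morphology,
                               n_phases = 30, cohort_mean_cycle_ms = NULL,
                               strict = FALSE) {
  strain_type <- match.arg(strain_type, c("GCS", "GLS"))
  morphology  <- match.arg(morphology, c("SLV", "SRV"))
  if (!all(vapply(curves, inherits, logical(1), "strain_curve")))
    stop("curves must all be strain_curve objects", call. = FALSE)
  keep <- vapply(curves, function(cv)
    cv$strain_type == strain_type && cv$morphology == morphology,
    logical(1))
  if (strict && !all(keep))
    stop("curves from more than one stratum supplied with strict = TRUE",
         call. = FALSE)
  sel <- curves[keep]
  stratum <- c(strain_type = strain_type, morphology = morphology)
  if (length(sel) == 0L) {
    return(structure(
      list(stratum = stratum, subject_ids = character(0),
           matrix = matrix(numeric(0), nrow = 0, ncol = n_phases),
           n_phases = n_phases,
           cohort_mean_cycle_ms = NA_real_, empty = TRUE),
      class = "curve_matrix"))
  }
  if (is.null(cohort_mean_cycle_ms))
    cohort_mean_cycle_ms <- mean(vapply(sel, cycle_length_ms, numeric(1)))
  rows <- t(vapply(sel, function(cv)
    resample_to_phases(normalize_heart_rate(cv, cohort_mean_cycle_ms),
                       n_phases),
    numeric(n_phases)))
  ids <- vapply(sel, function(cv) cv$subject_id, character(1))
  rownames(rows) <- ids
  structure(
    list(stratum = stratum, subject_ids = ids, matrix = rows,
         n_phases = n_phases,
         cohort_mean_cycle_ms = cohort_mean_cycle_ms, empty = FALSE),
    class = "curve_matrix")
}

#' @export
print.curve_matrix <- function(x, ...) {
  cat(sprintf("<curve_matrix> %s/%s: %d subjects x %d phases (mean cycle %.0f ms)\n",
              x$stratum[["strain_type"]], x$stratum[["morphology"]],
              nrow(x$matrix), x$n_phases, x$cohort_mean_cycle_ms))
  invisible(x)
}
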