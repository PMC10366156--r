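# File formats and the end-to-end pipeline: long-format curve CSV in/out,
# model/score/survival exports with a JSON provenance sidecar, and the
# orchestrator running simulate -> normalize -> PCA -> score -> survival
# -> associations per stratum.

curve_csv_cols <- c("subject_id", "strain_type", "morphology", "time_ms",
                    "strain_percent", "heart_rate_bpm")

#' Write strain curves to a long-format CSV
#'
#' One row per sample: `subject_id, strain_type, morphology, time_ms,
#' strain_percent, heart_rate_bpm`.
#'
#' @param curves List of [strain_curve()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(subject_id = cv$subject_id, strain_type = cv$strain_type,
               morphology = cv$morphology, time_ms = cv$times,
               strain_percent = cv$values, heart_rate_bpm = cv$heart_rate,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read strain curves from a long-format CSV
#'
#' Strict schema check against the columns written by [write_curves()];
#' rows are grouped by (subject, strain type) and sorted by time, so the
#' result does not depend on row order. Duplicated sample times, missing
#' values or non-positive heart rates are reported with the offending
#' subject.
#'
#' @param path Input file path.
#' @return List of [strain_curve()] objects (one per subject x strain
#'   type), ordered by first appearance in the file.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(curve_csv_cols, names(df))
  if (length(missing_cols) > 0)
    stop("curve file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) return(list())
  num_cols <- c("time_ms", "strain_percent", "heart_rate_bpm")
  for (cc in num_cols) {
    bad <- !is.finite(df[[cc]])
    if (any(bad))
      stop("non-finite ", cc, " for subject ",
           df$subject_id[which(bad)[1]], " (row ", which(bad)[1], ")",
           call. = FALSE)
  }
  key <- paste(df$subject_id, df$strain_type, sep = "\r")
  first_seen <- !duplicated(key)
  ord_keys <- key[first_seen]
  out <- lapply(ord_keys, function(k) {
    g <- df[key == k, , drop = FALSE]
    dup <- duplicated(g$time_ms)
    if (any(dup))
      stop("duplicated sample time ", g$time_ms[which(dup)[1]],
           " ms for subject ", g$subject_id[1], " (", g$strain_type[1],
           ")", call. = FALSE)
    g <- g[order(g$time_ms), , drop = FALSE]
    if (length(unique(g$morphology)) != 1 ||
        length(unique(g$heart_rate_bpm)) != 1)
      stop("inconsistent morphology or heart rate for subject ",
           g$subject_id[1], " (", g$strain_type[1], ")", call. = FALSE)
    strain_curve(g$subject_id[1], g$strain_type[1], g$morphology[1],
                 times = g$time_ms, values = g$strain_percent,
                 heart_rate = g$heart_rate_bpm[1])
  })
  out
}

#' Export a curve matrix as a wide CSV
#'
#' One row per subject, columns `subject_id, phase_01..phase_NN`.
#'
#' @param mat A [build_curve_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "curve_matrix"))
  df <- as.data.frame(mat$matrix)
  names(df) <- sprintf("phase_%02d", seq_len(mat$n_phases))
  df <- cbind(data.frame(subject_id = mat$subject_ids,
                         stringsAsFactors = FALSE), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a shape model (CSV + JSON sidecar)
#'
#' Writes the mean curve and component vectors as a phases-by-columns CSV
#' and the eigenvalues, explained fractions, conventions and stratum to a
#' JSON sidecar `<path>.json`.
#'
#' @param model A [fit_shape_model()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  k <- ncol(model$components)
  df <- data.frame(phase = seq_along(model$mean_curve),
                   mean_curve = model$mean_curve)
  comp <- as.data.frame(model$components)
  names(comp) <- paste0("pc", seq_len(k))
  utils::write.csv(cbind(df, comp), path, row.names = FALSE)
  jsonlite::write_json(
    list(stratum = as.list(model$stratum),
         n_subjects = model$n_subjects,
         eigenvalues = model$eigenvalues,
         explained_fraction = model$explained_fraction,
         sign_convention = "pc1: positive score deepens mean |strain|; others: largest-magnitude element positive",
         centering = "scores centered by default"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Supply either
#' `curves_path` (a long-format curve CSV plus a `subjects` table) or a
#' [cohort_config()] to simulate.
#'
#' @param simulation A [cohort_config()], or `NULL` when reading files.
#' @param curves_path Long-format curve CSV (ignored when simulating).
#' @param subjects A subject-records data.frame (ignored when simulating).
#' @param n_phases Phases per resampled curve (default 30).
#' @param variance_threshold Cumulative explained-variance retention
#'   threshold (default 0.90).
#' @param centered Score convention (default `TRUE`).
#' @param survival_covariates Columns of the subject table to test in
#'   single-variable Cox models (PC scores are always added).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Seed for any simulation (overrides the one in
#'   `simulation` when not `NULL`).
#'
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = NULL, curves_path = NULL,
                            subjects = NULL, n_phases = 30,
                            variance_threshold = 0.90, centered = TRUE,
                            survival_covariates = c("edvi", "esvi", "ef",
                                                    "ci", "peak_gcs",
                                                    "peak_gls"),
                            out_dir = NULL, seed = NULL) {
  if (is.null(simulation) && is.null(curves_path))
    stop("either a simulation config or a curves_path is required",
         call. = FALSE)
  stopifnot(variance_threshold > 0, variance_threshold <= 1,
            n_phases >= 2)
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation, "cohort_config"))
    if (!is.null(seed)) simulation$seed <- as.integer(seed)
  }
  structure(
    list(simulation = simulation, curves_path = curves_path,
         subjects = subjects, n_phases = n_phases,
         variance_threshold = variance_threshold, centered = centered,
         survival_covariates = survival_covariates, out_dir = out_dir,
         seed = if (!is.null(simulation)) simulation$seed else seed),
    class = "pipeline_config")
}

strata_grid <- function() {
  expand.grid(strain_type = c("GCS", "GLS"),
              morphology = c("SLV", "SRV"),
              stringsAsFactors = FALSE)
}

#' Run the full strain-curve shape-mode pipeline
#'
#' Per (strain type x morphology) stratum: assemble the phase-normalized
#' curve matrix, fit the shape model, retain components by the
#' explained-variance threshold, compute subject scores, run
#' single-variable Cox models over hemodynamic covariates and the
#' retained PC scores, and compute strain-EF association statistics.
#' Strata with fewer than 2 curves are skipped with a warning. All
#' randomness comes from the simulation seed, so a fixed configuration
#' reproduces the bundle exactly.
#'
#' @param config A [pipeline_config()].
#'
#' @return A report bundle: list with `strata` (per-stratum list of
#'   `matrix`, `model`, `k_retained`, `scores`, `modes`), `subjects` (with
#'   score columns merged in), `cox` (tidy data.frame), `associations`
#'   (tidy data.frame), `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulation)) {
    cohort <- generate_cohort(config$simulation)
    curves <- cohort$curves
    subjects <- cohort$subjects
  } else {
    curves <- read_curves(config$curves_path)
    subjects <- config$subjects
    if (is.null(subjects))
      stop("a subjects table is required when reading curves from file",
           call. = FALSE)
  }

  grid <- strata_grid()
  strata <- list()
  for (i in seq_len(nrow(grid))) {
    st <- grid$strain_type[i]; mo <- grid$morphology[i]
    key <- paste(st, mo, sep = "_")
    mat <- build_curve_matrix(curves, st, mo, n_phases = config$n_phases)
    if (mat$empty || nrow(mat$matrix) < 2) {
      warning("stratum ", key, " has fewer than 2 curves; skipped",
              call. = FALSE)
      next
    }
    model <- fit_shape_model(mat)
    k <- select_components(model, config$variance_threshold)
    scores <- compute_scores(model, mat, centered = config$centered)
    modes <- if (ncol(model$components) >= 3)
      characterize_modes(model) else NULL
    strata[[key]] <- list(matrix = mat, model = model, k_retained = k,
                          scores = scores, modes = modes)
  }

  # merge retained scores into the subject table
  for (key in names(strata)) {
    s <- strata[[key]]
    k <- s$k_retained
    sc <- s$scores$scores[, seq_len(k), drop = FALSE]
    colnames(sc) <- sprintf("%s_pc%d", tolower(key), seq_len(k))
    m <- match(s$scores$subject_ids, subjects$subject_id)
    for (j in seq_len(ncol(sc))) {
      subjects[[colnames(sc)[j]]] <- NA_real_
      subjects[[colnames(sc)[j]]][m] <- sc[, j]
    }
  }

  # single-variable Cox per morphology group
  cox_rows <- list()
  for (mo in c("SLV", "SRV")) {
    sub <- subjects[subjects$morphology == mo, , drop = FALSE]
    if (sum(sub$event) < 2) next
    score_cols <- grep(paste0("_", tolower(mo), "_pc"), names(subjects),
                       value = TRUE)
    covs <- c(intersect(config$survival_covariates, names(sub)), score_cols)
    for (cv in covs) {
      flip <- cv %in% c("peak_gcs", "peak_gls")
      res <- tryCatch(cox_univariable(sub, cv, per_unit_worsening = flip),
                      error = function(e) NULL)
      if (is.null(res)) next
      cox_rows[[length(cox_rows) + 1L]] <- data.frame(
        morphology = mo, covariate = cv, n = res$n,
        n_events = res$n_events, hr = res$hr, ci_low = res$ci95[1],
        ci_high = res$ci95[2], p = res$p, per_unit_worsening = flip,
        stringsAsFactors = FALSE)
    }
  }
  cox_tab <- if (length(cox_rows)) do.call(rbind, cox_rows) else NULL

  # strain-EF / volume associations per morphology
  assoc_rows <- list()
  for (mo in c("SLV", "SRV")) {
    sub <- subjects[subjects$morphology == mo, , drop = FALSE]
    if (nrow(sub) < 3) next
    pairs <- list(c("peak_gcs", "ef"), c("peak_gls", "ef"))
    for (pp in pairs) {
      a <- tryCatch(correlate_with_slope(sub[[pp[1]]], sub[[pp[2]]]),
                    error = function(e) NULL)
      if (is.null(a)) next
      assoc_rows[[length(assoc_rows) + 1L]] <- data.frame(
        morphology = mo, x = pp[1], y = pp[2], r = a$r, p = a$p,
        slope = a$slope, n = a$n, stringsAsFactors = FALSE)
    }
  }
  assoc_tab <- if (length(assoc_rows)) do.call(rbind, assoc_rows) else NULL

  provenance <- list(
    seed = config$seed, n_phases = config$n_phases,
    variance_threshold = config$variance_threshold,
    centered_scores = config$centered,
    tie_method = "breslow",
    sign_convention = "pc1 deepens mean |strain|; others largest element positive",
    simulated = !is.null(config$simulation),
    strata_fitted = names(strata),
    package_version = as.character(utils::packageVersion("strainshape")))

  bundle <- list(strata = strata, subjects = subjects, cox = cox_tab,
                 associations = assoc_tab, provenance = provenance)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    utils::write.csv(subjects, file.path(od, "subjects.csv"),
                     row.names = FALSE)
    if (!is.null(cox_tab))
      utils::write.csv(cox_tab, file.path(od, "cox_univariable.csv"),
                       row.names = FALSE)
    if (!is.null(assoc_tab))
      utils::write.csv(assoc_tab, file.path(od, "associations.csv"),
                       row.names = FALSE)
    for (key in names(strata)) {
      write_shape_model(strata[[key]]$model,
                        file.path(od, paste0("model_", key, ".csv")))
      if (!is.null(strata[[key]]$modes))
        utils::write.csv(strata[[key]]$modes,
                         file.path(od, paste0("modes_", key, ".csv")),
                         row.names = FALSE)
    }
    jsonlite::write_json(provenance, file.path(od, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}
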