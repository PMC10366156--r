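# Shape-mode extraction: PCA of a phase-normalized curve matrix, explained
# variance, component retention, patient shape scores and mode
# reconstruction for interpretation.

#' Fit a shape model to a curve matrix
#'
#' Principal component analysis of the subjects-by-phases strain matrix of
#' one stratum: the mean strain-time curve plus an orthonormal basis of
#' deformation modes from the eigendecomposition of the sample covariance
#' (divisor n - 1) of the mean-centered rows. Eigenvalues below
#' `1e-12 * lambda_1` are treated as numerically zero and dropped.
#'
#' A deterministic sign convention is applied (PCA component signs are
#' arbitrary): the first component is oriented so that a positive score
#' increases the curve's mean absolute deviation from zero (a deeper
#' overall deflection); every other component is oriented so its
#' largest-magnitude element is positive.
#'
#' @param mat A [build_curve_matrix()] result, or a plain numeric matrix
#'   (subjects x phases).
#'
#' @return Object of class `"shape_model"`: `stratum`, `mean_curve`,
#'   `components` (phases x K, orthonormal columns), `eigenvalues`
#'   (non-increasing, percent^2), `explained_fraction`, `n_subjects`.
#' @export
fit_shape_model <- function(mat) {
  x <- if (inherits(mat, "curve_matrix")) mat$matrix else as.matrix(mat)
  stratum <- if (inherits(mat, "curve_matrix")) mat$stratum else
    c(strain_type = NA_character_, morphology = NA_character_)
  if (nrow(x) < 2)
    stop("at least 2 curves are required to fit a shape model", call. = FALSE)
  if (any(!is.finite(x)))
    stop("curve matrix contains missing or non-finite values", call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (nrow(x) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (lam[1] <= 0)
    stop("degenerate curve matrix: total variance is zero", call. = FALSE)
  keep <- lam > 1e-12 * lam[1]
  lam <- lam[keep]
  comp <- eg$vectors[, keep, drop = FALSE]
  # sign convention
  for (j in seq_len(ncol(comp))) {
    flip <- if (j == 1L) sum(sign(mu) * comp[, 1L]) < 0 else
      comp[which.max(abs(comp[, j])), j] < 0
    if (flip) comp[, j] <- -comp[, j]
  }
  structure(
    list(stratum = stratum, mean_curve = mu, components = comp,
         eigenvalues = lam, explained_fraction = lam / sum(lam),
         n_subjects = nrow(x)),
    class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  k <- min(3L, length(x$eigenvalues))
  cat(sprintf("<shape_model> %s/%s: %d subjects, %d modes; top %d explain %s\n",
              x$stratum[["strain_type"]], x$stratum[["morphology"]],
              x$n_subjects, length(x$eigenvalues), k,
              paste(sprintf("%.1f%%", 100 * x$explained_fraction[1:k]),
                    collapse = " + ")))
  invisible(x)
}

#' Number of components needed to pass an explained-variance threshold
#'
#' Returns the smallest k whose cumulative explained-variance fraction
#' exceeds `threshold` (default 0.90, the retention rule under which the
#' first three strain-curve modes are kept).
#'
#' @param model A [fit_shape_model()] result.
#' @param threshold Cumulative explained-variance fraction in (0, 1].
#' @return Integer component count.
#' @export
select_components <- function(model, threshold = 0.90) {
  stopifnot(inherits(model, "shape_model"),
            threshold > 0, threshold <= 1)
  cum <- cumsum(model$explained_fraction)
  k <- which(cum > threshold)
  if (length(k) == 0L) length(cum) else k[1L]
}

#' Patient-specific shape scores
#'
#' Projects each subject's curve onto the shape-model components:
#' `score[i, n] = p_n . (eps_i - mean_curve)` under the default centered
#' convention, or `p_n . eps_i` raw. The two differ per component only by
#' the constant `p_n . mean_curve`, so downstream hazard ratios are
#' unaffected by the choice; centered scores have mean zero and variance
#' equal to the component eigenvalue.
#'
#' @param model A [fit_shape_model()] result.
#' @param mat A [build_curve_matrix()] result or numeric matrix with
#'   columns matching the model dimension.
#' @param centered Use the centered convention (default `TRUE`).
#'
#' @return Object of class `"score_set"`: `stratum`, `subject_ids`,
#'   `scores` (subjects x K, columns `score_pc1` ...), `centered`.
#' @export
compute_scores <- function(model, mat, centered = TRUE) {
  stopifnot(inherits(model, "shape_model"))
  x <- if (inherits(mat, "curve_matrix")) mat$matrix else as.matrix(mat)
  ids <- if (inherits(mat, "curve_matrix")) mat$subject_ids else
    rownames(x) %||% as.character(seq_len(nrow(x)))
  if (ncol(x) != length(model$mean_curve))
    stop("curve matrix has ", ncol(x), " phases but the model expects ",
         length(model$mean_curve), call. = FALSE)
  xs <- if (centered) sweep(x, 2, model$mean_curve) else x
  sc <- xs %*% model$components
  colnames(sc) <- paste0("score_pc", seq_len(ncol(sc)))
  rownames(sc) <- ids
  structure(
    list(stratum = model$stratum, subject_ids = ids, scores = sc,
         centered = centered),
    class = "score_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct an extreme variation of one shape mode
#'
#' Returns `mean_curve + multiplier * p_n` — with `multiplier = c * sd_n`
#' (`sd_n = sqrt(eigenvalue_n)`) this produces the extreme positive /
#' negative mode variations plotted against the mean curve when
#' interpreting what each component does to curve shape.
#'
#' @param model A [fit_shape_model()] result.
#' @param n Component index (1-based).
#' @param multiplier Scalar score value along the component.
#' @return Numeric vector, same length as the mean curve.
#' @export
reconstruct_mode <- function(model, n, multiplier) {
  stopifnot(inherits(model, "shape_model"))
  if (!is.numeric(n) || n < 1 || n > ncol(model$components))
    stop("component index out of range (model has ",
         ncol(model$components), " components)", call. = FALSE)
  model$mean_curve + multiplier * model$components[, n]
}

perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# depth of the late-diastolic notch: largest downward deviation of the
# recovery limb from the straight chord joining the peak to the final
# sample (0 for a uniform, affine recovery)
post_peak_notch_depth <- function(v) {
  i0 <- which.min(v)
  n <- length(v)
  if (n - i0 < 3) return(0)
  idx <- i0:n
  chord <- v[i0] + (v[n] - v[i0]) * (idx - i0) / (n - i0)
  max(0, max(chord - v[idx]))
}

# late/early post-peak recovery slope ratio of a curve vector
post_peak_slope_ratio <- function(v) {
  i0 <- which.min(v)
  rec <- v[i0:length(v)]
  m <- length(rec)
  if (m < 5) return(NA_real_)
  half <- ceiling(m / 2)
  fit_slope <- function(y) {
    t <- seq_along(y)
    stats::cov(t, y) / stats::var(t)
  }
  early <- fit_slope(rec[1:half])
  late <- fit_slope(rec[half:m])
  if (abs(early) < 1e-12) return(NA_real_)
  late / early
}

#' Quantitative descriptors and automatic labelling of the leading modes
#'
#' For each of the first `n_modes` components, compares the +c SD and
#' -c SD extreme reconstructions and measures how the mode deforms the
#' curve: change in peak amplitude (percent), shift of the peak phase
#' (phase indices), and change of the late/early post-peak recovery-slope
#' ratio. Each mode is then labelled `"amplitude"`, `"time_to_peak"` or
#' `"post_systolic_slope"` by the feature-to-mode assignment maximizing
#' the total descriptor magnitude after normalizing each descriptor
#' across modes; the recovery-shape feature is scored by the
#' chord-deviation notch depth of the recovery limb.
#'
#' @param model A [fit_shape_model()] result with at least `n_modes`
#'   components.
#' @param n_modes Number of leading modes to characterize (default 3).
#' @param c_sd Extremeness of the reconstructions in SD units (default
#'   1.5; mild enough that each mode's reconstruction deforms mainly the
#'   one curve feature it encodes).
#'
#' @return data.frame with one row per mode: `mode`,
#'   `explained_fraction`, `delta_peak` (percent), `delta_time_to_peak`
#'   (phase indices), `delta_slope_ratio` (late/early recovery-slope
#'   fit), `delta_notch_depth` (percent, chord deviation of the recovery
#'   limb), `label`.
#' @export
characterize_modes <- function(model, n_modes = 3, c_sd = 1.5) {
  stopifnot(inherits(model, "shape_model"))
  if (ncol(model$components) < n_modes)
    stop("model has only ", ncol(model$components),
         " components; ", n_modes, " requested", call. = FALSE)
  d_peak <- d_tpk <- d_slope <- d_notch <- numeric(n_modes)
  for (j in seq_len(n_modes)) {
    m <- c_sd * sqrt(model$eigenvalues[j])
    hi <- reconstruct_mode(model, j, +m)
    lo <- reconstruct_mode(model, j, -m)
    d_peak[j] <- min(hi) - min(lo)
    d_tpk[j] <- which.min(hi) - which.min(lo)
    rhi <- post_peak_slope_ratio(hi)
    rlo <- post_peak_slope_ratio(lo)
    d_slope[j] <- if (is.na(rhi) || is.na(rlo)) 0 else rhi - rlo
    d_notch[j] <- post_peak_notch_depth(hi) - post_peak_notch_depth(lo)
  }
  # labelling uses the chord-deviation notch depth for the recovery-shape
  # feature: unlike the raw late/early slope ratio it is insensitive to
  # how far the time-to-peak mode drags the recovery window around
  desc <- cbind(amplitude = abs(d_peak),
                time_to_peak = abs(d_tpk),
                post_systolic_slope = abs(d_notch))
  norm <- sweep(desc, 2, pmax(apply(desc, 2, max), 1e-12), "/")
  # assign features to modes by the permutation maximizing the total
  # normalized descriptor score (robust against one mode dominating two
  # descriptors at once)
  labels <- rep(NA_character_, n_modes)
  k <- min(n_modes, 3L)
  perms <- perm_matrix(3L)
  best_total <- -Inf
  best_perm <- perms[1, ]
  for (r in seq_len(nrow(perms))) {
    pr <- perms[r, ]
    total <- sum(norm[cbind(seq_len(k), pr[seq_len(k)])])
    if (total > best_total) { best_total <- total; best_perm <- pr }
  }
  labels[seq_len(k)] <- colnames(desc)[best_perm[seq_len(k)]]
  data.frame(mode = seq_len(n_modes),
             explained_fraction = model$explained_fraction[seq_len(n_modes)],
             delta_peak = d_peak, delta_time_to_peak = d_tpk,
             delta_slope_ratio = d_slope, delta_notch_depth = d_notch,
             label = labels, stringsAsFactors = FALSE)
}
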