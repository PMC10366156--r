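# Synthetic single-ventricle cohort generator: strain-time curves with
# controlled latent shape factors (peak amplitude, time to peak, mono- vs
# biphasic diastolic recovery), Table-style hemodynamics, and
# proportional-hazards event histories.

#' Parametric strain-time curve template
#'
#' Defines one subject's idealized strain-time curve by three latent shape
#' factors. The curve descends from 0 to a negative systolic peak along a
#' half-sinusoid over `[0, time_to_peak_frac]` of the cycle, then recovers
#' toward 0. At `biphasic_weight = 0` the recovery is a single uniform
#' (affine) slope; as the weight grows, a late-diastolic notch of depth
#' `biphasic_weight * biphasic_depth` splits the recovery into a shallower
#' early and a steeper late relaxation slope — the morphology that
#' corresponds to a double-peaked (early + late) diastolic strain rate.
#'
#' The notch deviation is anchored at fixed cardiac phases (zero before
#' `max(time_to_peak_frac, 0.55)`, deepest near phase 0.75, zero at
#' end-cycle), so the recovery-shape factor deforms the curve in a
#' direction largely independent of peak amplitude and peak timing. Its
#' depth is capped at 80% of the local distance between the uniform
#' recovery line and the peak so the peak remains the unique global
#' minimum and the curve returns exactly to 0 at end-cycle.
#'
#' @param amplitude Peak strain in percent, strictly negative.
#' @param time_to_peak_frac Phase of peak strain as a fraction of the
#'   cycle, in (0, 1).
#' @param biphasic_weight Recovery-shape weight in `[0, 1]`.
#' @param heart_rate Heart rate in beats/min (> 0).
#' @param biphasic_depth Notch depth at weight 1, percent strain
#'   (default 5.4).
#'
#' @return Object of class `"curve_template"` with the inputs plus the
#'   derived notch geometry (`notch_left`, `notch_apex`, `notch_depth`)
#'   and `early_diastolic_slope` / `late_diastolic_slope` (percent per
#'   unit phase fraction, positive = recovery toward zero).
#' @export
curve_template <- function(amplitude, time_to_peak_frac, biphasic_weight,
                           heart_rate, biphasic_depth = 5.4) {
  vals <- c(amplitude, time_to_peak_frac, biphasic_weight, heart_rate,
            biphasic_depth)
  if (!all(is.finite(vals)))
    stop("curve template parameters must all be finite", call. = FALSE)
  if (amplitude >= 0)
    stop("amplitude must be negative (strain shortening)", call. = FALSE)
  if (time_to_peak_frac <= 0 || time_to_peak_frac >= 1)
    stop("time_to_peak_frac must lie strictly inside (0, 1)", call. = FALSE)
  if (biphasic_weight < 0 || biphasic_weight > 1)
    stop("biphasic_weight must lie in [0, 1]", call. = FALSE)
  if (heart_rate <= 0)
    stop("heart_rate must be positive", call. = FALSE)
  if (biphasic_depth < 0)
    stop("biphasic_depth must be non-negative", call. = FALSE)
  out <- structure(
    list(amplitude = amplitude,
         time_to_peak_frac = time_to_peak_frac,
         biphasic_weight = biphasic_weight,
         heart_rate = heart_rate,
         biphasic_depth = biphasic_depth),
    class = "curve_template")
  template_geometry(out)
}

# Derive notch geometry and the two diastolic segment slopes; called by
# the constructor and again after peak-phase snapping.
template_geometry <- function(params) {
  tpk <- params$time_to_peak_frac
  A <- params$amplitude
  left <- max(tpk, 0.55)
  apex <- max(0.75, left + 0.25 * (1 - left))
  lin_apex <- A * (1 - (apex - tpk) / (1 - tpk))
  cap <- 0.8 * (lin_apex - A)
  depth <- min(params$biphasic_depth * params$biphasic_weight, cap)
  eps_apex <- lin_apex - depth
  params$notch_left <- left
  params$notch_apex <- apex
  params$notch_depth <- depth
  params$early_diastolic_slope <- (eps_apex - A) / (apex - tpk)
  params$late_diastolic_slope <- -eps_apex / (1 - apex)
  params
}

# Evaluate the noiseless template at phase fractions p in [0, 1].
eval_template <- function(params, p) {
  tpk <- params$time_to_peak_frac
  A <- params$amplitude
  out <- numeric(length(p))
  sys <- p <= tpk
  out[sys] <- A * sin((pi / 2) * p[sys] / tpk)
  out[!sys] <- A * (1 - (p[!sys] - tpk) / (1 - tpk))
  if (params$notch_depth > 0) {
    l <- params$notch_left; ap <- params$notch_apex
    tent <- ifelse(p <= l, 0,
                   ifelse(p <= ap, (p - l) / (ap - l), (1 - p) / (1 - ap)))
    out <- out - params$notch_depth * tent
  }
  out
}

#' Synthesize one noisy strain-time curve from a template
#'
#' Samples the template at `n_samples` uniformly spaced times over one
#' cardiac cycle (duration `60000 / heart_rate` ms) and adds i.i.d.
#' Gaussian measurement noise. The requested time-to-peak is snapped to
#' the nearest sample phase so the noiseless curve attains its specified
#' peak amplitude exactly at a sampled phase (mirroring how a phase-binned
#' cine acquisition quantizes peak timing).
#'
#' @param params A [curve_template()].
#' @param n_samples Number of acquired samples over the cycle (>= 8).
#' @param noise_sd Gaussian noise SD per sample, percent (>= 0).
#' @param subject_id,strain_type,morphology Metadata passed through to the
#'   returned [strain_curve()].
#'
#' @return A [strain_curve()], with attribute `"realized_time_to_peak"`
#'   giving the snapped peak-phase fraction actually used.
#' @export
synthesize_curve <- function(params, n_samples = 30, noise_sd = 0,
                             subject_id = "S1", strain_type = "GCS",
                             morphology = "SLV") {
  stopifnot(inherits(params, "curve_template"))
  if (n_samples < 8) stop("n_samples must be at least 8", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be a non-negative finite number", call. = FALSE)
  p <- seq(0, 1, length.out = n_samples)
  # snap the peak to an interior sample phase
  interior <- p[-c(1L, n_samples)]
  tpk_real <- interior[which.min(abs(interior - params$time_to_peak_frac))]
  snapped <- params
  snapped$time_to_peak_frac <- tpk_real
  snapped <- template_geometry(snapped)
  vals <- eval_template(snapped, p)
  if (noise_sd > 0)
    vals <- vals + stats::rnorm(n_samples, 0, noise_sd)
  cycle_ms <- 60000 / params$heart_rate
  out <- strain_curve(subject_id, strain_type, morphology,
                      times = p * cycle_ms, values = vals,
                      heart_rate = params$heart_rate)
  attr(out, "realized_time_to_peak") <- tpk_real
  out
}

#' Configuration for a synthetic single-ventricle cohort
#'
#' Default parameter values emulate the statistical structure of a
#' Fontan CMR cohort: morphology-specific peak-strain distributions
#' (single left ventricles contract more strongly than single right
#' ventricles), heart-rate variability, hemodynamics (EF generated as a
#' linear function of circumferential-strain amplitude plus noise, volume
#' indices log-normal), and an exponential proportional-hazards composite
#' event model driven by the standardized latent shape factors, with
#' uniform entry-staggered censoring.
#'
#' @param n_slv,n_srv Subjects per morphology stratum.
#' @param amplitude Named list `SLV`/`SRV`, each a named list `GCS`/`GLS`
#'   of `c(mean, sd)` peak strain in percent (negative means).
#' @param heart_rate Named list `SLV`/`SRV` of `c(mean, sd)` in beats/min.
#' @param time_to_peak `c(mean, sd)` of the peak-phase fraction.
#' @param biphasic `c(mean, sd)` of the recovery-shape weight (draws are
#'   clamped to `[0, 1]`).
#' @param biphasic_depth Late-diastolic notch depth at weight 1 (percent
#'   strain), passed to [curve_template()].
#' @param gcs_gls_cor Correlation between a subject's GCS and GLS
#'   amplitude z-scores.
#' @param noise_sd Per-sample curve noise SD, percent.
#' @param hazard_coefficients Named log-hazard increments per 1 SD of each
#'   latent factor (`amplitude`: positive = weaker, less-negative strain
#'   is riskier; `time_to_peak`; `biphasic`: negative = a distinct late
#'   diastolic relaxation slope is protective). Amplitude/time-to-peak/
#'   biphasic z-scores are taken from the subject's GCS curve factors.
#' @param baseline_hazard Baseline event rate, events per year.
#' @param follow_up_max Administrative end of follow-up, years.
#' @param entry_spread Width of the uniform censoring window, years:
#'   censoring times are drawn from
#'   `Uniform(follow_up_max - entry_spread, follow_up_max)` (0 =
#'   administrative censoring at `follow_up_max` exactly).
#' @param n_phases_acquired Nominal acquired samples per cycle.
#' @param irregular_frac Fraction of subjects acquired with fewer phases
#'   (drawn from 20 to `n_phases_acquired - 1`), emulating occasional
#'   protocol deviations.
#' @param seed Integer RNG seed.
#'
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(
    n_slv = 67, n_srv = 55,
    amplitude = list(
      SLV = list(GCS = c(mean = -15.4, sd = 3.0),
                 GLS = c(mean = -13.4, sd = 3.0)),
      SRV = list(GCS = c(mean = -11.1, sd = 2.6),
                 GLS = c(mean = -11.7, sd = 2.8))),
    heart_rate = list(SLV = c(mean = 76, sd = 16),
                      SRV = c(mean = 77, sd = 25)),
    time_to_peak = c(mean = 0.40, sd = 0.095),
    biphasic = c(mean = 0.50, sd = 0.45),
    biphasic_depth = 5.4,
    gcs_gls_cor = 0.5,
    noise_sd = 0.55,
    hazard_coefficients = c(amplitude = 0.7, time_to_peak = 0,
                            biphasic = -0.5),
    baseline_hazard = 0.06,
    follow_up_max = 5,
    entry_spread = 4.5,
    n_phases_acquired = 30,
    irregular_frac = 0.04,
    seed = 20230724) {
  stopifnot(n_slv >= 0, n_srv >= 0,
            time_to_peak[["sd"]] >= 0, biphasic[["sd"]] >= 0,
            noise_sd >= 0, baseline_hazard >= 0,
            follow_up_max > 0, entry_spread >= 0,
            entry_spread <= follow_up_max,
            n_phases_acquired >= 8,
            irregular_frac >= 0, irregular_frac <= 1)
  for (m in c("SLV", "SRV")) for (s in c("GCS", "GLS")) {
    a <- amplitude[[m]][[s]]
    stopifnot(a[["mean"]] < 0, a[["sd"]] >= 0)
  }
  structure(
    list(n_slv = n_slv, n_srv = n_srv, amplitude = amplitude,
         heart_rate = heart_rate, time_to_peak = time_to_peak,
         biphasic = biphasic, biphasic_depth = biphasic_depth,
         gcs_gls_cor = gcs_gls_cor,
         noise_sd = noise_sd, hazard_coefficients = hazard_coefficients,
         baseline_hazard = baseline_hazard, follow_up_max = follow_up_max,
         entry_spread = entry_spread,
         n_phases_acquired = n_phases_acquired,
         irregular_frac = irregular_frac, seed = as.integer(seed)),
    class = "cohort_config")
}

# morphology-specific hemodynamic distributions (cohort-descriptive
# means/SDs and medians/IQRs; volume indices log-normal)
.hemo_defaults <- list(
  SLV = list(age = c(14.4, 4.1), bsa = c(1.5, 0.3), female = 0.522,
             ci = c(3.2, 1.0), ef_intercept = 26.36, ef_slope = -1.6,
             ef_noise_sd = 5.1,
             edvi_meanlog = log(81), edvi_sdlog = 0.267,
             esvi_meanlog = log(39), esvi_sdlog = 0.383),
  SRV = list(age = c(10.6, 4.4), bsa = c(1.2, 0.4), female = 0.345,
             ci = c(3.9, 1.5), ef_intercept = 21.69, ef_slope = -2.1,
             ef_noise_sd = 7.2,
             edvi_meanlog = log(101), edvi_sdlog = 0.295,
             esvi_meanlog = log(54), esvi_sdlog = 0.379))

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic single-ventricle cohort
#'
#' Draws per-subject latent shape factors, synthesizes GCS and GLS
#' strain-time curves from them, generates hemodynamics, and simulates a
#' composite-event history from an exponential proportional-hazards model
#' whose log-hazard is linear in the standardized latent factors. All
#' randomness flows from `config$seed`; repeated calls with the same
#' config are identical.
#'
#' @param config A [cohort_config()].
#'
#' @return List with components:
#'   \describe{
#'     \item{curves}{list of [strain_curve()] (two per subject: GCS, GLS)}
#'     \item{subjects}{data.frame of subject records (hemodynamics,
#'       morphology, follow-up time in years, event indicator)}
#'     \item{latent}{data.frame of the realized latent factors per
#'       (subject, strain type) — the ground truth for recovery tests}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  morph <- rep(c("SLV", "SRV"), c(config$n_slv, config$n_srv))
  n <- length(morph)
  if (n == 0L)
    return(list(curves = list(),
                subjects = empty_subjects(), latent = empty_latent()))
  ids <- sprintf("SV%03d", seq_len(n))

  # latent shape factors: correlated GCS/GLS amplitude z-scores, shared
  # timing and recovery-shape factors per subject
  rho <- config$gcs_gls_cor
  z_shared <- stats::rnorm(n)
  z_gcs <- sqrt(rho) * z_shared + sqrt(1 - rho) * stats::rnorm(n)
  z_gls <- sqrt(rho) * z_shared + sqrt(1 - rho) * stats::rnorm(n)
  tpk <- rnorm_trunc(n, config$time_to_peak[["mean"]],
                     config$time_to_peak[["sd"]], lower = 0.10)
  tpk <- pmin(tpk, 0.85)
  w <- pmin(pmax(stats::rnorm(n, config$biphasic[["mean"]],
                              config$biphasic[["sd"]]), 0), 1)
  hr <- rnorm_trunc(n, 0, 1, lower = -Inf)  # placeholder, filled per morph
  for (m in c("SLV", "SRV")) {
    i <- morph == m
    hr[i] <- rnorm_trunc(sum(i), config$heart_rate[[m]][["mean"]],
                         config$heart_rate[[m]][["sd"]], lower = 40)
  }

  n_phase <- rep(config$n_phases_acquired, n)
  irr <- stats::runif(n) < config$irregular_frac
  if (any(irr))
    n_phase[irr] <- sample(20:(config$n_phases_acquired - 1), sum(irr),
                           replace = TRUE)

  curves <- vector("list", 2L * n)
  latent <- vector("list", 2L * n)
  amp_mat <- matrix(NA_real_, n, 2,
                    dimnames = list(NULL, c("GCS", "GLS")))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in c("GCS", "GLS")) {
      par <- config$amplitude[[morph[i]]][[s]]
      z <- if (s == "GCS") z_gcs[i] else z_gls[i]
      amp <- par[["mean"]] + par[["sd"]] * z
      if (amp > -1) amp <- -1  # keep curves physiologic (nonzero peak)
      amp_mat[i, s] <- amp
      tmpl <- curve_template(amplitude = amp, time_to_peak_frac = tpk[i],
                             biphasic_weight = w[i], heart_rate = hr[i],
                             biphasic_depth = config$biphasic_depth)
      cv <- synthesize_curve(tmpl, n_samples = n_phase[i],
                             noise_sd = config$noise_sd,
                             subject_id = ids[i], strain_type = s,
                             morphology = morph[i])
      k <- k + 1L
      curves[[k]] <- cv
      latent[[k]] <- data.frame(
        subject_id = ids[i], morphology = morph[i], strain_type = s,
        amplitude = amp,
        time_to_peak_frac = attr(cv, "realized_time_to_peak"),
        biphasic_weight = w[i],
        stringsAsFactors = FALSE)
    }
  }
  latent <- do.call(rbind, latent)

  # hemodynamics: EF linear in GCS amplitude (more negative strain ->
  # higher EF), volumes log-normal, others per-morphology normal
  hd <- .hemo_defaults
  age <- ef <- ci <- edvi <- esvi <- bsa <- numeric(n)
  sex <- character(n)
  for (m in c("SLV", "SRV")) {
    i <- morph == m
    d <- hd[[m]]
    age[i] <- rnorm_trunc(sum(i), d$age[1], d$age[2], lower = 3)
    bsa[i] <- rnorm_trunc(sum(i), d$bsa[1], d$bsa[2], lower = 0.4)
    sex[i] <- ifelse(stats::runif(sum(i)) < d$female, "F", "M")
    ef[i] <- d$ef_intercept + d$ef_slope * amp_mat[i, "GCS"] +
      stats::rnorm(sum(i), 0, d$ef_noise_sd)
    ci[i] <- rnorm_trunc(sum(i), d$ci[1], d$ci[2], lower = 0.5)
    edvi[i] <- stats::rlnorm(sum(i), d$edvi_meanlog, d$edvi_sdlog)
    esvi[i] <- stats::rlnorm(sum(i), d$esvi_meanlog, d$esvi_sdlog)
  }
  ef <- pmin(pmax(ef, 5), 80)

  # exponential proportional hazards on standardized GCS latent factors
  hc <- config$hazard_coefficients
  z_amp <- z_gcs                     # amplitude z: higher = weaker strain
  z_tpk <- if (config$time_to_peak[["sd"]] > 0)
    (tpk - config$time_to_peak[["mean"]]) / config$time_to_peak[["sd"]]
  else rep(0, n)
  z_w <- if (config$biphasic[["sd"]] > 0)
    (w - config$biphasic[["mean"]]) / config$biphasic[["sd"]]
  else rep(0, n)
  loghaz <- log(config$baseline_hazard) +
    hc[["amplitude"]] * z_amp + hc[["time_to_peak"]] * z_tpk +
    hc[["biphasic"]] * z_w
  t_event <- if (config$baseline_hazard > 0)
    stats::rexp(n, rate = exp(loghaz)) else rep(Inf, n)
  t_cens <- stats::runif(n, config$follow_up_max - config$entry_spread,
                         config$follow_up_max)
  fu <- pmin(t_event, t_cens)
  ev <- t_event <= t_cens

  subjects <- data.frame(
    subject_id = ids, morphology = morph, age_at_cmr = age, sex = sex,
    bsa = bsa, edvi = edvi, esvi = esvi, ef = ef, ci = ci,
    heart_rate = hr,
    peak_gcs = amp_mat[, "GCS"], peak_gls = amp_mat[, "GLS"],
    follow_up_time = fu, event = ev, stringsAsFactors = FALSE)

  list(curves = curves, subjects = subjects, latent = latent)
}

empty_subjects <- function() {
  data.frame(subject_id = character(0), morphology = character(0),
             age_at_cmr = numeric(0), sex = character(0),
             bsa = numeric(0), edvi = numeric(0), esvi = numeric(0),
             ef = numeric(0), ci = numeric(0), heart_rate = numeric(0),
             peak_gcs = numeric(0), peak_gls = numeric(0),
             follow_up_time = numeric(0), event = logical(0),
             stringsAsFactors = FALSE)
}

empty_latent <- function() {
  data.frame(subject_id = character(0), morphology = character(0),
             strain_type = character(0), amplitude = numeric(0),
             time_to_peak_frac = numeric(0), biphasic_weight = numeric(0),
             stringsAsFactors = FALSE)
}
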