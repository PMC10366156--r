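# Outcome analysis: single-variable Cox proportional hazards, ROC-derived
# cutoffs, Kaplan-Meier estimation and the log-rank test. Model fitting is
# delegated to the survival package (Breslow tie handling).

#' Single-variable Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ x` by partial likelihood with Breslow
#' handling of tied event times and reports the hazard ratio with a Wald
#' 95% confidence interval and p-value.
#'
#' For strain covariates set `per_unit_worsening = TRUE` to report the
#' hazard ratio per 1% *worsening* strain (toward weaker contraction, i.e.
#' smaller magnitude), so that HR > 1 means weaker strain carries more
#' events. Internally the covariate is mapped to `-|x|`: on the native
#' signed (negative) scale this is the identity, on an absolute-value
#' scale it is an explicit sign flip; either way a unit increase of the
#' transformed covariate is 1% of worsening. Requires a covariate of a
#' single sign.
#'
#' @param records data.frame with columns `follow_up_time` (years),
#'   `event` (logical/0-1) and the covariate.
#' @param covariate Name of the covariate column.
#' @param per_unit_worsening Report the HR per 1% worsening strain
#'   (default `FALSE`).
#' @param conf_level Confidence level for the Wald interval.
#'
#' @return Object of class `"cox_result"`: list with `covariate`, `beta`,
#'   `se`, `hr`, `ci95`, `p`, `n`, `n_events`, `flipped`.
#' @export
cox_univariable <- function(records, covariate, per_unit_worsening = FALSE,
                            conf_level = 0.95) {
  x <- records[[covariate]]
  if (is.null(x)) stop("no column '", covariate, "' in records", call. = FALSE)
  time <- records$follow_up_time
  event <- as.integer(records$event)
  ok <- is.finite(x) & is.finite(time)
  x <- x[ok]; time <- time[ok]; event <- event[ok]
  if (sum(event) < 2)
    stop("fewer than 2 events: cannot fit a Cox model for '", covariate,
         "'", call. = FALSE)
  if (stats::var(x) == 0)
    stop("covariate '", covariate, "' has zero variance", call. = FALSE)
  if (per_unit_worsening) {
    if (any(x > 0) && any(x < 0))
      stop("per_unit_worsening needs a single-signed covariate (strain ",
           "on its native negative or absolute scale)", call. = FALSE)
    x <- -abs(x)
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ x,
                         ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  if (any(is.na(fit$coefficients)))
    stop("Cox fit failed to converge for '", covariate, "'", call. = FALSE)
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(covariate = covariate, beta = beta, se = se, hr = exp(beta),
         ci95 = exp(beta + c(-1, 1) * zq * se),
         p = 2 * stats::pnorm(-abs(beta / se)),
         n = length(x), n_events = sum(event),
         flipped = per_unit_worsening),
    class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH: %s  HR %.2f (95%% CI %.2f-%.2f), p = %.3g  [n = %d, events = %d]%s\n",
              x$covariate, x$hr, x$ci95[1], x$ci95[2], x$p, x$n, x$n_events,
              if (x$flipped) " (per unit worsening)" else ""))
  invisible(x)
}

#' ROC-optimal (Youden) cutoff of a covariate for event status
#'
#' Enumerates all candidate thresholds (midpoints between consecutive
#' distinct covariate values) and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1 for classifying event status. The
#' high-risk direction (values above vs below the threshold) is chosen
#' from the sign of the covariate-event association. Ties in J are broken
#' toward the threshold that yields the larger high-risk group.
#'
#' @param records data.frame with `event` and the covariate column.
#' @param covariate Covariate column name.
#'
#' @return List with `threshold`, `direction` (`">="` or `"<="` defining
#'   the high-risk side), `youden_j`, `sensitivity`, `specificity`.
#' @export
roc_cutoff <- function(records, covariate) {
  x <- records[[covariate]]
  if (is.null(x)) stop("no column '", covariate, "' in records", call. = FALSE)
  ev <- as.logical(records$event)
  ok <- is.finite(x)
  x <- x[ok]; ev <- ev[ok]
  if (all(ev) || !any(ev))
    stop("cutoff undefined: need both event and non-event subjects",
         call. = FALSE)
  ux <- sort(unique(x))
  if (length(ux) < 2)
    stop("cutoff undefined: covariate '", covariate,
         "' is identical for all subjects", call. = FALSE)
  # high-risk direction from the association sign
  higher_risk <- mean(x[ev]) >= mean(x[!ev])
  cand <- (ux[-1] + ux[-length(ux)]) / 2
  best <- NULL
  for (thr in cand) {
    high <- if (higher_risk) x >= thr else x <= thr
    sens <- sum(high & ev) / sum(ev)
    spec <- sum(!high & !ev) / sum(!ev)
    j <- sens + spec - 1
    n_high <- sum(high)
    if (is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 && n_high > best$n_high)) {
      best <- list(threshold = thr,
                   direction = if (higher_risk) ">=" else "<=",
                   youden_j = j, sensitivity = sens, specificity = spec,
                   n_high = n_high)
    }
  }
  best[c("threshold", "direction", "youden_j", "sensitivity",
         "specificity")]
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator; censored subjects leave the risk set after
#' their time.
#'
#' @param records data.frame with `follow_up_time` and `event`.
#' @param group Vector of group labels, one per record (default: a single
#'   group).
#'
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`, sorted by group then time; groups with no subjects are
#'   absent.
#' @export
kaplan_meier <- function(records, group = NULL) {
  time <- records$follow_up_time
  event <- as.integer(records$event)
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)
  out <- lapply(split(seq_along(time), group), function(idx) {
    if (length(idx) == 0L) return(NULL)
    fit <- survival::survfit(
      survival::Surv(time[idx], event[idx]) ~ 1, conf.type = "none")
    data.frame(group = group[idx[1]], time = fit$time,
               n_risk = fit$n.risk, n_event = fit$n.event,
               survival = fit$surv, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-group log-rank test
#'
#' Compares survival between two groups with the standard log-rank
#' statistic (observed vs expected events summed over distinct event
#' times), referred to chi-square with 1 df.
#'
#' @param records data.frame with `follow_up_time` and `event`.
#' @param group Two-level group vector, one entry per record.
#' @return List with `chi_square`, `p`, `n` per group, `observed`,
#'   `expected` per group.
#' @export
logrank_test <- function(records, group) {
  time <- records$follow_up_time
  event <- as.integer(records$event)
  group <- as.character(group)
  tab <- table(group)
  if (length(tab) != 2 || any(tab == 0))
    stop("log-rank test needs exactly two non-empty groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  chisq <- unname(sd$chisq)
  list(chi_square = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = as.vector(sd$n), observed = as.vector(sd$obs),
       expected = as.vector(sd$exp))
}

#' First-event-wins coding of a composite clinical outcome
#'
#' Collapses a table of dated clinical events into one (time, event) pair
#' per subject: follow-up ends at the first event whose type is in the
#' accepted composite list; subjects with no accepted event are censored
#' at their follow-up end. Event types outside the composite are ignored.
#'
#' @param event_table data.frame with `subject_id`, `type`, `time`
#'   (years from CMR); may have zero rows or several rows per subject.
#' @param subjects data.frame with `subject_id` and `censor_time` (end of
#'   study follow-up, years).
#' @param event_types Character vector of types in the composite; default
#'   death, transplant, plastic bronchitis, protein-losing enteropathy.
#'
#' @return data.frame `subject_id`, `follow_up_time`, `event`.
#' @export
composite_outcome <- function(event_table, subjects,
                              event_types = c("death", "transplant",
                                              "plastic_bronchitis",
                                              "protein_losing_enteropathy")) {
  stopifnot(all(c("subject_id", "censor_time") %in% names(subjects)))
  out <- data.frame(subject_id = subjects$subject_id,
                    follow_up_time = subjects$censor_time,
                    event = FALSE, stringsAsFactors = FALSE)
  if (nrow(event_table) > 0) {
    keep <- event_table$type %in% event_types
    ev <- event_table[keep, , drop = FALSE]
    if (nrow(ev) > 0) {
      first <- stats::aggregate(time ~ subject_id, data = ev, FUN = min)
      m <- match(first$subject_id, out$subject_id)
      bad <- is.na(m)
      if (any(bad))
        stop("event table references unknown subject(s): ",
             paste(first$subject_id[bad], collapse = ", "), call. = FALSE)
      sooner <- first$time <= out$follow_up_time[m]
      out$follow_up_time[m[sooner]] <- first$time[sooner]
      out$event[m[sooner]] <- TRUE
    }
  }
  out
}
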