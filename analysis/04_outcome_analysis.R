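#!/usr/bin/env Rscript
# Stage 4 — outcome analysis.
#
# Single-variable Cox proportional-hazards models per morphology group
# over the CMR hemodynamics, peak strain (per 1% worsening) and the
# retained shape scores; for covariates associated with events, derives
# the Youden-optimal cutoff, dichotomizes, and compares freedom from
# events by Kaplan-Meier and the log-rank test. Writes tidy tables under
# results/survival/ and prints a forest-style summary.

suppressMessages(library(strainshape))

subjects <- read.csv("results/cohort/subjects.csv")
scores <- read.csv("results/pca/scores.csv")
out_dir <- "results/survival"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# merge retained per-stratum scores into the subject table
for (st in c("GCS", "GLS")) for (mo in c("SLV", "SRV")) {
  sc <- scores[scores$strain_type == st & scores$morphology == mo, ]
  for (col in grep("^score_pc", names(sc), value = TRUE)) {
    dest <- sprintf("%s_%s", tolower(st), sub("score_", "", col))
    subjects[[dest]] <- NA_real_
    subjects[[dest]][match(sc$subject_id, subjects$subject_id)] <- sc[[col]]
  }
}

cox_rows <- list(); km_rows <- list(); cut_rows <- list()
for (mo in c("SLV", "SRV")) {
  sub <- subjects[subjects$morphology == mo, ]
  if (sum(sub$event) < 2) { message(mo, ": fewer than 2 events, skipped"); next }
  covs <- c("edvi", "esvi", "ef", "ci", "peak_gcs", "peak_gls",
            grep("^(gcs|gls)_pc", names(sub), value = TRUE))
  for (cv in covs) {
    flip <- cv %in% c("peak_gcs", "peak_gls")
    fit <- tryCatch(cox_univariable(sub, cv, per_unit_worsening = flip),
                    error = function(e) NULL)
    if (is.null(fit)) next
    cox_rows[[paste(mo, cv)]] <- data.frame(
      morphology = mo, covariate = cv, n = fit$n, events = fit$n_events,
      hr = fit$hr, ci_low = fit$ci95[1], ci_high = fit$ci95[2], p = fit$p,
      per_unit_worsening = flip)
    if (fit$p <= 0.05) {
      cut <- roc_cutoff(sub, cv)
      grp <- ifelse(
        (if (cut$direction == ">=") sub[[cv]] >= cut$threshold
         else sub[[cv]] <= cut$threshold), "high_risk", "low_risk")
      lr <- logrank_test(sub, grp)
      km <- kaplan_meier(sub, grp)
      km$morphology <- mo; km$covariate <- cv
      km_rows[[paste(mo, cv)]] <- km
      cut_rows[[paste(mo, cv)]] <- data.frame(
        morphology = mo, covariate = cv, threshold = cut$threshold,
        direction = cut$direction, youden_j = cut$youden_j,
        logrank_chisq = lr$chi_square, logrank_p = lr$p)
    }
  }
}

cox_tab <- do.call(rbind, cox_rows); rownames(cox_tab) <- NULL
write.csv(cox_tab, file.path(out_dir, "cox_univariable.csv"), row.names = FALSE)
if (length(cut_rows)) {
  cuts <- do.call(rbind, cut_rows); rownames(cuts) <- NULL
  write.csv(cuts, file.path(out_dir, "roc_cutoffs_logrank.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, km_rows), file.path(out_dir, "kaplan_meier.csv"),
            row.names = FALSE)
}

message("single-variable Cox proportional hazards (HR per unit; strain per 1% worsening):")
for (i in seq_len(nrow(cox_tab))) {
  r <- cox_tab[i, ]
  message(sprintf("  %-4s %-12s HR %5.2f (%4.2f-%5.2f)  p = %.3f%s",
                  r$morphology, r$covariate, r$hr, r$ci_low, r$ci_high,
                  r$p, ifelse(r$p <= 0.05, " *", "")))
}
if (length(cut_rows))
  for (i in seq_len(nrow(cuts))) {
    r <- cuts[i, ]
    message(sprintf(
      "  %-4s %-12s cutoff %s %.2f: log-rank chi2 %.2f, p = %.3f",
      r$morphology, r$covariate, r$direction, r$threshold,
      r$logrank_chisq, r$logrank_p))
  }
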