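#!/usr/bin/env Rscript
# Stage 5 — descriptive comparisons and strain-hemodynamics associations.
#
# Compares the two morphology groups variable by variable (t-test or
# Mann-Whitney for continuous measures after normality triage; skewed
# positive variables are log-transformed), then quantifies the
# correlation and regression slope of EF and the volume indices against
# peak strain per morphology. Writes results/associations/.

suppressMessages(library(strainshape))

subjects <- read.csv("results/cohort/subjects.csv")
out_dir <- "results/associations"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

slv <- subjects[subjects$morphology == "SLV", ]
srv <- subjects[subjects$morphology == "SRV", ]

cont_vars <- c("age_at_cmr", "bsa", "edvi", "esvi", "ef", "ci",
               "heart_rate", "peak_gcs", "peak_gls")
cmp_rows <- lapply(cont_vars, function(v) {
  res <- compare_groups(slv[[v]], srv[[v]])
  fmt <- function(s) if (res$test == "t")
    sprintf("%.1f +/- %.1f", s[["mean"]], s[["sd"]])
  else sprintf("%.1f (%.1f-%.1f)", s[["median"]], s[["q1"]], s[["q3"]])
  data.frame(variable = v, slv = fmt(res$summary_a),
             srv = fmt(res$summary_b), test = res$test, p = res$p)
})
sex <- compare_groups(slv$sex, srv$sex, kind = "categorical")
cmp_rows[[length(cmp_rows) + 1]] <- data.frame(
  variable = "sex", slv = sprintf("%d F", sex$summary_a[["F"]]),
  srv = sprintf("%d F", sex$summary_b[["F"]]), test = sex$test, p = sex$p)
cmp <- do.call(rbind, cmp_rows)
write.csv(cmp, file.path(out_dir, "group_comparison.csv"), row.names = FALSE)
message("SLV vs SRV comparison:")
for (i in seq_len(nrow(cmp)))
  message(sprintf("  %-10s %-18s vs %-18s %-12s p = %.3f", cmp$variable[i],
                  cmp$slv[i], cmp$srv[i], cmp$test[i], cmp$p[i]))

# strain vs EF / volume indices; volume indices are log-transformed when
# the normality triage flags them skewed
assoc_rows <- list()
for (mo in c("SLV", "SRV")) {
  sub <- subjects[subjects$morphology == mo, ]
  for (pair in list(c("peak_gcs", "ef"), c("peak_gls", "ef"),
                    c("peak_gcs", "edvi"), c("peak_gls", "edvi"),
                    c("peak_gcs", "esvi"), c("peak_gls", "esvi"))) {
    y <- sub[[pair[2]]]
    ylab <- pair[2]
    if (pair[2] %in% c("edvi", "esvi")) {
      tr <- check_normality_and_transform(y)
      if (tr$transformed) { y <- tr$values; ylab <- paste0("log_", pair[2]) }
    }
    a <- correlate_with_slope(sub[[pair[1]]], y)
    assoc_rows[[paste(mo, pair[1], pair[2])]] <- data.frame(
      morphology = mo, x = pair[1], y = ylab, r = a$r, p = a$p,
      slope = a$slope, n = a$n)
  }
}
assoc <- do.call(rbind, assoc_rows); rownames(assoc) <- NULL
write.csv(assoc, file.path(out_dir, "strain_associations.csv"),
          row.names = FALSE)
message("strain-hemodynamics associations (Pearson r; OLS slope dY/dX):")
for (i in seq_len(nrow(assoc)))
  message(sprintf("  %-4s %s ~ %-9s r = %5.2f  slope = %6.2f  p = %.4f",
                  assoc$morphology[i], assoc$y[i], assoc$x[i],
                  assoc$r[i], assoc$slope[i], assoc$p[i]))
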