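#!/usr/bin/env Rscript
# Stage 2 — temporal normalization and phase resampling.
#
# Reads the simulated curves, rescales each subject's time axis to the
# stratum-average cardiac-cycle period (heart-rate adjustment), resamples
# every curve to 30 phases, and writes one subjects x phases matrix per
# (strain type x morphology) stratum to results/matrices/.

suppressMessages(library(strainshape))

curves <- read_curves("results/cohort/curves.csv")
out_dir <- "results/matrices"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (st in c("GCS", "GLS")) for (mo in c("SLV", "SRV")) {
  m <- build_curve_matrix(curves, st, mo, n_phases = 30)
  if (m$empty) { message("stratum ", st, "/", mo, " empty; skipped"); next }
  write_curve_matrix(m, file.path(out_dir, sprintf("%s_%s.csv", st, mo)))
  message(sprintf("%s/%s: %d curves -> %d x %d matrix (mean cycle %.0f ms)",
                  st, mo, nrow(m$matrix), nrow(m$matrix), m$n_phases,
                  m$cohort_mean_cycle_ms))
}
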