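# shared fixture builders (all synthetic, generated at test time)

# a plain triangular strain curve with known geometry
make_triangle_curve <- function(subject_id = "T1", heart_rate = 60,
                                n = 11, peak = -10, peak_at = 6,
                                strain_type = "GCS", morphology = "SLV") {
  cycle <- 60000 / heart_rate
  times <- seq(0, cycle, length.out = n)
  up <- seq(0, peak, length.out = peak_at)
  down <- seq(peak, 0, length.out = n - peak_at + 1)[-1]
  strain_curve(subject_id, strain_type, morphology,
               times = times, values = c(up, down),
               heart_rate = heart_rate)
}

# small default-structure cohort (fast; used by several suites)
small_cohort <- function(seed = 11, n_slv = 40, n_srv = 40, ...) {
  generate_cohort(cohort_config(n_slv = n_slv, n_srv = n_srv,
                                seed = seed, ...))
}

# survival records data.frame from raw vectors
surv_records <- function(time, event, ...) {
  data.frame(follow_up_time = time, event = event, ...)
}
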