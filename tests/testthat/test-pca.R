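# Shape-model fitting, component selection, scores, reconstruction and
# mode characterization.

test_that("a rank-1 construction is recovered as a single dominant component", {
  set.seed(12)
  p <- rnorm(30); p <- p / sqrt(sum(p^2))
  mu <- -10 * sin(seq(0, pi, length.out = 30))
  a <- rnorm(25, sd = 3)
  x <- t(vapply(a, function(ai) mu + ai * p, numeric(30)))
  model <- fit_shape_model(x)
  expect_gt(abs(sum(model$components[, 1] * p)), 1 - 1e-10)
  expect_equal(model$explained_fraction[1], 1)
  expect_equal(model$mean_curve, colMeans(x))
})

test_that("degenerate and rank-limited matrices are handled", {
  x <- matrix(rep(c(1, -5, 2), each = 4), nrow = 4)
  expect_error(fit_shape_model(x), "degenerate")
  expect_error(fit_shape_model(x[1, , drop = FALSE]), "at least 2")
  set.seed(3)
  two <- matrix(rnorm(60), nrow = 2)
  m2 <- fit_shape_model(two)
  expect_length(m2$eigenvalues, 1)  # rank bound n - 1
})

test_that("eigenvalues match an independent SVD of the centered matrix", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(8 * 12), nrow = 8)
    model <- fit_shape_model(x)
    xc <- sweep(x, 2, colMeans(x))
    lam_svd <- svd(xc)$d^2 / (nrow(x) - 1)
    lam_svd <- lam_svd[lam_svd > 1e-12 * lam_svd[1]]
    expect_equal(model$eigenvalues, lam_svd, tolerance = 1e-10)
  }
})

test_that("components are orthonormal and complete", {
  coh <- small_cohort(seed = 7, n_slv = 40, n_srv = 0)
  m <- build_curve_matrix(coh$curves, "GCS", "SLV")
  model <- fit_shape_model(m)
  g <- crossprod(model$components)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-10)
  # completeness: mean + sum of score_n * p_n restores each row
  sc <- compute_scores(model, m)$scores
  recon <- sweep(sc %*% t(model$components), 2, model$mean_curve, "+")
  expect_lt(max(abs(recon - m$matrix)), 1e-8)
})

test_that("component retention returns the smallest k passing the threshold", {
  fake <- structure(list(explained_fraction = c(0.55, 0.25, 0.12, 0.05,
                                                0.03)),
                    class = "shape_model")
  expect_equal(select_components(fake, 0.90), 3)
  expect_equal(select_components(
    structure(list(explained_fraction = 1), class = "shape_model"), 0.90), 1)
  expect_equal(select_components(fake, 0.50), 1)
  # the threshold is strict: a cumulative fraction equal to it not enough
  expect_equal(select_components(fake, 0.55), 2)
})

test_that("scores follow the centered dot-product convention", {
  coh <- small_cohort(seed = 17, n_slv = 20, n_srv = 0)
  m <- build_curve_matrix(coh$curves, "GLS", "SLV")
  model <- fit_shape_model(m)
  ss <- compute_scores(model, m)
  # brute-force oracle: explicit sum over phases
  for (i in c(1, 7, 20)) for (n in 1:3) {
    brute <- 0
    for (k in 1:30)
      brute <- brute + model$components[k, n] *
        (m$matrix[i, k] - model$mean_curve[k])
    expect_equal(unname(ss$scores[i, n]), unname(brute), tolerance = 1e-10)
  }
  # column means zero, variance equals the eigenvalue
  expect_lt(max(abs(colMeans(ss$scores))), 1e-10)
  expect_equal(unname(apply(ss$scores, 2, var)),
               model$eigenvalues, tolerance = 1e-8)
  # the mean patient scores zero on every component
  mean_scores <- compute_scores(
    model, matrix(model$mean_curve, nrow = 1))$scores
  expect_lt(max(abs(mean_scores)), 1e-10)
  # raw convention differs by the constant p_n . mean_curve
  raw <- compute_scores(model, m, centered = FALSE)
  offset <- drop(model$mean_curve %*% model$components)
  expect_equal(sweep(raw$scores, 2, offset), ss$scores,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(compute_scores(model, m$matrix[, 1:10]), "phases")
})

test_that("mode reconstruction is linear and symmetric about the mean curve", {
  coh <- small_cohort(seed = 23, n_slv = 15, n_srv = 0)
  m <- build_curve_matrix(coh$curves, "GCS", "SLV")
  model <- fit_shape_model(m)
  expect_equal(reconstruct_mode(model, 1, 0), model$mean_curve)
  c1 <- 2 * sqrt(model$eigenvalues[2])
  hi <- reconstruct_mode(model, 2, c1)
  lo <- reconstruct_mode(model, 2, -c1)
  expect_equal(hi + lo, 2 * model$mean_curve, tolerance = 1e-10)
  expect_error(reconstruct_mode(model, 99, 1), "out of range")
})

test_that("single-factor cohorts concentrate variance on a matching first mode", {
  # amplitude-only variation
  amp_only <- generate_cohort(cohort_config(
    n_slv = 200, n_srv = 0, seed = 61,
    time_to_peak = c(mean = 0.4, sd = 0),
    biphasic = c(mean = 0.5, sd = 0), noise_sd = 0.05))
  m <- build_curve_matrix(amp_only$curves, "GCS", "SLV")
  model <- fit_shape_model(m)
  expect_gt(model$explained_fraction[1], 0.95)
  sc <- compute_scores(model, m)$scores
  lat <- amp_only$latent[amp_only$latent$strain_type == "GCS", ]
  expect_gt(abs(cor(sc[, 1], lat$amplitude)), 0.95)
  ch <- characterize_modes(model, n_modes = 1)
  expect_gt(abs(ch$delta_peak), 2)
  expect_lte(abs(ch$delta_time_to_peak), 1)

  # time-shift-only variation
  tpk_only <- generate_cohort(cohort_config(
    n_slv = 200, n_srv = 0, seed = 62,
    amplitude = list(
      SLV = list(GCS = c(mean = -15.4, sd = 0), GLS = c(mean = -13.4, sd = 0)),
      SRV = list(GCS = c(mean = -11.1, sd = 0), GLS = c(mean = -11.7, sd = 0))),
    biphasic = c(mean = 0.5, sd = 0), noise_sd = 0.05))
  m2 <- build_curve_matrix(tpk_only$curves, "GCS", "SLV")
  model2 <- fit_shape_model(m2)
  ch2 <- characterize_modes(model2, n_modes = 1)
  expect_gte(abs(ch2$delta_time_to_peak), 1)
  expect_lt(abs(ch2$delta_peak), 1)
  sc2 <- compute_scores(model2, m2)$scores
  lat2 <- tpk_only$latent[tpk_only$latent$strain_type == "GCS", ]
  expect_gt(abs(cor(sc2[, 1], lat2$time_to_peak_frac,
                    method = "spearman")), 0.95)
})

test_that("three-factor cohorts are labelled amplitude / time-to-peak / slope in order", {
  # stochastic property: evaluated as the mean over a few seeded cohorts
  cors <- matrix(0, 0, 3)
  for (seed in 1:3) {
    coh <- generate_cohort(cohort_config(n_slv = 200, n_srv = 0,
                                         seed = seed, noise_sd = 0.05))
    m <- build_curve_matrix(coh$curves, "GCS", "SLV")
    model <- fit_shape_model(m)
    ch <- characterize_modes(model)
    expect_identical(ch$label, c("amplitude", "time_to_peak",
                                 "post_systolic_slope"))
    sc <- compute_scores(model, m)$scores
    lat <- coh$latent[coh$latent$strain_type == "GCS", ]
    cors <- rbind(cors, abs(c(
      cor(sc[, 1], lat$amplitude, method = "spearman"),
      cor(sc[, 2], lat$time_to_peak_frac, method = "spearman"),
      cor(sc[, 3], lat$biphasic_weight, method = "spearman"))))
  }
  expect_true(all(colMeans(cors) > 0.8))
  expect_error(characterize_modes(model, n_modes = 40), "components")
})
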