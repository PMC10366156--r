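# Cox regression, ROC cutoffs, Kaplan-Meier and log-rank, cross-checked
# against independently coded oracles.

test_that("Cox beta matches a grid-search maximization of the partial likelihood", {
  # events on both covariate levels so the partial-likelihood maximum is
  # finite (a covariate that separates the late risk sets has an
  # infinite MLE)
  rec <- surv_records(time = c(1, 2, 3, 4), event = c(1, 1, 1, 0),
                      x = c(0, 1, 0, 1))
  fit <- cox_univariable(rec, "x")
  # independent oracle: hand-written Breslow partial log-likelihood,
  # maximized by golden-section search
  pll <- function(b) {
    risk <- exp(b * rec$x)
    ll <- 0
    for (i in which(rec$event == 1)) {
      at_risk <- rec$follow_up_time >= rec$follow_up_time[i]
      ll <- ll + b * rec$x[i] - log(sum(risk[at_risk]))
    }
    ll
  }
  opt <- optimize(pll, c(-20, 20), maximum = TRUE, tol = 1e-9)
  expect_equal(fit$beta, opt$maximum, tolerance = 1e-4)
  expect_true(fit$ci95[1] < fit$hr && fit$hr < fit$ci95[2])
})

test_that("a covariate independent of outcome gives beta near zero", {
  set.seed(5)
  n <- 500
  t_ev <- rexp(n, 0.2); cns <- runif(n, 0, 6)
  rec <- surv_records(time = pmin(t_ev, cns), event = t_ev <= cns,
                      x = rnorm(n))
  fit <- cox_univariable(rec, "x")
  expect_lt(abs(fit$beta), 3 * fit$se)
})

test_that("a true hazard ratio of 2 is recovered from a simulated cohort", {
  set.seed(9)
  n <- 500
  x <- rnorm(n)
  t_ev <- rexp(n, rate = 0.15 * exp(log(2) * x))
  cns <- runif(n, 0, 6)
  rec <- surv_records(time = pmin(t_ev, cns), event = t_ev <= cns, x = x)
  fit <- cox_univariable(rec, "x")
  expect_gt(mean(rec$event), 0.25)
  expect_true(fit$hr > 1.6 && fit$hr < 2.5)
  expect_true(fit$ci95[1] < 2 && 2 < fit$ci95[2])
})

test_that("Cox beta is invariant to covariate shift, and the worsening convention is scale-consistent", {
  set.seed(13)
  n <- 120
  x <- -abs(rnorm(n, -14, 3))  # strain on its native negative scale
  t_ev <- rexp(n, 0.1 * exp(0.2 * x + 2.8)); cns <- runif(n, 0, 5)
  rec <- surv_records(time = pmin(t_ev, cns), event = t_ev <= cns, x = x)
  rec$x_shift <- rec$x + 100
  f1 <- cox_univariable(rec, "x")
  f2 <- cox_univariable(rec, "x_shift")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  # on the signed scale a unit increase already is 1% worsening
  f3 <- cox_univariable(rec, "x", per_unit_worsening = TRUE)
  expect_equal(f3$beta, f1$beta, tolerance = 1e-8)
  # on the absolute-value scale the explicit sign flip restores it
  rec$x_abs <- abs(rec$x)
  f4 <- cox_univariable(rec, "x_abs", per_unit_worsening = TRUE)
  expect_equal(f4$beta, f1$beta, tolerance = 1e-8)
  expect_error(cox_univariable(
    surv_records(time = rec$follow_up_time, event = rec$event,
                 x = rnorm(n)), "x", per_unit_worsening = TRUE),
    "single-signed")
})

test_that("Cox preconditions are enforced", {
  rec <- surv_records(time = 1:5, event = c(1, 0, 0, 0, 0), x = rnorm(5))
  expect_error(cox_univariable(rec, "x"), "fewer than 2 events")
  rec2 <- surv_records(time = 1:5, event = c(1, 1, 1, 0, 0),
                       x = rep(2, 5))
  expect_error(cox_univariable(rec2, "x"), "zero variance")
  expect_error(cox_univariable(rec2, "nope"), "no column")
})

test_that("ROC cutoff maximizes Youden's J, enumerated exhaustively", {
  # perfect separation: midpoint of the gap, J = 1
  rec <- surv_records(time = rep(1, 8), event = c(rep(FALSE, 4), rep(TRUE, 4)),
                      x = c(1, 2, 3, 4, 8, 9, 10, 11))
  cut <- roc_cutoff(rec, "x")
  expect_equal(cut$threshold, 6)
  expect_equal(cut$youden_j, 1)
  expect_equal(cut$direction, ">=")

  # overlapping toy data vs independent enumeration over all midpoints
  rec2 <- surv_records(
    time = rep(1, 8),
    event = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    x = c(2, 3, 3.5, 4, 5, 6, 7, 9))
  cut2 <- roc_cutoff(rec2, "x")
  ux <- sort(unique(rec2$x))
  cands <- (ux[-1] + ux[-length(ux)]) / 2
  js <- vapply(cands, function(thr) {
    sens <- sum(rec2$x >= thr & rec2$event) / sum(rec2$event)
    spec <- sum(rec2$x < thr & !rec2$event) / sum(!rec2$event)
    sens + spec - 1
  }, numeric(1))
  expect_equal(cut2$youden_j, max(js))
  expect_true(cut2$threshold %in% cands[js == max(js)])
  # tie-break: the largest qualifying high-risk group
  expect_equal(cut2$threshold, min(cands[js == max(js)]))

  expect_error(roc_cutoff(surv_records(time = 1:4, event = rep(TRUE, 4),
                                       x = 1:4), "x"), "undefined")
  expect_error(roc_cutoff(surv_records(time = 1:4,
                                       event = c(TRUE, TRUE, FALSE, FALSE),
                                       x = rep(1, 4)), "x"), "identical")
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  rec <- surv_records(time = c(1, 1.5, 2), event = c(TRUE, FALSE, TRUE))
  km <- kaplan_meier(rec)
  # at t=1: 3 at risk, 1 event -> S = 2/3; censor at 1.5; at t=2: 1 at
  # risk, 1 event -> S = 0
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 2], 0)

  none <- kaplan_meier(surv_records(time = c(2, 3, 4),
                                    event = rep(FALSE, 3)))
  expect_true(all(none$survival == 1))

  all_at_once <- kaplan_meier(surv_records(time = rep(2, 5),
                                           event = rep(TRUE, 5)))
  expect_equal(nrow(all_at_once[all_at_once$n_event > 0, ]), 1)
  expect_equal(all_at_once$survival[all_at_once$time == 2], 0)
})

test_that("without censoring the KM estimate equals the empirical survival function", {
  set.seed(2)
  tm <- round(rexp(40, 0.3), 2)
  km <- kaplan_meier(surv_records(time = tm, event = rep(TRUE, 40)))
  for (i in seq_len(nrow(km)))
    expect_equal(km$survival[i], mean(tm > km$time[i]))
})

test_that("log-rank statistic matches the direct observed-vs-expected sum", {
  rec <- surv_records(
    time = c(1, 2, 3, 4, 5, 2.5, 3.5, 4.5, 6, 7),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  grp <- rep(c("a", "b"), each = 5)
  res <- logrank_test(rec, grp)
  # independent oracle: O - E and hypergeometric variance per event time
  tm <- rec$follow_up_time
  ev_times <- sort(unique(tm[rec$event]))
  o_minus_e <- 0; v <- 0
  for (tt in ev_times) {
    at <- tm >= tt
    d <- sum(rec$event & tm == tt)
    n_all <- sum(at); n_a <- sum(at & grp == "a")
    d_a <- sum(rec$event & tm == tt & grp == "a")
    o_minus_e <- o_minus_e + d_a - d * n_a / n_all
    if (n_all > 1)
      v <- v + d * (n_a / n_all) * (1 - n_a / n_all) *
        (n_all - d) / (n_all - 1)
  }
  expect_equal(res$chi_square, o_minus_e^2 / v, tolerance = 1e-10)
  # symmetry in group labels
  flip <- logrank_test(rec, rev(grp))
  expect_equal(flip$chi_square, res$chi_square, tolerance = 1e-10)
})

test_that("identical groups give a log-rank statistic of zero", {
  base <- surv_records(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  rec <- rbind(base, base)
  res <- logrank_test(rec, rep(c("a", "b"), each = 4))
  expect_equal(res$chi_square, 0, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-10)
  expect_error(logrank_test(base, rep("a", 4)), "two non-empty")
})

test_that("composite outcome coding is first-event-wins over the accepted types", {
  subjects <- data.frame(subject_id = c("s1", "s2", "s3", "s4"),
                         censor_time = c(5, 5, 5, 5))
  events <- data.frame(
    subject_id = c("s1", "s1", "s2", "s3"),
    type = c("plastic_bronchitis", "death", "transplant_evaluation",
             "transplant"),
    time = c(2, 3, 1, 4))
  out <- composite_outcome(events, subjects)
  expect_equal(out$follow_up_time, c(2, 5, 4, 5))
  expect_equal(out$event, c(TRUE, FALSE, TRUE, FALSE))
  # widening the accepted list pulls in the referral event
  out2 <- composite_outcome(events, subjects,
                            event_types = c("death", "transplant",
                                            "transplant_evaluation"))
  expect_equal(out2$follow_up_time[2], 1)
  expect_true(out2$event[2])
  expect_error(composite_outcome(
    data.frame(subject_id = "zz", type = "death", time = 1), subjects),
    "unknown")
})
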