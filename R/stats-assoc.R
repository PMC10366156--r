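# Descriptive and associative statistics: normality checks with log
# transformation of skewed variables, two-group comparisons, and
# correlation / regression-slope analyses between strain and volumetric
# indices.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness and kurtosis into the K^2
#' omnibus statistic, referred to chi-square with 2 df. Uses the
#' D'Agostino transformation for skewness and the Anscombe-Glynn
#' transformation for kurtosis.
#'
#' @param x Numeric vector, n >= 20 (the kurtosis approximation degrades
#'   below that).
#' @return List with `statistic` (K^2), `p`, `z_skewness`, `z_kurtosis`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20)
    stop("D'Agostino-Pearson test needs n >= 20, got ", n, call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  m <- function(k) mean((x - mean(x))^k)
  b1 <- m(3) / m(2)^1.5
  b2 <- m(4) / m(2)^2

  # skewness (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2,
       p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2)
}

#' Normality check with optional natural-log transformation
#'
#' Runs three normality tests — D'Agostino-Pearson omnibus, Shapiro-Wilk,
#' and the Lilliefors (Kolmogorov-Smirnov type) test — and flags the
#' variable non-normal when at least `majority` of them reject at `alpha`.
#' Skewed strictly-positive variables are returned natural-log
#' transformed, with the transformation recorded.
#'
#' @param values Numeric vector, n >= 8.
#' @param alpha Per-test significance level (default 0.05).
#' @param majority Number of rejecting tests needed to call the variable
#'   non-normal (default 2 of 3).
#' @param transform Attempt the log transform of non-normal variables
#'   (default `TRUE`).
#'
#' @return List with `is_normal`, `p_values` (named, one per test),
#'   `values` (possibly transformed), `transformed` flag.
#' @export
check_normality_and_transform <- function(values, alpha = 0.05,
                                          majority = 2, transform = TRUE) {
  x <- values[is.finite(values)]
  if (length(x) < 8)
    stop("normality check needs n >= 8", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  p <- c(dagostino_pearson = dagostino_pearson_test(x)$p,
         shapiro_wilk = stats::shapiro.test(x)$p.value,
         kolmogorov_smirnov = nortest::lillie.test(x)$p.value)
  is_normal <- sum(p < alpha) < majority
  out <- list(is_normal = is_normal, p_values = p, values = x,
              transformed = FALSE)
  if (!is_normal && transform) {
    if (any(x <= 0))
      stop("log transform requested for a variable with non-positive ",
           "values", call. = FALSE)
    out$values <- log(x)
    out$transformed <- TRUE
  }
  out
}

#' Two-group comparison dictated by the nature of the variable
#'
#' Continuous variables: unpaired t-test with mean +/- SD summaries when
#' both groups look normal, Mann-Whitney with median (IQR) otherwise.
#' Categorical variables: chi-square, switching to Fisher's exact test
#' when any expected cell count is below 5.
#'
#' @param a,b The two groups: numeric vectors (continuous) or vectors of
#'   category labels (categorical).
#' @param kind `"continuous"` or `"categorical"`.
#' @param force_test Override the automatic choice: one of `"t"`,
#'   `"mann_whitney"`, `"chi_square"`, `"fisher"`.
#'
#' @return List with `test`, `p`, `summary_a`, `summary_b` (named numeric
#'   summaries for continuous; counts for categorical).
#' @export
compare_groups <- function(a, b, kind = c("continuous", "categorical"),
                           force_test = NULL) {
  kind <- match.arg(kind)
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (kind == "continuous") {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    normal <- if (is.null(force_test)) {
      both_checkable <- length(a) >= 20 && length(b) >= 20
      if (both_checkable)
        check_normality_and_transform(a, transform = FALSE)$is_normal &&
          check_normality_and_transform(b, transform = FALSE)$is_normal
      else TRUE
    } else force_test == "t"
    if (normal) {
      p <- if (stats::sd(a) == 0 && stats::sd(b) == 0 &&
               mean(a) == mean(b)) 1
      else stats::t.test(a, b, var.equal = FALSE)$p.value
      list(test = "t", p = p,
           summary_a = c(mean = mean(a), sd = stats::sd(a)),
           summary_b = c(mean = mean(b), sd = stats::sd(b)))
    } else {
      p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      qa <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
      qb <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
      list(test = "mann_whitney", p = p,
           summary_a = c(median = qa[2], q1 = qa[1], q3 = qa[3]),
           summary_b = c(median = qb[2], q1 = qb[1], q3 = qb[3]))
    }
  } else {
    lev <- sort(unique(c(as.character(a), as.character(b))))
    tab <- rbind(table(factor(a, levels = lev)),
                 table(factor(b, levels = lev)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_fisher <- if (is.null(force_test)) any(expected < 5)
    else force_test == "fisher"
    if (use_fisher) {
      list(test = "fisher", p = stats::fisher.test(tab)$p.value,
           summary_a = tab[1, ], summary_b = tab[2, ])
    } else {
      list(test = "chi_square",
           p = suppressWarnings(stats::chisq.test(tab,
                                                  correct = FALSE)$p.value),
           summary_a = tab[1, ], summary_b = tab[2, ])
    }
  }
}

#' Pearson correlation with ordinary least-squares slope
#'
#' Pearson r with a two-sided p-value, plus the OLS slope and intercept of
#' `y` on `x` (the dY/dX read off a scatter of, e.g., EF against peak
#' strain). Log-transform skewed variables upstream.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
correlate_with_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate input: zero variance in x or y", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  slope <- stats::cov(x, y) / stats::var(x)
  list(r = unname(ct$estimate), p = ct$p.value, slope = slope,
       intercept = mean(y) - slope * mean(x), n = n)
}
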