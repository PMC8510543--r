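#' Correlation with a two-tailed t-distribution p-value
#'
#' Pearson or Spearman (midranks for ties) correlation; the p-value comes
#' from the two-tailed t distribution with n - 2 degrees of freedom,
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method "pearson" or "spearman".
#' @return `data.frame` row: `test_name`, `statistic` (rho), `df`, `p_raw`,
#'   `flag` (NA or "degenerate" when a variance is zero).
#' @export
cor_stat <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(test_name = method, statistic = NA_real_,
                      df = NA_real_, p_raw = NA_real_, flag = "degenerate",
                      stringsAsFactors = FALSE))
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  rho <- stats::cor(x, y)
  tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  data.frame(test_name = method, statistic = rho, df = n - 2,
             p_raw = min(p, 1), flag = NA_character_,
             stringsAsFactors = FALSE)
}

#' Two-sample t test
#'
#' Pooled-variance Student's test by default (Welch by flag), two-tailed.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param variant "pooled" or "welch".
#' @return `data.frame` row: `test_name`, `statistic`, `df`, `p_raw`, `flag`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2 ||
      (stats::sd(a) == 0 && stats::sd(b) == 0)) {
    return(data.frame(test_name = paste0("t_", variant),
                      statistic = NA_real_, df = NA_real_, p_raw = NA_real_,
                      flag = "degenerate", stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  data.frame(test_name = paste0("t_", variant),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_raw = tt$p.value, flag = NA_character_,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test
#'
#' Midranks are used throughout. When the total enumeration of labelings
#' `choose(n_a + n_b, n_a)` is at most `exact_max`, the two-sided p-value is
#' computed by complete enumeration of the rank-sum null distribution
#' (correct under ties); otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b Numeric samples, each n >= 1.
#' @param exact_max Enumeration budget (default 1e5 labelings).
#' @return `data.frame` row with the U statistic of sample `a` and the
#'   two-sided p-value.
#' @export
mann_whitney <- function(a, b, exact_max = 1e5) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) {
    return(data.frame(test_name = "mann_whitney", statistic = NA_real_,
                      df = NA_real_, p_raw = NA_real_, flag = "degenerate",
                      stringsAsFactors = FALSE))
  }
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (choose(na + nb, na) <= exact_max) {
    combs <- utils::combn(na + nb, na)
    sums <- colSums(matrix(r[combs], nrow = na))
    Uperm <- sums - na * (na + 1) / 2
    p <- mean(abs(Uperm - mu) >= abs(U - mu) - 1e-9)
  } else {
    n <- na + nb
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sigma  # continuity correction
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  data.frame(test_name = "mann_whitney", statistic = U, df = NA_real_,
             p_raw = p, flag = NA_character_, stringsAsFactors = FALSE)
}

#' Least-squares linear fit with slope standard error and F test
#'
#' @param x,y Numeric vectors, n >= 3, `x` not constant.
#' @return Object of class `fit_result`: list with `model = "linear"`,
#'   `slope`, `intercept`, `slope_se`, `intercept_se`, `df`, `r_squared`,
#'   `p_F`, and `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("degenerate (constant) predictor")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit warning
  co <- sm$coefficients
  p_F <- if (!is.null(sm$fstatistic)) {
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  } else NA_real_
  structure(list(model = "linear",
                 slope = unname(co["x", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 slope_se = unname(co["x", "Std. Error"]),
                 intercept_se = unname(co["(Intercept)", "Std. Error"]),
                 df = fit$df.residual, r_squared = sm$r.squared, p_F = p_F,
                 n = length(x)),
            class = "fit_result")
}

#' Test equality of two regression slopes
#'
#' `t = (b1 - b2) / sqrt(se1^2 + se2^2)` with Welch-Satterthwaite degrees of
#' freedom; two-tailed p.
#'
#' @param fit1,fit2 [linear_fit()] results.
#' @return `data.frame` row: statistic, df, p_raw.
#' @export
slope_equality_test <- function(fit1, fit2) {
  se2 <- fit1$slope_se^2 + fit2$slope_se^2
  tval <- (fit1$slope - fit2$slope) / sqrt(se2)
  df <- se2^2 / (fit1$slope_se^4 / fit1$df + fit2$slope_se^4 / fit2$df)
  data.frame(test_name = "slope_equality", statistic = tval, df = df,
             p_raw = 2 * stats::pt(-abs(tval), df = df),
             flag = NA_character_, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; `NA` entries are passed through
#' and do not count toward the family size. Holm's method is available for
#' comparison.
#'
#' @param p Vector of raw p-values in [0, 1].
#' @param method "BH" (default) or "holm".
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p, method = c("BH", "holm")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Fit a Gaussian curve to a histogram
#'
#' Bins the values, then least-squares fits bin counts against
#' `a * exp(-(x - mu)^2 / (2 * sigma^2))` starting from the modal count,
#' weighted mean, and weighted SD. Reports the coefficient of determination
#' of the fitted curve against the bin counts.
#'
#' @param values Numeric sample.
#' @param bin_width Histogram bin width (default 1; bins centered on
#'   multiples of `bin_width`).
#' @return Object of class `fit_result`: list with `model = "gaussian"`,
#'   `amplitude`, `mean`, `sd`, `r_squared`, `bins` (data.frame of centers
#'   and counts).
#' @export
fit_gaussian_histogram <- function(values, bin_width = 1) {
  values <- values[is.finite(values)]
  centers <- round(values / bin_width) * bin_width
  tab <- table(centers)
  x <- as.numeric(names(tab)); yc <- as.numeric(tab)
  if (sum(yc > 0) < 5) stop("need at least 5 nonzero bins for a Gaussian fit")
  a0 <- max(yc)
  mu0 <- sum(x * yc) / sum(yc)
  s0 <- sqrt(sum(yc * (x - mu0)^2) / sum(yc))
  fit <- minpack.lm::nlsLM(yc ~ a * exp(-(x - mu)^2 / (2 * s^2)),
                           start = list(a = a0, mu = mu0, s = s0),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-10))
  pred <- stats::predict(fit)
  r2 <- 1 - sum((yc - pred)^2) / sum((yc - mean(yc))^2)
  cf <- stats::coef(fit)
  structure(list(model = "gaussian", amplitude = unname(cf["a"]),
                 mean = unname(cf["mu"]), sd = abs(unname(cf["s"])),
                 r_squared = r2,
                 bins = data.frame(center = x, count = yc)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$model == "gaussian") {
    cat(sprintf("Gaussian fit: a = %.3g, mean = %.3g, sd = %.3g, R^2 = %.4f\n",
                x$amplitude, x$mean, x$sd, x$r_squared))
  } else {
    cat(sprintf(
      "Linear fit: slope = %.4g (SE %.3g), intercept = %.4g, R^2 = %.4f\n",
      x$slope, x$slope_se, x$intercept, x$r_squared))
    if (is.finite(x$p_F)) cat(sprintf("  F-test p = %.3g\n", x$p_F))
  }
  invisible(x)
}

#' Poisson reference histogram
#'
#' Expected counts per integer bin under a Poisson distribution with the
#' sample mean — the reference against which an observed mutations-per-CDS
#' histogram is judged over- or under-dispersed.
#'
#' @param values Non-negative integer sample.
#' @param kmax Largest bin (default: sample maximum).
#' @return `data.frame` with `k`, `observed`, `expected`.
#' @export
poisson_expected_histogram <- function(values, kmax = max(values)) {
  values <- values[is.finite(values)]
  lambda <- mean(values)
  k <- 0:kmax
  obs <- tabulate(values + 1L, nbins = kmax + 1L)
  data.frame(k = k, observed = obs,
             expected = length(values) * stats::dpois(k, lambda))
}

#' Box-and-whisker statistics with the 1.5 x IQR outlier rule
#'
#' Quartiles use the linear-interpolation convention (`quantile` type 7).
#' A value is an outlier when it is at or beyond 1.5 interquartile ranges
#' below Q1 or above Q3; whiskers end at the most extreme non-outliers.
#'
#' @param values Numeric sample, n >= 1.
#' @return list: `q1`, `median`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers` (values), `mean`.
#' @export
box_stats <- function(values) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  out <- values >= q[3] + 1.5 * iqr | values <= q[1] - 1.5 * iqr
  if (iqr == 0) out <- values != q[2]  # degenerate box: flag anything off-median
  inside <- values[!out]
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_lo = if (length(inside)) min(inside) else q[2],
       whisker_hi = if (length(inside)) max(inside) else q[2],
       outliers = sort(values[out]), mean = mean(values))
}
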