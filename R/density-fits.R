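#' Linear fit of a density-by-eccentricity curve
#'
#' Ordinary least squares of density on eccentricity, `y = a x + b`. Negative
#' slopes indicate denser coverage near the fovea than the periphery.
#' Adjusted R^2 uses the two-parameter correction
#' `1 - (1 - R^2)(N - 1)/(N - 2)`.
#'
#' @param curve data.frame with `ecc` and `density` (>= 3 bins).
#' @return list with `slope`, `intercept`, `adjR2` and `degenerate` flag
#'   (set when the curve has zero variance, leaving the slope 0).
#' @export
fitDensityLinear <- function(curve) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 3L)
  x <- curve$ecc; y <- curve$density
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = y[1], adjR2 = NA_real_,
                degenerate = TRUE))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  n <- length(y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adjR2 = 1 - (1 - r2) * (n - 1) / (n - 2),
       degenerate = FALSE)
}

# generalized logistic curve used for density profiles
logisticCurve <- function(x, a, b, c, d) a + (b - a) / (1 + 10^((c - x) * d))

#' Generalized-logistic fit of a density-by-eccentricity curve
#'
#' Nonlinear least squares of `y = a + (b - a) / (1 + 10^((c - x) d))`, where
#' a and b are the two asymptotes, c the inflection point (the curve equals
#' `(a + b)/2` at `x = c`) and d the steepness. Because the roles of a and b
#' as low- and high-eccentricity asymptotes swap with the sign of d, the
#' result also reports `asymptoteLow`/`asymptoteHigh` (the limits as x tends
#' to -Inf and +Inf). Initialization is multistart over steepness signs and
#' magnitudes; adjusted R^2 uses the four-parameter correction.
#'
#' @param curve data.frame with `ecc` and `density` (>= 5 bins).
#' @return list with `a`, `b`, `c`, `d`, `adjR2`, `asymptoteLow`,
#'   `asymptoteHigh`, `converged` and `degenerate` flags.
#' @export
fitDensityLogistic <- function(curve) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 5L)
  x <- curve$ecc; y <- curve$density
  if (diff(range(y)) < 1e-12)
    return(list(a = y[1], b = y[1], c = NA_real_, d = NA_real_,
                adjR2 = NA_real_, asymptoteLow = y[1], asymptoteHigh = y[1],
                converged = FALSE, degenerate = TRUE))
  starts <- expand.grid(d = c(-0.5, -0.2, -0.05, 0.05, 0.2, 0.5),
                        c = stats::quantile(x, c(0.25, 0.5, 0.75)))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    st <- list(a = max(y), b = min(y), c = starts$c[k], d = starts$d[k])
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ a + (b - a) / (1 + 10^((c - x) * d)),
      start = st, control = minpack.lm::nls.lm.control(maxiter = 200))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(list(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                adjR2 = NA_real_, asymptoteLow = NA_real_,
                asymptoteHigh = NA_real_, converged = FALSE,
                degenerate = FALSE))
  cf <- as.list(stats::coef(best$fit))
  n <- length(y)
  r2 <- 1 - best$rss / sum((y - mean(y))^2)
  lowHigh <- if (cf$d > 0) c(cf$a, cf$b) else c(cf$b, cf$a)
  list(a = cf$a, b = cf$b, c = cf$c, d = cf$d,
       adjR2 = 1 - (1 - r2) * (n - 1) / (n - 4),
       asymptoteLow = lowHigh[1], asymptoteHigh = lowHigh[2],
       converged = TRUE, degenerate = FALSE)
}
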