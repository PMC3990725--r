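# Statistical layer: Pearson chi-square tests, Sidak thresholds, and the
# linear-versus-quadratic snowball comparison by Gaussian-MLE AIC.

#' Chi-square goodness-of-fit test
#'
#' Pearson statistic `sum((O - E)^2 / E)` against a fully specified
#' expectation, with `df = length - 1` and the upper-tail p-value of the
#' chi-square distribution (the regularized upper incomplete gamma
#' function; at `df = 2` it reduces to `exp(-x/2)`).
#'
#' @param observed Vector of observed counts.
#' @param expected Vector of expected values, all positive, same length.
#' @return A list of class `chisq_result`: `statistic`, `df`, `p`.
#' @examples
#' chisq_gof(c(9, 0, 3), uniform_expected(12, 3))
#' @export
chisq_gof <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length", call. = FALSE)
  if (length(observed) < 2)
    stop("need at least two categories", call. = FALSE)
  if (any(!is.finite(expected)) || any(expected <= 0))
    stop("expected values must all be positive", call. = FALSE)
  if (any(observed < 0))
    stop("observed counts must be nonnegative", call. = FALSE)
  statistic <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = statistic, df = df,
                 p = stats::pchisq(statistic, df, lower.tail = FALSE)),
            class = "chisq_result")
}

#' Uniform expected allocation over categories
#'
#' Spreads a total evenly: `n` observations over `k` categories gives
#' `n / k` expected per category (e.g. 12 lethal regions over 3
#' developmental stages -> 4 per stage).
#'
#' @param n Total count.
#' @param k Number of categories.
#' @return Numeric vector of length `k`.
#' @export
uniform_expected <- function(n, k) rep(n / k, k)

#' Stage-uniformity test of lethal-region counts
#'
#' Tests whether lethal regions are uniformly distributed over the
#' embryonic, larval and pupal stages.
#'
#' @param stage_counts Named counts as from [count_by_stage()].
#' @return A `chisq_result`.
#' @export
stage_uniformity_test <- function(stage_counts) {
  chisq_gof(as.numeric(stage_counts),
            uniform_expected(sum(stage_counts), length(stage_counts)))
}

#' Chi-square homogeneity test of a contingency table
#'
#' Pearson statistic on an r x k table of counts against independence
#' expectations `rowSum * colSum / total`, with
#' `df = (rows - 1) * (cols - 1)` and no continuity correction. All row
#' and column marginals must be positive.
#'
#' @param counts A matrix (or 2-row rbind) of nonnegative counts.
#' @return A `chisq_result`.
#' @export
chisq_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table needs at least 2 rows and 2 columns",
         call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal in contingency table", call. = FALSE)
  expected <- outer(rs, cs) / sum(counts)
  statistic <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  structure(list(statistic = statistic, df = df,
                 p = stats::pchisq(statistic, df, lower.tail = FALSE)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Sidak-corrected per-comparison significance threshold
#'
#' For `m` independent comparisons at family-wise level `alpha`, the
#' per-comparison threshold `1 - (1 - alpha)^(1/m)`; strictly decreasing
#' in `m` and equal to `alpha` at `m = 1`.
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of comparisons, a positive integer.
#' @return The per-comparison p-value threshold.
#' @examples
#' sidak_threshold(0.05, 18)
#' @export
sidak_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(m) || m < 1 || m != round(m))
    stop("m must be a positive integer", call. = FALSE)
  1 - (1 - alpha)^(1 / m)
}

#' Polynomial fit with Gaussian maximum-likelihood AIC
#'
#' Ordinary least squares of counts on divergence with an intercept and
#' polynomial terms up to `degree`. The Gaussian maximum likelihood is
#' `-(n/2) (log 2*pi + log(rss/n) + 1)` and
#' `AIC = 2k - 2 loglik` with `k = degree + 2` (the coefficients plus the
#' residual scale). A residual sum of squares below `rss_floor` marks the
#' fit degenerate (exact interpolation, unbounded likelihood); its AIC is
#' reported as `-Inf` with `degenerate = TRUE` rather than a spuriously
#' finite number.
#'
#' @param data data.frame with columns `Ks` and `n_regions` (as from
#'   [snowball_dataset()]).
#' @param degree 1 (linear) or 2 (quadratic).
#' @param rss_floor Degeneracy floor on the residual sum of squares.
#' @param quadratic `"full"` (intercept + linear + quadratic terms, the
#'   conventional reading of a quadratic model) or `"pure"` (intercept +
#'   quadratic term only), for sensitivity analysis; ignored at degree 1.
#' @return A list of class `poly_fit`: `degree`, `coefficients`, `rss`,
#'   `loglik`, `aic`, `n`, `degenerate`, `fitted`.
#' @export
fit_poly_gaussian <- function(data, degree, rss_floor = 1e-12,
                              quadratic = c("full", "pure")) {
  quadratic <- match.arg(quadratic)
  if (!degree %in% 1:2) stop("degree must be 1 or 2", call. = FALSE)
  x <- data$Ks
  y <- data$n_regions
  n <- length(x)
  k_coef <- if (degree == 2 && quadratic == "pure") 2L else degree + 1L
  if (n <= k_coef + 1L)
    stop("need more than ", k_coef + 1L, " points to fit degree ", degree,
         " with a residual scale; got ", n, call. = FALSE)
  if (length(unique(x)) < k_coef)
    stop("collinear design: only ", length(unique(x)),
         " distinct divergence values for ", k_coef, " coefficients",
         call. = FALSE)
  fit <- if (degree == 1) {
    stats::lm(y ~ x)
  } else if (quadratic == "full") {
    stats::lm(y ~ x + I(x^2))
  } else {
    stats::lm(y ~ I(x^2))
  }
  rss <- sum(stats::residuals(fit)^2)
  degenerate <- rss < rss_floor
  loglik <- if (degenerate) Inf else
    -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
  k <- k_coef + 1L  # residual scale counts as a parameter
  aic <- if (degenerate) -Inf else 2 * k - 2 * loglik
  structure(list(degree = degree, coefficients = stats::coef(fit),
                 rss = rss, loglik = loglik, aic = aic, n = n,
                 degenerate = degenerate,
                 fitted = as.numeric(stats::fitted(fit))),
            class = "poly_fit")
}

#' Linear-versus-quadratic snowball comparison
#'
#' Fits both models to the (divergence, region count) points and prefers
#' the lower AIC. Under the snowball hypothesis the number of
#' incompatibilities grows faster than linearly with divergence, so a
#' preferred quadratic is the snowball-consistent outcome. A degenerate
#' (exactly interpolating) quadratic is reported as preferred with its
#' flag surfaced, never as a finite AIC.
#'
#' @param data data.frame with columns `Ks` and `n_regions`.
#' @param rss_floor,quadratic Passed to [fit_poly_gaussian()].
#' @return A list: `linear` and `quadratic` (`poly_fit`s),
#'   `preferred_degree` (1 or 2), `delta_aic` (linear - quadratic; `Inf`
#'   when the quadratic is degenerate).
#' @export
snowball_compare <- function(data, rss_floor = 1e-12,
                             quadratic = c("full", "pure")) {
  quadratic <- match.arg(quadratic)
  lin <- fit_poly_gaussian(data, 1, rss_floor)
  quad <- fit_poly_gaussian(data, 2, rss_floor, quadratic)
  preferred <- if (quad$aic <= lin$aic) 2L else 1L
  list(linear = lin, quadratic = quad, preferred_degree = preferred,
       delta_aic = lin$aic - quad$aic)
}
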