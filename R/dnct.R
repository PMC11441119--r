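#' Distribution function of the doubly non-central t-distribution
#'
#' CDF of `T = (Z + delta) / sqrt(W / df)` with `Z` standard normal independent
#' of `W`, a non-central chi-square variable with `df` degrees of freedom and
#' non-centrality `lam`. Computed by conditioning on the Poisson mixing
#' variable of the non-central chi-square:
#' \deqn{F(x; df, \delta, \lambda) = \sum_{j \ge 0}
#'   e^{-\lambda/2} \frac{(\lambda/2)^j}{j!}\,
#'   F_{nct}\!\big(x \sqrt{(df + 2j)/df};\; df + 2j,\; \delta\big),}
#' where \eqn{F_{nct}} is the singly non-central t CDF (given the mixing value
#' `j`, `W` is a central chi-square with `df + 2j` degrees of freedom, so `T`
#' is a rescaled singly non-central t variable). Each term is a
#' well-conditioned [stats::pt()] call; the series is truncated once the
#' neglected Poisson mass falls below `tol`. At `lam = 0` the sum collapses to
#' the singly non-central t CDF and, additionally with `delta = 0`, to the
#' central t CDF.
#'
#' Vectorized over `x`, `delta` and `lam` (recycled to a common length).
#'
#' @param x Quantile(s).
#' @param df Degrees of freedom (positive scalar).
#' @param delta Numerator non-centrality parameter(s).
#' @param lam Non-negative denominator (chi-square) non-centrality
#'   parameter(s).
#' @param tol Truncation tolerance for the Poisson series, in `(0, 1e-6)`.
#' @param max_terms Hard cap on the number of series terms; exceeding it with
#'   more than `tol` Poisson mass unaccounted for is an error.
#' @return Probabilities `P(T <= x)`, clipped to `[0, 1]`.
#' @examples
#' dnct_cdf(0, df = 10)                          # 0.5, central t
#' dnct_cdf(2, df = 30, delta = 0.5)             # singly non-central collapse
#' dnct_cdf(2, df = 10, delta = 0.3, lam = 0.8)
#' @export
dnct_cdf <- function(x, df, delta = 0, lam = 0, tol = 1e-12,
                     max_terms = 10000L) {
  if (!is.numeric(df) || length(df) != 1L || !is.finite(df) || df <= 0)
    stop("'df' must be a single positive number", call. = FALSE)
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0 || tol >= 1e-6)
    stop("'tol' must lie in (0, 1e-6)", call. = FALSE)
  if (any(!is.finite(delta)) || any(!is.finite(lam)) || any(lam < 0))
    stop("'delta' must be finite and 'lam' finite and non-negative",
         call. = FALSE)
  n <- max(length(x), length(delta), length(lam))
  x <- rep_len(x, n); delta <- rep_len(delta, n); lam <- rep_len(lam, n)
  vapply(seq_len(n), function(i)
    dnct_cdf_scalar(x[i], df, delta[i], lam[i], tol, max_terms),
    numeric(1))
}

dnct_cdf_scalar <- function(x, df, delta, lam, tol, max_terms) {
  if (is.na(x)) return(NA_real_)
  if (x == Inf) return(1)
  if (x == -Inf) return(0)
  nct <- function(q, nu) {
    # pt()'s ncp branch is less accurate than its central branch; dispatch.
    # Its far-tail precision warnings concern absolute errors ~1e-6 orders
    # below the probabilities of interest here.
    if (delta == 0) pt(q, df = nu)
    else suppressWarnings(pt(q, df = nu, ncp = delta))
  }
  if (lam == 0) return(min(1, max(0, nct(x, df))))
  h <- lam / 2
  jmax <- qpois(1 - tol, h)
  if (jmax + 1L > max_terms) {
    achieved <- ppois(max_terms - 1L, h, lower.tail = FALSE)
    stop(sprintf(paste0("doubly non-central t series needs more than %d terms",
                        " (remaining Poisson mass %.3e > tol %.3e)"),
                 max_terms, achieved, tol), call. = FALSE)
  }
  j <- 0:jmax
  w <- dpois(j, h)
  terms <- vapply(j, function(jj)
    nct(x * sqrt((df + 2 * jj) / df), df + 2 * jj), numeric(1))
  min(1, max(0, sum(w * terms)))
}

#' Two-sided rejection probability of a biased t statistic
#'
#' Probability that a doubly non-central t statistic falls outside the
#' two-sided acceptance region `[c_low, -c_low]`, i.e. `P(|S| > |c_low|)`,
#' computed as `F(c_low; df, delta, lam) + F(c_low; df, -delta, lam)`. `c_low`
#' is the lower-tail central-t critical value `t_df(alpha*/2)` (negative for
#' any level below 1); with `delta = lam = 0` the result is exactly the
#' per-test level `alpha*`. Symmetric in the sign of `delta`.
#'
#' Vectorized over `delta` and `lam`.
#'
#' @param c_low Lower-tail critical value (scalar, `<= 0`).
#' @param df Degrees of freedom.
#' @inheritParams dnct_cdf
#' @return Rejection probabilities in `[0, 1]`.
#' @export
dnct_two_sided_rejection <- function(c_low, df, delta = 0, lam = 0,
                                     tol = 1e-12, max_terms = 10000L) {
  if (!is.numeric(c_low) || length(c_low) != 1L || c_low > 0)
    stop("'c_low' must be a single non-positive lower-tail critical value",
         call. = FALSE)
  p <- dnct_cdf(c_low, df, delta, lam, tol, max_terms) +
       dnct_cdf(c_low, df, -delta, lam, tol, max_terms)
  pmin(1, pmax(0, p))
}
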