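#' Trial design for a two-arm multi-endpoint comparison
#'
#' Collects the design constants of a randomized two-arm parallel-group trial
#' with `m` continuous endpoints analysed by endpoint-wise pooled-variance
#' t-tests: total sample size, nominal significance level, endpoint standard
#' deviations, an optional endpoint correlation matrix and the expected
#' response vectors of the two arms (equal, and zero by default, under the
#' global null).
#'
#' @param N Total sample size (`>= 4`, so both arms can hold two patients and
#'   the pooled t-test has `N - 2 >= 2` degrees of freedom).
#' @param m Number of endpoints (`>= 1`).
#' @param alpha Nominal significance level in `(0, 1)`.
#' @param sigma Endpoint standard deviations (positive; recycled to length
#'   `m`).
#' @param corr Optional `m x m` endpoint correlation matrix: symmetric, unit
#'   diagonal, positive semidefinite. `NULL` means independent endpoints.
#' @param mu_E,mu_C Expected response vectors of the treatment and control arm
#'   (recycled to length `m`); defaults 0.
#' @return An object of class `"trial_design"` with element `Sigma`, the
#'   implied covariance matrix `diag(sigma) %*% corr %*% diag(sigma)`.
#' @examples
#' trial_design(N = 32, m = 2, alpha = 0.05)
#' @export
trial_design <- function(N, m, alpha = 0.05, sigma = 1, corr = NULL,
                         mu_E = 0, mu_C = 0) {
  if (!is.numeric(N) || length(N) != 1L || N < 4 || N != round(N))
    stop("'N' must be an integer >= 4", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'m' must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  sigma <- rep_len(as.numeric(sigma), m)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("'sigma' must be positive", call. = FALSE)
  if (!is.null(corr)) {
    corr <- as.matrix(corr)
    if (!all(dim(corr) == c(m, m)) || any(abs(corr - t(corr)) > 1e-10) ||
        any(abs(diag(corr) - 1) > 1e-10))
      stop("'corr' must be a symmetric m x m matrix with unit diagonal",
           call. = FALSE)
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop("'corr' must be positive semidefinite (min eigenvalue ",
           signif(min(ev), 3), ")", call. = FALSE)
  }
  Sigma <- if (is.null(corr)) diag(sigma^2, m) else diag(sigma) %*% corr %*% diag(sigma)
  structure(list(N = as.integer(N), m = as.integer(m), alpha = alpha,
                 sigma = sigma, corr = corr, Sigma = Sigma,
                 mu_E = rep_len(as.numeric(mu_E), m),
                 mu_C = rep_len(as.numeric(mu_C), m)),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Two-arm trial design: N = %d, m = %d endpoint(s), alpha = %g\n",
              x$N, x$m, x$alpha))
  cat("  sigma:", paste(signif(x$sigma, 6), collapse = ", "), "\n")
  cat("  endpoints:", if (is.null(x$corr)) "independent" else "correlated", "\n")
  invisible(x)
}

arm_sizes <- function(t) {
  n_E <- sum(t)
  n_C <- length(t) - n_E
  if (n_E < 1L || n_C < 1L)
    stop("degenerate allocation sequence: both arms must receive at least ",
         "one patient", call. = FALSE)
  c(n_E = n_E, n_C = n_C)
}

#' Non-centrality parameters of a biased t statistic
#'
#' For a fixed allocation sequence and one endpoint's bias column, computes the
#' non-centrality parameters of the doubly non-central t-distribution followed
#' by the pooled-variance two-sample t statistic under the component null:
#' \deqn{\delta = \frac{1}{\sigma}\sqrt{\frac{n_E n_C}{N}}
#'   (\Delta\mu + \bar\tau_E - \bar\tau_C), \qquad
#'  \lambda = \frac{1}{\sigma^2}\Big[\sum_{j: t_j = 1} (\tau_j - \bar\tau_E)^2
#'   + \sum_{j: t_j = 0} (\tau_j - \bar\tau_C)^2\Big],}
#' where \eqn{\bar\tau_E}, \eqn{\bar\tau_C} are the arm-wise means of the bias
#' shifts. The mean bias difference acts like a spurious treatment effect
#' (through `delta`); the within-arm spread of the bias inflates the pooled
#' variance (through `lam`).
#'
#' @param t Allocation sequence (0/1 vector; both arms non-empty).
#' @param tau_col Bias shifts for this endpoint, one per patient.
#' @param sigma_k Endpoint standard deviation (positive).
#' @param mu_diff_k True mean difference `mu_E - mu_C` for this endpoint
#'   (0 under the null).
#' @return A list with elements `delta` and `lam`.
#' @examples
#' noncentrality(c(1, 0, 1, 0), c(0, -0.1, 0, -0.1), 1)  # delta 0.1, lam 0
#' @export
noncentrality <- function(t, tau_col, sigma_k, mu_diff_k = 0) {
  t <- check_sequence(t)
  stopifnot(length(tau_col) == length(t), is.numeric(sigma_k), sigma_k > 0)
  n <- arm_sizes(t)
  N <- length(t)
  tbar_E <- sum(tau_col[t == 1L]) / n[["n_E"]]
  tbar_C <- sum(tau_col[t == 0L]) / n[["n_C"]]
  delta <- sqrt(n[["n_E"]] * n[["n_C"]] / N) *
    (mu_diff_k + tbar_E - tbar_C) / sigma_k
  lam <- (sum((tau_col[t == 1L] - tbar_E)^2) +
          sum((tau_col[t == 0L] - tbar_C)^2)) / sigma_k^2
  list(delta = delta, lam = lam)
}

#' Actual Sidak family-wise error rate of one randomization list
#'
#' Closed-form family-wise error rate of the Sidak procedure for a fixed
#' allocation sequence under the convergence-strategy bias model, assuming
#' independent endpoints. Each component null is tested two-sided at the
#' Sidak-adjusted level `alpha* = 1 - (1 - alpha)^(1/m)`; under bias the
#' per-endpoint rejection probability is evaluated from the doubly non-central
#' t-distribution with the sequence's non-centrality parameters, and the FWER
#' is `1 - prod_k (1 - p_k)`. With all bias effects zero the result is exactly
#' `alpha`.
#'
#' @param t Allocation sequence (0/1 vector).
#' @param tau `N x m` bias matrix (from [bias_matrix()]).
#' @param design A [trial_design()] with independent endpoints
#'   (`corr = NULL` or the identity).
#' @return The per-list family-wise error rate, in `[0, 1]`.
#' @seealso [sidak_fwer_correlated()] for correlated endpoints,
#'   [aon_t1e()] for the all-or-none procedure.
#' @export
sidak_fwer <- function(t, tau, design) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.null(design$corr) && any(abs(design$corr - diag(design$m)) > 1e-12))
    stop("sidak_fwer() assumes independent endpoints; use ",
         "sidak_fwer_correlated() for a non-identity correlation",
         call. = FALSE)
  sidak_fwer_core(t, tau, sigma = design$sigma,
                  mu_diff = design$mu_E - design$mu_C,
                  alpha = design$alpha, m_level = design$m, N = design$N)
}

# Shared Sidak kernel: independent components with standard deviations
# `sigma`, level adjusted for `m_level` endpoints; components may be dropped
# (degenerate zero-variance principal components) by passing them absent.
sidak_fwer_core <- function(t, tau, sigma, mu_diff, alpha, m_level, N) {
  t <- check_sequence(t)
  if (length(t) != N) stop("sequence length does not match design N", call. = FALSE)
  tau <- as.matrix(tau)
  stopifnot(nrow(tau) == N, ncol(tau) == length(sigma))
  df <- N - 2L
  alpha_star <- 1 - (1 - alpha)^(1 / m_level)
  c_low <- qt(alpha_star / 2, df)
  p <- vapply(seq_along(sigma), function(k) {
    nc <- noncentrality(t, tau[, k], sigma[k], mu_diff[k])
    dnct_two_sided_rejection(c_low, df, nc$delta, nc$lam)
  }, numeric(1))
  min(1, max(0, 1 - prod(1 - p)))
}

#' Principal-component transform of a trial design
#'
#' Eigendecomposition of the endpoint covariance matrix
#' `Sigma = diag(sigma) %*% corr %*% diag(sigma)`, returning the orthonormal
#' eigenvector matrix `A` (columns ordered by descending eigenvalue) used to
#' decorrelate the patient responses: the transformed responses `A^T X_j` have
#' independent components with variances equal to the eigenvalues. Eigenvector
#' signs are fixed deterministically (each column's largest-magnitude entry is
#' made positive, ties resolved at the lowest index) so repeated-eigenvalue
#' designs give reproducible bases.
#'
#' @param design A [trial_design()].
#' @return A list with `A` (m x m orthonormal matrix) and `eigenvalues`
#'   (non-increasing, non-negative).
#' @export
pca_transform <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  e <- eigen(design$Sigma, symmetric = TRUE)
  vals <- e$values
  if (min(vals) < -1e-10)
    stop("covariance matrix is not positive semidefinite", call. = FALSE)
  vals <- pmax(vals, 0)
  A <- e$vectors
  lead <- integer(ncol(A))
  for (k in seq_len(ncol(A))) {
    lead[k] <- which.max(abs(A[, k]))
    if (A[lead[k], k] < 0) A[, k] <- -A[, k]
  }
  # stable order: descending eigenvalue, ties broken by the row index of the
  # column's largest-magnitude entry (repeated eigenvalues otherwise leave
  # the basis order up to the eigensolver)
  ord <- order(-signif(vals, 12), lead)
  list(A = A[, ord, drop = FALSE], eigenvalues = vals[ord])
}

#' Actual Sidak family-wise error rate with correlated endpoints
#'
#' Extends [sidak_fwer()] to positively correlated endpoints by transforming
#' the responses to principal components: the bias vectors and mean
#' differences are rotated by the eigenvector matrix of the endpoint
#' covariance (`tau'_j = A^T tau_j`), the component standard deviations become
#' the square roots of the eigenvalues, and the independent-endpoint Sidak
#' formula is applied to the transformed (independent) components. Components
#' with zero eigenvalue carry no test and are dropped from the product, while
#' the Sidak adjustment keeps the original endpoint count. With an identity
#' correlation this reduces exactly to [sidak_fwer()].
#'
#' @inheritParams sidak_fwer
#' @param design A [trial_design()] (any positive semidefinite correlation).
#' @return The per-list family-wise error rate, in `[0, 1]`.
#' @export
sidak_fwer_correlated <- function(t, tau, design) {
  stopifnot(inherits(design, "trial_design"))
  pc <- pca_transform(design)
  tau <- as.matrix(tau)
  stopifnot(ncol(tau) == design$m)
  tau_pc <- tau %*% pc$A                      # rows are (A^T tau_j)^T
  mu_diff_pc <- drop(crossprod(pc$A, design$mu_E - design$mu_C))
  keep <- pc$eigenvalues > 1e-12 * max(pc$eigenvalues, 1e-300)
  sidak_fwer_core(t, tau_pc[, keep, drop = FALSE],
                  sigma = sqrt(pc$eigenvalues[keep]),
                  mu_diff = mu_diff_pc[keep],
                  alpha = design$alpha, m_level = design$m, N = design$N)
}

#' Actual type I error rate of the all-or-none procedure
#'
#' Closed-form type I error rate of the all-or-none (intersection-union)
#' procedure for a fixed allocation sequence under the convergence-strategy
#' bias model. Each component is tested one-sided at the unadjusted level
#' `alpha`; the size of the intersection-union test over the union null is
#' attained where all but the least-favourable component carry arbitrarily
#' strong effects, giving
#' `max_k F(t_df(alpha); df, -delta_k, lam_k)` with `F` the doubly
#' non-central t CDF. The computation applies unchanged to correlated
#' endpoints. With all bias effects zero the result is exactly `alpha`.
#'
#' @inheritParams sidak_fwer
#' @param design A [trial_design()].
#' @return The per-list type I error rate, in `[0, 1]`.
#' @export
aon_t1e <- function(t, tau, design) {
  stopifnot(inherits(design, "trial_design"))
  t <- check_sequence(t)
  if (length(t) != design$N)
    stop("sequence length does not match design N", call. = FALSE)
  tau <- as.matrix(tau)
  stopifnot(nrow(tau) == design$N, ncol(tau) == design$m)
  df <- design$N - 2L
  c_one <- qt(design$alpha, df)
  mu_diff <- design$mu_E - design$mu_C
  p <- vapply(seq_len(design$m), function(k) {
    nc <- noncentrality(t, tau[, k], design$sigma[k], mu_diff[k])
    dnct_cdf(c_one, df, -nc$delta, nc$lam)
  }, numeric(1))
  min(1, max(0, max(p)))
}
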