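#' Simulate patient responses under the biased response model
#'
#' Draws one trial's worth of patient responses from the linear bias model:
#' patient `j`'s response vector is the arm mean (`mu_E` if `t_j = 1`, `mu_C`
#' otherwise) plus the bias shift `tau_j` plus a multivariate normal error
#' with covariance `diag(sigma) %*% corr %*% diag(sigma)`, independently
#' across patients.
#'
#' @param t Allocation sequence (0/1 vector of length `N`).
#' @param tau `N x m` bias matrix.
#' @param design A [trial_design()].
#' @return An `N x m` matrix of responses.
#' @export
simulate_responses <- function(t, tau, design) {
  stopifnot(inherits(design, "trial_design"))
  t <- check_sequence(t)
  tau <- as.matrix(tau)
  stopifnot(length(t) == design$N, nrow(tau) == design$N,
            ncol(tau) == design$m)
  L <- chol_psd(design$Sigma)
  eps <- matrix(rnorm(design$N * design$m), design$N, design$m) %*% L
  mu <- outer(t, design$mu_E) + outer(1L - t, design$mu_C)
  mu + tau + eps
}

# Upper-triangular factor L with Sigma = t(L) %*% L, tolerating PSD matrices
# with zero eigenvalues via the eigendecomposition.
chol_psd <- function(Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(Sigma, symmetric = TRUE)
  if (min(e$values) < -1e-10)
    stop("covariance matrix is not positive semidefinite", call. = FALSE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(Sigma)))
}

#' Empirical rejection rate by brute-force trial simulation
#'
#' Validation instrument for the closed-form error rates: simulates `n_sim`
#' trials from the biased response model for a fixed allocation sequence,
#' runs the actual endpoint-wise pooled-variance two-sample t-tests, applies
#' the decision rule and returns the rejection fraction.
#'
#' * `procedure = "sidak"`: reject if any endpoint's `|S_k|` exceeds the
#'   two-sided central-t critical value at the Sidak-adjusted level
#'   `alpha* = 1 - (1 - alpha)^(1/m)`. With correlated endpoints the tests are
#'   applied to the principal-component-transformed responses (`A^T X_j`),
#'   which is the independent-component test problem the closed form
#'   evaluates; set `transform = FALSE` to test the raw components instead.
#' * `procedure = "all_or_none"`: reject if `S_k` exceeds the one-sided
#'   critical value `t_df(1 - alpha)` for every endpoint in
#'   `null_components`. Components not listed are treated as rejecting with
#'   certainty -- the limiting least-favourable configuration of the union
#'   null in which those components carry arbitrarily strong effects. The
#'   default (all components) estimates the joint rejection probability,
#'   which is bounded above by each component's marginal rate; the size of
#'   the intersection-union test is the maximum over single active
#'   components.
#'
#' @param t Allocation sequence (both arms must hold at least two patients so
#'   per-arm variances are defined).
#' @param tau `N x m` bias matrix.
#' @param design A [trial_design()].
#' @param procedure `"sidak"` or `"all_or_none"`.
#' @param n_sim Number of simulated trials.
#' @param null_components Integer indices of the endpoints whose nulls are
#'   enforced in the all-or-none decision (see above). Ignored for
#'   `"sidak"`.
#' @param transform Apply the principal-component transform before testing
#'   (Sidak path with a non-identity correlation only).
#' @param chunk Number of trials simulated per block (memory control).
#' @return The empirical rejection fraction.
#' @export
empirical_rate <- function(t, tau, design,
                           procedure = c("sidak", "all_or_none"),
                           n_sim = 10000L, null_components = seq_len(design$m),
                           transform = TRUE, chunk = 100000L) {
  procedure <- match.arg(procedure)
  stopifnot(inherits(design, "trial_design"))
  t <- check_sequence(t)
  tau <- as.matrix(tau)
  stopifnot(length(t) == design$N, nrow(tau) == design$N,
            ncol(tau) == design$m)
  n <- arm_sizes(t)
  if (n[["n_E"]] < 2L || n[["n_C"]] < 2L)
    stop("the simulation oracle needs at least two patients per arm",
         call. = FALSE)
  if (!is.numeric(n_sim) || length(n_sim) != 1L || n_sim < 1)
    stop("'n_sim' must be a positive integer", call. = FALSE)
  null_components <- sort(unique(as.integer(null_components)))
  if (any(null_components < 1L) || any(null_components > design$m))
    stop("'null_components' must index endpoints 1..m", call. = FALSE)

  m <- design$m
  N <- design$N
  df <- N - 2L
  mu <- outer(t, design$mu_E) + outer(1L - t, design$mu_C)
  shift <- mu + tau                       # N x m fixed part of every trial

  use_pca <- procedure == "sidak" && transform && !is.null(design$corr) &&
    any(abs(design$corr - diag(m)) > 1e-14)
  if (use_pca) {
    pc <- pca_transform(design)
    keep <- pc$eigenvalues > 1e-12 * max(pc$eigenvalues, 1e-300)
    A <- pc$A[, keep, drop = FALSE]
    shift_t <- shift %*% A
    m_test <- ncol(A)
  } else {
    shift_t <- shift
    m_test <- m
  }

  if (procedure == "sidak") {
    alpha_star <- 1 - (1 - design$alpha)^(1 / m)
    crit <- qt(1 - alpha_star / 2, df)
  } else {
    crit <- qt(1 - design$alpha, df)
  }

  L <- chol_psd(design$Sigma)
  nE <- n[["n_E"]]; nC <- n[["n_C"]]
  w <- sqrt(nE * nC / N)

  n_rej <- 0
  done <- 0L
  while (done < n_sim) {
    nb <- as.integer(min(chunk, n_sim - done))
    # per-arm sums and sums of squares per endpoint, accumulated position by
    # position so the full nb x N x m response array is never materialized;
    # one error draw per patient-trial is shared by all endpoints, preserving
    # within-trial dependence
    sE <- matrix(0, nb, m_test); sC <- matrix(0, nb, m_test)
    qE <- matrix(0, nb, m_test); qC <- matrix(0, nb, m_test)
    for (j in seq_len(N)) {
      ej <- matrix(rnorm(nb * m), nb, m) %*% L
      xj <- if (use_pca) ej %*% A else ej
      xj <- xj + rep(shift_t[j, ], each = nb)
      if (t[j] == 1L) { sE <- sE + xj; qE <- qE + xj^2 }
      else            { sC <- sC + xj; qC <- qC + xj^2 }
    }
    mE <- sE / nE; mC <- sC / nC
    pooled <- ((qE - nE * mE^2) + (qC - nC * mC^2)) / df
    S <- w * (mE - mC) / sqrt(pooled)
    rej <- if (procedure == "sidak") {
      rowSums(abs(S) > crit) > 0L
    } else {
      rowSums(S[, null_components, drop = FALSE] > crit) ==
        length(null_components)
    }
    n_rej <- n_rej + sum(rej)
    done <- done + nb
  }
  n_rej / n_sim
}
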