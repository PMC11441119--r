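#' Endpoint-specific allocation-bias policy
#'
#' Bundles the endpoint-specific allocation-bias effects `eta_k >= 0` (in
#' response units) of the convergence-strategy biasing policy. An unmasked
#' investigator who predicts that the under-represented arm is due next will
#' enrol a better responder (+eta_k shift on every endpoint) when the control
#' arm leads, a worse responder (-eta_k) when the treatment arm leads, and a
#' neutral responder when the arms are balanced.
#'
#' `eta` may either be given directly, or derived as a fraction `nu` of
#' endpoint effect sizes via `effect_size_eta()`.
#'
#' @param eta Numeric vector of `m >= 1` non-negative bias effects.
#' @return An object of class `"bias_policy"`.
#' @seealso [effect_size_eta()], [bias_matrix()]
#' @examples
#' bias_policy(c(0.1024, 0.1024))
#' @export
bias_policy <- function(eta) {
  if (!is.numeric(eta) || length(eta) < 1L || any(!is.finite(eta)) || any(eta < 0))
    stop("'eta' must be a vector of finite non-negative bias effects",
         call. = FALSE)
  structure(list(eta = as.numeric(eta), m = length(eta)), class = "bias_policy")
}

#' @export
print.bias_policy <- function(x, ...) {
  cat("Allocation-bias policy (convergence strategy), m =", x$m,
      "endpoint(s)\n  eta:", paste(signif(x$eta, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Bias effects as a fraction of effect sizes
#'
#' Builds a [bias_policy()] with `eta_k = nu * E_k`, expressing allocation-bias
#' effects as a proportion `nu` of anticipated endpoint effect sizes `E_k`
#' (the convention used when bias magnitudes are anchored to previously
#' published effects).
#'
#' @param nu Non-negative scalar fraction (e.g. `0.1` for bias effects of 10%
#'   of the effect size).
#' @param effect_sizes Positive effect sizes, one per endpoint (recycled to
#'   `m` if scalar).
#' @param m Number of endpoints when `effect_sizes` is scalar (default 1 x
#'   length of `effect_sizes`).
#' @return A [bias_policy()].
#' @examples
#' effect_size_eta(0.1, 1.024, m = 2)  # eta = (0.1024, 0.1024)
#' @export
effect_size_eta <- function(nu, effect_sizes, m = length(effect_sizes)) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu < 0)
    stop("'nu' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(effect_sizes) || any(effect_sizes <= 0))
    stop("'effect_sizes' must be positive", call. = FALSE)
  bias_policy(nu * rep_len(effect_sizes, m))
}

#' Bias matrix of an allocation sequence under the convergence strategy
#'
#' Evaluates the biasing policy along an allocation sequence: patient `j`
#' receives the response shift `tau[j, k] = -eta_k`, `0` or `+eta_k` according
#' to whether the treatment arm led, the arms were balanced, or the control arm
#' led after the first `j - 1` assignments. The shift depends only on the
#' imbalance history, not on patient `j`'s own realized assignment.
#'
#' @param t Allocation sequence (vector of 0/1).
#' @param policy A [bias_policy()].
#' @return An `N x m` numeric matrix of response shifts `tau[j, k]`.
#' @examples
#' bias_matrix(c(1, 0, 1, 0), bias_policy(0.1))  # column (0, -0.1, 0, -0.1)
#' @export
bias_matrix <- function(t, policy) {
  t <- check_sequence(t)
  stopifnot(inherits(policy, "bias_policy"))
  D_prev <- imbalance_trajectory(t)[seq_along(t)]  # D_0 .. D_{N-1}
  s <- -sign(D_prev)                               # tau multiplier per patient
  outer(as.numeric(s), policy$eta)
}
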