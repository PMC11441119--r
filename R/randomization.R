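#' Specify a randomization procedure
#'
#' Constructs a validated randomization-procedure (RP) specification for one of
#' the seven procedures supported by the package:
#'
#' * `CR` -- complete randomization: every assignment is a fair coin toss.
#' * `EBC` -- Efron's biased coin with probability `p >= 0.5` of assigning the
#'   under-represented arm.
#' * `BSD` -- big stick design: fair coin until the maximum tolerated imbalance
#'   `b` is reached, then a deterministic assignment to the smaller arm.
#' * `CHEN` -- Chen's design: Efron's biased coin with probability `p` inside
#'   the imbalance corridor, deterministic at imbalance `b`.
#' * `MP` -- maximal procedure: uniform distribution over all sequences that
#'   never exceed imbalance `b` and end balanced.
#' * `RAR` -- random allocation rule: uniform over all sequences with exactly
#'   `N/2` treatment assignments.
#' * `PBR` -- permuted block randomization: independent random allocation rule
#'   blocks of length `block_size`.
#'
#' @param name One of `"CR"`, `"EBC"`, `"BSD"`, `"CHEN"`, `"MP"`, `"RAR"`,
#'   `"PBR"`.
#' @param p Biased-coin probability in `[0.5, 1]`; required for `EBC` and
#'   `CHEN`, forbidden otherwise.
#' @param b Maximum tolerated imbalance (positive integer); required for
#'   `BSD`, `CHEN` and `MP`, forbidden otherwise.
#' @param block_size Positive even block length; required for `PBR`, forbidden
#'   otherwise.
#'
#' @return An object of class `"rp_spec"`.
#' @examples
#' rp_spec("BSD", b = 3)
#' rp_spec("CHEN", p = 0.67, b = 2)
#' rp_spec("PBR", block_size = 4)
#' @export
rp_spec <- function(name, p = NULL, b = NULL, block_size = NULL) {
  name <- match.arg(name, c("CR", "EBC", "BSD", "CHEN", "MP", "RAR", "PBR"))
  needs_p <- name %in% c("EBC", "CHEN")
  needs_b <- name %in% c("BSD", "CHEN", "MP")
  needs_k <- name == "PBR"
  if (needs_p) {
    if (is.null(p)) stop("'p' is required for ", name, call. = FALSE)
    if (!is.numeric(p) || length(p) != 1L || p < 0.5 || p > 1)
      stop("'p' must be a single probability in [0.5, 1]", call. = FALSE)
  } else if (!is.null(p)) {
    stop("'p' is only meaningful for EBC and CHEN", call. = FALSE)
  }
  if (needs_b) {
    if (is.null(b)) stop("'b' is required for ", name, call. = FALSE)
    if (!is.numeric(b) || length(b) != 1L || b < 1 || b != round(b))
      stop("'b' must be a positive integer", call. = FALSE)
    b <- as.integer(b)
  } else if (!is.null(b)) {
    stop("'b' is only meaningful for BSD, CHEN and MP", call. = FALSE)
  }
  if (needs_k) {
    if (is.null(block_size)) stop("'block_size' is required for PBR", call. = FALSE)
    if (!is.numeric(block_size) || length(block_size) != 1L ||
        block_size < 2 || block_size != round(block_size) || block_size %% 2 != 0)
      stop("'block_size' must be a positive even integer", call. = FALSE)
    block_size <- as.integer(block_size)
  } else if (!is.null(block_size)) {
    stop("'block_size' is only meaningful for PBR", call. = FALSE)
  }
  structure(list(name = name, p = p, b = b, block_size = block_size),
            class = "rp_spec")
}

#' @export
print.rp_spec <- function(x, ...) {
  cat(rp_label(x), "\n")
  invisible(x)
}

#' Human-readable label of a randomization procedure
#'
#' @param spec An [rp_spec()] object.
#' @return A string such as `"BSD(3)"` or `"CHEN(2,0.67)"`.
#' @export
rp_label <- function(spec) {
  switch(spec$name,
    CR   = "CR",
    RAR  = "RAR",
    EBC  = sprintf("EBC(%g)", spec$p),
    BSD  = sprintf("BSD(%d)", spec$b),
    MP   = sprintf("MP(%d)", spec$b),
    CHEN = sprintf("CHEN(%d,%g)", spec$b, spec$p),
    PBR  = sprintf("PBR(%d)", spec$block_size))
}

check_rp_N <- function(spec, N) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("'N' must be an integer >= 2", call. = FALSE)
  N <- as.integer(N)
  if (spec$name %in% c("RAR", "MP") && N %% 2L != 0L)
    stop(spec$name, " requires an even total sample size N", call. = FALSE)
  if (spec$name == "PBR" && N %% spec$block_size != 0L)
    stop("PBR requires N divisible by block_size (got N = ", N,
         ", block_size = ", spec$block_size, ")", call. = FALSE)
  N
}

#' Count admissible completions for the maximal procedure
#'
#' For the maximal procedure MP(b) -- the uniform distribution over all
#' allocation sequences of length `N` whose running imbalance never exceeds
#' `b` in absolute value and which end balanced -- computes the table of path
#' counts `count(j, d)`: the number of admissible +/-1 imbalance paths from
#' state `(j, d)` to `(N, 0)` staying within `|d| <= b`. Sampling one
#' assignment at a time with probability proportional to the number of
#' admissible completions draws a sequence exactly uniformly from the support.
#'
#' @param N Even positive total sample size.
#' @param b Positive integer maximum tolerated imbalance.
#' @return An `(N + 1) x (2b + 1)` matrix of counts; rows are steps
#'   `j = 0..N` (dimnames `"0".."N"`), columns imbalances `d = -b..b`.
#' @examples
#' mp_path_counts(4, 1)["0", "0"]  # 4 admissible sequences
#' @export
mp_path_counts <- function(N, b) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N) || N %% 2 != 0)
    stop("'N' must be an even integer >= 2", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || b < 1 || b != round(b))
    stop("'b' must be a positive integer", call. = FALSE)
  N <- as.integer(N); b <- as.integer(b)
  d_vals <- (-b):b
  cnt <- matrix(0, nrow = N + 1L, ncol = 2L * b + 1L,
                dimnames = list(0:N, d_vals))
  cnt[N + 1L, b + 1L] <- 1  # count(N, 0) = 1
  for (j in (N - 1L):0L) {
    for (di in seq_along(d_vals)) {
      d <- d_vals[di]
      up   <- if (abs(d + 1L) <= b) cnt[j + 2L, di + 1L] else 0
      down <- if (abs(d - 1L) <= b) cnt[j + 2L, di - 1L] else 0
      cnt[j + 1L, di] <- up + down
    }
  }
  cnt
}

#' Generate allocation sequences from a randomization procedure
#'
#' Draws `r` allocation sequences of length `N` from the exact sampling
#' distribution of the specified randomization procedure. `1` codes the
#' treatment arm (E), `0` the control arm (C). Forced assignments (big stick /
#' Chen at the imbalance boundary, maximal procedure with a single admissible
#' arm) are made deterministically without consuming randomness, so seeded
#' streams are reproducible across procedures.
#'
#' @param spec An [rp_spec()] object.
#' @param N Total sample size (even for `RAR` and `MP`; a multiple of
#'   `block_size` for `PBR`).
#' @param r Number of sequences to draw.
#' @return For `generate_sequences`, an `r x N` integer matrix of 0/1
#'   assignments, one sequence per row. `generate_sequence` returns a single
#'   sequence as an integer vector.
#' @examples
#' set.seed(1)
#' generate_sequence(rp_spec("MP", b = 1), N = 4)
#' generate_sequences(rp_spec("RAR"), N = 4, r = 3)
#' @export
generate_sequences <- function(spec, N, r = 1L) {
  stopifnot(inherits(spec, "rp_spec"))
  N <- check_rp_N(spec, N)
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r != round(r))
    stop("'r' must be a positive integer", call. = FALSE)
  r <- as.integer(r)
  t_mat <- switch(spec$name,
    CR  = matrix(rbinom(r * N, 1L, 0.5), nrow = r, ncol = N),
    RAR = rar_matrix(r, N),
    PBR = {
      k <- spec$block_size
      blocks <- rar_matrix(r * (N %/% k), k)
      matrix(t(blocks), nrow = r, ncol = N, byrow = TRUE)
    },
    EBC  = coin_matrix(r, N, p = spec$p, b = Inf),
    BSD  = coin_matrix(r, N, p = 0.5, b = spec$b),
    CHEN = coin_matrix(r, N, p = spec$p, b = spec$b),
    MP   = mp_matrix(r, N, spec$b))
  storage.mode(t_mat) <- "integer"
  t_mat
}

#' @rdname generate_sequences
#' @export
generate_sequence <- function(spec, N) {
  drop(generate_sequences(spec, N, r = 1L))
}

# r sequences with exactly N/2 (or floor/ceil split for odd blocks -- not
# reached: callers guarantee even N) treatment assignments, uniform over
# permutations; one global order() call instead of r per-row shuffles.
rar_matrix <- function(r, N) {
  n1 <- N %/% 2L
  keys <- runif(r * N)
  grp <- rep(seq_len(r), each = N)
  o <- order(grp, keys)
  arm <- integer(r * N)
  arm[o] <- rep_len(c(rep(1L, n1), rep(0L, N - n1)), r * N)
  matrix(arm, nrow = r, ncol = N, byrow = TRUE)
}

# Biased/fair coin with optional maximum tolerated imbalance b, vectorized
# across the r parallel sequences. p is the probability of assigning the
# under-represented arm when the imbalance is nonzero; at |D| = b the
# assignment is forced without drawing a random number.
coin_matrix <- function(r, N, p, b) {
  t_mat <- matrix(0L, nrow = r, ncol = N)
  D <- integer(r)
  for (j in seq_len(N)) {
    prob <- ifelse(D == 0L, 0.5, ifelse(D < 0L, p, 1 - p))
    tj <- integer(r)
    forced <- abs(D) >= b
    free <- !forced
    if (any(free)) tj[free] <- as.integer(runif(sum(free)) < prob[free])
    tj[forced] <- as.integer(D[forced] < 0L)
    t_mat[, j] <- tj
    D <- D + 2L * tj - 1L
  }
  t_mat
}

# Exact maximal-procedure sampler via the backward path-count table:
# at state (j-1, d) assign treatment with probability
# count(j, d+1) / count(j-1, d). Forced moves (probability 0 or 1) consume no
# randomness.
mp_matrix <- function(r, N, b) {
  cnt <- mp_path_counts(N, b)
  t_mat <- matrix(0L, nrow = r, ncol = N)
  D <- integer(r)
  for (j in seq_len(N)) {
    here <- cnt[cbind(j, D + b + 1L)]           # count(j-1, D)
    up_ok <- abs(D + 1L) <= b
    up <- numeric(r)
    up[up_ok] <- cnt[cbind(j + 1L, D[up_ok] + 1L + b + 1L)]  # count(j, D+1)
    prob <- up / here
    tj <- integer(r)
    free <- prob > 0 & prob < 1
    tj[free] <- as.integer(runif(sum(free)) < prob[free])
    tj[prob >= 1] <- 1L
    t_mat[, j] <- tj
    D <- D + 2L * tj - 1L
  }
  t_mat
}

#' Imbalance trajectory of an allocation sequence
#'
#' The running imbalance `D_j = N_E(j) - N_C(j)` after each of the first `j`
#' assignments, with `D_0 = 0`.
#'
#' @param t An allocation sequence: vector of 0/1 assignments.
#' @return Integer vector of length `length(t) + 1`, named `"0"` to
#'   `"length(t)"`.
#' @examples
#' imbalance_trajectory(c(1, 0, 1, 0))  # 0 1 0 1 0
#' @export
imbalance_trajectory <- function(t) {
  t <- check_sequence(t)
  D <- c(0L, cumsum(2L * t - 1L))
  names(D) <- 0:length(t)
  D
}

check_sequence <- function(t) {
  if (!is.numeric(t) || length(t) < 1L || any(!t %in% c(0, 1)))
    stop("an allocation sequence must be a vector of 0/1 assignments",
         call. = FALSE)
  as.integer(t)
}
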