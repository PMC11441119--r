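# Shared fixtures and independent oracles used across test files.

# The full roster of randomization procedures examined in the reference
# simulation settings.
roster_rps <- function() {
  list(rp_spec("CR"), rp_spec("BSD", b = 3), rp_spec("MP", b = 3),
       rp_spec("PBR", block_size = 4), rp_spec("RAR"),
       rp_spec("EBC", p = 0.67), rp_spec("CHEN", p = 0.67, b = 2))
}

# All 2^N allocation sequences of length N, one per row.
all_sequences <- function(N) {
  as.matrix(expand.grid(rep(list(0:1), N)))[, N:1, drop = FALSE]
}

# Exact probability of a sequence under a randomization procedure, computed
# directly from the defining transition rules / uniformity statements --
# independent of the samplers in R/randomization.R.
exact_seq_prob <- function(spec, t) {
  N <- length(t)
  name <- spec$name
  if (name == "RAR") {
    return(if (sum(t) == N / 2) 1 / choose(N, N / 2) else 0)
  }
  if (name == "PBR") {
    k <- spec$block_size
    pr <- 1
    for (bl in seq_len(N / k)) {
      blk <- t[((bl - 1) * k + 1):(bl * k)]
      pr <- pr * (if (sum(blk) == k / 2) 1 / choose(k, k / 2) else 0)
    }
    return(pr)
  }
  if (name == "MP") {
    D <- c(0, cumsum(2 * t - 1))
    ok <- all(abs(D) <= spec$b) && D[N + 1] == 0
    if (!ok) return(0)
    seqs <- all_sequences(N)
    n_adm <- sum(apply(seqs, 1, function(s) {
      Ds <- c(0, cumsum(2 * s - 1))
      all(abs(Ds) <= spec$b) && Ds[N + 1] == 0
    }))
    return(1 / n_adm)
  }
  # coin-type rules: CR, EBC(p), BSD(b), CHEN(p,b)
  p <- switch(name, CR = 0.5, EBC = spec$p, BSD = 0.5, CHEN = spec$p)
  b <- switch(name, CR = Inf, EBC = Inf, BSD = spec$b, CHEN = spec$b)
  pr <- 1
  D <- 0
  for (j in seq_len(N)) {
    p1 <- if (abs(D) >= b) as.numeric(D < 0)
          else if (D == 0) 0.5 else if (D < 0) p else 1 - p
    pr <- pr * (if (t[j] == 1) p1 else 1 - p1)
    D <- D + 2 * t[j] - 1
  }
  pr
}

# Exact distribution of a procedure over all length-N sequences; rows of
# `seqs` align with `prob`.
exact_rp_dist <- function(spec, N) {
  seqs <- all_sequences(N)
  prob <- apply(seqs, 1, function(s) exact_seq_prob(spec, s))
  list(seqs = seqs, prob = prob, key = apply(seqs, 1, paste, collapse = ""))
}

# Chi-square goodness-of-fit of sampled sequences against the exact
# distribution; also asserts no draw falls outside the support.
expect_matches_exact_dist <- function(spec, N, r = 1e5, alpha = 0.001) {
  dist <- exact_rp_dist(spec, N)
  t_mat <- generate_sequences(spec, N, r)
  key <- apply(t_mat, 1, paste, collapse = "")
  support <- dist$key[dist$prob > 0]
  expect_true(all(key %in% support),
              label = paste(rp_label(spec), "draws stay in the support"))
  obs <- table(factor(key, levels = support))
  pval <- suppressWarnings(
    stats::chisq.test(as.vector(obs), p = dist$prob[dist$prob > 0])$p.value)
  expect_gt(pval, alpha)
}

small_design <- function(N = 4, m = 2, ...) trial_design(N = N, m = m, ...)

# Exchangeable correlation matrix R_rho.
exch_corr <- function(m, rho) {
  R <- matrix(rho, m, m)
  diag(R) <- 1
  R
}
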