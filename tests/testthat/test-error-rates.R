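test_that("noncentrality matches hand computations", {
  nc <- noncentrality(c(1, 0, 1, 0), c(0, -0.1, 0, -0.1), 1)
  expect_equal(nc$delta, 0.1, tolerance = 1e-14)
  expect_equal(nc$lam, 0, tolerance = 1e-14)
  nc <- noncentrality(c(1, 1, 0, 0), c(0, -0.1, -0.1, -0.1), 1)
  expect_equal(nc$delta, 0.05, tolerance = 1e-14)
  expect_equal(nc$lam, 0.005, tolerance = 1e-14)
  nc <- noncentrality(c(1, 0, 1, 0), rep(0, 4), 2)
  expect_equal(nc$delta, 0)
  expect_equal(nc$lam, 0)
  # sigma scales delta by 1/sigma, lam by 1/sigma^2; mu_diff adds to delta
  nc2 <- noncentrality(c(1, 1, 0, 0), c(0, -0.1, -0.1, -0.1), 2)
  expect_equal(nc2$delta, 0.025)
  expect_equal(nc2$lam, 0.00125)
  nc3 <- noncentrality(c(1, 0, 1, 0), rep(0, 4), 1, mu_diff_k = 0.5)
  expect_equal(nc3$delta, 0.5)
  expect_error(noncentrality(c(1, 1, 1, 1), rep(0, 4), 1), "degenerate")
})

test_that("arm swap negates delta, keeps lambda, preserves the Sidak FWER", {
  set.seed(31)
  pol <- bias_policy(c(0.3, 0.5))
  d <- trial_design(N = 8, m = 2)
  for (i in 1:10) {
    t <- generate_sequence(rp_spec("BSD", b = 2), 8)
    tau <- bias_matrix(t, pol)
    for (k in 1:2) {
      # swapping the arm labels with the bias shifts held fixed negates the
      # mean-difference non-centrality and keeps the variance inflation
      nc <- noncentrality(t, tau[, k], 1)
      nc_sw <- noncentrality(1L - t, tau[, k], 1)
      expect_equal(nc_sw$delta, -nc$delta, tolerance = 1e-12)
      expect_equal(nc_sw$lam, nc$lam, tolerance = 1e-12)
    }
    # the two-sided Sidak FWER is invariant under that swap
    expect_equal(sidak_fwer(1L - t, tau, d), sidak_fwer(t, tau, d),
                 tolerance = 1e-12)
    # re-deriving the shifts from the swapped history negates tau as well,
    # restoring delta: the biasing policy treats the arms symmetrically
    tau_sw <- bias_matrix(1L - t, pol)
    nc_full <- noncentrality(1L - t, tau_sw[, 1], 1)
    expect_equal(nc_full$delta, noncentrality(t, tau[, 1], 1)$delta,
                 tolerance = 1e-12)
  }
})

test_that("unbiased error rates equal alpha exactly for every procedure", {
  set.seed(17)
  for (N in c(4, 12)) {
    d <- trial_design(N = N, m = 3, alpha = 0.05)
    pol <- bias_policy(c(0, 0, 0))
    specs <- list(rp_spec("CR"), rp_spec("RAR"), rp_spec("MP", b = 2))
    for (spec in specs) {
      t <- generate_sequence(spec, N)
      if (sum(t) == 0 || sum(t) == N) next
      tau <- bias_matrix(t, pol)
      expect_equal(sidak_fwer(t, tau, d), 0.05, tolerance = 1e-10)
      expect_equal(aon_t1e(t, tau, d), 0.05, tolerance = 1e-10)
    }
  }
})

test_that("Sidak FWER matches the lambda = 0 closed form on a balanced list", {
  # alternating list: tau has zero within-arm spread, so lam = 0 and the
  # two singly non-central t CDF calls give the whole answer
  t <- c(1, 0, 1, 0)
  d <- trial_design(N = 4, m = 2, alpha = 0.05)
  pol <- bias_policy(c(0.1, 0.1))
  tau <- bias_matrix(t, pol)
  df <- 2
  alpha_star <- 1 - 0.95^(1 / 2)
  c_low <- qt(alpha_star / 2, df)
  p_k <- pt(c_low, df, ncp = 0.1) + pt(c_low, df, ncp = -0.1)
  expect_equal(sidak_fwer(t, tau, d), 1 - (1 - p_k)^2, tolerance = 1e-12)
})

test_that("pca_transform matches closed-form eigensystems", {
  # identity covariance: eigenvalues 1, identity basis
  pc <- pca_transform(trial_design(N = 8, m = 3))
  expect_equal(pc$eigenvalues, rep(1, 3))
  expect_equal(pc$A, diag(3))
  # 2x2 with rho = 0.5: eigenvalues 1.5 / 0.5, (1,1)/sqrt(2) and (1,-1)/sqrt(2)
  pc2 <- pca_transform(trial_design(N = 8, m = 2, corr = exch_corr(2, 0.5)))
  expect_equal(pc2$eigenvalues, c(1.5, 0.5), tolerance = 1e-12)
  expect_equal(abs(pc2$A), matrix(1 / sqrt(2), 2, 2), tolerance = 1e-12)
  # sign convention: largest-magnitude entry of each column positive
  expect_true(all(apply(pc2$A, 2, function(col) col[which.max(abs(col))] > 0)))
  # exchangeable m = 5, rho = 0.9: spectrum (1 + 4 rho, 1 - rho x4)
  pc5 <- pca_transform(trial_design(N = 8, m = 5, corr = exch_corr(5, 0.9)))
  expect_equal(pc5$eigenvalues, c(4.6, rep(0.1, 4)), tolerance = 1e-10)
  # orthonormality and the eigen-equation
  d5 <- trial_design(N = 8, m = 5, corr = exch_corr(5, 0.9))
  expect_equal(crossprod(pc5$A), diag(5), tolerance = 1e-10)
  for (k in 1:5)
    expect_equal(drop(d5$Sigma %*% pc5$A[, k]),
                 pc5$eigenvalues[k] * pc5$A[, k], tolerance = 1e-8)
})

test_that("correlated Sidak FWER reduces to the independent case at corr = I", {
  set.seed(41)
  d_id <- trial_design(N = 12, m = 3, corr = diag(3), sigma = c(1, 2, 0.5))
  pol <- bias_policy(c(0.2, 0.4, 0.1))
  for (i in 1:8) {
    t <- generate_sequence(rp_spec("EBC", p = 0.67), 12)
    if (sum(t) == 0 || sum(t) == 12) next
    tau <- bias_matrix(t, pol)
    expect_equal(sidak_fwer_correlated(t, tau, d_id),
                 sidak_fwer(t, tau, d_id), tolerance = 1e-12)
  }
})

test_that("error rates are invariant to endpoint relabelling", {
  set.seed(43)
  t <- generate_sequence(rp_spec("BSD", b = 3), 12)
  perm <- c(3, 1, 2)
  sig <- c(1, 1.5, 2)
  eta <- c(0.1, 0.3, 0.2)
  R <- exch_corr(3, 0.4)
  d1 <- trial_design(N = 12, m = 3, sigma = sig, corr = R)
  d2 <- trial_design(N = 12, m = 3, sigma = sig[perm], corr = R[perm, perm])
  tau1 <- bias_matrix(t, bias_policy(eta))
  tau2 <- bias_matrix(t, bias_policy(eta[perm]))
  expect_equal(sidak_fwer_correlated(t, tau1, d1),
               sidak_fwer_correlated(t, tau2, d2), tolerance = 1e-10)
  expect_equal(aon_t1e(t, tau1, d1), aon_t1e(t, tau2, d2), tolerance = 1e-12)
  # homogeneous effects + exchangeable correlation: fully symmetric
  d_h <- trial_design(N = 12, m = 3, corr = exch_corr(3, 0.6))
  tau_h <- bias_matrix(t, bias_policy(rep(0.2, 3)))
  expect_equal(sidak_fwer_correlated(t, tau_h, d_h),
               sidak_fwer_correlated(t, tau_h, d_h), tolerance = 0)
})

test_that("all-or-none T1E is the worst single-component rate", {
  set.seed(47)
  d <- trial_design(N = 12, m = 3, sigma = c(1, 2, 4))
  pol <- bias_policy(c(0.2, 0.2, 0.2))
  df <- 10
  c_one <- qt(0.05, df)
  for (i in 1:8) {
    t <- generate_sequence(rp_spec("CR"), 12)
    if (sum(t) == 0 || sum(t) == 12) next
    tau <- bias_matrix(t, pol)
    per_k <- vapply(1:3, function(k) {
      nc <- noncentrality(t, tau[, k], d$sigma[k])
      dnct_cdf(c_one, df, -nc$delta, nc$lam)
    }, numeric(1))
    expect_equal(aon_t1e(t, tau, d), max(per_k), tolerance = 1e-12)
  }
})

test_that("identically distributed components give m-independent T1E", {
  set.seed(53)
  for (i in 1:5) {
    t <- generate_sequence(rp_spec("PBR", block_size = 4), 32)
    tau2 <- bias_matrix(t, bias_policy(rep(0.1024, 2)))
    tau5 <- bias_matrix(t, bias_policy(rep(0.1024, 5)))
    expect_equal(aon_t1e(t, tau2, trial_design(32, 2)),
                 aon_t1e(t, tau5, trial_design(32, 5)), tolerance = 1e-14)
  }
})

test_that("batch rates agree with the per-list functions on all paths", {
  set.seed(59)
  N <- 16
  t_mat <- generate_sequences(rp_spec("CHEN", p = 0.67, b = 2), N, r = 20)
  # heterogeneous effects, unequal sigmas, independent endpoints
  pol <- bias_policy(c(0.15, 0.4))
  d_ind <- trial_design(N = N, m = 2, sigma = c(1, 1.7))
  got <- error_rates_batch(t_mat, pol, d_ind, "sidak")
  want <- apply(t_mat, 1, function(t)
    sidak_fwer(t, bias_matrix(t, pol), d_ind))
  expect_equal(got, want, tolerance = 1e-10)
  # correlated endpoints: batch uses the PCA path
  d_cor <- trial_design(N = N, m = 2, sigma = c(1, 1.7),
                        corr = exch_corr(2, 0.6))
  got_c <- error_rates_batch(t_mat, pol, d_cor, "sidak")
  want_c <- apply(t_mat, 1, function(t)
    sidak_fwer_correlated(t, bias_matrix(t, pol), d_cor))
  expect_equal(got_c, want_c, tolerance = 1e-10)
  # all-or-none
  got_a <- error_rates_batch(t_mat, pol, d_cor, "all_or_none")
  want_a <- apply(t_mat, 1, function(t)
    aon_t1e(t, bias_matrix(t, pol), d_cor))
  expect_equal(got_a, want_a, tolerance = 1e-10)
  # degenerate rows come back NA
  t_deg <- rbind(rep(1L, N), t_mat[1, ])
  expect_true(is.na(error_rates_batch(t_deg, pol, d_ind, "sidak")[1]))
})

test_that("design validation rejects malformed inputs", {
  expect_error(trial_design(3, 2), ">= 4")
  expect_error(trial_design(8, 2, alpha = 1.2), "alpha")
  expect_error(trial_design(8, 2, sigma = c(1, -1)), "positive")
  expect_error(trial_design(8, 2, corr = matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
  expect_error(trial_design(8, 2, corr = matrix(c(1, 0.2, 0.4, 1), 2)),
               "symmetric")
  bad <- exch_corr(2, 0.5)
  expect_error(sidak_fwer(c(1, 0, 1, 0, 1, 0, 1, 0),
                          matrix(0, 8, 2),
                          trial_design(8, 2, corr = bad)),
               "correlated")
})
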