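rt_chain <- function() {
  fx <- make_fixture("chain", n_reactions = 1, seed = 2)
  fx
}

test_that("the energy map R = [RT S', I] is assembled correctly", {
  fx <- rt_chain()    # single reaction A -> B
  R <- assemble_R(fx$network, fx$priors)
  RT <- 8.31446e-3 * 298.15
  expect_equal(dim(R), c(1L, 3L))
  expect_equal(R[1, ], c(-RT, RT, 1), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(RT, 2.4790, tolerance = 1e-4)
})

test_that("the energy map reproduces direct evaluation on random draws", {
  fx <- make_fixture("random", n_reactions = 6, seed = 4)
  R <- assemble_R(fx$network, fx$priors)
  SG <- fx$network$S[, fx$network$gamma, drop = FALSE]
  set.seed(1)
  for (i in 1:100) {
    lnc <- rnorm(nrow(SG))
    dg0 <- rnorm(ncol(SG))
    direct <- dg0 + fx$priors$RT * drop(t(SG) %*% lnc)
    expect_equal(drop(R %*% c(lnc, dg0)), direct, tolerance = 1e-12)
  }
})

test_that("joint covariance matches the hand expansion for one reaction", {
  fx <- rt_chain()
  sp <- build_thermo_space(fx$network, fx$priors)
  RT <- fx$priors$RT
  sA <- fx$priors$Sigma_c[1, 1]
  sB <- fx$priors$Sigma_c[2, 2]
  s0 <- fx$priors$Sigma_dg0[1, 1]
  expect_equal(drop(sp$Sigma_r), RT^2 * (sA + sB) + s0, tolerance = 1e-12)
})

test_that("zero prior covariance collapses the space to a point", {
  fx <- rt_chain()
  pr <- thermo_priors(mu_c = fx$priors$mu_c, Sigma_c = 0,
                      mu_dg0 = fx$priors$mu_dg0, Sigma_dg0 = 0)
  sp <- build_thermo_space(fx$network, pr)
  expect_identical(sp$q, 0L)
  expect_equal(max(abs(sp$Sigma_t)), 0)
  expect_equal(thermo_state(sp, numeric(0))$t, sp$mu_t)
})

test_that("Monte-Carlo covariance of t matches the assembled Sigma_t", {
  fx <- make_fixture("lumped", seed = 7)
  sp <- build_thermo_space(fx$network, fx$priors)
  set.seed(9)
  n <- 1e5
  m <- nrow(fx$network$S)
  g <- length(fx$network$gamma)
  Lc <- chol(fx$priors$Sigma_c)
  f0 <- psd_factor(fx$priors$Sigma_dg0)
  lnc <- matrix(rnorm(n * m), n) %*% Lc
  dg0 <- matrix(rnorm(n * f0$q), n) %*% t(f0$Q)
  lnc <- sweep(lnc, 2, -fx$priors$mu_c)
  dg0 <- sweep(dg0, 2, -fx$priors$mu_dg0)
  SG <- fx$network$S[, fx$network$gamma]
  dg <- dg0 + fx$priors$RT * lnc %*% SG
  emp <- cov(cbind(lnc, dg0, dg))
  expect_lt(max(abs(emp - sp$Sigma_t)), 0.05 * max(diag(sp$Sigma_t)))
})

test_that("psd factorization is rank revealing and reconstructs", {
  f <- psd_factor(diag(3))
  expect_identical(f$q, 3L)
  expect_equal(f$Q %*% t(f$Q), diag(3), tolerance = 1e-12)

  u <- c(1, -2, 0.5)
  f1 <- psd_factor(u %*% t(u))
  expect_identical(f1$q, 1L)

  # group-contribution-style covariance: correlated rows, deficient rank
  A <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  Sig <- A %*% diag(c(2, 3)) %*% t(A)
  fg <- psd_factor(Sig)
  expect_identical(fg$q, 2L)
  expect_lt(max(abs(fg$Q %*% t(fg$Q) - Sig)), 1e-10)

  expect_error(psd_factor(matrix(c(1, 0, 0, -1), 2)), "negative eigenvalue")
})

test_that("chi-square thresholds match quantile identities", {
  expect_equal(chi2_threshold(1, 0.95), 3.841, tolerance = 1e-3)
  # CDF of chi2 with 2 df at 2 is 1 - exp(-1)
  expect_equal(chi2_threshold(2, 1 - exp(-1)), 2, tolerance = 1e-12)
  expect_gt(chi2_threshold(3, 0.999999), chi2_threshold(3, 0.95))
  expect_error(chi2_threshold(2, 1.2), "alpha")
  expect_error(chi2_threshold(0, 0.9), "q must be")
})

test_that("whitened coordinates reproduce the Mahalanobis form", {
  fx <- make_fixture("lumped", seed = 3, rank_deficient = TRUE)
  sp <- build_thermo_space(fx$network, fx$priors)
  expect_equal(thermo_state(sp, numeric(sp$q))$t, sp$mu_t)
  set.seed(2)
  for (i in 1:20) {
    m <- rnorm(sp$q)
    t_vec <- thermo_state(sp, m)$t
    qf <- drop(t(t_vec - sp$mu_t) %*% sp$Sigma_t_pinv %*% (t_vec - sp$mu_t))
    expect_equal(qf, sum(m^2), tolerance = 1e-8)
  }
})

test_that("every generated state satisfies the linear energy identity", {
  for (topo in c("chain", "lumped", "branch")) {
    fx <- make_fixture(topo, seed = 5)
    sp <- build_thermo_space(fx$network, fx$priors)
    SG <- fx$network$S[, fx$network$gamma, drop = FALSE]
    set.seed(8)
    for (i in 1:25) {
      st <- thermo_state(sp, rnorm(sp$q))
      resid <- st$dg - st$dg0 - sp$RT * drop(t(SG) %*% st$ln_c)
      expect_lt(max(abs(resid)), 1e-8)
    }
  }
})

test_that("rank-deficient standard-energy priors shrink the reduced rank", {
  fx <- make_fixture("lumped", seed = 1)     # lumped reaction => dependency
  sp <- build_thermo_space(fx$network, fx$priors)
  expect_lt(sp$q_r, length(sp$gamma_ids))
  full <- make_fixture("lumped", seed = 1)
  full$priors$Sigma_dg0 <- diag(3)         # break the dependency
  sp2 <- build_thermo_space(full$network, full$priors)
  expect_identical(sp2$q_r, length(sp2$gamma_ids))
})

test_that("conditioning on energies has the right degenerate limits", {
  fx <- make_fixture("chain", n_reactions = 2, seed = 6)
  pr <- fx$priors
  sp <- build_thermo_space(fx$network, pr)
  # at the prior mean the conditional mean is the prior mean
  cond <- condition_on_dg(sp, sp$mu_r)
  expect_equal(cond$mean, c(pr$mu_c, pr$mu_dg0), tolerance = 1e-9)

  # exact standard energies: conditional dg0 degenerate at mu0, and the
  # conditional ln c mean reproduces dg through the activity term
  pr0 <- thermo_priors(pr$mu_c, pr$Sigma_c, pr$mu_dg0, Sigma_dg0 = 0)
  sp0 <- build_thermo_space(fx$network, pr0)
  dg <- drop(sp0$mu_r + sp0$Q_r %*% rnorm(sp0$q_r))
  c0 <- condition_on_dg(sp0, dg)
  m <- nrow(fx$network$S)
  g <- length(fx$network$gamma)
  expect_equal(c0$mean[m + seq_len(g)], pr$mu_dg0, tolerance = 1e-8)
  expect_lt(max(abs(c0$cov[m + seq_len(g), m + seq_len(g)])), 1e-9)
  SG <- fx$network$S[, fx$network$gamma, drop = FALSE]
  dg_from_c <- pr$mu_dg0 + sp0$RT * drop(t(SG) %*% c0$mean[seq_len(m)])
  expect_equal(dg_from_c, dg, tolerance = 1e-8, ignore_attr = TRUE)

  # a vector outside the support is rejected
  if (sp$q_r < length(sp$mu_r)) {
    expect_error(condition_on_dg(sp, sp$mu_r + 1e3 * rnorm(length(sp$mu_r))),
                 "support")
  }
})

test_that("conditional moments match a rejection oracle on 2 reactions", {
  fx <- make_fixture("chain", n_reactions = 2, seed = 3)
  sp <- build_thermo_space(fx$network, fx$priors)
  dg_target <- drop(sp$mu_r + sp$Q_r %*% c(0.4, -0.3))
  cond <- condition_on_dg(sp, dg_target)
  # rejection: joint prior draws whose mapped energies land near dg_target
  set.seed(4)
  n <- 6e5
  m <- nrow(fx$network$S)
  Lc <- chol(fx$priors$Sigma_c)
  f0 <- psd_factor(fx$priors$Sigma_dg0)
  lnc <- sweep(matrix(rnorm(n * m), n) %*% Lc, 2, -fx$priors$mu_c)
  dg0 <- sweep(matrix(rnorm(n * f0$q), n) %*% t(f0$Q), 2,
               -fx$priors$mu_dg0)
  SG <- fx$network$S[, fx$network$gamma]
  dg <- dg0 + fx$priors$RT * lnc %*% SG
  keep <- sqrt(rowSums(sweep(dg, 2, dg_target)^2)) < 0.35
  expect_gt(sum(keep), 500)
  emp_mean <- colMeans(cbind(lnc, dg0)[keep, ])
  se <- apply(cbind(lnc, dg0)[keep, ], 2, sd) / sqrt(sum(keep))
  expect_true(all(abs(emp_mean - cond$mean) < 3 * se + 0.05))
})

test_that("serialization round-trips the space geometry", {
  fx <- make_fixture("lumped", seed = 2)
  sp <- build_thermo_space(fx$network, fx$priors)
  p <- withr::local_tempfile(fileext = ".json")
  write_thermo_space(sp, p)
  back <- read_thermo_space(p)
  expect_equal(back$mu_t, sp$mu_t, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$Sigma_r, sp$Sigma_r, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$q_r, sp$q_r)
  expect_equal(back$chi2_r, sp$chi2_r)
  m <- rnorm(sp$q)
  expect_equal(thermo_state(back, m)$t, thermo_state(sp, m)$t,
               tolerance = 1e-10, ignore_attr = TRUE)
})
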