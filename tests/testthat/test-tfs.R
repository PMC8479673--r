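test_that("steady-state feasibility matches flux coupling on the lumped
           pathway fixture", {
  fx <- make_fixture("lumped", seed = 1)
  cache <- new.env()
  # both sequential steps share their flux, the shortcut is free
  expect_true(steady_state_feasible(fx$network, c(1L, 1L, 1L),
                                    cache = cache))
  expect_false(steady_state_feasible(fx$network, c(1L, -1L, 1L),
                                     cache = cache))
  expect_true(steady_state_feasible(fx$network, c(-1L, -1L, -1L),
                                    cache = cache))
  # memoization: cached value is returned without recomputation
  expect_true("+++" %in% ls(cache))
})

test_that("patterns flipping an irreversible reaction fail the precheck", {
  fx <- make_fixture("chain", n_reactions = 2, reversible = FALSE, seed = 1)
  expect_false(steady_state_feasible(fx$network, c(-1L, -1L)))
})

test_that("ray intersection partitions the chord consistently with a dense
           scan", {
  fx <- make_fixture("random", n_reactions = 6, seed = 13)
  sp <- build_thermo_space(fx$network, fx$priors)
  pts <- find_initial_points(fx$network, sp)
  m0 <- pts[[1]]$m_r
  cache <- new.env()
  fixed <- thermoflux:::fixed_directions(fx$network)
  set.seed(5)
  for (rep in 1:40) {
    u <- rnorm(sp$q_r)
    u <- u / sqrt(sum(u^2))
    segs <- intersect_ray(sp, fx$network, m0, u, cache = cache)
    expect_gt(nrow(segs), 0)
    # segments are ordered, disjoint, and the current point's segment is
    # feasible
    expect_true(all(diff(c(t(segs[, c("a", "b")]))) >= -1e-12))
    cur <- which(segs$a <= 0 & segs$b >= 0)
    expect_true(segs$feasible[cur])
    # dense scan: orthant at sampled points matches the segment signature
    for (i in seq_len(nrow(segs))) {
      ss <- seq(segs$a[i] + 1e-9, segs$b[i] - 1e-9, length.out = 25)
      dg <- sp$mu_r + sp$Q_r %*% (outer(m0, rep(1, 25)) + outer(u, ss))
      signs <- ifelse(dg < 0, 1L, -1L)
      signs[!is.na(fixed), ] <- fixed[!is.na(fixed)]
      keys <- thermoflux:::orthant_key(signs)
      expect_true(all(keys == segs$signature[i]))
    }
    # inside the ball
    ends <- outer(m0, rep(1, 2)) + outer(u, range(segs$a, segs$b))
    expect_true(all(colSums(ends^2) <= sp$chi2_r + 1e-6))
  }
})

test_that("rays never cross more orthant cells than sign-constrained
           reactions plus one", {
  fx <- make_fixture("random", n_reactions = 6, seed = 13)
  sp <- build_thermo_space(fx$network, fx$priors)
  pts <- find_initial_points(fx$network, sp)
  cache <- new.env()
  g_free <- sum(is.na(thermoflux:::fixed_directions(fx$network)))
  set.seed(11)
  for (rep in 1:200) {
    u <- rnorm(sp$q_r)
    u <- u / sqrt(sum(u^2))
    segs <- intersect_ray(sp, fx$network, pts[[1]]$m_r, u, cache = cache)
    expect_lte(attr(segs, "n_crossed"), g_free + 1)
  }
})

test_that("a degenerate chord from an exterior point errors", {
  fx <- make_fixture("lumped", seed = 1)
  sp <- build_thermo_space(fx$network, fx$priors)
  far <- rep(10, sp$q_r)
  expect_error(intersect_ray(sp, fx$network, far, c(1, rep(0, sp$q_r - 1))),
               "inside the ball")
})

test_that("tail-segment weights stay finite in log scale", {
  lw <- thermoflux:::log_pnorm_diff(c(8, -9, -0.5), c(9, -8, 0.5))
  expect_true(all(is.finite(lw)))
  expect_equal(exp(lw[3]), pnorm(0.5) - pnorm(-0.5), tolerance = 1e-12)
  # symmetric tails have equal mass
  expect_equal(lw[1], lw[2], tolerance = 1e-10)
  # truncated draws from a far-tail segment remain inside it
  u <- seq(0.05, 0.95, by = 0.1)
  x <- vapply(u, function(ui) thermoflux:::truncnorm_draw(8, 9, ui),
              numeric(1))
  expect_true(all(is.finite(x) & x >= 8 & x <= 9))
  expect_true(all(diff(x) > 0))     # monotone in u
})

test_that("single-chord sampling reproduces the truncated normal", {
  # one reversible reaction, both directions feasible: the stationary law in
  # the 1-D whitened coordinate is the standard normal truncated to the ball
  fx <- make_fixture("chain", n_reactions = 1, seed = 2)
  pr <- thermo_priors(fx$priors$mu_c, 0, fx$priors$mu_dg0, 4^2)
  sp <- build_thermo_space(fx$network, pr)
  expect_identical(sp$q_r, 1L)
  s <- run_tfs(fx$network, sp, n_steps = 6000, n_chains = 2, seed = 4,
               burn_in = 0.1, n_retain = 2000)
  r <- sqrt(sp$chi2_r)
  draws <- (pool_dg(s) - sp$mu_r) / sqrt(drop(sp$Sigma_r))
  ptrunc <- function(x) (pnorm(pmin(pmax(x, -r), r)) - pnorm(-r)) /
    (pnorm(r) - pnorm(-r))
  ks <- suppressWarnings(ks.test(draws, ptrunc))
  expect_gt(ks$p.value, 0.01)
})

test_that("orthant probabilities on one reversible reaction match the
           truncated-normal split", {
  fx <- make_fixture("chain", n_reactions = 1, seed = 6)
  pr <- thermo_priors(fx$priors$mu_c, 0.5^2, mu_dg0 = 1.5, Sigma_dg0 = 2^2)
  sp <- build_thermo_space(fx$network, pr)
  s <- run_tfs(fx$network, sp, n_steps = 8000, n_chains = 4, seed = 2,
               burn_in = 0.2, n_retain = 1000)
  r <- sqrt(sp$chi2_r)
  mu <- drop(sp$mu_r)
  sd <- sqrt(drop(sp$Sigma_r))
  lo <- pnorm(-r)
  p_neg <- (pnorm(pmin(pmax(-mu / sd, -r), r)) - lo) /
    (pnorm(r) - lo)                      # P(dg < 0 | inside ball)
  p_hat <- s$orthants$probability[s$orthants$signature == "+"]
  se <- orthant_prob_tol(s, Inf, p_neg)("+")
  expect_lt(abs(p_hat - p_neg), max(se, 0.03))
})

test_that("sampled orthant frequencies match the rejection oracle", {
  fx <- make_fixture("lumped", seed = 1)
  sp <- build_thermo_space(fx$network, fx$priors)
  s <- run_tfs(fx$network, sp, n_steps = 4000, n_chains = 4, seed = 7,
               n_retain = 800)
  ro <- rejection_oracle(fx$network, sp, n_draws = 2e5, seed = 3)
  tol_fun <- NULL
  for (i in seq_len(nrow(ro$orthants))) {
    sig <- ro$orthants$signature[i]
    p_ref <- ro$orthants$probability[i]
    p_hat <- s$orthants$probability[match(sig, s$orthants$signature)]
    if (is.na(p_hat)) p_hat <- 0
    tol <- orthant_prob_tol(s, sum(ro$orthants$count), p_ref)(sig)
    expect_lt(abs(p_hat - p_ref), max(tol, 0.03), label = sig)
  }
})

test_that("every retained sample respects the space constraints", {
  fx <- make_fixture("random", n_reactions = 6, seed = 13)
  sp <- build_thermo_space(fx$network, fx$priors)
  s <- run_tfs(fx$network, sp, n_steps = 1500, n_chains = 2, seed = 9,
               n_retain = 300)
  fixed <- thermoflux:::fixed_directions(fx$network)
  cache <- new.env()
  for (ch in seq_along(s$dg)) {
    dg <- s$dg[[ch]]
    mm <- s$m[[ch]]
    expect_true(all(rowSums(mm^2) <= sp$chi2_r + 1e-9))
    for (k in which(!is.na(fixed)))
      expect_true(all(fixed[k] * dg[, k] < 0))
    signs <- ifelse(dg < 0, 1L, -1L)
    for (i in seq_len(nrow(signs)))
      expect_true(steady_state_feasible(fx$network, signs[i, ],
                                        cache = cache))
  }
})

test_that("identical seeds give identical chains; different seeds differ", {
  fx <- make_fixture("lumped", seed = 2)
  sp <- build_thermo_space(fx$network, fx$priors)
  a <- run_tfs(fx$network, sp, n_steps = 400, n_chains = 2, seed = 5)
  b <- run_tfs(fx$network, sp, n_steps = 400, n_chains = 2, seed = 5)
  c <- run_tfs(fx$network, sp, n_steps = 400, n_chains = 2, seed = 6)
  expect_identical(a$dg, b$dg)
  expect_identical(a$orthants, b$orthants)
  expect_false(identical(a$dg, c$dg))
})

test_that("chains started in different orthants converge on a connected
           space", {
  fx <- make_fixture("lumped", seed = 1)
  sp <- build_thermo_space(fx$network, fx$priors)
  s <- run_tfs(fx$network, sp, n_steps = 12000, n_chains = 4, seed = 11,
               n_retain = 2000)
  expect_lt(max(s$psrf, na.rm = TRUE), 1.05)
  expect_gt(min(s$ess, na.rm = TRUE), 100)
})

test_that("reparametrization leaves the stationary marginals unchanged", {
  fx <- make_fixture("branch", seed = 2)
  sp <- build_thermo_space(fx$network, fx$priors)
  base <- run_tfs(fx$network, sp, n_steps = 8000, n_chains = 2, seed = 3,
                  n_retain = 1500)
  # no adaptation below threshold
  sp_same <- adapt_parametrization(sp, rep(1, sp$q_r))
  expect_identical(sp_same$sampling_scales, sp$sampling_scales)
  # inflate one direction only
  pilot <- rep(1, sp$q_r)
  pilot[1] <- 1.5
  sp_ad <- adapt_parametrization(sp, pilot)
  expect_equal(sp_ad$sampling_scales[1], 1.5^2)
  expect_true(all(sp_ad$sampling_scales[-1] == 1))
  ad <- run_tfs(fx$network, sp_ad, n_steps = 8000, n_chains = 2, seed = 13,
                n_retain = 1500)
  for (k in seq_along(sp$gamma_ids)) {
    ks <- suppressWarnings(ks.test(pool_dg(base)[, k], pool_dg(ad)[, k]))
    expect_gt(ks$p.value, 0.005)
  }
})

test_that("conditional draws reconstruct consistent full states", {
  fx <- make_fixture("lumped", seed = 2)
  sp <- build_thermo_space(fx$network, fx$priors)
  s <- run_tfs(fx$network, sp, n_steps = 1000, n_chains = 2, seed = 8,
               n_retain = 250)
  dg <- pool_dg(s)
  cs <- sample_concentrations(sp, dg, seed = 4)
  SG <- fx$network$S[, fx$network$gamma]
  resid <- dg - cs$dg0 - sp$RT * cs$ln_c %*% SG
  expect_lt(max(abs(resid)), 1e-8)
  # degenerate standard energies: activity term reproduces dg exactly
  pr0 <- thermo_priors(fx$priors$mu_c, fx$priors$Sigma_c,
                       fx$priors$mu_dg0, 0)
  sp0 <- build_thermo_space(fx$network, pr0)
  dg0_draw <- t(sp0$mu_r + sp0$Q_r %*% matrix(rnorm(5 * sp0$q_r), sp0$q_r))
  cs0 <- sample_concentrations(sp0, dg0_draw, seed = 2)
  expect_lt(max(abs(sweep(cs0$dg0, 2, fx$priors$mu_dg0))), 1e-8)
  resid0 <- dg0_draw - cs0$dg0 - sp0$RT * cs0$ln_c %*% SG
  expect_lt(max(abs(resid0)), 1e-8)
  # conditioning at the reduced mean returns the prior means
  csm <- sample_concentrations(sp, matrix(sp$mu_r, 1), seed = 1)
  cond <- condition_on_dg(sp, sp$mu_r)
  expect_equal(cond$mean, c(fx$priors$mu_c, fx$priors$mu_dg0),
               tolerance = 1e-9, ignore_attr = TRUE)
})
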