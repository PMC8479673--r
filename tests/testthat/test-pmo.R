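single_rxn_space <- function(mu_dg0, lb = -10, sd0 = 2, sd_c = 0) {
  S <- matrix(c(-1, 1, 1, 0, 0, -1), 2, 3,
              dimnames = list(c("A", "B"), c("R1", "EX_A", "EX_B")))
  net <- metabolic_network(S, lb = c(lb, -10, -10), ub = c(10, 10, 10))
  net <- select_thermo_reactions(net)
  pr <- thermo_priors(mu_c = c(log(1e-4), log(1e-4)), Sigma_c = sd_c^2,
                      mu_dg0 = mu_dg0, Sigma_dg0 = sd0^2)
  list(net = net, sp = build_thermo_space(net, pr))
}

test_that("a reaction favorable at the prior mean has the mode at the mean", {
  x <- single_rxn_space(mu_dg0 = -12)
  fit <- solve_pmo(x$net, x$sp)
  expect_identical(fit$status, "optimal")
  expect_equal(fit$objective, 0, tolerance = 1e-9)
  expect_equal(fit$t_star$t, x$sp$mu_t, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(abs(fit$z$z) < 1e-6, na.rm = TRUE))
})

test_that("forced forward flux against an unfavorable prior lands on the
           second-law boundary with the closed-form objective", {
  eps <- 0.1
  # irreversible with mu(dg) > 0: wide enough prior that the boundary state
  # stays inside the confidence ellipsoid
  x <- single_rxn_space(mu_dg0 = 5, lb = 0, sd0 = 4)
  fit <- solve_pmo(x$net, x$sp, eps = eps)
  expect_identical(fit$status, "optimal")
  sigma_r <- sqrt(drop(x$sp$Sigma_r))
  mu_r <- drop(x$sp$mu_r)
  expect_equal(fit$t_star$dg, -eps, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$objective, ((mu_r + eps) / sigma_r)^2, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("the optimizer matches exhaustive orthant enumeration", {
  cases <- list(
    make_fixture("lumped", seed = 1),
    make_fixture("lumped", seed = 8),
    make_fixture("branch", seed = 2),
    make_fixture("random", n_reactions = 6, seed = 13),
    make_fixture("random", n_reactions = 8, seed = 7, rank_deficient = TRUE)
  )
  for (fx in cases) {
    sp <- build_thermo_space(fx$network, fx$priors)
    fit <- solve_pmo(fx$network, sp)
    ref <- pmo_oracle(fx$network, sp)
    if (is.finite(ref)) {
      expect_identical(fit$status, "optimal")
      expect_equal(fit$objective, ref, tolerance = 1e-6,
                   label = paste(fx$topology, fx$seed))
    } else {
      expect_identical(fit$status, "infeasible")
    }
  }
})

test_that("optimal states satisfy steady state, the second law and the
           confidence constraint", {
  fx <- make_fixture("lumped", seed = 4)
  sp <- build_thermo_space(fx$network, fx$priors)
  fit <- solve_pmo(fx$network, sp, eps = 0.1, v_min = 1e-6)
  v <- fit$v_star
  expect_lt(max(abs(fx$network$S %*% v)), 1e-8)
  dg <- fit$t_star$dg
  vG <- v[fx$network$gamma]
  expect_true(all(sign(vG) * dg <= -0.1 + 1e-9))
  expect_true(all(abs(vG) >= 1e-6 - 1e-12))
  expect_lte(fit$objective, sp$chi2 + 1e-9)
})

test_that("additional constraints never decrease the optimum", {
  fx <- make_fixture("lumped", seed = 6)
  sp <- build_thermo_space(fx$network, fx$priors)
  base <- solve_pmo(fx$network, sp)
  # fix a direction
  sig <- key_sign <- substr(base$signature, 1, 1)
  flip <- if (sig == "+") -1L else 1L
  con <- solve_pmo(fx$network, sp,
                   direction_constraints = c(R1 = flip))
  if (con$status == "optimal")
    expect_gte(con$objective, base$objective - 1e-9)
  # measured concentration far from the prior mean
  con2 <- solve_pmo(fx$network, sp,
                    concentration_constraints = tibble::tibble(
                      metabolite = "A", lb = log(1e-2), ub = log(1e-2)))
  if (con2$status == "optimal") {
    expect_gte(con2$objective, base$objective - 1e-9)
    expect_equal(fit_lnc <- con2$t_star$ln_c[1], log(1e-2),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("flux bound overrides narrow the witness", {
  fx <- make_fixture("chain", n_reactions = 2, seed = 2)
  sp <- build_thermo_space(fx$network, fx$priors)
  fit <- solve_pmo(fx$network, sp,
                   flux_constraints = tibble::tibble(
                     reaction = "R1", lb = 1, ub = 2))
  expect_identical(fit$status, "optimal")
  expect_gte(fit$v_star[["R1"]], 1 - 1e-9)
  expect_lte(fit$v_star[["R1"]], 2 + 1e-9)
})

test_that("z-scores follow the definition and flag degenerate sds", {
  fx <- make_fixture("chain", n_reactions = 1, seed = 2)
  sp <- build_thermo_space(fx$network, fx$priors)
  z0 <- z_scores(sp$mu_t, sp)
  expect_true(all(z0$z == 0))
  t2 <- sp$mu_t + 2 * sqrt(diag(sp$Sigma_t))
  z2 <- z_scores(t2, sp)
  expect_true(all(abs(z2$z[z2$sd > 0] - 2) < 1e-9))
  # zero-sd variable away from its mean is flagged NA
  pr0 <- thermo_priors(fx$priors$mu_c, 0, fx$priors$mu_dg0, 1)
  sp0 <- build_thermo_space(fx$network, pr0)
  zt <- sp0$mu_t
  zt[1] <- zt[1] + 1
  expect_true(is.na(z_scores(zt, sp0)$z[1]))
})

test_that("anomaly classification applies both rules", {
  fx <- make_fixture("chain", n_reactions = 1, seed = 2)
  net <- fx$network
  net$compartment <- c("c", "p")       # second metabolite periplasmic
  sp <- build_thermo_space(net, fx$priors)
  z <- z_scores(sp$mu_t, sp)
  z$z[z$kind == "ln_c"] <- c(0.5, 1.2)
  out <- classify_anomalies(z, net, theta = 1)
  expect_identical(out$metabolite, "M2")
  expect_identical(out$rule, "z")

  # periplasmic metabolite at 12 mM with z = 0 is flagged by concentration
  z2 <- z_scores(sp$mu_t, sp)
  z2$value[2] <- log(0.012)
  out2 <- classify_anomalies(z2, net, theta = 1)
  expect_identical(out2$metabolite, "M2")
  expect_identical(out2$rule, "concentration")

  # huge theta and low concentrations: nothing flagged
  out3 <- classify_anomalies(z_scores(sp$mu_t, sp), net, theta = Inf)
  expect_identical(nrow(out3), 0L)
})

test_that("initial points cover both directions of a reversible reaction", {
  x <- single_rxn_space(mu_dg0 = 0, sd0 = 4)
  pts <- find_initial_points(x$net, x$sp)
  expect_lte(length(pts), 2)
  sigs <- vapply(pts, `[[`, "", "signature")
  expect_identical(sort(sigs), c("+", "-"))
})

test_that("an all-irreversible network yields exactly one starting point", {
  fx <- make_fixture("chain", n_reactions = 3, reversible = FALSE, seed = 2)
  sp <- build_thermo_space(fx$network, fx$priors)
  pts <- find_initial_points(fx$network, sp)
  expect_identical(length(pts), 1L)
})

test_that("starting points are strictly interior and orthant-feasible", {
  fx <- make_fixture("lumped", seed = 9)
  sp <- build_thermo_space(fx$network, fx$priors)
  pts <- find_initial_points(fx$network, sp)
  cache <- new.env()
  for (p in pts) {
    expect_lt(sum(p$m_r^2), sp$chi2_r)           # strictly inside
    dg <- reduced_dg(sp, p$m_r)
    expect_true(all(p$signs * dg < 0))           # strict second law
    expect_true(steady_state_feasible(fx$network, p$signs, cache = cache))
  }
})
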