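test_that("an orthant polytope of a chain is the expected segment", {
  fx <- make_fixture("chain", n_reactions = 2, seed = 2)
  v_min <- 1e-3
  poly <- build_orthant_polytope(fx$network, c(1L, 1L), v_min = v_min)
  X <- chrr_sample(poly, 500, seed = 1)
  # all fluxes equal along the chain (including exchanges, up to sign
  # convention) and confined to [v_min, 10]
  expect_lt(max(abs(X[, "R1"] - X[, "R2"])), 1e-9)
  expect_true(all(X[, "R1"] >= v_min - 1e-9 & X[, "R1"] <= 10 + 1e-9))
  expect_lt(max(abs(fx$network$S %*% t(X))), 1e-8)
  # uniform along the segment
  ks <- suppressWarnings(
    ks.test(X[, "R1"], "punif", v_min, max(X[, "R1"])))
  expect_gt(ks$p.value, 0.005)
})

test_that("patterns flipping an irreversible reaction are rejected before
           construction", {
  fx <- make_fixture("chain", n_reactions = 2, reversible = FALSE, seed = 2)
  expect_error(build_orthant_polytope(fx$network, c(-1L, 1L)),
               "irreversible")
})

test_that("polytope emptiness agrees with the feasibility oracle", {
  fx <- make_fixture("random", n_reactions = 6, seed = 13)
  g <- length(fx$network$gamma)
  combos <- as.matrix(expand.grid(rep(list(c(1L, -1L)), g)))
  cache <- new.env()
  for (i in seq_len(nrow(combos))) {
    d <- combos[i, ]
    feas <- steady_state_feasible(fx$network, d, cache = cache)
    fixed <- thermoflux:::fixed_directions(fx$network)
    if (any(!is.na(fixed) & d != fixed)) next
    built <- tryCatch(
      build_orthant_polytope(fx$network, d),
      error = function(e) NULL)
    expect_identical(!is.null(built), feas,
                     label = paste(d, collapse = ","))
  }
})

test_that("coordinate hit-and-run is uniform on a hypercube", {
  box <- make_polytope(lb = rep(0, 3), ub = rep(1, 3),
                       names = paste0("x", 1:3))
  X <- chrr_sample(box, 1e4, seed = 2)
  se <- sqrt(1 / 12) / sqrt(nrow(X))
  expect_true(all(abs(colMeans(X) - 0.5) < 3 * se + 0.005))
  expect_true(all(X >= 0 & X <= 1))
  # second moment of U(0,1)
  expect_true(all(abs(colMeans(X^2) - 1 / 3) < 0.01))
})

test_that("coordinate hit-and-run is uniform on the 2-simplex", {
  sx <- make_polytope(A_eq = matrix(1, 1, 3), b_eq = 1,
                      lb = rep(0, 3), ub = rep(1, 3))
  X <- chrr_sample(sx, 1e4, seed = 3)
  # Dirichlet(1,1,1) moments: mean 1/3, sd sqrt(1/18)
  se <- sqrt(1 / 18) / sqrt(nrow(X))
  expect_true(all(abs(colMeans(X) - 1 / 3) < 3 * se + 0.005))
  expect_lt(max(abs(rowSums(X) - 1)), 1e-9)
  expect_true(all(X > -1e-9))
})

test_that("a 1-D polytope gives uniform draws (KS)", {
  seg <- make_polytope(lb = -2, ub = 5, names = "x")
  X <- chrr_sample(seg, 4000, seed = 4)
  ks <- suppressWarnings(ks.test(X[, 1], "punif", -2, 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("chrr draws are deterministic given the seed", {
  box <- make_polytope(lb = rep(0, 2), ub = rep(1, 2))
  expect_identical(chrr_sample(box, 100, seed = 7),
                   chrr_sample(box, 100, seed = 7))
  expect_false(identical(chrr_sample(box, 100, seed = 7),
                         chrr_sample(box, 100, seed = 8)))
})

test_that("a single-orthant table sends all draws to that orthant", {
  fx <- make_fixture("chain", n_reactions = 2, seed = 2)
  tab <- tibble::tibble(signature = "++", probability = 1)
  fs <- sample_flux_mixture(fx$network, tab, n_total = 50, seed = 1)
  expect_identical(nrow(fs$samples), 50L)
  expect_true(all(fs$samples$orthant == "++"))
})

test_that("draw counts follow orthant probabilities up to rounding", {
  fx <- make_fixture("lumped", seed = 1)
  tab <- tibble::tibble(signature = c("+++", "---"),
                        probability = c(0.1, 0.9))
  fs <- sample_flux_mixture(fx$network, tab, n_total = 1000, seed = 2)
  alloc <- fs$allocation
  expect_identical(alloc$n_draws[alloc$signature == "---"], 900L)
  expect_identical(alloc$n_draws[alloc$signature == "+++"], 100L)
  # tags match the allocation
  expect_identical(sum(fs$samples$orthant == "---"), 900L)
  # every draw respects its orthant's signs on constrained reactions
  gam <- fx$network$reaction_ids[fx$network$gamma]
  for (sig in alloc$signature) {
    d <- thermoflux:::key_to_signs(sig)
    sub <- as.matrix(fs$samples[fs$samples$orthant == sig, gam])
    expect_true(all(sweep(sub, 2, d, `*`) > 0))
  }
})

test_that("the pooled flux mixture matches closed-form orthant-wise
           moments on a chain", {
  # both chain orthants are segments [v_min, 10]; mixture of uniforms with
  # weights (p, 1-p) has mean p*E[U+] + (1-p)*E[U-]
  fx <- make_fixture("chain", n_reactions = 2, seed = 2)
  p <- 0.7
  tab <- tibble::tibble(signature = c("++", "--"), probability = c(p, 1 - p))
  fs <- sample_flux_mixture(fx$network, tab, n_total = 4000, seed = 5)
  v <- fs$samples$R1
  mid <- (1e-6 + 10) / 2
  expect_equal(mean(v), p * mid + (1 - p) * (-mid), tolerance = 0.15)
  expect_equal(mean(v > 0), p, tolerance = 0.02)
})

test_that("direction calls honor the agreement threshold", {
  M <- cbind(a = rep(1, 100), b = c(rep(1, 96), rep(-1, 4)),
             c = c(rep(1, 50), rep(-1, 50)))
  out <- call_directions(M, threshold = 0.95)
  expect_identical(out$call, c("forward", "forward", "reversible"))
  out2 <- call_directions(-M, threshold = 0.95)
  expect_identical(out2$call, c("backward", "backward", "reversible"))
})

test_that("direction calls from fluxes and energies agree when well
           resolved", {
  fx <- make_fixture("chain", n_reactions = 2, seed = 4)
  sp <- build_thermo_space(fx$network, fx$priors)
  s <- run_tfs(fx$network, sp, n_steps = 2000, n_chains = 2, seed = 3,
               n_retain = 500)
  fs <- sample_flux_mixture(fx$network, s$orthants, n_total = 500, seed = 4)
  from_dg <- call_directions(s)
  from_flux <- call_directions(fs)
  both <- dplyr::inner_join(from_dg, from_flux, by = "reaction")
  resolved <- both$call.x != "reversible" & both$call.y != "reversible"
  expect_true(all(both$call.x[resolved] == both$call.y[resolved]))
})
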