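# Synthetic networks, priors and ground-truth oracles.
#
# Fixtures are small (2-12 reactions) and deterministic given (topology,
# seed).  Standard-energy covariances can be generated group-contribution
# style (dg0 = A g with independent group energies g), which makes them
# rank-deficient exactly when the topology carries a stoichiometric
# dependency -- e.g. a shortcut reaction equal to the sum of two steps, whose
# energy is then the sum of the step energies.

#' Generate a toy network with thermodynamic priors
#'
#' Topologies:
#' \describe{
#'   \item{chain}{linear pathway `M1 -> M2 -> ... `, import/export exchanges.}
#'   \item{branch}{a branch point: one substrate, two alternative products.}
#'   \item{cycle}{a three-reaction internal loop plus an exchange.}
#'   \item{lumped}{two sequential reactions `A -> B -> C` plus the lumped
#'     shortcut `A -> C`; the shortcut's energy equals the sum of the step
#'     energies, so the reduced covariance drops rank when the priors respect
#'     the dependency.}
#'   \item{propionate}{a propionate-metabolism motif with three irreversible
#'     reactions closing a directed loop (acyl-CoA ligase against the
#'     phosphotransferase/kinase degradation route) -- a deliberately
#'     inconsistent model exhibiting a forced internal cycle.}
#'   \item{random}{a random sparse network with import/export exchanges.}
#' }
#'
#' @param topology fixture family, see details.
#' @param n_reactions number of internal reactions (chain/random).
#' @param reversible logical vector (recycled) marking internal reactions as
#'   reversible; defaults per topology.
#' @param seed integer seed controlling the random draws of prior means/sds
#'   (and topology for `"random"`).
#' @param sd_ln_c prior standard deviation of log-concentrations.
#' @param mu_ln_c prior mean of log-concentrations (default ln 1e-4 M).
#' @param dg0_sd_range range the standard-energy group sds are drawn from
#'   (kJ/mol).
#' @param rank_deficient generate the standard-energy covariance from shared
#'   group energies (rank-deficient when dependencies exist) instead of a
#'   diagonal.
#' @param fixed make the `propionate` motif consistent (ligase reversible).
#' @return list with `network` (constrained set already selected) and
#'   `priors`.
#' @export
make_fixture <- function(topology = c("chain", "branch", "cycle", "lumped",
                                      "propionate", "random"),
                         n_reactions = 4, reversible = NULL, seed = 1,
                         sd_ln_c = 1.0, mu_ln_c = log(1e-4),
                         dg0_sd_range = c(1, 10), rank_deficient = FALSE,
                         fixed = FALSE) {
  topology <- match.arg(topology)
  build <- switch(topology,
                  chain = fixture_chain(n_reactions, reversible),
                  branch = fixture_branch(reversible),
                  cycle = fixture_cycle(reversible),
                  lumped = fixture_lumped(),
                  propionate = fixture_propionate(fixed),
                  random = fixture_random(n_reactions, reversible, seed))
  net <- build$network
  net <- select_thermo_reactions(net)
  g <- length(net$gamma)
  m <- nrow(net$S)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  # group-contribution style priors on the internal reactions
  if (topology == "lumped" || rank_deficient || topology == "propionate") {
    # each metabolite has a formation-energy-like group variable; reaction
    # standard energies are stoichiometric combinations, so stoichiometric
    # dependencies carry over to the covariance (and to the means).
    SG <- net$S[, net$gamma, drop = FALSE]
    gf <- stats::runif(m, -15, 5)
    sdf <- stats::runif(m, dg0_sd_range[1], dg0_sd_range[2]) / 2
    mu_dg0 <- drop(t(SG) %*% gf)
    Sigma_dg0 <- t(SG) %*% diag(sdf^2, m) %*% SG
  } else {
    mu_dg0 <- stats::runif(g, -20, 5)
    Sigma_dg0 <- diag(stats::runif(g, dg0_sd_range[1], dg0_sd_range[2])^2, g)
  }
  priors <- thermo_priors(
    mu_c = rep(mu_ln_c, m),
    Sigma_c = rep(sd_ln_c^2, m),
    mu_dg0 = mu_dg0,
    Sigma_dg0 = Sigma_dg0
  )
  list(network = net, priors = priors, topology = topology, seed = seed)
}

rxn_matrix <- function(mets, rxns) {
  # rxns: named list of named coefficient vectors
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, names(rxns)))
  for (j in names(rxns)) S[names(rxns[[j]]), j] <- rxns[[j]]
  S
}

fixture_chain <- function(n, reversible) {
  if (n < 1) stop("chain needs >= 1 reaction", call. = FALSE)
  mets <- paste0("M", seq_len(n + 1))
  rxns <- stats::setNames(
    lapply(seq_len(n), function(i)
      stats::setNames(c(-1, 1), mets[c(i, i + 1)])),
    paste0("R", seq_len(n)))
  rxns$EX_in <- stats::setNames(1, mets[1])
  rxns$EX_out <- stats::setNames(-1, mets[n + 1])
  S <- rxn_matrix(mets, rxns)
  rev <- rep_len(if (is.null(reversible)) TRUE else reversible, n)
  lb <- c(ifelse(rev, -10, 0), -10, -10)
  ub <- rep(10, n + 2)
  role <- c(rep("internal", n), "exchange", "exchange")
  list(network = metabolic_network(S, lb, ub, role = role))
}

fixture_branch <- function(reversible) {
  S <- rxn_matrix(
    c("A", "B", "C"),
    list(R1 = c(A = -1, B = 1),
         R2 = c(A = -1, C = 1),
         EX_A = c(A = 1),
         EX_B = c(B = -1),
         EX_C = c(C = -1)))
  rev <- rep_len(if (is.null(reversible)) TRUE else reversible, 2)
  lb <- c(ifelse(rev, -10, 0), -10, -10, -10)
  ub <- rep(10, 5)
  list(network = metabolic_network(S, lb, ub))
}

fixture_cycle <- function(reversible) {
  S <- rxn_matrix(
    c("A", "B", "C"),
    list(R1 = c(A = -1, B = 1),
         R2 = c(B = -1, C = 1),
         R3 = c(C = -1, A = 1),
         EX_A = c(A = 1),
         EX_B = c(B = -1),
         EX_C = c(C = -1)))
  rev <- rep_len(if (is.null(reversible)) TRUE else reversible, 3)
  lb <- c(ifelse(rev, -10, 0), rep(-10, 3))
  ub <- rep(10, 6)
  list(network = metabolic_network(S, lb, ub))
}

fixture_lumped <- function() {
  S <- rxn_matrix(
    c("A", "B", "C"),
    list(R1 = c(A = -1, B = 1),
         R2 = c(B = -1, C = 1),
         R3 = c(A = -1, C = 1),
         EX_A = c(A = 1),
         EX_C = c(C = -1)))
  list(network = metabolic_network(S, lb = c(-10, -10, -10, -10, -10),
                                   ub = rep(10, 5)))
}

fixture_propionate <- function(fixed) {
  # ppa: propionate, ppcoa: propanoyl-CoA, ppap: propanoyl phosphate.
  # ACCOAL (ligase, ppa -> ppcoa), PTA2 (ppcoa -> ppap), PPAKr (ppap -> ppa)
  # all irreversible close a directed loop whose energies sum to zero: a
  # structural inconsistency.  `fixed = TRUE` makes the ligase reversible.
  S <- rxn_matrix(
    c("ppa", "ppcoa", "ppap", "coa"),
    list(ACCOAL = c(ppa = -1, coa = -1, ppcoa = 1),
         PTA2 = c(ppcoa = -1, ppap = 1, coa = 1),
         PPAKr = c(ppap = -1, ppa = 1),
         EX_ppcoa = c(ppcoa = -1),
         EX_ppa = c(ppa = -1),
         EX_coa = c(coa = -1)))
  lb <- c(if (fixed) -10 else 0, 0, 0, -10, 0, -10)
  ub <- rep(10, 6)
  list(network = metabolic_network(S, lb, ub))
}

fixture_random <- function(n, reversible, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  for (try in 0:49) {
    set.seed(seed * 1000L + try)
    m <- max(2L, n - sample(0:2, 1))
    mets <- paste0("M", seq_len(m))
    rxns <- list()
    for (j in seq_len(n)) {
      ns <- sample(1:2, 1)
      np <- sample(1:2, 1)
      subs <- sample(mets, ns)
      prods <- sample(setdiff(mets, subs), min(np, m - ns))
      rxns[[paste0("R", j)]] <- stats::setNames(
        c(rep(-1, length(subs)), rep(1, length(prods))), c(subs, prods))
    }
    # exchanges on two random metabolites plus any dead ends
    deg <- rowSums(rxn_matrix(mets, rxns) != 0)
    exch <- unique(c(sample(mets, min(2, m)), mets[deg <= 1]))
    for (e in exch) rxns[[paste0("EX_", e)]] <- stats::setNames(-1, e)
    S <- rxn_matrix(mets, rxns)
    n_all <- ncol(S)
    rev <- rep_len(if (is.null(reversible))
      sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.7, .3))
      else reversible, n)
    lb <- c(ifelse(rev, -10, 0), rep(-10, n_all - n))
    ub <- rep(10, n_all)
    net <- metabolic_network(S, lb, ub)
    ok <- tryCatch({
      net2 <- suppressWarnings(select_thermo_reactions(net))
      length(net2$gamma) >= 2
    }, error = function(e) FALSE)
    if (ok) return(list(network = net))
  }
  stop("could not generate a valid random fixture", call. = FALSE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Rejection-sampling ground truth for the thermodynamic space
#'
#' Draws reaction energies from the reduced Gaussian truncated to the
#' confidence ellipsoid, discards draws whose direction pattern violates an
#' irreversibility or fails the steady-state flux check, and reports
#' empirical orthant probabilities plus the retained draws.  Serves as the
#' independent oracle for the Hit-and-Run sampler.
#'
#' @param network a `pta_network` (constrained set selected).
#' @param space the matching `pta_thermo_space`.
#' @param n_draws number of proposal draws.
#' @param seed integer seed.
#' @param v_min minimum flux magnitude defining "nonzero flux".
#' @param batch internal batch size.
#' @return list with `orthants` (tibble: signature, count, probability),
#'   `samples` (retained dg draws, one row per draw), `acceptance` rate.
#' @export
rejection_oracle <- function(network, space, n_draws = 1e5, seed = 1,
                             v_min = 1e-6, batch = 1e5) {
  g <- length(space$mu_r)
  if (g > 12) stop("rejection oracle is limited to gamma <= 12", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  cache <- new.env(parent = emptyenv())
  fixed <- fixed_directions(network)
  counts <- new.env(parent = emptyenv())
  kept <- list()
  n_done <- 0
  n_acc <- 0
  pow2 <- 2^(seq_len(g) - 1)
  while (n_done < n_draws) {
    nb <- min(batch, n_draws - n_done)
    n_done <- n_done + nb
    M <- matrix(stats::rnorm(nb * space$q_r), space$q_r, nb)
    inside <- colSums(M^2) <= space$chi2_r
    M <- M[, inside, drop = FALSE]
    if (!ncol(M)) next
    DG <- space$mu_r + space$Q_r %*% M          # g x n
    signs <- ifelse(DG < 0, 1L, -1L)            # flux direction = -sign(dg)
    ok <- rep(TRUE, ncol(DG))
    if (any(!is.na(fixed))) {
      fi <- which(!is.na(fixed))
      ok <- colSums(signs[fi, , drop = FALSE] != fixed[fi]) == 0
    }
    idx <- which(ok)
    if (!length(idx)) next
    # integer-encode sign patterns; one feasibility call per unique pattern
    code <- drop(pow2 %*% (signs[, idx, drop = FALSE] > 0))
    ucode <- unique(code)
    ufeas <- vapply(ucode, function(cd) {
      k <- idx[match(cd, code)]
      steady_state_feasible(network, signs[, k], v_min = v_min,
                            cache = cache)
    }, logical(1))
    feas <- ufeas[match(code, ucode)]
    acc <- idx[feas]
    n_acc <- n_acc + length(acc)
    if (length(acc)) {
      ukeys <- orthant_key(signs[, idx[match(ucode, code)], drop = FALSE])
      tab <- table(factor(code[feas], levels = ucode))
      for (ui in which(tab > 0)) {
        key <- ukeys[ui]
        counts[[key]] <- (counts[[key]] %||% 0L) + as.integer(tab[ui])
      }
      kept[[length(kept) + 1]] <- t(DG[, acc, drop = FALSE])
    }
  }
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  acc_rate <- n_acc / n_draws
  if (acc_rate < 1e-5)
    warning("acceptance rate below 1e-5; fixture is too constrained",
            call. = FALSE)
  samples <- if (length(kept)) do.call(rbind, kept) else
    matrix(0, 0, g)
  colnames(samples) <- space$gamma_ids
  list(
    orthants = tibble::tibble(
      signature = keys, count = as.integer(cnt),
      probability = if (n_acc) cnt / n_acc else rep(NA_real_, length(cnt))
    ) |> dplyr::arrange(dplyr::desc(.data$count)),
    samples = samples,
    acceptance = acc_rate
  )
}

#' Exhaustive feasible-orthant reference for tiny networks
#'
#' Enumerates all `2^gamma` direction patterns, checks steady-state
#' feasibility of each, and computes each feasible orthant's probability mass
#' under the reduced Gaussian truncated to the confidence ellipsoid by
#' deterministic tensor-grid quadrature in the whitened coordinates.
#'
#' @param network a `pta_network` (constrained set selected).
#' @param space the matching `pta_thermo_space`.
#' @param v_min minimum flux magnitude.
#' @param nodes quadrature nodes per whitened dimension; default scales with
#'   the reduced dimension (finer grids in low dimension, where the
#'   discontinuous orthant indicator needs them).
#' @return tibble: signature, feasible, probability (normalized over feasible
#'   orthants).
#' @export
enumerate_orthants <- function(network, space, v_min = 1e-6, nodes = NULL) {
  g <- length(space$mu_r)
  if (g > 6) stop("exhaustive enumeration is limited to gamma <= 6",
                  call. = FALSE)
  if (space$q_r > 4) stop("quadrature limited to reduced rank <= 4",
                          call. = FALSE)
  if (is.null(nodes)) nodes <- c(2000L, 300L, 80L, 36L)[max(space$q_r, 1)]
  cache <- new.env(parent = emptyenv())
  fixed <- fixed_directions(network)
  r <- sqrt(space$chi2_r)
  # tensor Gauss-Legendre grid over [-r, r]^q_r, weighted by the std normal
  gl <- gauss_legendre(nodes, -r, r)
  grids <- rep(list(gl$x), space$q_r)
  Mgrid <- as.matrix(expand.grid(grids))
  W <- apply(as.matrix(expand.grid(rep(list(gl$w), space$q_r))), 1, prod)
  dens <- exp(-rowSums(Mgrid^2) / 2)
  inside <- rowSums(Mgrid^2) <= space$chi2_r
  W <- W * dens * inside
  DG <- space$mu_r + space$Q_r %*% t(Mgrid)     # g x npoints
  signs_mat <- ifelse(DG < 0, 1L, -1L)
  point_key <- orthant_key(signs_mat)
  all_signs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), g)))
  res <- purrr::map_dfr(seq_len(nrow(all_signs)), function(i) {
    d <- all_signs[i, ]
    if (any(!is.na(fixed) & d != fixed))
      return(tibble::tibble(signature = orthant_key(matrix(d)), feasible = FALSE,
                            mass = 0))
    feas <- steady_state_feasible(network, d, v_min = v_min, cache = cache)
    key <- orthant_key(matrix(d))
    mass <- if (feas) sum(W[point_key == key]) else 0
    tibble::tibble(signature = key, feasible = feas, mass = mass)
  })
  tot <- sum(res$mass)
  if (tot <= 0) stop("no feasible orthant carries probability mass",
                     call. = FALSE)
  res |>
    dplyr::mutate(probability = .data$mass / tot) |>
    dplyr::select(-"mass") |>
    dplyr::arrange(dplyr::desc(.data$probability))
}

gauss_legendre <- function(n, a, b) {
  # Golub-Welsch: nodes/weights from the Jacobi matrix of Legendre polynomials
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  eg <- eigen(J, symmetric = TRUE)
  x <- eg$values
  w <- 2 * eg$vectors[1, ]^2
  list(x = (a + b) / 2 + (b - a) / 2 * x, w = (b - a) / 2 * w)
}

# canonical hashable orthant signature ("+-+" style), columns of a sign matrix
orthant_key <- function(signs) {
  apply(matrix(ifelse(signs > 0, "+", "-"), nrow = nrow(signs)), 2,
        paste0, collapse = "")
}

# flux direction forced by irreversibility, per constrained reaction:
# +1 forward-only, -1 backward-only, NA free
fixed_directions <- function(network) {
  gamma <- network$gamma
  dir <- rep(NA_integer_, length(gamma))
  dir[network$lb[gamma] >= 0] <- 1L
  dir[network$ub[gamma] <= 0] <- -1L
  dir
}
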