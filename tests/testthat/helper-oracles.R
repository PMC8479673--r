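# Independent reference implementations used as oracles.  These deliberately
# avoid the package's own code paths: feasibility goes straight through
# quadprog, optimization over direction patterns is exhaustive, EFMs come
# from nullspace enumeration over supports.

# direct QP feasibility of {S v = 0, lb <= v <= ub} (+ optional rows A v <= b)
feas_direct <- function(S, lb, ub, A = NULL, b = NULL) {
  n <- ncol(S)
  Am <- t(S)
  bv <- numeric(nrow(S))
  meq <- nrow(S)
  fin <- is.finite(lb)
  Am <- cbind(Am, diag(n)[, fin, drop = FALSE])
  bv <- c(bv, lb[fin])
  fin <- is.finite(ub)
  Am <- cbind(Am, -diag(n)[, fin, drop = FALSE])
  bv <- c(bv, -ub[fin])
  if (!is.null(A)) {
    Am <- cbind(Am, -t(A))
    bv <- c(bv, -b)
  }
  res <- tryCatch(
    quadprog::solve.QP(diag(n), numeric(n), Am, bv, meq = meq),
    error = function(e) NULL)
  !is.null(res)
}

# exhaustive enumeration of all direction patterns with per-orthant QP in
# reduced coordinates: the reference for solve_pmo
pmo_oracle <- function(network, space, eps = 0.1, v_min = 1e-6) {
  g <- length(space$gamma_ids)
  fixed <- thermoflux:::fixed_directions(network)
  combos <- as.matrix(expand.grid(rep(list(c(1L, -1L)), g)))
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    d <- combos[i, ]
    if (any(!is.na(fixed) & d != fixed)) next
    lb <- network$lb
    ub <- network$ub
    for (k in seq_len(g)) {
      j <- network$gamma[k]
      if (d[k] > 0) lb[j] <- max(lb[j], v_min) else ub[j] <- min(ub[j], -v_min)
    }
    if (any(lb > ub) || !feas_direct(network$S, lb, ub)) next
    # min ||w||^2 s.t. d_i (mu_r + Q_r w)_i <= -eps, in reduced coordinates
    A <- d * space$Q_r
    bvec <- -eps - d * space$mu_r
    qr_dim <- space$q_r
    sol <- tryCatch(
      quadprog::solve.QP(diag(qr_dim), numeric(qr_dim), -t(A), -bvec),
      error = function(e) NULL)
    if (is.null(sol)) next
    val <- sum(sol$solution^2)
    if (val <= space$chi2 + 1e-9) best <- min(best, val)
  }
  best
}

# brute-force internal EFM enumeration: nullspace over candidate supports
efm_oracle <- function(network, tol = 1e-9) {
  internal <- which(network$role == "internal" &
                      !grepl("^ATPM", network$reaction_ids))
  S <- network$S[, internal, drop = FALSE]
  n <- length(internal)
  modes <- list()
  for (size in seq_len(n)) {
    supports <- utils::combn(n, size, simplify = FALSE)
    for (supp in supports) {
      Ssub <- S[, supp, drop = FALSE]
      sv <- svd(Ssub, nu = 0, nv = size)
      rank <- sum(sv$d > tol * max(sv$d, 1))
      if (size - rank != 1) next
      v_full <- sv$v[, size]
      if (any(abs(v_full) < tol)) next          # not full support => minimal
      # orientation must respect irreversibility in one of the two signs
      ok_dir <- function(v) {
        all((v > 0 & network$ub[internal[supp]] > 0) |
              (v < 0 & network$lb[internal[supp]] < 0))
      }
      v <- NULL
      if (ok_dir(v_full)) v <- v_full
      else if (ok_dir(-v_full)) v <- -v_full
      if (is.null(v)) next
      # support-minimality against previously found modes
      is_minimal <- !any(vapply(modes, function(m)
        all(m$support %in% supp) && length(m$support) < size, logical(1)))
      if (!is_minimal) next
      modes[[length(modes) + 1]] <-
        list(support = supp, reactions = network$reaction_ids[internal[supp]],
             v = v / min(abs(v)))
    }
  }
  modes
}

# second, independently coded split-chain PSRF (textbook formula)
psrf_ref <- function(chains, rank_normalize = TRUE) {
  half <- lapply(chains, function(x) {
    n <- length(x)
    h <- floor(n / 2)
    list(x[1:h], x[(n - h + 1):n])
  })
  segs <- unlist(half, recursive = FALSE)
  if (rank_normalize) {
    pool <- unlist(segs)
    r <- rank(pool, ties.method = "average")
    z <- qnorm((r - 3 / 8) / (length(pool) + 1 / 4))
    lens <- vapply(segs, length, integer(1))
    idx <- cumsum(c(0, lens))
    segs <- lapply(seq_along(segs), function(k) z[(idx[k] + 1):idx[k + 1]])
  }
  M <- length(segs)
  n <- length(segs[[1]])
  mns <- vapply(segs, mean, numeric(1))
  vrs <- vapply(segs, var, numeric(1))
  W <- mean(vrs)
  B <- n / (M - 1) * sum((mns - mean(mns))^2)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# second ESS implementation: explicit autocovariance sums
ess_ref <- function(chains) {
  segs <- unlist(lapply(chains, function(x) {
    n <- length(x)
    h <- floor(n / 2)
    list(x[1:h], x[(n - h + 1):n])
  }), recursive = FALSE)
  M <- length(segs)
  n <- length(segs[[1]])
  W <- mean(vapply(segs, var, numeric(1)))
  mns <- vapply(segs, mean, numeric(1))
  var_plus <- (n - 1) / n * W + var(mns)
  acov_t <- function(x, t) {
    x <- x - mean(x)
    sum(x[1:(n - t)] * x[(t + 1):n]) / n
  }
  lag_max <- min(n - 2, 2000)
  rho <- numeric(lag_max + 1)
  rho[1] <- 1
  for (t in seq_len(lag_max)) {
    rho[t + 1] <- 1 - (W - mean(vapply(segs, acov_t, numeric(1), t = t))) /
      var_plus
  }
  P <- numeric(0)
  for (k in seq_len(floor((lag_max) / 2))) {
    p <- rho[2 * k] + rho[2 * k + 1]
    if (p <= 0) break
    P <- c(P, p)
  }
  if (length(P) > 1) P <- cummin(P)
  min(M * n / max(1, 1 + 2 * sum(P)), M * n)
}

# dg samples pooled from a pta_samples object
pool_dg <- function(samples) do.call(rbind, samples$dg)

# combined 3-SE bound for comparing an MCMC orthant probability against a
# rejection estimate: between-chain spread for the MCMC side, binomial for
# the rejection side
orthant_prob_tol <- function(samples, oracle_n, p) {
  per_chain <- function(sig) {
    # recompute per-chain orthant frequencies from retained draws' signs
    vapply(samples$dg, function(m) {
      signs <- ifelse(m < 0, "+", "-")
      keys <- apply(signs, 1, paste0, collapse = "")
      mean(keys == sig)
    }, numeric(1))
  }
  function(sig) {
    pc <- per_chain(sig)
    se_mc <- stats::sd(pc) / sqrt(length(pc))
    se_or <- sqrt(p * (1 - p) / oracle_n)
    3 * sqrt(se_mc^2 + se_or^2) + 2 / (samples$config$n_retain *
                                         samples$config$n_chains)
  }
}
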