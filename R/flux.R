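# Flux sampling with the thermodynamic orthant distribution as prior.
#
# Each feasible orthant (direction pattern) defines a flux polytope:
# the steady-state null space intersected with sign-tightened bounds.
# Polytopes are sampled uniformly with Coordinate Hit-and-Run after a
# rounding transform (iterative covariance-based approximation of the
# polytope's inertial ellipsoid); orthants contribute draws proportionally
# to their sampled probability.

#' Build the flux polytope of an orthant
#'
#' Intersects the steady-state flux space with the orthant's direction
#' constraints (`v_i >= v_min` or `v_i <= -v_min` on constrained reactions),
#' eliminates the equality constraints by a null-space parametrization and
#' prepares a rounding transform.
#'
#' @param network a `pta_network` with the constrained set selected.
#' @param signs direction pattern over the constrained set.
#' @param v_min minimum flux magnitude.
#' @param rounding_seed seed of the deterministic pilot used for rounding.
#' @return a `pta_polytope` whose ambient coordinates are fluxes.
#' @export
build_orthant_polytope <- function(network, signs, v_min = 1e-6,
                                   rounding_seed = 1) {
  fixed <- fixed_directions(network)
  if (any(!is.na(fixed) & signs != fixed))
    stop("direction pattern flips an irreversible reaction", call. = FALSE)
  lb <- network$lb
  ub <- network$ub
  for (k in seq_along(network$gamma)) {
    j <- network$gamma[k]
    if (signs[k] > 0) lb[j] <- max(lb[j], v_min)
    else ub[j] <- min(ub[j], -v_min)
  }
  if (any(lb > ub))
    stop("empty polytope: direction pattern conflicts with bounds",
         call. = FALSE)
  make_polytope(A_eq = network$S, b_eq = numeric(nrow(network$S)),
                lb = lb, ub = ub, names = network$reaction_ids,
                rounding_seed = rounding_seed)
}

#' Construct a bounded polytope from equalities, bounds and inequalities
#'
#' General H-representation constructor used by the flux sampler and usable
#' directly for tests (boxes, simplices).  Equalities are eliminated by an
#' orthonormal null-space parametrization around a least-norm interior
#' point.
#'
#' @param A_eq,b_eq equality constraints (optional).
#' @param lb,ub box bounds on the ambient variables (optional).
#' @param A_le,b_le extra inequalities (optional).
#' @param names ambient variable names.
#' @param rounding_seed seed of the deterministic rounding pilot.
#' @param rounding_rounds covariance-rounding iterations (0 disables).
#' @return a `pta_polytope`.
#' @export
make_polytope <- function(A_eq = NULL, b_eq = NULL, lb = NULL, ub = NULL,
                          A_le = NULL, b_le = NULL, names = NULL,
                          rounding_seed = 1, rounding_rounds = 2) {
  n <- if (!is.null(A_eq)) ncol(A_eq) else if (!is.null(lb)) length(lb)
    else ncol(A_le)
  if (is.null(lb)) lb <- rep(-Inf, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  A <- A_le
  b <- b_le
  fin <- is.finite(ub)
  if (any(fin)) { A <- rbind(A, diag(n)[fin, , drop = FALSE]); b <- c(b, ub[fin]) }
  fin <- is.finite(lb)
  if (any(fin)) { A <- rbind(A, -diag(n)[fin, , drop = FALSE]); b <- c(b, -lb[fin]) }
  # interior-ish particular point: least-norm toward the box center
  center <- ifelse(is.finite(lb) & is.finite(ub), (lb + ub) / 2, 0)
  res <- solve_least_norm(n, A_eq = A_eq, b_eq = b_eq, A_le = A, b_le = b,
                          x0 = center)
  if (res$status != "optimal")
    stop("empty polytope", call. = FALSE)
  x0 <- res$x
  if (!is.null(A_eq)) {
    sv <- svd(A_eq, nu = 0, nv = n)
    r <- sum(sv$d > 1e-10 * max(sv$d, 1))
    N <- sv$v[, setdiff(seq_len(n), seq_len(r)), drop = FALSE]
  } else {
    N <- diag(n)
  }
  if (!ncol(N)) stop("polytope has dimension zero", call. = FALSE)
  Az <- A %*% N
  bz <- b - drop(A %*% x0)
  # drop numerically inactive rows
  rn <- sqrt(rowSums(Az^2))
  keep <- rn > 1e-12
  poly <- structure(
    list(offset = x0, basis = N, A = Az[keep, , drop = FALSE],
         b = bz[keep], names = names,
         center = numeric(ncol(N)), T_round = diag(ncol(N))),
    class = "pta_polytope"
  )
  if (rounding_rounds > 0)
    poly <- round_polytope(poly, rounds = rounding_rounds,
                           seed = rounding_seed)
  poly
}

#' @export
print.pta_polytope <- function(x, ...) {
  cat(sprintf("<pta_polytope> dimension %d, %d facets (ambient %d)\n",
              ncol(x$A), nrow(x$A), length(x$offset)))
  invisible(x)
}

# chord of coordinate i through point y (rounded coordinates)
coord_chord <- function(A, slack, i) {
  ai <- A[, i]
  lo <- -Inf
  hi <- Inf
  pos <- ai > 1e-14
  neg <- ai < -1e-14
  if (any(pos)) hi <- min(slack[pos] / ai[pos])
  if (any(neg)) lo <- max(slack[neg] / ai[neg])
  c(lo, hi)
}

# covariance-based rounding: short pilot runs estimate the shape of the
# polytope; the transform whitens it so coordinate chords have similar size
round_polytope <- function(poly, rounds = 2, seed = 1, pilot = 400) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  k <- ncol(poly$A)
  if (k == 0) return(poly)
  for (r in seq_len(rounds)) {
    set.seed(seed + r)
    Y <- chrr_core(poly, n = pilot, thin = max(2L, k), warm = 10L * k)
    C <- stats::cov(Y)
    eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
    vals <- pmax(eg$values, max(eg$values) * 1e-10)
    if (max(vals) <= 0) break
    Tnew <- eg$vectors %*% diag(sqrt(vals), k)
    mu <- colMeans(Y)
    # compose: y-coords replaced by y', with y = mu + Tnew y'
    poly$center <- poly$center + drop(poly$T_round %*% mu)
    poly$T_round <- poly$T_round %*% Tnew
  }
  poly
}

# Coordinate Hit-and-Run in rounded coordinates; returns raw y draws
chrr_core <- function(poly, n, thin, warm = 0L, start = NULL) {
  k <- ncol(poly$A)
  A <- poly$A %*% poly$T_round
  b0 <- poly$b - drop(poly$A %*% poly$center)
  y <- if (is.null(start)) numeric(k) else start
  slack <- b0 - drop(A %*% y)
  if (min(slack) < -1e-9)
    stop("rounding start point left the polytope", call. = FALSE)
  out <- matrix(NA_real_, n, k)
  total <- warm + n * thin
  degenerate <- rep(FALSE, k)
  row <- 0L
  for (step in seq_len(total)) {
    i <- sample.int(k, 1)
    if (!degenerate[i]) {
      ch <- coord_chord(A, slack, i)
      if (!all(is.finite(ch)))
        stop("polytope is unbounded along a coordinate", call. = FALSE)
      if (ch[2] - ch[1] < 1e-12) {
        degenerate[i] <- TRUE
      } else {
        d <- stats::runif(1, ch[1], ch[2])
        y[i] <- y[i] + d
        slack <- slack - d * A[, i]
      }
    }
    if (step > warm && (step - warm) %% thin == 0) {
      row <- row + 1L
      out[row, ] <- y
    }
  }
  if (any(degenerate))
    warning("collapsed ", sum(degenerate),
            " numerically degenerate polytope dimension(s)", call. = FALSE)
  out[seq_len(row), , drop = FALSE]
}

#' Uniform samples from a polytope (Coordinate Hit-and-Run with Rounding)
#'
#' @param polytope a `pta_polytope`.
#' @param n number of draws.
#' @param seed integer seed (deterministic streams).
#' @param thin steps between retained draws (default `5 * dimension`).
#' @return matrix of draws in ambient coordinates (one row per draw).
#' @export
chrr_sample <- function(polytope, n, seed = 1, thin = NULL) {
  k <- ncol(polytope$A)
  if (is.null(thin)) thin <- max(1L, 5L * k)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  Y <- chrr_core(polytope, n = n, thin = thin, warm = 20L * k)
  Z <- sweep(Y %*% t(polytope$T_round), 2, -polytope$center)
  X <- sweep(Z %*% t(polytope$basis), 2, -polytope$offset)
  colnames(X) <- polytope$names
  X
}

#' Sample fluxes from the orthant mixture
#'
#' Draws `n_orthants` orthants probability-proportional-to-size without
#' replacement from the sampled orthant table, renormalizes their
#' probabilities, allocates `n_total` draws by largest remainder, and
#' samples each orthant's flux polytope uniformly with CHRR.
#'
#' @param network a `pta_network` with the constrained set selected.
#' @param orthant_table tibble with `signature` and `probability` columns
#'   (from [run_tfs()] or [rejection_oracle()]).
#' @param n_total total number of flux draws.
#' @param n_orthants orthants to include (default: all in the table).
#' @param seed integer seed.
#' @param v_min minimum flux magnitude.
#' @return an object of class `pta_flux_samples`: `$samples` (tibble of flux
#'   draws, one column per reaction plus `orthant`), `$allocation` (tibble:
#'   signature, probability, n_draws).
#' @export
sample_flux_mixture <- function(network, orthant_table, n_total = 1000,
                                n_orthants = NULL, seed = 1, v_min = 1e-6) {
  if (!nrow(orthant_table)) stop("empty orthant table", call. = FALSE)
  tab <- dplyr::arrange(orthant_table, dplyr::desc(.data$probability),
                        .data$signature)
  if (is.null(n_orthants)) n_orthants <- nrow(tab)
  n_orthants <- min(n_orthants, nrow(tab))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  # PPS without replacement
  chosen <- integer(0)
  left <- seq_len(nrow(tab))
  p <- tab$probability
  for (i in seq_len(n_orthants)) {
    pick <- left[sample.int(length(left), 1, prob = p[left])]
    chosen <- c(chosen, pick)
    left <- setdiff(left, pick)
  }
  sel <- tab[sort(chosen), ]
  w <- sel$probability / sum(sel$probability)
  n_draw <- floor(w * n_total)
  rem <- n_total - sum(n_draw)
  if (rem > 0) {
    frac <- w * n_total - n_draw
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n_draw[extra] <- n_draw[extra] + 1L
  }
  out <- list()
  for (i in seq_len(nrow(sel))) {
    if (n_draw[i] == 0) next
    signs <- key_to_signs(sel$signature[i])
    poly <- build_orthant_polytope(network, signs, v_min = v_min,
                                   rounding_seed = seed + i)
    X <- chrr_sample(poly, n_draw[i], seed = seed + 1000L + i)
    out[[length(out) + 1]] <- tibble::as_tibble(X) |>
      dplyr::mutate(orthant = sel$signature[i])
  }
  structure(
    list(samples = dplyr::bind_rows(out),
         allocation = tibble::tibble(signature = sel$signature,
                                     probability = w,
                                     n_draws = as.integer(n_draw)),
         gamma_ids = network$reaction_ids[network$gamma]),
    class = "pta_flux_samples"
  )
}

key_to_signs <- function(key) {
  ifelse(strsplit(key, "")[[1]] == "+", 1L, -1L)
}

#' @export
print.pta_flux_samples <- function(x, ...) {
  cat(sprintf("<pta_flux_samples> %d draws from %d orthant(s)\n",
              nrow(x$samples), nrow(x$allocation)))
  invisible(x)
}

#' Tidy flux draws
#' @param x a `pta_flux_samples` object.
#' @param ... unused.
#' @return long tibble: `draw`, `orthant`, `reaction`, `flux`.
#' @export
tidy.pta_flux_samples <- function(x, ...) {
  x$samples |>
    dplyr::mutate(draw = dplyr::row_number()) |>
    tidyr::pivot_longer(-c("draw", "orthant"), names_to = "reaction",
                        values_to = "flux")
}

#' Call reaction directions from samples
#'
#' A reaction is called irreversible (forward or backward) when at least
#' `threshold` of the samples agree on its direction.  Accepts flux draws
#' (`pta_flux_samples` or a matrix of fluxes) or energy draws
#' (`pta_samples`; the direction is the sign of the negated energy).
#'
#' @param samples draws, see details.
#' @param threshold agreement fraction for an irreversible call.
#' @return tibble: `reaction`, `fraction_forward`, `call` in
#'   `forward`/`backward`/`reversible`.
#' @export
call_directions <- function(samples, threshold = 0.95) {
  if (inherits(samples, "pta_flux_samples")) {
    M <- as.matrix(samples$samples[samples$gamma_ids])
  } else if (inherits(samples, "pta_samples")) {
    M <- -do.call(rbind, samples$dg)      # direction = sign of -dG'
  } else {
    M <- as.matrix(samples)
  }
  if (!nrow(M)) stop("no samples", call. = FALSE)
  frac <- colMeans(M > 0)
  tibble::tibble(
    reaction = colnames(M) %||% paste0("R", seq_len(ncol(M))),
    fraction_forward = frac,
    call = dplyr::case_when(frac >= threshold ~ "forward",
                            frac <= 1 - threshold ~ "backward",
                            TRUE ~ "reversible")
  )
}
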