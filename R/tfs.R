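# Hit-and-Run MCMC over the steady-state thermodynamic space.
#
# The sampler works in whitened reduced coordinates m (dimension q_r), where
# the target is a standard multivariate normal truncated to the confidence
# ball and to the union of orthants (energy sign patterns) that admit a
# steady-state flux distribution with matching directions.  Each step shoots
# a random ray, intersects it with the ball and the fixed-sign constraints
# of irreversible reactions, partitions the chord at the zero crossings of
# the reaction energies, discards sub-segments whose orthant fails the
# steady-state linear program (memoized per signature), weighs the surviving
# segments by their truncated-normal mass, and draws the next point by
# inverse-CDF sampling on the selected segment.  An optional diagonal
# reparametrization (adapt_parametrization) rescales poorly mixing
# directions; the along-ray density is then a general 1-D normal, so the
# stationary distribution is unchanged.

#' Steady-state feasibility of a direction pattern
#'
#' TRUE iff a flux distribution exists satisfying the stoichiometric
#' steady-state constraints and carrying at least `v_min` in the prescribed
#' direction on every constrained reaction.  Results are memoized by orthant
#' signature in `cache` (an environment), so repeated queries cost one hash
#' lookup.
#'
#' @param network a `pta_network` with the constrained set selected.
#' @param signs integer direction vector over the constrained set
#'   (+1 forward, -1 backward).
#' @param v_min minimum flux magnitude.
#' @param cache environment used as memo table (optional).
#' @return logical scalar.
#' @export
steady_state_feasible <- function(network, signs, v_min = 1e-6,
                                  cache = NULL) {
  fixed <- fixed_directions(network)
  bad <- !is.na(fixed) & signs != fixed
  if (any(bad)) return(FALSE)                     # irreversibility precheck
  key <- orthant_key(matrix(signs))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  ok <- partial_flux_feasible(network$S, network$lb, network$ub,
                              network$gamma, signs, v_min)
  if (!is.null(cache)) cache[[key]] <- ok
  ok
}

# log(Phi(b) - Phi(a)) for a standard normal, stable in both tails
log_pnorm_diff <- function(a, b) {
  stopifnot(all(b >= a))
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    if (a[i] >= 0) {
      la <- stats::pnorm(a[i], lower.tail = FALSE, log.p = TRUE)
      lb <- stats::pnorm(b[i], lower.tail = FALSE, log.p = TRUE)
      out[i] <- la + log1p(-exp(lb - la))
    } else if (b[i] <= 0) {
      la <- stats::pnorm(a[i], log.p = TRUE)
      lb <- stats::pnorm(b[i], log.p = TRUE)
      out[i] <- lb + log1p(-exp(la - lb))
    } else {
      out[i] <- log(stats::pnorm(b[i]) - stats::pnorm(a[i]))
    }
  }
  out
}

# inverse-CDF draw from a standard normal truncated to [a, b]; u in (0, 1)
truncnorm_draw <- function(a, b, u) {
  if (a >= 0) return(-truncnorm_draw(-b, -a, 1 - u))
  if (b <= 0) {
    la <- stats::pnorm(a, log.p = TRUE)
    lb <- stats::pnorm(b, log.p = TRUE)
    lp <- logsumexp2(lb + log(u), la + log1p(-u))
    return(stats::qnorm(lp, log.p = TRUE))
  }
  pa <- stats::pnorm(a)
  pb <- stats::pnorm(b)
  stats::qnorm(pa + u * (pb - pa))
}

logsumexp2 <- function(x, y) {
  m <- pmax(x, y)
  m + log(exp(x - m) + exp(y - m))
}

#' Intersect a sampling ray with the thermodynamic space
#'
#' Intersects the ray `m(s) = m0 + s * direction` with the confidence ball
#' and the sign constraints of irreversible reactions, splits the chord at
#' the zero crossings of the reaction energies, and tests each sub-segment's
#' orthant for steady-state feasibility.
#'
#' @param space a `pta_thermo_space`.
#' @param network the `pta_network` (for the feasibility program).
#' @param m0 current point, reduced whitened coordinates (length `q_r`),
#'   strictly inside the ball.
#' @param direction unit ray direction (length `q_r`).
#' @param v_min minimum flux magnitude.
#' @param cache memo environment for feasibility calls.
#' @return tibble of segments: `a`, `b` (ray parameter), `signature`,
#'   `feasible`; plus attribute `n_crossed`, the number of distinct orthant
#'   cells the chord crosses.
#' @export
intersect_ray <- function(space, network, m0, direction, v_min = 1e-6,
                          cache = NULL) {
  seg <- ray_segments(space, network, m0, direction, v_min = v_min,
                      cache = cache)
  out <- tibble::tibble(a = seg$a, b = seg$b, signature = seg$signature,
                        feasible = seg$feasible)
  attr(out, "n_crossed") <- seg$n_crossed
  out
}

# allocation-light workhorse behind intersect_ray / sample_step
ray_segments <- function(space, network, m0, direction, v_min = 1e-6,
                         cache = NULL, fixed = NULL) {
  scales <- space$sampling_scales
  x0 <- scales * m0          # coordinates in the isotropic metric
  xu <- scales * direction
  aa <- sum(xu^2)
  bb <- 2 * sum(x0 * xu)
  cc <- sum(x0^2) - space$chi2_r
  disc <- bb^2 - 4 * aa * cc
  if (disc <= 0 || aa == 0)
    stop("degenerate chord: current point is not strictly inside the ball",
         call. = FALSE)
  s_lo <- (-bb - sqrt(disc)) / (2 * aa)
  s_hi <- (-bb + sqrt(disc)) / (2 * aa)
  dg0_vec <- drop(space$mu_r + space$Q_r %*% x0)
  grad <- drop(space$Q_r %*% xu)
  if (is.null(fixed)) fixed <- fixed_directions(network)
  # irreversible reactions restrict the chord: flux dir f => f * dg(s) <= 0
  for (k in which(!is.na(fixed))) {
    f <- fixed[k]
    slope <- f * grad[k]
    inter <- f * dg0_vec[k]
    if (abs(slope) < 1e-14) {
      if (inter > 0) s_lo <- s_hi + 1    # empty (cannot happen from inside)
    } else {
      s_star <- -inter / slope
      if (slope > 0) s_hi <- min(s_hi, s_star) else s_lo <- max(s_lo, s_star)
    }
  }
  if (s_lo >= s_hi)
    stop("empty chord: current point violates a fixed-direction constraint",
         call. = FALSE)
  free <- which(is.na(fixed))
  bp <- numeric(0)
  for (k in free) {
    if (abs(grad[k]) < 1e-14) next
    s_star <- -dg0_vec[k] / grad[k]
    if (s_star > s_lo && s_star < s_hi) bp <- c(bp, s_star)
  }
  bp <- sort(bp)
  if (length(bp) > 1) bp <- bp[c(TRUE, diff(bp) > 1e-12)]  # merge grazing
  edges <- c(s_lo, bp, s_hi)
  n_seg <- length(edges) - 1
  a <- edges[-length(edges)]
  b <- edges[-1]
  mid <- (a + b) / 2
  sig <- character(n_seg)
  feas <- logical(n_seg)
  fix_idx <- which(!is.na(fixed))
  for (i in seq_len(n_seg)) {
    dg_mid <- dg0_vec + mid[i] * grad
    signs <- ifelse(dg_mid < 0, 1L, -1L)
    signs[fix_idx] <- fixed[fix_idx]
    key <- paste(ifelse(signs > 0, "+", "-"), collapse = "")
    sig[i] <- key
    cached <- if (!is.null(cache)) cache[[key]] else NULL
    feas[i] <- if (!is.null(cached)) cached else
      steady_state_feasible(network, signs, v_min = v_min, cache = cache)
  }
  list(a = a, b = b, signature = sig, feasible = feas,
       n_crossed = length(unique(sig)))
}

#' One Hit-and-Run step
#'
#' Draws a uniform ray direction, intersects it with the space, selects a
#' feasible segment with probability proportional to its (general) normal
#' mass along the ray, and draws the next point from the truncated normal on
#' that segment.  Weights are computed in log scale, so far-tail segments do
#' not underflow.
#'
#' @param space a `pta_thermo_space`.
#' @param network the `pta_network`.
#' @param m0 current reduced point.
#' @param v_min minimum flux magnitude.
#' @param cache feasibility memo environment.
#' @return list: `m` (next point), `signature` (its orthant), `n_crossed`.
#' @export
sample_step <- function(space, network, m0, v_min = 1e-6, cache = NULL,
                        fixed = NULL) {
  q_r <- space$q_r
  u <- stats::rnorm(q_r)
  u <- u / sqrt(sum(u^2))
  segs <- ray_segments(space, network, m0, u, v_min = v_min, cache = cache,
                       fixed = fixed)
  keep <- which(segs$feasible)
  if (!length(keep))
    stop("no feasible segment on the ray; chain state is corrupt",
         call. = FALSE)
  # along-ray density: with scaling D, ||D(m0+su)||^2 is quadratic in s,
  # giving a normal with mean -beta/(2 alpha), sd 1/sqrt(alpha)
  scales <- space$sampling_scales
  xu <- scales * u
  alpha <- sum(xu^2)
  beta <- 2 * sum((scales * m0) * xu)
  mu_s <- -beta / (2 * alpha)
  sd_s <- 1 / sqrt(alpha)
  za <- (segs$a[keep] - mu_s) / sd_s
  zb <- (segs$b[keep] - mu_s) / sd_s
  lw <- log_pnorm_diff(za, zb)
  lw <- lw - max(lw)
  w <- exp(lw)
  pick <- keep[sample.int(length(keep), 1, prob = w)]
  zz <- truncnorm_draw((segs$a[pick] - mu_s) / sd_s,
                       (segs$b[pick] - mu_s) / sd_s,
                       stats::runif(1))
  s <- mu_s + sd_s * zz
  s <- min(max(s, segs$a[pick] + 1e-12), segs$b[pick] - 1e-12)
  list(m = m0 + s * u,
       signature = segs$signature[pick],
       n_crossed = segs$n_crossed)
}

#' Sample the steady-state thermodynamic space
#'
#' Runs several Hit-and-Run chains from over-dispersed starting points (one
#' per feasible direction pattern found by [find_initial_points()]), pools
#' orthant visit counts after burn-in, retains thinned reaction-energy
#' samples, and computes convergence diagnostics.
#'
#' @param network a `pta_network` with the constrained set selected.
#' @param space the matching `pta_thermo_space`.
#' @param n_steps steps per chain.
#' @param n_chains number of chains (initial points are recycled if fewer
#'   patterns exist).
#' @param seed integer seed; the run is fully deterministic given
#'   `(seed, config)`.
#' @param init_points optional list from [find_initial_points()].
#' @param burn_in fraction of steps discarded before counting/retaining.
#' @param n_retain retained (thinned) energy samples per chain.
#' @param v_min minimum flux magnitude.
#' @param eps second-law margin used when computing initial points.
#' @return an object of class `pta_samples`: per-chain retained `dg` draws,
#'   reduced-coordinate draws, pooled orthant table, diagnostics and the
#'   maximum number of orthants crossed by any ray.
#' @export
run_tfs <- function(network, space, n_steps = 2000, n_chains = 4, seed = 1,
                    init_points = NULL, burn_in = 0.2,
                    n_retain = min(500, n_steps), v_min = 1e-6, eps = 0.1) {
  if (n_chains < 2) stop("at least 2 chains are required", call. = FALSE)
  if (is.null(init_points))
    init_points <- find_initial_points(network, space, eps = eps,
                                       v_min = v_min)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  cache <- new.env(parent = emptyenv())
  burn <- floor(burn_in * n_steps)
  retain_at <- unique(round(seq(burn + 1, n_steps, length.out = n_retain)))
  g <- length(space$gamma_ids)
  counts <- new.env(parent = emptyenv())
  chains_dg <- vector("list", n_chains)
  chains_m <- vector("list", n_chains)
  max_crossed <- 0L
  chain_seen <- vector("list", n_chains)
  fixed <- fixed_directions(network)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + 7919L * ch)
    # chain state lives in sampling coordinates w (whitened m = scales * w)
    m <- init_points[[(ch - 1) %% length(init_points) + 1]]$m_r /
      space$sampling_scales
    dg_keep <- matrix(NA_real_, length(retain_at), g)
    m_keep <- matrix(NA_real_, length(retain_at), space$q_r)
    kidx <- 1L
    seen <- character(0)
    for (step in seq_len(n_steps)) {
      st <- sample_step(space, network, m, v_min = v_min, cache = cache,
                        fixed = fixed)
      m <- st$m
      max_crossed <- max(max_crossed, st$n_crossed)
      if (step > burn) {
        counts[[st$signature]] <- (counts[[st$signature]] %||% 0L) + 1L
        seen <- union(seen, st$signature)
        if (kidx <= length(retain_at) && step == retain_at[kidx]) {
          dg_keep[kidx, ] <- reduced_dg(space, space$sampling_scales * m)
          m_keep[kidx, ] <- m
          kidx <- kidx + 1L
        }
      }
    }
    chain_seen[[ch]] <- seen
    colnames(dg_keep) <- space$gamma_ids
    chains_dg[[ch]] <- dg_keep
    chains_m[[ch]] <- m_keep
  }
  # stagnation: every chain stuck in one orthant, but not all in the same
  if (all(lengths(chain_seen) == 1) &&
      length(unique(unlist(chain_seen))) > 1)
    warning("chains remained in distinct single orthants; ",
            "the space may be disconnected or mixing is poor", call. = FALSE)
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  orthants <- tibble::tibble(
    signature = keys, count = as.integer(cnt),
    probability = cnt / sum(cnt)
  ) |> dplyr::arrange(dplyr::desc(.data$count))
  diag_psrf <- tryCatch(psrf(chains_dg), error = function(e) NULL)
  diag_ess <- tryCatch(ess(chains_dg), error = function(e) NULL)
  structure(
    list(dg = chains_dg, m = chains_m, orthants = orthants,
         psrf = diag_psrf, ess = diag_ess,
         max_orthants_crossed = max_crossed,
         gamma_ids = space$gamma_ids,
         config = list(n_steps = n_steps, n_chains = n_chains, seed = seed,
                       burn_in = burn_in, n_retain = length(retain_at),
                       v_min = v_min, alpha = space$alpha)),
    class = "pta_samples"
  )
}

#' @export
print.pta_samples <- function(x, ...) {
  cat(sprintf("<pta_samples> %d chains x %d retained draws, %d orthants visited\n",
              x$config$n_chains, x$config$n_retain, nrow(x$orthants)))
  if (!is.null(x$psrf))
    cat(sprintf("  max PSRF %.3f, min ESS %.0f\n",
                max(x$psrf, na.rm = TRUE), min(x$ess, na.rm = TRUE)))
  invisible(x)
}

#' Tidy retained energy samples
#' @param x a `pta_samples` object.
#' @param ... unused.
#' @return long tibble: `chain`, `draw`, `reaction`, `dg`.
#' @export
tidy.pta_samples <- function(x, ...) {
  purrr::map_dfr(seq_along(x$dg), function(ch) {
    m <- x$dg[[ch]]
    tibble::as_tibble(m) |>
      dplyr::mutate(chain = ch, draw = dplyr::row_number()) |>
      tidyr::pivot_longer(-c("chain", "draw"), names_to = "reaction",
                          values_to = "dg")
  })
}

#' One-row summary of a sampling run
#' @param x a `pta_samples` object.
#' @param ... unused.
#' @return tibble: chains, retained draws, orthants visited, worst PSRF,
#'   smallest ESS, max orthants crossed by a ray.
#' @export
glance.pta_samples <- function(x, ...) {
  tibble::tibble(
    n_chains = x$config$n_chains,
    n_retain = x$config$n_retain,
    n_orthants = nrow(x$orthants),
    max_psrf = if (is.null(x$psrf)) NA_real_ else max(x$psrf, na.rm = TRUE),
    min_ess = if (is.null(x$ess)) NA_real_ else min(x$ess, na.rm = TRUE),
    max_orthants_crossed = x$max_orthants_crossed
  )
}

#' Rescale poorly mixing directions
#'
#' Inflates the proposal scale of reduced-coordinate dimensions whose pilot
#' PSRF exceeds `threshold` (inflation proportional to PSRF^2).  The
#' along-ray density accounts for the rescaling, so the stationary
#' distribution is unchanged; only the exploration geometry differs.
#'
#' @param space a `pta_thermo_space`.
#' @param pilot_psrf PSRF per reduced dimension (from a pilot run's `m`
#'   chains).
#' @param threshold PSRF above which a dimension is rescaled.
#' @return the space with updated `sampling_scales`.
#' @export
adapt_parametrization <- function(space, pilot_psrf, threshold = 1.1) {
  stopifnot(length(pilot_psrf) == space$q_r)
  infl <- ifelse(!is.na(pilot_psrf) & pilot_psrf > threshold,
                 pilot_psrf^2, 1)
  # sampling coordinate w relates to whitened m by m = scales * w
  space$sampling_scales <- space$sampling_scales * infl
  space
}

#' Conditional concentration and standard-energy draws
#'
#' For each reaction-energy sample, draws `(ln c, dG'0)` from the Gaussian
#' conditional of the joint given the energies (Schur complement of the
#' reduced covariance).  Every returned triple satisfies the linear identity
#' between energies, standard energies and log-concentrations to numerical
#' precision.
#'
#' @param space a `pta_thermo_space`.
#' @param dg_samples matrix of energy draws (rows = draws, columns =
#'   constrained reactions), e.g. `do.call(rbind, samples$dg)`.
#' @param seed integer seed.
#' @return list with matrices `ln_c` (draws x metabolites) and `dg0`
#'   (draws x reactions).
#' @export
sample_concentrations <- function(space, dg_samples, seed = 1) {
  dg_samples <- as.matrix(dg_samples)
  n <- nrow(dg_samples)
  cond0 <- condition_on_dg(space, drop(dg_samples[1, ]))
  m <- length(space$idx$lnc)
  g <- length(space$mu_r)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  qq <- ncol(cond0$Q)
  Z <- matrix(stats::rnorm(n * qq), n, qq)
  mu_u <- space$mu_t[seq_len(m + g)]
  # mean_i = mu_u + gain (dg_i - mu_r); noise shares the factor across draws
  dev <- sweep(dg_samples, 2, space$mu_r)
  means <- matrix(mu_u, n, m + g, byrow = TRUE) + dev %*% t(cond0$gain)
  draws <- means + Z %*% t(cond0$Q)
  list(ln_c = draws[, seq_len(m), drop = FALSE],
       dg0 = draws[, m + seq_len(g), drop = FALSE])
}
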