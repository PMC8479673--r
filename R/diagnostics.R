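# Convergence metrics and distribution-comparison utilities.

as_chain_list <- function(chains) {
  if (is.matrix(chains)) chains <- list(chains)
  if (!is.list(chains) || length(chains) < 1)
    stop("chains must be a list of matrices (iterations x dimensions)",
         call. = FALSE)
  chains <- lapply(chains, function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  })
  d <- vapply(chains, ncol, integer(1))
  n <- vapply(chains, nrow, integer(1))
  if (length(unique(d)) != 1 || length(unique(n)) != 1)
    stop("all chains must have identical dimensions", call. = FALSE)
  chains
}

split_chains <- function(chains) {
  n <- nrow(chains[[1]])
  h <- floor(n / 2)
  unlist(lapply(chains, function(x)
    list(x[seq_len(h), , drop = FALSE],
         x[(n - h + 1):n, , drop = FALSE])), recursive = FALSE)
}

rank_normalize <- function(mats) {
  d <- ncol(mats[[1]])
  n <- nrow(mats[[1]])
  S <- length(mats) * n
  for (j in seq_len(d)) {
    pool <- unlist(lapply(mats, function(x) x[, j]))
    z <- stats::qnorm((rank(pool, ties.method = "average") - 3 / 8) /
                        (S + 1 / 4))
    for (k in seq_along(mats)) mats[[k]][, j] <- z[((k - 1) * n + 1):(k * n)]
  }
  mats
}

plain_rhat <- function(mats) {
  n <- nrow(mats[[1]])
  d <- ncol(mats[[1]])
  vapply(seq_len(d), function(j) {
    means <- vapply(mats, function(x) mean(x[, j]), numeric(1))
    vars <- vapply(mats, function(x) stats::var(x[, j]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(if (B <= 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Potential scale reduction factor
#'
#' Split-chain PSRF per dimension.  The default applies rank normalization
#' before computing the classic between/within-variance ratio (the modern
#' recommended criterion); `type = "plain"` gives the classic statistic on
#' the raw draws.
#'
#' @param chains list of matrices, one per chain (iterations x dimensions),
#'   or a single matrix for one dimension per column... each chain must have
#'   the same shape.
#' @param type `"rank"` (rank-normalized, default) or `"plain"`.
#' @return named numeric vector, one PSRF per dimension.
#' @export
psrf <- function(chains, type = c("rank", "plain")) {
  type <- match.arg(type)
  chains <- as_chain_list(chains)
  if (length(chains) < 2)
    stop("psrf needs at least 2 chains", call. = FALSE)
  if (nrow(chains[[1]]) < 4)
    stop("psrf needs chains of length >= 4", call. = FALSE)
  mats <- split_chains(chains)
  if (type == "rank") mats <- rank_normalize(mats)
  out <- plain_rhat(mats)
  names(out) <- colnames(chains[[1]])
  out
}

#' Effective sample size
#'
#' Autocorrelation-based ESS per dimension across split chains, with
#' Geyer-style truncation at the first non-positive pair of consecutive
#' autocorrelation sums (and a monotone envelope).  Constant chains are
#' reported as `NA` (degenerate).
#'
#' @param chains as in [psrf()].
#' @return named numeric vector, one ESS per dimension.
#' @export
ess <- function(chains) {
  chains <- as_chain_list(chains)
  if (nrow(chains[[1]]) < 4)
    stop("ess needs chains of length >= 4", call. = FALSE)
  mats <- split_chains(chains)
  M <- length(mats)
  n <- nrow(mats[[1]])
  d <- ncol(mats[[1]])
  out <- vapply(seq_len(d), function(j) {
    draws <- lapply(mats, function(x) x[, j])
    vars <- vapply(draws, stats::var, numeric(1))
    means <- vapply(draws, mean, numeric(1))
    W <- mean(vars)
    var_plus <- (n - 1) / n * W +
      (if (M > 1) stats::var(means) else 0)
    if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
    lag_max <- min(n - 2L, 2000L)
    acov <- vapply(draws, function(x) {
      x <- x - mean(x)
      stats::acf(x, lag.max = lag_max, plot = FALSE, type = "covariance",
                 demean = FALSE)$acf[, 1, 1]
    }, numeric(lag_max + 1L))
    rho <- 1 - (W - rowMeans(acov)) / var_plus
    rho[1] <- 1
    # pairwise sums, initial positive + monotone decreasing sequence
    max_pairs <- floor((length(rho) - 1) / 2)
    P <- numeric(0)
    for (k in seq_len(max_pairs)) {
      p <- rho[2 * k] + rho[2 * k + 1]
      if (p <= 0) break
      P <- c(P, p)
    }
    if (length(P) > 1) P <- cummin(P)
    tau <- max(1, 1 + 2 * sum(P))
    min(M * n / tau, M * n)
  }, numeric(1))
  names(out) <- colnames(chains[[1]])
  out
}

#' Gaussian Kullback-Leibler divergence
#'
#' `KL( N(mean1, sd1^2) || N(mean0, sd0^2) )` in nats (closed form).
#'
#' @param mean1,sd1 "posterior" parameters.
#' @param mean0,sd0 "prior" (reference) parameters.
#' @return numeric (vectorized).
#' @export
kl_gaussian <- function(mean1, sd1, mean0, sd0) {
  log(sd0 / sd1) + (sd1^2 + (mean1 - mean0)^2) / (2 * sd0^2) - 0.5
}

#' KL divergence between a sampled posterior and its Gaussian prior
#'
#' The posterior marginal of each variable is summarized by moment matching
#' (a Gaussian with the sample mean and sd), then compared to the prior with
#' the closed-form Gaussian KL.  Both directions are returned.
#'
#' @param prior_mean,prior_sd prior marginal parameters (recycled).
#' @param samples matrix of posterior draws (rows = draws, columns =
#'   variables) with at least 100 rows.
#' @return tibble: `variable`, `posterior_mean`, `posterior_sd`,
#'   `kl` (posterior || prior) and `kl_reverse`.
#' @export
kl_prior_posterior <- function(prior_mean, prior_sd, samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 100)
    stop("need at least 100 samples for moment matching", call. = FALSE)
  pm <- rep_len(prior_mean, ncol(samples))
  ps <- rep_len(prior_sd, ncol(samples))
  m1 <- colMeans(samples)
  s1 <- apply(samples, 2, stats::sd)
  if (any(s1 <= 0))
    stop("degenerate sample variance in column(s): ",
         paste(which(s1 <= 0), collapse = ", "), call. = FALSE)
  tibble::tibble(
    variable = colnames(samples) %||% paste0("V", seq_len(ncol(samples))),
    posterior_mean = m1,
    posterior_sd = s1,
    kl = kl_gaussian(m1, s1, pm, ps),
    kl_reverse = kl_gaussian(pm, ps, m1, s1)
  )
}

#' Distribution descriptors for comparison utilities
#'
#' Lightweight parametric/empirical descriptors consumed by [hellinger()]:
#' a Gaussian, a uniform interval (e.g. a feasibility range from interval
#' arithmetic), or a histogram built from samples.
#'
#' @param mean,sd Gaussian parameters.
#' @return a `pta_dist` object.
#' @export
dist_gaussian <- function(mean, sd) {
  structure(list(type = "gaussian", mean = mean, sd = sd),
            class = "pta_dist")
}

#' @rdname dist_gaussian
#' @param min,max uniform support.
#' @export
dist_uniform <- function(min, max) {
  stopifnot(max > min)
  structure(list(type = "uniform", min = min, max = max),
            class = "pta_dist")
}

#' @rdname dist_gaussian
#' @param samples draws summarized as a histogram.
#' @param bins number of histogram bins.
#' @export
dist_histogram <- function(samples, bins = 64) {
  h <- graphics::hist(samples, breaks = bins, plot = FALSE)
  structure(list(type = "histogram", breaks = h$breaks,
                 density = h$density),
            class = "pta_dist")
}

dist_support <- function(d) {
  switch(d$type,
         gaussian = c(d$mean - 10 * d$sd, d$mean + 10 * d$sd),
         uniform = c(d$min, d$max),
         histogram = range(d$breaks))
}

dist_density <- function(d, x) {
  switch(d$type,
         gaussian = stats::dnorm(x, d$mean, d$sd),
         uniform = stats::dunif(x, d$min, d$max),
         histogram = {
           i <- findInterval(x, d$breaks, rightmost.closed = TRUE)
           out <- numeric(length(x))
           ok <- i >= 1 & i <= length(d$density)
           out[ok] <- d$density[i[ok]]
           out
         })
}

#' Hellinger distance between two distributions
#'
#' Closed form for Gaussian-Gaussian pairs; numeric integration of the
#' Bhattacharyya coefficient on a shared grid otherwise.  Distributions with
#' disjoint supports are at distance 1.
#'
#' @param dist_a,dist_b `pta_dist` descriptors (see [dist_gaussian()]), or
#'   numeric sample vectors (converted to histograms).
#' @param grid_size number of integration points for the numeric branch.
#' @return Hellinger distance in `[0, 1]`.
#' @export
hellinger <- function(dist_a, dist_b, grid_size = 4096) {
  if (is.numeric(dist_a)) dist_a <- dist_histogram(dist_a)
  if (is.numeric(dist_b)) dist_b <- dist_histogram(dist_b)
  if (dist_a$type == "gaussian" && dist_b$type == "gaussian") {
    s2 <- dist_a$sd^2 + dist_b$sd^2
    bc <- sqrt(2 * dist_a$sd * dist_b$sd / s2) *
      exp(-(dist_a$mean - dist_b$mean)^2 / (4 * s2))
    return(sqrt(max(0, 1 - bc)))
  }
  ra <- dist_support(dist_a)
  rb <- dist_support(dist_b)
  lo <- max(ra[1], rb[1])
  hi <- min(ra[2], rb[2])
  if (hi <= lo) return(1)
  x <- seq(lo, hi, length.out = grid_size)
  dx <- x[2] - x[1]
  bc <- sum(sqrt(dist_density(dist_a, x) * dist_density(dist_b, x))) * dx
  sqrt(max(0, min(1, 1 - min(bc, 1))))
}

#' Gate-style diagnostics summary
#'
#' Computes PSRF and ESS for a sampling run and reports whether the
#' configured convergence gates pass.
#'
#' @param samples a `pta_samples` object.
#' @param psrf_gate,ess_gate thresholds.
#' @return list with `table` (tibble per reaction) and `pass`.
#' @export
diagnose_samples <- function(samples, psrf_gate = 1.1, ess_gate = 100) {
  r <- psrf(samples$dg)
  e <- ess(samples$dg)
  tab <- tibble::tibble(reaction = samples$gamma_ids, psrf = r, ess = e)
  list(table = tab,
       pass = all(r < psrf_gate, na.rm = TRUE) &&
         all(e > ess_gate, na.rm = TRUE))
}
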