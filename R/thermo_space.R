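# The joint Gaussian over t = [ln c, dG'0, dG'] and its low-rank geometry.
#
# With ln c ~ N(mu_c, Sigma_c) and dG'0 ~ N(mu0, Sigma0), the reaction
# energies dG' = dG'0 + RT * t(S_Gamma) ln c are Gaussian with
#   mu_r = R [mu_c; mu0],   Sigma_r = R blockdiag(Sigma_c, Sigma0) R',
#   R = [RT * t(S_Gamma), I].
# The stacked vector t is Gaussian with the block covariance Sigma_t; its
# support is the affine subspace where the linear identity holds exactly.
# A factor Q (Sigma_t = Q Q', q columns) expresses t = mu_t + Q m with
# m standard normal, so the confidence region (t - mu_t)' pinv(Sigma_t)
# (t - mu_t) <= chi2_{q, alpha} becomes the ball ||m||^2 <= chi2_{q, alpha}.

#' Assemble the linear map from [ln c, dG'0] to reaction energies
#'
#' Returns `R = [RT * t(S_Gamma), I]`, the gamma x (m + gamma) matrix that
#' maps stacked log-concentrations and standard energies to transformed
#' reaction energies.
#'
#' @param network a `pta_network` with the constrained set selected.
#' @param priors a `pta_priors` (supplies RT).
#' @return a numeric matrix.
#' @export
assemble_R <- function(network, priors) {
  gamma <- network$gamma
  SG <- network$S[, gamma, drop = FALSE]
  cbind(priors$RT * t(SG), diag(length(gamma)))
}

#' Rank-revealing symmetric PSD factorization
#'
#' Eigendecomposition-based square root: returns `Q` with `q` columns scaled
#' by the square roots of the retained eigenvalues, so `Q %*% t(Q)`
#' reconstructs `Sigma` and coordinates `m` with `x = Q m` are standard
#' normal under `x ~ N(0, Sigma)`.
#'
#' @param Sigma symmetric positive semidefinite matrix.
#' @param rank_tol eigenvalues below `rank_tol * max(eigenvalue)` are
#'   treated as zero.
#' @return list with `Q` (matrix, `q` columns), `q` (numerical rank),
#'   `values` (retained eigenvalues) and `pinv` (pseudo-inverse of Sigma).
#' @export
psd_factor <- function(Sigma, rank_tol = 1e-9) {
  Sigma <- (Sigma + t(Sigma)) / 2
  n <- nrow(Sigma)
  if (n == 0 || all(Sigma == 0)) {
    return(list(Q = matrix(0, n, 0), q = 0L, values = numeric(0),
                pinv = matrix(0, n, n)))
  }
  eg <- eigen(Sigma, symmetric = TRUE)
  lmax <- max(eg$values)
  if (min(eg$values) < -1e-6 * max(lmax, 1))
    stop("matrix has a significantly negative eigenvalue: ",
         format(min(eg$values)), call. = FALSE)
  keep <- eg$values > rank_tol * lmax
  q <- sum(keep)
  V <- eg$vectors[, keep, drop = FALSE]
  lam <- eg$values[keep]
  list(Q = V %*% diag(sqrt(lam), q),
       q = as.integer(q),
       values = lam,
       pinv = V %*% diag(1 / lam, q) %*% t(V))
}

#' Chi-square confidence threshold
#'
#' The `alpha`-quantile of the chi-square distribution with `q` degrees of
#' freedom, the squared radius of the confidence ball in whitened
#' coordinates.
#'
#' @param q degrees of freedom (>= 1).
#' @param alpha confidence level in (0, 1).
#' @return scalar threshold.
#' @export
chi2_threshold <- function(q, alpha = 0.95) {
  if (q < 1) stop("q must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  stats::qchisq(alpha, df = q)
}

#' Build the joint thermodynamic space
#'
#' Assembles the Gaussian over `t = [ln c, dG'0, dG']`, its rank-revealing
#' factor, the confidence threshold, and the reduced form over the reaction
#' energies alone (used by the optimizer and the sampler, which only need
#' `dG'`).
#'
#' @param network a `pta_network` with the constrained set selected.
#' @param priors a `pta_priors`.
#' @param alpha confidence level for the chi-square threshold.
#' @param rank_tol relative eigenvalue cutoff for numerical rank.
#' @return an object of class `pta_thermo_space`.
#' @export
build_thermo_space <- function(network, priors, alpha = 0.95,
                               rank_tol = 1e-9) {
  gamma <- network$gamma
  if (!length(gamma))
    stop("select the constrained reaction set first ",
         "(see select_thermo_reactions)", call. = FALSE)
  m <- nrow(network$S)
  g <- length(gamma)
  if (length(priors$mu_c) != m || length(priors$mu_dg0) != g)
    stop("priors do not match network dimensions", call. = FALSE)
  RT <- priors$RT
  SG <- network$S[, gamma, drop = FALSE]
  R_mat <- assemble_R(network, priors)
  mu_u <- c(priors$mu_c, priors$mu_dg0)
  mu_r <- drop(R_mat %*% mu_u)
  A <- RT * priors$Sigma_c %*% SG                   # m x g, = RT Sigma_c S_G
  Sigma_r <- RT^2 * t(SG) %*% priors$Sigma_c %*% SG + priors$Sigma_dg0
  Sigma_t <- rbind(
    cbind(priors$Sigma_c, matrix(0, m, g), A),
    cbind(matrix(0, g, m), priors$Sigma_dg0, priors$Sigma_dg0),
    cbind(t(A), priors$Sigma_dg0, Sigma_r)
  )
  mu_t <- c(mu_u, mu_r)
  fac <- psd_factor(Sigma_t, rank_tol)
  red <- psd_factor(Sigma_r, rank_tol)
  idx <- list(lnc = seq_len(m), dg0 = m + seq_len(g), dg = m + g + seq_len(g))
  structure(
    list(network = network, priors = priors,
         R_mat = R_mat, RT = RT,
         mu_t = mu_t, Sigma_t = Sigma_t, Q = fac$Q, q = fac$q,
         Sigma_t_pinv = fac$pinv,
         mu_r = mu_r, Sigma_r = Sigma_r, Q_r = red$Q, q_r = red$q,
         Sigma_r_pinv = red$pinv,
         B = rbind(A, priors$Sigma_dg0),            # (m+g) x g block of Sigma_t
         alpha = alpha,
         chi2 = if (fac$q >= 1) chi2_threshold(fac$q, alpha) else 0,
         chi2_r = if (red$q >= 1) chi2_threshold(red$q, alpha) else 0,
         sampling_scales = rep(1, red$q),
         idx = idx,
         gamma_ids = network$reaction_ids[gamma]),
    class = "pta_thermo_space"
  )
}

#' @export
print.pta_thermo_space <- function(x, ...) {
  cat(sprintf(paste0("<pta_thermo_space> gamma = %d reactions, rank q = %d ",
                     "(reduced q_r = %d), alpha = %.3f\n"),
              length(x$gamma_ids), x$q, x$q_r, x$alpha))
  invisible(x)
}

#' Map whitened coordinates to the full thermodynamic state
#'
#' `t = mu_t + Q m`.  The returned vector satisfies the linear identity
#' between energies, standard energies and log-concentrations by
#' construction.
#'
#' @param space a `pta_thermo_space`.
#' @param m_vec whitened coordinate vector of length `q`.
#' @return named list with components `t`, `ln_c`, `dg0`, `dg`.
#' @export
thermo_state <- function(space, m_vec) {
  if (length(m_vec) != space$q)
    stop("m_vec must have length q = ", space$q, call. = FALSE)
  t_vec <- space$mu_t + drop(space$Q %*% m_vec)
  list(t = t_vec,
       ln_c = t_vec[space$idx$lnc],
       dg0 = t_vec[space$idx$dg0],
       dg = t_vec[space$idx$dg])
}

#' Reaction energies from reduced coordinates
#' @param space a `pta_thermo_space`.
#' @param m_r reduced coordinate vector (length `q_r`) or matrix with
#'   `q_r` rows (one column per draw).
#' @return energy vector, or matrix with one column per draw.
#' @export
reduced_dg <- function(space, m_r) {
  if (is.matrix(m_r)) space$mu_r + space$Q_r %*% m_r
  else drop(space$mu_r + space$Q_r %*% m_r)
}

#' Condition the joint on observed reaction energies
#'
#' Gaussian conditional of `[ln c, dG'0]` given `dG' = dg`, computed with the
#' Schur complement of the reduced covariance in the joint covariance.  A
#' generalized inverse is used, so rank-deficient reduced covariances (the
#' group-contribution case) are handled; `dg` must lie in the support of the
#' reduced distribution.
#'
#' @param space a `pta_thermo_space`.
#' @param dg reaction-energy vector (length gamma).
#' @param tol residual tolerance for the support check.
#' @return list with `mean` (length m + gamma), `cov`, and a factor `Q` of
#'   `cov` for sampling.
#' @export
condition_on_dg <- function(space, dg, tol = 1e-6) {
  resid <- dg - space$mu_r
  proj <- drop(space$Sigma_r %*% (space$Sigma_r_pinv %*% resid))
  if (max(abs(proj - resid)) > tol * max(1, max(abs(resid))))
    stop("dg is outside the support of the reduced distribution",
         call. = FALSE)
  gain <- space$B %*% space$Sigma_r_pinv
  mu_u <- c(space$priors$mu_c, space$priors$mu_dg0)
  mean <- mu_u + drop(gain %*% resid)
  m <- length(space$priors$mu_c)
  g <- length(space$mu_r)
  blockdiag <- rbind(cbind(space$priors$Sigma_c, matrix(0, m, g)),
                     cbind(matrix(0, g, m), space$priors$Sigma_dg0))
  cov <- blockdiag - gain %*% t(space$B)
  cov <- (cov + t(cov)) / 2
  fac <- psd_factor(cov, rank_tol = 1e-9)
  list(mean = mean, cov = cov, Q = fac$Q, gain = gain)
}

#' Serialize a thermodynamic space to JSON
#'
#' Stores means, factors, ranks and the confidence level so a space can be
#' reused across runs without rebuilding.
#'
#' @param space a `pta_thermo_space`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thermo_space <- function(space, path) {
  flat <- function(x) list(dim = dim(x), data = as.vector(x))
  payload <- list(
    header = list(format = "thermoflux-space", version = 1L,
                  alpha = space$alpha, q = space$q, q_r = space$q_r,
                  gamma_ids = space$gamma_ids),
    RT = space$RT,
    mu_t = unname(space$mu_t), Sigma_t = flat(space$Sigma_t),
    Q = flat(space$Q),
    mu_r = unname(space$mu_r), Sigma_r = flat(space$Sigma_r),
    Q_r = flat(space$Q_r)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized thermodynamic space
#'
#' Restores the fields written by [write_thermo_space()].  The result
#' supports the geometric operations (state reconstruction, conditioning,
#' sampling) but carries no network, so operations that need the
#' stoichiometry must use the original object.
#'
#' @param path path written by [write_thermo_space()].
#' @return a `pta_thermo_space` (without network/priors attached).
#' @export
read_thermo_space <- function(path) {
  p <- jsonlite::fromJSON(path)
  unflat <- function(x) matrix(x$data, x$dim[1], x$dim[2])
  q <- p$header$q
  q_r <- p$header$q_r
  g <- length(p$mu_r)
  Sigma_t <- unflat(p$Sigma_t)
  Sigma_r <- unflat(p$Sigma_r)
  fac <- psd_factor(Sigma_t)
  red <- psd_factor(Sigma_r)
  m <- length(p$mu_t) - 2 * g
  structure(
    list(network = NULL, priors = NULL,
         R_mat = NULL, RT = p$RT,
         mu_t = p$mu_t, Sigma_t = Sigma_t,
         Q = unflat(p$Q), q = q,
         Sigma_t_pinv = fac$pinv,
         mu_r = p$mu_r, Sigma_r = Sigma_r,
         Q_r = unflat(p$Q_r), q_r = q_r,
         Sigma_r_pinv = red$pinv,
         B = NULL,
         alpha = p$header$alpha,
         chi2 = if (q >= 1) chi2_threshold(q, p$header$alpha) else 0,
         chi2_r = if (q_r >= 1) chi2_threshold(q_r, p$header$alpha) else 0,
         sampling_scales = rep(1, q_r),
         idx = list(lnc = seq_len(m), dg0 = m + seq_len(g),
                    dg = m + g + seq_len(g)),
         gamma_ids = p$header$gamma_ids),
    class = "pta_thermo_space"
  )
}
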