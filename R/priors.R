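# Priors for log-concentrations and standard Gibbs reaction energies.

#' Construct thermodynamic priors
#'
#' Log-normal prior on metabolite concentrations (natural log, molar) and a
#' Gaussian prior on standard Gibbs reaction energies (kJ/mol).  The
#' standard-energy covariance may be rank-deficient, as produced by
#' group-contribution estimators whose uncertainties are shared across
#' reactions.
#'
#' @param mu_c,Sigma_c mean vector and covariance of `ln c` (one entry per
#'   metabolite; a scalar/vector `Sigma_c` is taken as a diagonal of
#'   variances).
#' @param mu_dg0,Sigma_dg0 mean and covariance of the standard reaction
#'   energies, one entry per thermodynamically constrained reaction.
#' @param temperature temperature in Kelvin.
#' @param R_gas gas constant, kJ/(mol K).
#' @return an object of class `pta_priors` with the `RT` product attached.
#' @export
thermo_priors <- function(mu_c, Sigma_c, mu_dg0, Sigma_dg0,
                          temperature = 298.15, R_gas = 8.31446e-3) {
  as_cov <- function(x, n, what) {
    if (is.matrix(x)) {
      if (!all(dim(x) == n)) stop(what, " has wrong dimensions", call. = FALSE)
      x <- (x + t(x)) / 2
    } else {
      x <- diag(rep_len(as.numeric(x), n), n)
    }
    ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop(what, " is not positive semidefinite", call. = FALSE)
    x
  }
  m <- length(mu_c)
  g <- length(mu_dg0)
  structure(
    list(mu_c = as.numeric(mu_c),
         Sigma_c = as_cov(Sigma_c, m, "Sigma_c"),
         mu_dg0 = as.numeric(mu_dg0),
         Sigma_dg0 = as_cov(Sigma_dg0, g, "Sigma_dg0"),
         temperature = temperature,
         R_gas = R_gas,
         RT = R_gas * temperature),
    class = "pta_priors"
  )
}

#' @export
print.pta_priors <- function(x, ...) {
  cat(sprintf("<pta_priors> %d metabolites, %d reactions, T = %.2f K (RT = %.4f kJ/mol)\n",
              length(x$mu_c), length(x$mu_dg0), x$temperature, x$RT))
  invisible(x)
}

#' Read priors from tab-separated tables
#'
#' `conc_path` must have columns `metabolite_id`, `mean_ln_c`, `sd`; rows are
#' matched to the network's metabolites.  `dg0_path` must have columns
#' `reaction_id`, `mean_dg0`, `sd`, matched to the constrained reactions.  An
#' optional dense covariance CSV (`dg0_cov_path`, with a header of reaction
#' ids) overrides the diagonal standard-energy covariance.
#'
#' @param network a `pta_network` with the constrained set selected.
#' @param conc_path,dg0_path,dg0_cov_path file paths (see details).
#' @param temperature temperature in Kelvin.
#' @return a [thermo_priors()] object.
#' @export
read_priors <- function(network, conc_path, dg0_path, dg0_cov_path = NULL,
                        temperature = 298.15) {
  ct <- utils::read.delim(conc_path, stringsAsFactors = FALSE)
  gt <- utils::read.delim(dg0_path, stringsAsFactors = FALSE)
  i <- match(network$metabolite_ids, ct$metabolite_id)
  if (anyNA(i)) stop("missing concentration prior for: ",
                     paste(network$metabolite_ids[is.na(i)], collapse = ", "),
                     call. = FALSE)
  gamma_ids <- network$reaction_ids[network$gamma]
  j <- match(gamma_ids, gt$reaction_id)
  if (anyNA(j)) stop("missing standard-energy prior for: ",
                     paste(gamma_ids[is.na(j)], collapse = ", "),
                     call. = FALSE)
  Sigma_dg0 <- diag(gt$sd[j]^2, length(j))
  if (!is.null(dg0_cov_path)) {
    cm <- as.matrix(utils::read.csv(dg0_cov_path, row.names = 1,
                                    check.names = FALSE))
    Sigma_dg0 <- cm[gamma_ids, gamma_ids]
  }
  thermo_priors(mu_c = ct$mean_ln_c[i], Sigma_c = ct$sd[i]^2,
                mu_dg0 = gt$mean_dg0[j], Sigma_dg0 = Sigma_dg0,
                temperature = temperature)
}

#' Write priors as tab-separated tables
#'
#' Inverse of [read_priors()]; writes the concentration table, the
#' standard-energy table and the dense covariance CSV.
#'
#' @param network a `pta_network` with the constrained set selected.
#' @param priors a `pta_priors` object.
#' @param conc_path,dg0_path,dg0_cov_path output paths.
#' @return invisibly, the paths written.
#' @export
write_priors <- function(network, priors, conc_path, dg0_path,
                         dg0_cov_path = NULL) {
  utils::write.table(
    data.frame(metabolite_id = network$metabolite_ids,
               mean_ln_c = priors$mu_c,
               sd = sqrt(diag(priors$Sigma_c))),
    conc_path, sep = "\t", row.names = FALSE, quote = FALSE)
  gamma_ids <- network$reaction_ids[network$gamma]
  utils::write.table(
    data.frame(reaction_id = gamma_ids,
               mean_dg0 = priors$mu_dg0,
               sd = sqrt(diag(priors$Sigma_dg0))),
    dg0_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(dg0_cov_path)) {
    cm <- priors$Sigma_dg0
    dimnames(cm) <- list(gamma_ids, gamma_ids)
    utils::write.csv(cm, dg0_cov_path)
  }
  invisible(c(conc_path, dg0_path, dg0_cov_path))
}
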