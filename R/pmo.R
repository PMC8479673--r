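# Probabilistic metabolic optimization: find the most probable
# thermodynamic state compatible with steady state and the second law.
#
# In whitened coordinates the problem is
#     minimize ||m||^2
#     s.t.     S v = 0, lb <= v <= ub, |v_i| >= v_min (i in Gamma)
#              sign(v_i) * dG'_i(m) <= -eps
#              ||m||^2 <= chi2_{q, alpha}
# The direction binaries are handled by an exact branch-and-bound: fixing a
# subset of directions gives a convex least-norm QP whose value lower-bounds
# every completion, and a steady-state LP prunes orthants without a flux
# witness.  Because the objective *is* the ellipsoid's quadratic form, the
# hard confidence constraint reduces to an acceptance test on the optimum:
# either the unconstrained-norm minimum lies inside the ball (then it is the
# constrained optimum) or the orthant is infeasible at confidence alpha.

dg_rows <- function(space, reduced) {
  if (reduced) list(mu = space$mu_r, Qd = space$Q_r, dim = space$q_r,
                    radius2 = space$chi2_r)
  else list(mu = space$mu_r, Qd = space$Q[space$idx$dg, , drop = FALSE],
            dim = space$q, radius2 = space$chi2)
}

# least-norm point of one orthant of the energy space (signs = flux
# directions; energies get the opposite sign).  extra_A/extra_b: additional
# linear inequalities A m <= b (e.g. measured concentrations).
orthant_qp <- function(geom, signs, eps, extra_A = NULL, extra_b = NULL,
                       margin = NULL) {
  act <- which(!is.na(signs))
  A <- NULL
  b <- NULL
  if (length(act)) {
    if (is.null(margin)) margin <- rep(eps, length(geom$mu))
    A <- signs[act] * geom$Qd[act, , drop = FALSE]
    b <- -margin[act] - signs[act] * geom$mu[act]
  }
  A <- rbind(A, extra_A)
  b <- c(b, extra_b)
  res <- solve_least_norm(geom$dim, A_le = A, b_le = b)
  res
}

#' Solve the probabilistic metabolic optimization problem
#'
#' Finds the globally most probable thermodynamic state (the mode of the
#' joint Gaussian restricted to the steady-state thermodynamic space) by
#' exact branch-and-bound over reaction directions with convex least-norm
#' subproblems.
#'
#' @param network a `pta_network` with the constrained set selected.
#' @param space the matching `pta_thermo_space`.
#' @param direction_constraints optional named integer vector
#'   (`c(R1 = 1, R2 = -1)`) fixing flux directions of constrained reactions.
#' @param flux_constraints optional tibble/data.frame with columns
#'   `reaction`, `lb`, `ub` overriding bounds (e.g. measured rates).
#' @param concentration_constraints optional tibble with columns
#'   `metabolite`, `lb`, `ub` bounding `ln c` (natural log, molar).
#' @param eps second-law margin: `sign(v_i) * dG'_i <= -eps` (kJ/mol).
#' @param v_min minimum flux magnitude for constrained reactions.
#' @return an object of class `pta_pmo`: `m_star`, `t_star` (list with
#'   `ln_c`, `dg0`, `dg`), `v_star`, `objective`, `status`, `signature`, and
#'   a tidy `z` table of per-variable z-scores.
#' @export
solve_pmo <- function(network, space, direction_constraints = NULL,
                      flux_constraints = NULL,
                      concentration_constraints = NULL,
                      eps = 0.1, v_min = 1e-6) {
  g <- length(space$gamma_ids)
  geom <- dg_rows(space, reduced = FALSE)
  lb <- network$lb
  ub <- network$ub
  if (!is.null(flux_constraints)) {
    j <- match(flux_constraints$reaction, network$reaction_ids)
    if (anyNA(j)) stop("unknown reaction in flux_constraints", call. = FALSE)
    lb[j] <- pmax(lb[j], flux_constraints$lb)
    ub[j] <- pmin(ub[j], flux_constraints$ub)
    if (any(lb > ub)) stop("flux constraints are inconsistent with bounds",
                           call. = FALSE)
  }
  extra_A <- NULL
  extra_b <- NULL
  if (!is.null(concentration_constraints)) {
    i <- match(concentration_constraints$metabolite, network$metabolite_ids)
    if (anyNA(i)) stop("unknown metabolite in concentration_constraints",
                       call. = FALSE)
    Qc <- space$Q[space$idx$lnc, , drop = FALSE]
    mu_c <- space$mu_t[space$idx$lnc]
    lo <- concentration_constraints$lb
    hi <- concentration_constraints$ub
    fin_hi <- is.finite(hi)
    fin_lo <- is.finite(lo)
    extra_A <- rbind(Qc[i[fin_hi], , drop = FALSE],
                     -Qc[i[fin_lo], , drop = FALSE])
    extra_b <- c(hi[fin_hi] - mu_c[i[fin_hi]],
                 -(lo[fin_lo] - mu_c[i[fin_lo]]))
  }
  allowed <- allowed_signs(network, direction_constraints)
  cache <- new.env(parent = emptyenv())
  ss_ok <- function(signs) {
    partial_flux_feasible(network$S, lb, ub, network$gamma, signs, v_min)
  }

  best <- list(obj = Inf, m = NULL, signs = NULL)
  recurse <- function(signs, level) {
    rel <- orthant_qp(geom, signs, eps, extra_A, extra_b)
    if (rel$status != "optimal" || rel$value > geom$radius2 + 1e-9) return()
    if (rel$value >= best$obj - 1e-9 && !is.null(best$m)) {
      # equal-objective branches still explored for lexicographic tie-break
      if (rel$value > best$obj + 1e-9) return()
    }
    if (!ss_ok(signs)) return()
    if (level > g) {
      sig <- orthant_key(matrix(signs))
      if (rel$value < best$obj - 1e-9 ||
          (rel$value <= best$obj + 1e-9 &&
           (is.null(best$signs) || sig < orthant_key(matrix(best$signs))))) {
        best <<- list(obj = rel$value, m = rel$x, signs = signs)
      }
      return()
    }
    # explore the branch matching the relaxation's current energy sign first
    dg_rel <- geom$mu[level] + drop(geom$Qd[level, , drop = FALSE] %*% rel$x)
    pref <- if (dg_rel <= 0) 1L else -1L
    for (s in unique(c(pref, -pref))) {
      if (!(s %in% allowed[[level]])) next
      signs2 <- signs
      signs2[level] <- s
      recurse(signs2, level + 1L)
    }
  }
  recurse(rep(NA_integer_, g), 1L)

  if (!is.finite(best$obj)) {
    return(structure(list(status = "infeasible", objective = NA_real_,
                          m_star = NULL, t_star = NULL, v_star = NULL,
                          signature = NULL, z = NULL, space = space),
                     class = "pta_pmo"))
  }
  # flux witness for the optimal orthant
  wit <- flux_witness(network$S, lb, ub, network$gamma, best$signs, v_min)
  st <- thermo_state(space, best$m)
  z <- z_scores(st$t, space)
  structure(
    list(status = "optimal",
         objective = best$obj,
         m_star = best$m,
         t_star = st,
         v_star = wit,
         signature = orthant_key(matrix(best$signs)),
         signs = best$signs,
         z = z,
         eps = eps, v_min = v_min,
         space = space, network = network),
    class = "pta_pmo"
  )
}

allowed_signs <- function(network, direction_constraints) {
  gamma <- network$gamma
  fixed <- fixed_directions(network)
  allowed <- lapply(seq_along(gamma), function(k) {
    if (!is.na(fixed[k])) fixed[k] else c(1L, -1L)
  })
  if (!is.null(direction_constraints)) {
    ids <- network$reaction_ids[gamma]
    for (nm in names(direction_constraints)) {
      k <- match(nm, ids)
      if (is.na(k)) stop("direction constraint on a reaction outside the ",
                         "constrained set: ", nm, call. = FALSE)
      s <- as.integer(direction_constraints[[nm]])
      if (!(s %in% allowed[[k]]))
        stop("direction constraint on ", nm,
             " conflicts with irreversibility", call. = FALSE)
      allowed[[k]] <- s
    }
  }
  allowed
}

# steady-state LP with a (possibly partial) sign assignment on Gamma
partial_flux_feasible <- function(S, lb, ub, gamma, signs, v_min) {
  act <- which(!is.na(signs))
  for (k in act) {
    j <- gamma[k]
    if (signs[k] > 0) lb[j] <- max(lb[j], v_min)
    else ub[j] <- min(ub[j], -v_min)
  }
  if (any(lb > ub)) return(FALSE)
  polyhedron_feasible(ncol(S), A_eq = S, b_eq = numeric(nrow(S)),
                      lb = lb, ub = ub)$feasible
}

flux_witness <- function(S, lb, ub, gamma, signs, v_min) {
  for (k in seq_along(gamma)) {
    j <- gamma[k]
    if (signs[k] > 0) lb[j] <- max(lb[j], v_min)
    else ub[j] <- min(ub[j], -v_min)
  }
  res <- polyhedron_feasible(ncol(S), A_eq = S, b_eq = numeric(nrow(S)),
                             lb = lb, ub = ub)
  if (!res$feasible) return(NULL)
  stats::setNames(res$x, colnames(S))
}

#' Per-variable z-scores of a thermodynamic state
#'
#' Deviation of each component of `t` from its prior mean in units of prior
#' standard deviation.  Variables with zero prior variance get `z = 0` when
#' they sit at the mean and `NA` (flagged) otherwise.
#'
#' @param t_vec full state vector (length `m + 2 gamma`), e.g. `t_star$t`.
#' @param space a `pta_thermo_space`.
#' @return tibble: `kind` (`ln_c`, `dg0`, `dg`), `id`, `value`, `mean`, `sd`,
#'   `z`.
#' @export
z_scores <- function(t_vec, space) {
  sd_t <- sqrt(pmax(diag(space$Sigma_t), 0))
  dev <- t_vec - space$mu_t
  z <- ifelse(sd_t > 0, dev / sd_t,
              ifelse(abs(dev) <= 1e-8, 0, NA_real_))
  met_ids <- if (!is.null(space$network)) space$network$metabolite_ids
    else paste0("M", seq_along(space$idx$lnc))
  tibble::tibble(
    kind = rep(c("ln_c", "dg0", "dg"),
               c(length(space$idx$lnc), length(space$idx$dg0),
                 length(space$idx$dg))),
    id = c(met_ids, space$gamma_ids, space$gamma_ids),
    value = t_vec,
    mean = space$mu_t,
    sd = sd_t,
    z = z
  )
}

#' Classify concentration anomalies
#'
#' Flags metabolites whose predicted state deviates from the prior by more
#' than `theta` standard deviations, and non-intracellular metabolites whose
#' predicted concentration reaches 10 mM.
#'
#' @param z z-score tibble from [z_scores()] (or a `pta_pmo` object).
#' @param network the `pta_network` (supplies compartments); taken from the
#'   fit when `z` is a `pta_pmo`.
#' @param theta z-score threshold (conservative default 1).
#' @param conc_threshold concentration threshold for non-intracellular
#'   metabolites (molar; default 10 mM).
#' @param intracellular compartment labels counted as intracellular.
#' @return tibble of flagged metabolites: `metabolite`, `compartment`,
#'   `ln_c`, `concentration`, `z`, `rule` (`"z"` or `"concentration"`).
#' @export
classify_anomalies <- function(z, network = NULL, theta = 1,
                               conc_threshold = 0.01,
                               intracellular = "c") {
  if (inherits(z, "pta_pmo")) {
    if (is.null(network)) network <- z$network
    z <- z$z
  }
  if (is.null(network)) stop("network is required", call. = FALSE)
  zc <- z[z$kind == "ln_c", ]
  comp <- network$compartment[match(zc$id, network$metabolite_ids)]
  conc <- exp(zc$value)
  flag_z <- !is.na(zc$z) & abs(zc$z) > theta
  flag_c <- !(comp %in% intracellular) & conc >= conc_threshold
  flagged <- flag_z | flag_c | is.na(zc$z)
  tibble::tibble(
    metabolite = zc$id[flagged],
    compartment = comp[flagged],
    ln_c = zc$value[flagged],
    concentration = conc[flagged],
    z = zc$z[flagged],
    rule = dplyr::case_when(flag_z[flagged] ~ "z",
                            flag_c[flagged] ~ "concentration",
                            TRUE ~ "degenerate")
  )
}

#' Initial points for the thermodynamic-space sampler
#'
#' For every reversible constrained reaction, flux maximization and
#' minimization LPs propose two direction patterns; each pattern is completed
#' into a feasible orthant by the optimizer and turned into a strictly
#' interior point of the (reduced) thermodynamic space by maximizing an
#' interiority margin (bisection over a shrunken confidence ball with
#' sign margins proportional to each energy's prior sd).  Points are
#' deduplicated by orthant signature.
#'
#' @param network a `pta_network` with the constrained set selected.
#' @param space the matching `pta_thermo_space`.
#' @param eps second-law margin (kJ/mol).
#' @param v_min minimum flux magnitude.
#' @param max_points cap on returned points.
#' @return list of starting points, each a list with `m_r` (reduced
#'   coordinates), `signature`, `signs`.
#' @export
find_initial_points <- function(network, space, eps = 0.1, v_min = 1e-6,
                                max_points = 16) {
  g <- length(space$gamma_ids)
  gamma <- network$gamma
  fixed <- fixed_directions(network)
  rev_idx <- which(is.na(fixed))
  patterns <- list()
  if (length(rev_idx)) {
    for (k in rev_idx) {
      for (maxi in c(TRUE, FALSE)) {
        obj <- numeric(ncol(network$S))
        obj[gamma[k]] <- 1
        res <- solve_lp(obj, A_eq = network$S,
                        b_eq = numeric(nrow(network$S)),
                        lb = network$lb, ub = network$ub, maximize = maxi)
        if (res$status != "optimal") next
        v <- res$x[gamma]
        pat <- ifelse(abs(v) >= v_min, as.integer(sign(v)), NA_integer_)
        pat[!is.na(fixed)] <- fixed[!is.na(fixed)]
        patterns[[length(patterns) + 1]] <- pat
        # fallback pattern constraining only the optimized reaction, in
        # case the full flux-extreme sign set is thermodynamically
        # infeasible at this confidence
        solo <- rep(NA_integer_, g)
        solo[k] <- pat[k]
        solo[!is.na(fixed)] <- fixed[!is.na(fixed)]
        patterns[[length(patterns) + 1]] <- solo
      }
    }
  }
  patterns[[length(patterns) + 1]] <- fixed    # unconstrained completion
  geom <- dg_rows(space, reduced = TRUE)
  sds <- sqrt(pmax(diag(space$Sigma_r), 0))
  points <- list()
  seen <- character(0)
  for (pat in patterns) {
    dc <- stats::setNames(pat[!is.na(pat)], space$gamma_ids[!is.na(pat)])
    fit <- solve_pmo(network, space, direction_constraints = dc,
                     eps = eps, v_min = v_min)
    if (fit$status != "optimal") next
    sig <- fit$signature
    if (sig %in% seen) next
    point <- interior_point(geom, fit$signs, eps, sds)
    if (is.null(point)) next
    seen <- c(seen, sig)
    points[[length(points) + 1]] <-
      list(m_r = point, signature = sig, signs = fit$signs)
    if (length(points) >= max_points) break
  }
  if (!length(points))
    stop("no thermodynamically feasible orthant found; ",
         "run assess_structure() to look for forced internal cycles",
         call. = FALSE)
  points
}

# maximize delta such that the least-norm point with sign margins
# eps + delta * sd_i fits inside the ball of squared radius
# chi2 * (1 - delta)^2; bisection on delta in [0, 1)
interior_point <- function(geom, signs, eps, sds) {
  feas_at <- function(delta) {
    res <- orthant_qp(geom, signs, eps, margin = eps + delta * sds)
    if (res$status != "optimal") return(NULL)
    if (res$value > geom$radius2 * (1 - delta)^2 + 1e-12) return(NULL)
    res$x
  }
  best <- feas_at(0)
  if (is.null(best)) return(NULL)
  lo <- 0
  hi <- 1
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    x <- feas_at(mid)
    if (!is.null(x)) {
      best <- x
      lo <- mid
    } else hi <- mid
  }
  best
}

#' @export
print.pta_pmo <- function(x, ...) {
  cat("<pta_pmo> status:", x$status)
  if (x$status == "optimal")
    cat(sprintf(", ||m*||^2 = %.4f (chi2 = %.3f), orthant %s",
                x$objective, x$space$chi2, x$signature))
  cat("\n")
  invisible(x)
}

#' Tidy a PMO fit
#' @param x a `pta_pmo` object.
#' @param ... unused.
#' @return the per-variable z-score tibble (empty when infeasible).
#' @export
tidy.pta_pmo <- function(x, ...) {
  if (is.null(x$z)) return(tibble::tibble())
  x$z
}

#' One-row summary of a PMO fit
#' @param x a `pta_pmo` object.
#' @param ... unused.
#' @return tibble with status, objective, chi-square threshold, orthant
#'   signature and the number of |z| > 1 variables.
#' @export
glance.pta_pmo <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    objective = x$objective,
    chi2 = x$space$chi2,
    signature = x$signature %||% NA_character_,
    n_high_z = if (is.null(x$z)) NA_integer_ else
      sum(abs(x$z$z) > 1, na.rm = TRUE)
  )
}
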