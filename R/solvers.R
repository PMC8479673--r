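# Internal optimization backends.
#
# Convex quadratic programs use the dual active-set method in
# `quadprog::solve.QP`, whose "inconsistent constraints" error doubles as an
# exact feasibility oracle for polyhedra.  Linear programs in this package
# are desk-scale (tens of variables) and always bounded, so they are solved
# by bisection on the objective level against that feasibility oracle --
# slower per call than a simplex, but free of the degeneracy pathologies of
# dense textbook simplex implementations.

# Largest bound substituted for +/-Inf when converting to standard form.
BIG_BOUND <- 1e6

#' Solve a small dense linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `A_eq x = b_eq`,
#' `A_le x <= b_le` and box bounds `lb <= x <= ub`.
#'
#' @param obj objective coefficients.
#' @param A_eq,b_eq equality constraints (may be `NULL`).
#' @param A_le,b_le inequality constraints (may be `NULL`).
#' @param lb,ub bounds; infinite entries are clamped to an internal big bound.
#' @param maximize maximize instead of minimize.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `x` and `value`.
#' @keywords internal
#' @noRd
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lb, ub, maximize = FALSE) {
  n <- length(obj)
  lb <- pmax(lb, -BIG_BOUND)
  ub <- pmin(ub, BIG_BOUND)
  if (any(lb > ub)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  # substitute out fixed variables (the simplex backend mishandles
  # zero-width columns) and drop equality rows that become trivial
  fixed <- (ub - lb) < 1e-12
  if (any(fixed)) {
    xf <- lb
    free <- which(!fixed)
    adj <- function(A, b, idx) {
      if (is.null(A)) return(list(A = NULL, b = NULL))
      A <- matrix(A, ncol = n)
      b2 <- b - drop(A[, fixed, drop = FALSE] %*% xf[fixed])
      list(A = A[, free, drop = FALSE], b = b2)
    }
    eq <- adj(A_eq, b_eq)
    le <- adj(A_le, b_le)
    if (!length(free)) {
      ok <- TRUE
      if (!is.null(eq$A)) ok <- ok && all(abs(eq$b) < 1e-9)
      if (!is.null(le$A)) ok <- ok && all(le$b > -1e-9)
      if (!ok) return(list(status = "infeasible", x = NULL,
                           value = NA_real_))
      return(list(status = "optimal", x = xf, value = sum(obj * xf)))
    }
    sub <- solve_lp(obj[free], A_eq = eq$A, b_eq = eq$b,
                    A_le = le$A, b_le = le$b,
                    lb = lb[free], ub = ub[free], maximize = maximize)
    if (sub$status != "optimal") return(sub)
    x <- xf
    x[free] <- sub$x
    return(list(status = "optimal", x = x, value = sum(obj * x)))
  }
  if (!is.null(A_eq)) {
    A_eq <- matrix(A_eq, ncol = n)
    null_row <- rowSums(abs(A_eq)) < 1e-12
    if (any(null_row)) {
      if (any(abs(b_eq[null_row]) > 1e-9))
        return(list(status = "infeasible", x = NULL, value = NA_real_))
      A_eq <- A_eq[!null_row, , drop = FALSE]
      b_eq <- b_eq[!null_row]
      if (!nrow(A_eq)) { A_eq <- NULL; b_eq <- NULL }
    }
  }
  if (!maximize) {
    res <- solve_lp(-obj, A_eq, b_eq, A_le, b_le, lb, ub, maximize = TRUE)
    if (res$status == "optimal") res$value <- -res$value
    return(res)
  }
  feas <- polyhedron_feasible(n, A_eq = A_eq, b_eq = b_eq,
                              A_le = A_le, b_le = b_le, lb = lb, ub = ub)
  if (!feas$feasible)
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  witness <- feas$x
  lo <- sum(obj * witness)
  hi <- sum(pmax(obj * lb, obj * ub))   # coordinatewise upper envelope
  if (hi - lo > 0) {
    A_base <- if (is.null(A_le)) NULL else matrix(A_le, ncol = n)
    for (it in seq_len(120L)) {
      tol <- 1e-11 * max(1, abs(lo), abs(hi))
      if (hi - lo <= tol) break
      mid <- (lo + hi) / 2
      f <- polyhedron_feasible(n, A_eq = A_eq, b_eq = b_eq,
                               A_le = rbind(A_base, -obj),
                               b_le = c(b_le, -mid),
                               lb = lb, ub = ub)
      if (f$feasible) {
        witness <- f$x
        lo <- max(mid, sum(obj * witness))
      } else {
        hi <- mid
      }
    }
  }
  list(status = "optimal", x = witness, value = lo)
}

#' Least-norm convex QP: minimize ||x||^2 (or ||x - x0||^2)
#'
#' subject to `A_eq x = b_eq`, `A_le x <= b_le`.  Returns status
#' "infeasible" when the constraint polyhedron is empty.
#'
#' @keywords internal
#' @noRd
solve_least_norm <- function(n, A_eq = NULL, b_eq = NULL,
                             A_le = NULL, b_le = NULL, x0 = NULL) {
  if (is.null(x0)) x0 <- numeric(n)
  Amat <- NULL
  bvec <- NULL
  meq <- 0L
  if (!is.null(A_eq) && nrow(matrix(A_eq, ncol = n)) > 0) {
    A_eq <- matrix(A_eq, ncol = n)
    Amat <- t(A_eq)
    bvec <- b_eq
    meq <- nrow(A_eq)
  }
  if (!is.null(A_le) && nrow(matrix(A_le, ncol = n)) > 0) {
    A_le <- matrix(A_le, ncol = n)
    Amat <- cbind(Amat, -t(A_le))
    bvec <- c(bvec, -b_le)
  }
  if (is.null(Amat)) {
    return(list(status = "optimal", x = x0, value = 0))
  }
  res <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = x0, Amat = Amat,
                       bvec = bvec, meq = meq),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    if (grepl("inconsistent|no solution", conditionMessage(res))) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    stop("QP solver failure: ", conditionMessage(res), call. = FALSE)
  }
  x <- res$solution
  list(status = "optimal", x = x, value = sum((x - x0)^2))
}

#' Feasibility of a polyhedron {x : A_eq x = b_eq, A_le x <= b_le, lb<=x<=ub}
#'
#' Exact check via the dual active-set QP (empty iff solve.QP errors).
#' Returns a witness point when feasible.
#'
#' @keywords internal
#' @noRd
polyhedron_feasible <- function(n, A_eq = NULL, b_eq = NULL,
                                A_le = NULL, b_le = NULL,
                                lb = NULL, ub = NULL) {
  A <- A_le
  b <- b_le
  if (!is.null(lb)) {
    fin <- is.finite(lb)
    if (any(fin)) {
      A <- rbind(A, -diag(n)[fin, , drop = FALSE])
      b <- c(b, -lb[fin])
    }
  }
  if (!is.null(ub)) {
    fin <- is.finite(ub)
    if (any(fin)) {
      A <- rbind(A, diag(n)[fin, , drop = FALSE])
      b <- c(b, ub[fin])
    }
  }
  res <- solve_least_norm(n, A_eq = A_eq, b_eq = b_eq, A_le = A, b_le = b)
  list(feasible = res$status == "optimal", x = res$x)
}
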