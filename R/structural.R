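# Structural thermodynamic assessment: internal elementary flux modes and
# forced internal cycles.
#
# An internal EFM is a support-minimal steady-state mode of the subnetwork
# obtained by blocking exchange, biomass and maintenance reactions.  A forced
# internal cycle is an internal EFM that is active -- with its signs -- in
# every nonzero flux distribution of the original model; since a loop's
# reaction energies sum to zero, such a cycle can never satisfy the second
# law and marks inconsistent irreversibility annotations.

#' Enumerate internal elementary flux modes
#'
#' Exact double-description enumeration on the flux cone of the internal
#' subnetwork (exchange, biomass and maintenance reactions blocked),
#' respecting irreversibility annotations.  Reversible reactions are split
#' into forward/backward parts; the extreme rays of the resulting pointed
#' cone are the EFMs.  Intended for reduced or toy networks; enumeration
#' aborts if the working ray set exceeds `cap`.
#'
#' @param network a `pta_network`.
#' @param cap hard limit on intermediate rays (loud failure, no truncation).
#' @param tol zero tolerance on stoichiometric residuals.
#' @param maintenance_pattern extra regular expression marking
#'   ATP-maintenance reactions by id.
#' @return tibble with one row per EFM: `efm` id, `reaction`, `coefficient`
#'   (normalized flux ratio), `sign`.
#' @export
enumerate_internal_efms <- function(network, cap = 1e6, tol = 1e-10,
                                    maintenance_pattern = "^ATPM") {
  validate_network(network)
  internal <- network$role == "internal" &
    !grepl(maintenance_pattern, network$reaction_ids)
  if (!any(internal))
    stop("internal subnetwork is empty", call. = FALSE)
  idx <- which(internal)
  S <- network$S[, idx, drop = FALSE]
  fwd_ok <- network$ub[idx] > 0
  bwd_ok <- network$lb[idx] < 0
  # split columns; remember the original reaction and direction of each part
  cols <- list()
  col_rxn <- integer(0)
  col_dir <- integer(0)
  for (k in seq_along(idx)) {
    if (fwd_ok[k]) {
      cols[[length(cols) + 1]] <- S[, k]
      col_rxn <- c(col_rxn, idx[k]); col_dir <- c(col_dir, 1L)
    }
    if (bwd_ok[k]) {
      cols[[length(cols) + 1]] <- -S[, k]
      col_rxn <- c(col_rxn, idx[k]); col_dir <- c(col_dir, -1L)
    }
  }
  A <- do.call(cbind, cols)
  n_split <- ncol(A)
  # double description: start from the nonnegative orthant's extreme rays and
  # intersect with each mass-balance hyperplane in turn
  rays <- diag(n_split)
  for (row in seq_len(nrow(A))) {
    a <- A[row, ]
    val <- drop(rays %*% a)
    pos <- which(val > tol)
    neg <- which(val < -tol)
    zer <- which(abs(val) <= tol)
    new_rays <- rays[zer, , drop = FALSE]
    if (length(pos) && length(neg)) {
      zero_sets <- lapply(seq_len(nrow(rays)),
                          function(i) which(abs(rays[i, ]) <= tol))
      for (p in pos) for (q in neg) {
        # support-based adjacency: no third ray's zero set contains both
        zs <- intersect(zero_sets[[p]], zero_sets[[q]])
        adjacent <- TRUE
        for (o in seq_len(nrow(rays))) {
          if (o == p || o == q) next
          if (all(zs %in% zero_sets[[o]])) { adjacent <- FALSE; break }
        }
        if (!adjacent) next
        r_new <- val[p] * rays[q, ] - val[q] * rays[p, ]
        r_new <- r_new / max(abs(r_new))
        new_rays <- rbind(new_rays, r_new)
      }
    }
    rays <- new_rays
    if (nrow(rays) > cap)
      stop("EFM enumeration exceeded the ray cap (", cap, ")", call. = FALSE)
    if (!nrow(rays)) break
  }
  # fold split parts back to signed fluxes; drop futile forward/backward pairs
  modes <- list()
  seen <- character(0)
  if (nrow(rays)) for (i in seq_len(nrow(rays))) {
    x <- rays[i, ]
    v <- numeric(ncol(network$S))
    for (k in seq_len(n_split))
      v[col_rxn[k]] <- v[col_rxn[k]] + col_dir[k] * x[k]
    supp <- which(abs(v) > tol)
    if (!length(supp)) next                       # pure futile pair
    v <- v / min(abs(v[supp]))
    # canonical orientation: leading coefficient positive when the reversed
    # mode also respects the irreversibility annotations
    if (v[supp[1]] < 0) {
      w <- -v
      ok <- all((w[supp] > 0 & network$ub[supp] > 0) |
                  (w[supp] < 0 & network$lb[supp] < 0))
      if (ok) v <- w
    }
    if (max(abs(v - round(v))) < 1e-6) v <- round(v)
    key <- paste(supp, signif(v[supp], 9), collapse = ";")
    key_neg <- paste(supp, signif(-v[supp], 9), collapse = ";")
    if (key %in% seen) next
    if (key_neg %in% seen) next                   # sign-symmetric duplicate
    seen <- c(seen, key)
    modes[[length(modes) + 1]] <- v
  }
  # support minimality guard (the DD construction already ensures it)
  if (length(modes) > 1) {
    supports <- lapply(modes, function(v) which(abs(v) > tol))
    keep <- vapply(seq_along(modes), function(i) {
      !any(vapply(seq_along(modes), function(j) {
        j != i && length(supports[[j]]) < length(supports[[i]]) &&
          all(supports[[j]] %in% supports[[i]])
      }, logical(1)))
    }, logical(1))
    modes <- modes[keep]
  }
  if (!length(modes)) {
    return(tibble::tibble(efm = integer(0), reaction = character(0),
                          coefficient = numeric(0), sign = integer(0)))
  }
  purrr::map_dfr(seq_along(modes), function(i) {
    v <- modes[[i]]
    supp <- which(abs(v) > tol)
    tibble::tibble(efm = i,
                   reaction = network$reaction_ids[supp],
                   coefficient = v[supp],
                   sign = as.integer(sign(v[supp])))
  })
}

#' Find forced internal cycles
#'
#' An internal EFM is reported as a forced cycle when (i) its sign pattern is
#' realizable in the original model, (ii) flipping any single sign of the
#' pattern yields an infeasible flux program, and (iii) no nonzero flux
#' distribution exists with the whole support silenced.  Each reported cycle
#' carries per-reaction infeasibility certificates for the sign flips.
#'
#' @param network a `pta_network` (original bounds, not blocked).
#' @param efms tibble from [enumerate_internal_efms()]; enumerated on demand
#'   when `NULL`.
#' @param v_min flux magnitude that counts as "active".
#' @return tibble with one row per forced cycle and reaction: `cycle`,
#'   `reaction`, `sign`, plus a `suggestion` column naming the reversibility
#'   relaxation that would break the cycle.
#' @export
find_forced_cycles <- function(network, efms = NULL, v_min = 1e-6) {
  validate_network(network)
  if (is.null(efms)) efms <- enumerate_internal_efms(network)
  if (!nrow(efms)) {
    return(tibble::tibble(cycle = integer(0), reaction = character(0),
                          sign = integer(0), suggestion = character(0)))
  }
  S <- network$S
  n <- ncol(S)
  m <- nrow(S)
  sign_feasible <- function(ridx, signs) {
    lb <- network$lb
    ub <- network$ub
    for (k in seq_along(ridx)) {
      j <- ridx[k]
      if (signs[k] > 0) lb[j] <- max(lb[j], v_min)
      else ub[j] <- min(ub[j], -v_min)
    }
    if (any(lb > ub)) return(FALSE)
    polyhedron_feasible(n, A_eq = S, b_eq = numeric(m),
                        lb = lb, ub = ub)$feasible
  }
  out <- list()
  cyc <- 0L
  for (id in unique(efms$efm)) {
    sub <- efms[efms$efm == id, ]
    ridx <- match(sub$reaction, network$reaction_ids)
    signs <- sub$sign
    if (!sign_feasible(ridx, signs)) next          # pattern never realizable
    flips_blocked <- vapply(seq_along(ridx), function(k) {
      flipped <- signs
      flipped[k] <- -flipped[k]
      !sign_feasible(ridx, flipped)
    }, logical(1))
    if (!all(flips_blocked)) next
    # can the model carry flux with the cycle silenced?
    lb0 <- network$lb; ub0 <- network$ub
    lb0[ridx] <- 0; ub0[ridx] <- 0
    others <- setdiff(seq_len(n), ridx)
    silenced_active <- FALSE
    for (k in others) {
      obj <- numeric(n); obj[k] <- 1
      hi <- solve_lp(obj, A_eq = S, b_eq = numeric(m), lb = lb0, ub = ub0,
                     maximize = TRUE)
      if (hi$status == "optimal" && hi$value >= v_min) {
        silenced_active <- TRUE; break
      }
      lo <- solve_lp(obj, A_eq = S, b_eq = numeric(m), lb = lb0, ub = ub0,
                     maximize = FALSE)
      if (lo$status == "optimal" && lo$value <= -v_min) {
        silenced_active <- TRUE; break
      }
    }
    if (silenced_active) next
    cyc <- cyc + 1L
    irrev <- (signs > 0 & network$lb[ridx] >= 0) |
      (signs < 0 & network$ub[ridx] <= 0)
    out[[cyc]] <- tibble::tibble(
      cycle = cyc,
      reaction = sub$reaction,
      sign = signs,
      suggestion = ifelse(irrev,
                          paste0("make ", sub$reaction, " reversible"),
                          "already reversible"))
  }
  if (!length(out)) {
    return(tibble::tibble(cycle = integer(0), reaction = character(0),
                          sign = integer(0), suggestion = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Structural assessment report
#'
#' Convenience wrapper: enumerates internal EFMs, finds forced cycles and
#' returns both plus a verdict.
#'
#' @param network a `pta_network`.
#' @param v_min activity threshold for the feasibility programs.
#' @return list with `efms`, `forced_cycles`, `consistent` (no forced cycle).
#' @export
assess_structure <- function(network, v_min = 1e-6) {
  efms <- enumerate_internal_efms(network)
  forced <- find_forced_cycles(network, efms, v_min = v_min)
  list(efms = efms, forced_cycles = forced,
       consistent = nrow(forced) == 0)
}
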