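# Constraint-based model container and I/O (COBRA JSON and SBML L3 + fbc).

#' Construct a constraint-based metabolic network
#'
#' Bundles the stoichiometric matrix, flux bounds and reaction role flags into
#' a validated `pta_network` object.  Roles distinguish the unbalanced
#' pseudo-reactions (exchange, biomass, maintenance) from the internal,
#' mass-balanced reactions eligible for thermodynamic constraints.
#'
#' @param S stoichiometric matrix, metabolites x reactions. Row and column
#'   names (if present) are used as identifiers.
#' @param lb,ub flux bounds per reaction (mmol/gDW/h).
#' @param reaction_ids,metabolite_ids identifiers; default taken from
#'   `dimnames(S)`.
#' @param compartment compartment label per metabolite (default `"c"`).
#' @param role per-reaction role: one of `"exchange"`, `"biomass"`,
#'   `"maintenance"`, `"internal"`. Guessed from identifiers when missing
#'   (`EX_`/single-sided stoichiometry => exchange, `biomass` => biomass,
#'   `ATPM` => maintenance).
#' @return an object of class `pta_network`.
#' @examples
#' S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "r1"))
#' net <- metabolic_network(S, lb = 0, ub = 10)
#' @export
metabolic_network <- function(S, lb, ub,
                              reaction_ids = colnames(S),
                              metabolite_ids = rownames(S),
                              compartment = NULL,
                              role = NULL) {
  S <- as.matrix(S)
  m <- nrow(S)
  n <- ncol(S)
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(n))
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(m))
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (is.null(compartment)) compartment <- rep("c", m)
  if (is.null(role)) role <- guess_roles(S, reaction_ids)
  role <- match.arg(role, c("internal", "exchange", "biomass", "maintenance"),
                    several.ok = TRUE)
  role <- rep_len(role, n)
  net <- structure(
    list(S = `dimnames<-`(S, list(metabolite_ids, reaction_ids)),
         lb = lb, ub = ub,
         reaction_ids = reaction_ids,
         metabolite_ids = metabolite_ids,
         compartment = rep_len(compartment, m),
         role = role,
         gamma = integer(0)),
    class = "pta_network"
  )
  validate_network(net)
  net
}

guess_roles <- function(S, ids) {
  one_sided <- apply(S, 2, function(col) {
    nz <- col[col != 0]
    length(nz) == 0 || all(nz > 0) || all(nz < 0)
  })
  role <- rep("internal", ncol(S))
  role[one_sided | grepl("^(EX|DM|SK)_", ids)] <- "exchange"
  role[grepl("biomass", ids, ignore.case = TRUE)] <- "biomass"
  role[grepl("^ATPM", ids)] <- "maintenance"
  role
}

#' Validate a metabolic network
#'
#' Checks dimensional consistency, `lb <= ub`, role values, and that every
#' reaction in the thermodynamically constrained set is internal and carries
#' both substrates and products (mass-balanced in S).
#'
#' @param network a `pta_network`.
#' @return the network, invisibly; errors describe the first violation found.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "pta_network"))
  S <- network$S
  n <- ncol(S)
  m <- nrow(S)
  if (length(network$lb) != n || length(network$ub) != n)
    stop("bound vectors must have one entry per reaction", call. = FALSE)
  if (any(network$lb > network$ub))
    stop("lb > ub for reaction(s): ",
         paste(network$reaction_ids[network$lb > network$ub], collapse = ", "),
         call. = FALSE)
  if (length(network$role) != n)
    stop("role flags must have one entry per reaction", call. = FALSE)
  if (length(network$compartment) != m)
    stop("compartment must have one entry per metabolite", call. = FALSE)
  if (length(network$gamma)) {
    if (any(network$role[network$gamma] != "internal"))
      stop("thermodynamically constrained reactions must be internal",
           call. = FALSE)
    bal <- vapply(network$gamma, function(j) {
      col <- S[, j]
      any(col < 0) && any(col > 0)
    }, logical(1))
    if (!all(bal))
      stop("unbalanced reaction(s) in the constrained set: ",
           paste(network$reaction_ids[network$gamma[!bal]], collapse = ", "),
           call. = FALSE)
  }
  invisible(network)
}

#' @export
print.pta_network <- function(x, ...) {
  cat(sprintf("<pta_network> %d metabolites x %d reactions\n",
              nrow(x$S), ncol(x$S)))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
                    collapse = ", ")))
  if (length(x$gamma))
    cat(sprintf("  thermodynamically constrained (gamma): %d\n",
                length(x$gamma)))
  invisible(x)
}

#' Summarize reactions of a network as a tibble
#'
#' @param x a `pta_network`.
#' @param ... unused.
#' @return a tibble with one row per reaction: id, role, bounds, whether the
#'   reaction is in the thermodynamically constrained set.
#' @export
tidy.pta_network <- function(x, ...) {
  tibble::tibble(
    reaction = x$reaction_ids,
    role = x$role,
    lb = x$lb,
    ub = x$ub,
    thermo_constrained = seq_along(x$reaction_ids) %in% x$gamma
  )
}

#' Read a constraint-based model
#'
#' Supports the COBRA-style JSON dialect and SBML Level 3 with the `fbc`
#' flux-bounds package.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"cobra-json"` or `"sbml"`.
#' @return a validated [metabolic_network()].
#' @export
load_network <- function(path, format = c("auto", "cobra-json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "cobra-json"
  }
  switch(format,
         "cobra-json" = read_cobra_json(path),
         "sbml" = read_sbml(path))
}

read_cobra_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("not a COBRA-style JSON model: ", path, call. = FALSE)
  met_ids <- vapply(doc$metabolites, `[[`, "", "id")
  comp <- vapply(doc$metabolites, function(m)
    if (is.null(m$compartment)) "c" else as.character(m$compartment), "")
  n <- length(doc$reactions)
  S <- matrix(0, length(met_ids), n,
              dimnames = list(met_ids, vapply(doc$reactions, `[[`, "", "id")))
  lb <- ub <- numeric(n)
  role <- character(n)
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    coef <- unlist(r$metabolites)
    if (length(coef)) {
      miss <- setdiff(names(coef), met_ids)
      if (length(miss))
        stop("reaction ", r$id, " references unknown metabolite(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      S[names(coef), j] <- as.numeric(coef)
    }
    lb[j] <- if (is.null(r$lower_bound)) -BIG_BOUND else r$lower_bound
    ub[j] <- if (is.null(r$upper_bound)) BIG_BOUND else r$upper_bound
    role[j] <- if (is.null(r$role)) NA_character_ else r$role
  }
  if (anyNA(role)) role <- ifelse(is.na(role), guess_roles(S, colnames(S)), role)
  metabolic_network(S, lb, ub, compartment = comp, role = role)
}

#' Write a model to COBRA-style JSON or SBML
#'
#' @param network a `pta_network`.
#' @param path output path.
#' @param format `"cobra-json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("cobra-json", "sbml")) {
  format <- match.arg(format)
  validate_network(network)
  if (format == "cobra-json") write_cobra_json(network, path)
  else write_sbml(network, path)
  invisible(path)
}

write_cobra_json <- function(network, path) {
  mets <- purrr::map2(network$metabolite_ids, network$compartment,
                      function(id, comp) list(id = id, compartment = comp))
  rxns <- purrr::map(seq_along(network$reaction_ids), function(j) {
    col <- network$S[, j]
    nz <- which(col != 0)
    list(
      id = network$reaction_ids[j],
      metabolites = as.list(stats::setNames(unname(col[nz]),
                                            network$metabolite_ids[nz])),
      lower_bound = network$lb[j],
      upper_bound = network$ub[j],
      role = network$role[j]
    )
  })
  jsonlite::write_json(list(id = "model", metabolites = mets, reactions = rxns),
                       path, auto_unbox = TRUE, digits = NA)
}

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_sbml <- function(network, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    level = "3", version = "1", "fbc:required" = "false"
  )
  model <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "true")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (cid in unique(network$compartment))
    xml2::xml_add_child(comps, "compartment", id = sbml_id(cid),
                        constant = "true")
  species <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_along(network$metabolite_ids))
    xml2::xml_add_child(species, "species",
                        id = sbml_id(network$metabolite_ids[i]),
                        name = network$metabolite_ids[i],
                        compartment = sbml_id(network$compartment[i]),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  params <- xml2::xml_add_child(model, "listOfParameters")
  bound_par <- function(v, j, side) {
    pid <- sprintf("%s_%s", side, sbml_id(network$reaction_ids[j]))
    xml2::xml_add_child(params, "parameter", id = pid,
                        value = format(v, digits = 17), constant = "true")
    pid
  }
  rxns <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_along(network$reaction_ids)) {
    lbid <- bound_par(network$lb[j], j, "lb")
    ubid <- bound_par(network$ub[j], j, "ub")
    rx <- xml2::xml_add_child(rxns, "reaction",
                              id = sbml_id(network$reaction_ids[j]),
                              name = network$reaction_ids[j],
                              reversible = ifelse(network$lb[j] < 0, "true", "false"),
                              fast = "false",
                              "fbc:lowerFluxBound" = lbid,
                              "fbc:upperFluxBound" = ubid)
    xml2::xml_set_attr(rx, "sboTerm", role_to_sbo(network$role[j]))
    col <- network$S[, j]
    if (any(col < 0)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in which(col < 0))
        xml2::xml_add_child(lr, "speciesReference",
                            species = sbml_id(network$metabolite_ids[i]),
                            stoichiometry = format(-col[i], digits = 17),
                            constant = "true")
    }
    if (any(col > 0)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in which(col > 0))
        xml2::xml_add_child(lp, "speciesReference",
                            species = sbml_id(network$metabolite_ids[i]),
                            stoichiometry = format(col[i], digits = 17),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, path)
}

# SBO terms used to round-trip role flags through SBML.
role_to_sbo <- function(role) {
  switch(role,
         exchange = "SBO:0000627",
         biomass = "SBO:0000629",
         maintenance = "SBO:0000630",
         "SBO:0000176")
}
sbo_to_role <- function(sbo) {
  switch(sbo %||% "",
         "SBO:0000627" = "exchange",
         "SBO:0000629" = "biomass",
         "SBO:0000630" = "maintenance",
         NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met_ids <- xml2::xml_attr(sp, "name")
  met_ids[is.na(met_ids)] <- xml2::xml_attr(sp, "id")[is.na(met_ids)]
  sid <- xml2::xml_attr(sp, "id")
  comp <- xml2::xml_attr(sp, "compartment")
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  n <- length(rx)
  if (n == 0) stop("no reactions found in SBML file: ", path, call. = FALSE)
  ids <- xml2::xml_attr(rx, "name")
  ids[is.na(ids)] <- xml2::xml_attr(rx, "id")[is.na(ids)]
  S <- matrix(0, length(met_ids), n, dimnames = list(met_ids, ids))
  lb <- ub <- numeric(n)
  role <- character(n)
  for (j in seq_len(n)) {
    node <- rx[[j]]
    for (ref in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      i <- match(xml2::xml_attr(ref, "species"), sid)
      S[i, j] <- S[i, j] - as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      i <- match(xml2::xml_attr(ref, "species"), sid)
      S[i, j] <- S[i, j] + as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    lbid <- xml2::xml_attr(node, "lowerFluxBound")
    ubid <- xml2::xml_attr(node, "upperFluxBound")
    lb[j] <- if (!is.na(lbid) && lbid %in% names(parval)) parval[[lbid]] else -BIG_BOUND
    ub[j] <- if (!is.na(ubid) && ubid %in% names(parval)) parval[[ubid]] else BIG_BOUND
    role[j] <- sbo_to_role(xml2::xml_attr(node, "sboTerm"))
  }
  if (anyNA(role)) role <- ifelse(is.na(role), guess_roles(S, ids), role)
  metabolic_network(S, lb, ub, compartment = comp, role = role)
}

#' Select the thermodynamically constrained reaction set
#'
#' Returns the (updated) network with the ordered index set of reactions that
#' receive Gibbs-energy constraints: all internal reactions except the given
#' exclusions.  Structurally blocked reactions are removed from the set with a
#' warning, since the second law combined with the nonzero-flux requirement
#' cannot hold for a reaction that never carries flux.
#'
#' @param network a `pta_network`.
#' @param exclude_roles roles excluded from the set.
#' @param exclude_ids reaction ids (or regular expressions when
#'   `ids_are_patterns`) excluded from the set, e.g. water transport.
#' @param ids_are_patterns treat `exclude_ids` as regular expressions.
#' @param drop_blocked remove structurally blocked reactions (default TRUE).
#' @return the network with `$gamma` set (ordered indices).
#' @export
select_thermo_reactions <- function(network,
                                    exclude_roles = c("exchange", "biomass",
                                                      "maintenance"),
                                    exclude_ids = character(),
                                    ids_are_patterns = FALSE,
                                    drop_blocked = TRUE) {
  validate_network(network)
  keep <- !(network$role %in% exclude_roles)
  if (length(exclude_ids)) {
    if (ids_are_patterns) {
      for (p in exclude_ids) keep <- keep & !grepl(p, network$reaction_ids)
    } else {
      keep <- keep & !(network$reaction_ids %in% exclude_ids)
    }
  }
  gamma <- which(keep)
  if (!length(gamma))
    stop("no reactions left for thermodynamic constraints", call. = FALSE)
  if (drop_blocked) {
    blocked <- detect_blocked_reactions(network)
    drop <- intersect(gamma, blocked)
    if (length(drop)) {
      warning("removing structurally blocked reaction(s) from the ",
              "constrained set: ",
              paste(network$reaction_ids[drop], collapse = ", "),
              call. = FALSE)
      gamma <- setdiff(gamma, drop)
    }
    if (!length(gamma))
      stop("all candidate reactions are structurally blocked", call. = FALSE)
  }
  network$gamma <- gamma
  validate_network(network)
  network
}

#' Detect structurally blocked reactions
#'
#' A reaction is blocked when it carries zero flux in every steady-state
#' solution.  Detected by maximizing and minimizing each flux with a linear
#' program; blocked iff the optimal |v| stays below `tol` in both directions.
#'
#' @param network a `pta_network`.
#' @param tol flux magnitude below which a reaction counts as blocked.
#' @return integer vector of blocked reaction indices.
#' @export
detect_blocked_reactions <- function(network, tol = 1e-9) {
  validate_network(network)
  n <- ncol(network$S)
  blocked <- logical(n)
  for (j in seq_len(n)) {
    obj <- numeric(n)
    obj[j] <- 1
    hi <- solve_lp(obj, A_eq = network$S, b_eq = numeric(nrow(network$S)),
                   lb = network$lb, ub = network$ub, maximize = TRUE)
    if (hi$status == "optimal" && abs(hi$value) >= tol) next
    lo <- solve_lp(obj, A_eq = network$S, b_eq = numeric(nrow(network$S)),
                   lb = network$lb, ub = network$ub, maximize = FALSE)
    blocked[j] <- !(lo$status == "optimal" && abs(lo$value) >= tol)
  }
  which(blocked)
}
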