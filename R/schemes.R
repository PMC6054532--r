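# Declarative kinetic schemes: species, reversible mass-action reactions and
# named rate constants. Concentrations are microM throughout, time in seconds;
# unit conversion happens only at I/O boundaries.

#' Recognised rate-constant names
#'
#' First-order constants (\code{k1}, \code{k_m1}, \code{k_m2}, \code{k3},
#' \code{k_m3}, \code{k_m4}) carry units of 1/s; the bimolecular association
#' constants \code{k2} and \code{k4} carry 1/(microM s). \code{k_m*} denotes
#' the reverse ("minus") constant of step *.
#' @keywords internal
.rate_names <- c("k1", "k_m1", "k2", "k_m2", "k3", "k_m3", "k4", "k_m4")

#' Create a species
#'
#' @param name Unique species label within a scheme.
#' @param role One of \code{"free_enzyme_state"}, \code{"free_ligand"},
#'   \code{"complex"}.
#' @param state_tag Optional conformational label (e.g. \code{"DFG_in"},
#'   \code{"DFG_out"}, \code{"DFG_out_star"} for the induced-fit state).
#' @return A list of class \code{kin_species}.
#' @export
kin_species <- function(name, role, state_tag = NA_character_) {
  role <- match.arg(role, c("free_enzyme_state", "free_ligand", "complex"))
  structure(list(name = name, role = role, state_tag = state_tag),
            class = "kin_species")
}

#' Create a reversible reaction
#'
#' A reaction has one or two reactants and one or two products; bimolecular
#' association steps must have exactly one free-ligand reactant. Forward and
#' reverse rate constants are referenced by name and resolved against the
#' scheme's constant table, so two reactions may share a constant (used for
#' schemes with a common induced-fit step).
#'
#' @param reactants,products Character vectors of species names (length 1-2).
#' @param forward_name,reverse_name Rate-constant labels.
#' @param forward_order 1 (unimolecular) or 2 (bimolecular association).
#' @return A list of class \code{kin_reaction}.
#' @export
kin_reaction <- function(reactants, products, forward_name, reverse_name,
                         forward_order = length(reactants)) {
  stopifnot(length(reactants) %in% 1:2, length(products) %in% 1:2,
            forward_order %in% 1:2, forward_order == length(reactants))
  structure(list(reactants = reactants, products = products,
                 forward_name = forward_name, reverse_name = reverse_name,
                 forward_order = forward_order),
            class = "kin_reaction")
}

#' Create a rate-constant table
#'
#' @param ... Named numeric values among
#'   \code{k1, k_m1, k2, k_m2, k3, k_m3, k4, k_m4}. All must be >= 0.
#' @param errors Optional named numeric vector of standard errors for a
#'   subset of the constants.
#' @return A list of class \code{rate_constants} with elements \code{values}
#'   and \code{errors} (named numeric vectors).
#' @export
rate_constants <- function(..., errors = NULL) {
  values <- unlist(list(...))
  if (length(values) && is.null(names(values)))
    stop("rate constants must be named")
  bad <- setdiff(names(values), .rate_names)
  if (length(bad))
    stop("unknown rate-constant name(s): ", paste(bad, collapse = ", "),
         "; valid names are ", paste(.rate_names, collapse = ", "))
  if (any(values < 0, na.rm = TRUE)) stop("rate constants must be >= 0")
  if (!is.null(errors)) {
    bad <- setdiff(names(errors), .rate_names)
    if (length(bad)) stop("unknown error name(s): ", paste(bad, collapse = ", "))
    if (any(errors < 0, na.rm = TRUE)) stop("standard errors must be >= 0")
  }
  structure(list(values = values, errors = errors), class = "rate_constants")
}

#' Assemble and validate a kinetic scheme
#'
#' Checks the structural invariants: unique species names, exactly one free
#' ligand, every reaction references declared species, per-reaction enzyme and
#' ligand balance (so total enzyme and total ligand are conserved exactly by
#' the mass-action equations), only constants named by some reaction may be
#' set, and acyclicity of the reaction graph once the ligand node is removed
#' (these mechanisms contain no thermodynamic cycle, so no detailed-balance
#' constraint is imposed).
#'
#' @param name Scheme label.
#' @param species List of \code{\link{kin_species}}.
#' @param reactions List of \code{\link{kin_reaction}}.
#' @param constants A \code{\link{rate_constants}} table (may be empty; all
#'   constants must be set before simulation).
#' @return A list of class \code{kinetic_scheme}.
#' @export
kinetic_scheme <- function(name, species, reactions,
                           constants = rate_constants()) {
  sp_names <- vapply(species, `[[`, character(1), "name")
  roles    <- vapply(species, `[[`, character(1), "role")
  if (anyDuplicated(sp_names)) stop("species names must be unique")
  if (sum(roles == "free_ligand") != 1L)
    stop("a scheme must contain exactly one free_ligand species")
  ligand <- sp_names[roles == "free_ligand"]
  for (rx in reactions) {
    refs <- c(rx$reactants, rx$products)
    unknown <- setdiff(refs, sp_names)
    if (length(unknown))
      stop("reaction references undeclared species: ",
           paste(unknown, collapse = ", "))
    if (rx$forward_order == 2 && sum(rx$reactants == ligand) != 1L)
      stop("bimolecular reactions must have exactly one free_ligand reactant")
    # mass balance: enzyme and ligand content equal on both sides
    content <- function(sp) {
      role <- roles[match(sp, sp_names)]
      c(enzyme = sum(role != "free_ligand"),
        ligand = sum(role != "free_enzyme_state"))
    }
    if (!identical(content(rx$reactants), content(rx$products)))
      stop("reaction does not balance enzyme/ligand content: ",
           paste(rx$reactants, collapse = "+"), " <-> ",
           paste(rx$products, collapse = "+"))
  }
  named <- unique(unlist(lapply(reactions, function(r)
    c(r$forward_name, r$reverse_name))))
  extra <- setdiff(names(constants$values), named)
  if (length(extra))
    stop("constants not named by any reaction: ", paste(extra, collapse = ", "))
  scheme <- structure(list(name = name, species = species,
                           reactions = reactions, constants = constants),
                      class = "kinetic_scheme")
  if (.has_cycle(scheme))
    stop("reaction graph (excluding the ligand) must be acyclic")
  scheme
}

# acyclicity of the undirected species graph with the ligand node removed
.has_cycle <- function(scheme) {
  sp <- scheme_species_names(scheme)
  ligand <- scheme_ligand(scheme)
  nodes <- setdiff(sp, ligand)
  edges <- lapply(scheme$reactions, function(rx) {
    ends <- setdiff(c(rx$reactants, rx$products), ligand)
    if (length(ends) == 2) ends else NULL
  })
  edges <- Filter(Negate(is.null), edges)
  # union-find
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (e in edges) {
    a <- find(e[1]); b <- find(e[2])
    if (a == b) return(TRUE)
    parent[[a]] <- b
  }
  FALSE
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme>", x$name, "\n")
  cat(" species: ", paste(scheme_species_names(x), collapse = ", "), "\n")
  for (rx in x$reactions)
    cat(sprintf("  %s <-> %s   [%s / %s]\n",
                paste(rx$reactants, collapse = " + "),
                paste(rx$products, collapse = " + "),
                rx$forward_name, rx$reverse_name))
  v <- x$constants$values
  if (length(v))
    cat(" constants:", paste(sprintf("%s=%g", names(v), v), collapse = ", "),
        "\n")
  invisible(x)
}

scheme_species_names <- function(scheme)
  vapply(scheme$species, `[[`, character(1), "name")

scheme_roles <- function(scheme)
  stats::setNames(vapply(scheme$species, `[[`, character(1), "role"),
                  scheme_species_names(scheme))

scheme_ligand <- function(scheme) {
  roles <- scheme_roles(scheme)
  names(roles)[roles == "free_ligand"]
}

#' Species names carrying enzyme / ligand
#' @keywords internal
scheme_enzyme_species <- function(scheme) {
  roles <- scheme_roles(scheme)
  names(roles)[roles != "free_ligand"]
}

scheme_bound_species <- function(scheme) {
  roles <- scheme_roles(scheme)
  names(roles)[roles == "complex"]
}

#' Rate-constant names a scheme requires
#' @param scheme A \code{kinetic_scheme}.
#' @return Character vector of constant names referenced by the reactions.
#' @export
scheme_constant_names <- function(scheme)
  unique(unlist(lapply(scheme$reactions, function(r)
    c(r$forward_name, r$reverse_name))))

#' Replace or update a scheme's constants
#'
#' @param scheme A \code{kinetic_scheme}.
#' @param constants A \code{rate_constants} table; values merge over any
#'   already present.
#' @return The updated scheme.
#' @export
set_constants <- function(scheme, constants) {
  v <- scheme$constants$values
  v[names(constants$values)] <- constants$values
  e <- scheme$constants$errors
  if (!is.null(constants$errors)) {
    if (is.null(e)) e <- numeric(0)
    e[names(constants$errors)] <- constants$errors
  }
  kinetic_scheme(scheme$name, scheme$species, scheme$reactions,
                 rate_constants_from_vectors(v, e))
}

#' Build a rate-constant table from named vectors
#'
#' Programmatic counterpart of \code{\link{rate_constants}} for when the
#' values already live in a named numeric vector.
#'
#' @param values Named numeric vector of rate constants.
#' @param errors Optional named numeric vector of standard errors.
#' @return A \code{rate_constants} table.
#' @export
rate_constants_from_vectors <- function(values, errors = NULL) {
  k <- do.call(rate_constants, as.list(values))
  k$errors <- errors
  k
}

.require_constants <- function(scheme) {
  need <- scheme_constant_names(scheme)
  have <- names(scheme$constants$values)
  missing <- setdiff(need, have[!is.na(scheme$constants$values)])
  if (length(missing))
    stop("rate constant(s) not set: ", paste(missing, collapse = ", "))
  scheme$constants$values[need]
}

#' Canonical binding mechanisms
#'
#' Returns one of the four mechanisms used for ATP-competitive kinase
#' inhibitors, in the orientation in which the conformational equilibrium
#' constant is K1 = k_m1/k1 (reverse over forward):
#' \describe{
#'   \item{\code{cs_binding}}{Conformational selection then binding:
#'     E_in <-> E_out (k1/k_m1); E_out + I <-> E_out.I (k2/k_m2).
#'     Two steps, four species (Gleevec).}
#'   \item{\code{binding_if}}{Binding then induced fit:
#'     E + I <-> E.I (k2/k_m2); E.I <-> E_star.I (k3/k_m3) (nucleotide).}
#'   \item{\code{cs_binding_if}}{Conformational selection, binding, induced
#'     fit: three steps, five species (Danusertib).}
#'   \item{\code{branched}}{Binding to both conformational states, with an
#'     induced-fit step only from the in-state complex:
#'     E_out <-> E_in (k1/k_m1); E_in + I <-> E_in.I (k2/k_m2);
#'     E_in.I <-> E_in_star.I (k3/k_m3); E_out + I <-> E_out.I (k4/k_m4).
#'     There is no edge between the two ligand-bound branches (AT9283).}
#' }
#'
#' @param mechanism_id One of \code{"cs_binding"}, \code{"binding_if"},
#'   \code{"cs_binding_if"}, \code{"branched"}.
#' @param constants Optional \code{\link{rate_constants}} to attach.
#' @return A \code{kinetic_scheme}.
#' @export
canonical_scheme <- function(mechanism_id, constants = rate_constants()) {
  ids <- c("cs_binding", "binding_if", "cs_binding_if", "branched")
  if (!is.character(mechanism_id) || length(mechanism_id) != 1 ||
      !mechanism_id %in% ids)
    stop("unknown mechanism_id; valid ids: ", paste(ids, collapse = ", "))
  E_in  <- kin_species("E_in",  "free_enzyme_state", "DFG_in")
  E_out <- kin_species("E_out", "free_enzyme_state", "DFG_out")
  I     <- kin_species("I",     "free_ligand")
  sw <- switch(mechanism_id,
    cs_binding = list(
      species = list(E_in, E_out, I,
                     kin_species("E_out.I", "complex", "DFG_out")),
      reactions = list(
        kin_reaction("E_in", "E_out", "k1", "k_m1"),
        kin_reaction(c("E_out", "I"), "E_out.I", "k2", "k_m2"))),
    binding_if = list(
      species = list(kin_species("E", "free_enzyme_state"), I,
                     kin_species("E.I", "complex"),
                     kin_species("E_star.I", "complex", "starred")),
      reactions = list(
        kin_reaction(c("E", "I"), "E.I", "k2", "k_m2"),
        kin_reaction("E.I", "E_star.I", "k3", "k_m3"))),
    cs_binding_if = list(
      species = list(E_in, E_out, I,
                     kin_species("E_out.I", "complex", "DFG_out"),
                     kin_species("E_out_star.I", "complex", "DFG_out_star")),
      reactions = list(
        kin_reaction("E_in", "E_out", "k1", "k_m1"),
        kin_reaction(c("E_out", "I"), "E_out.I", "k2", "k_m2"),
        kin_reaction("E_out.I", "E_out_star.I", "k3", "k_m3"))),
    branched = list(
      species = list(E_out, E_in, I,
                     kin_species("E_in.I", "complex", "DFG_in"),
                     kin_species("E_in_star.I", "complex", "DFG_in_star"),
                     kin_species("E_out.I", "complex", "DFG_out")),
      reactions = list(
        kin_reaction("E_out", "E_in", "k1", "k_m1"),
        kin_reaction(c("E_in", "I"), "E_in.I", "k2", "k_m2"),
        kin_reaction("E_in.I", "E_in_star.I", "k3", "k_m3"),
        kin_reaction(c("E_out", "I"), "E_out.I", "k4", "k_m4"))))
  kinetic_scheme(mechanism_id, sw$species, sw$reactions, constants)
}

#' Mass-action rate equations of a scheme
#'
#' Builds the derivative function d[conc]/dt for the scheme's reaction set.
#' Bimolecular steps contribute terms of the form k2 [E_state] [I]; the
#' resulting system conserves total enzyme and total ligand exactly in exact
#' arithmetic.
#'
#' @param scheme A \code{kinetic_scheme} with all referenced constants set.
#' @return A function \code{f(conc)} mapping a named concentration vector
#'   (microM) to its time derivative (microM/s), with attribute
#'   \code{"species"} giving the expected ordering.
#' @export
rate_equations <- function(scheme) {
  k <- .require_constants(scheme)
  sp <- scheme_species_names(scheme)
  n <- length(sp)
  # precompute index representation of each reaction
  rxs <- lapply(scheme$reactions, function(rx) {
    list(ri = match(rx$reactants, sp), pi = match(rx$products, sp),
         kf = unname(k[rx$forward_name]), kr = unname(k[rx$reverse_name]))
  })
  f <- function(conc) {
    d <- numeric(n)
    for (rx in rxs) {
      flux <- rx$kf * prod(conc[rx$ri]) - rx$kr * prod(conc[rx$pi])
      d[rx$ri] <- d[rx$ri] - flux
      d[rx$pi] <- d[rx$pi] + flux
    }
    names(d) <- sp
    d
  }
  attr(f, "species") <- sp
  f
}

#' Serialize a scheme to JSON
#'
#' Numbers are written at full precision so a load/save round trip is
#' bit-exact.
#'
#' @param scheme A \code{kinetic_scheme}.
#' @param path File path; if \code{NULL}, the JSON string is returned.
#' @return \code{path} invisibly, or a JSON string.
#' @export
write_scheme_json <- function(scheme, path = NULL) {
  obj <- list(
    name = scheme$name,
    species = lapply(scheme$species, function(s)
      list(name = s$name, role = s$role, state_tag = s$state_tag)),
    reactions = lapply(scheme$reactions, function(r)
      list(reactants = as.list(r$reactants), products = as.list(r$products),
           forward_name = r$forward_name, reverse_name = r$reverse_name,
           forward_order = r$forward_order)),
    constants = list(values = as.list(scheme$constants$values),
                     errors = as.list(scheme$constants$errors)))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Load a scheme from JSON
#'
#' The file is schema-validated on load: it must carry \code{name},
#' \code{species}, \code{reactions} and \code{constants} fields with the
#' structure produced by \code{\link{write_scheme_json}}, and the resulting
#' scheme must satisfy all structural invariants.
#'
#' @param path File path or a JSON string.
#' @return A \code{kinetic_scheme}.
#' @export
read_scheme_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("name", "species", "reactions", "constants")
  missing <- setdiff(need, names(obj))
  if (length(missing))
    stop("scheme JSON missing field(s): ", paste(missing, collapse = ", "))
  species <- lapply(obj$species, function(s) {
    if (is.null(s$name) || is.null(s$role))
      stop("scheme JSON: each species needs 'name' and 'role'")
    kin_species(s$name, s$role,
                if (is.null(s$state_tag)) NA_character_ else s$state_tag)
  })
  reactions <- lapply(obj$reactions, function(r) {
    if (is.null(r$reactants) || is.null(r$products) ||
        is.null(r$forward_name) || is.null(r$reverse_name))
      stop("scheme JSON: malformed reaction entry")
    kin_reaction(unlist(r$reactants), unlist(r$products),
                 r$forward_name, r$reverse_name)
  })
  values <- unlist(obj$constants$values)
  errors <- if (length(obj$constants$errors)) unlist(obj$constants$errors)
  constants <- if (length(values))
    rate_constants_from_vectors(values, errors) else rate_constants()
  kinetic_scheme(obj$name, species, reactions, constants)
}
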