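# Forward simulation of binding experiments: stiff ODE propagation of a
# scheme under a measurement protocol, algebraic equilibria, and relaxation
# rates of the linearised (pseudo-first-order) system.

#' Experiment protocol
#'
#' Describes one executable experiment. Kinds:
#' \describe{
#'   \item{association_mix}{Stopped-flow mixing: enzyme pre-equilibrated
#'     among its free conformational states, ligand added at t = 0.}
#'   \item{dilution_dissociation}{Complex pre-equilibrated among all states
#'     at the pre-dilution concentrations, then every concentration divided
#'     by \code{dilution_factor} at t = 0.}
#'   \item{double_jump}{Surface (flow-cell) experiment: association with the
#'     free-ligand concentration held constant for \code{incubation_time},
#'     then dissociation with free ligand held at zero. Sampling covers the
#'     dissociation segment.}
#'   \item{equilibrium_titration}{Equilibrium signal versus a series of total
#'     ligand concentrations.}
#' }
#'
#' @param kind Protocol kind (see Details).
#' @param enzyme_total Total enzyme, microM.
#' @param ligand_total Total ligand, microM (a series for titrations).
#' @param dilution_factor Fold dilution (> 1), dilution kinds only.
#' @param incubation_time Association duration before the dissociation jump
#'   (s), double-jump only.
#' @param dead_time Instrument dead time (s); the signal is evaluated
#'   \code{dead_time} after mixing, which is why sub-millisecond events are
#'   invisible in stopped flow. Default 1.5 ms.
#' @param sample_times Strictly increasing sampling grid (s), measured on the
#'   instrument clock (0 = first observable point).
#' @return A list of class \code{kin_protocol}.
#' @export
kin_protocol <- function(kind, enzyme_total, ligand_total,
                         dilution_factor = NULL, incubation_time = NULL,
                         dead_time = 1.5e-3, sample_times = NULL) {
  kind <- match.arg(kind, c("association_mix", "dilution_dissociation",
                            "double_jump", "equilibrium_titration"))
  if (any(enzyme_total < 0) || any(ligand_total < 0))
    stop("concentrations must be >= 0")
  if (kind != "equilibrium_titration") {
    if (is.null(sample_times) || length(sample_times) < 2 ||
        any(diff(sample_times) <= 0))
      stop("sample_times must be strictly increasing")
  }
  if (kind == "dilution_dissociation") {
    if (is.null(dilution_factor) || dilution_factor <= 1)
      stop("dilution_factor must be > 1")
  }
  if (kind == "double_jump" &&
      (is.null(incubation_time) || incubation_time <= 0))
    stop("double_jump requires a positive incubation_time")
  structure(list(kind = kind, enzyme_total = enzyme_total,
                 ligand_total = ligand_total,
                 dilution_factor = dilution_factor,
                 incubation_time = incubation_time, dead_time = dead_time,
                 sample_times = sample_times),
            class = "kin_protocol")
}

#' Observable map: species concentrations to measured signal
#'
#' Fluorescence mode: signal = offset + sum(coefficient_s * [s]), optionally
#' multiplied by exp(-photobleach_rate * t). Surface-mass mode emulates
#' label-free waveguide interferometry: all ligand-containing complexes
#' contribute with one common coefficient and free species contribute
#' nothing (enforced at construction).
#'
#' @param coefficients Named numeric vector, signal (a.u.) per microM of each
#'   species; species not named contribute zero.
#' @param offset Baseline signal, a.u.
#' @param photobleach_rate First-order bleaching rate (1/s); 0 disables.
#' @param mode \code{"fluorescence"} or \code{"surface_mass"}.
#' @param scheme Required for \code{surface_mass} validation.
#' @return A list of class \code{kin_observable}.
#' @export
observable_map <- function(coefficients, offset = 0, photobleach_rate = 0,
                           mode = c("fluorescence", "surface_mass"),
                           scheme = NULL) {
  mode <- match.arg(mode)
  if (mode == "surface_mass") {
    if (is.null(scheme))
      stop("surface_mass mode needs the scheme to validate coefficients")
    bound <- scheme_bound_species(scheme)
    free_named <- setdiff(names(coefficients), bound)
    if (any(coefficients[free_named] != 0))
      stop("surface_mass mode: free species must have zero coefficient")
    cb <- coefficients[intersect(names(coefficients), bound)]
    if (length(cb) != length(bound) || length(unique(unname(cb))) != 1)
      stop("surface_mass mode: all ligand-containing complexes must share ",
           "one coefficient")
  }
  structure(list(coefficients = coefficients, offset = offset,
                 photobleach_rate = photobleach_rate, mode = mode),
            class = "kin_observable")
}

#' Surface-mass observable for a scheme
#' @param scheme A \code{kinetic_scheme}.
#' @param coefficient Common response (a.u. per microM of bound complex).
#' @return A \code{kin_observable} in surface-mass mode.
#' @export
surface_observable <- function(scheme, coefficient = 1) {
  bound <- scheme_bound_species(scheme)
  observable_map(stats::setNames(rep(coefficient, length(bound)), bound),
                 mode = "surface_mass", scheme = scheme)
}

.eval_observable <- function(observable, times, conc_matrix) {
  sig <- rep(observable$offset, length(times))
  for (sp in names(observable$coefficients)) {
    if (sp %in% colnames(conc_matrix))
      sig <- sig + observable$coefficients[[sp]] * conc_matrix[, sp]
  }
  if (observable$photobleach_rate > 0)
    sig <- sig * exp(-observable$photobleach_rate * times)
  sig
}

#' Algebraic equilibrium of a scheme
#'
#' Exploits the tree structure of these mechanisms: every species
#' concentration is expressed relative to a reference free-enzyme state as a
#' product of step equilibrium constants (and the free-ligand concentration
#' for bimolecular steps); ligand conservation then reduces to a monotone
#' scalar equation solved by bisection to near machine precision.
#'
#' @param scheme A \code{kinetic_scheme} with constants set.
#' @param enzyme_total,ligand_total Totals, microM.
#' @return Named concentration vector (microM) at equilibrium.
#' @export
equilibrium_concentrations <- function(scheme, enzyme_total, ligand_total) {
  k <- .require_constants(scheme)
  sp <- scheme_species_names(scheme)
  ligand <- scheme_ligand(scheme)
  enz <- scheme_enzyme_species(scheme)
  bound <- scheme_bound_species(scheme)
  ref <- enz[1]
  # weights: conc(species) = w(species; L) * conc(ref), by BFS over reactions
  weights_at <- function(L) {
    w <- stats::setNames(rep(NA_real_, length(enz)), enz)
    w[ref] <- 1
    repeat {
      progressed <- FALSE
      for (rx in scheme$reactions) {
        a <- setdiff(rx$reactants, ligand)
        b <- setdiff(rx$products, ligand)
        keq <- k[rx$forward_name] / k[rx$reverse_name]  # forward over reverse
        lig_fwd <- ligand %in% rx$reactants
        if (!is.na(w[a]) && is.na(w[b])) {
          w[b] <- w[a] * keq * (if (lig_fwd) L else 1)
          progressed <- TRUE
        } else if (is.na(w[a]) && !is.na(w[b])) {
          w[a] <- w[b] / (keq * (if (lig_fwd) L else 1))
          progressed <- TRUE
        }
      }
      if (!progressed) break
    }
    if (anyNA(w)) stop("scheme is not connected; equilibrium undefined")
    w
  }
  conc_at <- function(L) {
    w <- weights_at(L)
    cref <- enzyme_total / sum(w)
    conc <- stats::setNames(numeric(length(sp)), sp)
    conc[enz] <- w * cref
    conc[ligand] <- L
    conc
  }
  if (ligand_total <= 0) return(conc_at(0))
  if (length(bound) == 0) return(conc_at(ligand_total))
  bound_at <- function(L) sum(conc_at(L)[bound])
  g <- function(L) L + bound_at(L) - ligand_total  # increasing in L
  upper <- ligand_total
  root <- stats::uniroot(g, lower = 0, upper = upper, tol = 1e-14 *
                           max(1, ligand_total), maxiter = 2000)$root
  conc_at(root)
}

#' Conformational pre-equilibrium of the free enzyme
#' @param scheme A \code{kinetic_scheme} with constants set.
#' @param enzyme_total Total enzyme, microM.
#' @return Named concentration vector with ligand and complexes at zero.
#' @export
free_enzyme_equilibrium <- function(scheme, enzyme_total)
  equilibrium_concentrations(scheme, enzyme_total, 0)

# deSolve derivative wrapper; `clamp` = indices whose derivative is zeroed
.ode_func <- function(deriv, clamp = integer(0)) {
  function(t, y, parms) {
    d <- deriv(y)
    if (length(clamp)) d[clamp] <- 0
    list(d)
  }
}

.integrate <- function(scheme, y0, times, clamp_species = character(0),
                       rtol = 1e-8, atol = 1e-10) {
  sp <- scheme_species_names(scheme)
  deriv <- rate_equations(scheme)
  clamp <- match(clamp_species, sp)
  tt <- times
  add0 <- tt[1] > 0
  if (add0) tt <- c(0, tt)
  out <- deSolve::ode(y = stats::setNames(y0, sp), times = tt,
                      func = .ode_func(deriv, clamp), parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed to converge; consider loosening rtol/atol ",
         "(defaults 1e-8/1e-10) or shortening the time span")
  m <- out[, sp, drop = FALSE]
  if (add0) m <- m[-1, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Simulate a protocol
#'
#' Propagates the scheme under the protocol with a stiff implicit integrator
#' (lsoda, rtol 1e-8 / atol 1e-10 by default; the canonical schemes span
#' rates from about 7e-4 to 50 per second) and renders the observable on the
#' sampling grid, evaluated \code{dead_time} after mixing.
#'
#' @param scheme A \code{kinetic_scheme} with constants set.
#' @param protocol A \code{\link{kin_protocol}}.
#' @param observable A \code{\link{observable_map}}.
#' @param rtol,atol Solver tolerances.
#' @return A \code{kin_trace}: list with \code{times} (instrument clock, s;
#'   for titrations the ligand series, microM), \code{signal} (a.u.),
#'   \code{species} (concentration matrix, microM), \code{protocol},
#'   \code{noise_sigma} (0 for noiseless simulation).
#' @export
propagate <- function(scheme, protocol, observable, rtol = 1e-8,
                      atol = 1e-10) {
  sp <- scheme_species_names(scheme)
  ligand <- scheme_ligand(scheme)
  if (protocol$kind == "equilibrium_titration") {
    m <- t(vapply(protocol$ligand_total, function(L)
      equilibrium_concentrations(scheme, protocol$enzyme_total, L),
      numeric(length(sp))))
    colnames(m) <- sp
    sig <- .eval_observable(observable, rep(0, nrow(m)), m)
    return(kin_trace(protocol$ligand_total, sig, protocol, species = m))
  }
  t_eval <- protocol$sample_times + protocol$dead_time
  if (protocol$kind == "association_mix") {
    y0 <- free_enzyme_equilibrium(scheme, protocol$enzyme_total)
    y0[ligand] <- protocol$ligand_total
    m <- .integrate(scheme, y0, t_eval, rtol = rtol, atol = atol)
  } else if (protocol$kind == "dilution_dissociation") {
    y0 <- equilibrium_concentrations(scheme, protocol$enzyme_total,
                                     protocol$ligand_total)
    y0 <- y0 / protocol$dilution_factor
    m <- .integrate(scheme, y0, t_eval, rtol = rtol, atol = atol)
  } else if (protocol$kind == "double_jump") {
    # association segment: constant free ligand in the flow cell
    y0 <- free_enzyme_equilibrium(scheme, protocol$enzyme_total)
    y0[ligand] <- protocol$ligand_total
    seg1 <- .integrate(scheme, y0, c(protocol$incubation_time / 2,
                                     protocol$incubation_time),
                       clamp_species = ligand, rtol = rtol, atol = atol)
    y1 <- seg1[nrow(seg1), ]
    y1[ligand] <- 0  # buffer wash removes free drug
    m <- .integrate(scheme, y1, t_eval, clamp_species = ligand,
                    rtol = rtol, atol = atol)
  }
  colnames(m) <- sp
  sig <- .eval_observable(observable, t_eval, m)
  kin_trace(protocol$sample_times, sig, protocol, species = m)
}

#' Construct a trace
#' @param times Sampling grid (s), or ligand series for titrations (microM).
#' @param signal Observed signal, a.u.
#' @param protocol The generating \code{kin_protocol} (or NULL for imported
#'   data).
#' @param species Optional species-concentration matrix (microM).
#' @param noise_sigma Known additive noise s.d. (a.u.), >= 0.
#' @return A list of class \code{kin_trace}.
#' @export
kin_trace <- function(times, signal, protocol = NULL, species = NULL,
                      noise_sigma = 0) {
  if (length(times) != length(signal))
    stop("times and signal lengths differ")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(times = times, signal = signal, species = species,
                 protocol = protocol, noise_sigma = noise_sigma),
            class = "kin_trace")
}

#' Relaxation rates under the pseudo-first-order approximation
#'
#' Treats the free-ligand concentration as a constant (large excess, or
#' clamped by a flow cell), making the enzyme subsystem linear. Returns the
#' nonzero eigenvalues of the negated rate matrix, i.e. the relaxation rates
#' of the observable kinetic phases, sorted ascending. Their number is the
#' number of enzyme-containing species minus one (one eigenvalue is zero by
#' enzyme conservation).
#'
#' @param scheme A \code{kinetic_scheme} with constants set.
#' @param ligand_conc Fixed free-ligand concentration, microM.
#' @return Numeric vector of relaxation rates (1/s), ascending.
#' @export
eigen_rates <- function(scheme, ligand_conc) {
  M <- .enzyme_rate_matrix(scheme, ligand_conc)
  ev <- eigen(-M, only.values = TRUE)$values
  if (any(abs(Im(ev)) > 1e-8 * (abs(Re(ev)) + 1e-12)))
    warning("complex relaxation rates detected; returning real parts")
  ev <- Re(ev)
  ev <- sort(ev)
  ev <- ev[-1]  # drop the (near-)zero conservation eigenvalue
  if (any(ev < -1e-8))
    warning("negative relaxation rate: system not relaxing")
  ev
}

# Linear rate matrix over enzyme-containing species with [ligand] fixed.
.enzyme_rate_matrix <- function(scheme, ligand_conc) {
  k <- .require_constants(scheme)
  enz <- scheme_enzyme_species(scheme)
  ligand <- scheme_ligand(scheme)
  n <- length(enz)
  M <- matrix(0, n, n, dimnames = list(enz, enz))
  add_edge <- function(from, to, rate) {
    M[to, from] <<- M[to, from] + rate
    M[from, from] <<- M[from, from] - rate
  }
  for (rx in scheme$reactions) {
    a <- setdiff(rx$reactants, ligand)
    b <- setdiff(rx$products, ligand)
    kf <- k[rx$forward_name]
    kr <- k[rx$reverse_name]
    if (ligand %in% rx$reactants) kf <- kf * ligand_conc
    add_edge(a, b, unname(kf))
    add_edge(b, a, unname(kr))
  }
  M
}

# Dissociation subsystem: ligand-bound species only, free ligand clamped to
# zero so escape through the physical dissociation step(s) is irreversible.
.dissociation_matrix <- function(scheme) {
  k <- .require_constants(scheme)
  bound <- scheme_bound_species(scheme)
  if (!length(bound)) stop("scheme has no ligand-bound species")
  ligand <- scheme_ligand(scheme)
  n <- length(bound)
  M <- matrix(0, n, n, dimnames = list(bound, bound))
  for (rx in scheme$reactions) {
    a <- setdiff(rx$reactants, ligand)
    b <- setdiff(rx$products, ligand)
    kf <- unname(k[rx$forward_name])
    kr <- unname(k[rx$reverse_name])
    if (a %in% bound && b %in% bound) {
      M[b, a] <- M[b, a] + kf; M[a, a] <- M[a, a] - kf
      M[a, b] <- M[a, b] + kr; M[b, b] <- M[b, b] - kr
    } else if (b %in% bound && !(a %in% bound)) {
      # complex <-> free + ligand: with ligand at zero only the escape flows
      M[b, b] <- M[b, b] - kr
    } else if (a %in% bound && !(b %in% bound)) {
      M[a, a] <- M[a, a] - kf
    }
  }
  M
}
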