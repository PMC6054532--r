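# Closed-form macroscopic quantities from microscopic rate constants:
# step equilibrium constants, overall dissociation constants per mechanism,
# the conformational-selection affinity penalty, kinetic-partitioning
# predictions of the observed off-rate, and delta-method error propagation.

# Step equilibrium constants, defined reverse over forward so K2 and K4
# carry microM units (dissociation constants of the binding steps).
.K_defs <- list(
  K1 = function(k) k[["k_m1"]] / k[["k1"]],
  K2 = function(k) k[["k_m2"]] / k[["k2"]],
  K3 = function(k) k[["k_m3"]] / k[["k3"]],
  K4 = function(k) k[["k_m4"]] / k[["k4"]])

.kd_forms <- list(
  cs_binding    = function(k) (.K_defs$K1(k) + 1) * .K_defs$K2(k),
  binding_if    = function(k) {
    K3 <- .K_defs$K3(k)
    .K_defs$K2(k) * K3 / (K3 + 1)
  },
  cs_binding_if = function(k) {
    K3 <- .K_defs$K3(k)
    (.K_defs$K1(k) + 1) * .K_defs$K2(k) * K3 / (K3 + 1)
  },
  branched      = function(k) {
    K1 <- .K_defs$K1(k); K2 <- .K_defs$K2(k)
    K3 <- .K_defs$K3(k); K4 <- .K_defs$K4(k)
    (K1 + 1) * K2 * K3 * K4 / (K1 * K2 * K3 + K3 * K4 + K4)
  })

.kd_inputs <- list(
  cs_binding    = c("k1", "k_m1", "k2", "k_m2"),
  binding_if    = c("k2", "k_m2", "k3", "k_m3"),
  cs_binding_if = c("k1", "k_m1", "k2", "k_m2", "k3", "k_m3"),
  branched      = c("k1", "k_m1", "k2", "k_m2", "k3", "k_m3", "k4", "k_m4"))

.check_inputs <- function(mechanism_id, constants) {
  need <- .kd_inputs[[mechanism_id]]
  if (is.null(need))
    stop("unknown mechanism_id; valid ids: ",
         paste(names(.kd_forms), collapse = ", "))
  have <- names(constants$values)[!is.na(constants$values)]
  missing <- setdiff(need, have)
  if (length(missing))
    stop("missing rate constant(s): ", paste(missing, collapse = ", "))
  as.list(constants$values[need])
}

# first-order (delta-method) propagation assuming independent errors;
# numeric central-difference gradient
.delta_error <- function(f, values, errors) {
  g <- vapply(names(values), function(nm) {
    h <- max(abs(values[[nm]]), 1e-12) * 1e-6
    up <- values; up[[nm]] <- up[[nm]] + h
    dn <- values; dn[[nm]] <- dn[[nm]] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
  sqrt(sum((g * errors[names(values)])^2))
}

#' Overall dissociation constant from microscopic rate constants
#'
#' Evaluates the closed-form macroscopic KD of a canonical mechanism with
#' K1 = k_m1/k1, K2 = k_m2/k2 (microM), K3 = k_m3/k3, K4 = k_m4/k4 (microM):
#' \itemize{
#'   \item \code{cs_binding}: KD = (K1 + 1) K2
#'   \item \code{binding_if}: KD = K2 K3 / (K3 + 1)
#'   \item \code{cs_binding_if}: KD = (K1 + 1) K2 K3 / (K3 + 1)
#'   \item \code{branched}: KD = (K1 + 1) K2 K3 K4 /
#'     (K1 K2 K3 + K3 K4 + K4)
#' }
#' Errors, when present on every required input, are propagated to first
#' order assuming independence.
#'
#' @param mechanism_id One of the canonical mechanism ids.
#' @param constants A \code{\link{rate_constants}} table.
#' @return A list of class \code{derived_constants}: step constants K1-K4
#'   (those defined by the mechanism), \code{KD} (microM), and matching
#'   \code{*_se} standard errors when input errors are available.
#' @export
kd_overall <- function(mechanism_id, constants) {
  k <- .check_inputs(mechanism_id, constants)
  need <- .kd_inputs[[mechanism_id]]
  steps <- intersect(names(.K_defs),
                     paste0("K", unique(gsub("\\D", "", need))))
  out <- list(mechanism = mechanism_id)
  for (s in steps) out[[s]] <- .K_defs[[s]](k)
  out$KD <- .kd_forms[[mechanism_id]](k)
  err <- constants$errors
  if (!is.null(err) && all(need %in% names(err))) {
    ev <- err[need]
    for (s in steps) {
      nms <- need[gsub("[^0-9]", "", need) == gsub("[^0-9]", "", s)]
      out[[paste0(s, "_se")]] <-
        .delta_error(function(x) .K_defs[[s]](x), k[nms], ev[nms])
    }
    out$KD_se <- .delta_error(.kd_forms[[mechanism_id]], k, ev)
  }
  structure(out, class = "derived_constants")
}

#' Conformational-selection affinity penalty
#'
#' A pre-existing conformational equilibrium in which only one free-enzyme
#' state binds the ligand weakens the overall affinity by the factor
#' (K1 + 1) = 1 + k_m1/k1. With the 25-degree DFG-flip rates of Aurora A
#' (k1 = 0.09/s, k_m1 = 0.06/s) this is 1.67, i.e. roughly 1.6-fold.
#'
#' @param constants A \code{rate_constants} table with \code{k1} and
#'   \code{k_m1} set (> 0).
#' @return List with \code{penalty} and, when both errors are given,
#'   \code{penalty_se}.
#' @export
cs_penalty <- function(constants) {
  v <- constants$values
  if (is.na(v["k1"]) || is.na(v["k_m1"]) || !all(c("k1", "k_m1") %in% names(v)))
    stop("cs_penalty needs k1 and k_m1")
  if (v[["k1"]] <= 0) stop("k1 must be > 0")
  f <- function(k) 1 + k[["k_m1"]] / k[["k1"]]
  out <- list(penalty = f(as.list(v)))
  err <- constants$errors
  if (!is.null(err) && all(c("k1", "k_m1") %in% names(err)))
    out$penalty_se <- .delta_error(f, as.list(v[c("k1", "k_m1")]), err)
  out
}

#' Observed off-rate predicted by kinetic partitioning
#'
#' After the free drug is removed, the ligand-bound subsystem relaxes with
#' escape through the physical dissociation step(s) irreversible. The
#' intermediate partitions between escape (k_m2) and re-trapping into the
#' tightened complex (k3), so the observed off-rate is the slow eigenvalue of
#' that subsystem -- always at most k_m3 for the three-step scheme, and for
#' k_m3 << k_m2 + k3 close to k_m3 * k_m2 / (k_m2 + k3 + k_m3).
#'
#' @param mechanism_id A canonical mechanism id.
#' @param constants A \code{rate_constants} table.
#' @return A list of class \code{partition_prediction}: \code{lambda_slow}
#'   and \code{lambda_fast} (1/s; the two extreme eigenvalues), all
#'   eigenvalues in \code{rates}, and \code{escape_probability}
#'   (k_m2/(k_m2 + k3), NA when the scheme has no step after binding).
#' @export
predict_observed_off <- function(mechanism_id, constants) {
  scheme <- canonical_scheme(mechanism_id, constants)
  M <- .dissociation_matrix(scheme)
  ev <- sort(Re(eigen(-M, only.values = TRUE)$values))
  k <- constants$values
  esc <- if (all(c("k_m2", "k3") %in% names(k)) && !anyNA(k[c("k_m2", "k3")]))
    unname(k["k_m2"] / (k["k_m2"] + k["k3"])) else NA_real_
  structure(list(lambda_slow = ev[1], lambda_fast = ev[length(ev)],
                 rates = ev, escape_probability = esc),
            class = "partition_prediction")
}

# registry of scalar expressions for standalone error propagation
.expression_registry <- function() {
  exprs <- list(
    K1 = list(f = .K_defs$K1, inputs = c("k1", "k_m1")),
    K2 = list(f = .K_defs$K2, inputs = c("k2", "k_m2")),
    K3 = list(f = .K_defs$K3, inputs = c("k3", "k_m3")),
    K4 = list(f = .K_defs$K4, inputs = c("k4", "k_m4")),
    cs_penalty = list(f = function(k) 1 + k[["k_m1"]] / k[["k1"]],
                      inputs = c("k1", "k_m1")))
  for (id in names(.kd_forms))
    exprs[[paste0("KD_", id)]] <- list(f = .kd_forms[[id]],
                                       inputs = .kd_inputs[[id]])
  exprs
}

#' Delta-method uncertainty for a derived quantity
#'
#' First-order propagation assuming independent errors on the inputs (no
#' covariances are available from the fits, a documented limitation).
#'
#' @param expression_id One of \code{"K1"}, \code{"K2"}, \code{"K3"},
#'   \code{"K4"}, \code{"cs_penalty"}, or \code{"KD_<mechanism_id>"}.
#' @param constants A \code{rate_constants} table; every input of the
#'   expression must carry a standard error.
#' @return List with \code{value} and \code{se}.
#' @export
propagate_uncertainty <- function(expression_id, constants) {
  reg <- .expression_registry()
  ex <- reg[[expression_id]]
  if (is.null(ex))
    stop("unknown expression_id; valid ids: ",
         paste(names(reg), collapse = ", "))
  v <- constants$values
  missing_v <- setdiff(ex$inputs, names(v)[!is.na(v)])
  if (length(missing_v))
    stop("missing value(s): ", paste(missing_v, collapse = ", "))
  err <- constants$errors
  missing_e <- setdiff(ex$inputs, names(err))
  if (length(missing_e))
    stop("missing standard error(s) for: ", paste(missing_e, collapse = ", "))
  vals <- as.list(v[ex$inputs])
  list(value = ex$f(vals), se = .delta_error(ex$f, vals, err[ex$inputs]))
}

#' Mechanism report
#'
#' Bundles the derived equilibrium constants, overall KD, the
#' conformational-selection penalty (when the mechanism has a free-enzyme
#' equilibrium) and the kinetic-partitioning prediction into one list,
#' suitable for JSON export.
#'
#' @param mechanism_id A canonical mechanism id.
#' @param constants A \code{rate_constants} table.
#' @return A list.
#' @export
mechanism_report <- function(mechanism_id, constants) {
  rep <- list(mechanism = mechanism_id,
              constants = as.list(constants$values),
              derived = unclass(kd_overall(mechanism_id, constants)))
  if (all(c("k1", "k_m1") %in% names(constants$values)))
    rep$cs_penalty <- cs_penalty(constants)
  rep$partitioning <- unclass(predict_observed_off(mechanism_id, constants))
  rep
}
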