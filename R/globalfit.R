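# Simultaneous fitting of one scheme's rate constants against heterogeneous
# experiments. Rate constants are optimised in log10 space (they span five
# decades); per-experiment-type observable coefficients are profiled out by
# weighted linear least squares at every iteration (variable projection), so
# the nonlinear search runs only over the rate constants.

#' Bundle experiments for global fitting
#'
#' @param experiments List of entries, each a list with \code{protocol}
#'   (\code{kin_protocol}), \code{trace} (\code{kin_trace}) and optionally
#'   \code{group} (experiments in one group share observable coefficients;
#'   defaults to the protocol kind) and \code{weight} (multiplier on
#'   1/sigma^2 weights, default 1).
#' @param scheme_name Id of the scheme the experiments probe.
#' @return A list of class \code{experiment_set}.
#' @export
experiment_set <- function(experiments, scheme_name) {
  for (e in experiments) {
    if (!inherits(e$protocol, "kin_protocol") ||
        !inherits(e$trace, "kin_trace"))
      stop("each experiment needs a kin_protocol and a kin_trace")
  }
  structure(list(experiments = experiments, scheme_name = scheme_name),
            class = "experiment_set")
}

.experiment_group <- function(e)
  if (!is.null(e$group)) e$group else e$protocol$kind

# noise s.d. for weighting: the trace's recorded sigma when present,
# otherwise estimated from first differences of the late half of the trace
.trace_sigma <- function(trace) {
  if (!is.null(trace$noise_sigma) && trace$noise_sigma > 0)
    return(trace$noise_sigma)
  tail_part <- trace$signal[seq(ceiling(length(trace$signal) / 2),
                                length(trace$signal))]
  s <- stats::mad(diff(tail_part)) / sqrt(2)
  if (!is.finite(s) || s <= 0) s <- stats::sd(trace$signal) * 0.01 + 1e-12
  s
}

# Simulate all experiments at the given constants and profile the linear
# observable parameters per group. Returns weighted residuals and metadata.
.global_residuals <- function(dataset, scheme, values, detail = FALSE) {
  scheme <- set_constants(scheme, rate_constants_from_vectors(values))
  exps <- dataset$experiments
  sims <- vector("list", length(exps))
  for (i in seq_along(exps)) {
    e <- exps[[i]]
    sims[[i]] <- tryCatch(
      propagate(scheme, e$protocol, .null_observable(scheme, e$protocol)),
      error = function(err) NULL)
    if (is.null(sims[[i]]))
      return(if (detail) NULL else rep(1e6, sum(vapply(exps, function(x)
        length(x$trace$signal), numeric(1)))))
  }
  groups <- vapply(exps, .experiment_group, character(1))
  res <- vector("list", length(exps))
  coefs <- list()
  n_lin <- 0L
  for (g in unique(groups)) {
    idx <- which(groups == g)
    Xs <- list(); ys <- list(); ws <- list()
    for (i in idx) {
      X <- .design_matrix(scheme, exps[[i]], sims[[i]])
      sg <- .trace_sigma(exps[[i]]$trace)
      w <- sqrt((if (is.null(exps[[i]]$weight)) 1 else exps[[i]]$weight)) / sg
      Xs[[length(Xs) + 1]] <- X * w
      ys[[length(ys) + 1]] <- exps[[i]]$trace$signal * w
      ws[[length(ws) + 1]] <- rep(w, length(exps[[i]]$trace$signal))
    }
    Xg <- do.call(rbind, Xs)
    yg <- unlist(ys)
    lf <- stats::lm.fit(Xg, yg)
    beta <- lf$coefficients
    beta[is.na(beta)] <- 0
    n_lin <- n_lin + sum(abs(lf$coefficients) >= 0, na.rm = TRUE)
    coefs[[g]] <- beta
    pos <- 1L
    for (j in seq_along(idx)) {
      n <- length(ys[[j]])
      pred <- drop(Xs[[j]] %*% beta)
      res[[idx[j]]] <- pred - ys[[j]]
      pos <- pos + n
    }
  }
  r <- unlist(res)
  if (!detail) return(r)
  list(residuals = r, coefficients = coefs, n_linear = n_lin, sims = sims)
}

# observable used only to drive propagate(); signal recomputed from species
.null_observable <- function(scheme, protocol) {
  sp <- scheme_species_names(scheme)
  observable_map(stats::setNames(rep(0, length(sp)), sp))
}

# Design matrix mapping linear observable parameters to the signal of one
# experiment: fluorescence uses an offset plus one coefficient per
# enzyme-containing species; surface-type protocols (double jump) use the
# summed bound mass plus an offset; titrations use bound mass plus offset.
.design_matrix <- function(scheme, e, sim) {
  enz <- scheme_enzyme_species(scheme)
  bound <- scheme_bound_species(scheme)
  kind <- e$protocol$kind
  if (kind %in% c("double_jump", "equilibrium_titration")) {
    cbind(offset = 1, bound = rowSums(sim$species[, bound, drop = FALSE]))
  } else {
    cbind(offset = 1, sim$species[, enz, drop = FALSE])
  }
}

#' Global fit of rate constants to an experiment set
#'
#' Weighted least squares over all traces jointly: rate constants are shared
#' across traces, fluorescence coefficients per species are shared across
#' concentrations within an experiment group and profiled out linearly.
#' Optimisation runs in log10 space by Levenberg-Marquardt from
#' \code{n_starts} log-uniform perturbations of the initial constants
#' (seeded, deterministic). Standard errors come from the Jacobian at the
#' optimum; a parameter whose standard error exceeds 10 times its value is
#' flagged structurally unidentifiable.
#'
#' @param dataset An \code{\link{experiment_set}}.
#' @param scheme The \code{kinetic_scheme} to fit.
#' @param init \code{rate_constants} starting values (defaults to the
#'   scheme's constants).
#' @param bounds Two-element list \code{list(lower=, upper=)} in natural
#'   units; default c(1e-6, 1e4).
#' @param fixed Character vector of constant names held at their initial
#'   values.
#' @param n_starts Multi-start count (default 8).
#' @param seed Integer seed for the start perturbations.
#' @param perturb Log10 half-width of start perturbations (default 0.5).
#' @return A list of class \code{global_fit_result}: \code{estimates},
#'   \code{se}, \code{unidentifiable} (standard error over 10 times the
#'   value), \code{poorly_determined} (standard error over a quarter of the
#'   value), \code{coefficients}
#'   (per group), \code{reduced_chisq}, \code{chisq}, \code{n_obs},
#'   \code{n_par}, \code{aic}, \code{converged}, \code{seed},
#'   \code{deviance_trace} (best start's objective per iteration).
#' @export
global_fit <- function(dataset, scheme, init = NULL, bounds = NULL,
                       fixed = character(0), n_starts = 8, seed = 1,
                       perturb = 0.5) {
  if (is.null(init)) init <- scheme$constants
  need <- scheme_constant_names(scheme)
  iv <- init$values
  missing <- setdiff(need, names(iv)[!is.na(iv)])
  if (length(missing))
    stop("init missing constant(s): ", paste(missing, collapse = ", "))
  free <- setdiff(need, fixed)
  if (!length(free)) stop("no free parameters")
  lower <- if (is.null(bounds)) 1e-6 else bounds$lower
  upper <- if (is.null(bounds)) 1e4 else bounds$upper
  if (any(iv[free] < lower | iv[free] > upper))
    stop("init outside bounds")
  base_lp <- log10(iv[free])
  assemble <- function(lp) {
    v <- iv[need]
    v[free] <- 10^lp
    v
  }
  fn <- function(lp) .global_residuals(dataset, scheme, assemble(lp))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  starts <- c(list(base_lp), lapply(seq_len(max(0, n_starts - 1)),
    function(i) base_lp + stats::runif(length(free), -perturb, perturb)))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, log10(lower)), log10(upper))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = fn,
                         lower = rep(log10(lower), length(free)),
                         upper = rep(log10(upper), length(free)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-10, ftol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("global fit failed for all starts")
  detail <- .global_residuals(dataset, scheme, assemble(best$par),
                              detail = TRUE)
  n_obs <- length(detail$residuals)
  n_par <- length(free) + detail$n_linear
  dof <- max(n_obs - n_par, 1)
  chisq <- best$deviance
  # errors: covariance of log10 params from the LM Jacobian, mapped to
  # natural units by the delta method
  se <- rep(NA_real_, length(free))
  cov_l <- tryCatch(chisq / dof * solve(best$hessian), error = function(e)
    NULL)
  if (!is.null(cov_l)) {
    se_l <- sqrt(pmax(diag(cov_l), 0))
    se <- 10^best$par * log(10) * se_l
  }
  est <- stats::setNames(10^best$par, free)
  names(se) <- free
  unident <- free[is.finite(se) & se > 10 * est]
  # softer reporting tier: a constant whose standard error exceeds a
  # quarter of its value is not usefully determined by these data
  poorly <- free[!is.finite(se) | se > 0.25 * est]
  converged <- best$info %in% 1:4
  if (!converged)
    warning("optimizer did not report convergence; returning best-so-far")
  structure(list(
    estimates = est, se = se, fixed = iv[intersect(fixed, need)],
    unidentifiable = unident, poorly_determined = poorly,
    coefficients = detail$coefficients,
    chisq = chisq, reduced_chisq = chisq / dof, n_obs = n_obs,
    n_par = n_par, aic = chisq + 2 * n_par, converged = converged,
    seed = seed, deviance_trace = best$rsstrace),
    class = "global_fit_result")
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat("<global_fit_result>\n")
  for (nm in names(x$estimates))
    cat(sprintf("  %-5s = %.4g +/- %.2g%s\n", nm, x$estimates[[nm]],
                x$se[[nm]],
                if (nm %in% x$unidentifiable) "  [unidentifiable]" else ""))
  cat(sprintf("  reduced chi-square %.3g over %d points, %d parameters\n",
              x$reduced_chisq, x$n_obs, x$n_par))
  invisible(x)
}

#' Rank candidate mechanisms against one dataset
#'
#' Fits every scheme to the dataset and ranks by AIC (chi-square + 2 p for
#' Gaussian errors with known sigma). A model is marked \code{failed} when
#' its reduced chi-square exceeds the best model's by more than
#' \code{fail_factor} (default 3), the operational version of a model that
#' "cannot explain the experimental traces".
#'
#' @param dataset An \code{\link{experiment_set}}.
#' @param schemes List of >= 2 \code{kinetic_scheme}s with initial constants
#'   set.
#' @param fixed Per-scheme list of fixed constant names (recycled if a
#'   single character vector).
#' @param n_starts,seed Passed to \code{\link{global_fit}}.
#' @param fail_factor Rejection multiplier on the best reduced chi-square.
#' @return A list of class \code{model_comparison}: \code{table} (data frame
#'   sorted by AIC: scheme, reduced_chisq, aic, delta_aic, failed) and
#'   \code{fits} (named list of \code{global_fit_result}).
#' @export
compare_models <- function(dataset, schemes, fixed = character(0),
                           n_starts = 4, seed = 1, fail_factor = 3) {
  if (length(schemes) < 2) stop("need at least 2 candidate schemes")
  nms <- vapply(seq_along(schemes), function(i) {
    nm <- schemes[[i]]$name
    if (nm %in% vapply(schemes[seq_len(i - 1)], `[[`, character(1), "name"))
      paste0(nm, ".", i) else nm
  }, character(1))
  if (!is.list(fixed)) fixed <- rep(list(fixed), length(schemes))
  fits <- stats::setNames(vector("list", length(schemes)), nms)
  for (i in seq_along(schemes))
    fits[[i]] <- global_fit(dataset, schemes[[i]], fixed = fixed[[i]],
                            n_starts = n_starts, seed = seed)
  tab <- data.frame(
    scheme = nms,
    reduced_chisq = vapply(fits, `[[`, numeric(1), "reduced_chisq"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    row.names = NULL)
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  best_rc <- min(tab$reduced_chisq)
  tab$failed <- tab$reduced_chisq > fail_factor * best_rc
  structure(list(table = tab, fits = fits), class = "model_comparison")
}
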