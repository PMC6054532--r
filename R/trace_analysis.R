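# Phenomenological estimators applied to individual traces and derived
# series: multi-exponential fits (variable projection with deterministic
# multi-start), observed-rate versus concentration models for the
# conformational-selection, induced-fit and binding phases, the tight-binding
# quadratic titration fit, and Lorentzian deconvolution of 1D spectra.

#' Observed-rate series
#'
#' One kinetic phase's observed relaxation rate across a ligand
#' concentration ladder.
#'
#' @param ligand_concs Ligand concentrations, microM (distinct).
#' @param kobs Observed rates, 1/s.
#' @param errors Standard errors on \code{kobs} (1/s); equal weights when
#'   omitted.
#' @param phase_label \code{"fast"} or \code{"slow"}.
#' @return A list of class \code{kobs_series}.
#' @export
kobs_series <- function(ligand_concs, kobs, errors = NULL,
                        phase_label = c("fast", "slow")) {
  phase_label <- match.arg(phase_label)
  if (length(ligand_concs) != length(kobs))
    stop("ligand_concs and kobs lengths differ")
  if (anyDuplicated(ligand_concs)) stop("concentrations must be distinct")
  if (!is.null(errors) && length(errors) != length(kobs))
    stop("errors length mismatch")
  structure(list(ligand_concs = ligand_concs, kobs = kobs, errors = errors,
                 phase_label = phase_label), class = "kobs_series")
}

.series_weights <- function(series) {
  if (is.null(series$errors)) rep(1, length(series$kobs))
  else 1 / series$errors^2
}

# linear least squares for amplitudes/offset at fixed rates (variable
# projection); returns residuals and coefficients
.exp_design <- function(times, rates)
  cbind(1, vapply(rates, function(r) exp(-r * times),
                  numeric(length(times))))

.exp_profile <- function(times, signal, rates) {
  X <- .exp_design(times, rates)
  fit <- stats::lm.fit(X, signal)
  list(coef = fit$coefficients, resid = fit$residuals)
}

#' Fit a sum of exponentials to a trace
#'
#' Model: signal(t) = offset + sum_i amplitude_i exp(-rate_i t), with signed
#' amplitudes so rising and falling phases can coexist. Rates are optimised
#' in log space by Levenberg-Marquardt with the amplitudes and offset
#' profiled out linearly (variable projection); a deterministic grid of
#' perturbed initialisations guards against local minima. Standard errors
#' come from the Jacobian of the full model at the optimum.
#'
#' @param trace A \code{kin_trace}, or anything with \code{times} and
#'   \code{signal}.
#' @param n_phases 1 or 2.
#' @param n_starts Number of initialisations (>= 1).
#' @return A list of class \code{exponential_fit}: \code{rates} (1/s,
#'   descending), \code{amplitudes} (a.u., aligned with rates),
#'   \code{offset}, \code{rates_se}, \code{amplitudes_se}, \code{offset_se},
#'   \code{rms} (residual root mean square), \code{fitted}.
#' @export
fit_exponentials <- function(trace, n_phases = 1, n_starts = 5) {
  stopifnot(n_phases %in% 1:2)
  times <- trace$times
  signal <- trace$signal
  if (length(times) < 10) stop("need at least 10 samples")
  t_pos <- times[times > 0]
  t_lo <- if (length(t_pos)) min(t_pos) else diff(range(times)) / length(times)
  t_hi <- max(times)
  lr_lo <- log10(0.3 / t_hi)
  lr_hi <- log10(3 / t_lo)
  base <- if (n_phases == 1) mean(c(lr_lo, lr_hi)) else
    c(lr_hi - (lr_hi - lr_lo) / 3, lr_lo + (lr_hi - lr_lo) / 3)
  # deterministic perturbation grid (no RNG involvement)
  shifts <- seq(-1, 1, length.out = max(1, n_starts))
  best <- NULL
  for (s in shifts) {
    init <- base + s * c(0.8, -0.8)[seq_len(n_phases)]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = init, fn = function(lr)
        .exp_profile(times, signal, 10^lr)$resid,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("exponential fit failed for all starts")
  rates <- 10^best$par
  prof <- .exp_profile(times, signal, rates)
  ord <- order(rates, decreasing = TRUE)
  rates <- rates[ord]
  amps <- prof$coef[-1][ord]
  offset <- prof$coef[1]
  # full-model Jacobian for standard errors
  theta <- c(offset, amps, rates)
  model <- function(th) {
    off <- th[1]; a <- th[2:(1 + n_phases)]
    r <- th[(2 + n_phases):(1 + 2 * n_phases)]
    off + .exp_design(times, r)[, -1, drop = FALSE] %*% a
  }
  J <- vapply(seq_along(theta), function(j) {
    h <- max(abs(theta[j]), 1e-8) * 1e-6
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    (model(up) - model(dn)) / (2 * h)
  }, numeric(length(times)))
  dof <- length(times) - length(theta)
  sigma2 <- sum(prof$resid^2) / max(dof, 1)
  JtJ <- crossprod(J)
  kappa <- tryCatch(kappa(JtJ, exact = TRUE), error = function(e) Inf)
  if (n_phases == 2 &&
      (kappa > 1e12 || abs(diff(log(rates))) < 0.02))
    warning("rates nearly collinear; consider n_phases = ", n_phases - 1)
  cov <- tryCatch(sigma2 * solve(JtJ), error = function(e)
    matrix(NA_real_, length(theta), length(theta)))
  se <- sqrt(pmax(diag(cov), 0))
  structure(list(
    n_phases = n_phases,
    rates = unname(rates), amplitudes = unname(amps),
    offset = unname(offset),
    rates_se = unname(se[(2 + n_phases):(1 + 2 * n_phases)]),
    amplitudes_se = unname(se[2:(1 + n_phases)]),
    offset_se = unname(se[1]),
    rms = sqrt(mean(prof$resid^2)),
    fitted = as.numeric(model(theta))), class = "exponential_fit")
}

#' Conformational-selection analysis of a slow-phase rate series
#'
#' Under the rapid-equilibrium approximation (binding fast compared with the
#' conformational step), the slow observed rate follows
#' kobs = k1 + k_m1 / (1 + [I]/([E] + k_m2/k2)), which is linear in k1 and
#' k_m1 once the concentration term is computed -- so the fit is an exact
#' weighted linear regression. The fitted curve obeys the limits
#' kobs([I] = 0) = k1 + k_m1 and kobs([I] -> Inf) = k1.
#'
#' @param series A \code{\link{kobs_series}}, decreasing with concentration
#'   (a rising series indicates an induced-fit phase and is rejected).
#' @param enzyme_conc Enzyme concentration [E], microM.
#' @param K2_app Apparent binding-step dissociation constant k_m2/k2, microM.
#' @return List with \code{k1}, \code{k_m1}, standard errors, and
#'   \code{fitted}.
#' @export
fit_kobs_conformational_selection <- function(series, enzyme_conc, K2_app) {
  x <- series$ligand_concs
  y <- series$kobs
  if (length(x) >= 3 &&
      stats::coef(stats::lm(y ~ x))[2] > 0)
    stop("kobs increases with concentration: not conformational selection; ",
         "consider fit_kobs_induced_fit")
  g <- 1 / (1 + x / (enzyme_conc + K2_app))
  w <- .series_weights(series)
  fit <- stats::lm(y ~ g, weights = w)
  co <- summary(fit)$coefficients
  list(k1 = unname(co["(Intercept)", "Estimate"]),
       k_m1 = unname(co["g", "Estimate"]),
       k1_se = unname(co["(Intercept)", "Std. Error"]),
       k_m1_se = unname(co["g", "Std. Error"]),
       fitted = unname(stats::fitted(fit)))
}

#' Induced-fit analysis of a saturating rate series
#'
#' Fits the hyperbola kobs = k_m3 + k3 [I] / (K_half + [I]). The plateau
#' (k3 + k_m3) is the saturating observed rate of the conformational step
#' inside the complex and the [I] = 0 intercept estimates k_m3. K_half is
#' reported but not interpreted.
#'
#' @param series A \code{\link{kobs_series}}, increasing and saturating.
#' @return List with \code{k3_plus_km3} (plateau), \code{K_half} (microM,
#'   NA when unidentifiable), \code{k_m3_intercept}, standard errors and
#'   \code{fitted}.
#' @export
fit_kobs_induced_fit <- function(series) {
  x <- series$ligand_concs
  y <- series$kobs
  w <- .series_weights(series)
  if (stats::sd(y) < 1e-12 * max(abs(y), 1e-300)) {
    warning("constant series: K_half unidentifiable")
    return(list(k3_plus_km3 = mean(y), K_half = NA_real_,
                k_m3_intercept = mean(y), k3_plus_km3_se = 0,
                K_half_se = NA_real_, k_m3_intercept_se = 0,
                fitted = rep(mean(y), length(y))))
  }
  lin <- stats::lm(y ~ x, weights = w)
  start <- list(km3 = max(min(y), 1e-6), k3 = max(max(y) - min(y), 1e-6),
                Khalf = stats::median(x))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ km3 + k3 * x / (Khalf + x), start = start,
                      weights = w,
                      lower = c(0, 1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    stop("hyperbolic fit failed; series may be the linear binding phase")
  # curvature check: does the hyperbola beat a straight line?
  if (sum(stats::resid(fit)^2) > 0.95 * sum(stats::resid(lin)^2))
    warning("no detectable saturation: this looks like the binding phase ",
            "(linear in concentration)")
  co <- summary(fit)$coefficients
  list(k3_plus_km3 = unname(co["km3", 1] + co["k3", 1]),
       K_half = unname(co["Khalf", 1]),
       k_m3_intercept = unname(co["km3", 1]),
       k3_plus_km3_se = sqrt(sum(co[c("km3", "k3"), 2]^2)),
       K_half_se = unname(co["Khalf", 2]),
       k_m3_intercept_se = unname(co["km3", 2]),
       fitted = unname(stats::fitted(fit)))
}

#' Linear analysis of the binding-phase rate series
#'
#' Weighted linear regression kobs = k2 [I] + k_m2: the slope is the
#' bimolecular association constant and the intercept the physical
#' dissociation rate.
#'
#' @param series A \code{\link{kobs_series}} with >= 3 concentrations.
#' @return List with \code{slope} (1/(microM s)), \code{intercept} (1/s),
#'   standard errors and \code{fitted}.
#' @export
fit_kobs_linear <- function(series) {
  x <- series$ligand_concs
  if (length(x) < 3) stop("need at least 3 concentrations")
  w <- .series_weights(series)
  fit <- stats::lm(series$kobs ~ x, weights = w)
  co <- summary(fit)$coefficients
  list(slope = unname(co["x", 1]), intercept = unname(co["(Intercept)", 1]),
       slope_se = unname(co["x", 2]),
       intercept_se = unname(co["(Intercept)", 2]),
       fitted = unname(stats::fitted(fit)))
}

#' Concentration bound at equilibrium under tight binding
#'
#' Root of the quadratic [EI]^2 - ([I] + [Et] + KD) [EI] + [Et][I] = 0 on
#' the physical branch.
#' @param I Total ligand, microM (vectorised).
#' @param Et Total enzyme, microM.
#' @param KD Dissociation constant, microM.
#' @return Bound concentration, microM.
#' @export
tight_binding_bound <- function(I, Et, KD) {
  b <- I + Et + KD
  (b - sqrt(pmax(b^2 - 4 * Et * I, 0))) / 2
}

#' Tight-binding titration fit
#'
#' Fits F = F0 + A * bound([I]; Et, KD) by Levenberg-Marquardt, where
#' bound() is the quadratic tight-binding isotherm (valid when [Et] is
#' comparable to KD, unlike the hyperbolic approximation). The response A is
#' expressed per microM bound, so F([I] = 0) = F0 and F(Inf) = F0 + A Et.
#'
#' @param concs Total ligand concentrations, microM.
#' @param F Fluorescence signal, a.u.
#' @param Et Total enzyme (known), microM.
#' @return A list of class \code{titration_fit}: \code{F0}, \code{A},
#'   \code{KD} (microM), \code{Et}, standard errors and \code{fitted}.
#' @export
fit_titration <- function(concs, F, Et) {
  stopifnot(Et > 0, length(concs) == length(F))
  span <- max(F) - min(F)
  # KD fitted in log space so it stays positive without box constraints
  start <- list(F0 = unname(F[which.min(concs)]),
                A = sign(F[which.max(concs)] - F[which.min(concs)]) *
                  max(span / Et, 1e-8),
                lKD = log(max(stats::median(concs), 1e-9)))
  fit <- minpack.lm::nlsLM(
    F ~ F0 + A * tight_binding_bound(concs, Et, exp(lKD)), start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- summary(fit)$coefficients
  KD <- exp(unname(co["lKD", 1]))
  if (KD > max(concs))
    warning("KD exceeds the largest titrated concentration; ",
            "estimate is weakly constrained")
  structure(list(F0 = unname(co["F0", 1]), A = unname(co["A", 1]), KD = KD,
                 Et = Et, F0_se = unname(co["F0", 2]),
                 A_se = unname(co["A", 2]),
                 KD_se = KD * unname(co["lKD", 2]),
                 fitted = unname(stats::fitted(fit))),
            class = "titration_fit")
}

# Lorentzian peak: amplitude * (w/2)^2 / ((x - c)^2 + (w/2)^2), so the
# integral over x is amplitude * width * pi / 2 (area normalisation used
# throughout; widths are FWHM).
.lorentz <- function(x, center, hw) hw^2 / ((x - center)^2 + hw^2)

#' Deconvolve a 1D spectrum into Lorentzian lines
#'
#' Fits n_peaks Lorentzians A_i (w_i/2)^2 / ((x - c_i)^2 + (w_i/2)^2) to a
#' processed 1D spectrum by Levenberg-Marquardt from a deterministic grid of
#' initialisations seeded by peak picking. Widths (FWHM) are reported in Hz
#' via the spectrometer frequency; the peak integral is
#' amplitude * width_Hz * pi/2 (a.u. Hz). With \code{equal_integrals} the
#' integrals of all peaks are constrained equal (one shared area parameter),
#' the constraint used when signals are known to arise from equivalent
#' single spins.
#'
#' @param spectrum Data frame or list with \code{ppm} and \code{intensity}.
#' @param n_peaks Number of peaks (>= 1).
#' @param equal_integrals Constrain all integrals equal.
#' @param sfrq_mhz Spectrometer frequency for the observed nucleus (MHz),
#'   needed to convert ppm to Hz.
#' @param n_starts Initialisations per fit.
#' @return A list of class \code{lorentzian_fit}: \code{peaks} (data frame
#'   sorted by center: center_ppm, width_hz, amplitude, integral),
#'   \code{linewidth_ratio} (max/min FWHM), \code{rms}, \code{resolved}
#'   (logical), \code{fitted}.
#' @export
deconvolve_lorentzians <- function(spectrum, n_peaks, equal_integrals = FALSE,
                                   sfrq_mhz = 470.3, n_starts = 5) {
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  x <- spectrum$ppm
  y <- spectrum$intensity
  noise_floor <- stats::mad(y)
  if (max(y) <= 0 ||
      (noise_floor > 0 && max(y) - stats::median(y) < 5 * noise_floor) ||
      stats::sd(y) < 1e-12 * max(abs(y), 1e-300))
    stop("spectrum carries no signal to deconvolve (no peak rises above ",
         "the noise floor)")
  # peak picking: local maxima ranked by height
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  if (!length(is_max)) is_max <- which.max(y)
  is_max <- is_max[order(y[is_max], decreasing = TRUE)]
  centers0 <- x[is_max[seq_len(min(n_peaks, length(is_max)))]]
  while (length(centers0) < n_peaks)
    centers0 <- c(centers0, stats::median(x))
  w0_ppm <- diff(range(x)) / 40
  # parameters: centers (ppm), log10 half-widths (ppm), log10 amplitudes
  # (or one shared log10 area when equal_integrals)
  pack_model <- function(par) {
    centers <- par[seq_len(n_peaks)]
    hw <- 10^par[n_peaks + seq_len(n_peaks)]
    if (equal_integrals) {
      area <- 10^par[2 * n_peaks + 1]           # a.u. Hz
      amp <- 2 * area / (pi * 2 * hw * sfrq_mhz) # FWHM_hz = 2 hw sfrq
    } else {
      amp <- 10^par[2 * n_peaks + seq_len(n_peaks)]
    }
    rowSums(vapply(seq_len(n_peaks), function(i)
      amp[i] * .lorentz(x, centers[i], hw[i]), numeric(length(x))))
  }
  amp0 <- pmax(y[vapply(centers0, function(c0) which.min(abs(x - c0)),
                        integer(1))], max(y) * 1e-3)
  base_par <- c(centers0, rep(log10(w0_ppm / 2), n_peaks),
                if (equal_integrals)
                  log10(mean(amp0) * w0_ppm * sfrq_mhz * pi / 2)
                else log10(amp0))
  best <- NULL
  for (s in seq(-1, 1, length.out = max(1, n_starts))) {
    par0 <- base_par
    par0[n_peaks + seq_len(n_peaks)] <- par0[n_peaks + seq_len(n_peaks)] +
      s * 0.5 * (-1)^(seq_len(n_peaks))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = function(p) pack_model(p) - y,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("Lorentzian fit failed for all starts")
  par <- best$par
  centers <- par[seq_len(n_peaks)]
  hw_ppm <- 10^par[n_peaks + seq_len(n_peaks)]
  width_hz <- 2 * hw_ppm * sfrq_mhz
  if (equal_integrals) {
    area <- rep(10^par[2 * n_peaks + 1], n_peaks)
    amp <- 2 * area / (pi * width_hz)
  } else {
    amp <- 10^par[2 * n_peaks + seq_len(n_peaks)]
    area <- amp * width_hz * pi / 2
  }
  ord <- order(centers)
  peaks <- data.frame(center_ppm = centers[ord], width_hz = width_hz[ord],
                      amplitude = amp[ord], integral = area[ord])
  resolved <- TRUE
  if (n_peaks > 1) {
    hw_s <- hw_ppm[ord]
    for (i in seq_len(n_peaks - 1)) {
      sep <- peaks$center_ppm[i + 1] - peaks$center_ppm[i]
      if (sep < 0.5 * (hw_s[i] + hw_s[i + 1])) resolved <- FALSE
    }
  }
  if (!resolved)
    warning("peaks overlap within half their linewidths; ",
            "positions and widths are not independently resolved")
  structure(list(peaks = peaks,
                 linewidth_ratio = max(width_hz) / min(width_hz),
                 rms = sqrt(best$deviance / length(y)),
                 resolved = resolved,
                 fitted = pack_model(par)),
            class = "lorentzian_fit")
}
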