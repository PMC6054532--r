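# Deterministic synthetic-data generator: reproduces the study's experiment
# battery (stopped-flow association ladders, dilution dissociation,
# flow-cell double jumps, equilibrium titrations, 1D spectra) from the
# printed rate constants, with additive iid Gaussian noise at 1% of each
# trace's dynamic range by default (traces emulate averages of >= 5
# replicates, so low noise is realistic).

# mant-ATP induced-fit constants are not printed individually; they are
# derived once from the printed slow-phase plateau (k3 + k_m3 = 21/s) and
# the observed dissociation rate (17.2/s) via the dissociation-subsystem
# eigenvalue relation lambda^2 - lambda (k_m2 + k3 + k_m3) + k_m2 k_m3 = 0.
.mant_if_constants <- function(k_m2 = 50, plateau = 21, lambda_obs = 17.2) {
  k_m3 <- lambda_obs * (k_m2 + plateau - lambda_obs) / k_m2
  c(k3 = plateau - k_m3, k_m3 = k_m3)
}

.fixture_table <- function() {
  mant <- .mant_if_constants()
  list(
    gleevec_10C = list(
      mechanism = "cs_binding",
      constants = rate_constants(k1 = 0.014, k_m1 = 0.011, k2 = 1.1,
                                 k_m2 = 31),
      # fast decrease on binding, slow increase on conformational selection
      coefficients = c(E_in = 0.5, E_out = 1.0, "E_out.I" = 0.7),
      assoc_concs = 2 * (45 / 2)^(seq(0, 7) / 7),    # 2-45 microM ladder
      assoc_spans = c(0.25, 120),                    # two timescales, s
      enzyme = 0.5,
      dilution = list(enzyme = 5, ligand = 5, factor = 11, span = 0.25),
      double_jump = NULL,
      titration = list(Et = 1, concs = 0.37 * (40 / 0.37)^(seq(0, 7) / 7))),
    gleevec_25C = list(
      mechanism = "cs_binding",
      constants = rate_constants(k1 = 0.09, k_m1 = 0.06, k2 = 1.1,
                                 k_m2 = 31),
      coefficients = c(E_in = 0.5, E_out = 1.0, "E_out.I" = 0.7),
      assoc_concs = 2 * (45 / 2)^(seq(0, 7) / 7),
      assoc_spans = c(0.25, 60),
      enzyme = 0.5,
      dilution = list(enzyme = 5, ligand = 5, factor = 11, span = 0.25),
      double_jump = NULL,
      titration = list(Et = 1, concs = 0.37 * (40 / 0.37)^(seq(0, 7) / 7))),
    danusertib_25C = list(
      mechanism = "cs_binding_if",
      constants = rate_constants(k1 = 0.09, k_m1 = 0.06, k2 = 0.4,
                                 k_m2 = 6.8, k3 = 16, k_m3 = 7.1e-4),
      # fluorescence rises on binding and again on the induced fit; the
      # free states share one coefficient (conformational phase has nearly
      # zero amplitude at 25 degrees)
      coefficients = c(E_in = 0.5, E_out = 0.5, "E_out.I" = 0.8,
                       "E_out_star.I" = 1.2),
      assoc_concs = 0.25 * 2^(0:7),                  # 0.25-32 microM
      assoc_spans = c(2),
      enzyme = 0.5,
      dilution = list(enzyme = 0.03, ligand = 0.03, factor = 30,
                      span = 21600, step = 160),
      double_jump = list(ligand = 1, incubations = c(0.2, 0.4, 0.8, 2),
                         span = 60),
      titration = list(Et = 0.004,
                       concs = c(0.1, 0.2, 0.4, 0.8, 2.4, 7.2, 21.6,
                                 64.8) / 1000)),
    at9283_25C = list(
      mechanism = "branched",
      constants = rate_constants(k1 = 0.06, k_m1 = 0.09, k2 = 3.4,
                                 k_m2 = 1.0e-2, k3 = 0.79, k_m3 = 1.0e-2,
                                 k4 = 3.4, k_m4 = 10),
      coefficients = c(E_in = 0.5, E_out = 0.5, "E_in.I" = 0.9,
                       "E_in_star.I" = 1.3, "E_out.I" = 0.9),
      assoc_concs = 0.25 * 2^(0:7),
      assoc_spans = c(30),
      enzyme = 0.5,
      dilution = list(enzyme = 0.03, ligand = 0.03, factor = 30,
                      span = 10800, step = 40),
      double_jump = list(ligand = 1, incubations = c(1, 3), span = 60),
      titration = list(Et = 0.004,
                       concs = c(0.03, 0.27, 0.8, 2.4, 7.2, 21.6,
                                 64.8) / 1000)),
    mantATP_10C = list(
      mechanism = "binding_if",
      constants = rate_constants(k2 = 0.8, k_m2 = 50,
                                 k3 = unname(mant["k3"]),
                                 k_m3 = unname(mant["k_m3"])),
      coefficients = c(E = 0.3, "E.I" = 0.8, "E_star.I" = 1.2),
      assoc_concs = 5 * 2^(seq(0, 7) / 1.4),         # 5-160 microM
      assoc_spans = c(0.5),
      enzyme = 0.5,
      dilution = list(enzyme = 10, ligand = 10, factor = 11, span = 0.5),
      double_jump = NULL,
      titration = list(Et = 1, concs = 0.5 * (160 / 0.5)^(seq(0, 7) / 7))))
}

#' A named ligand fixture
#'
#' Returns the scheme (with generating constants), default observable
#' coefficients and the default protocol battery for one of the study's
#' ligand/temperature conditions.
#'
#' @param name One of \code{"gleevec_10C"}, \code{"gleevec_25C"},
#'   \code{"danusertib_25C"}, \code{"at9283_25C"}, \code{"mantATP_10C"}.
#' @return A list of class \code{ligand_fixture} with elements
#'   \code{name}, \code{mechanism}, \code{scheme}, \code{coefficients} and
#'   the protocol battery descriptors.
#' @export
ligand_fixture <- function(name) {
  tab <- .fixture_table()
  fx <- tab[[name]]
  if (is.null(fx))
    stop("unknown fixture; valid names: ",
         paste(names(tab), collapse = ", "))
  fx$name <- name
  fx$scheme <- canonical_scheme(fx$mechanism, fx$constants)
  class(fx) <- "ligand_fixture"
  fx
}

.add_noise <- function(signal, noise_frac) {
  span <- diff(range(signal))
  if (span <= 0) span <- max(abs(signal), 1)
  sigma <- noise_frac * span
  list(signal = signal + stats::rnorm(length(signal), 0, sigma),
       sigma = sigma)
}

#' Generate a synthetic experiment set for a fixture
#'
#' Simulates the fixture's full protocol battery (association traces over a
#' concentration ladder, dilution dissociation, double-jump where the study
#' performed one, equilibrium titration) from its generating constants and
#' adds iid Gaussian noise, deterministic given \code{seed}. With
#' \code{n_replicates > 1} each trace is the average of that many noisy
#' replicates, emulating the replicate averaging of the measurements.
#'
#' @param fixture A \code{\link{ligand_fixture}} or its name.
#' @param seed Integer seed (mandatory; all randomness flows from it).
#' @param noise_frac Noise s.d. as a fraction of each trace's dynamic range
#'   (default 0.01).
#' @param n_replicates Replicates averaged per trace.
#' @param overrides Named numeric vector replacing generating constants
#'   (unknown names are an error).
#' @param assoc_points,dj_points Samples per association / double-jump
#'   trace.
#' @return An \code{\link{experiment_set}} whose traces carry their true
#'   \code{noise_sigma}.
#' @export
make_dataset <- function(fixture, seed, noise_frac = 0.01, n_replicates = 1,
                         overrides = NULL, assoc_points = 120,
                         dj_points = 200) {
  if (is.character(fixture)) fixture <- ligand_fixture(fixture)
  if (missing(seed)) stop("seed is mandatory")
  scheme <- fixture$scheme
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), scheme_constant_names(scheme))
    if (length(bad))
      stop("overrides name unknown constant(s): ",
           paste(bad, collapse = ", "))
    scheme <- set_constants(scheme,
                            rate_constants_from_vectors(unlist(overrides)))
  }
  obs_fluor <- observable_map(fixture$coefficients, offset = 0.1)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  exps <- list()
  add <- function(protocol, observable, group) {
    clean <- propagate(scheme, protocol, observable)
    sigs <- replicate(n_replicates,
                      .add_noise(clean$signal, noise_frac)$signal)
    sigma <- noise_frac * max(diff(range(clean$signal)), 1e-12) /
      sqrt(n_replicates)
    tr <- kin_trace(clean$times, rowMeans(matrix(sigs, ncol = n_replicates)),
                    protocol, noise_sigma = sigma)
    exps[[length(exps) + 1]] <<- list(protocol = protocol, trace = tr,
                                      group = group)
  }
  for (span in fixture$assoc_spans) {
    for (conc in fixture$assoc_concs) {
      pr <- kin_protocol("association_mix", fixture$enzyme, conc,
                         sample_times = seq(0, span,
                                            length.out = assoc_points))
      add(pr, obs_fluor, "fluorescence")
    }
  }
  dl <- fixture$dilution
  if (!is.null(dl)) {
    step <- if (!is.null(dl$step)) dl$step else dl$span / 150
    pr <- kin_protocol("dilution_dissociation", dl$enzyme, dl$ligand,
                       dilution_factor = dl$factor,
                       sample_times = seq(0, dl$span, by = step))
    add(pr, obs_fluor, "fluorescence")
  }
  dj <- fixture$double_jump
  if (!is.null(dj)) {
    for (inc in dj$incubations) {
      # log-spaced sampling resolves both the fast (tens per second) escape
      # of the encounter complex and the long dissociation window
      st <- c(0, 10^seq(log10(2e-3), log10(dj$span),
                        length.out = dj_points - 1))
      pr <- kin_protocol("double_jump", fixture$enzyme, dj$ligand,
                         incubation_time = inc, dead_time = 0,
                         sample_times = st)
      add(pr, surface_observable(scheme), "surface")
    }
  }
  ti <- fixture$titration
  if (!is.null(ti)) {
    pr <- kin_protocol("equilibrium_titration", ti$Et, ti$concs)
    add(pr, surface_observable(scheme), "titration")
  }
  experiment_set(exps, fixture$name)
}

#' Generate a synthetic 1D spectrum
#'
#' Sum of Lorentzian lines (amplitude w^2/4 / ((x-c)^2 + w^2/4), FWHM w) on
#' a ppm grid plus iid Gaussian noise; deterministic given \code{seed}.
#'
#' @param centers Peak centers, ppm.
#' @param widths_hz FWHM linewidths, Hz (> 0).
#' @param integrals Peak areas, a.u. Hz.
#' @param noise_sigma Additive noise s.d., a.u.
#' @param seed Integer seed.
#' @param sfrq_mhz Spectrometer frequency, MHz.
#' @param ppm_range Two-element grid range; defaults to the peaks padded by
#'   ten mean linewidths.
#' @param n_points Grid size.
#' @return Data frame with \code{ppm} and \code{intensity}.
#' @export
make_spectrum <- function(centers, widths_hz, integrals, noise_sigma = 0,
                          seed = 1, sfrq_mhz = 470.3, ppm_range = NULL,
                          n_points = 2048) {
  n <- length(centers)
  if (length(widths_hz) != n || length(integrals) != n)
    stop("centers, widths_hz and integrals must have equal length")
  if (n > 0 && any(widths_hz <= 0)) stop("widths must be > 0")
  if (is.null(ppm_range)) {
    pad <- if (n) 10 * mean(widths_hz) / sfrq_mhz else 1
    ppm_range <- if (n) range(centers) + c(-pad, pad) else c(-1, 1)
  }
  x <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  y <- numeric(n_points)
  for (i in seq_len(n)) {
    hw <- widths_hz[i] / sfrq_mhz / 2           # half-width in ppm
    amp <- 2 * integrals[i] / (pi * widths_hz[i])
    y <- y + amp * hw^2 / ((x - centers[i])^2 + hw^2)
  }
  if (noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()))
    y <- y + stats::rnorm(n_points, 0, noise_sigma)
  }
  data.frame(ppm = x, intensity = y)
}
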