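# Phenomenological estimators: exponential fits, kobs-vs-concentration
# models, tight-binding titration, Lorentzian deconvolution.

test_that("noiseless exponential sums are recovered to 1e-6 relative", {
  t <- seq(0, 2, length.out = 200)
  one <- fit_exponentials(kin_trace(t, 2 * exp(-5 * t)), 1)
  expect_equal(one$rates, 5, tolerance = 1e-6)
  expect_equal(one$amplitudes, 2, tolerance = 1e-6)
  expect_equal(one$offset, 0, tolerance = 1e-6)

  t2 <- seq(0, 40, length.out = 400)
  two <- fit_exponentials(kin_trace(t2, exp(-10 * t2) -
                                      0.5 * exp(-0.1 * t2) + 1), 2)
  expect_equal(two$rates, c(10, 0.1), tolerance = 1e-6)
  expect_equal(two$amplitudes, c(1, -0.5), tolerance = 1e-6)
  expect_equal(two$offset, 1, tolerance = 1e-6)

  expect_error(fit_exponentials(kin_trace(1:5, 1:5), 1), "10 samples")
})

test_that("double-exponential fit of a simulated association matches the
          relaxation spectrum", {
  # binding + induced fit has exactly two relaxation modes, so the biphasic
  # fit must reproduce eigen_rates even at 1% noise
  sch <- canonical_scheme("binding_if", mant_atp_k)
  obs <- observable_map(c(E = 0.3, "E.I" = 0.8, "E_star.I" = 1.2),
                        offset = 0.1)
  ev <- eigen_rates(sch, 50)
  tr <- propagate(sch, kin_protocol("association_mix", 0.5, 50,
                                    dead_time = 0,
                                    sample_times = seq(0, 0.6,
                                                       length.out = 600)),
                  obs)
  set.seed(5)
  noisy <- kin_trace(tr$times,
                     tr$signal + rnorm(600, 0, 0.01 * diff(range(tr$signal))))
  fit <- fit_exponentials(noisy, 2)
  expect_equal(fit$rates[1], ev[2], tolerance = 0.03)
  expect_equal(fit$rates[2], ev[1], tolerance = 0.03)

  # three-step scheme: the dominant fitted phases track the two fastest
  # eigenvalues, biased slightly by the slow conformational-selection mode
  dsch <- canonical_scheme("cs_binding_if", danusertib_k)
  dobs <- observable_map(c(E_in = 0.5, E_out = 0.5, "E_out.I" = 2.0,
                           "E_out_star.I" = 1.0), offset = 0.1)
  dev <- eigen_rates(dsch, 8)
  dtr <- propagate(dsch, kin_protocol("association_mix", 0.5, 8,
                                      dead_time = 0,
                                      sample_times = seq(0, 1.5,
                                                         length.out = 600)),
                   dobs)
  set.seed(6)
  dnoisy <- kin_trace(dtr$times, dtr$signal +
                        rnorm(600, 0, 0.01 * diff(range(dtr$signal))))
  dfit <- fit_exponentials(dnoisy, 2)
  expect_equal(dfit$rates[1], dev[3], tolerance = 0.1)
  expect_equal(dfit$rates[2], dev[2], tolerance = 0.3)
})

test_that("conformational-selection fit recovers the DFG flip rates", {
  # exact limits first
  expect_equal(0.014 + 0.011, 0.025)  # kobs at [I] = 0 is k1 + k_m1
  sch <- canonical_scheme("cs_binding", gleevec_10C_k)
  concs <- seq(2, 45, length.out = 10)
  slow <- vapply(concs, function(L) eigen_rates(sch, L)[1], numeric(1))
  fit <- fit_kobs_conformational_selection(
    kobs_series(concs, slow, phase_label = "slow"), 0.5, 31 / 1.1)
  expect_equal(fit$k1, 0.014, tolerance = 0.05)
  expect_equal(fit$k_m1, 0.011, tolerance = 0.05)
  # fitted-curve limits: k1 + k_m1 at zero drug, k1 at saturation
  expect_equal(fit$k1 + fit$k_m1, 0.025, tolerance = 0.05)

  # a rising series is not conformational selection
  expect_error(fit_kobs_conformational_selection(
    kobs_series(concs, 0.1 + 0.01 * concs), 0.5, 28),
    "induced")
})

test_that("induced-fit hyperbola finds the plateau and intercept", {
  x <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
  y <- 5e-3 + 12 * x / (6 + x)
  fit <- fit_kobs_induced_fit(kobs_series(x, y))
  expect_equal(fit$k3_plus_km3, 12.005, tolerance = 1e-4)
  expect_equal(fit$K_half, 6, tolerance = 1e-3)
  expect_equal(fit$k_m3_intercept, 5e-3, tolerance = 1e-2)

  # constant series: plateau equals the constant, K_half flagged
  expect_warning(cf <- fit_kobs_induced_fit(kobs_series(x, rep(3, 8))),
                 "unidentifiable")
  expect_equal(cf$k3_plus_km3, 3)
  expect_true(is.na(cf$K_half))

  # a straight line has no saturation: advised to be the binding phase
  expect_error(fit_kobs_induced_fit(kobs_series(x, 1 + 2 * x)), "binding")
})

test_that("saturating ladders of the Danusertib eigen-spectrum plateau near
          the printed induced-fit rate", {
  sch <- canonical_scheme("cs_binding_if", danusertib_k)
  lad <- 2.5 * 2^(0:9)               # up to 1280 microM: deep saturation
  mid <- vapply(lad, function(L) sort(eigen_rates(sch, L))[2], numeric(1))
  fit <- fit_kobs_induced_fit(kobs_series(lad, mid))
  expect_equal(fit$k3_plus_km3, 16, tolerance = 2 / 16)  # printed 16 +/- 2
})

test_that("weighted linear kobs fit matches the generating line", {
  x <- seq(2, 45, length.out = 8)
  fit <- suppressWarnings(fit_kobs_linear(kobs_series(x, 1.1 * x + 31)))
  expect_equal(fit$slope, 1.1, tolerance = 1e-9)
  expect_equal(fit$intercept, 31, tolerance = 1e-9)
  cf <- suppressWarnings(fit_kobs_linear(kobs_series(x, rep(7, 8))))
  expect_equal(cf$slope, 0, tolerance = 1e-12)
  expect_error(fit_kobs_linear(kobs_series(c(1, 2), c(1, 2))), "3")
})

test_that("tight-binding bound concentration matches the quadratic root", {
  expect_equal(tight_binding_bound(22, 1, 22), oracle_bound(22, 1, 22),
               tolerance = 1e-10)
  expect_equal(tight_binding_bound(22, 1, 22), 0.4943189, tolerance = 1e-6)
  expect_equal(tight_binding_bound(0, 1, 22), 0)
  # vectorised and capped by both totals
  b <- tight_binding_bound(c(0.1, 1, 1e4), 1, 22)
  expect_true(all(b <= 1) && all(b <= c(0.1, 1, 1e4)))
})

test_that("titration fit recovers KD within 2 SE across noise realisations", {
  concs <- 0.5 * (160 / 0.5)^(seq(0, 15) / 15)
  truth <- 22
  clean <- 0.2 + 1 * tight_binding_bound(concs, 1, truth)
  hits <- 0
  set.seed(101)
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    FF <- clean + rnorm(length(concs), 0, 0.01 * diff(range(clean)))
    fit <- fit_titration(concs, FF, 1)
    if (abs(fit$KD - truth) <= 2 * fit$KD_se) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)

  # F([I]=0) = F0 on the fitted curve
  fit <- fit_titration(concs, clean, 1)
  expect_equal(fit$F0, 0.2, tolerance = 1e-4)
  expect_equal(fit$KD, 22, tolerance = 1e-3)

  # weakly constrained warning when KD is beyond the titrated range
  expect_warning(
    fit_titration(concs / 100, 0.2 + tight_binding_bound(concs / 100, 1, 22),
                  1), "weakly constrained")
})

test_that("Lorentzian deconvolution round-trips single and multiple peaks", {
  sp <- make_spectrum(0, 10, 1, noise_sigma = 0, sfrq_mhz = 470.3)
  fit <- deconvolve_lorentzians(sp, 1, sfrq_mhz = 470.3)
  expect_equal(fit$peaks$center_ppm, 0, tolerance = 1e-6)
  expect_equal(fit$peaks$width_hz, 10, tolerance = 1e-4)
  expect_equal(fit$peaks$integral, 1, tolerance = 1e-4)

  # four peaks, equal integrals, one five-fold broader: ratio recovered
  sp4 <- make_spectrum(c(-1.2, -0.4, 0.5, 1.3), c(10, 10, 50, 10),
                       rep(1, 4), noise_sigma = 2e-4, seed = 9)
  fit4 <- deconvolve_lorentzians(sp4, 4, equal_integrals = TRUE)
  expect_equal(fit4$linewidth_ratio, 5, tolerance = 0.05)
  expect_equal(fit4$peaks$integral, rep(fit4$peaks$integral[1], 4))

  # two peaks closer than a fraction of their width are flagged unresolved
  hw_ppm <- 10 / 470.3 / 2
  spc <- make_spectrum(c(0, 0.2 * 2 * hw_ppm), c(10, 10), c(1, 1))
  expect_warning(fitc <- deconvolve_lorentzians(spc, 2), "resolved")
  expect_false(fitc$resolved)

  expect_error(deconvolve_lorentzians(sp, 0), "n_peaks")
  flat <- make_spectrum(numeric(0), numeric(0), numeric(0),
                        noise_sigma = 1e-3, seed = 2)
  expect_error(deconvolve_lorentzians(flat, 1), "no signal")
})
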