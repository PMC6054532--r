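# Forward simulation: protocol propagation, conservation, equilibrium
# consistency and pseudo-first-order relaxation rates.

test_that("association of Gleevec at 10C is biphasic on the right scales", {
  sch <- canonical_scheme("cs_binding", gleevec_10C_k)
  obs <- observable_map(c(E_in = 0.5, E_out = 1.0, "E_out.I" = 0.7),
                        offset = 0.1)
  fast <- propagate(sch, kin_protocol("association_mix", 0.5, 4.5,
                                      sample_times = seq(0, 0.25,
                                                         length.out = 200)),
                    obs)
  # fast phase: signal decreases and is complete within 0.25 s
  expect_lt(fast$signal[200], fast$signal[1])
  k_fast <- 1.1 * 4.5 + 31   # pseudo-first-order binding rate
  drop_total <- fast$signal[1] - min(fast$signal)
  at_5tau <- fast$signal[which.min(abs(fast$times - 5 / k_fast))]
  expect_lt(abs(at_5tau - min(fast$signal)), 0.05 * drop_total)

  # slow phase: fluorescence rises over hundreds of seconds at ~k_slow
  slow <- propagate(sch, kin_protocol("association_mix", 0.5, 4.5,
                                      sample_times = seq(0.5, 400,
                                                         length.out = 200)),
                    obs)
  expect_gt(slow$signal[200], slow$signal[1])
  rise <- slow$signal[200] - slow$signal[1]
  mid <- slow$signal[which.min(abs(slow$times - 60))] - slow$signal[1]
  expect_gt(mid / rise, 0.5)  # appreciable progress only after tens of s
})

test_that("zero ligand reduces association to conformational relaxation", {
  sch <- canonical_scheme("cs_binding", gleevec_10C_k)
  obs <- observable_map(c(E_in = 1, E_out = 0))
  tr <- propagate(sch, kin_protocol("association_mix", 1, 0,
                                    sample_times = seq(0, 300,
                                                       length.out = 50)),
                  obs)
  # free-state start is already at conformational equilibrium, so the
  # trajectory is flat...
  expect_lt(diff(range(tr$signal)), 1e-9)
  # ...and the free subsystem relaxes at k1 + k_m1 (the slow eigenvalue at
  # zero ligand; the fast one is the k_m2 drain of the empty complex)
  expect_equal(eigen_rates(sch, 0)[1], 0.014 + 0.011, tolerance = 1e-12)
})

test_that("totals are conserved along every protocol trajectory", {
  sch <- canonical_scheme("cs_binding_if", danusertib_k)
  enz <- c("E_in", "E_out", "E_out.I", "E_out_star.I")
  lig <- c("I", "E_out.I", "E_out_star.I")
  obs <- observable_map(c(E_in = 0.5, E_out = 0.5, "E_out.I" = 0.8,
                          "E_out_star.I" = 1.2))
  assoc <- propagate(sch, kin_protocol("association_mix", 0.5, 2,
                                       sample_times = seq(0, 100,
                                                          length.out = 80)),
                     obs)
  expect_lt(max(abs(rowSums(assoc$species[, enz]) - 0.5)) / 0.5, 1e-9)
  expect_lt(max(abs(rowSums(assoc$species[, lig]) - 2)) / 2, 1e-9)

  dil <- propagate(sch, kin_protocol("dilution_dissociation", 0.03, 0.03,
                                     dilution_factor = 30,
                                     sample_times = seq(0, 2000,
                                                        length.out = 60)),
                   obs)
  tot <- 0.03 / 30
  expect_lt(max(abs(rowSums(dil$species[, enz]) - tot)) / tot, 1e-9)
  expect_lt(max(abs(rowSums(dil$species[, lig]) - tot)) / tot, 1e-9)
})

test_that("long-time ODE state matches the algebraic equilibrium", {
  for (id in c("cs_binding", "binding_if", "cs_binding_if", "branched")) {
    need <- scheme_constant_names(canonical_scheme(id))
    kv <- stats::setNames(
      c(k1 = 0.05, k_m1 = 0.08, k2 = 1.2, k_m2 = 8, k3 = 3, k_m3 = 0.4,
        k4 = 0.7, k_m4 = 5)[need], need)
    sch <- canonical_scheme(id, rate_constants_from_vectors(kv))
    sp <- vapply(sch$species, `[[`, character(1), "name")
    obs <- observable_map(stats::setNames(rep(1, length(sp)), sp))
    tr <- propagate(sch, kin_protocol("association_mix", 0.5, 5,
                                      sample_times = c(0, 2000, 4000)),
                    obs)
    eq <- equilibrium_concentrations(sch, 0.5, 5)
    expect_equal(unname(tr$species[3, sp]), unname(eq[sp]),
                 tolerance = 1e-6)
  }
})

test_that("long-time occupancy matches the closed-form KD", {
  # association at ligand = 10 x KD: occupancy from the closed form
  sch <- canonical_scheme("cs_binding_if", danusertib_k)
  KD <- kd_overall("cs_binding_if", danusertib_k)$KD
  Et <- 1e-4                      # trace enzyme so ligand stays ~free
  L <- 10 * KD
  obs <- observable_map(c("E_out.I" = 1, "E_out_star.I" = 1))
  tr <- propagate(sch, kin_protocol("association_mix", Et, L,
                                    sample_times = c(0, 2e4, 4e4)), obs)
  bound <- sum(tr$species[3, c("E_out.I", "E_out_star.I")])
  occupancy <- bound / Et
  expect_equal(occupancy, L / (L + KD), tolerance = 1e-3)
})

test_that("pseudo-first-order exponential fits agree with eigen_rates", {
  sch <- canonical_scheme("cs_binding", gleevec_10C_k)
  obs <- observable_map(c(E_in = 0.5, E_out = 1.0, "E_out.I" = 0.7))
  L <- 20      # 40x enzyme
  rates <- eigen_rates(sch, L)
  tr <- propagate(sch, kin_protocol("association_mix", 0.5, L, dead_time = 0,
                                    sample_times = seq(0, 0.25,
                                                       length.out = 300)),
                  obs)
  fit <- fit_exponentials(kin_trace(tr$times, tr$signal), 1)
  expect_equal(fit$rates[1], rates[2], tolerance = 0.02)
})

test_that("eigen_rates of the binding phase are linear in concentration", {
  sch <- canonical_scheme("cs_binding", gleevec_10C_k)
  concs <- seq(2, 45, length.out = 8)
  fast <- vapply(concs, function(L) eigen_rates(sch, L)[2], numeric(1))
  fit <- fit_kobs_linear(kobs_series(concs, fast))
  expect_equal(fit$slope, 1.1, tolerance = 1e-3)
  expect_equal(fit$intercept, 31, tolerance = 1e-2)
})

test_that("double jump with long incubation reproduces dilution decay", {
  sch <- canonical_scheme("cs_binding_if", danusertib_k)
  st <- 10^seq(-2, log10(5000), length.out = 60)
  dj <- propagate(sch, kin_protocol("double_jump", 0.5, 1,
                                    incubation_time = 5e4, dead_time = 0,
                                    sample_times = st),
                  surface_observable(sch))
  # equilibrated complex, then an essentially infinite dilution (free
  # ligand far below KD, so no rebinding)
  dil <- propagate(sch, kin_protocol("dilution_dissociation", 0.5, 1,
                                     dilution_factor = 1e7, dead_time = 0,
                                     sample_times = st),
                   surface_observable(sch))
  bcols <- c("E_out.I", "E_out_star.I")
  f_dj <- rowSums(dj$species[, bcols]) / sum(dj$species[1, bcols])
  f_dil <- rowSums(dil$species[, bcols]) / sum(dil$species[1, bcols])
  expect_equal(f_dj, f_dil, tolerance = 1e-3)
})

test_that("surface-mass observables reject unequal coefficients", {
  sch <- canonical_scheme("cs_binding_if", danusertib_k)
  expect_error(observable_map(c("E_out.I" = 1, "E_out_star.I" = 2),
                              mode = "surface_mass", scheme = sch),
               "share")
  expect_error(observable_map(c(E_in = 1, "E_out.I" = 1,
                                "E_out_star.I" = 1),
                              mode = "surface_mass", scheme = sch),
               "free species")
})

test_that("photobleaching multiplies the signal by a decaying exponential", {
  sch <- canonical_scheme("cs_binding", gleevec_10C_k)
  pr <- kin_protocol("association_mix", 0.5, 0,
                     sample_times = seq(0, 100, length.out = 20))
  base <- propagate(sch, pr, observable_map(c(E_in = 1, E_out = 1)))
  bleach <- propagate(sch, pr, observable_map(c(E_in = 1, E_out = 1),
                                              photobleach_rate = 0.01))
  expect_equal(bleach$signal,
               base$signal * exp(-0.01 * (pr$sample_times + pr$dead_time)),
               tolerance = 1e-10)
})
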