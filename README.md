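# kinbind

Kinetic dissection of multi-step drug binding to conformationally dynamic
protein kinases.

Protein kinases interconvert between an active (DFG-in) and an inactive
(DFG-out) conformation, and ATP-competitive inhibitors engage them through
combinations of three elementary steps: conformational selection of a
binding-competent state, the physical binding step, and an induced-fit
conformational change of the drug-bound complex. Which steps a drug uses
determines its affinity, selectivity and residence time. `kinbind`
implements the full analysis workflow used to resolve such mechanisms from
stopped-flow fluorescence, dilution-dissociation, surface double-jump and
equilibrium-titration data:

- **Schemes** — declarative mass-action models of the four canonical
  mechanisms (`canonical_scheme`: `cs_binding`, `binding_if`,
  `cs_binding_if`, `branched`) and arbitrary user schemes, with JSON
  serialisation.
- **Simulation** — stiff ODE propagation of any scheme under the four
  experiment protocols (`propagate`), algebraic equilibria, and exact
  pseudo-first-order relaxation spectra (`eigen_rates`).
- **Trace analysis** — multi-exponential fits, the observed-rate versus
  concentration models for conformational selection (decreasing kobs),
  induced fit (saturating kobs) and binding (linear kobs), the
  tight-binding quadratic titration fit, and Lorentzian deconvolution of
  1D spectra.
- **Mechanism calculators** — closed-form macroscopic K_D from microscopic
  constants with first-order error propagation (`kd_overall`,
  `propagate_uncertainty`), the conformational-selection affinity penalty
  (K1 + 1) (`cs_penalty`), and kinetic-partitioning predictions of observed
  off-rates (`predict_observed_off`).
- **Global fitting** — simultaneous weighted least squares over
  heterogeneous experiments with shared rate constants, profiled observable
  coefficients, multi-start Levenberg–Marquardt in log space,
  identifiability flags, and AIC model ranking (`global_fit`,
  `compare_models`).
- **Synthetic data** — a deterministic generator reproducing the study
  batteries of five ligand fixtures from published rate constants
  (`make_dataset`, `make_spectrum`), so every stage is testable without
  instrument data.

The macroscopic dissociation constants follow directly from the step
equilibrium constants K1 = k₋₁/k₁, K2 = k₋₂/k₂ (µM), K3 = k₋₃/k₃,
K4 = k₋₄/k₄ (µM):

| mechanism | K_D |
|---|---|
| conformational selection + binding | (K1+1)·K2 |
| binding + induced fit | K2·K3/(K3+1) |
| selection + binding + induced fit | (K1+1)·K2·K3/(K3+1) |
| branched (both states bind, in-state induced fit) | (K1+1)·K2·K3·K4/(K1·K2·K3 + K3·K4 + K4) |

## Worked example

An Aurora-kinase-like three-step binder (conformational selection at
k₁ = 0.09 s⁻¹ / k₋₁ = 0.06 s⁻¹, binding at k₂ = 0.4 µM⁻¹s⁻¹ /
k₋₂ = 6.8 s⁻¹, induced fit at k₃ = 16 s⁻¹ / k₋₃ = 7.1×10⁻⁴ s⁻¹):

```r
library(kinbind)

k <- rate_constants(k1 = 0.09, k_m1 = 0.06, k2 = 0.4, k_m2 = 6.8,
                    k3 = 16, k_m3 = 7.1e-4)

kd_overall("cs_binding_if", k)$KD * 1000
#> [1] 1.257236
cs_penalty(k)$penalty
#> [1] 1.666667
predict_observed_off("cs_binding_if", k)$lambda_slow
#> [1] 0.0002117498
```

Reading: the overall K_D is 1.26 nM even though the binding step alone is
17 µM — the far-shifted induced fit (K3 ≈ 4.4×10⁻⁵) tightens binding by
four orders of magnitude, while the conformational pre-equilibrium costs a
1.67-fold weakening. After drug removal the complex dissociates at
2.1×10⁻⁴ s⁻¹, three-fold slower than the microscopic reverse induced-fit
rate, because the encounter complex is re-trapped (kinetic partitioning:
escape probability k₋₂/(k₋₂+k₃) ≈ 0.30).

A full synthetic study and its global fit:

```r
ds  <- make_dataset("danusertib_25C", seed = 7)    # 14 experiments
fx  <- ligand_fixture("danusertib_25C")
fit <- global_fit(ds, fx$scheme, fixed = c("k1", "k_m1"), seed = 1)
fit$estimates    # recovers the generating constants
```

A thin command-line wrapper over the same functions ships at
`inst/cli/kinbind.R` (`generate`, `simulate`, `analyze`, `fit`, `compare`,
`report`).

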