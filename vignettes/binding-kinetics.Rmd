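---
title: "Dissecting multi-step inhibitor binding to a conformationally dynamic kinase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting multi-step inhibitor binding to a conformationally dynamic kinase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinbind)
```

## The problem

ATP-competitive kinase inhibitors rarely bind in a single step. The kinase
itself interconverts between an active (DFG-in) and an inactive (DFG-out)
conformation, the drug's physical binding step is followed in many cases by
a conformational change of the complex (induced fit), and some ligands can
engage both DFG states. Which of these steps an inhibitor exploits decides
its affinity, its selectivity and its residence time on the target. The
experiments that resolve the steps — stopped-flow fluorescence mixing,
dilution dissociation, surface (waveguide-interferometry) double jumps and
equilibrium titrations — each see only projections of the mechanism, so the
microscopic rate constants must be extracted by globally fitting all of
them at once against an explicit mass-action model.

`kinbind` implements that workflow end to end: declarative kinetic schemes,
a stiff forward simulator for each experiment protocol, the standard
phenomenological estimators, closed-form macroscopic dissociation
constants, kinetic-partitioning predictions and a global fitting engine,
plus a synthetic-data generator so the whole pipeline can be validated
without any instrument.

## The four canonical mechanisms

With K1 = k~-1~/k1 (conformational pre-equilibrium), K2 = k~-2~/k2 (physical
binding, in µM), K3 = k~-3~/k3 (induced fit) and K4 = k~-4~/k4 (second
binding step), the macroscopic dissociation constants are

* conformational selection then binding (`cs_binding`):
  K~D~ = (K1 + 1) K2
* binding then induced fit (`binding_if`):
  K~D~ = K2 K3 / (K3 + 1)
* conformational selection, binding, induced fit (`cs_binding_if`):
  K~D~ = (K1 + 1) K2 K3 / (K3 + 1)
* binding to both conformations with an induced-fit step only from the
  in-state complex (`branched`):
  K~D~ = (K1 + 1) K2 K3 K4 / (K1 K2 K3 + K3 K4 + K4).

Two factors do all the work: a conformational pre-equilibrium always
*weakens* affinity by (K1 + 1), while a far-shifted induced-fit step
*tightens* it by K3/(K3 + 1). The branched scheme deliberately has no edge
between its two ligand-bound branches, so none of these mechanisms contains
a thermodynamic cycle and no detailed-balance constraint is needed (the
scheme validator asserts acyclicity).

```{r}
k <- rate_constants(k1 = 0.09, k_m1 = 0.06, k2 = 0.4, k_m2 = 6.8,
                    k3 = 16, k_m3 = 7.1e-4)
kd_overall("cs_binding_if", k)$KD * 1000   # nM
cs_penalty(k)$penalty                      # fold-weakening by (K1 + 1)
```

## Units, conventions, numerical choices

* Concentrations are µM and times are seconds everywhere inside the
  package; conversions happen only at I/O boundaries. All printed constants
  in the literature this package targets are in those units, which is the
  cheapest way to avoid unit bugs.
* Rate constants are stored in linear space; the global fitter transforms
  to log10 internally because the constants span five decades (about 7e-4
  to 50 s^-1^).
* The ODE integrator is `deSolve::lsoda` with rtol 1e-8 / atol 1e-10.
  Fixed-step explicit methods were rejected: the schemes are stiff (five
  decades of rates in one system).
* Stopped-flow dead time defaults to 1.5 ms; the observable is evaluated
  that long after mixing, which is why sub-millisecond events are invisible
  in the simulated traces, exactly as on the instrument.
* Photobleaching is modelled as signal × exp(−rate·t) and is off by
  default.
* Equilibria are computed algebraically, not by long pre-integration: the
  acyclic schemes let every species be expressed through step equilibrium
  constants relative to a reference state, and ligand conservation then
  becomes a monotone scalar root-finding problem solved essentially to
  machine precision. Dilution protocols pre-equilibrate with this solver
  and then divide all concentrations by the dilution factor.
* Double jumps approximate the flow cell by clamping the free-ligand
  concentration: constant during the association segment, zero during
  dissociation. No mass-transport limitation is modelled.

## Phenomenological estimators

`fit_exponentials` fits signed sums of exponentials by variable projection
(amplitudes and offset profiled out linearly, rates optimised in log space)
from a deterministic grid of initialisations; standard errors come from the
full-model Jacobian. `fit_kobs_conformational_selection` implements the
rapid-equilibrium result kobs = k1 + k~-1~/(1 + [I]/([E] + k~-2~/k2)). The
grouping of the concentration term was chosen because it reproduces both
limits that identify conformational selection — kobs → k1 + k~-1~ at zero
drug and kobs → k1 at saturation — and once the concentration term is fixed
the model is *linear* in k1 and k~-1~, so the fit is an exact weighted
regression. `fit_kobs_induced_fit` fits the saturating hyperbola
kobs = k~-3~ + k3[I]/(K~half~ + [I]); K~half~ is reported but deliberately
not interpreted. `fit_titration` uses the tight-binding quadratic isotherm
(valid when the enzyme concentration is comparable to K~D~), with K~D~
fitted in log space so it stays positive without box constraints.

A caveat the estimators make explicit: the textbook phase labels ("fast
phase = binding, slow phase = induced fit") are rapid-equilibrium
approximations. With the Danusertib-like constants (k~-2~ = 6.8 s^-1^,
k3 = 16 s^-1^) the fast relaxation eigenvalue is close to
k2[I] + k~-2~ + k3, not k2[I] + k~-2~, and the hyperbolic plateau estimate
converges to k3 + k~-3~ only when the concentration ladder genuinely
saturates the binding step. The package therefore exposes `eigen_rates`,
the exact relaxation spectrum under the pseudo-first-order approximation,
and the tests compare fitted rates against those eigenvalues rather than
against the approximate labels.

`deconvolve_lorentzians` fits peak shapes A (w/2)^2^/((x−c)^2^ + (w/2)^2^),
so the integral is A·w·π/2 (widths are FWHM, reported in Hz through the
spectrometer frequency). With `equal_integrals` the areas are constrained
to a single shared parameter — the right constraint when all signals are
known to come from equivalent single spins — which is what makes a 5-fold
linewidth outlier (a severely exchange-broadened resonance next to a mobile
loop) unambiguous. Peaks closer than half their combined linewidths are
flagged unresolved.

## Kinetic partitioning

After free drug is removed, the encounter complex partitions between escape
(k~-2~) and re-trapping into the tightened complex (k3). The observed
off-rate is the slow eigenvalue of the bound subsystem with escape
irreversible — always at most k~-3~, and ≈ k~-3~·k~-2~/(k~-2~ + k3 + k~-3~)
when the reverse induced fit is slow. This is why a dilution experiment can
report an off-rate several-fold slower than the microscopic reverse
induced-fit constant obtained by global fitting; the two numbers are
consistent, not contradictory.

```{r}
predict_observed_off("cs_binding_if", k)$lambda_slow   # 1/s
```

## Global fitting

`global_fit` shares the rate constants across all traces and profiles the
observable parameters out linearly at every iteration: fluorescence traces
get an offset plus one coefficient per enzyme-containing species, shared
across concentrations within an experiment group; surface traces get a
single bound-mass response. The nonlinear search (Levenberg–Marquardt,
log10 parameters, bounds 1e-6 to 1e4 in natural units) therefore runs only
over the rate constants. Multi-start initialisation (default 8 log-uniform
perturbations, seeded) guards against the local minima that make kinetic
intuition unreliable for multi-step schemes. Weights are 1/sigma^2^ with
sigma taken from the trace's recorded noise level or estimated from
late-time first differences. Standard errors come from the Jacobian at the
optimum; the reduced chi-square uses dof = points − free parameters
(including the profiled linear ones).

Two reporting tiers describe weak parameters: `poorly_determined` (standard
error above a quarter of the value — the conventional point at which a
kineticist stops quoting a number) and `unidentifiable` (standard error
above ten times the value, i.e. structurally undetermined). In the
synthetic Danusertib battery the physical dissociation rate k~-2~ moves
from ~1% relative error to ~30% when the double-jump traces are removed —
poorly determined, though not structurally unidentifiable, which
recapitulates why the double-jump experiment is worth performing at all.

`compare_models` ranks candidate schemes by AIC (chi-square + 2p, Gaussian
errors with known sigma); a model whose reduced chi-square exceeds the best
model's by more than 3× is marked failed, the operational version of a
mechanism that "cannot explain the data".

## The synthetic-data generator

`make_dataset` reproduces the study's experiment battery for five
ligand/temperature fixtures (Gleevec at 10 °C and 25 °C, Danusertib and
AT9283 at 25 °C, mant-ATP at 10 °C) from the published rate constants:
an 8-point association ladder, a dilution-dissociation decay, double jumps
where the study performed them (Danusertib 0.2/0.4/0.8/2 s, AT9283 1/3 s,
both at 1 µM drug), and an equilibrium titration over the published
concentration ranges. Noise is additive iid Gaussian at 1% of each trace's
dynamic range — realistic because the emulated measurements are averages of
at least five replicates — and everything is deterministic given the seed.

Choices worth knowing about:

* Association ladders are geometric. Where the study names only the
  titration range in its captions, the association ladder is the package's
  choice (Danusertib/AT9283: 0.25–32 µM; Gleevec: 2–45 µM, the range of the
  published rate plot; mant-ATP: 5–160 µM).
* Double-jump dissociation is sampled log-spaced from 2 ms to 60 s. The
  surface instrument resolves the ~23 s^-1^ escape of the encounter
  complex; uniform sampling at the window scale would alias that decay and
  wash out most of the information that makes k~-2~ identifiable.
* Fluorescence coefficients per fixture reproduce the published signal
  directions (Gleevec: fast decrease then slow increase; the others:
  increases), with the two free states given equal coefficients for
  Danusertib at 25 °C, where the conformational-selection phase had
  vanishing amplitude.
* The mant-ATP induced-fit pair is not published directly; the fixture
  derives k3 and k~-3~ once from the published plateau (21 s^-1^) and
  observed off-rate (17.2 s^-1^) through the dissociation-subsystem
  eigenvalue relation.
* The AT9283 fixture's out-state binding step (k4, k~-4~) is not published;
  the fixture uses k4 = 3.4 µM^-1^s^-1^ (physical binding like the in-state
  step) and k~-4~ = 10 s^-1^ (weak, no induced fit behind it) as documented
  package choices. The 25 °C Gleevec fixture carries the 10 °C binding-step
  constants because binding at 25 °C was too fast to measure; it is only
  used for the conformational step.

What the generator does *not* emulate: lamp flicker, refractive-index
jumps, inner-filter effects, mass-transport limitation in the flow cell, or
temperature dependence. Passing tests on these synthetic data therefore
demonstrate that the estimators and the global fitter are correct and
well-conditioned under the published kinetic regimes — not that they are
robust to every instrument artifact of real traces.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full Danusertib battery
(14 experiments, ≈1900 points) through the global fitter with the
conformational-step rates fixed as knowns, two multi-starts and a two-fold
perturbed initial guess; smaller two-step datasets are used for the
coverage and invariance properties. These sizes were chosen so the whole
validation runs in minutes on one core while leaving every parameter of
interest identifiable. All randomness flows from explicit seeds; fits are
deterministic given seed up to the optimizer's stopping tolerance in flat
directions.

## Known limitations

* Error propagation assumes independent uncertainties on the microscopic
  constants (no covariances are available from the published fits).
* The pseudo-first-order eigenvalue analysis treats the ligand as clamped;
  at ligand-to-enzyme ratios below ~20 the exact relaxation rates shift.
* Variable-projection standard errors ignore the (small) correlation
  between rate constants and the profiled observable coefficients.
* The branched scheme's out-state branch is kinetically silent in most
  observables; its constants are only weakly testable.
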