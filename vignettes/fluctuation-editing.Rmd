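---
title: "Fluctuation editing: models, fitting choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation editing: models, fitting choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctedit)
```

## The problem

Affinity maturation of antibodies usually targets the
complementarity-determining regions (CDRs), the loops that contact the
antigen. *Fluctuation editing* takes the opposite route: it looks for
residues **outside** the CDR whose millisecond-timescale conformational
exchange, measured by CPMG relaxation dispersion, suggests that they
destabilise the binding-competent conformation; mutating such a residue to
alanine can damp the fluctuation and increase affinity. This package
implements the quantitative core of that workflow on an antibody Fv
fragment (paired heavy- and light-chain variable domains): dispersion
model fitting, candidate selection, mutant evaluation by calorimetry, and
bound-form ensemble analysis, together with seeded generators that make
every stage testable against known ground truth.

## Two-state exchange models

A nucleus exchanging between a major and a minor conformation with rate
$k_\mathrm{ex} = k_{AB} + k_{BA}$, minor population $p_B$ and chemical-shift
difference $\Delta\omega$ relaxes with an effective rate
$R_{2,\mathrm{eff}}(\nu_\mathrm{CPMG})$ that decreases as the CPMG pulsing
frequency grows. We use the convention
$\nu_\mathrm{CPMG} = 1/(2\tau_\mathrm{cp})$ with $\tau_\mathrm{cp}$ the
delay between consecutive 180° pulses.

Three forward models are provided:

* **Luz–Meiboom** (`luz_meiboom_r2eff()`), valid in fast exchange
  ($k_\mathrm{ex} \gg \Delta\omega$):
  $R_{2,\mathrm{eff}} = R_2^0 + \frac{\Phi}{k_\mathrm{ex}}
  \left[1 - \frac{4\nu}{k_\mathrm{ex}}
  \tanh\frac{k_\mathrm{ex}}{4\nu}\right]$, where
  $\Phi = p_A p_B \Delta\omega^2$ is the only shift/population combination
  identifiable in this regime.
* **Carver–Richards** (`carver_richards_r2eff()`), the closed form for
  two-state exchange with equal intrinsic rates, valid through slow and
  intermediate exchange, parameterised by $p_B$ and $\Delta\omega$.
* A numerical **Bloch–McConnell propagator**
  (`bloch_mcconnell_r2eff()`) that evolves the two-state transverse
  magnetization through an explicit echo train with ideal refocusing
  pulses, using closed-form exponentials of the $2\times 2$ complex
  evolution operator per half-echo.

The propagator is the package's single source of truth for prefactor
conventions: the exact $\eta_\pm$, $D_\pm$ normalisations of the
Carver–Richards form differ between papers, so ours are pinned by requiring
agreement with the propagator rather than by citation. Amplitudes are
carried in ppm ($\Delta\delta$ or $\Phi_\mathrm{ppm^2}$) and converted to
rad/s per static field with the ¹⁵N/¹H frequency ratio 0.10136767, so one
parameter set predicts every field and the $B_0^2$ scaling of $\Phi$ is
automatic.

Two numerical points deserve mention. First, the closed forms describe the
*asymptotic* decay rate of the slowly-relaxing eigenmode, while the
propagator reports the intensity-based rate $-\ln(|M_A(T)|/|M_A(0)|)/T$;
the two differ by a projection offset of order $1/T$ that can reach
0.5 s⁻¹ for strong dispersions at the experimental 40 ms constant-time
period. The oracle-equivalence checks therefore use a 1 s period, where
the worst closed-form/propagator discrepancy over a 100-set grid spanning
slow, intermediate and fast exchange is below 0.03 s⁻¹; that is what the
"agreement within 0.05 s⁻¹" contract tests — conventions, not
finite-duration effects. Second, in deep slow exchange
($k_\mathrm{ex} \ll \Delta\omega$) CPMG profiles genuinely oscillate with
$\nu_\mathrm{CPMG}$ (the $\cos\eta_-$ term); monotone decay is only
asserted for $k_\mathrm{ex}/\Delta\omega \ge 0.5$. arccosh arguments
pushed below 1 by floating rounding are clamped to 1 and counted
(`acosh_clamp_count()`), never raised.

## Global cluster fitting

`fit_dispersion()` performs the global fit: all residues in a cluster share
one $k_\mathrm{ex}$ (and, for Carver–Richards, optionally one $p_B$),
amplitudes are per residue in ppm, and $R_2^0$ is free per residue per
field. The objective is the standard weighted least squares
$\sum \left[(R_{2,\mathrm{eff}}^\mathrm{obs} - R_{2,\mathrm{eff}}^\mathrm{model})/\sigma\right]^2$.
Because the model is linear in $R_2^0$, those parameters are profiled out
analytically inside the optimiser (their information-matrix contribution
is restored afterwards, so degrees of freedom and standard errors count
them as free parameters). A multi-start strategy over eight log-spaced
$k_\mathrm{ex}$ values between 50 and 5000 s⁻¹ guards against local
minima; the fit is deterministic given the data and configuration, and the
start log is kept in the returned object. Parameter errors come from the
covariance at the optimum; a leave-one-point-out jackknife for
$k_\mathrm{ex}$ is available behind a flag.

Before fitting, `exclude_flat_curves()` removes residues whose effective
R2 changed by less than 1 s⁻¹ over the whole frequency range on every
field — the standard pre-filter for non-dispersive residues; the rule is
strict (a range of exactly 1 s⁻¹ is kept), idempotent and
order-independent, and every exclusion is logged with its range.

Model and regime selection follow the classical recipe: fits are compared
by reduced $\chi^2$ and by the F test
$F = \frac{(\chi^2_s - \chi^2_c)/(\mathrm{dof}_s - \mathrm{dof}_c)}
{\chi^2_c/\mathrm{dof}_c}$, selecting the more complex model at
$\alpha = 0.05$ (the level is our choice; ties and negative numerators
keep the simple model). `cluster_search()` fits alternative residue
partitions, ranks them by total reduced $\chi^2$ and reports F tests
between nested partitions. Measurement errors are taken from the input
table; if absent they are estimated from replicate $\nu_\mathrm{CPMG}$
points, falling back to a floor of 0.2 s⁻¹.

## Candidate selection

`select_candidates()` applies four criteria; a residue is a mutation
candidate iff it

1. displays relaxation dispersion (survived exclusion and fitting),
2. lies outside the CDR,
3. is large (not Ala, Gly, Ser, Thr or Val), and
4. has relative solvent accessibility above 20% (strict).

CDR boundaries are configurable (`cdr_definition()`); Kabat ranges ship as
the default scheme since numbering conventions differ, and the test
fixtures pass explicit ranges so nothing depends on the scheme choice.
Relative accessibility is whole-residue Shrake–Rupley area (probe 1.4 Å,
960 deterministic golden-spiral points per atom) over the Tien et al.
theoretical maximum for that residue type; the algorithm is implemented in
the package because no installed R package computes solvent-accessible
areas directly. Chemical-shift perturbations between free and bound forms
use the conventional composite
$\sqrt{\Delta\delta_H^2 + (0.14\,\Delta\delta_N)^2}$ and are flagged
against the mean and mean-plus-one-population-SD thresholds of all
residues with data. Every rejection records the first failed criterion in
the order above, and selection is a pure function of the annotation table:
lowering the ASA threshold or dropping a criterion can only grow the
selected set.

## Binding thermodynamics

Mutant evaluation uses standard identities, kJ/mol and Kelvin throughout
(kcal accepted on input at 4.184 kJ/kcal):
$\Delta G = -RT\ln K_A$ with $R = 8.314$ J/(mol·K), and
$T\Delta S = \Delta H - \Delta G$, which therefore holds exactly for every
assembled record. The binding heat-capacity change is the
$1/\sigma^2$-weighted least-squares slope of $\Delta H$ versus $T$, with
the slope's standard error taken from the weighted normal equations; the
weighting matters — the reference enthalpy series with its published
per-point errors reproduces the published $\Delta C_p$ values only under
$1/\sigma^2$ weights.

The one-site ITC forward model (`one_site_itc_heats()`) uses
perfect-mixing volume displacement (each injection dilutes the cell by
$1 - v/V_0$) and solves the 1:1 mass-balance quadratic in its
cancellation-free form, so mass balance holds to machine precision.
`fit_itc()` inverts isotherms by least squares over
$(\log_{10} K_A, \Delta H, n)$ with multi-start on $\log_{10} K_A$ from 4
to 12. The default generator geometry mirrors the reference experiment
(25 × 10 µl of 30 µM titrant into 2 µM macromolecule); the instrument cell
volume is not part of the published protocol, so the VP-ITC standard
1.4 ml is the package default. Note the Wiseman-parameter caveat: at
$c = K_A \cdot [\mathrm{cell}] \approx 4000$ the isotherm is nearly
rectangular and $K_A$ is weakly identifiable — noiseless round trips
recover $\Delta H$ and $n$ to well under 1% and $K_A$ comfortably within
a factor 1.5, while at low $c$ (say $K_A = 10^6$ M⁻¹) $K_A$ itself is
recovered to ~1%. DSC enthalpy is baseline-corrected trapezoidal
integration only (multi-transition deconvolution is out of scope); when no
baseline is stored a line is fitted to the flanking 10% windows, with a
warning if those windows appear to overlap the transition.

## Bound-form ensemble analysis

The bound form of an antibody often shows too little millisecond exchange
to fit, so faster motions are compared on snapshot ensembles (multi-model
PDB files, one frame per model, such as structures extracted every
nanosecond from a trajectory). `ca_distance_series()` extracts per-frame
Cα–Cα distances; `compare_distance_distributions()` reports the median
shift and a two-sided Mann–Whitney rank-sum test — exact enumeration when
both samples have at most 8 untied values, otherwise the normal
approximation with tie and continuity corrections. The choice of a rank
test is ours (the reference analysis reports p-values without naming a
test), which is why published p-values are not reproduction targets.

## Synthetic data: what it emulates, and what it does not

All generators are seeded (single integer seed; per-kind Mersenne–Twister
substreams; callers' RNG state restored) and emit machine-readable ground
truth next to the data:

* `gen_dispersion_dataset()` — clustered two-state curves at 600.13 and
  750.13 MHz plus Gaussian noise of σ = 0.3 s⁻¹, a noise level at which
  recovered $k_\mathrm{ex}$ standard errors match the ±15–50 s⁻¹ scale of
  the reference fits. The published experiment does not state its
  $\tau_\mathrm{cp}$ grid or constant-time period, so the defaults
  (40 ms, 12 points at 25–1000 Hz in multiples of 25 Hz so the echo count
  is exact) are fixture choices, not reproductions. Flat decoy residues
  carry amplitudes below 0.5 s⁻¹ and have their noise redrawn until the
  realised range stays below the 1 s⁻¹ rule, so the exclusion filter
  removes them by construction.
* `gen_itc_experiment()` — one-site isotherms at the reference geometry
  with Gaussian heat noise (default 0.1 µcal).
* `gen_annotation_fixture()` — 32 dispersive residues of which exactly 8
  pass all four criteria (counts mirror the reference bookkeeping; the
  *identities* of the real residues are in supplementary material not
  reproduced here, so the fixture makes no claim about them).
* `gen_snapshot_ensemble()` — isotropic Gaussian perturbations of a base
  structure (default: a synthetic two-chain helical minifold, clearly
  labelled synthetic).

These emulate measurement noise and the data shapes of the real pipeline,
not spectrometer artefacts, baseline drifts, non-uniform sampling or
force-field physics. Passing recovery tests therefore demonstrates the
correctness and calibration of the estimators under the stated noise
model, nothing more: on real data, error bars inherit whatever the peak
intensities' true noise is, and cluster membership must be argued from
structure, not assumed.

## Problem sizes used by the packaged checks

The recovery studies fit 20 seeded replicates per scenario (10-residue
clusters for the wild-type rates 840 and 2033 s⁻¹, 6-residue fast-exchange
clusters for the mutant rates 753 and 657 s⁻¹, two fields, 12 points per
curve), regime selection uses 50 replicates per regime with 2-residue
clusters, and the oracle-equivalence grid uses 100 parameter sets at 12
frequencies. These sizes give stable means and percentages while keeping
the full suite comfortably fast on a laptop.

## Known limitations

* Equal intrinsic $R_2^0$ for both exchanging states is assumed (the
  population-average convention); off-resonance effects, finite pulse
  widths, R1ρ and three-state exchange are out of scope.
* The intensity-based propagator rate and the closed forms differ by the
  documented $O(1/T)$ projection offset at short constant-time periods.
* In fast exchange only $\Phi$ is identifiable; Carver–Richards fits of
  fast-exchange data park $p_B$ at a bound and its error is meaningless
  there — the F test exists precisely to detect this.
* The ITC model treats heats of dilution as an optional constant offset,
  and $K_A$ is intrinsically soft in the high-$c$ regime.
* Monte-Carlo parameter-error estimation is not implemented; errors are
  covariance-based with an optional jackknife.
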