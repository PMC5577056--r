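# fluctedit

Quantitative tools for **fluctuation editing**: engineering higher-affinity
antibodies by damping millisecond conformational exchange at residues
*outside* the complementarity-determining regions (CDRs).

Affinity maturation usually mutates the CDR loops that contact the antigen.
Fluctuation editing instead uses CPMG relaxation dispersion — an NMR
experiment that quantifies millisecond-timescale exchange between
conformations — to find framework residues of the antibody Fv fragment
whose fluctuations destabilise the binding-competent state, and mutates
them to alanine. This package implements the computational core of that
workflow for structural biologists and NMR spectroscopists:

* **Dispersion models** — Luz–Meiboom (fast exchange) and Carver–Richards
  (slow/intermediate) closed forms for the effective relaxation rate
  R₂,eff(ν₍CPMG₎) of a two-state exchange process
  (k_ex, p_minor, Δω), validated against a numerical Bloch–McConnell
  propagator that serves as the convention oracle.
* **Global cluster fitting** — `fit_dispersion()` fits all residues of a
  cluster with one shared k_ex (weighted least squares, ppm-level
  amplitudes shared across static fields, multi-start, covariance errors),
  after `exclude_flat_curves()` removes profiles whose R₂ changes by less
  than 1 s⁻¹. Model and clustering choices are made by reduced χ² and F
  tests (`f_test_select()`, `cluster_search()`).
* **Candidate selection** — `select_candidates()` applies the four
  fluctuation-editing criteria: shows dispersion ∧ non-CDR ∧ large residue
  (not A/G/S/T/V) ∧ relative solvent accessibility > 20%
  (Shrake–Rupley ASA over theoretical maxima), plus composite
  chemical-shift-perturbation flags.
* **Mutant evaluation** — one-site ITC isotherm simulation and fitting
  (K_A, ΔH, n), ΔG = −RT ln K_A and TΔS = ΔH − ΔG decomposition,
  1/σ²-weighted ΔC_p regression, DSC enthalpy integration, and Cα
  distance-distribution comparison between bound-form snapshot ensembles
  (median shift + Mann–Whitney test).
* **Synthetic data** — seeded generators with ground truth for every input
  (dispersion tables, isotherms, annotation fixtures, multi-model PDB
  ensembles), so the whole pipeline is testable offline.

## Worked example

Simulate a two-cluster dispersion data set at 600/750 MHz (wild-type-like
rates of 840 and 2033 s⁻¹ plus flat decoys), filter, and fit the first
cluster globally:

```r
library(fluctedit)

sim  <- gen_dispersion_dataset(dispersion_scenario(seed = 42))
filt <- exclude_flat_curves(sim$curves)          # drops the 4 decoys
fit  <- fit_dispersion(
  filt$kept[filt$kept$residue_id %in% sim$truth$members[["1"]], ],
  model = "carver_richards")
fit
#> Global two-state dispersion fit (carver_richards)
#>   10 residues, 240 points, chi2 = 213, red. chi2 = 1.024
#>   shared k_ex = 810.2 +/- 26.7 1/s
#>   shared p_minor = 0.0302 +/- 0.0010
```

The generating rate (840 s⁻¹) is recovered within 1.1 standard errors, the
generating p_minor (0.03) almost exactly, and a reduced χ² near 1 confirms
the noise model. Thermodynamic evaluation of a mutant from its measured
association constant and binding enthalpy:

```r
binding_thermodynamics(ka = 2.0e9, delta_h = -99.50, temperature = 293)
#> Binding thermodynamics at 293.0 K
#>   K_A = 2e+09 1/M
#>   dG  = -52.17 kJ/mol
#>   dH  = -99.50 kJ/mol
#>   TdS = -47.33 kJ/mol

dcp <- delta_cp_weighted(c(293, 298, 303), c(-99.50, -113.40, -130.29),
                         c(0.25, 0.36, 1.45))
sprintf("dCp = %.2f +/- %.2f kJ/mol/K", dcp$delta_cp, dcp$delta_cp_se)
#> "dCp = -2.85 +/- 0.08 kJ/mol/K"
```

A binding free energy of −52 kJ/mol driven by a large favourable enthalpy
against an entropic penalty, and a strongly negative ΔC_p indicating
burial of apolar surface on binding. Selection on a fixture of 32
fluctuating residues:

```r
fx <- gen_annotation_fixture(annotation_scenario(seed = 42))
select_candidates(fx$annotations)
#> Fluctuation-editing selection: 8 candidate(s), 24 rejected (ASA > 20%)
#>   selected: L:C23, H:E109, L:Q101, L:P36, H:P7, L:Y98, H:R79, L:I88
#>   rejections by reason:
#>        in_cdr       low_asa small_residue
#>            10             6             8
```

A command-line wrapper over the same stages is installed at
`system.file("cli", "fluctedit.R", package = "fluctedit")`:

```sh
Rscript fluctedit.R simulate       --out run --seed 1
Rscript fluctedit.R fit-dispersion --out run
Rscript fluctedit.R select         --out run
```

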