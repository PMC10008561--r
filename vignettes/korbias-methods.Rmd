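---
title: "Methods: conformational states and operational-model bias at KOR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational states and operational-model bias at KOR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(korbias)
```

## Scope

`korbias` implements two linked analyses of biased agonism at the
κ-opioid receptor: classification of MD-trajectory frames into three
intracellular conformational states with replicate-level occupancy
statistics, and quantification of ligand bias from dose–response data via
the Black–Leff operational model. This vignette records the models, the
parameters that matter, the numerical choices, and the points where the
design was genuinely open.

## Structural track

### Coordinate conventions and superposition

All vertical-displacement and in-plane rotation metrics assume a
membrane-aligned reference with **+z pointing extracellular** (the OPM
convention). Every frame is superposed onto a reference structure —
typically the crystal structure or the first frame — by a proper rigid
least-squares (Kabsch) fit of the Cα atoms of TM2, TM3 and TM5. The
selection lives in the YAML config, not in code; the same TM2/3/5
selection is used for all metrics. Reflections are excluded by
construction (the fitted rotation always has determinant +1), and
selections of fewer than three or collinear atoms raise a degenerate-
alignment error rather than returning a meaningless fit.

### Per-frame observables

* **T94–D334 contact distance**: minimum over the Asp carboxylate oxygens
  {OD1, OD2} to the Thr hydroxyl oxygen OG1. Captions in the source
  literature name chemical groups rather than atoms; taking the minimum
  over equivalent oxygens is the standard convention, and the same rule
  is used for the K227 {NZ} to E297 {OE1, OE2} salt bridge.
* **TM7 rotation**: the helix tangent is approximated by the XY-projected
  difference of the Cα positions of residues 7.47 and 7.48; the metric is
  the signed angle from the reference frame's tangent to the current
  frame's. The sign convention — positive = counter-clockwise viewed down
  +z, i.e. from the extracellular side — is a deliberate choice: the
  classification threshold ("rotation < −20°") implies a signed angle,
  but the measurement protocol as described ("the angle between these
  vectors") does not fix the orientation. The convention is therefore
  exposed as `tm7_sign` in `metric_config()` so users can flip it without
  touching thresholds.
* **Q115 rotamer**: the signed IUPAC torsion of the side-chain atoms
  C–CA–CG–CD, in (−180°, 180°]. "Rotated towards TM1" is operationalized
  as a circular excursion of more than `q115_window` (default 60°) from
  the reference (crystallographic) dihedral, because the source analysis
  reports percentages of time without printing a cutoff.
* **W287 vertical displacement**: mean z of the indole ring atoms
  {CG, CD1, CD2, NE1, CE2, CE3, CZ2, CZ3, CH2} minus the same mean in the
  reference; "downward" (towards intracellular) means at or below
  `w287_down_cutoff` (default −0.5 Å). Again the cutoff is a package
  default, not a published value, and is configurable.

### Classification rule

Classification is a total, deterministic function with fixed precedence
and *strict* inequalities:

1. **occluded** if the T94–D334 distance < 3.5 Å,
2. otherwise **alternative** if the TM7 rotation < −20°,
3. otherwise **canonical**.

A frame at exactly 3.5 Å is therefore not occluded, and a frame at
exactly −20° is not alternative. The two thresholds are the published
values and are the defaults of `metric_config()`.

### Occupancy and cross-condition statistics

Occupancies are reported per replicate and pooled. Pooling is
frame-weighted by default (total frames in a state over total frames),
with the unweighted replicate mean reported alongside, since published
pooled percentages do not state which convention was used. Frames are
equally weighted with no burn-in discard; users may drop initial frames
before calling `occupancy()` if desired.

The statistical test behind published occupancy p-values is not named in
the source. The package defaults to an **exact two-sided Mann–Whitney
rank test** on per-replicate fractions, computed by exhaustive
enumeration over all assignments with midranks (so ties are handled and
identical groups give p = 1 exactly); enumeration is practical for the
replicate counts in scope (≤ ~12 per group). A seeded Monte-Carlo
permutation test on the difference of means is available as an
alternative; its p-value uses the add-one estimator so it is never
exactly zero. No attempt is made to reproduce specific printed p-values —
they depend on the unavailable μs-scale trajectories.

## Pharmacological track

### Operational model and identifiability

Responses are modeled as
`Y = Emax·B / (B + (10^X + 10^logKA)^n)` with `B = 10^(X·n)·10^(logτ·n)`,
Emax fixed at 100 (data are percent of the reference maximum) and a
single slope `n` shared across ligands within one pathway (pathways are
fitted separately; slopes are not shared across pathways). For `n = 1`
the model implies EC50 = K_A/(τ+1) and plateau = Emax·τ/(τ+1); both
identities are exercised by the tests on noise-free data.

For a full agonist, τ and K_A trade off along a ridge and are not
separately identifiable; only log(τ/K_A) is well determined. The fit
therefore applies a soft bound logτ ≤ 3 and always reports log(τ/K_A)
with a standard error from the joint covariance, computed with a
pseudo-inverse when the normal matrix is singular along the ridge. All
bias quantities depend only on log(τ/K_A), never on the τ/K_A split.

### Bias quantities

Within each pathway, Δlog(τ/K_A) = log(τ/K_A)_ligand −
log(τ/K_A)_reference. Between pathways, ΔΔlog(τ/K_A) =
Δlog(G pathway) − Δlog(arrestin pathway), so bias factors
(10^ΔΔlog) above 1 indicate G-protein preference. The reference ligand's
Δ and ΔΔ are identically zero by construction — `delta_log()` returns an
exact 0 when test and reference coincide — so its bias factor is exactly
1 regardless of noise; this is the package's headline end-to-end
invariant.

Two averaging modes exist. The default **per-experiment** mode fits each
independent experiment (replicate) separately, computes Δlog within each
experiment, and averages across experiments with the empirical standard
error (df = experiments − 1 per pathway), matching the practice of
averaging transduction coefficients across experiments and cancelling
day-to-day assay effects. The **global** mode fits all data jointly and
propagates standard errors from the fit covariance; it is used when no
replicate structure is available.

Confidence intervals on bias factors are symmetric in log space:
10^(ΔΔ ± t(df)·se). The published intervals' construction and df are not
stated; a t-interval on ΔΔlog with pooled replicate df is the
conventional choice and is recorded in the output. A zero standard error
(the reference against itself) yields the degenerate interval equal to
the point estimate rather than an omitted one; a negative or undefined
standard error omits the interval with a warning.

### Curve-fit numerics

All nonlinear fits use deterministic Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) from fixed, data-derived starting values (logEC50
at the median tested concentration, logτ = 0), with no random
restarts, so repeated fits are bit-identical. Non-convergence and flat
(degenerate) inputs return flagged results rather than throwing
mid-pipeline; logistic fits whose EC50 falls more than 2 log units
outside the tested range are flagged "extrapolated". Covariances are
`(J'J)^{-1}·s²` at the optimum.

### Binding module

Competition curves are fitted as a descending logistic with slope fixed
at −1 (the one-site model; a variable slope is available behind a flag)
and converted to Ki by Cheng–Prusoff, `Ki = IC50/(1 + L/Kd)`; in log10
this is a constant offset, so se(logKi) = se(logIC50). Nonspecific
binding in dissociation fits is a free plateau parameter by default and
may be fixed from a blocker-defined value. `t½ = ln 2 / koff`, with
se(t½) by the delta method.

## Synthetic-data module

The trajectory generator does **not** simulate physics. Atoms are placed
analytically so each metric equals its per-state target plus independent
Gaussian noise: the Asp oxygens sit on a ray at the target distance from
the Thr hydroxyl, the 7.47/7.48 Cα pair is rotated in the XY plane by the
target angle, the Gln side-chain torsion is constructed directly, and the
Trp ring is shifted vertically. A fixed, noise-free set of anchor Cα
atoms stands in for the TM2/3/5 selection, and each frame can be given a
random rigid motion that superposition must remove exactly — this
exercises the alignment path without perturbing the metrics. State labels
come from a fixed sequence or a first-order Markov chain started at its
stationary distribution.

Default study conditions (chosen once, stated here):

* state targets — occluded (2.8 Å, −30°), alternative (6.0 Å, −40°),
  canonical (6.0 Å, 0°): each ~2 noise SDs inside its region;
* metric noise — 0.3 Å on distances, 5° on angles, the classifier-fidelity
  study condition;
* dose–response — 8 log-spaced concentrations (10^−11 to 10^−4 M),
  3 replicates, Gaussian noise SD 2 (% of Emax);
* recovery scenario — reference logτ = 0.7, test ligand logτ = 0.4
  (a ~72%-plateau partial agonist, representative of the efficacious
  agonists used in bias assays). This matters: the precision of
  log(τ/K_A) degrades sharply with efficacy. A Fisher-information
  calculation at this design gives sd ≈ 0.044 for the logτ = 0.4 ligand
  but ≈ 0.078 at logτ = −0.1; the fitted estimator attains this bound, so
  a "within 0.1 log units in ≥95% of runs" recovery property is only
  achievable for reasonably efficacious agonists, and the package's
  recovery tests are run under that condition.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: temporal autocorrelation of MD frames (each
frame's noise is independent, so occupancy standard errors on real
trajectories will be larger than binomial), correlated metric
fluctuations, non-Gaussian assay noise, baseline drift, receptor reserve,
and any coupling between the structural and pharmacological tracks.
Problem sizes in the tests (up to 5,000 frames, 200 simulated assay
datasets) were chosen as comfortable desk-scale study sizes.

## Trajectory I/O

The multi-model PDB reader honors only ATOM/HETATM, MODEL and ENDMDL
records, with coordinates from the fixed columns 31–54; this minimal
dialect is sufficient for both synthetic and real inputs, keeps the
atom-identity consistency check across MODELs strict (same atoms, same
order), and lets parse errors name the offending line. Binary trajectory
formats (DCD/XTC) are out of scope; convert externally. Writing uses
standard fixed-width columns at 3-decimal precision, so coordinate round
trips are exact to 10^-3 Å.

## Known limitations

* The three-state rule is fixed by design; no clustering, Markov-state
  modeling or free-energy analysis is provided.
* The exact-rank test enumerates `choose(n1+n2, n1)` assignments; beyond
  ~12 per group use the permutation method.
* Published occupancies, p-values and experimental bias factors require
  the original μs trajectories and raw assay data; the package reproduces
  their defining computations, not the numbers themselves.
* Saturation binding (Kd/Bmax) is not modeled; radioligand Kd is an
  input.

## Session info

```{r}
sessionInfo()
```
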