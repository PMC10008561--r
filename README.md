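# korbias

Conformational-state classification and signaling-bias quantification for
the κ-opioid receptor (KOR) and related GPCRs.

KOR agonists are promising non-addictive analgesics, but their side-effect
profile appears to track which intracellular transducer they engage: G
protein versus β-arrestin. This package implements the two computational
analyses used to connect receptor conformation to that functional
selectivity:

1. **Structural track.** Molecular-dynamics snapshots (multi-model PDB)
   are superposed on the Cα atoms of TM2/TM3/TM5, and each frame is scored
   with five geometric observables of the coupling interface and binding
   pocket: the T94^2.39^–D334^8.47^ oxygen contact distance, the rotation
   of the bottom of TM7 measured from the XY tangent at S324^7.47^→L325^7.48^,
   the Q115^2.60^ C–CA–CG–CD rotamer dihedral, the K227^5.39^–E297^6.58^
   salt-bridge distance, and the vertical displacement of the W287^6.48^
   indole ring ("rotamer toggle switch"). Frames are classified by a fixed
   precedence rule into three intracellular states:

   - **occluded** if the T94–D334 distance < 3.5 Å,
   - otherwise **alternative** if the TM7 rotation < −20°,
   - otherwise **canonical** active.

   State occupancies are summarized per replicate and pooled, and compared
   across ligand conditions with an exact rank (Mann–Whitney) test or a
   seeded permutation test.

2. **Pharmacological track.** Dose–response data are fitted with the
   Black–Leff operational model,

   ```
   B = 10^(X·n) · 10^(logτ·n)
   Y = Emax · B / [ B + (10^X + 10^logKA)^n ]
   ```

   with Emax fixed at 100 and one Hill slope n shared across ligands
   within a pathway. The transduction coefficient log(τ/K_A) summarizes
   agonism per pathway; bias is quantified as

   ```
   Δlog(τ/K_A)  = log(τ/K_A)_ligand − log(τ/K_A)_reference      (per pathway)
   ΔΔlog(τ/K_A) = Δlog(G pathway) − Δlog(arrestin pathway)
   bias factor  = 10^ΔΔlog(τ/K_A)     (with a t-based 95% CI in log space)
   ```

   Supporting fits cover radioligand competition (one-site Ki via the
   Cheng–Prusoff correction `Ki = IC50 / (1 + L/Kd)`), one-phase
   exponential dissociation kinetics (`t½ = ln 2 / koff`), and
   mutant-vs-wild-type potency fold-change matrices.

A seeded synthetic-data module generates reduced-topology trajectories and
assay datasets with known ground truth, so the entire pipeline is testable
without any external data.

## Worked example

```r
library(korbias)

## --- structural track: planted-state trajectory -> occupancy ----------
p <- matrix(c(0.90, 0.05, 0.05,
              0.08, 0.84, 0.08,
              0.05, 0.05, 0.90), 3, 3, byrow = TRUE,
            dimnames = list(state_levels(), state_levels()))
pres <- state_prescription(transition = p, n_frames = 2000)
sim  <- simulate_trajectory(pres, seed = 42)
spec <- alignment_spec(sim$reference, sim$alignment_residues)
metrics <- compute_frame_metrics(sim$trajectory, spec = spec)
occupancy(list(rep1 = classify_frames(metrics)))
#> <state_occupancy> 1 replicate(s), 2000 frames
#> pooled:  occluded 39.9%, alternative 23.1%, canonical 37.1%

## --- pharmacological track: planted bias -> bias factor ---------------
truth <- data.frame(
  ligand  = c("U50,488", "nalfurafine", "U50,488", "nalfurafine"),
  pathway = c("Gprotein", "Gprotein", "arrestin", "arrestin"),
  logtau  = c(1.0, 0.6, 1.0, 0.1),
  logKA   = c(-8.0, -8.5, -8.0, -7.6))   # planted ddelta = 1.4
ds <- simulate_dose_response(assay_prescription(truth, noise_sd = 2), seed = 42)
compute_bias(ds$data, "U50,488", "Gprotein", "arrestin")
#> <bias_analysis> reference 'U50,488', pathways Gprotein vs arrestin, mode per-experiment
#>        ligand delta_g se_delta_g delta_arr se_delta_arr ddelta se_ddelta bias_factor ci_low ci_high
#> 1     U50,488   0.000      0.000       0.0        0.000   0.00    0.0000         1.0   1.0     1.0
#> 2 nalfurafine   0.126      0.055      -1.3        0.027   1.42    0.0612        26.5  17.9    39.1
```

The occupancy line gives the fraction of simulation frames in each of the
three intracellular states (here recovering the planted Markov chain's
stationary proportions). In the bias table, the reference ligand's bias
factor is exactly 1 by construction; the test ligand's fitted
ΔΔlog(τ/K_A) of 1.42 ± 0.06 (planted truth 1.4) corresponds to a ~27-fold
G-protein preference, with a 95% confidence interval obtained by
exponentiating the t-interval in log space.

Potency fold changes use plain EC50 ratios, e.g. a variant/wild-type pair
of 108 nM / 1.32 nM:

```r
potency_fold_change(108e-9, 1.32e-9)$fold_rounded
#> [1] 82
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/korbias.R`
(subcommands `classify`, `occupancy`, `compare`, `bias`, `fit-ki`,
`fit-dissoc`, `simulate-traj`); run it with `Rscript` and `--help`-style
usage in the script header. The residue map, alignment ranges and
classification thresholds are configured in
`inst/extdata/kor_config.yaml`.

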