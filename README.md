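# smfs

Analysis of single-molecule **magnetic force spectroscopy (MFS)**
experiments on ligand-responsive RNA structures — riboswitch aptamers in
particular — for biophysicists who need to go from raw bead-height traces
to mechanistic statements about how a small molecule stabilizes an RNA
fold.

In an MFS experiment an RNA is tethered between a surface and a
paramagnetic bead, a calibrated force is applied, and the bead's Z-position
is tracked (30 Hz). Two protocols are analyzed:

* **Force ramps** (~1–25 pN, many cycles): unfolding/refolding appear as
  abrupt 10–25 nm jumps; the package segments cycles, detects the jumps by
  density clustering of the force–extension data (cross-validated against
  an exhaustive changepoint oracle), filters analyzable structures
  (unfolding force 5–15 pN, size 10–25 nm, >20 cycles, >80% unfolding,
  present in more than half the conditions), normalizes forces by each
  bead's own control medians, and summarizes distributions via a
  peak-median statistic and the fraction of high-force cycles above the
  control's 95th percentile.
* **Constant force**: the molecule hops between folded and unfolded
  states; a two-state Viterbi decoder (KDE emission levels, Gaussian
  emissions, symmetric switching prior) assigns states, dwell times are
  extracted and fitted as mixtures of 1–3 exponentials by maximum
  likelihood with BIC model-order selection
  (BIC = −2·logL + (2k−1)·ln n), and log rates, log(1/lifetime), are
  aggregated across molecules after per-molecule control normalization
  (Kramers–Bell: log rates are linear in force, so bead-magnetism offsets
  subtract out).

Dose responses are fitted with three saturation models: the MFS response
curve *y* = (u + b·x/K_D)/(1 + x/K_D) (EC50 of force shifts or occupancy),
one-site total binding B_max·x/(K_D + x) + ns·x + bg (fluorescence/MST
K_D), and termination efficiency e_min + (e_max − e_min)·x/(T_50 + x)
(T_50 from single-round transcription termination gels, with efficiency =
terminated / (terminated + read-through)).

Because instrument data of this kind are rarely deposited, the package
includes a first-class mechanistic trace simulator (Bell–Evans kinetics,
per-sample Markov stepping for ramps, exact Gillespie sampling at constant
force) with two ligand modes: a *kinetic stabilizer* that saturably slows
unfolding (and can speed refolding), and a *pseudoknot inducer* that
commits refolding events to a far more stable fold with probability
c/(c + K_D). Every analysis stage is tested against this generator's
ground truth. See the methods vignette
(`vignettes/smfs-methods.Rmd`) for the models, parameter choices and
limitations.

## Worked example

Simulate a small ramp cohort under a kinetic-stabilizer ligand with a
planted half-saturation of 400 µM, run the full pipeline, and fit the dose
response:

```r
library(smfs)
set.seed(42)

model    <- kinetic_model(ligand_mode = "kinetic_stabilizer",
                          K_D_ligand = kd_for_half_saturation(400e-6, 2),
                          stabilization_factor = 2)
protocol <- protocol_ramp()          # 1-25 pN at 1 pN/s, 50 cycles, 30 Hz
cohort   <- simulate_ramp_cohort(model, protocol,
                                 concentrations = 10^seq(-5, -2, length.out = 8),
                                 n_beads = 6)
traces   <- unlist(lapply(cohort, function(b)
              lapply(b$runs, function(r) r$trace)), recursive = FALSE)

res <- analyze_ramp_cohort(traces)
res$selection[, c("bead_id", "selected")]
#>   bead_id selected
#> 1 bead001     TRUE
#> 2 bead002     TRUE
#> 3 bead003     TRUE
#> 4 bead004     TRUE
#> 5 bead005     TRUE
#> 6 bead006     TRUE

res$fit_unfold
#> <dose-response fit: mfs_saturation>
#>   u          1.01456 (SE 0.0306)
#>   b          1.14273 (SE 0.0274)
#>   K_D        0.000134139 (SE 0.000171)
#>   residual norm 0.7275 over 54 points
```

All six simulated molecules pass the selection filters. The fitted curve
says: at zero ligand the normalized unfolding force is 1.01 (the control
self-normalizes to ~1), at saturation it rises to 1.14 (a ~14% increase in
the force needed to unfold), and the half-maximal concentration K_D is the
EC50 estimate — here 134 µM with a standard error of similar magnitude,
which is the expected precision for a cohort this small (6 beads); the
study-scale reproduction below uses 20 beads and 12 concentrations.

The constant-force side is driven the same way: `assign_states()` →
`extract_dwells()` → `fit_exp_mixture()` → `aggregate_rates()` /
`occupancy_vs_concentration()`, or end-to-end via
`analyze_dwell_cohort()`. `run_pipeline()` runs either analysis from a
YAML configuration and writes CSV/JSON tables plus a manifest,
byte-reproducibly for a fixed seed.

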