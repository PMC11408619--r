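---
title: "Models and methods behind smfs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smfs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfs)
```

# The experiment this package analyzes

In magnetic force spectroscopy (MFS) a structured RNA — here a riboswitch
aptamer — is tethered between a surface and a paramagnetic bead. A
calibrated magnetic force is applied while the bead's vertical (Z) position
is tracked, typically at 30 Hz. Two protocols carry the information:

* **Force ramps**: the force is swept slowly up (~1 to ~25 pN) and back
  down, many times. Unfolding and refolding appear as abrupt jumps in bead
  height (10–25 nm for the structures considered here), and the forces at
  which the jumps occur characterize the structure's mechanical stability.
* **Constant force**: near the equilibrium force the molecule hops between
  folded and unfolded states; the residence ("dwell") times in each state
  measure the unfolding and refolding rates directly.

Small-molecule ligands can stabilize the fold in two mechanistically
distinct ways, and distinguishing them is the analytical point of the
package. A *thermodynamic* stabilizer (the cognate metabolite of a
riboswitch) converts refolding events into a much more stable, persistently
folded conformation — a pseudoknot — producing a second, high-force
population of rupture events whose occupancy grows with concentration. A
*kinetic* stabilizer leaves the folded conformation unchanged but slows its
unfolding (and can speed refolding), shifting the single rupture-force peak
without creating a second one.

# The kinetic model

All simulated kinetics follow Bell–Evans force dependence:

$$k_u(F) = k_{u0}\, e^{F x_u / k_B T}, \qquad
  k_f(F) = k_{f0}\, e^{-F x_f / k_B T}.$$

`kBT` defaults to 4.07 pN·nm (22 °C). The default Bell parameters
(`k_unfold0 = 0.004` s⁻¹, `x_unfold = 2` nm, `k_fold0 = 30` s⁻¹,
`x_fold = 4` nm) were chosen so that, on a 1 pN/s ramp, the control
molecule's median unfolding force lands near 9 pN — inside the 5–15 pN
selection window used by the analysis — with a refolding peak near 3 pN and
a folded/unfolded equilibrium near 6 pN. For a linear ramp at rate $r$ the
median rupture force has the closed form

$$F_{med} = \frac{k_BT}{x}\,
  \ln\!\Big(1 + \ln 2\, \frac{x\,r}{k_BT\,k_0}\Big),$$

implemented as `ramp_median_force()` and used as an independent oracle on
the simulator.

Ligand action enters in one of two modes:

* `kinetic_stabilizer`: $k_u \to k_u \cdot s(c)$ with
  $s(c) = 1/(1 + (g-1)\,h)$, $h = c/(c + K_D)$, and $g$ the maximal
  fold-reduction (`stabilization_factor`). Optionally the refolding rate is
  multiplied by the analogous saturable enhancement
  (`fold_enhancement_factor`, `K_D_fold`), reflecting a ligand that binds a
  partially folded state and speeds its closure.
* `pseudoknot_inducer`: each refolding event commits the molecule to the
  pseudoknot state with probability $h = c/(c+K_D)$; that state unfolds
  with its own (much slower) Bell kinetics, placing its rupture peak near
  18 pN by default.

## The planted EC50: an exact calibration

Under the kinetic-stabilizer model the median rupture force shifts by
$\Delta F(c) = (k_BT/x_u) \ln(1 + (g-1)h)$. The shift reaches half of its
maximal value $(k_BT/x_u)\ln g$ exactly when $1 + (g-1)h = \sqrt g$, i.e.
at $h^\ast = 1/(\sqrt g + 1)$, which corresponds to

$$c^\ast = K_D / \sqrt g.$$

So to plant a target half-saturation concentration (an EC50) in the
simulated dose response one sets $K_D = EC_{50}\sqrt g$
(`kd_for_half_saturation()`). The same algebra applies to the refolding
side with $g$ the fold-enhancement factor. We verified numerically that a
hyperbolic saturation fit to the ideal response recovers the planted
$c^\ast$ to well under 1% for $g = 2$.

`stabilization_factor = 2` is the package default. With the study design
used in the acceptance analysis (20 beads × 50 cycles × 12 concentrations)
this effect size makes the fitted EC50 carry a sampling uncertainty of
roughly 30–40% — the same relative precision as published MFS EC50
estimates of this kind, which is the regime the generator is meant to
emulate. A larger factor would sharpen the estimate, but at the cost of
simulating an effect stronger than the experiments suggest.

# The trace simulator

Ramp traces evolve the hidden state by a time-inhomogeneous Markov chain
discretized at the sampling rate: the transition probability per sample is
$1 - e^{-k(F)\Delta t}$ with the rate evaluated at the recorded force. A
resolution guard stops the simulation with an error if the hazard of the
*occupied* state ever exceeds one expected transition per sample
($k\Delta t > 1$); below that the discretization error is negligible for
every statistic used here (the coarse 30 Hz chain agrees with a 10× finer
chain in the test suite). Constant-force traces are sampled exactly
(Gillespie) in continuous time and then rasterized.

Extension is `baseline + compliance·F` plus `delta_L` when unfolded, with
Gaussian measurement noise. The reference noise regime is a constant 2 nm
tracking noise; a force-dependent Brownian term with variance
$k_BT \cdot L / F$ (tether extension estimate $L$, default 40 nm) can be
added with `brownian_noise = TRUE` and is what the Brownian quality-control
filter expects. Per-molecule heterogeneity enters through `delta_L` drawn
from U[12, 22] nm and a bead-specific force-calibration factor drawn from
U[0.92, 1.08]; the latter is exactly the variation that per-bead control
normalization is designed to remove.

What the generator does **not** emulate: worm-like-chain tether elasticity
(a linear compliance stands in; the analysis only uses extension
*differences*), slow instrumental drift, camera blur, bead rotation, and
multi-state folding intermediates beyond the pre-pseudoknot/pseudoknot
dichotomy. Passing tests therefore demonstrate correctness of the analysis
chain under idealized two-state kinetics with realistic noise and
heterogeneity — not robustness to every artifact of real recordings.

# Ramp analysis

* **Quality control** (`qc_brownian`): within quiescent high-force windows
  the detrended extension variance is compared with the Brownian
  expectation $k_BT L / F$; a trace fails when the majority of windows fall
  outside a factor-2 band.
* **Cycle segmentation** (`segment_cycles`): extrema of the median-filtered
  force; boundaries are refined on the raw force so they are exact for a
  clean command signal. Trailing partial cycles are flagged, not analyzed.
* **Event detection** (`detect_events`): within each ramp phase the
  extension is median-filtered (0.33 s; a median filter leaves step edges
  in place), robustly detrended against force, and clustered by the modes
  of its kernel density. Modes closer than the minimum jump size (5 nm) are
  merged — two levels closer than a resolvable jump are one state. An event
  is emitted at each persistent cluster switch; its size is the difference
  of local medians at the boundary force after removing each cluster's own
  linear force–extension trend, excluding a guard zone around the boundary
  where the median filter blends the levels. The independent oracle is an
  exhaustive greedy binary-segmentation changepoint fit with a BIC stop
  (effective sample size reduced by the filter width), followed by a pooled
  within-segment slope refit. Both methods are exact on noise-free data and
  agree within 0.5 pN / 2 nm on ≥95% of events in the reference noise
  regime. By default one unfolding and one refolding event is reported per
  cycle — the largest jump, with near-ties (within 2 nm) resolved to the
  earliest event so the choice is stable across detectors.
* **Selection** (`select_structures`): a structure is analyzable when its
  control condition shows a median unfolding force in 5–15 pN, a median
  unfolding size in 10–25 nm, more than 20 analyzable cycles, an unfolding
  event in strictly more than 80% of cycles, and presence in more than half
  of the conditions. Cycles with no events count as analyzable (the
  structure simply stayed folded) — both in the unfold-proportion filter
  and in the high-force fraction.
* **Normalization** (`normalize_forces`): forces are *divided* by the
  bead's control medians (per direction). Division, not subtraction,
  because bead-to-bead magnetism differences act multiplicatively on force,
  and it makes the control distribution center at 1.
* **High-force fraction** (`high_force_fraction`): the threshold is the
  95th percentile of the control normalized unfolding forces
  (linear-interpolation percentile, `quantile(type = 7)` — the convention
  must be pinned for reproducibility); a condition's fraction counts cycles
  above threshold plus cycles that never unfolded, over analyzable cycles.
* **Dose response**: per structure and condition, the response is the
  median of the normalized forces within ±1 bandwidth of the modal peak of
  their Gaussian KDE (Silverman bandwidth) — a peak-median that tracks the
  dominant population even when a second one appears. The saturation model
  $y = (u + b\,x/K_D)/(1 + x/K_D)$ is fitted by Levenberg–Marquardt after
  profiling $K_D$ over a decade grid (u and b are conditionally linear, so
  every start is the exact conditional optimum); the fit is flagged
  non-identifiable when $|b - u| < 2\,SE(b-u)$.

# Constant-force analysis

Noise exclusion removes traces whose extension range within any 1 s window
exceeds twice the expected structure length, traces that never respond to
force, and (under cognate-ligand conditions) traces that never reach the
folded state. State assignment is a deliberately simple two-state decoder:
the two dominant modes of the extension density give fixed emission levels
(modes closer than 5 nm are merged), a common emission SD is estimated from
within-mode samples, and a Viterbi pass with a symmetric switching prior
(0.01 per sample) assigns each point. Runs shorter than 2 samples are
merged into their neighbors — at 30 Hz, events faster than 2/30 s are not
resolvable, so the dwell quantum is honest about the instrument.

Dwell durations are run lengths over the sampling rate; the first and last
residences are censored and excluded from fitting by default (with many
dwells per trace the bias from dropping two of them is negligible; a
censoring-aware likelihood was considered and left out to keep the MLE in
closed form at k = 1).

Lifetime distributions are fitted as mixtures of 1–3 exponentials by EM
(multistart, seedable; lifetimes floored at a tenth of the shortest dwell
to keep the likelihood bounded). Model order is chosen by BIC with
$p = 2k - 1$ free parameters (k lifetimes, k − 1 weights). The k = 1 MLE is
the sample mean, exactly. On 500-dwell samples the BIC choice is correct in
well over 90% of seeded runs both for single-exponential data and for a
planted (1 s, 10 s) half-and-half mixture.

Rates are aggregated across molecules on the log scale,
$\log(1/\text{lifetime})$, with each molecule's condition value normalized
by subtracting its own control value — under Bell kinetics log-rates are
linear in force, so this removes the bead-specific force-calibration
offset. For cognate-ligand conditions the two mixture components are used
instead of the pooled mean: the short lifetime tracks the pre-pseudoknot
state, the long one the pseudoknot, and the weight of the long component is
the pseudoknot occupancy, which can itself be fitted against concentration
with the saturation model. Pooling is per-molecule-then-average, matching
the idea that molecules, not dwells, are the independent units.

# Dose-response fitters

Three saturation models are provided, all fitted by profiled multistart
least squares: the MFS response model above; one-site total binding,
$signal = B_{max}x/(K_D + x) + ns\cdot x + bg$, with a toggle to pin the
nonspecific slope at zero (the two variants bracket the conventions of
common fitting software; the default floats the slope); and termination
efficiency, $e(x) = e_{min} + (e_{max}-e_{min})\,x/(T_{50}+x)$, whose
direction is free via the ordering of $e_{min}, e_{max}$. Termination
efficiency itself is the terminated band intensity over the total.
Uncertainties come from the Jacobian, and for $T_{50}$ additionally from a
seeded residual bootstrap (1000 resamples by default), mirroring
replicate-scatter error bars. Fits with the half-saturation constant beyond
the tested range are flagged `not_saturated` rather than trusted.

# Numerical and design choices worth knowing

* Units are fixed at ingest (s, nm, pN, molar); the CSV dialect carries
  them in the column names, and mismatches are errors, not conversions.
* HDF5 containers are not read or written by this build; the CSV dialect is
  the interchange format.
* The percentile convention (linear interpolation), the KDE bandwidth
  (Silverman), the BIC parameter count, the dwell quantum, and the per-cycle
  single-event rule are all pinned deliberately — each is a place where two
  reasonable conventions would give slightly different numbers.
* Problem sizes in the test-suite reproductions (for example 200 cycles for
  the detector cross-validation, 100 seeded runs for the BIC rates, 20
  beads × 50 cycles × 12 concentrations for the EC50 recovery) are the
  study-design sizes the analyses are meant for; the EC50 recovery at that
  size carries the ~30–40% sampling uncertainty discussed above, so its
  point estimate moves substantially between seeds while remaining unbiased.
* `run_pipeline()` writes no timestamps, so identical configuration and
  seed reproduce every output byte for byte.

# Known limitations

The event detector assumes at most a handful of well-separated extension
levels per ramp phase; molecules with many intermediates would need the
multi-event mode (`multi = TRUE`) and a more permissive selection. The
two-state decoder cannot separate the pseudoknot from the pre-pseudoknot
fold by extension (they differ in lifetime, not length); that distinction
is made downstream by the mixture analysis, as intended. The equilibrium
force of stepped constant-force protocols is reported descriptively (the
force with nearest 50/50 occupancy) and not modeled further.
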