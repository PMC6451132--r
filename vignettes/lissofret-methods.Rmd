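---
title: "Models and methods behind lissofret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lissofret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lissofret)
```

This vignette is the package's own account of its models, conventions and
numerical choices. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` compute.

## The thermodynamic binding model

A pre-translocation 80S ribosome with donor-labelled P-site tRNA and
acceptor-labelled A-site tRNA interconverts between a high-FRET Classical
state and two hybrid states. An E-site inhibitor binds both conformations
but stabilizes the classical one. The package models four species —
Classical, Hybrid, Classical·drug, Hybrid·drug — with Boltzmann weights
`1`, `K0`, `[I]/KI`, `[I]/(KI·K2)`, giving the classical fraction

$$f_c([I]) = \frac{1 + [I]/K_I}{1 + K_0 + ([I]/K_I)\,(1 + 1/K_2)}.$$

`K0` and `K2` are dimensionless classical→hybrid equilibrium constants on
the drug-free and drug-bound ribosome; `KI` carries the concentration
unit (μM throughout). The limits `f_c(0) = 1/(1+K_0)` and
`f_c(\infty) = 1/(1+1/K_2)` anchor the two plateaus, and `f_c` is monotone
with the sign of `K0 − 1/K2`. The implementation
(`predict_fraction_classical()`) is verified in the tests against the
explicit partition-function computation.

Drug binding is treated as pre-equilibrated at each concentration, as in
a titration experiment where the drug is allowed to equilibrate with
surface-immobilized complexes before acquisition; no binding kinetics are
simulated.

## What the synthetic-data generator emulates

`simulate_traces()` / `simulate_titration()` generate the study
conditions every downstream stage is tested on:

* **States and emissions.** Three states with Gaussian FRET emissions at
  the published species values — yeast 0.65/0.40/0.22 (SD 0.04/0.06/0.05),
  human 0.71/0.44/0.26 (SD 0.05/0.06/0.07). Intensity noise adds on top of
  these widths when efficiencies are recomputed from rendered intensities.
* **Hybrid split.** The binding model lumps both hybrid states; the
  generator divides hybrid occupancy by `hybrid_split` (fraction in
  Hybrid2): 0.6 for yeast, which favours Hybrid2, and 0.4 for human,
  which favours Hybrid1.
* **Dynamics.** No dwell-time constants are established for these
  complexes, so kinetics are free parameters: the chain stays put each
  frame with probability `1 − dt/dwell_mean` and otherwise redraws the
  state from the stationary distribution. This makes the stationary law
  exactly the thermodynamic occupancy for any dwell choice (state *i*'s
  mean dwell is `dwell_mean/(1 − π_i)`). Default `dwell_mean` is 0.5 s,
  comfortably above the 40 ms frame so idealization sees resolvable
  dwells; only equilibrium occupancies enter the acceptance surface.
* **Photophysics.** 40 ms frames, 600 frames per movie, total intensity
  1000 (arbitrary units) split `donor = total(1−E)`,
  `acceptor = total·E`, additive per-channel Gaussian noise (SD 40
  signal, 30 background), single-step photobleaching with an 8 s
  exponential lifetime, and donor blinks as a 0.02 s⁻¹ Poisson process
  with 0.12 s mean duration zeroing both channels. These are plausible
  TIRF camera-scale values chosen once; bleaching at 8 s ≈ 200 frames
  means roughly a fifth of traces die before the 50-frame QC lifetime, a
  realistic attrition level.
* **Randomness.** Everything flows from one integer seed. A master seed
  drawn with `set.seed()` yields per-concentration (and, in recovery
  studies, per-replicate) sub-seeds via `sample.int()`; each trace then
  consumes a common RNG stream sequentially. Identical seeds give
  byte-identical datasets.

What the generator does **not** emulate: gamma/crosstalk corrections,
acceptor direct excitation or photophysics, laser/illumination geometry,
intensity drift, and multi-step bleaching of the genuine fluorophores.
Passing recovery tests therefore demonstrate correctness of the analysis
chain under the stated statistical model, not robustness to every
instrumental artifact of real recordings.

## Trace selection

`apply_qc()` implements the standard smFRET selection criteria: a single
catastrophic photobleaching event, signal/background-noise ≥ 8, signal/
signal-noise ≥ 6, fewer than four donor blinks, donor–acceptor
correlation < 0.5, and at least 50 frames (2 s) with FRET ≥ 0.15. The
two noise ratios are not uniquely defined by that wording; the package
uses the conventions of common smFRET software and makes them
configurable:

* *signal/background-noise*: mean pre-bleach total intensity over the SD
  of the post-bleach total;
* *signal/signal-noise*: mean pre-bleach total over the first-difference
  (detrended) SD of the pre-bleach total, computed outside blink windows;
* *correlation*: Pearson correlation of raw pre-bleach donor and acceptor
  (a `detrended` mode using first differences is available — whether the
  original analyses used raw or corrected intensities is not knowable
  from the criteria alone, and raw is the default);
* *lifetime*: pre-bleach frames whose raw frame-wise FRET is ≥ 0.15,
  counted before idealization.

Photobleach detection is mean-shift binary segmentation on total
intensity. Split points are located by the weighted CUSUM statistic
(an unweighted mean difference prefers short extreme segments and can
shatter a single step); a split is accepted when its raw mean shift
exceeds `k·σ` with `k = 4`. The per-frame noise σ comes from upper
quantiles of absolute first differences (0.9 and 0.98 quantiles, scaled
by the Gaussian constants), which stays valid when large parts of a
trace are noiseless. The bleach frame is the first downward step after
which *every* later segment mean sits at background — a blink's recovery
segment violates this, so blinks are never mistaken for the bleach — and
`n_bleach_steps` counts only sustained downward steps for the same
reason. A blink is a pre-bleach run of frames (minimum one) with total
intensity below background + `k·σ_bg` in both channels, followed by
recovery.

The filter is a pure function of (trace, criteria): idempotent, and
monotone in every threshold (property-tested).

## Idealization

`compute_fret()` computes `E = acceptor/(acceptor + donor)` on pre-bleach
frames, masking frames whose total falls below 30 % of the trace's mean
pre-bleach total (blinks, partial dropouts). `fit_hmm()` runs Baum–Welch
on a three-state Gaussian-emission HMM with all transitions allowed and
one transition matrix shared across the traces of a condition; masked
frames are marginalized (emission likelihood 1). Numerical conventions:

* Default mode holds emission means *and* SDs fixed at the species'
  published state values and estimates only the transition matrix and
  initial distribution — the state definitions are fixed quantities in
  this analysis tradition. A free-fit mode (`fix_means = FALSE`,
  `fix_sds = FALSE`) exists and is what the classical-mean recovery
  studies use; whether the original software fixed or estimated emissions
  per condition is unstated, so both are provided with fixed as default.
* Variance floor `1e-4` (SD floor 0.01) against state collapse in free
  fits; engaging the floor flags the fit.
* Convergence when the log-likelihood improves by less than `tolerance`
  (default 0.01) or after `max_iterations`; the log-likelihood trace is
  stored and its monotonicity asserted in tests.
* Viterbi decoding per trace, log-space, ties broken toward the lowest
  state index; no explicit dark state is modelled (QC removes blink-heavy
  traces first).
* Scaled forward–backward recursions in compiled code; correctness is
  pinned to exhaustive path enumeration for short series.

## Titration points and the isotherm fit

`fraction_classical()` pools Viterbi-assigned frames across traces within
a concentration (the pooled frame fraction, not the mean of per-trace
fractions — both are defensible; pooling weights traces by their
information content) and attaches a bootstrap-over-traces SEM (default
1000 resamples, seeded).

`fit_titration()` minimizes `Σ w (f_obs − f_c)²` with `w = 1/sem²`
(unweighted fallback when any SEM is zero), on log-parameters so all
constants stay positive, using Levenberg–Marquardt from a small
multi-start grid (data-driven `K0`/`K2` starts, five log-spaced `KI`
starts spanning the concentration range). Standard errors come from the
curvature at the optimum (pseudo-inverse when the Hessian is singular),
mapped to the natural scale by the delta method. A parameter whose
relative standard error exceeds 1 — typically `K2` when the titration
never approaches saturation, occasionally with a runaway point estimate —
is flagged `weakly_identified` rather than silently reported. Per-drug
independent fits are the default; `K0` is not shared across drugs.

Because `K0` and `K2` are never published for these complexes, recovery
studies generate data with `K0 = 4`, `K2 = 10`: a drug-free classical
fraction of 0.2 and a saturating fraction ≈ 0.91, qualitatively matching
the hybrid-state preference of drug-free pre-translocation complexes and
the titration plateaus. These are synthetic choices, not measured values.

**Study sizes.** The packaged recovery studies (acceptance tests and
`scripts/acceptance.R`) simulate 200 traces per concentration — of which
roughly 70 % survive QC — across six concentrations, and take the median
fitted `K_I` over 25 independently seeded replicates. These sizes give a
median standard error well inside the published uncertainty bands while
keeping a full five-study run in minutes on one CPU; they are the
package's documented defaults, and all sizes are arguments.

## Contact geometry

* Ring centroids are plain atom-coordinate means; ring normals are the
  smallest-principal-axis eigenvector of the centered ring atoms (the
  total-least-squares plane), sign-normalized so the largest component is
  positive.
* For purine halogen–π contacts the **six-membered ring** centroid is the
  default reference; published distance reports rarely say which center
  was used, so `five` and `fused` modes are selectable and worth
  reporting when they differ materially (> 0.2 Å).
* Cutoffs follow halogen–π literature conventions: centroid distance
  ≤ 4.5 Å, face-on when the halogen–centroid vector is within 40° of the
  ring normal; polar contacts use a 3.6 Å heavy-atom screen without
  requiring hydrogens. All cutoffs are arguments.
* Superposition is the SVD (Kabsch) construction with the reflection
  guard. Published pocket RMSDs depend on atom selections ("minimized
  E-site regions") that are not fully specified; `superpose_rmsd()`
  therefore takes explicit paired selections and makes no claim about
  reproducing any particular published selection.
* Structures are read via bio3d (PDB and mmCIF), first model only,
  as-deposited numbering, altlocs resolved to highest occupancy, elements
  inferred from atom names when absent.

`synthetic_esite_pocket()` builds an idealized pocket — two guanines, a
cytosine and a two-chlorine ligand at textbook contact geometry — so the
whole measurement chain runs and is demonstrable without any coordinate
download. It is labelled synthetic everywhere; measurements on it
validate the machinery, not any deposited model.

## Interaction-energy ledger

`lissoclimide_energies()` ships the per-component BLYP-D3 interaction
energies of the reduced C45 and CL pocket models (components `PVF`,
`Cyto`, `Gua`, plus the all-components net row) as a plain CSV fixture.
These are consumed as printed inputs — the quantum-chemical pipeline that
produced them is out of scope. `compare_energy_tables()` reports signed
per-component and net differences and each table's additivity gap
(net − Σ components), the many-body residual. The packaged values yield a
net |CL − C45| difference of 12.23 kcal/mol, reproduced exactly in the
tests; note these energies exclude deformation and desolvation terms, so
they rank interactions rather than predict affinities.

## Known limitations

* Dissociation/association kinetics (rate constants, dead-time
  correction) are out of scope; the simulator's dwell times are
  placeholders that only need to dominate the frame time.
* The emission model is Gaussian per state on the efficiency scale;
  beta-like distortions near 0/1 are not modelled.
* QC noise-ratio definitions are conventions (documented above), not a
  reconstruction of any specific software's internals.
* Superposition RMSD values are selection-dependent; the package provides
  the operation, not canonical selections.
* The free-fit HMM estimates one emission set per condition; per-trace
  heterogeneity is not modelled.
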