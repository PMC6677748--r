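---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`statorna` implements the computational layer of a Na⁺-conduction study of
the PomA/PomB flagellar stator: geometric statistics over MD trajectory
frames, aggregation of constant-velocity pulling (steered-MD) force logs,
and ATR-FTIR difference-spectroscopy processing with Hill binding fits. This
vignette records the models, the tunable parameters and their defaults, the
numerical decisions taken where the procedure was genuinely open, and what
the synthetic generators do and do not establish.

## Trajectory statistics

**Containers.** A `trajectory` couples a fixed topology (one row per atom:
serial, name, residue, chain, element) with an `n_atoms × 3 × n_frames`
coordinate array in Å and per-frame times in ns. Multi-model PDB is the
interchange format; both `ATOM` and `HETATM` records are ingested because
waters and ions are commonly deposited as `HETATM`. Residue names occupy
columns 18–21 so that four-character lipid names (POPE, POPG) survive a
round trip; coordinates round-trip to the 10⁻³ Å precision of the format.
Frame times default to 0, 1, 2, … ns (per-ns saved frames); the membrane
normal is +z with the periplasmic side positive, and a trajectory-level
`z_flip` flag flips the convention (the sign is not dictated by the data).

**Contact fraction** (default cutoff 3.5 Å): for each residue, the fraction
of frames in which *any non-hydrogen* atom of the residue lies within the
cutoff of any probe atom (the Na⁺ ion, or water oxygens). The frame set is
exactly the supplied trajectory view — `select_frames(traj, 25, 1)` restricts
a 400-frame per-ns trajectory to its last 375 frames — and frames are
weighted uniformly. Distances are plain Euclidean with no minimum-image
wrap: deposited frames are whole-molecule. Hydrogens are identified from
the PDB element column when present, else by a name heuristic (leading
digits stripped; monoatomic ions resolved by a fixed lookup requiring atom
name = residue name, so THR `HG1` is hydrogen while residue `NA`'s `NA` is
sodium).

**Coordination number** (default cutoff 2.5 Å): the count of polar atoms
(O, N, S) belonging to protein or water within the cutoff of the ion;
hydrogens and the ion itself never count. A species filter gives the
protein-only and water-only counts, which sum to the total in every frame.

**Hydrophobic thickness**: per frame, `mean(z_top) − mean(z_bottom)` over
leaflet marker atoms — phosphorus atoms, or ester carbons (`C21`/`C31`
naming family, configurable) for the tighter bound. When leaflets are not
given explicitly they are assigned per frame by the sign of the marker z
about the median marker z; the original procedure is not documented, and the
median split is deterministic and robust to drift of the bilayer midplane.

**Helix assignment**: no specific propensity tool is documented, so a
deterministic dihedral-window rule is used: a residue is helical iff
φ ∈ [−100°, −30°], ψ ∈ [−80°, 5°], and it belongs to a run of ≥ 4
consecutive such residues within one chain with contiguous numbering.
Chain termini and residues with missing backbone atoms are unassessed and
break runs — so an ideal 10-residue helix yields 8 assessed, all-helical
residues in one run. The rule needs no hydrogen placement or H-bond
energies, which keeps it testable against geometry built from exact
internal coordinates (`build_peptide`).

**Kabsch RMSD**: optimal translation plus proper rotation via SVD with the
determinant sign correction; symmetric, zero iff congruent (tolerance
10⁻⁶), and equal to the closed form on degenerate two-point sets (0.5 Å for
segments of length 1 vs 2).

## Steered-MD force profiles

Force logs are plain TSV (`time_ps`, `z_A`, `force_kcal_mol_A`, `#`
comments). Records from all trials of a set (10 in the production protocol)
are pooled, sorted by ion z with a stable (trial, time) tie-break, and the
value sequence is smoothed with a centered moving average — 501 points for
force, 101 for coordination. "~500 surrounding points" is normalized to a
symmetric odd window including the point itself, truncated at the edges;
the off-by-one relative to a 500-point window is immaterial at this width,
and smoothing the pooled sequence (not per-trial curves) matches how the
sets are assembled. The smoother is length-preserving, stays within the
input's range, and preserves a constant series exactly.

The peak is the global maximum of the smoothed curve; secondary local maxima
above a prominence threshold (default 5 % of the range) are also reported.
The mutant/WT comparison statistic is `max(mut)/max(wt)`; free-energy
estimates (Jarzynski, umbrella) are deliberately out of scope because the
pulling speed regime does not support them.

## The pulling surrogate

`simulate_smd_1d` evolves the ion's z by overdamped (inertia-free) Langevin
dynamics in a user-specified sum-of-Gaussians potential, with the spring
anchored at `z₀ + v·t`:

> dz = [−U′(z) + k(z_anchor − z)]/γ · dt + √(2 k_B T dt/γ) ξ

Defaults are the production schedule (k = 6.16 kcal mol⁻¹ Å⁻²,
v = 0.05 Å/ps, 50 Å in 1000 ps), T = 310 K, and γ = 20 kcal ps mol⁻¹ Å⁻²,
chosen so the flat-potential drag force γv equals 1 kcal mol⁻¹ Å⁻¹ at the
default velocity. The recorded observable is the spring force
`k(z_anchor − z)`, positive when pulling toward +z. Integration uses
Euler–Maruyama; stability requires `dt < γ/(k + max|U″|)`, checked against a
numerical bound on U″ before the run, and a diverging trajectory aborts with
advice to reduce `dt`. The lateral x/y restraint of the 3D protocol has no
1D counterpart and is carried as metadata only.

Two verifiable limits anchor the surrogate. (i) Flat potential at T = 0:
after a relaxation transient of ~γ/k the recorded force equals γv exactly.
(ii) Quasi-static regime (low velocity, modest noise): the smoothed force
profile tracks dU/dz + γv, so the peak sits within 1 Å of argmax dU/dz and
within 10 % of its magnitude. The acceptance tests run this limit at
v = 0.0125 Å/ps, γ = 40, T = 60 K with a 2001-point window — a *regime
choice for testing the deterministic limit*, not a change to the default
generator. For the ×1.42 barrier-scaling check the barrier (height
25 kcal/mol, width 2 Å) is chosen once so that the barrier force
(≈7.6 kcal mol⁻¹ Å⁻¹) dominates the drag and noise floor, mirroring force
peaks that tower over the baseline; the additive drag still biases the
ratio slightly below 1.42 (≈1.36–1.42 across seeds), inside the ±10 %
acceptance band.

## FTIR processing

Spectra live on a strictly descending uniform grid (default 1800→1000 cm⁻¹
at the 2 cm⁻¹ instrument resolution). The chain is: pointwise
ligand-on-minus-off differences; pointwise averaging over forward/backward
binding cycles (6–30 in practice); optional baseline-drift subtraction —
least squares over band-free anchor windows (default 1780–1750 and
1010–1000 cm⁻¹, linear by default, polynomial optional) applied to the full
spectrum; and the Na⁺−K⁺ double difference, which cancels non-selective
cation responses exactly and isolates the Na⁺-selective bands (mutants
lacking the selective site give flat lines).

**Band intensity** is the value at the positive-lobe wavenumber minus the
value at the negative-lobe wavenumber, each snapped to the nearest
gridpoint — a point estimate, not an integrated area, because the plotted
quantity is peak/trough intensities at named positions (1662(+)/1648(−) and
1115(+)/1061(−) cm⁻¹; note 1115 and 1061 are odd numbers on an even grid,
hence the snap).

**Hill fits** minimize squared error of I(C) = A·Cⁿ/(K_dⁿ + Cⁿ) in
log-parameter space (positivity for free), starting from A₀ = max intensity,
K_d₀ = concentration nearest half-max, n₀ = 1, with two deterministic
jittered restarts and a Nelder–Mead polish; non-convergence from all starts
is an error carrying the best SSE. On noiseless data over the
six-concentration design (0.5–100 mM) recovery is better than 10⁻⁴ relative
across K_d ∈ [0.5, 50] mM, n ∈ [0.5, 2].

**Coordination-mode classification**: ν_as − ν_s ≤ 140 cm⁻¹ calls
bidentate/pseudobridged, ≥ 150 calls less-bidentate, the gap is
indeterminate. The thresholds separate the two published ranges (100–139 vs
159–164 cm⁻¹) with a buffer and are configurable.

## Synthetic generators: what a green test establishes

Every generator returns a `(data, truth)` pair and draws all randomness from
one explicit seed (identical seeds give bit-identical outputs).

- **Membrane**: 324 POPE : 108 POPG pseudo-lipids on a lattice
  (60 Å²/lipid), balanced leaflets, phosphorus markers at ±thickness/2 with
  0.5 Å Gaussian jitter and ester carbons 4 Å inward. Default thickness is
  38.2 Å, the measured initial-model value. It emulates leaflet marker
  geometry only — no acyl chains, no protein, no undulations — so it
  validates the thickness *estimator*, not membrane physics.
- **Scripted binding trajectories**: the probe sits exactly 2.0 Å from the
  target residue during scripted frame intervals and ≥ 10 Å from everything
  otherwise, so contact fractions are known *exactly*. Intervals must not
  overlap across residues (a single probe cannot serve two sites 30 Å
  apart in one frame; the interval API is 1-based inclusive).
- **FTIR model**: signed Gaussian bands (σ = 6 cm⁻¹) at the observed band
  positions. All amide/carboxylate Na⁺-selective bands share one Hill
  response (K_d 3.5 mM, n 0.9) and the Thr C–O bands (1115/1086/1061) share
  the other (K_d 6.5 mM, n 0.7) — one binding curve per spectral region, as
  the fits assume; non-selective bands (responding to all cations,
  K_d 8 mM, n 1 — a choice, stated once) are placed at 1700 and 1580 cm⁻¹
  where their 6 cm⁻¹ tails are < 10⁻⁸ at the fitted pairs, so noiseless
  recovery is exact to the 10⁻⁴ tolerance. Default noise sd 0.005 and
  drift sd 0.01 give visually realistic single-cycle spectra. The model
  does not emulate H/D band shifts, lineshape asymmetry or water-vapor
  artifacts.
- **Pulling surrogate**: see above. It reproduces the *structure* of the
  analysis (pooling, smoothing, peaks, ratios, convergence) — never the
  absolute force magnitudes of the all-atom system.

Consequently the trajectory-derived headline numbers of the original study
(water affinities 1.00/1.00/0.98/0.95, the ~8 Å vs ~19 Å sliding distances,
the 1.42/1.36 force-peak ratios) are *not* reproducible without the original
cluster-scale trajectories; the tests instead close the loop against
brute-force oracles and generator ground truth, and treat the ~-valued
distances as qualitative context. The deposited initial/105 ns/305 ns
coordinate models are not redistributable inside the package, so the
deposited-model checks (38.2 ± 0.3 Å phosphorus thickness, 16.29 Å Q54–V149
Cα distance) run on synthetic stand-ins built at the printed geometry; if a
user supplies the deposited PDB via
`options(statorna.dataset1_pdb = "path")`, the same assertions run on the
real coordinates.

## Pipeline

Run configs are JSON (the `yaml` package is not a guaranteed dependency of
the target environment), validated against a closed schema before any stage
runs; all defaults are the study parameters (3.5/2.5 Å cutoffs, 501/101
windows, 6.16 spring, 0.05 Å/ps, NaCl series 0.5–100 mM). The `synth` stage
writes every input class to disk and the analysis stages read them back, so
a pipeline run exercises the same I/O paths as user data. The manifest
records package and R versions, the seed, all parameters and an md5 per
output; identical config + seed gives byte-identical tables.

## Known limitations

- No periodic minimum-image distances (flag-gated orthorhombic wrap was
  considered and dropped: deposited frames are whole-molecule; document your
  own wrapping if you feed raw engine output).
- Helix assignment is binary helix/non-helix; no DSSP-style classes.
- The 1D surrogate has no inertia, no lateral restraint and no
  z-dependent friction.
- Band intensities are point estimates; integrated areas would be more
  robust to small calibration shifts but would not match the plotted
  quantity.
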