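---
title: "The mechanical Ising model behind repeatspring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mechanical Ising model behind repeatspring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatspring)
```

`repeatspring` models the equilibrium force response of consensus
tetratricopeptide repeat (CTPR) solenoids in a dual-trap optical-tweezers
assay and extracts helix- and repeat-level folding energetics from
force–distance curves (FDCs). This vignette explains the model, its
assumptions, the tunable parameters, the numerics, and what the synthetic
data can and cannot tell you about real measurements.

## The model

**Folding energetics.** Each CTPR repeat contributes an A- and a B-helix to
a one-dimensional lattice. A configuration assigns every helix a binary fold
state; helices are indexed from the C-terminus (index 0 is the C-terminal
B-helix). Unfolded helices define the zero of energy. Folded helices
contribute intrinsic energies `g_A`, `g_B` (kT), and adjacent folded pairs
contribute an interface term: `g_AB` inside a repeat, `g_BA` between
repeats. An optional model variant adds next-nearest-neighbor couplings
`g_AA`, `g_BB` between like helices of adjacent repeats; these are
constrained non-positive, since an extra interfacial contact either
stabilizes or is absent. Collapsing a repeat gives the two numbers usually
quoted for repeat proteins,

\[
\Delta G_\mathrm{unit} = g_A + g_B + g_{AB}, \qquad
\Delta G_\mathrm{nn} = g_{BA}, \qquad
\Delta G_\mathrm{tot}(N) = N\,\Delta G_\mathrm{unit} + (N-1)\,\Delta G_\mathrm{nn}.
\]

The first identity is a convention: all intra-repeat structure is assigned
to the unit term and the inter-repeat interface carries the coupling. It is
the only decomposition consistent with the total-energy relation above, and
`config_fold_energy()` of a fully folded array reproduces
`total_free_energy()` exactly (this is asserted in the tests).

**Expanding repeat energies to helices.** When only `dG_unit` and `dG_nn`
are known, `helix_params_from_repeat()` distributes them over the helix
lattice. The *uniform* split gives every adjacent-helix interface the
coupling (`g_AB = g_BA = dG_nn`) and divides the remainder equally
(`g_A = g_B = (dG_unit - dG_nn)/2`). It is exactly mirror-symmetric, which
makes it the right bookkeeping for zero-force statistics (the minimal
stable unit below) but makes the two array ends thermodynamically
identical — a symmetric model cannot prefer either terminus. Because the
C-terminal B-helix of a real CTPR is solvent-exposed and held only by its
intra-repeat interface, the construct presets use a mildly *asymmetric*
split in which the B-helix is `delta = 0.5` kT less stable than the A-helix
(sums preserved). The 0.5 kT scale is a package choice: large enough that
unzipping reliably starts at helix 0, small enough to leave plateau forces
and minimal-unit counts unchanged. Helix-resolved energies from global fits
to the original data are not public, so this asymmetry should be read as
qualitative.

**Configuration spaces.** Three enumerations are supported.
`full` is all \(2^n\) states (capped at 24 units). `zipper` keeps the empty
state and every single contiguous folded block — \(n(n+1)/2 + 1\) states —
and is exact enough for all constructs studied here. `skip` removes
configurations whose entire folded content is one or two helices that touch
neither terminus (short folding nuclei in the interior are statistically
negligible; terminal frays are kept). For four helices the skip filter
removes exactly `0100`, `0010` and `0110`, leaving 13 of 16 states. Note
that a lone *internal* contiguous block of one or two helices is a zipper
state that skip removes, so zipper is not literally a subset of skip; the
two agree on everything with three or more folded helices or terminal
contact, and their predicted FDCs agree to well under 0.05 pN for the
arrays tested.

**Mechanics.** At trap separation \(d\), each configuration's tension
\(F^*(c, d)\) balances the serial network: two harmonic traps (0.30 pN/nm
each), a dsDNA handle modelled as an extensible worm-like chain (contour
350 nm, persistence 40 nm, stretch modulus 1200 pN), and the unfolded
polypeptide as a Marko–Siggia worm-like chain (persistence 0.9 nm,
0.365 nm of contour per residue, 17 residues per helix unit). These handle
and chain constants are standard literature stand-ins — the original
construct's values are not published — and every one of them is
configurable (`network_from_config()` accepts the flat keys `kT_pNnm`,
`trap_stiffness_pN_per_nm`, `handle.Lc_nm`, `handle.Lp_nm`, `handle.K_pN`,
`chain.Lp_nm`, `chain.nm_per_residue`). The folded remainder enters as a
rigid extension: each maximal folded segment spanning \(m\) repeats (a lone
helix counts as half a repeat) contributes the chord of a circular helix,

\[
\xi(m) = \sqrt{(m\,r)^2 + \bigl(2R\sin(m\,\phi/2)\bigr)^2} + \xi_0 .
\]

The chord flattens once per completed superhelical turn, and that geometric
modulation is what produces the reproducible force oscillations across the
plateau; replacing it with the beads-on-a-string interpolation
\(\xi = (n_\mathrm{folded}/n)\,\xi_\mathrm{max}\) (kept as
`extension_model = "beads"`) flattens the plateau. The geometry presets are
calibrated to the CTPR solenoid: 45° of superhelical phase per repeat
(about eight repeats per turn), 0.95 nm rise per repeat and a 2.2 nm axis
radius for the parental variant, 2.6 nm radius and 0.85 nm rise for the
wider, shorter redesigned variant, with a 1 nm terminal offset. The radius
refers to the path of the repeat centroids, not the solenoid's outer
envelope: with an outer-envelope radius (~3.5 nm) the chord modulation
reaches ±1.7 pN and no defined plateau survives, while the axis-radius
calibration gives the observed sub-pN oscillations and exactly two and
three periods for 20- and 26-repeat arrays.

**The observable.** With total stored energy
\(E(c,d) = G_\mathrm{fold}(c) + G_\mathrm{mech}(F^*(c,d))/kT\), the model
FDC is the Boltzmann average of the per-configuration tensions. This equals
the derivative of the total free energy \(-kT\ln Z(d)\) with respect to
separation; both routes are implemented (`equilibrium_fdc()`,
`fdc_from_free_energy()`) and agree to better than 0.05 pN on the default
grid, and the integral of the model force over separation reproduces the
free-energy difference between the endpoints to a relative 10⁻³
(thermodynamic consistency tests).

## Derived statistics

* **Fold-probability profiles** (`helix_fold_profile()`): per-helix
  marginals versus separation. With the preset asymmetry, helix 0 loses
  fold probability at smaller separation than the N-terminal helix —
  unzipping starts at the C-terminus.
* **Seed size** (`seed_size()`): the separation at which the fully
  unfolded configuration reaches 50% population is found by bisection
  (0.01 nm tolerance), and the expected folded-helix count over the
  remaining configurations is reported. It is insensitive to array length.
* **Minimal stable unit** (`minimal_stable_unit()`): the shortest run of
  consecutive folded helices with negative fold energy under the uniform
  split — three helices for the redesigned variant
  (`dG_unit = 1.1`, `dG_nn = -11.0` kT), two for the parental one
  (`-1.9`, `-12.7` kT). A single parental repeat is marginally stable and
  about 13% unfolded at equilibrium (`fraction_unfolded(-1.9)`).
* **Folding work** (`unfolding_work()`): the trapezoidal area between the
  measured (or model) curve and the always-unfolded reference of the same
  construct, negated so folding work is negative. The reference-baseline
  choice is validated against the partition-function identity
  \(W_F \approx -kT\ln(Z/Z_\mathrm{unfolded})\big|_{d_1}^{d_2}\) (5%
  relative) rather than against any published convention, which is not
  available in detail.
* **Plateau force** (`plateau_force()`): a single Gaussian fitted to the
  force histogram (0.1 pN bins) inside the plateau window. The window is
  auto-detected as the longest run with local slope below 0.02 pN/nm
  (slope from a ±5 nm local regression), merging sub-threshold runs
  separated by less than 50 nm so that superhelical oscillation flanks do
  not split the plateau. For noiseless model curves the histogram is built
  by spreading each point with its thermal mixture force SD — the
  occupation histogram of an idealized curve is a sum of spikes and would
  make the fit degenerate — which reproduces what an instrument records.

## Fitting

`fit_fdc()` performs bounded Levenberg–Marquardt least squares of the model
force against an averaged FDC. Three details matter in practice:

1. **Cached mechanics.** The state space, folded extensions and force
   balances do not depend on the Ising energies, so they are computed once
   per fit and only the fold energies are re-scored per iteration.
2. **Multistart.** The residual surface has a curved, shallow valley along
   the direction that trades intrinsic against interfacial stability (the
   familiar diagonal scatter of per-molecule estimates); a single start can
   stall partway along it. The optimizer runs from a small grid of starting
   points and keeps the best minimum; nested variants are best started from
   the simpler variant's optimum (`start =`), which guarantees the nested
   RSS ordering that AIC comparison assumes.
3. **Offset nuisance parameters.** Rigid distance and force offsets are
   estimated alongside the energetics (`fit_offsets = TRUE`). Cycle
   alignment removes relative offsets but the reference curve's own
   zero-distance and force-baseline miscalibration survives averaging;
   absorbing it in the fit removes a bias and makes the curvature standard
   errors cover (a 20-replicate simulation gives 2σ coverage of 20/20 with
   offsets versus 12/20 without). Residuals are inverse-variance weighted
   by the per-bin standard errors when present.

`compare_models()` ranks variants by the Gaussian-residual AIC
\(n\ln(\mathrm{RSS}/n) + 2k\). `fit_denaturation()` implements the global
ensemble analysis: a repeat-level homopolymer Ising model across several
array lengths with a linear denaturant dependence of the intrinsic energy
(`dG_unit(D) = dG_unit + m_unit D`), a denaturant-independent coupling, and
linear folded/unfolded baselines; the fraction folded comes from exact
enumeration up to 15 repeats and a log-rescaled transfer-matrix recursion
beyond.

## The synthetic-data generator

`generate_fdc_cycles()` emulates the instrument around the exact model
curve: additive Gaussian force noise with variance
\(\sigma_\mathrm{instr}^2 + \mathrm{Var}_\mathrm{mix}(F) + kT\,k_\mathrm{eff}\),
where the mixture variance (configuration-to-configuration force spread at
fixed separation) makes the plateau and dip visibly noisier than the linker
branches, as in the measurements; plus per-cycle rigid offsets
(SD 0.2 pN and 1 nm) emulating per-molecule miscalibration. Stretch and
relax sweeps follow the same equilibrium curve, as observed at pulling
speeds at or below 100 nm/s. Defaults: 0.3 pN instrument noise, thermal
term on, 0.25 nm separation grid (the engine's default grid step), all
reproducible from a single integer seed. `generate_denaturation()` produces
the matching chemical-denaturation families with sloping baselines.

What the generator does *not* emulate: time-resolved hopping kinetics and
loading-rate-dependent hysteresis (only the equilibrium regime is modelled),
instrument drift within a cycle, bead Brownian dynamics, tether rupture, or
anharmonic trap profiles. Passing the round-trip tests therefore shows that
the estimators are consistent and calibrated for equilibrium data with
white force noise and rigid offsets — not that they are robust to drift or
kinetic artifacts in real traces.

`align_fdcs()` estimates per-cycle rigid offsets against the first cycle by
scanning the distance offset in 0.5 nm steps with the force offset profiled
out in closed form, then refining continuously. Because FDC branches are
locally straight, pure least squares is nearly degenerate along
\(\delta F = \mathrm{slope}\times\delta d\) and noisy curves wander 2–3 nm
along that valley; a weak Gaussian prior at the known offset scales
(0.2 pN, 1 nm) regularizes the degenerate direction and vanishes for
noiseless curves.

## Numerical choices

* Marko–Siggia inversion: 13 vectorized bisection halvings bracket the
  relative extension to ~10⁻⁶, five clamped Newton steps polish to machine
  precision (the residual is increasing and convex, so clamped Newton
  cannot leave the bracket).
* Force balances: the public `series_force_balance()` uses `uniroot` on a
  [0, 200] pN bracket with 10⁻⁶ pN tolerance and returns exactly 0 below
  slack; the engine uses 52 fixed vectorized halvings of the same bracket.
  Configurations whose elements cannot span the gap even at the bracket top
  are sterically excluded (infinite stored energy) rather than evaluated at
  a capped force.
* Stored stretching energies: closed antiderivatives of the Marko–Siggia
  form in the engine; the public `stretch_free_energy()` integrates
  adaptively and is cross-checked against a Richardson-refined trapezoid in
  the tests.
* Boltzmann weights are exponentiated after subtracting the minimum energy;
  probabilities normalize to 1 within 10⁻¹².
* Ranking ties in `ensemble_snapshot()` break by folded-helix count
  (descending), then lexicographic fold-state string.
* Default grids: 0.25 nm separation step; 1 nm averaging bins; 0.1 pN
  histogram bins; d* bisection tolerance 0.01 nm.
* Study sizes used in the test suite: 5–10-repeat constructs, 30 cycles per
  molecule, 20 replicates for the coverage and model-selection studies —
  sizes at which every study completes in minutes while the Monte-Carlo
  assertions (≥90% coverage, ≥18/20 AIC selections) remain sharp.

## Known limitations

* The folded remainder is rigid and aligned with the pulling axis; no
  orientational averaging or elastic deformation of the superhelix is
  modelled. The geometry parameters are calibrated stand-ins, not refined
  structural measurements.
* Helix-level asymmetry (`delta`) is a qualitative device for pathway
  directionality; only its sign is supported by structural reasoning.
* Everything is equilibrium thermodynamics: no rates, no hysteresis, no
  loading-rate dependence.
* The `skip`/`full` enumerations are exponential and capped at 24 units;
  long arrays require `zipper` (which the energetics comparisons justify).
* Absolute plateau forces inherit the uncertainty of the handle/chain
  stand-in constants; with the defaults the simulated plateau centers sit
  a few percent below the experimentally quoted values (12.0 versus
  ≈12.5 pN for the parental variant, 9.3 versus ≈9.5 pN for the
  redesigned one) while their ordering and separation-dependence are
  reproduced.
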