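---
title: "Difference maps, extrapolated structure factors, and population transfer: methods"
author: "trxmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference maps, extrapolated structure factors, and population transfer: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trxmap)
```

## The problem

In a pump–probe crystallography experiment only a fraction *p* of the
molecules in each microcrystal enters the photocycle.  The merged
"pumped" amplitudes therefore belong to a mixed crystal whose structure
factors are, per reflection, the complex population-weighted sum

\[ F_\mathrm{mix}(h) = (1-p)\,F_\mathrm{dark}(h) + p\,F_\mathrm{light}(h), \]

while the deposited observable is only the modulus
\(|F_\mathrm{pump}| \approx |F_\mathrm{mix}|\).  Everything this package
does — difference maps, extrapolation, population-transfer estimates,
and the geometry analytics around them — is downstream of that mixing.

## Difference maps

The difference map (DMAP) is the Fourier synthesis of
\(\Delta|F| = |F_\mathrm{pump}| - |F_\mathrm{dark}|\) with phases of the
refined dark model:

\[ \Delta\rho(r) = \tfrac{1}{V} \sum_h w_h\, \Delta|F|_h\,
   e^{i\Phi_\mathrm{dark}(h)} e^{-2\pi i h\cdot r} . \]

Before differencing, the pump set is brought onto the dark scale by a
least-squares fit of \(|F_\mathrm{pump}| \approx k\,e^{-Bs^2/4}|F_\mathrm{dark}|\)
(`scale_datasets()`).  Reflections present in only one set are dropped,
never zero-filled, and the completeness loss is reported: a zero-filled
difference coefficient is a fabricated measurement and biases the map.

Outliers are suppressed with the q-weighting of the difference-Fourier
lineage (`weight_differences()`):

\[ w_h = \frac{1}{1 + \sigma_{\Delta,h}^2/\langle\sigma_\Delta^2\rangle
        + \alpha\,\Delta|F|_h^2 / \langle \Delta|F|^2\rangle},
   \qquad \alpha = 1 \text{ by default.} \]

Maps are sigma-scaled over all grid points (no solvent mask), which is
the convention behind quoted feature heights such as "−15 σ".  Peak
search (`find_peaks()`) refines the band-limited map by exact Fourier
(zero-padding) interpolation before the 26-neighbour extremum test, so
reported heights are stable to about 1% against the choice of synthesis
grid; each peak is attributed to the nearest atom under minimum-image
distances.

## Extrapolated structure factors and the choice of N_ext

Extrapolation amplifies the minority state so it can be modelled as if
fully occupied:

\[ |F_\mathrm{ext}| = |FC_\mathrm{dark}| + N\,\Delta|F|, \qquad
   \text{phases } \Phi_\mathrm{dark}, \]

with \(|FC_\mathrm{dark}|\) calculated from the refined dark model
rather than taken from the noisy dark measurement.

Because the extrapolated map is exactly linear in \(N\) when negative
coefficients are treated as phase flips,

\[ \rho_\mathrm{ext}(r; N) = \rho_\mathrm{calc,dark}(r) + N\,\Delta\rho(r), \]

`next_scan()` synthesizes the two component maps once and evaluates the
whole scan algebraically.  Clamping negative amplitudes at zero is done
only when exporting amplitude sets for external refinement programs
(with a quality warning above 5% clamped): inside the scan, clamping
would rectify noise into a systematically positive density and can
suppress the zero crossing entirely.

The scan criterion operationalizes "the dark density at strong negative
difference features just vanishes": the mask is the set of grid points
within 2 Å of the user-named atoms (for a retinal system, the
isomerizing chain atoms and the displaced ion) **that also carry a
strong negative DMAP feature** (≤ −3 σ by default, relaxed adaptively
for weak signals).  Restricting the sphere to the negative features
matters: with displacements of 1–2 Å at ~1.8 Å resolution the arriving
(light-state) density overlaps a plain sphere around the vacated site
and pushes the zero crossing far too high.  The chosen `n_ext` is the
first zero crossing of the mean masked density, linearly interpolated
and snapped to the scan grid; the negative-density sum S(N) is retained
for inspection (`plot()` method) because its growth past the crossing is
the classic false-negative-feature diagnostic of over-extrapolation.

### The factor of two and the population transfer

A difference Fourier map computed from amplitude differences with
reference phases shows features at roughly **half** their true height:
\(\Delta|F|\) is the projection of the complex difference onto the dark
phase direction, and the in-phase half is all the map sees.  The dark
density at a vacated site is therefore cancelled near
\(N \approx 2/p\), not \(1/p\), and the population transfer follows the
half-height convention

\[ \mathrm{PT} \;=\; \frac{2 \times 100}{N_\mathrm{ext}}\ \%. \]

This is not just first-order algebra; it is what the package's own
simulator shows.  Noise-free synthetic experiments put the zero crossing
at \(2/p\) times a modest overlap factor, never anywhere near
\(1/(2p)\); an implementation using \(\mathrm{PT} = 100/(2N)\) would
misreport the simulated ground truth several-fold, which is why the
end-to-end recovery tests pin this convention down.

Two further choices were measured rather than assumed:

* **Raw Δ|F| feeds extrapolation by default** (`use_weights = FALSE`).
  The α-term of the q-weight lands precisely on the large-|Δ|F|
  reflections that carry the localized-change signal; feeding α = 1
  weighted differences into the scan inflates `n_ext` two- to three-fold
  on simulated data.  Weighted differences remain the default for the
  sigma-scaled DMAP itself, where the overall scale cancels and outlier
  suppression is the point.  A flag restores weighted extrapolation
  (weights are then normalized to mean 1 so the Δ|F| scale — and with it
  the physical meaning of N — is preserved).
* **Phased extrapolation uses the unsigned observed difference.**
  `phased_extrapolation()` forms
  \(PF_\mathrm{ext} = FC_\mathrm{dark} + N\,|\Delta|F|_\mathrm{obs}|\,
  e^{i\varphi_\Delta}\) with \(\varphi_\Delta\) the phase of
  \(FC_\mathrm{light} - FC_\mathrm{dark}\).  The sign of the observed
  difference is itself the projection of that same calculated direction
  onto the dark phase; keeping it multiplies the correction by
  \(2\cos\theta\) whose average over reflections is ~0, and the phased
  map degenerates to the dark map (correlation with the true light
  density ≈ 0.02 on noise-free simulations, against 0.92–1.00 for the
  unsigned form).

## The synthetic two-state crystal

`build_toy_system()` generates a P1 cell (30 Å cube) containing a
10-residue poly-glycine helix, a planar 15-carbon conjugated chain
ending in a Schiff-base-like nitrogen, one chloride ion 3.2 Å from that
nitrogen, and ~10 seeded waters (67 atoms).  The light state rotates the
chain tip about the C13–C14 bond (default −175°, flipping the
C12-C13-C14-C15 torsion from 180° to 5°, the magnitude of an
all-trans → 13-cis isomerization) and displaces the ion by exactly
1.3 Å — the displacement scale reported for the chloride-pump system
this emulates.  `simulate_observed()` then applies the complex mixture
above — mixing amplitudes instead of complex structure factors would
build the factor-of-two convention into the data rather than test it —
and adds Gaussian noise with standard deviation `noise_frac` times the
mean amplitude of each of 10 resolution shells (the resolution-dependent
SNR profile of a serial-crystallography merge, without partiality
modelling).  Defaults: p = 0.05, 3% noise, d_min = 1.8 Å.

What the simulator does **not** emulate — and what passing tests
therefore do not certify on real data: space-group symmetry beyond P1,
bulk solvent, anisotropic or correlated errors, indexing ambiguity,
partiality, radiation damage, and model-phase error in
\(\Phi_\mathrm{dark}\) (the simulator's dark phases are exact; real dark
models are not).  The ±30% recovery band used in the acceptance tests is
calibrated to this idealized regime.

## Numerical choices

* Structure factors: Cromer–Mann 4-Gaussian + constant coefficients for
  H, C, N, O, P, S and the **Cl⁻ anion** (the anion's 18-electron
  low-angle scattering is the physically consistent choice for a
  chloride counter-ion).  The FFT back end samples per-atom Gaussians on
  a grid of spacing d_min/4 with a +12 Å² anti-aliasing B added during
  sampling and deconvolved afterwards, truncating each Gaussian where
  its exponent reaches −25; it agrees with direct summation to better
  than 10⁻³ of the strongest amplitude (tested at 10⁻³, typically
  ~10⁻⁷).
* Map synthesis uses the Friedel-expanded hemisphere on a grid of
  spacing ≤ d_min/3; F(000) is omitted, so unscaled maps are relative to
  the cell mean.
* The scan grid defaults to N = 2…200 in steps of 1: the expected
  crossing sits at ~2/p, i.e. at N = 100 for the weakest study
  condition p = 0.02.
* Degenerate inputs fail loudly: collinear torsion atoms, empty masks,
  all-zero differences, duplicate Miller indices, and scans whose mean
  mask density never crosses zero all raise errors that name the
  problem.
* Altloc handling: selections reduce alternate conformers to the
  highest-occupancy one unless an `altloc` clause addresses them.
* All inter-model geometry (displacements, no-fit RMSD, plane rotations,
  kinks) is computed in the shared crystal frame with no superposition,
  matching how time-delay structures refined in the same lattice are
  compared.  Helix kinks use least-squares Cα axes oriented N→C; this
  axis convention is one defensible choice among several, so kink
  values should be compared across time points (ordering), not to
  absolute numbers derived with other conventions.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: 67-atom models, ~9,700 unique reflections to 1.8 Å in a 30 Å P1
cell, 50³ map grids, and a 30-run recovery study (p ∈ {0.02, 0.05,
0.10} × 10 seeds at 3% noise).  A single end-to-end run takes a few
seconds on one CPU; the full recovery study about three minutes.

## Known limitations

No bulk-solvent model (calculated amplitudes are vacuum amplitudes), no
anomalous scattering, no anisotropic B, no French–Wilson conversion
(inputs are amplitudes), no twinning, and no refinement: extrapolated
and phased-extrapolated amplitude sets are exported for external
real-space or reciprocal-space refinement tools.  Deposited-entry
geometry checks require the user to supply the coordinate files; the
package does not download them.
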