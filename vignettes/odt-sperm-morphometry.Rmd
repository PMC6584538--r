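---
title: "Simulated holotomography and label-free sperm morphometry with odtmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated holotomography and label-free sperm morphometry with odtmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`odtmorph` implements a complete computational counterpart of label-free
sperm morphometry by optical diffraction tomography (ODT, also called
holotomography): synthetic 3D refractive-index (RI) phantoms of
spermatozoa, an angle-scanned holographic forward model, tomographic
reconstruction with missing-cone regularization, and the quantitative
2D/3D morphometrics used to compare two cattle breeds (Holstein, "HO",
vs a native breed, "KN"). Because no raw tomograms from the original
instrument are public, the synthetic-data generator *defines* the study
conditions: phantoms are built from the published summary dimensions and
the pipeline is validated by recovering those numbers, plus analytic and
property-based oracles.

# The physical model

## Refractive index as contrast

A cell in medium of index $n_m$ (default 1.337, phosphate-buffered
saline) is described by its RI map $n(\mathbf r)$. The dry-mass
(non-aqueous) concentration is linearly related to the RI elevation by
the refractive-index increment $\alpha$:

$$ c(\mathbf r) = \frac{n(\mathbf r) - n_m}{\alpha}, $$

with $\alpha = 0.19\,\mathrm{mL/g}$, the common value for protein and
nucleic acid. With $\alpha$ in mL/g, $c$ comes out in
$\mathrm{fg/\mu m^3}$ (numerically g/L). Dry mass of a region is mean
concentration times occupied volume (pg). These two constants are not
published for the original experiment; 1.337/0.19 are the standard
instrument-class values and reproduce the correspondence between the
published RI band limits and band concentrations (e.g. the RI-III band
midpoint 1.3731 maps to about 190 fg/µm³, inside the published midpiece
RI-III range). Both are configuration keys.

## The phantom

A spermatozoon is modelled as three solids joined along a medial axis:

* **head** — a triaxial ellipsoid, flattened in $z$ (thickness defaults
  to half the width, matching the reported bilateral symmetry of bovine
  heads);
* **midpiece** — a cylinder (default radius 0.4 µm) with a coaxial
  high-RI core (default radius 0.25 µm) in the RI-III band, standing in
  for the mitochondria-rich band;
* **tail** — a linearly tapered filament (base 0.35 µm, tip 0.1 µm),
  optionally bent along a circular arc (`curvature`, 1/µm).

The compartments occupy *disjoint axis intervals*
($[0, L_h]$, $(L_h, L_h+L_m]$, the rest), so designed boundary
arclengths are exact ground truth for the segmentation tests, and
analytic compartment volumes are closed-form. Head thickness, midpiece
and tail radii are not published; the defaults above are standing
values chosen at biological plausibility and all remain configurable.
Default voxel pitch is 0.1 µm isotropic — finer than the instrument's
lateral resolution, so voxelization error stays well below measurement
tolerances. `design_ho()` / `design_kn()` carry the published mean 2D
dimensions; `design_calibrated()` instead matches published *volumes*
(the published whole-cell volume exceeds the sum of the published part
volumes because it was segmented with a wider RI window; the calibrated
design absorbs the difference into the midpiece and tail
proportionally).

Populations are drawn per-parameter from truncated normal distributions
(±4 SD and physical bounds); the published between-cell SDs of the four
2D dimensions are the defaults, with 30 cells per breed (five bulls,
six cells each, unit of replication = cell, as in the study design).
The paper does not state the between-cell distribution; truncated
normal is the minimal choice consistent with the printed mean ± SD.

## Forward model

For illumination direction $\mathbf s_0$ and wavenumber
$k_m = n_m k_0$, the first-order (Rytov) scattering model links the
complex Rytov phase $\psi = \log(U/U_{inc})$ of the detected field to
the scattering potential $V = k_0^2 (n^2 - n_m^2)$ through the Fourier
diffraction theorem: the 2D spectrum of $\psi$ samples the Ewald-sphere
cap

$$ k_z = \sqrt{k_m^2 - k_x^2 - k_y^2} - k_m s_{0z}, $$

shifted by the illumination wavevector and limited by the detection NA.
The forward model evaluates the cap *exactly* in $z$ (slice-wise DFT),
so it is the adjoint-consistent forward direction of the inverse used in
reconstruction; for zero contrast it returns the undisturbed tilted
plane wave identically. Validity requires weak scattering (contrast
≲ 0.05; the phantoms stay below 0.037).

Off-axis holograms are $|U + R|^2$ with a tilted plane-wave reference.
The default carrier sits one detection passband below the camera
Nyquist frequency per axis — the largest alias-free choice — because
with matched illumination and detection NA (1.2/1.2) the illumination
tilt reaches the edge of the detection band and a smaller carrier
cannot separate the sideband from the autocorrelation terms.
Illumination directions and the carrier are snapped onto the DFT
frequency grid of the frame (adjustments a fraction of a degree), so
the tilted waves are periodic over the frame and the synthetic
hologram–demodulation loop is free of spectral leakage. Optional
intensity noise is Gaussian at a stated SNR (dB), seeded.

The published optics are only implied by the reported resolution: at
the shipped defaults (532 nm, NA 1.2/1.2, water-class medium) the Lauer
criterion

$$ \delta_{lat} = \frac{\lambda}{2(\mathrm{NA}_{ill} + \mathrm{NA}_{det})},
   \qquad
   \delta_{ax} = \frac{\lambda}{2 n_m - \sqrt{n_m^2-\mathrm{NA}_{det}^2}
   - \sqrt{n_m^2-\mathrm{NA}_{ill}^2}} $$

gives (111, 356) nm, matching the published (110, 360) nm pair. The
half-period lateral convention is the one under which any physical
wavelength/NA combination can reproduce that pair.

## Reconstruction

Per frame: mix down by the carrier, crop the sideband (radius
NA/λ plus a small grid margin, bounded away from DC), remove the
illumination ramp, and unwrap the phase by the unweighted
least-squares (DCT/Poisson) method — exact for fields whose true
gradients stay below π per pixel, which weak scatterers satisfy.
Each field's Rytov spectrum is then gridded onto its Ewald cap by
nearest-voxel assignment with multiplicity averaging (interpolating
gridders are deliberately out of scope).

The missing cone — axial frequencies never measured because of the
finite illumination/detection apertures — is treated by a
Gerchberg–Papoulis-type iteration: clamp $n \ge n_m$ in real space
(non-negative contrast), restore the measured voxels in frequency
space; stop at the iteration cap (default 100) or when the relative RI
change falls below `tol` (default 1e-4; neither value is published).
Two numerical choices matter:

* **Hermitian symmetrization** (default on): the scattering potential
  of a non-absorbing object is real, so its spectrum must satisfy
  $V(-\mathbf k) = \overline{V(\mathbf k)}$. Averaging each measured
  voxel with its conjugate mirror enforces this; without it the
  non-Hermitian residue of the Rytov data drives a slow positive drift
  of the background (measured: background error growing from ~0.0025
  to ~0.0045 over 200 iterations, vs stable ~0.0009 with
  symmetrization).
* **Divergence guard**: the iteration aborts with its trace if the
  relative change grows by more than 5% three iterations in a row.

What the reconstruction can and cannot do: for a weak sphere
(Δn = 0.01, r = 2 µm, 30 angles, 128³ voxels) the in-sphere RI RMSE
reaches ~0.0013 after 100 iterations (naive: ~0.005) and background
voxels ≥ 1 µm from the surface stay within ±0.001 of the medium. The
0–1 µm shell around the object carries the band-limited edge response
(axial resolution ≈ 0.36 µm) plus missing-cone ghost lobes of order
0.002 for this contrast; no band-limited method can push that shell
under 1e-3, so background fidelity is stated outside it. Axial
elongation before regularization is demonstrated on a *point-like*
scatterer (r = 0.15 µm), where the anisotropic PSF dominates; a
2 µm sphere is object-dominated and shows a FWHM ratio of only ~1.2
regardless of the algorithm.

## Morphometry

**3D.** Cell material is an RI window (default 1.3400–1.3850; the
wider 1.3350–1.3850 window used for the whole-cell figures is
selectable), restricted to the largest 26-connected component. RI is
quantized to 4 decimals before banding so the published band limits
(RI-I 1.3451–1.3520, RI-II 1.3521–1.3640, RI-III 1.3641–1.3820, closed
at both ends) tile the range without gaps. Volume is voxel counting.
Surface area is a marching-tetrahedra mesh of the mask's signed
Euclidean distance field (zero level midway between opposite-phase
voxel centres), lightly smoothed (σ = 0.5 voxel) and relaxed by 40
Taubin λ/µ passes — the combination that reproduces the analytic
oracles (sphere +1.3…+1.8% monotone in resolution, cube −4%,
cylinder +1%); smoothed-binary meshing cannot satisfy the sphere and
cube oracles simultaneously. Whole-region areas fill internal cavities
first (outermost surface); per-band areas mesh the band mask itself,
internal surfaces included, the only convention consistent with band
areas exceeding region outer areas in the published tables. Sphericity
is $\pi^{1/3}(6V)^{2/3}/A$. Bands occupying fewer than 10 voxels are
reported undetectable (the threshold is not published).

The head/midpiece/tail split is not described in the source study; the
documented stand-in extracts the medial axis from the z-projection
(Zhang–Suen thinning, longest skeleton path, smoothing spline, tips
extended to the silhouette boundary), orients it thick-end first, and
places the head/midpiece boundary where the silhouette width falls
below 25% of the maximal head width, advanced down the shoulder to the
anatomical neck; the midpiece/tail boundary sits at the end of the
high-RI (RI-III) core, or at a configurable fallback length (13.9 µm)
when no core exists. On the designed phantoms the recovered boundaries
sit within ~0.1 µm of ground truth.

**2D.** Phase maps are line integrals of RI contrast
($\phi = 2\pi/\lambda \int \Delta n\, dz$). Segmentation is Otsu with
hysteresis (component of pixels above 0.15× the Otsu threshold seeded
by above-threshold pixels), with one-pixel morphological bridging so the
hair-thin neck between head and midpiece cannot split the cell; plain
Otsu discards most of the dim tail and was rejected. The same axis and
width-profile machinery as in 3D yields head length/width; the
midpiece/tail boundary uses the largest downward step of the
*centre-line* phase profile (the per-sample maximum, insensitive to
silhouette-width quantization), reflecting the optical-density drop at
the end of the midpiece. Midpiece and tail are reported as disjoint
segments; a cell whose projected midpiece/tail density step is
unresolved (voxel pitch ≳ 0.15 µm with a weak midpiece shell) cannot be
split reliably — the default 0.1 µm pitch resolves it for both breed
designs.

**Statistics.** Two-group comparison is the two-sided pooled-variance
Student's t-test, mean ± sample SD, with the two-tier annotation
(\*, P < 0.05; \*\*, P < 0.01) and the letter style of the published
tables (different lower-case letters P < 0.05, capitals P < 0.01). No
multiple-testing correction is applied, matching the source analysis;
bull-level nesting is likewise not modelled. Parameters undetectable in
half or more cells of a group render as "–" without a test.

# What the synthetic data do and do not show

The generator reproduces: the published 2D dimensions and their
between-cell spread, published compartment volumes, concentrations and
dry masses (under the RI/increment defaults), the band structure
(RI-III confined to the midpiece core, no RI-III in the tail), weak
optical contrast, and 30-angle cone illumination. It does not emulate:
intracellular texture (the acrosomal cavity system, RI gradients within
compartments — phantom compartments are uniform), instrument
aberrations and speckle, motility, or inter-bull variance components.
Consequently, passing tests demonstrate correctness of the *computational
chain* under the published summary statistics — not instrument-level
fidelity on real cells; heavily textured or aberrated data would stress
the segmentation in ways these phantoms cannot.

Two published values are *not* forced: the printed head sphericity
(0.67) differs from $\psi(\bar V,\bar A) \approx 0.70$ of the printed
head volume/area, and the printed head dry mass (6.496 pg) differs from
printed concentration × volume (7.15 pg); the study's per-cell averaging
conventions are unknown, so the package pins only the self-consistent
definitions (`sphericity(V, A)` and mean concentration × volume) and
validates them against analytic fixtures and the self-consistent printed
pairs (whole-cell 72.5 fg/µm³ × 145.3 µm³ ≈ 10.49 pg).

# Problem sizes and determinism

Default problem sizes used throughout the examples and tests: phantoms
at 0.1 µm voxels (a full cell is ≈ 70 × 714 × 70 voxels), reconstruction
demonstrations at 128³ with 30 angles and ≤ 100 iterations, population
studies with 30 cells per breed. Every stochastic step (population
sampling, hologram noise) takes an explicit seed, flows from the
pipeline's root seed, and restores the caller's RNG state; reruns of
`run_pipeline()` with the same config are bit-identical for the
deterministic stages.

# Known limitations

* Single-scattering only; contrast beyond ~0.05 warns and degrades.
* Nearest-voxel gridding leaves sub-voxel cap placement error; the
  near-object shell after reconstruction carries ~2e-3 ripple at
  Δn = 0.01.
* The hologram round trip is exact to ~1e-3 only in the weak-phase
  regime (second-order harmonics of the Rytov phase fall outside the
  sideband crop).
* The 2D midpiece/tail boundary needs the projected density step to be
  resolved (see above).
* Compartment splitting assumes an elongated, non-self-crossing cell
  (bounding-box aspect ≥ 1.5; bends up to a half-turn).
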