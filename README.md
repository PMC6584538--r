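# odtmorph

Label-free sperm morphometry by simulated optical diffraction tomography
(holotomography), in R.

Quantitative phase imaging measures the optical phase delay
φ = (2π/λ)∫Δn dz of a cell, and angle-scanned holotomography extends it
to the full 3D refractive-index (RI) map n(**r**): each off-axis
hologram is demodulated to a complex field, the Rytov phase spectrum of
every illumination angle fills one Ewald-sphere cap of the scattering
potential V = k₀²(n² − n_m²) (Fourier diffraction theorem), and the
unmeasured "missing cone" of axial frequencies is restored by an
iterative non-negativity (Gerchberg–Papoulis) regularization. Because
cytoplasmic RI is proportional to dry-mass concentration through the
refractive-index increment α (c = Δn/α, α = 0.19 mL/g), the tomogram
doubles as a densitometer: per-compartment volume, surface area,
sphericity ψ = π^⅓(6V)^⅔/A, concentration and dry mass follow directly.

The package implements this chain end to end for bovine spermatozoa —
for which no public tomograms exist — by simulation: parametric 3D RI
phantoms (ellipsoidal head, cylindrical midpiece with a high-RI
mitochondrial core, tapered tail) built from published morphometric
means ± SDs of two cattle breeds (HO and KN), a first-order
weak-scattering forward model with off-axis hologram synthesis,
tomographic reconstruction, 2D phase-map morphometry (head
length/width, midpiece and tail lengths), 3D compartment and RI-band
morphometry (bands RI-I 1.3451–1.3520, RI-II 1.3521–1.3640, RI-III
1.3641–1.3820), and two-group reporting with Student's t-tests and
significance letters. It is aimed at researchers developing or
validating quantitative-phase morphometry pipelines who need a fully
controlled, reproducible substitute for instrument data.

## Worked example

Build a phantom from the published HO design, project its phase map,
and re-measure the four 2D parameters:

```r
library(odtmorph)

tom <- build_phantom(design_ho(), voxel_size = 0.1)  # 0.1 um voxels
pm  <- project_phase(tom, wavelength = 0.532)
measure_2d(pm)
#> <morphometry_2d> head 9.103 x 4.901 um, midpiece 13.785 um, tail 46.453 um
```

The inputs were 9.053 × 4.954, 13.926 and 46.415 µm — every parameter is
recovered within 1.1%. 3D morphometry of the same phantom:

```r
rec <- measure_3d(tom, cell_id = "ho1", group = "HO")
subset(rec, band == "all",
       c(region, volume_um3, surface_area_um2, concentration_fg_um3,
         dry_mass_pg, sphericity))
#>      region volume_um3 surface_area_um2 concentration_fg_um3 dry_mass_pg sphericity
#>        cell     73.568           192.74                86.55       6.368         NA
#>        head     58.229            91.74                75.84       4.416      0.792
#>    midpiece      7.200            36.78               134.18       0.966         NA
#>        tail      8.139            65.64               121.05       0.985         NA
```

The tail × RI-III rows of `band_decomposition()` come back
undetectable, mirroring the published tables (the high-RI material is
confined to the midpiece core). A full two-breed study — sample 30
cells per breed from the published means/SDs, measure each, compare —
is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1))
res$report          # mean ± SD per breed, t, p, significance letters
```

Tomographic reconstruction of a weak sphere (Δn = 0.01, r = 2 µm,
30 angles, 128³ voxels) recovers the interior RI with RMSE ≈ 0.0013
after 100 non-negativity iterations (naive inverse: ≈ 0.005), and
`lauer_resolution(illumination_plan())` reports the (110.8, 355.9) nm
lateral/axial resolution pair of the simulated optics.

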