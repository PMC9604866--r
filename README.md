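# sarcmi — SAR-guided confocal microwave imaging for breast tumor localization

Ultra-wideband (UWB) confocal microwave imaging (CMI) detects breast tumors
by exploiting the dielectric contrast between malignant and normal tissue:
short microwave pulses are transmitted into the breast from antennas around
it, and the backscattered signals are synthetically focused to form an
image whose intensity peaks at strong scatterers. `sarcmi` implements a
*SAR-guided* variant of the classic delay-and-sum (DAS) reconstruction for
this problem, together with a synthetic forward simulator, so the entire
chain — phantom, pulse, acquisition, pre-localization, aperture planning,
reconstruction, evaluation — runs end to end at desk scale with no
external data. It is aimed at researchers prototyping radar-based breast
imaging algorithms and at teaching the signal chain.

## The method

**Pre-localization by specific absorption rate.** For a tissue with
conductivity σ (S/m), mass density ρ (kg/m³) and internal electric field
magnitude E (V/m), the specific absorption rate is

    SAR = σ E² / ρ   [W/kg]

Malignant inclusions absorb markedly more energy than surrounding tissue,
so the spatial maximum of SAR points at the tumor. `sarcmi` computes SAR
on a voxel lattice from a field grid (here produced by a deterministic
stand-in illumination model) and takes the argmax as the tumor estimate.

**Reduced-aperture acquisition.** Instead of a full 360° scan, a small
monostatic aperture (by default a 3 × 3 grid with 10° angular separation,
10 mm standoff) is planned around the radial direction through the SAR
estimate. Each position records one backscatter waveform; the excitation
is a Gaussian monocycle

    S(t) = −A (2π/τ) (t − Tc) exp(−½ (2π(t − Tc)/τ)²),  τ = 1/f₀,  f₀ = 5.8 GHz

**Reconstruction.** With tumor-free records B and cancerous records TB
(per grid position XY):

1. calibration: `T_XY(t) = TB_XY(t) − B_XY(t)`
2. row-average clutter removal: `P_XY(t) = T_XY(t) − (1/n) Σ_Y T_XY(t)`
3. synthetic focusing over a 350 × 350 pixel grid: for each pixel
   (xᵢ, yⱼ), `D_XY = 2 √((X−xᵢ)² + (Y−yⱼ)² + h²)`,
   `t_XY = D_XY √εr / c`, and `I(xᵢ, yⱼ) = Σ_XY P_XY(t_XY)^q` (q even,
   default 2).

The image peak localizes the tumor. A conventional full-ring baseline
(36 positions, 360°) runs through the same chain for comparison.

## Worked example

```r
library(sarcmi)
res <- run_pipeline()   # default 50 mm phantom, 5 mm tumor at (20, -13, 14)
print(res)
```

```
SAR-guided CMI pipeline run: status ok
Tumor estimate: (20.00, -13.00, 14.00) mm, SAR max 0.00286 W/kg, peak ratio 69.82 -> detected
DAS intensity image: 350 x 350 pixels over [-50, 50] x [-50, 50] mm
  peak 1.457e-08 at (19.91, -13.04) mm; 0 out-of-span samples
loc err 0.09 mm | SCR 2.66 dB | peak 1.46e-08 | FWHM 8.02 mm | DETECTED
```

Reading the output: the SAR maximum lands exactly on the tumor center
voxel; the reconstructed 350 × 350 image peaks 0.09 mm from the true
center (about a third of a pixel), with a 2.66 dB signal-to-clutter ratio
and an 8 mm full width at half maximum. `run_scenario_suite()` repeats
this over tumor radii (1, 3, 5 mm), four tumor dielectric models and
antenna counts (4 and 9, SAR-guided vs uniform ring);
`run_comparison()` adds seeded noisy replicates of the guided-vs-ring
comparison.

A thin command-line front end over the same functions is installed at
`inst/cli/sarcmi` (subcommands `simulate`, `pipeline`, `reconstruct`,
`evaluate`, `compare`; config via `--config FILE` in YAML or JSON).

## Scope and limitations

The forward model is a point-scatterer delay/attenuation model with
straight-ray propagation, not a full-wave solver; the illumination field
behind the SAR map is a deterministic 1/d surrogate. Antenna design,
mass-averaged SAR (1 g/10 g), 3-D volumetric reconstruction and
multiple-tumor detection are out of scope. See the methods vignette
(`vignettes/sar-guided-imaging.Rmd`) for the model assumptions, parameter
choices and numerical conventions.
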