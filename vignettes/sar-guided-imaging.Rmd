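---
title: "SAR-guided delay-and-sum microwave imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SAR-guided delay-and-sum microwave imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcmi)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the parameters that matter, and
the numerical conventions that make the chain deterministic and testable.

## 1. The problem and the phantom

Confocal microwave imaging exploits the permittivity and conductivity
contrast between malignant and normal breast tissue. The study phantom is
a hemisphere of radius 50 mm with a 2 mm skin shell, in a right-handed
millimetre frame with the origin at the center of the hemisphere base and
the hemisphere in $z \ge 0$. Tissue dielectrics (relative permittivity
$\epsilon_r$, conductivity $\sigma$ in S/m):

| tissue   | $\epsilon_r$ | $\sigma$ | note |
|----------|------:|------:|------|
| skin     | 37    | 1.1   | fixed by the standard phantom |
| tumor    | 50    | 1.2   | Stage-1 design size: 5 mm radius |
| interior | 9     | 0.4   | adipose-dominated literature values, overridable |

Mass density is not part of the standard phantom description; we default
to 1000 kg/m³ for all tissues. The SAR *argmax* is invariant to a common
density scale, so only relative densities could matter, and none of the
shipped scenarios override them.

The default tumor sits at (20, −13, 14) mm. The hemispherical geometry
admits no literal reading of some published tumor coordinates for this
phantom class (points tens of millimetres outside the dome); we place the
default tumor at an off-center, mid-depth location consistent with the
reduced-aperture geometry, and every scenario accepts arbitrary valid
placements. A tumor must satisfy $|c| + r \le R - t_{skin}$ (fully
interior) and $c_z \ge 0$; violations raise geometry errors naming the
violated constraint.

## 2. Excitation pulse

The excitation is a Gaussian monocycle,
$S(t) = -A\,\frac{2\pi}{\tau}(t - T_c)\exp\!\big(-\tfrac12
(\tfrac{2\pi (t-T_c)}{\tau})^2\big)$, with $\tau = 1/f_0$ and
$f_0 = 5.8$ GHz (ISM band). Its closed-form properties anchor the unit
tests: $S(T_c) = 0$, odd symmetry about $T_c$, exactly two extrema at
$T_c \pm \tau/2\pi$, zero mean, and spectral magnitude
$\propto f e^{-\frac12 (f\tau)^2}$ peaking exactly at $f_0$.

Two conventions are deliberate:

* **Amplitude.** Textbook typesettings of this pulse carry an ambiguous
  leading "e". Since DAS images are invariant to a global pulse scale, the
  default normalizes the peak magnitude to 1 ($A = \sqrt{e}$); a
  `"literal"` flag reproduces the $A = e$ scale for comparability.
* **Causality.** $T_c$ defaults to $5\tau \approx 0.86$ ns so the sampled
  pulse is effectively causal on the default acquisition window of 512
  samples over 0–5 ns, which covers the 2–3 ns round-trip delays of the
  default geometry with margin.

## 3. Forward simulator: what it emulates and what it does not

`simulate_scan()` stands in for a full-wave electromagnetic solver. Each
monostatic waveform is a sum of:

* a position-independent antenna reverberation artifact (damped sinusoid
  at $f_0$, amplitude 0.01, 0.5 ns decay) — present identically in the
  tumor-free and cancerous records so that calibration demonstrably
  removes it;
* a skin specular echo at delay $2 d_{air}/c$ with Fresnel-style
  amplitude $(\sqrt{\epsilon_1}-\sqrt{\epsilon_2})/(\sqrt{\epsilon_1}+
  \sqrt{\epsilon_2})$;
* one echo per tumor at the piecewise straight-ray round-trip delay
  (air at $c$, tissue at $c/\sqrt{\epsilon_r}$), with amplitude combining
  the interior–tumor impedance contrast, round-trip attenuation
  $e^{-2\sum_i \alpha_i d_i}$ ($\alpha_{skin} = 0.1$,
  $\alpha_{interior} = 0.02$ Np/mm — plausible configurable values),
  $1/d^2$ spreading, a $\cos^4$ directivity pattern about the boresight
  (a moderately directive antenna), and a Rayleigh-type $(r/5\,
  \mathrm{mm})^3$ size factor so smaller tumors return weaker echoes;
* optional seeded white Gaussian noise. Noise is drawn once per record,
  independent of tumor content, so equal seeds give bit-identical records
  and the baseline is reproducible whether tumors are omitted or deleted.

Not emulated: refraction at the skin interface (consistent with the DAS
imaging model, which also ignores it), multiple scattering, antenna
dispersion, frequency-dependent tissue properties, and anatomical
heterogeneity. Passing tests therefore show that the *reconstruction
chain* is correct and well-conditioned under its own stated physics —
they do not validate performance on anatomically realistic data.

## 4. The SAR stand-in field and pre-localization

The SAR map needs an internal field. `synthesize_field()` provides a
deterministic surrogate: a $1/d$ incident decay from the source
(reference $|E| = 1$ V/m at 10 mm), multiplied inside each tumor by a
contrast enhancement that peaks at the tumor center (factor 8) and falls
off quadratically to 1 at the surface. The central concentration mirrors
the physical behaviour of a high-contrast dielectric sphere and makes the
SAR argmax fall essentially at the tumor center rather than at the
near-surface point a flat enhancement would select. The default contrast
of 8 keeps the tumor peak safely above the skin layer's
($\sigma = 1.1$) response for all four shipped tumor tissue models, the
weakest being $\sigma = 0.7$.

`locate_tumor()` returns the global SAR argmax (ties broken by
lexicographic voxel order, x fastest — deterministic and documented) and
a detection confidence: the ratio of the peak to the largest value
outside a 10 mm exclusion ball, computed on the *range-compensated* map
(SAR × squared distance to the recorded source). Range compensation is
what makes the confidence meaningful: the raw $1/d^2$ falloff of a smooth
field produces peak ratios well above 1 on a perfectly healthy phantom,
whereas the compensated map is flat per tissue, so healthy phantoms score
ratios near 1 and tumors score far above the default threshold of 2. An
all-zero map returns a no-detection signal rather than a position.

The SAR lattice defaults to 1 mm pitch over the hemisphere bounding box
(~525k voxels), fine enough to resolve a 1 mm radius tumor.

## 5. Aperture planning

`plan_aperture()` places antennas on the sphere of radius
$R + h = 60$ mm around the radial direction through the SAR estimate,
with boresights at the estimate. Rows are arcs of great circles stepped
by the angular separation (default 10°); consecutive positions along a
row are separated by exactly that angle (the scan-trajectory reading of
the angular spacing), across-row neighbours match it exactly on the
central column and to within a few percent off it — an exact equal-angle
grid does not exist on the sphere. A single-arc layout (`mode = "arc"`,
e.g. nine positions spanning 80°) is available as the alternative
reading of a "90° angle scan with 10° separation"; both readings are
supported and the configuration makes the choice explicit.

One degeneracy deserves emphasis: a *centered even grid* (e.g. 2 × 2)
around the true tumor direction is mirror-symmetric, so within-row
channels carry identical tumor responses and row-average clutter removal
annihilates the signal exactly. For antenna counts other than 9 the
scenario runner therefore plans a single 1 × n arc along the trajectory,
where inner and outer positions differ and the response survives.
Likewise `plan_full_ring()` (default 36 positions, 10° azimuth spacing,
ring plane at 20 mm height for the baseline scenarios) produces a 1 × n
grid whose single "row" mean is the all-position mean — the ring-mode
variant of clutter removal. A multi-row geometry with one column per row
would zero itself out; it is emitted with a warning.

## 6. Reconstruction: numerical choices

* **Calibration** subtracts the baseline record sample-wise; geometry and
  time axes must match to 1e-9 relative.
* **Clutter removal** subtracts each row's mean; the per-row sums of the
  output are zero to machine precision (asserted at 1e-12 of signal
  scale).
* **Velocity model.** The round-trip time is $D\sqrt{\epsilon_r}/c$ with
  $c = 2.9979 \times 10^8$ m/s. A `"literal"` flag implements $D
  \epsilon_r / c$, a form that appears in print; it is not the physical
  wave speed and with realistic permittivities it pushes delays beyond
  the recorded window (such samples read as zero and are counted, not
  errored).
* **Effective permittivity.** The delay model uses a single medium
  permittivity. The configuration default is the skin value 37; the
  pipeline's `"auto"` mode instead estimates it from the straight-ray
  path between the central antenna and the focal target
  ($\sqrt{\epsilon_{eff}}$ = optical path / geometric path, ≈ 6.6 for
  the default geometry — an "estimated average of the environment
  permittivity"). With the skin value, delays overshoot several-fold for
  a standoff-dominated path; the path-based estimate is what makes the
  delays land on the tumor response.
* **Imaging plane.** The 2-D image lives in an xy-plane at `plane_z`;
  each antenna's $h$ is its z-offset from that plane. The pipeline sets
  `plane_z` to the SAR estimate's depth, so the focusing distance at the
  true pixel equals the true 3-D distance — the natural use of the SAR
  guidance. Pixel count (350 × 350) is deliberately separated from the
  physical region (default the 100 × 100 mm footprint), pitch ≈ 0.29 mm.
* **Sampling.** Fractional delays are sampled by linear interpolation
  (nearest-sample optional). Raw sampling of a bipolar monocycle is
  zero at the exact echo center, so the scenario defaults sample the
  analytic-signal *envelope* (FFT Hilbert) offset by $T_c$: the envelope
  of the monocycle — and of its clutter-removal residuals — is centered
  at the pulse center, which keeps the image peak on the scatterer. Raw
  sampling with a $T_c + \tau/2\pi$ (pulse-peak) offset remains the
  Eq-literal option.
* **Intensity exponent.** $q = 2$ by default; any even $q$ is accepted
  since raising the power is a known artifact-suppression practice, with
  the exact exponent a free choice.

## 7. Evaluation and scenarios

Image quality is assessed by localization error (peak vs true center
projection), signal-to-clutter ratio (10 log₁₀ of max inside the tumor
disk over max outside the disk dilated by one radius; +∞ sentinel when
the outside is identically zero), peak value and FWHM. "Detection" is
operationalized as: peak within one tumor radius plus one pixel pitch of
the truth *and* SCR > 0 dB — a numeric stand-in for what the source
studies judged visually.

`run_scenario_suite()` runs noiseless single-shot scenarios: tumor radii
{1, 3, 5} mm, four tumor dielectric models (εr/σ: 50/1.2, 62.77/1.66,
54/0.7, 55.1/0.79), and antenna counts {4, 9} for SAR-guided vs
uniform-ring placement. `run_comparison()` runs 20 seeded noisy
replicates (noise sd 1e-5, about 8% of the strongest raw tumor echo in
the default geometry) of the off-center-tumor scenario for both
placements. Problem sizes throughout: 350 × 350 images for headline
numbers, 64–128 pixel grids and 2–5 mm SAR pitches in unit tests; a full
suite plus the acceptance script completes in a few minutes on one CPU
core.

## 8. Determinism and provenance

All randomness flows from integer seeds: the forward model's seed is
recorded in each record's metadata, the pipeline fans its global seed out
per stage via a stable string hash (`stage_seed()`), and scenario tables
embed their seeds. Equal seeds reproduce signals, images and tables bit
for bit; this is asserted in the test suite. Artifacts written to disk
(records, images, estimates, resolved configs) carry config hashes and
seeds.

## 9. Known limitations

* The forward simulator and the SAR field are surrogates; absolute SAR
  magnitudes and echo amplitudes are in arbitrary consistent units, and
  nothing here validates against measured or full-wave data.
* Imaging is 2-D at a chosen depth; a tumor far from the chosen plane
  defocuses rather than disappears.
* The straight-ray delay model ignores refraction; with strongly
  heterogeneous interiors the single effective permittivity would bias
  ranges.
* The conventional-ring baseline is simulated with the same surrogate
  physics, so comparisons measure geometry and processing effects, not
  hardware differences.
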