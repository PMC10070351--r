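---
title: "Rapidly-varying dark-field retrieval: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapidly-varying dark-field retrieval: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Speckle-based phase-contrast X-ray imaging records a reference-speckle
intensity $I_R(\mathbf r)$ (random mask in the beam, sample out) and a
sample-reference-speckle intensity $I_S(\mathbf r)$ (mask and sample in),
for each of $N$ mask positions. Under paraxial, monochromatic,
well-resolved-speckle conditions the two are linked by a Fokker–Planck
balance of coherent and diffusive transverse energy flow,

$$ I_R - I_S \;=\; \frac{\Delta}{k}\,\nabla_\perp\!\cdot\!\left[I_R\,
\nabla_\perp\phi_{\mathrm{ob}}\right] \;-\; \Delta\,\nabla_\perp^2\!\left[
D_{\mathrm{eff}}\, I_R\right], $$

with sample-to-detector distance $\Delta$, wavenumber $k$, phase-shift
$\phi_{\mathrm{ob}}$ (rad) and effective diffusion coefficient
$D_{\mathrm{eff}}$ (units of length: it aggregates position-dependent
small-angle scattering over the propagation distance). Two approximations
define the working model:

1. the cross term $\nabla_\perp I_R\cdot\nabla_\perp\phi_{\mathrm{ob}}$ of
   the coherent flow is neglected against $I_R\nabla_\perp^2
   \phi_{\mathrm{ob}}$ — the speckle intensity varies much faster than the
   sample-induced phase;
2. **no** slowly-varying assumption is made on $D_{\mathrm{eff}}$: expanding
   the dark-field Laplacian keeps its first derivatives as unknowns.

Each pixel then satisfies, per mask position $n$,

$$ \frac{I_{R_n}-I_{S_n}}{\Delta} \;=\; I_{R_n}\,c \;-\;
D\,\nabla_\perp^2 I_{R_n} \;-\; 2 D^x I_{R_n}^x \;-\; 2 D^y I_{R_n}^y, $$

a linear equation in $x=[c, D, D^x, D^y]$ where
$c=\nabla_\perp^2(\phi_{\mathrm{ob}}/k - D)$. Four independent mask
positions are the theoretical minimum; more over-determine the system and
stabilise it. The stages after the per-pixel solve are:

- **Fusion** (`combine_darkfield`): the directly-solved $D$ is reliable at
  low spatial frequency, the gradient-integrated solution
  $F^{-1}[F(D^x+iD^y)/(ik_x-k_y)]$ at high frequency; a Gaussian weight
  $e^{-\rho k^2}$ blends them into $D^{\mathrm{True}}_{\mathrm{eff,Phase}}$.
- **Phase** (`reconstruct_phase`): substituting the fused dark-field back
  into the simplified model isolates $\nabla_\perp^2\phi_{\mathrm{ob}}$,
  which the regularised inverse Laplacian integrates. Only the mean-free
  part of $\phi_{\mathrm{ob}}$ is recoverable (the DC bin is singular), so
  all comparisons are mean-adjusted.
- **Attenuation closure** (`attenuation_term`, `attenuating_darkfield`):
  for a single-material object the projection approximation gives
  $I_{\mathrm{ob}}=\exp(2\phi_{\mathrm{ob}}/\gamma)$ with
  $\gamma=\delta/\beta$, and
  $D^{\mathrm{True}}_{\mathrm{eff,Atten}} =
  D^{\mathrm{True}}_{\mathrm{eff,Phase}}/I_{\mathrm{ob}}$. Multi-material
  samples are treated as effective single-material with a user-supplied
  $\gamma$; only the single-$\gamma$ form is implemented.

The slowly-varying baseline (`solve_slowly_varying_baseline`) drops the
derivative terms, leaving two unknowns $[c, D]$ per pixel from $N\ge 2$
positions. It is retained purely as the comparison arm for edge-resolution
experiments: on piecewise-constant dark-field structure it over/under-shoots
at steps where the rapidly-varying system stays faithful.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `delta` | um | — | propagation distance (2 m in the canonical geometry) |
| `wavenumber_k` | 1/um | from energy | $2\pi E/(hc)$, $hc = 1.23984\times10^{-3}$ keV·um |
| `pixel_size` | um | — | carried on every field; all spectral operators are unit-bearing |
| `rho` | um² | — | Fourier cut-off of the dark-field fusion |
| `alpha` (solve) | units of A | `"auto"` | sd of the full coefficient matrix / $10^4$ |
| `alpha_phase` | (1/um)⁴ | `1e-4` | Tikhonov parameter of the inverse Laplacian |
| `gamma` | — | 1403 | $\delta/\beta$; 1403 suits plant tissue at 25 keV, 1146 water at 17 keV |

Two notes on the regularisers. The `"auto"` solve rule is the operating rule
for measured data; on noiseless synthetic data any $\alpha>0$ only biases an
otherwise exactly-determined solve, so the recovery tests pass `alpha = 0`
explicitly (with flat-fielded intensities near 1, the auto rule yields
$\alpha\sim5\times10^{-5}$, which visibly damps the small-magnitude
dark-field columns). Likewise `alpha_phase = 1e-4` is the operating value
for noisy data; it suppresses the lowest spatial frequencies of the phase
(where $k^4\ll\alpha$), so noiseless round trips use `alpha_phase = 0`.

The cut-off $\rho$ is convention-dependent: this package defines angular
frequencies $k_x = 2\pi\times$ cycles/um, so $\rho$ carries um² but its
numerical value cannot be transplanted from analyses using a different
transform convention. The sweep utility (`sweep_cutoff`) reports SNR as a
function of $\rho$ and the SNR-maximising value, and exposes a hook for an
external perceptual scorer; no-reference perceptual models (e.g. NIQE) are
not reimplemented because they depend on pretrained natural-scene-statistics
weights that cannot be verified here — the hook leaves the final blend of
SNR, perceptual score and visual judgement to the user.

## Numerical choices

- **Transform conventions.** Analysis with $e^{-ik\cdot r}$, synthesis with
  $e^{+ik\cdot r}$, so the derivative theorem reads
  $F(\partial_x g)=ik_xG$ and the gradient-integration denominator is
  $(ik_x-k_y)$ literally. `x` runs along matrix rows, `y` along columns.
- **Degenerate DC bins.** Gradient integration and the inverse Laplacian set
  the DC bin to zero (mean-free output; the offset is unrecoverable). In the
  fusion the second term's weight $(1-e^{-\rho k^2})$ vanishes at DC — a
  removable singularity set to zero exactly — so the output mean always
  equals the mean of the directly-solved map; near-DC bins divide through
  the regularised reciprocal $\overline{(ik_x-k_y)}/(k^2+\varepsilon)$,
  $\varepsilon=10^{-12}\max k^2$.
- **Derivative schemes.** Default for measured data: 2-pixel central
  differences with reflective edges (speckle data are noisy and
  non-periodic); spectral derivatives are available and used in
  self-consistency tests, where forward model and inversion share one
  discrete scheme so the linear system is consistent to rounding. The
  forward simulator evaluates the dark-field term in the same expanded form
  as the system assembly in *both* modes, so full minus simplified isolates
  exactly the neglected coherent cross term.
- **Solver.** The normal equations $(A^TA+\alpha^2I)x=A^Tb$ are solved by a
  vectorised per-pixel Cholesky (closed-form 2×2/4×4 factorisation applied
  to whole maps); a literal per-pixel QR on the augmented system
  $(A;\alpha I)$ is kept as the reference path and the two agree to
  rounding. Pixels whose unregularised pivots collapse are flagged and
  filled from a weakly regularised solve; all-zero pixels return zero.
  Negative recovered $D_{\mathrm{eff}}$ values are retained, not clipped —
  clipping would bias the Fourier fusion.
- **Boundary handling.** All spectral stages accept mirror padding
  (`pad > 0`, symmetric reflection, cropped after inversion) for measured
  frames with sharp borders. Synthetic tests run unpadded: the speckle
  generator is periodic by construction and the phantoms have interior
  support.
- **Phase set-combination.** The per-set estimates of
  $\nabla_\perp^2\phi_{\mathrm{ob}}$ are averaged over all $N$ sets by
  default (`mode = "average"`); a stacked pixel-wise least-squares variant
  (`"per-set-lsq"`) weights sets by $I_{R_n}^2$ and behaves almost
  identically on clean data. Averaging was chosen as the default because it
  treats every mask position identically and needs no extra regulariser.

## What the synthetic data do and do not emulate

`generate_speckle` soft-thresholds (tanh) a Gaussian-correlated random
field, then maps it affinely to the requested mean and visibility. This
emulates the operative properties of a sandpaper mask: a strictly positive,
spatially random field with a controllable autocorrelation FWHM (the
"speckle size", default target 130 um at 10 um pixels) and grain-like sharp
structure whose Laplacian carries enough power to condition the per-pixel
system — a purely Gaussian field at the same correlation length leaves the
dark-field columns an order of magnitude weaker. The internal
FWHM-per-sigma constant (3.17 at the default sharpness) was calibrated once
against the measured autocorrelation of generated fields. Independent mask
positions are emulated by independent seeds.

Phantoms combine smooth compact bumps (mollifiers with exact interior
support) for $\phi_{\mathrm{ob}}\le 0$ and, per kind, smooth and/or
piecewise-constant dark-field structure (disc, rectangle, and a
3-pixel-wide ridge for line-profile experiments). Default amplitudes
($\phi$ down to $-3$ rad, $D_{\mathrm{eff}}$ plateaus of $10^{-5}$ um)
keep the forward model inside its validity range at the canonical geometry
— at sharp dark-field steps the edge term scales as
$\Delta D/h^2$, which caps the plateau near $2.5\times10^{-5}$ um before
intensities go negative; the simulator rejects (rather than clips) any
phantom that drives $I_S<0$. Attenuation enters multiplicatively at the
exit surface (projection approximation), matching the single-material
closure rather than a fully attenuating transport model.

Not emulated: Fresnel fringing and free-space diffraction beyond the
coherent-flow term, partial coherence, polychromaticity, detector PSF,
frame registration errors, and structured (non-Gaussian) detector noise.
Passing round trips therefore demonstrate correctness of the inversion
under its own model assumptions, not robustness to every experimental
artefact.

## Test conditions and noise regime

The acceptance-level experiments run at $256\times256$, 10 um pixels,
$\Delta=2$ m, 25 keV, 130 um speckle size — matching the canonical geometry
while staying desk-sized; unit and property tests use $64^2$–$128^2$
grids. With the default phantom amplitudes the dark-field modulates the
per-set intensities by only a fraction of a percent away from edges, so 1%
additive Gaussian noise puts the solve firmly in the noise-limited regime:
per-pixel errors are then set by noise amplification, not by the noiseless
consistency floor. Noise robustness is therefore characterised by
monotonicity — the interior error decreases from $N=4$ to $N=15$ mask
positions on identical noisy data, and grows smoothly (no cliff) with the
noise level — rather than by a fixed multiple of the (essentially zero)
noiseless error.

The white-noise flatness check of the azimuthally averaged power spectrum
averages 64 independent realisations before comparing bins: the innermost
radial bin of a single $256^2$ field holds only ~12 Fourier pixels, whose
exponentially-distributed powers fluctuate ~30% by counting statistics
alone. Corner frequencies beyond the axial Nyquist are folded into the top
bin so that the bin populations cover every off-DC pixel exactly once and
Parseval holds to rounding.

## Known limitations

- The attenuation closure assumes a single effective $\gamma$; strongly
  heterogeneous samples violate it near interfaces.
- The phase is recovered only up to an additive constant, and its lowest
  spatial frequencies trade off against `alpha_phase`.
- The fusion assumes the solved derivative maps are spectrally consistent
  with the solved dark-field; heavy per-pixel outliers (flagged pixels)
  leak ringing into the blend — inspect the flag fraction in the manifest.
- The slowly-varying baseline implemented here is the two-unknown
  phase-object form; it is a comparison arm, not a faithful reimplementation
  of any particular published variant.
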