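---
title: "Models and methods: single-molecule pore accessibility and elution prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: single-molecule pore accessibility and elution prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Chromatographic stationary phases are porous silica particles, often coated
with a chiral or functional selector. How deep a small analyte actually
penetrates a particle under solvated, flowing conditions — and how long it
dwells on individual adsorption sites — controls band broadening and
retention, but is invisible to ensemble porosimetry. This package
implements an analysis chain for in-situ single-molecule localization
microscopy (SMLM) of analyte adsorption inside immobilized particles:

1. simulate single-molecule adsorption movies with known ground truth;
2. localize diffraction-limited spots to ~30 nm and build super-resolution
   maps;
3. quantify pore accessibility per particle (depth-from-edge distributions
   in % of particle radius, the 99% accessible-depth limit `d99`, and the
   accessible-area ratio `A_p/A_i`);
4. extract adsorption/desorption kinetics from linked dwell times;
5. predict ensemble elution peaks from the dwell-time distribution via the
   compound-Poisson (Lévy) stochastic theory of chromatography.

Because no raw microscopy data ships with the package, the simulator is a
first-class module: every downstream stage is validated against the
simulator's ground truth and against closed-form oracles.

# The synthetic-data model

A particle cross-section is an ellipse (semi-axes $a \ge b$, tilt
$\theta$). Analyte-accessible space is the elliptical annulus
$\rho \in [1-f,\,1]$ of the normalized elliptical radius
$\rho = \sqrt{(x'/a)^2 + (y'/b)^2}$; the accessible fraction $f$ is the
shell depth as a fraction of radius. $f = 1$ is a fully porous particle
(FPP); $f \approx 0.37$ reproduces a superficially porous particle (SPP)
with a 0.5-µm shell on a 1.35-µm-radius particle.

Adsorption sites are a Poisson point process, uniform over the accessible
annulus, at `site_density` sites/µm². Site kinetics follow the *n*-site
picture: each site draws (weight, $k_d$, $k_a$) i.i.d. from a finite
mixture; arrivals at a site are a homogeneous Poisson process at $k_a$ and
each dwell is exponential with mean $1/k_d$. Arrivals are non-blocking —
at nanomolar analyte the probability that a site is already occupied is
negligible, and non-blocking arrivals are exactly the Poisson-sojourn
assumption the elution theory uses downstream.

Rendering follows the camera model: an event active during a frame
deposits a pixel-integrated symmetric Gaussian (σ = `psf_sigma`), with
expected photons
`photons_per_frame × (fractional temporal overlap) × (axial sheet weight)`.
The illumination sheet is Gaussian in z with 2.3 µm FWHM (the shape is a
modeling choice; only the thickness is constrained experimentally). Pixel
values are Poisson(signal + background) plus Gaussian read noise, rounded
to 16-bit integers.

## Default study conditions and why

| parameter | default | rationale |
|---|---|---|
| frame interval | 32 ms | the acquisition's temporal sampling |
| pixel size | 100 nm | typical sCMOS + 60–100x HILO configuration |
| PSF sigma | 130 nm | diffraction-limited visible-light PSF |
| photons/frame | 2000 | bright rhodamine-class emitter |
| background | 10 ph/px | includes unrendered freely diffusing analyte |
| read noise | 2 e⁻ rms | modern sCMOS |
| sheet FWHM | 2.3 µm | measured light-sheet thickness |
| site density | 200 /µm² | see below |
| per-site arrival $k_a$ | 0.033 /s | see below |
| desorption mixture | w = (0.6, 0.4), $k_d$ = (12, 3) /s | two-class heterogeneity, dwells of ~2.7 and ~11 frames |
| frames | 1500 (48 s) | see below |

The spatial statistics are chosen so that one simulated acquisition
produces ~4000–6500 adsorption events and ~2–3 × 10⁴ localizations per
particle — the regime of the real experiments, whose per-curve statistics
pool >15 000 events. At these settings ~80% of sites light up at least
once, localization coverage of the accessible shell approaches saturation,
and the area-ratio estimator is meaningful (see below). These are the
package's fixed study conditions; they are set once here, not tuned per
experiment.

Freely diffusing molecules are not rendered: at 32-ms exposure a molecule
diffusing at µm²/s scales smears over many pixels and is indistinguishable
from background, which the background parameter absorbs. A bleaching rate
is exposed (`bleach_rate`) but defaults to 0; whether bleaching truncation
should be corrected in real dwell data is an open experimental question,
so the pipeline reports raw dwells.

The axial dimension is handled by treating each acquisition as one 2D
optical slice; 3D maps are stacks of independently simulated slices. Fitted
axial positions are out of scope — axial resolution comes from the optical
section, not from astigmatic fitting.

# Localization

Detection is a difference-of-Gaussians bandpass (σ and 2σ at the PSF
scale) followed by local maxima above `median + k × robust noise SD`, with
k = 4 and a minimum separation of 4 pixels. The noise scale is the robust
SD (MAD) of the fine residual level — the frame minus its PSF-scale blur —
the convention of wavelet-style single-molecule detectors; it is
insensitive to the spots themselves, and on pure-background frames the
false-positive rate is below one frame in twenty.

Each candidate is least-squares fit (Levenberg–Marquardt) with a symmetric
2D Gaussian plus constant offset on a 7×7-pixel ROI. Least squares rather
than MLE is a deliberate simplification: at ~2000 photons/spot the two are
practically indistinguishable and LSQ has no Poisson-weight failure modes
at low counts. Fits are rejected when σ leaves `[0.5, 2] × psf_sigma`,
photons drop below 100, or the optimizer fails, with a reason code.
Per-localization precision uses the Thompson-style formula
$$\sigma_{loc}^2 = \frac{s^2 + p^2/12}{N} +
  \frac{8\pi s^4 b^2}{p^2 N^2},$$
with PSF width $s$, pixel size $p$, photons $N$ and background $b$. No
drift correction is applied (single-particle fields, short acquisitions).

Super-resolution maps are 2D histograms of localization positions at a
30-nm map pixel, the lateral resolution scale.

# Accessibility metrics

**Outline.** The map is binarized (any localization marks a pixel), closed
morphologically with a disc, reduced to its largest connected component,
and holes are filled. The ellipse is then fit through the second-order
moments of the *convex hull* of that component (closed-form polygon
moments). The hull step matters: when only a thin accessible shell is
sampled, the closed component is a ring, and a single gap in the ring
defeats hole-filling — the raw moments of an annulus overestimate the
semi-axis by exactly $\sqrt{1 + (1-f)^2}$ (18% for $f = 0.37$). A particle
cross-section is convex, so the hull recovers the outer boundary in both
the filled-disc and broken-ring cases; on densely sampled synthetic discs
and shells the semi-axes are recovered within 2%.

**Closing radius.** The disc radius (default 5 map pixels = 150 nm)
couples to the map pixel and the lit-site spacing: it must bridge the
Poisson voids between discrete adsorption sites without filling a genuine
hollow core. At the default site statistics the lit-site spacing is
~80 nm, so a 150-nm disc saturates the accessible shell while remaining
far below the ~920-nm core radius of the SPP geometry; the default is
validated against the $f = 0.37$ annulus oracle (area-ratio error ~0.02,
and the hollow core stays open).

**Depths.** Each localization's depth from the particle edge is
$(1 - \min(\rho, 1)) \times 100$ in %r, using the elliptical coordinate so
%r is exact for eccentric outlines; the scalar radius is reported as
$r = (a+b)/2$. Localizations with $\rho > 1.05$ are excluded and counted —
they are localization noise outside the contour. The accessible-depth
limit `d99` is the 99th percentile (linear interpolation) of the depth
distribution: the depth beyond which 99% of analytes do not reach. The
alternative reading ("the depth that 99% fail to reach" as a first
percentile of a complementary distance) is rejected because only the
percentile convention reproduces the geometric limit of a known shell:
for a uniform annulus the depth CDF is
$F(u) = \frac{1 - (1-u)^2}{1 - (1-f)^2}$ on $[0, f]$, so
$$d_{99} = 100\left(1 - \sqrt{1 - 0.99\,(1 - (1-f)^2)}\right),$$
giving 90 %r for a full disc and 36.5 %r for $f = 0.37$ — the ~37 %r
expected for a 0.5-µm shell on a 1.35-µm-radius SPP.

**Accessible area.** $A_p$ counts covered map pixels (after the same
closing) whose centers fall inside the fitted ellipse, times the pixel
area; $A_p/A_i$ with $A_i = \pi a b$. For uniform shell sampling the dense
limit is $1 - (1-f)^2$. The estimator is slightly conservative (~0.02–0.04
low) because morphological closing cannot manufacture coverage at the
boundary half-pixel ring or inside unusually large inter-site voids; this
bias is part of the estimator's definition, matching how covered-area is
measured on real maps.

**Aggregation** across particles averages binned depth CDFs on a common
grid and reports mean ± sample SD for `d99` and $A_p/A_i$.

# Dwell-time kinetics

Localizations are linked across frames by greedy nearest-neighbor
association within 100 nm, tolerating one missed frame (`max_gap = 1`, a
single-frame blink). An event spanning $n$ frames has dwell
$t_D = n\,\Delta t$ — not $(n - \tfrac12)\Delta t$ — and all oracle
comparisons discretize the simulated truth identically. Events touching
the first or last frame are censored: excluded from dwell and rate
estimates (unbiased when mean dwell ≪ acquisition), retained in event
counts for $k_a$.

Frame quantization makes $n\,\Delta t$ overestimate the true sojourn by
one frame on average (an event with true dwell $t$ starting at a uniform
phase touches $1 + \lfloor (u+t)/\Delta t \rfloor$ frames). The package
therefore separates two conventions: the *definition* $k_d = 1/\bar t_D$
(the field's convention, `estimate_kd(..., frame_interval = 0)`), and the
*discretization-corrected* estimator $k_d = 1/(\bar t_D - \Delta t)$ used
by the pipeline, which recovers simulated rates within a few percent down
to dwells of ~3 frames. Both are exposed; site tables record which was
used via the `frame_interval_s` argument.

Sites are single-linkage clusters of event positions at a 60-nm threshold
(~2 map pixels). Per-site adsorption free energies use the
pseudo-first-order convention
$$K_{eq} = \frac{k_a}{k_d \cdot C/C^\circ}, \qquad
  \Delta G = -RT \ln K_{eq},$$
with $C^\circ$ = 1 M. The reference-state choice shifts all $\Delta G$ by
a constant — at $C$ = 1 nM the 1 M reference sits $RT\ln 10^9 \approx$
51 kJ/mol below an occupancy convention $K = k_a/k_d$ (recovered by
setting `concentration = 1`) — so the convention is always reported
alongside results. The *span* across sites, several kJ/mol under the
default kinetics, is reference-independent and is the quantity the
heterogeneity analysis uses.

# Elution prediction

The stochastic theory of chromatography treats a molecule's retention
time as $t_M + \sum_{i=1}^{K} t_{D,i}$ with $K \sim \mathrm{Poisson}(\bar n)$
sojourns drawn from the dwell distribution. In characteristic-function
form,
$$\Phi(\omega) = e^{i\omega t_M}\,
  \exp\!\big(\bar n\,(\varphi_s(\omega) - 1)\big),$$
where $\varphi_s$ is the dwell CF. The package uses the *empirical* CF
$\varphi_s(\omega) = \frac1N \sum_j e^{i\omega t_j}$ directly — no
exponential-mixture fit — so site heterogeneity enters exactly as
observed and no model selection is needed.

Numerics: the peak is the inverse FFT of $\Phi$ on a power-of-two grid
with step $\Delta t = \max(\min(t_D)/4,\ \text{frame interval}/4)$ and a
span covering the expected peak plus twelve standard deviations. The
unretained fraction $P(K{=}0) = e^{-\bar n}$ is a point mass at $t_M$; it
is removed analytically before the transform and re-added to its grid bin,
so the delta cannot ring across the grid. Two guards reject inadequate
grids rather than silently degrading: the density in the last 5% of the
time grid must be below $10^{-6}$ of the peak (aliasing), and any negative
lobe must stay below $10^{-3}$ of the peak before it is clipped; the
profile is then renormalized to unit area. Because the empirical CF of $N$
dwells has a noise floor of order $N^{-1/2}$, the continuous part of
$\Phi$ floors at roughly $\bar n e^{-\bar n} N^{-1/2}$; in practice the
method is reliable for $\bar n \gtrsim 30$, and the default is
$\bar n = 100$ with $t_M = 0$ (a "scaled elution" axis), since the true
mean number of adsorption steps in a packed column is not identifiable
from single-particle imaging.

Peak moments (area, center, variance, standardized skew) are trapezoidal;
first and second cumulants of the model equal
$t_M + \bar n\,\overline{t_D}$ and $\bar n\,\overline{t_D^2}$, which the
tests verify against the FFT profile at the 1% level and against direct
Monte-Carlo sampling at KS < 0.01. Removing dwells above the 95th
percentile — the analogue of stripping the functional coating with a
strong solvent — shifts the modeled centroid strictly earlier while the
skew stays positive: faster elution with preserved tailing character.
Mobile-phase dispersion, Eddy and longitudinal diffusion are intentionally
excluded; the model isolates the adsorptive contribution.

# Problem sizes

The test-suite and acceptance runs use one 128×128-px, 1500-frame movie
per geometry ($f \in \{0.37, 0.64, 1\}$, ~2–3 × 10⁴ localizations each), a
2400-frame sparse-site movie for kinetics recovery, 10⁵-point samples for
the closed-form depth oracles, and 10⁵ Monte-Carlo draws for the elution
cross-check. These sizes put Monte-Carlo error well inside each check's
tolerance while keeping a full run in minutes on one core.

# What passing tests do and do not show

The simulator emulates the statistical structure the analysis assumes:
Poisson sites, exponential mixtures, Gaussian PSF, Poisson + Gaussian
camera noise, uniform site occupancy within the accessible shell. Real
particles add effects outside this model — out-of-slice fluorescence,
refractive-index distortions inside the particle, non-uniform
functionalization, dye photophysics, stage drift. Recovery of $f$, $k_d$
and the elution cumulants on simulated data therefore validates the
*estimators* (their conventions, discretization handling and numerics),
not the microscope; on real data the same code path applies but those
systematic effects must be assessed separately.

# Known limitations

- Accessibility is 2D per optical slice; voxel-level 3D accessibility and
  per-pore-size analysis are out of scope.
- The area-ratio estimator is mildly conservative at finite site density
  (closing cannot bridge arbitrarily large voids).
- Dwell times are not corrected for photobleaching; the bleach-rate knob
  exists to study the effect, and defaults to off.
- Multi-emitter fitting is not implemented; heavily overlapping spots are
  suppressed by the detector's minimum-separation rule, which costs recall
  at high event concurrency.
- Absolute retention prediction requires $\bar n$ and $t_M$, which
  single-particle imaging does not constrain; the model reports trends
  (centroid shifts, tailing) on a scaled axis.
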