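# smlmchrom

Single-molecule imaging analysis of pore accessibility and adsorption
kinetics in chromatographic stationary-phase particles.

Porous silica particles — often coated with a chiral selector — are the
workhorse of HPLC, yet ensemble porosimetry says little about how deep a
small analyte actually penetrates a *solvated, functionalized* particle,
or how long it dwells on individual adsorption sites. In-situ
single-molecule localization microscopy (SMLM) answers both: adsorbed
analytes are localized to ~30 nm inside immobilized particles, maps of
those localizations quantify accessible pore space, and the dwell times
of individual adsorption events predict ensemble elution behavior.

`smlmchrom` implements the full analysis chain, with a ground-truth
simulator in place of raw microscopy data:

1. **synthetic data** — adsorption sites as a Poisson process on an
   accessible elliptical shell (fraction *f* of the radius), *n*-site
   first-order kinetics (mixture of desorption rates *k*<sub>d</sub>),
   pixel-integrated Gaussian PSF rendering with Poisson + read noise and
   a Gaussian light-sheet envelope;
2. **localization** — DoG detection, 2D Gaussian least-squares fitting
   with Thompson-style precision, 30-nm super-resolution maps;
3. **accessibility** — ellipse outline from the binarized map, per-
   localization depth from the particle edge in %*r*, the accessible-depth
   limit *d*<sub>99</sub> (99th percentile of depth), and the
   accessible-area ratio *A*<sub>p</sub>/*A*<sub>i</sub>. For a uniform
   shell of fraction *f* these have closed forms:
   *d*<sub>99</sub> = 100·(1 − √(1 − 0.99·(1−(1−*f*)²))) %*r* and
   *A*<sub>p</sub>/*A*<sub>i</sub> → 1 − (1−*f*)²;
4. **kinetics** — nearest-neighbor event linking, dwell times
   *t*<sub>D</sub> = *n*·Δ*t*, desorption rates *k*<sub>d</sub> =
   1/*t̄*<sub>D</sub> (with optional frame-discretization correction),
   site clustering, and per-site adsorption free energies
   ΔG = −RT ln K<sub>eq</sub>;
5. **elution** — the stochastic (compound-Poisson / Lévy) theory of
   chromatography: retention = *t*<sub>M</sub> + Σ of Poisson(*n̄*) dwell
   sojourns, synthesized from the *empirical* dwell characteristic
   function by FFT inversion of
   Φ(ω) = e<sup>iω t_M</sup> · exp(*n̄*(φ<sub>s</sub>(ω) − 1)),
   plus peak moments (area, center, variance, skew).

The methods vignette (`vignettes/smlmchrom-methods.Rmd`) documents every
model, default and numerical choice.

## Worked example

Simulate an SPP-like particle (2.5-µm radius, accessible shell
*f* = 0.37), localize every adsorption event, and quantify accessibility,
kinetics and predicted elution:

```r
library(smlmchrom)

res <- run_pipeline(
  list(seed = 7, particle = list(accessible_fraction = 0.37)),
  outdir = "spp_run")

str(res$accessibility)
#> $ d99_percent_r: num 36.9
#> $ Ap_um2       : num 11.4
#> $ Ai_um2       : num 19.9
#> $ ratio        : num 0.572
#> $ r_nm         : num 2520
#> $ n_loc        : int 19498
```

The recovered accessible-depth limit, 36.9 %*r* from 19 498
localizations, sits on the closed-form annulus limit
`d99_annulus(0.37)` = 36.5 %*r* — the geometry of a 0.5-µm porous shell
on a 1.35-µm-radius particle scaled to this particle — and the
accessible-area ratio 0.57 approaches its dense-sampling limit
1 − 0.63² = 0.60. The same run links 3 561 adsorption events into 436
sites and models the elution peak from their dwell times:

```r
res$moments
#> peak center 17.804 s, variance 7.718 s^2, skew 0.267
```

The positive skew is the tailing expected from rare long-lived
adsorptions; truncating those dwells (the solvent-treatment analogue,
`compare_conditions()`) shifts the modeled centroid strictly earlier
while tailing persists.

The numbered scripts under `analysis/` run the same chain as a narrative
workflow — `01_simulate.R` through `05_elution.R` — writing movies,
localization tables, accessibility summaries, kinetics tables and modeled
elution profiles under `results/`.

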