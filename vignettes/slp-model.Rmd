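---
title: "Modelling specific loss power in superparamagnetic hyperthermia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling specific loss power in superparamagnetic hyperthermia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slpsim)
```

## The physical model and its assumptions

A monodisperse ensemble of spherical single-domain nanoparticles with
packing fraction $\varepsilon$ sits in an alternating field of amplitude
$H$ and frequency $f$. In the linear-response (Debye) regime the
out-of-phase susceptibility dissipates

$$P_s \;=\; \pi \mu_0 f H^2 \,\chi_i\, \frac{3L(\xi)}{\xi}\,
  \frac{2\pi f \tau}{1+(2\pi f\tau)^2}\, \big/\, \rho
  \qquad [\mathrm{W\,g^{-1}}],$$

per gram of magnetic material, with the initial susceptibility
$\chi_i = \varepsilon\pi\mu_0 M_s^2 D^3/(18 k_B T)$, the Langevin
argument $\xi = \pi\mu_0 M_s D^3 H/(6 k_B T)$, and
$L(\xi)=\coth\xi - 1/\xi$. The chord factor $3L(\xi)/\xi \in (0,1]$
corrects the zero-field susceptibility for partial saturation at finite
amplitude; it is the only nonlinearity retained, so the model interpolates
between strict linear response ($\xi\to 0$) and the saturated regime
rather than solving the full nonlinear dynamics.

Two relaxation channels feed the Lorentzian. The Néel time
$\tau_N = \tau_0\exp(\pi K D^3/6k_BT)$ describes the internal moment
hopping over the anisotropy barrier $KV$; the Brown time
$\tau_B = \pi\eta D_h^3/(2k_BT)$ describes rigid rotation of the whole
particle against viscous drag. They combine harmonically,
$1/\tau = 1/\tau_N + 1/\tau_B$, so the faster channel dominates.
Immobilized particles (`slp_immobilized()`) keep only $\tau_N$.

The one structural subtlety of a core-shell particle is that the organic
coating enters *only* through the hydrodynamic diameter $D_h = D + 2d$
in $\tau_B$: susceptibility, Langevin argument and Néel barrier all use
the magnetic core diameter $D$. For a high-anisotropy material such as
cobalt ferrite this has a large consequence: $\tau_N$ explodes
exponentially beyond ~6 nm, so in a liquid the heating is carried almost
entirely by Brown rotation, the optimal diameter moves up to 9–17 nm,
and (unlike the Néel-dominated immobilized case) it shifts strongly with
field amplitude.

Deliberately out of scope: polydispersity, non-spherical shapes, dipolar
interactions (the coating is taken to isolate the particles), any
temperature-rise/bioheat modelling, and fitting to experimental heating
curves. $\varepsilon$ enters only linearly through $\chi_i$; no
concentration-dependent interaction correction is applied even at
$\varepsilon = 0.15$.

## Parameters, units and defaults

| Parameter | Meaning | Default (presets) |
|---|---|---|
| $M_s$ | spontaneous magnetization | 425 kA/m |
| $K$ | anisotropy constant | 200 kJ/m³ |
| $\rho$ | core material density | 5.29 g/cm³ |
| $\tau_0$ | Néel attempt time | $10^{-9}$ s |
| $d$ | organic shell thickness | 1.6 nm |
| $\eta$ | carrier viscosity | $7\times10^{-4}$ Pa·s |
| $T$ | temperature | 300 K |
| $\varepsilon$ | packing fraction | 0.024 / 0.15 |

The presets carry the conditions for γ-cyclodextrin-coated CoFe₂O₄
dispersed in saline: the shell thickness is the γ-CD torus height (~0.8 nm)
plus the polyacrylic-acid binding layer (~0.8 nm); the viscosity is that
of saline at body-adjacent temperature. "Room temperature" is fixed at
300 K and exposed as `T_K` in configs — the printed operating tables are
reproduced at this value to well under a percent, and the model's
temperature sensitivity over 290–310 K is mild. $M_{sat}$ is taken equal
to $M_s$ unless overridden.

Internally everything is strict SI; the display/file units of the field
(kA/m, kHz, nm, W/g) are converted exactly once, at the config/CLI
boundary. W/g is W/kg divided by 1000, normalized by the *core* mass only
(the coating mass is not counted, consistent with using a single core
density $\rho$).

## Numerical choices

* **Langevin stability.** For $\xi < 10^{-4}$, $L$ and $3L/\xi$ switch to
  Taylor series ($\xi/3 - \xi^3/45 + 2\xi^5/945$ and
  $1 - \xi^2/15 + 2\xi^4/315$) to avoid the catastrophic cancellation in
  $\coth\xi - 1/\xi$; the branches agree to ~$10^{-8}$ relative at the
  switch point, which is the cancellation floor of the closed form.
* **Néel overflow guard.** The exponent $\pi K D^3/6k_BT$ is clamped at
  700: beyond it $\tau_N$ is returned as `Inf`, a sentinel whose
  reciprocal is exactly zero in the harmonic combination. $e^{700}$ sits
  just below the double-precision ceiling, and $\tau_N > 10^{294}$ s is
  physically indistinguishable from infinite. At 25 nm the exponent
  (~395) is still below the guard; the finite but astronomical
  $\tau_N$ behaves identically in every downstream expression.
* **Diameter grid and refinement.** Sweeps use a 0.01 nm grid (1–25 nm or
  1–30 nm in the presets; 2 401–2 901 points, milliseconds to evaluate).
  Every strict interior local maximum is then refined by bracketed
  one-dimensional maximization (Brent's method, `stats::optimize`) inside
  its two neighbouring grid cells; refined locations agree with a
  brute-force 0.001 nm grid argmax to < 0.005 nm. Peaks closer than
  0.2 nm are merged (keeping the higher) to suppress float-noise twins,
  and boundary maxima are reported as warnings, never as peaks, since
  physically meaningful optima are interior.
* **Crossover root.** $\tau_N = \tau_B$ is solved on
  $\log(\tau_N/\tau_B)$ — monotone and well-scaled — with
  `stats::uniroot` to a relative tolerance of $10^{-9}$ in $D$.
* **Regime labels.** A diameter is labelled Néel or Brown when the other
  channel is more than tenfold slower, otherwise "mixed". The factor 10
  is a design choice mirroring the finite (~5.7–6.4 nm) band over which
  both mechanisms contribute comparably; labels near the crossover are
  therefore deliberately "mixed" even when one channel slightly leads.
* **Determinism.** The model is closed-form; no randomness exists
  anywhere, and identical inputs produce byte-identical CSV/JSON output
  (full precision in files, rounding only in human-readable displays:
  0.1 nm for diameters, 0.01 W/g for powers).

## What the sweeps show

```{r}
cfg <- slp_preset("cofe2o4_gcd")
field_response(cfg, H_values = c(10e3, 30e3, 50e3), f = 500e3)
```

The dominant peak is Brown-type throughout, its power rises steeply with
$H$, and its location falls — the behaviour that makes the coated,
dispersed system tunable where the immobilized one is not:

```{r}
imm <- slp_config(cfg$material, cfg$coating, cfg$medium,
                  sweep_spec(D_min = 1e-9, D_max = 25e-9,
                             D_step = 0.01e-9, epsilon = 0.024,
                             mode = "immobilized"))
field_response(imm, H_values = c(10e3, 50e3), f = 500e3)
```

The immobilized optimum stays pinned near 6.2 nm. Above ~1500 kHz the
dispersed curve develops a second, Néel-branch maximum at small
diameters:

```{r}
find_peaks(sweep_curve(cfg, f = 2000e3, H = 30e3))
crossover_diameter(cfg$material, cfg$coating, cfg$medium)
```

Note the Néel-branch peak at ~6.0 nm is labelled "mixed": it sits just
above the $\tau_N=\tau_B$ crossover (~5.95 nm), inside the factor-10
band.

## Design decisions that were genuinely open

* **Dominant peak = global maximum** over the diameter range; secondary
  maxima are listed separately by `frequency_response()` and
  `find_peaks()`. Only frequencies ≥ ~1500 kHz produce one.
* **Preset granularity.** Rather than exposing dozens of loose knobs, the
  two presets pin the canonical study conditions and `load_config()`
  overrides individual keys on top of them, rejecting unknown keys
  outright — silent typos in a physics config are worse than a hard
  error.
* **Crossover bracket default** (1–15 nm) spans the physically plausible
  single-domain range for this material; outside-bracket requests fail
  loudly rather than extrapolating.

## What passing tests do and do not show

The test suite pins every intermediate quantity to an independently coded
one-line oracle (relative error $<10^{-12}$ on random parameter draws),
verifies the analytic limits (linear response, immobile, coating-off,
$\varepsilon$-linearity, Lorentzian $\le 1/2$), and reproduces the
published operating tables for CoFe₂O₄–γ-CD to within 3% in peak power
and 0.25 nm in peak diameter. That validates the implementation of the
model, not the model's fidelity to any particular laboratory system:
real suspensions are polydisperse, interact dipolarly at high
concentration, heat up (changing $\eta$ and $T$), and may violate linear
response at the largest amplitudes considered. Agreement with measured
SAR values should be expected only at the factor-of-a-few level typical
of linear-response estimates.
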