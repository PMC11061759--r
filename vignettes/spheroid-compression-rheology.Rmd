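---
title: "Viscoelastic analysis of spheroid compression assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscoelastic analysis of spheroid compression assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherorheo)
```

## The assay and its mechanics

A multicellular spheroid sits in buffer in a well plate; a glass coverslip
is lowered onto it and left there. The coverslip's submerged weight,
$F = mg - \rho V g$, is constant, so the experiment is a creep test: the
spheroid flattens and spreads while an inverted microscope records its
diametral cross-section (by default at 0.5 Hz for 8 minutes, 240 frames).

Two modelling assumptions convert morphology to mechanics:

* **Stress.** $\sigma(t) = F/A(t)$ with $A(t)$ the measured diametral area.
  Because $A$ grows, $\sigma$ *decays* even though $F$ is constant. We use
  the diametral area, not a Hertzian contact patch, as the denominator —
  the assay measures the diametral plane, and for a strongly flattened
  spheroid the two approach each other.
* **Strain.** The compressed spheroid is treated as an oblate spheroid with
  axes $a=b=D>c=h$ conserving the initial spherical volume, so
  $h = D_0^3/D^2$ and the axial stretch is $h/h_0 = (D_0/D)^2$. Two
  conventions are carried throughout: `as_written` ($\lambda = (D_0/D)^2$,
  starts at 1, decreases) for reporting, and `engineering`
  ($\varepsilon = 1-\lambda$, starts at 0, grows) as the default for
  fitting and transforms, because a creep response that grows from zero is
  what the fitting machinery and the Fourier analysis expect. They are
  element-wise complements, so nothing is lost either way.

Neither the coverslip geometry nor the buffer density is a property of this
package: they are required configuration inputs. The documented example
values (22 × 22 × 0.15 mm glass at 2500 kg/m³; PBS at 1005 kg/m³; g = 9.81
m/s²) are non-authoritative defaults to be replaced with the instrument's
actual values.

## The Burgers model and its two roles

The four-element Burgers material — a Maxwell arm (spring $E_2$, dashpot
$\eta_2$) in series with a Kelvin–Voigt arm (spring $E_1$, dashpot
$\eta_1$) — obeys

$$\sigma + \left(\tfrac{\eta_1}{E_1}+\tfrac{\eta_2}{E_1}+\tfrac{\eta_2}{E_2}\right)\dot\sigma
  + \tfrac{\eta_1\eta_2}{E_1E_2}\ddot\sigma
  = \eta_2\dot\varepsilon + \tfrac{\eta_1}{E_1}\eta_2\ddot\varepsilon,$$

with time constants $\tau_1=\eta_1/E_1$ (retardation time),
$\tau_2=\eta_2/E_1$, $\tau_3=\eta_2/E_2$, $\kappa_1=\tau_1+\tau_2+\tau_3$,
always recomputed from the four coefficients. Its creep compliance is

$$J(t) = \frac{1}{E_2} + \frac{t}{\eta_2} +
         \frac{1-e^{-tE_1/\eta_1}}{E_1},$$

i.e. the governing equation as written assigns the instantaneous spring and
the terminal dashpot to the Maxwell arm $(E_2,\eta_2)$ and the retarded
response to the Kelvin–Voigt arm $(E_1,\eta_1)$. We verified this mapping
independently by integrating the mechanical network as a state-space ODE
(the test suite keeps that oracle). Some discussions of the same model use
the opposite naming — $E_1$ as the instantaneous modulus and $\eta_1$ as
the long-term viscosity. Rather than silently picking one, the equation's
assignment is authoritative internally and a `role_convention` switch
(`as_equation`, the default, vs `as_discussion`) swaps the $(E_1,\eta_1)$
and $(E_2,\eta_2)$ pairs *in reporting only*. The reported summary triple is
$(\eta_1, E_1, \tau_2)$ with $\tau_2$ defined as the Maxwell ratio
$\eta_2/E_2$ under the active convention, which is the triple commonly used
to compare cell lines.

In the frequency domain the same model gives the closed-form compressional
storage and loss moduli $E'(\omega), E''(\omega)$ implemented in
`burgers_moduli()`; a property test checks the printed real/imaginary forms
against the complex ratio
$(i\omega\eta_2-\tau_1\eta_2\omega^2)/(1+i\kappa_1\omega-\tau_1\tau_3\omega^2)$
to machine precision on 1000 random parameter sets.

## Fitting choices

`fit_burgers()` works in log-parameter space (positivity for free, and the
four coefficients span decades), with *relative* residuals matching the
multiplicative character of imaging noise, and five deterministic heuristic
starts: $E_2$ from the instantaneous jump, $\eta_2$ from the terminal
slope, $E_1$ from the retarded amplitude, and a small grid of candidate
retardation times (including a rise-time estimate) for $\eta_1$. The best
converged start wins; standard errors come from the Gauss–Newton Hessian by
the delta method.

Because the measured stress decays, two fitting modes exist and the choice
is the user's: `constant_stress` fits the analytic creep solution using the
first-sample (maximum) stress — adequate when the area growth is mild — and
`hereditary` fits the Boltzmann superposition response
$\varepsilon(t)=\sigma(t_1)J(t-t_1)+\int J(t-u)\,\dot\sigma(u)\,du$
evaluated in closed form for piecewise-linear stress (no quadrature). The
hereditary mode is the accurate one for this assay and is what the
round-trip tests use.

One boundary subtlety: a measured series starts with an undeformed
reference frame ($\varepsilon(t_0)=0$), while the creep solution jumps to
$\sigma_0/E_2$ at $t=0^+$. A leading zero-strain sample is therefore
treated as the pre-load reference and excluded from the residuals; records
of pure creep (load applied before the first sample) have no such point and
are used in full.

`fit_spectrum()` applies the same machinery to a measured spectrum —
log-space residuals jointly on $E'$ and $E''$ — to summarise *model-free*
spectra with the same parameter triple. Points below the record's
fundamental frequency are excluded, and a fit whose rms log-residual
exceeds 0.7 (roughly a factor-2 misfit) is rejected rather than reported.

## The model-free route

`sampled_fourier()` implements the piecewise-linear transform of a sampled
function with explicit end-point handling:

$$-\omega^2\hat g(\omega) = i\omega g(0)
 + \big(1-e^{-i\omega t_1}\big)\frac{g_1-g(0)}{t_1}
 + \dot g_\infty e^{-i\omega t_N}
 + \sum_{k=2}^{N}\frac{g_k-g_{k-1}}{t_k-t_{k-1}}
   \big(e^{-i\omega t_{k-1}}-e^{-i\omega t_k}\big),$$

with $g(0)$ defaulting to the linear extrapolation of the first two samples
(or the $t=0$ sample itself) and $\dot g_\infty$ to the least-squares slope
of the final 20% of samples; both are overridable. The formula is exact for
constants and ramps — the analytic-pair tests exploit that — and
`complex_modulus()` forms $E^*(\omega)$ as the transform ratio, in which
the $-\omega^2$ factors cancel.

The default frequency grid runs from the fundamental $2\pi/T$ to the
Nyquist limit $\pi/\Delta t$ at 20 points per decade; for the default
acquisition that is about $1.31\times10^{-2}$ to $1.57$ rad/s. Evaluating
below the fundamental is possible (the transform is a plain sum) and is how
sub-fundamental moduli around $10^{-3}$ rad/s can be quoted from an 8-min
record, but such points are *extrapolation*: the `extend_low_decades`
option produces them and every output flags them in an `extrapolated`
column, and validation properties ignore them. Within the window, the
transform's edges are the least trustworthy, so cross-route agreement is
asserted over the central two decades (a two-decade band centred on the
grid's geometric mean), where noiseless Burgers creep reproduces the
closed-form moduli within 5% (storage) and 10% (loss).

## Shear conversion, indentation, statistics

Isotropic linear viscoelasticity gives $E = 2G(1+\nu)$ frequency by
frequency, so spectra convert by a scalar: with the literature value
$\nu=0.4$ the divisor is exactly 2.8, and moving to incompressibility
($\nu=0.5$) lowers converted moduli by $1-1.4/1.5 \approx 6.7\%$
(`poisson_sensitivity()`). The loss tangent is conversion-invariant.

Nanoindentation creep records (load $F(t)$, displacement $\delta(t)$,
spherical tip radius $R$) are ingested by the same transform machinery with
a linearised Hertzian contact about the operating depth $\delta_0$ (by
default the mean displacement of the record): small oscillations obey
$dF = 2\sqrt{R\delta_0}\,[E/(1-\nu^2)]\,d\delta$, hence
$G^*(\omega) = (1-\nu)\hat F/(4\sqrt{R\delta_0}\,\hat\delta)$. The exact
contact prefactor used by commercial instruments is not standardised; this
first-order linearisation is our choice, isolated in
`indentation_moduli()` so an alternative can be substituted, and validated
by forward–inverse round trips.

Group comparisons use Welch's two-sided two-sample $t$-test (a deliberate
choice: small groups with no variance-equality guarantee), with stars
`**` for $p<0.005$ and `*` for $p<0.05$; summaries are mean ± SEM
($s/\sqrt n$).

## What the synthetic generator emulates — and what it does not

`simulate_compression()` reproduces the assay's defining feedback: constant
force, growing diametral area, hence decaying stress coupled to the Burgers
hereditary response, stepped explicitly per frame with an exact exponential
update of the Kelvin–Voigt state. The instantaneous elastic jump at
$t=0^+$ is solved self-consistently with the area feedback
($\varepsilon = c/(1+c)$, $c = F/(A_0E_2)$); without that the explicit
scheme rings over the first frames. Halving the step changes the
trajectory by under 0.5% (tested). Multiplicative Gaussian noise is applied
after the dynamics, to the measured areas and the strain record
independently; runs are deterministic given the seed, and unphysical
parameter/load combinations (stretch leaving $(0,1]$) abort.

Defaults are the assay's stated conditions: 0.5 Hz, 8 min (exactly 240
frames), 2% noise, a 400-µm spheroid. The default generating parameters
($E_1 = 2500$ Pa, $E_2 = 1200$ Pa, $\eta_1 = 2.67\times10^5$ Pa·s,
$\eta_2 = 8\times10^5$ Pa·s) put the moduli in the $10^2$–$10^3$ Pa range
typical of spheroids with a retardation time ($\approx 107$ s) well inside
the 480-s window. The default load is a *light effective load* (net
$\approx 3.9\times10^{-5}$ N, $\approx 310$ Pa on a 400-µm spheroid): a
full coverslip's net weight ($\sim$1 mN) over a single 400-µm diametral
area would impose $\sim$8 kPa and crush a $10^2$-Pa material — in practice
the load a single spheroid experiences is far smaller — so the generator's
default is chosen for physical self-consistency with the moduli scale, not
as a claim about any particular instrument.

`render_stack()` draws anti-aliased dark discs with Gaussian blur and
additive noise. That is enough to exercise segmentation (threshold choice,
morphology, calibration, gap handling) but deliberately omits
phase-contrast halo artifacts, internal cellular texture, debris and
illumination drift beyond a smooth surface. Passing the closure test
(images → segmentation → mechanics → fit recovering the generating
parameters within 15% at realistic noise) therefore validates the
*plumbing and numerics*, not the segmentation's robustness to every real
imaging pathology.

Segmentation itself — background flattening by a robust second-order
polynomial surface, Otsu threshold on inverted intensity, hole filling,
opening with a radius-2 disc, largest 8-connected component — is a
conventional pipeline; dark-object polarity is the default with a switch
for bright objects. Failed frames are gap-filled by linear interpolation
across at most 3 consecutive failures; longer gaps, or more than 20% failed
frames, abort the run rather than silently degrade it.

## Numerical choices and degenerate inputs

* Optimisation tolerances: `nls.lm` with `ftol = ptol = 1e-12`, 200
  iterations, multi-start; ties broken by lowest deviance.
* Flat strain records, single samples, non-monotone time grids, buoyant
  coverslips, non-positive areas and out-of-range Poisson ratios all raise
  errors naming the problem.
* Strain-transform magnitudes below $10^{-12}$ of the stress transform are
  excluded point-wise; negative model-free moduli are reported but
  messaged, never clipped.
* Problem sizes in the tests mirror the assay (240-frame records,
  160–256 px frames, 20-replicate recovery studies, 100–1000-set property
  sweeps) — chosen as representative of the science while keeping the
  whole suite under a minute.

## Known limitations

* The stress definition uses the diametral area; no wall effects,
  coverslip friction, surface tension or poroelastic drainage.
* Linear viscoelasticity throughout: spheroid strains of tens of percent
  are formally outside the small-strain regime, so the Burgers parameters
  are effective quantities — which is also why two analysis routes are
  carried and compared rather than trusting the model alone.
* The nanoindentation prefactor is a linearisation, not a full Hertz/JKR
  fit of approach curves.
* Sub-fundamental frequencies are extrapolations of the transform, flagged
  as such.
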