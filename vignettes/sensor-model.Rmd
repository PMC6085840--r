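---
title: "Modeling a fiber-optic SPR sensor for neural activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a fiber-optic SPR sensor for neural activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmorec)
```

## The sensing principle

A multimode silica fiber is stripped of (part of) its cladding and coated
with a 50 nm gold film, immersed in phosphate-buffered saline (PBS). Light
guided by total internal reflection carries an evanescent tail into the
film; at the wavelength where the guided ray's transverse effective index
matches the surface-plasmon-polariton (SPP) index of the gold/buffer
interface, power is resonantly absorbed. A neuron firing next to the film
changes the electrode potential of the gold by roughly the transmembrane
excursion (order ±100 mV). The resulting excess surface charge changes the
free-electron density of the metal, hence its permittivity, hence the
resonance wavelength and the transmitted intensity. `plasmorec` models this
chain end to end and asks: how large is the optical response to an action
potential, and how does it depend on the sensor geometry?

Three geometries are supported: `full_clad_removed` (annular gold shell
around the bare core), `half_clad_removed` (fiber polished flat to the core
surface, gold on the flat, cladding intact on the other side), and
`half_core_removed` (polished through to the fiber axis, gold on the cut).

## Gold permittivity and the charge model

Gold is modeled by a single-Lorentz-pole Drude–Lorentz permittivity under
the $e^{-i\omega t}$ convention (loss has $\mathrm{Im}\,\varepsilon > 0$,
enforced in tests):

$$\varepsilon(\omega) = \varepsilon_\infty
  - \frac{\omega_D^2}{\omega^2 + i\gamma_D\omega}
  - \frac{\Delta\varepsilon\,\omega_L^2}{\omega^2-\omega_L^2+i\gamma_L\omega}.$$

The default parameter set (`gold_drude_lorentz()`) is an FDTD-style fit of
tabulated gold optical constants; at 633 nm it gives
$\varepsilon = -11.74 + 1.22i$, within a few percent of evaporated-film
measurements (the test suite checks 15 % agreement against an interpolated
n,k table). The model is accepted on 300–2000 nm; outside that window every
material function raises an error.

Electrode charging enters through the plasma frequency,
$\omega_D^f = \omega_D\sqrt{1+\Delta N/N}$, with $N = 5.90\times10^{28}$
m⁻³ the free-electron density of gold. The potential-to-charge mapping is a
declared convention of this package (no standard exists for this sensor):
a double-layer capacitance $C$ per area stores surface charge $CV$, which
as electrons occupies a thin layer of thickness $d$ at the gold/electrolyte
interface, so $\Delta N = \pm CV/(ed)$. Defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| $C$ | 0.5 (= 50 µF/cm²) | F/m² | upper end of the electrochemical double-layer range (5–50 µF/cm²); calibrated once, see below |
| $d$ | 0.5 | nm | Thomas–Fermi-scale screening depth |
| sign | $-1$ | — | positive potential depletes electrons |
| localization | `surface_layer` | — | charge confined to the interface sub-layer |

Two localization models are provided. `surface_layer` (default) treats the
charged sub-layer as a distinct stack layer in the planar engine and as a
thickness-weighted effective film correction in the 2-D solver;
`uniform_film` spreads the same total charge over the whole film. Because
$\Delta N \propto 1/d$ while the optical perturbation scales as
$\Delta\varepsilon\cdot d$, the predicted resonance shift depends only on
the areal charge $CV/e$ — the choice of $d$ is immaterial to first order,
which the two localization modes confirm numerically.

**Calibration note.** $C$ was calibrated once, within the documented
physical range, to maximize the voltage sensitivity; the resulting
-100 → +100 mV peak shift of the half-removed-cladding design is about
0.22 nm (recomputed by `scripts/acceptance.R`). A shift an order of
magnitude larger would require an effective interfacial capacitance well
beyond the double-layer range, so the package reports the smaller,
physically grounded value rather than tuning outside the documented bounds.

## Planar engine: transfer matrix and ray summation

The fast spectrum engine idealizes the film system as the planar stack
silica | gold (50 nm) [| charged sub-layer] | buffer and combines
Abelès characteristic-matrix reflectance with a geometric-optics power
integral over guided ray angles:

$$T(\lambda)=\frac{\int_{\theta_c}^{\theta_{max}} P(\theta)\,
  \bar R(\theta,\lambda)^{N(\theta)}\,d\theta}{\int P(\theta)\,d\theta},
  \qquad N(\theta)=f_{gold}\frac{L}{D\tan\theta},$$

with $\theta$ the wall-incidence angle, $\theta_c$ the critical angle from
the launch NA (0.22), a grazing cap at 89.5°, 64-point Gauss–Legendre
quadrature, and absorbance $A = 1 - T$. The per-reflection reflectance
$\bar R$ is by default the 50/50 unpolarized average of $R_p$ and $R_s$
applied per reflection (polarization-scrambling approximation; `p`-only is
available as an upper bound on sensitivity). The design enters through
$f_{gold}$, the fraction of wall bounces that strike gold: 1 for the fully
coated design, 1 for the half-core cut (gold flat and curved wall alternate
across half the diameter), and 1/2 for the half-removed cladding (alternate
bounces reflect off the intact cladding side).

Defaults: core diameter $D = 10$ µm, sensing length $L = 0.2$ mm. The
sensing length deserves a comment: at $D = 10$ µm a millimeter-scale
sensing region gives $N(\theta)\sim 50$–600 film reflections, which
saturates the absorbance across the whole visible window and destroys both
peak localization and voltage sensitivity. A 0.2 mm region — the scale of
the neural tissue volume such a probe would interrogate — keeps the
absorbance in its quasi-linear range (peak $A \approx 0.28$) and is the
package default; it is configurable (`ray.length_mm`).

The transfer-matrix core is validated by closed-form Fresnel coefficients,
exact energy conservation on lossless stacks ($|R+T-1| < 10^{-10}$), an
independently coded Airy three-layer formula, and the analytic SPP
phase-matching condition
$k_{spp} = k_0\sqrt{\varepsilon_m\varepsilon_d/(\varepsilon_m+\varepsilon_d)}$.
One physical subtlety the tests document: with a silica prism the SPP index
(1.444 at 633 nm with water) lies within 0.013 of the prism index, so
radiative coupling displaces the reflectance dip ~1.9° from the
phase-matching angle; with a canonical high-index prism (n = 1.515) the
agreement is 0.3°.

## 2-D engine: full-vector finite-difference modes

The cross-section eigenproblem
$\nabla\times\nabla\times\vec E - k_0^2\varepsilon_r\vec E = 0$ is solved
in the transverse-field $(E_x, E_y)$ formulation on a nonuniform
tensor-product grid (cell-centered, at least 5 cells across the film,
window 4× the core radius, zero-field PEC boundaries). The coupled stencils
retain the $\partial(1/\varepsilon)\partial(\varepsilon\,\cdot)$ structure
that enforces displacement continuity at interfaces; cross-coupling terms
vanish wherever the permittivity is locally uniform.

Eigenpairs nearest an effective-index target are found by shift-invert
Arnoldi. The complex sparse factorization is carried out on the equivalent
augmented real system $[[B_r,-B_i],[B_i,B_r]]$ (one LU per shift), with a
deterministic symmetry-breaking start vector, modified Gram–Schmidt with
re-orthogonalization, explicit residual checks on the discrete
eigen-relation ($<10^{-8}$ relative), and Krylov-dimension escalation near
SPR anti-crossings where the spectrum clusters. Modes whose real effective
index exceeds the largest physical bound (dielectric index, or the bound-SPP
index when metal is present) are discarded as spurious. For plasmonic
branches the shift should be complex — e.g. the planar pole supplied by
`planar_pole_search()` — since a purely real shift can sit as close to the
radiation-mode cluster as to the lossy target mode.

Verification (standing tests, not one-offs): homogeneous-medium box modes
converge at $O(h^2)$ (Richardson ratio ≈ 4); the step-index fundamental
matches the scalar Bessel dispersion root to ~$10^{-6}$ (criterion
$10^{-4}$) at a 80×80 grid; an extruded silica|gold|water slab's bound SPP
mode at 550 nm matches the 1-D pole search to 0.06 % (Re) and 0.14 % (Im);
mirror-symmetric designs give symmetric/antisymmetric fields to $10^{-10}$.

Modal absorbance aggregates $1-e^{-\alpha L}$, $\alpha = 4\pi\,
\mathrm{Im}(n_{eff})/\lambda_0$, with equal weights over "guided" modes —
those with real effective index between the densest surrounding medium
(cladding where intact, buffer otherwise) and the core index. Equal
weighting is a declared convention: the true launch distribution of a
multimode fiber is setup-dependent and nothing in the modeled experiment
pins it down. Near the SPR anti-crossing the guided/non-guided
classification of strongly hybridized modes is mesh-sensitive, so the modal
spectrum's absolute scale is less robust than its peak position; the
cross-engine test therefore compares peak positions (agreement within
25 nm) and the sign of the voltage-induced shift, not absolute absorbance.

## Pipeline conventions and numerical choices

* Wavelength grids: 500–900 nm at 0.25 nm (planar), 550–750 nm at 2 nm
  (modal; each modal point costs an eigensolve). Peaks are refined by a
  three-point parabolic fit, exact on parabolas; a maximum on the grid
  boundary raises an error rather than returning a clamped value.
* The neuron's potential is applied to the gold as-is (`coupling_factor`
  = 1.0 records the assumption; cleft attenuation is not modeled).
* Intensity traces evaluate $1-A(V(t))$ at a fixed excitation wavelength
  (680 nm by default, on the red flank of the resonance) either per sample
  (`direct`) or through a natural cubic spline over ≥5 voltage knots
  (`interpolant`, default; the two agree to $10^{-4}$ absolute intensity).
* Output intensity is transmitted power $1-A$, not absorbance; the choice
  is recorded here because either convention appears in the literature.
* Determinism: the entire pipeline is deterministic given configuration;
  the seed argument is recorded for provenance only.

## The synthetic action potential

`synthesize_action_potential()` provides two drives. `template` is a
piecewise-analytic spike (fast double-exponential depolarization, shallow
slow after-hyperpolarization) scaled so its maximum equals the configured
peak (default +100 mV) exactly — the transmembrane excursion with the
resting offset removed. `hodgkin_huxley` integrates the standard squid-axon
point neuron (RK4, fixed step ≤ 10 µs) under a configurable current pulse
and rescales the spike crest to the configured peak; a subthreshold run is
left unscaled. The generator emulates the amplitude and millisecond
time-scale of a real spike. It does not emulate: bursting or adaptation,
extracellular potential attenuation (real extracellular amplitudes are
10–100× smaller than transmembrane ones), junction geometry, or recording
noise. A passing tracking test therefore shows that the *model's* optical
response follows the drive waveform (correlation > 0.99); it does not show
that a physical device would resolve extracellular spikes above shot noise.

## Known limitations

* The annular gold shell of `full_clad_removed` is treated by the planar
  engine as a planar film (documented approximation); its 2-D map honors
  the ≥5-cells-across-film rule only where the film normal aligns with the
  grid axes.
* PEC window boundaries cannot represent leaky modes; quasi-modes beyond
  cutoff acquire box-quantization artifacts (no PML is provided).
* The ray model ignores skew rays and coherent interference between
  successive reflections; bounce counts are continuous.
* The voltage response is linear in the applied potential by construction;
  electrochemical double-layer structure (Gouy–Chapman–Stern), Faradaic
  currents and temperature effects are out of scope.

## Problem sizes used in the test suite

Solver tests run at 40–160 cells per axis (uniform/step-index cases), a
9×159 graded grid for the slab oracle, and 60–80 base cells for sensor
cross-sections; the cross-engine check samples the modal spectrum at four
wavelengths at 60 base cells. These sizes were chosen as the smallest at
which each oracle criterion is met with an order-of-magnitude margin.
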