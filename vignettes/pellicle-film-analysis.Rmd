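---
title: "Models and methods: four-technique analysis of adsorbed pellicle films"
author: "pellifilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: four-technique analysis of adsorbed pellicle films}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pellifilm)
```

# Scope

`pellifilm` implements the computational side of a four-technique
characterisation of salivary pellicles — the thin proteinaceous films that
adsorb from saliva onto solid surfaces — and of their modification by
surfactants. The four techniques probe complementary aspects of the same
hydrated film:

* **Specular neutron reflectometry (NR)** resolves the out-of-plane
  structure (thickness, hydration, composition per layer) via slab models
  co-refined across isotopic solvent contrasts.
* **QCM-D** senses the "wet" areal mass (film plus hydrodynamically coupled
  solvent) through a viscoelastic (Voigt) film model.
* **Null ellipsometry** senses the "dry" adsorbed amount through de
  Feijter's equation.
* **AFM force-volume spectroscopy** probes the diffuse outer region through
  the decay length of the exponential steric repulsion felt on confinement.

Each analysis stage is paired with a seeded synthetic-data generator so that
every pipeline is verifiable by parameter recovery without instrument data.
The generators are first-class, tested code: analysis operations never read
generator truths; recoveries are compared post hoc.

# Scattering length densities and contrasts

SLDs are computed from atomic composition and mass density,
$\rho = \sum_i c_i b_i / V_m$, using a bundled table of bound coherent
scattering lengths (H and the deuterium isotope D are distinct entries).
Defaults reproduce the three buffers of the experiments: pure H$_2$O PBS
($-0.56 \times 10^{-6}\,\mathrm{\AA^{-2}}$ at 0.997 g/cm$^3$), pure D$_2$O
PBS ($6.36$ at 1.105 g/cm$^3$) and silicon-matched water, the 0.38:0.62
D$_2$O:H$_2$O mix ($2.07$). PBS salts are neglected — the buffers are
quoted at their pure-water values, which is standard practice at the
ionic strengths involved. Labile-hydrogen exchange between salivary
material and D$_2$O is off by default (no exchange model is implied by the
data); the dry SLDs are configurable so an exchanged value can be supplied
directly.

The dry SLD of salivary material is not established by the measurements
themselves; the default, $2.0 \times 10^{-6}\,\mathrm{\AA^{-2}}$, is
typical of hydrogenated protein/glycoprotein and is exposed as a parameter
of every model constructor.

# Neutron reflectivity

## Forward model

The Si/SiO$_2$/pellicle/solvent interface is a stratified stack. Each
pellicle layer carries thickness $t$, hydration $\phi$ (solvent volume
fraction), a dry composition split between salivary material and
surfactant, and a Gaussian interfacial roughness. The layer SLD at a given
contrast is

$$\rho = \phi\,\rho_{solv} + (1-\phi)\left(f_{sal}\rho_{sal} +
f_{surf}\rho_{surf}\right).$$

Reflectivity is computed by the Abelès transfer-matrix method with
Névot–Croce roughness damping, with the beam propagating through the
silicon substrate (solid–liquid cell geometry). The implementation is
checked in the test suite against an independently coded Parratt recursion
(relative $10^{-8}$ on random five-layer stacks), against the closed-form
Fresnel step, and against the critical-edge relation
$Q_c = \sqrt{16\pi\,\Delta\rho}$. Resolution smearing uses a Gaussian
kernel of constant relative FWHM (default $\Delta q/q = 4\%$, the
time-of-flight case), applied by quadrature over the kernel during fitting.
A constant background (default $10^{-7}$) is added to the model; it
represents the incoherent floor of a time-of-flight measurement and is the
same constant the generator applies.

## Co-refinement and uncertainties

All structural parameters are shared across contrasts; per-contrast solvent
SLDs are fixed at nominal values (nothing in the data suggests fitting
them). The misfit is the pooled $\chi^2$ weighted by the per-point
uncertainties. Optimisation is a seeded differential-evolution global
search inside physical bounds followed by a quasi-Newton polish on a
logit-transformed scale, which enforces bounds smoothly; fits are
deterministic given their seed. Pre-exposure fits fix the surfactant
fractions at zero (the film contains none yet); post-exposure fits free
them. Parameter uncertainties come from an affine-invariant ensemble MCMC
(stretch move) around the optimum with a Gaussian likelihood and uniform
priors within the bounds; the sampler is validated against an analytic
Gaussian posterior in the tests, and a warning is attached when the
acceptance fraction leaves $[0.1, 0.9]$.

The staged study (`run_nr_study`) mirrors the experimental sequence: the
bare block is characterised first (oxide thickness and roughnesses), the
oxide is then fixed while the two pellicle layers are refined, and the
treated film is refined last, seeded by the pre-treatment structure.

Degenerate inputs are handled structurally: zero-thickness layers drop out
of the stack, a solvent SLD equal to the substrate's produces no
reflectivity, and negative thicknesses are rejected.

# QCM-D

A single Voigt film (complex shear modulus $\mu + i\omega\eta$, density
fixed at 1.08 g/cm$^3$ for pellicles) loaded by a semi-infinite Newtonian
liquid is evaluated through the small-load approximation with the exact
transmission-line load impedance, relative to the bare crystal in the same
liquid, so a zero-thickness film gives exactly zero shift. In the rigid
thin limit this reduces to the Sauerbrey relation
$\Delta f_n = -2 n f_0^2 \rho h / Z_q$ within 1%, which the tests assert.
$\eta$ and $\mu$ are frequency-independent (the simplest Voigt variant,
standard in commercial fitting software). Bulk properties default to water
at 25 °C.

Fits run per time point across all overtones' $(\Delta f, \Delta D)$ with
five seeded starts to avoid the known $\eta$–$\mu$ degeneracy (ties broken
toward the thinner film); wet areal mass is $\rho h$. Traces are decimated
so at most a configurable number of points is fitted; plateau windows (the
final tenth of each flow step by default) are always fitted. The on-disk
CSV convention is overtone-normalised $\Delta f / n$; internal models use
raw shifts, and the readers/writers convert explicitly. The retention
ratio is defined as mass after / mass before — the fraction of the film
remaining — which keeps "complete removal" at 0 and "no effect" at 1.

# Ellipsometry

The forward model is the standard multilayer Fresnel computation for
ambient/film/SiO$_2$/Si at 442.9 nm; $\Psi = \arctan|\rho|$ and
$\Delta = \arg\rho$ with $\rho = r_p/r_s$. The angle of incidence is not
fixed by the analysed data and defaults to 68°; the adsorbed amount passes
through $(n_f, d_f)$, so the downstream mass is insensitive to this choice
once the inversion is self-consistent. Substrate constants default to
Si $\tilde n = 4.62 - 0.14i$ and SiO$_2$ $n = 1.466$, both overridable
per wafer. Inversion of $(\Psi, \Delta)$ to $(n_f, d_f)$ is a coarse grid
scan plus Nelder–Mead polish; solutions with large residual or vanishing
thickness are flagged ambiguous (the classic thin-film compensation
ambiguity). The dry mass follows de Feijter's equation
$\Gamma = (n_f - n_o)\,d_f/(dn/dc)$ with $dn/dc = 0.18$ ml/g; with $d_f$
in nm this is numerically in mg/m², and $\Gamma$ depends only on the
product $(n_f - n_o)\,d_f$ — an invariance the tests exercise, and the
reason the mass is far better determined than $n_f$ or $d_f$ separately.

# Force spectroscopy

The per-ramp pipeline follows the experimental processing order:

1. **Calibration.** The detector sensitivity is the inverse slope of the
   maximal-$R^2$ linear segment (at least 20% of samples, $R^2 \ge 0.99$)
   of a ramp on a rigid reference surface.
2. **Contact point.** The contact region is fitted with the sphere–plane
   Hertz law $F = F_c + B\,\delta^{3/2}$; the window is data above five
   times the noise floor, iterated once after the first estimate, and the
   first pass is restricted to the high-force end where the contact term
   dominates. The constant offset $F_c$ is profiled out linearly; it
   absorbs the steric force still acting at contact, which would otherwise
   bias $z_0$. The probe radius is not separated from the modulus: $B$ is
   reported as-is.
3. **Conversion.** Deflection (signal × sensitivity) is scaled by the
   spring constant (an input; nominally 0.1 N/m) to force, and the
   tip–sample distance is $d_{ts} = (z_0 - z_{piezo}) + \delta_{defl}$ with
   deflection positive for repulsive bending — the convention under which
   $d_{ts} \ge 0$ off contact and $d_{ts} \approx 0$ against a hard wall.
4. **Steric fit.** $F = F_0\,e^{-d_{ts}/\lambda_{exp}}$ over
   $d_{ts} > 5$ nm, log-linear initialisation then Levenberg–Marquardt.
   Ramps without a positive-force tail (e.g. on stiff aggregate domains)
   are flagged and excluded, and the exclusion count is reported.

Force-volume grids aggregate accepted $\lambda_{exp}$ into a
Freedman–Diaconis histogram with a Gaussian KDE overlay; the central value
is the median (robust against the skewed tail of per-ramp fits), spread is
the IQR, and condition comparisons report the ratio of medians with a
seeded bootstrap 95% interval. The ratio is exactly antisymmetric:
swapping conditions inverts it.

# Synthetic data: what it emulates, and what it does not

* **Reflectivity**: smeared model curves with multiplicative Gaussian noise
  (default 2% relative — typical time-of-flight statistics) and a constant
  background floor ($10^{-7}$); the uncertainty column is the generating
  sigma.
* **QCM-D**: stepwise schedules (baseline, saliva, rinse, surfactant,
  rinse) with single-exponential relaxation toward each step's target wet
  mass ($\tau = 300$ s); adsorption kinetics are deliberately not
  mechanistic. Instrument noise defaults to 0.2 Hz on raw $\Delta f$ and
  $0.05 \times 10^{-6}$ on $\Delta D$.
* **Force volume**: per ramp, the generative force law (exponential tail,
  continuous into an offset Hertz contact) is inverted through the
  cantilever model to piezo/detector coordinates with 0.05 nm-equivalent
  detector noise and 2 nm contact-position jitter emulating surface tilt
  across the scan; a hard-wall reference ramp accompanies each grid.
  An optional fraction of stiff, tail-free "aggregate" ramps emulates the
  sparse surfactant-aggregate domains seen on treated films.
* **Ellipsometry**: Gaussian noise on $(n_f, d_f)$ series (or on
  $(\Psi, \Delta)$ in raw mode).

The scenario truths are the published two-layer fits: the amphoteric
surfactant (CAPB) collapses the outer layer roughly three-fold
(325 Å → 117 Å) while barely touching the inner layer; the nonionic
surfactant (C$_{12}$E$_5$) leaves the outer layer within error and raises
inner hydration by ~8 points; the anionic reference (SDS) removes the film
essentially completely. Wet-mass steps give retentions near 0.85
(C$_{12}$E$_5$), 0.6 (CAPB) and ~0 (SDS), with dry (ellipsometric) removal
smaller than wet removal — the coupled-solvent signature.

What the generators do **not** emulate: instrument drift and crosstalk,
multiplicative gain errors, mechanistic adsorption (RSA/DLVO), pellicle-to-
pellicle biological variability (real films differ enough that co-refining
across films fails), multi-modal SLD profiles, or power-law rheology.
Passing recovery tests therefore demonstrates the correctness and
calibration of the analysis chain under the assumed noise structure, not
robustness to every artefact of real instruments.

# Numerical choices

* Transfer-matrix phases use the decaying-exponent convention, identical to
  Parratt for complex wavevectors; total reflection is exact below the
  critical edge.
* Smearing quadrature: 17 nodes over ±3.5σ of the Gaussian kernel.
* Differential evolution: rand/1/bin, population ≈ 4–5 per free parameter,
  reflection at bounds; the polish is `nlminb` on the logit scale.
* MCMC: stretch move with $a = 2$; walkers ≥ $2d + 2$; intervals are half
  the 16th–84th percentile range.
* Voigt fits run on $\log_{10}$ parameters inside generous physical bounds
  (thickness 0.1 nm–1 µm, viscosity 0.5–50 mPa·s, modulus $10^2$–$10^9$ Pa).
* Ellipsometric inversion grid: 25 × 61 over the configured bounds before
  the local polish.
* Hertz contact search: closed-form linear profile over $(F_c, B)$ with a
  0.5 nm-stepped scan then a bracketed 1-D optimisation of $z_0$.

## Problem sizes

The shipped tests and the demonstration (`run_demo`) use problem sizes
chosen to keep a full run comfortable on a single core while leaving every
recovery well determined: reflectivity grids of 70 points per contrast
(the full measured range 0.01–0.3 Å$^{-1}$), demonstration force-volume
grids of 24 × 24 ramps (the full 64 × 64 grids are exercised in the
acceptance checks), decimated QCM-D plateau fits, and short MCMC chains
for the demonstration tables. The demonstration asserts its tolerance
checks and reports any breach.

# Known limitations

* Single Voigt layer only; no multi-layer viscoelastic stacks or $n = 1$
  data.
* The NR model fits a fixed two-layer pellicle; freeform profiles are out
  of scope.
* No incoherent scattering or absorption corrections in SLDs.
* The ellipsometric model is single-wavelength and isotropic.
* MCMC intervals assume the Gaussian likelihood implied by the reported
  per-point uncertainties; they are credible intervals around the fitted
  optimum, not a full exploration of multi-modal ambiguities (e.g. the
  thickness–hydration trade-off at very high hydration, which the contrast
  series is designed to break).
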