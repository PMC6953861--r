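---
title: "Modelling electron-transfer vibronic spectra of odorants"
author: "vibronic package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling electron-transfer vibronic spectra of odorants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibronic)
```

## The model

The vibration theory of olfaction pictures odorant recognition as an
inelastic electron-transfer (ET) event: an electron hops from a donor site
onto the odorant molecule (turning it into a transient anion — or, in the
hole-transfer variant, a cation) and off again to an acceptor, and the
energy it sheds excites the odorant's vibrations.  In this
donor–bridge–acceptor picture the odorant's contribution is entirely
intramolecular, so the quantities that matter can be computed for the
isolated molecule in its two electronic states.

Each electronic state is treated as a harmonic surface: an equilibrium
geometry $x^{(0)}$, harmonic wavenumbers $\omega_j$, and a mass-weighted
normal-mode matrix $L$ with orthonormal columns ($n_v = 3n-6$ modes, or
$3n-5$ for linear molecules).  The geometry change between the two minima,
projected onto the modes of one state,

$$\Delta Q = L^\top M^{1/2}\,\bigl(x'^{(0)} - x^{(0)}\bigr),$$

gives one displacement per mode (units $\mathrm{amu}^{1/2}\,\mathrm{\AA}$),
and from it the Huang–Rhys factor and per-mode reorganization energy

$$\bar S_j = \frac{\omega_j \Delta Q_j^2}{2\hbar}, \qquad
  \lambda_j = \hbar\omega_j \bar S_j ,$$

with $\omega_j$ the angular frequency $2\pi c\,\tilde\omega_j$.  Summing
$\lambda_j$ over the modes of each basis gives the two relaxation energies
$\lambda_N$ and $\lambda_C$ whose sum is the intramolecular reorganization
energy $\lambda_i$; on exactly harmonic surfaces the mode sums coincide
with the adiabatic four-point energies
$\lambda_N = E_N(\mathrm{rel}) - E_N$, $\lambda_C = E_C(\mathrm{rel}) - E_C$,
and the test suite checks this identity to $10^{-10}$ on synthetic
quadratic pairs.

Line intensities come from Franck–Condon factors of the displaced
harmonic oscillator.  The general closed form uses generalized Laguerre
polynomials,

$$\mathrm{FCF}(\mu,\upsilon) = e^{-\bar S}\,\bar S^{\,\upsilon-\mu}\,
  \frac{\mu!}{\upsilon!}\,\bigl[L_\mu^{(\upsilon-\mu)}(\bar S)\bigr]^2,
  \qquad \upsilon \ge \mu,$$

which for transitions out of the vibrational ground state reduces to the
Poisson distribution $e^{-\bar S}\bar S^{\upsilon}/\upsilon!$.  Only
$\mu = 0$ progressions feed the spectra (a zero-temperature treatment);
finite-$\mu$ factors exist for testing and exploration.  Duschinsky
mixing between the two states' modes, $Q' = JQ + \Delta Q$ with
$J = (L')^\top L$, is computed and reported as a diagnostic but
deliberately neglected inside the Franck–Condon factors ($J = I$), which
is what makes the independent-mode product form above exact within the
model.

A spectrum is then a set of sticks — for each mode, lines at
$E_0 + \upsilon\,\tilde\omega_j$ weighted by the Poisson factors, plus one
0–0 line at $E_0$ weighted by $\prod_j e^{-\bar S_j}$ — convolved with a
unit-area Gaussian.  The ET **absorption** spectrum uses the neutral
state's $(\omega, \bar S)$ table, the **emission** spectrum the charged
state's: emission accompanies the charged-to-neutral relaxation, so its
bands sit at the charged-state frequencies.  For HCN this reproduces the
characteristic pair of band maxima — emission near 1704 cm⁻¹, absorption
near 2149 cm⁻¹, the emission band left-shifted — and the estimate that
the transition excites two phonons, since both stretch couplings
($\bar S = 1.978$ and $1.594$) round to 2 and the single-channel
activation energy $E_A = \hbar\omega(\upsilon - \bar S)^2/(4\bar S)$
vanishes at $\upsilon = \bar S$.

## Parameters that matter

* **Gaussian width `sigma` (default 100 cm⁻¹).**  Chosen to emulate the
  ~400 cm⁻¹ bandwidth attributed to biological tunneling-spectroscopy
  detection; two sticks closer than about $2\sigma$ merge into one band.
* **Ladder depth `upsilon_max` (default 10).**  Poisson weights beyond
  $\upsilon \approx \bar S + 5\sqrt{\bar S}$ are negligible for the
  couplings seen in small odorants ($\bar S \lesssim 2$); the HCN band
  positions are insensitive to any value from 1 to 10.
* **Stick mode.**  `"progression"` renders the full single-mode Poisson
  ladders; `"fundamentals"` keeps only the $\upsilon = 1$ line of each
  mode.  Both place the HCN band maxima identically; the progression mode
  additionally shows overtone shoulders (e.g. 3408 cm⁻¹ for the HCN
  anion).
* **Origin `e0` (default 0).**  Spectra are plotted against vibrational
  wavenumber relative to the 0–0 line; a nonzero electronic origin can be
  supplied when absolute transition energies are wanted.
* **Grid (default 0–4000 cm⁻¹, 1 cm⁻¹ step).**  Covers the fundamental
  region of organic molecules; the step is far below `sigma`, so
  discretization error is negligible (a warning fires if the step exceeds
  `sigma`).
* **Overlap window and peak-match tolerance.**  Band comparison uses the
  overlapping coefficient $\int_W \min(\hat a, \hat b)$ of window-area-
  normalized curves — a bounded, scale-free fraction, with whole-grid
  cosine similarity as a second opinion.  Peak matching uses a 250 cm⁻¹
  tolerance, about half the detection bandwidth above.

## Numerical choices

Internal units are amu, Å, cm⁻¹ and eV, with every conversion routed
through `physical_constants()`.  Both $\hbar$ and the cm⁻¹→eV factor are
derived from the same exact SI Planck constant at full double precision,
so the two expressions for $\lambda_j$ (via $\bar S$ and via $hc/e$)
agree to machine epsilon — this is what lets the harmonic partition
identity close to $10^{-10}$ rather than to the rounding level of
published constants.

Frame alignment is the mass-weighted Kabsch superposition (proper
rotations only; a fit that wants a reflection is rejected as a
stereochemistry mismatch).  This realizes the Eckart conditions, which
resolve the frame ambiguity the projection formulas leave open; whether
reference data were aligned the same way is generally unknowable, so this
is a documented package choice.  After projection, any component of the
mass-weighted displacement outside the span of the (rectilinear) mode
matrix is measured and a warning fires above 1% — it is reported, never
silently dropped.  Rectilinear modes are a stated deviation from
curvilinear-coordinate treatments; for the small displacements of
harmonic fixtures the two coincide, for strongly bent large-amplitude
motions they need not.

Franck–Condon evaluation uses three-term recurrences for the generalized
Laguerre polynomials and log-gamma factorial ratios, so quantum numbers
beyond 20 neither overflow nor lose the leading digits.  For
$\upsilon < \mu$ the symmetry $\mathrm{FCF}(\mu,\upsilon) =
\mathrm{FCF}(\upsilon,\mu)$ is applied before the closed form (whose
printed form assumes $\upsilon \ge \mu$).  The independent check is a
quadrature oracle: Hermite-function wavefunctions, one displaced by
$d = \sqrt{2\bar S}$, integrated by trapezoid rule over $\pm(12+d)$ with
4001 points; closed form and oracle agree to $10^{-8}$ over
$\bar S \le 3$, $\mu \le 3$, $\upsilon \le 8$.  Phonon estimates round
half away from zero, so couplings of 1.978 and 1.594 both give two
phonons.  Mode tables sort ascending in frequency, ties stable.

Degenerate bends of linear molecules are stored as the two distinct
rows the input provides (never merged); published tables that print a
single bend row are represented as given.  Published $\lambda$ values are
consistency-checked against $\hbar\omega\bar S$ at half a unit of the
last printed digit and flagged — not overwritten — on mismatch; the known
HCN anionic C–H row (printed 0.013 eV, recomputed 0.0124 eV) is the
motivating example.

## Synthetic fixtures: what they emulate and what they do not

`make_displaced_diatomic()` builds two harmonic states sharing one
stretch mode with bond lengths differing by $\Delta r$; the exact
coupling $\bar S = \omega\,\mu\,\Delta r^2/(2\hbar)$ travels with the
fixture.  `make_random_polyatomic()` draws a seeded random geometry,
constructs an orthonormal mode basis spanning exactly the
translation/rotation complement, and displaces the second state along the
modes so the pipeline must recover prescribed per-mode couplings to
$10^{-8}$ — couplings up to $\bar S = 2$, frequencies in 300–3500 cm⁻¹,
the range typical of odorant fundamentals.  The packaged HCN-like JSON
state models are likewise synthetic (geometry and modes constructed
in-package, labelled `synthetic`); only the packaged TSV tables carry the
published HCN numbers.

These fixtures are exactly harmonic, share frequencies between states,
and have mode matrices identical up to construction — so passing tests
demonstrate the projection algebra, unit handling and spectral synthesis,
not the anharmonicity, Duschinsky mixing or frequency shifts of real
molecules' DFT surfaces.  The isotopologue tables in
`synthetic_isotopologue_tables()` are constructed to show the reported
qualitative pattern (a ketone pair whose bands all match within
250 cm⁻¹ versus a perdeuterated macrocycle whose strong C–H stretch band
moves by the full $1/\sqrt2$ factor); they are stand-ins, not published
supplementary data, and the comparison checks built on them are
qualitative by design.

## Worked example

```{r hcn}
t1 <- table1_hcn()
t1$neutral

em <- emission_spectrum(t1$anionic)
ab <- absorption_spectrum(t1$neutral)
c(emission = em$grid[which.max(em$values)],
  absorption = ab$grid[which.max(ab$values)])

phonon_estimate(c(1.978, 1.594))
activation_energy(2149, 1.978, upsilon = 2)   # near-activationless
```

```{r plot, fig.width = 6, fig.height = 4}
plot(ab$grid, ab$values, type = "l", col = "firebrick",
     xlab = expression(tilde(nu)~(cm^-1)), ylab = "intensity")
lines(em$grid, em$values, col = "navy")
legend("topright", c("absorption (neutral basis)", "emission (charged basis)"),
       col = c("firebrick", "navy"), lty = 1, bty = "n")
```

The full pipeline from state models runs through `vibronic_model()`:

```{r model}
fx <- make_displaced_diatomic(1.00783, 14.003, 2000, 0.25)
vm <- vibronic_model(fx$neutral, fx$charged)
summary(vm)
```

## Known limitations

* Duschinsky mixing is diagnostic-only; spectra assume independent
  single-mode progressions, and cross-mode combination lines (quanta in
  two modes simultaneously) are not generated.
* Rectilinear normal modes; no curvilinear-coordinate or anharmonic
  corrections.
* No quantum chemistry: geometries, frequencies and modes are inputs
  (the JSON state-model schema is the interchange point for frequency
  calculations parsed elsewhere).
* No absolute ET rates: electronic couplings, outer-sphere
  reorganization and driving force are outside the model, as is any
  claim that spectral overlap equals perceptual similarity — the
  comparison module reports geometry-free spectral metrics only.
* IETS intensities use the simplest point-charge form
  $I_j = \sum_i q_i^2 \Delta x_{i,j}^2$ with user-supplied partial
  charges.
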