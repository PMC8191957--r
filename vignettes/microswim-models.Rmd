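---
title: "Biophysical models behind microswim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biophysical models behind microswim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microswim)
```

`microswim` turns tabulated observations of swimming microorganisms — body
size, appendage geometry, beat frequencies, swimming speed — into the
dynamic quantities that low-Reynolds-number hydrodynamics says must connect
them: motor torques for flagellated prokaryotes, predicted speeds for
flagellates and spermatozoa, and per-cilium forces, surface stresses and
effective slip velocities for ciliates. This vignette records the models,
the conventions, and the numerical and design choices, in enough detail
that every number the package produces can be traced back to a formula and
a unit convention.

## Regime and units

A cell of length $B$ swimming at speed $U$ in water has a steady Reynolds
number $\mathrm{Re} = \rho U B / \eta \ll 1$; its beating appendage of
length $\ell$ and angular rate $\omega$ has an oscillatory counterpart
$\mathrm{Re}_\omega = \rho \omega \ell^2/\eta$. Both are small for
essentially all unicellular swimmers, so all models below live in the
inertialess Stokes regime.

The working units are those of the source tables: lengths in µm, speeds in
µm s⁻¹, frequencies in cycles s⁻¹, viscosity in mPa s, stresses in mPa,
forces in pN and torques in pN nm. Two happy coincidences keep conversion
factors out of sight: µm s⁻¹ × mPa s × µm² = 1 pN nm exactly (the torque
estimator needs no constant), and 1 pN µm⁻² = 1 Pa = 10³ mPa (the factor
1000 in the force-per-cilium model). Everything else converts to SI
internally. The default medium is water at 25 °C, $\rho = 997$ kg m⁻³ and
$\eta = 0.89$ mPa s; these particular values were fixed by requiring that
the package reproduce the published Reynolds-number table and torque
estimates exactly, and the test suite documents that this single pair does
reproduce all of them at printed precision.

Frequencies deserve a warning: record tables store cycles per second, and
every model converts explicitly via $\omega = 2\pi f$. Published
Reynolds-number tables print the angular rate, which is why an *E. coli*
record with $f = 131$ appears there as $\omega = 823.1$.

## The value notation and the collapse policy

Printed cells look like `24.1 ± 10 (14.2 − 60)`, `(2 − 7)` or `max 35`.
`parse_quantity()` maps each cell onto a typed `quantity` (point, sd,
range, bound flag) with no unit conversion, and `format_quantity()` inverts
it; footnote daggers and stars are stripped but preserved. Models need one
number per cell, and the sources never state which value inside a printed
range they used, so the choice is made explicit: `collapse_policy()`
defaults to *mean if printed, else midpoint of the range, else the upper
bound* (flagged as bound-only). The midpoint convention is not arbitrary:
collapsing the flagellate ranges by midpoint is the only simple rule that
reproduces the published Reynolds numbers for *Giardia lamblia* at printed
precision, which is as close to a confirmation of the upstream convention
as the tables allow. Every estimate records which rule fired for which
field.

## Flagellated prokaryotes: resistive-force theory

A rigid helix (contour length $L$, pitch $\lambda$, radius $h$, filament
radius $b$, pitch angle $\theta = \arctan 2\pi h/\lambda$) rotating at rate
$\omega$ relative to the cell experiences axial force and torque linear in
$(U, \Omega + \omega)$ with resistance coefficients

$$f_{11} = (c_\parallel \cos^2\theta + c_\perp \sin^2\theta) L, \quad
f_{12} = (c_\perp - c_\parallel)\sin\theta\cos\theta\, h L, \quad
f_{22} = (c_\perp \cos^2\theta + c_\parallel \sin^2\theta) h^2 L,$$

with the slender-filament drag coefficients
$c_\perp = 4\pi\eta/(\log(L/b) + \tfrac12)$ and
$c_\parallel = 2\pi\eta/(\log(L/b) - \tfrac12)$. The prolate body
contributes $b_{11} = 3\pi\eta B\, C_{FB}$ (translation) and $b_{22}$
(axial rotation). Force and torque balance gives a 2×2 linear system
(`solve_swimming()`); the motor torque is
$T_m = f_{12} U + f_{22}(\Omega + \omega)$, and the ratio

$$\frac{U}{T_m} = \frac{f_{12}}{f_{12}^2 - f_{22}(b_{11} + f_{11})}$$

is independent of $b_{22}$ — convenient, because the body's rotational drag
is the one coefficient the data never constrain. The package still needs a
$b_{22}$ for the full solver and uses the standard prolate-spheroid closed
form (with the $8\pi\eta R^3$ sphere limit), but no reported quantity
depends on it.

The coupling ratio $f_{12}^2/(f_{11} f_{22})$ is maximised at
$\theta = \pi/4$ where it equals $((1-\gamma)/(1+\gamma))^2$ with
$\gamma = c_\parallel/c_\perp$; at the customary $\gamma = 1/2$ the bound
is $1/9$. Dropping the $f_{12}^2$ term therefore changes $|U/T_m|$ by at
most a factor $1/(1 - 1/9) = 1.125$ — note the direction: the simplified
expression *under*-estimates the exact magnitude, by up to 12.5%. With
$\theta$ fixed at $\pi/4$ the whole relation collapses to

$$U = \frac{T_m}{\eta\, \xi^2}, \qquad
\xi^2 = 9\pi h\left(B\, C_{FB}(W/B) + \frac{L}{\log(L/b) + \tfrac12}\right),$$

which `estimate_motor_torque()` inverts per record. The $+\tfrac12$ offset
follows from writing the tangential coefficient as $c_\perp/2$; deriving
through $c_\parallel$ directly would give $-\tfrac12$, and that variant is
exposed (`morphological_factor(..., variant = "parallel")`) but is not the
default, because the $+\tfrac12$ form is what reproduces the published
torque values. The filament radius defaults to $b = 0.01$ µm (2b = 0.02
µm); since $b$ enters only logarithmically, a bundle of several filaments
changes the estimate marginally. Multi-flagellated cells are treated as
one effective helix — during a run the filaments bundle and rotate
together — so the flagella count never enters this model. Records missing
any of $B, W, L, h, U$ are skipped with a structured reason rather than
imputed: the corresponding published plot includes only complete species.

Sign conventions: solved exactly as the balance equations dictate, $U$ and
$T_m$ come out negative for positive $\omega$ (the thrust points along
$-x$ for the chosen handedness). `solve_swimming()` returns the signed
solution so that balance residuals can be checked to machine precision;
the record-level estimators report magnitudes, which is what the published
figures show.

## Flagellated eukaryotes and spermatozoa: planar travelling waves

The beat is idealised as a single plane sine wave
$y = h \sin(2\pi(x + ct)/\lambda)$ with wave speed $c = \lambda f$ and
dimensionless amplitude $a = 2\pi h/\lambda$. Period-averaging the local
resistive forces gives three integrals: the arc length per wavelength
$\Lambda(a)$, and the thrust/drag integrals $I_1(a)$, $I_2(a)$. The
package evaluates all three by adaptive quadrature (`wave_integrals()`,
relative tolerance $10^{-10}$); the test suite checks them against
independent oracles — the elementary closed forms
$I_1 = 1 - (1+a^2)^{-1/2}$, $I_2 = 2 - (1+a^2)^{-1/2}$, and the complete
elliptic integral form of $\Lambda$ — to $10^{-8}$.

Arc-length conservation fixes the wave count
$n_w = L/(\lambda\,\Lambda(a))$, which is also the imputation engine: when
exactly one of $\lambda, h, n_w$ is missing, `impute_wave_parameter()`
solves this relation for it by bracketed root finding ($\Lambda$ is
strictly increasing, so the physical branch is unique). The solvability
conditions are sharp and tested: a missing amplitude requires
$L/(n_w \lambda) \ge 1$, a missing wavelength requires $L/n_w > 4h$ (the
slender-wave arc-length floor).

Balancing $N$ flagella against the body drag gives the speed

$$\frac{U}{\lambda f} =
\frac{I_1}{I_2 + \dfrac{3 B\, C_{FB}\, \Lambda\, (\log(L/b) - \tfrac12)}{2 N L}},$$

the package's `mode = "exact"`. The widely quoted closed form (`mode =
"approx"`) replaces the integrals by $\Lambda \approx \sqrt{1 + a^2/2}$,
$I_1 \approx (a^2/2)/(1+a^2/2)$, $I_2 \approx (1+a^2)/(1+a^2/2)$, and is
implemented exactly as printed. Tracing the derivation shows the printed
form also silently drops the $\Lambda$ factor from the body-load term, so
the two modes are not algebraically identical even within the
approximation budget; `mode = "exact"` is the reference and the
discrepancy is bounded and tested ($U_{approx}/U_{exact} \in
[1,\ 1.208\,\Lambda(a)]$).

On the accuracy of the closed forms themselves: the often-quoted figure is
13% for all $h/\lambda < 1$. Direct quadrature shows this holds for
$\Lambda$ (worst 8.7%) and $I_2$ (8.0%), both maximal at $a = 2\pi$, and
for the speed-relevant ratio $I_1/I_2$, whose worst error is exactly $1/8
= 12.5\%$ at $a = \sqrt3$. It does **not** hold for $I_1$ alone: its error
curve is non-monotone, peaking at 20.7% near $a \approx 2.2$ (i.e.
$h/\lambda \approx 0.35$, squarely in the physiological range) before
falling back to 12.9% at $a = 2\pi$. The package documents this honestly
rather than adjusting either the claim or the scan: the acceptance check
of the 13% figure is expected to fail, and the 12.5% ratio bound is the
defensible form of the statement.

Group conventions for missing data follow the source compilations: body
width from the group-average aspect ratio ($W/B = 0.60$ for flagellates,
$0.47$ for spermatozoa), flagellum radius fixed at $b = 0.2$ µm for both
groups, and $N = 1$ always for spermatozoa. Amplitudes beyond
$h/\lambda = 1$ are capped at $a = 2\pi$ with a warning, since the
approximations are unvalidated out there. Hydrodynamic interactions
between flagella are neglected (thrusts add linearly in $N$). Helical
(three-dimensional) beats, mastigoneme-bearing flagella and the two-wave
kinematics of some insect sperm are outside the model; for such species
the prediction is best read as a lower bound on the observed speed.

## Ciliates: three coarse-grained propulsion models

The cell is a prolate spheroid with polar radius
$r(\theta) = (W/2)/\sqrt{1 - e^2\cos^2\theta}$, surface area
$S = (\pi W^2/2)\,[1 + \arcsin(e)/(e\sqrt{1-e^2})]$ and the tangential
geometric moment $I_t = 2\pi \int_0^\pi [(r\sin\theta)^2 - r r'
\sin\theta\cos\theta]\, d\theta$ (evaluated by adaptive quadrature;
$I_t = \pi^2 R^2$ for a sphere). Cilia are assumed uniformly distributed
over the surface — no bald poles, no oral-groove structure.

* **Model A (constant tangential stress):**
  $U_\tau = \tau I_t / (3\pi\eta B\, C_{FB})$.
* **Model B (constant force per cilium):**
  $U_F = F N I_t / (3\pi\eta B S\, C_{FB})$, with the count $N$ resolved
  from whichever of $N$, areal density $\kappa$ ($N = \kappa S$) or
  spacing $d$ ($\kappa \approx 1/d^2$) the record carries, in that
  precedence; when both $N$ and $\kappa$ are present they are
  cross-checked and a disagreement beyond 50% warns. Models A and B are
  algebraically identical under $\tau = F N / S$, which the tests assert
  exactly.
* **Model C (squirmer with near-uniform surface slip):** the Lorentz
  reciprocal theorem turns any axisymmetric tangential surface velocity
  $u_s(\zeta)$, $\zeta = \cos\theta$, into a swimming speed
  $U_s = (\tau_0/2)\int_{-1}^{1} \sqrt{(1-\zeta^2)/(\tau_0^2-\zeta^2)}\,
  u_s(\zeta)\, d\zeta$ with $\tau_0 = 1/e$. For the canonical near-uniform
  profile the integral has the closed form
  $U_s = (\hat u_s/e^2)\,[1 - ((1-e^2)/e)\tanh^{-1} e]$, rising from
  $\tfrac23 \hat u_s$ (sphere) to $\hat u_s$ (needle). One orientation
  convention matters: substituting the literature's profile into the
  reciprocal-theorem integral literally yields the negative of the printed
  closed form, so the package defines $u_s > 0$ as *rearward* surface
  flow, making forward swimming positive and the quadrature and closed
  form agree to $10^{-8}$.

Each model inverts per record for $\tau$, $F$ or $\hat u_s$ given the
observed speed, with full imputation provenance, and `run_estimation()`
reports the cohort min/max envelope — the shaded-band numbers of published
speed-versus-geometry plots. Per-species reproduction of published force
tables is deliberately not claimed: those numbers depend on which value
inside each printed range the original analysis used, which is not stated;
with the midpoint policy the package lands within a factor of ~1.1–2 (the
*Tetrahymena pyriformis* force comes out 0.31 pN against a published
0.35 pN), and the tests assert order-of-magnitude agreement only.

## Synthetic cohorts and parameter recovery

`generate_cohort()` draws organism records whose body lengths and speeds
are log-normal — the published group histograms are strongly right-skewed,
"dominated by the low-values tails" — with the log-normal parameterised by
moment inversion so the configured group means and standard deviations are
matched exactly in expectation (verified at $n = 10^4$ within 3 standard
errors). Group defaults are the published per-group moments (e.g. ciliates
$\langle B\rangle = 194.87 \pm 207.45$ µm, $\langle U\rangle = 1147.57 \pm
1375.64$ µm s⁻¹). Aspect ratios are truncated normals on $(0, 1]$;
configurations whose untruncated mass on the support falls below 5% are
rejected as inconsistent. Appendage geometry (helix or wave parameters,
ciliary density) uses group-typical values chosen once: bacterial helices
around $L = 8.3$, $\lambda = 2.3$, $h = 0.3$ µm; flagellate waves around
$L = 40$, $\lambda = 24$, $h = 4$ µm at 35 Hz; sperm-like waves around
$L = 54$, $\lambda = 35$, $h = 8$ µm at 20 Hz; ciliary densities around
$\kappa = 0.5$ µm⁻². A single integer seed drives everything, with one
derived sub-stream per trait so streams do not interfere.

What the generator does *not* emulate: phylogenetic correlation between
traits (all traits are drawn independently), within-species variance
structure, measurement footnote semantics, and the long inter-group tails
of the real compilation. Passing recovery tests therefore demonstrate that
the estimators invert their own forward models under realistic magnitudes
and missingness — not that the models are faithful to any particular real
organism.

`forward_observe()` closes the loop: it fills $U$ from a chosen forward
model at a known parameter, optionally with multiplicative log-normal
noise of unit mean and given CV. At zero noise every estimator recovers
the truth to $10^{-10}$ (the inversions are exact algebra); at 20% noise
and $n = 500$ the cohort median recovers the parameter within 5% (the
log-normal's unit *mean* leaves its median at $(1 + \mathrm{cv}^2)^{-1/2}
\approx 0.981$, a visible but sub-tolerance bias that would matter at
higher noise).

## Numerical choices

* Quadrature: `stats::integrate` with relative tolerance $10^{-10}$
  everywhere ($I_t$, wave integrals, squirmer integral); deterministic, no
  randomised nodes; non-convergence is an error, never a silent fallback.
* Series switches: $C_{FB}$ uses its $e^4$ series below $e = 5\times
  10^{-3}$ (the raw expression loses ten digits to cancellation there);
  the spheroid area and the squirmer ratio switch similarly near the
  sphere; eccentricities are clamped at $1 - 10^{-12}$ so needle-like
  bodies stay finite.
* Root finding: `stats::uniroot` on analytically established brackets for
  the wave imputation; no multi-start heuristics are needed because the
  objective is monotone.
* Tie-breaks and precedence are always explicit: collapse rules
  (point → midpoint → bound), cilia-count routes ($N$ → $\kappa$ → $d$),
  and each fires into the provenance trail.

## Problem sizes and test scope

The test suite runs in well under a minute: quadrature-versus-oracle
checks on dozens of random geometries, 100-draw invariance checks for the
$b_{22}$-independence of $U/T_m$, moment checks on cohorts of $10^4$, and
recovery at $n = 500$. These sizes were chosen as the smallest at which
the statistical assertions have comfortable margins (3-standard-error
bands; median recovery at 5%), and the acceptance script's error scan uses
a 2000-point amplitude grid, dense enough to pin the worst case of a
smooth error curve to three digits.

## Known limitations

All cell bodies are spheroids; strongly non-spheroidal swimmers
(*Caulobacter*, *Stentor*, trumpet- or star-shaped cells) are approximated
crudely. Spirochaete and *Spiroplasma* body-wave mechanics have no model
here — their records parse and summarise but no estimator applies.
Metachronal coordination, power/recovery stroke asymmetry and inter-cilium
hydrodynamics are deliberately absent from models A–C, which is precisely
why their inverted parameters are *effective* quantities. And every
inverted parameter inherits the uncertainty of the collapse policy: where
a source printed only a range, a different in-range choice rescales the
estimate proportionally.
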