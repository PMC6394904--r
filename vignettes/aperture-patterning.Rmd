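---
title: "Modeling pollen aperture patterning with an activator-inhibitor system"
author: "PollenGM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pollen aperture patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PollenGM)
```

## The biological question

Arabidopsis pollen normally carries three apertures — stripes of the surface
where the exine wall is not deposited — equally spaced around the grain's
equator.  Mutants with higher ploidy and larger pollen develop four or more
apertures, ring-shaped apertures, or apertures at the poles.  PollenGM
implements a reaction–diffusion account of this patterning: a short-range
activator and a long-range inhibitor interact on the microspore surface, and
localized activator maxima ("spikes") mark future aperture positions.

## Model

The two morphogens follow the Gierer–Meinhardt equations

$$\frac{\partial A}{\partial t} = D_A \nabla^2 A - \mu_A A
  + \rho_1 \frac{(A+\rho_A)^2}{H},\qquad
  \frac{\partial H}{\partial t} = D_H \nabla^2 H - \mu_H H
  + \rho_2 A^2 + \rho_H,$$

with diffusion constants $D_A \ll D_H$, decay rates $\mu_A, \mu_H$, reaction
efficiencies $\rho_1 = \rho_2$ (equal magnitudes, different units) and small
basal production terms $\rho_A, \rho_H$.  The package defaults
(`gmParameters()`) are the wild-type parameterization:
$D_A = 1.1\,\mu m^2/s$, $D_H = 54\,\mu m^2/s$, $\mu_A = 0.21\,/s$,
$\mu_H = 0.6\,/s$, $\rho_1 = \rho_2 = 0.2$, $\rho_A = 0.003\,\mu M$,
$\rho_H = 10^{-4}\,\mu M/s$.

```{r}
p <- gmParameters()
steadyState(p)
turingCheck(p)
```

### Steady state and linear stability

The homogeneous steady state retains the basal terms: eliminating
$H = (\rho_2 A^2 + \rho_H)/\mu_H$ leaves a scalar root problem in $A$, solved
by Newton iteration from the closed form
$A^* = \rho_1\mu_H/(\rho_2\mu_A)$ that holds when $\rho_A = \rho_H = 0$.
With the defaults the full root differs from the closed form by under 1%.

`turingCheck()` evaluates the four standard two-species conditions for
diffusion-driven instability — ${\rm tr}\,J < 0$, $\det J > 0$,
$D_H f_A + D_A g_H > 0$ and $(D_H f_A + D_A g_H)^2 > 4 D_A D_H \det J$ —
at the analytic linearization ($f_A, f_H, g_A, g_H$; verified against finite
differences in the test suite).  When they hold, the unstable band of squared
wavenumbers is the pair of roots of
$D_A D_H k^4 - (D_H f_A + D_A g_H) k^2 + \det J = 0$; for the defaults this
is $k^2 \in (0.01275,\ 0.16664)\ \mu m^{-2}$, with the dispersion-rate
maximum near $k^2 \approx 0.053\,\mu m^{-2}$, i.e. a preferred wavelength of
about $27\,\mu m$.  `turingFactorInterval()` scans multiplicative scalings
of a single parameter (grid scan plus bisection to $10^{-3}$ relative
precision) for the range over which all four criteria continue to hold; the
intersection over all eight parameters is about 35%–287% of the defaults,
enclosing the reported 40%–270% robustness range.

## Domains

The sole size descriptor is the *front-view area* $a$ — the projected disc
area of an imaged grain — interpreted as $a = \pi R^2$.  Two domains are
built from it:

* `ringFromFrontArea(a, nNodes = 256)` — a periodic 1D ring of length
  $2\pi R$ (the equator), uniformly discretized.  The Laplacian is spectral
  (FFT), i.e. exact for grid-resolved modes.
* `sphereFromFrontArea(a, level = 3)` — the full microspore surface as a
  subdivided icosahedron projected to the sphere (level 3 = 642 vertices),
  carrying a cotangent-weight Laplace–Beltrami operator with lumped
  barycentric vertex areas.  A mesh was preferred over spherical-harmonic
  collocation because it gives a sparse M-matrix operator (positivity
  preserving under implicit diffusion) and a natural adjacency for the
  pattern classifier.  Sampled spherical harmonics of degree $l \le 4$
  reproduce their eigenvalues $-l(l+1)/R^2$ to within a few percent at
  level 3.

The wild-type front-view area is $550\,\mu m^2$ ($R = 13.2\,\mu m$); this
mapping puts the ring's preferred mode at $m \approx 3$, matching the
wild-type three-aperture pattern, with $350\,\mu m^2$ and $750\,\mu m^2$
(smaller and 2n-sized grains) bracketing modes 2 and 4.

## Simulation protocol

Initial conditions sit at the diffusion-free steady state with an
independent uniform random value in $\pm 5\times10^{-4}\,\mu M$ added per
node and species (`simConfig(noiseAmp = 5e-4)`); each replicate's stream is
seeded deterministically (`replicateSeed(baseSeed, condition, replicate)`).

`integrateGM()` advances the system with an IMEX Euler scheme: diffusion is
treated implicitly (exact diagonal division in Fourier space on the ring, a
cached sparse Cholesky solve of $M - \Delta t\,D\,L$ on the sphere) and the
reaction explicitly.  Two properties motivated this choice over an
off-the-shelf adaptive stiff integrator:

* the scheme's fixed point is exactly the discrete steady state
  ($D\,\nabla^2 u + R(u) = 0$), so the stopping rule can be evaluated on the
  true right-hand side and is attainable to machine accuracy;
* one factorization is reused for thousands of steps, which is what makes
  625-replicate campaigns affordable.

A run stops when $\max_i |du_i/dt|/u^*$ stays below
`steadyTol` $= 10^{-6}\,/s$ for both species over a 10 s window
(`tMax` $= 10^5$ s otherwise).  One guard supplements the rate rule: when
the parameter set admits unstable discrete modes on the domain, a
near-homogeneous field (peak-to-valley range below $0.5 A^*$) is never
declared converged — band modes growing from minute amplitudes (small
noise, or scaled kinetics with low growth rates) would otherwise satisfy
the rate tolerance transiently and freeze the run before the pattern
exists.  Pattern formation completes within
$\sim10^3$ s, but spike *positions* then drift for $\sim10^4$–$10^5$ s on
the sphere (near-neutral rotational modes).  Since the IMEX fixed point does
not depend on the step size, the solver switches from `dt` (0.25 s) to
`driftDt` (2 s) once the pattern is established (peak above $2A^*$) and all
relative rates are below `driftThreshold` ($10^{-3}/s$); in testing this
left every label unchanged while cutting run time about fourfold.  If the
accelerated step overshoots (possible for fast kinetics), the run is
retried once without acceleration.  A replicate that produces non-finite
values or a runaway activator ($> 10^6 A^*$) is reported as a diverged
(`failed`) outcome rather than an error, so campaigns never abort.

The linear regime of the solver is validated against the dispersion
relation: the measured growth rate of a seeded Fourier mode matches
`dispersionRate()` to within 5%.

## Stimuli

Transient stimuli add a spatial pattern to the *activator's initial
condition*; continuous stimuli add the same pattern as a forcing term
$F(x)$ to $dA/dt$ for the entire run.  The inhibitor is never stimulated.
Patterns: $k = 1..4$ spikes equally spaced on the equator, four spikes at
tetrahedron corners, an equatorial ring band, or a spatially uniform
offset.  Features are Gaussians in chord distance,
$a\,e^{-d^2/w^2}$.

The width $w$ deserves a note.  The printed stimulus expression has unit
length scale ($w = 1\,\mu m$), but stimuli are described as resembling the
spike patterns the model itself produces, whose measured half-maximum width
is $\approx 9\,\mu m$ (Gaussian $\sigma \approx 5.5\,\mu m$).  A
$1\,\mu m$ bump covers a fraction of one mesh cell and carries negligible
band-limited amplitude: in experiments it either had no effect or, at high
amplitude, nucleated extra spikes instead of steering the pattern.
`stimulusSpec()` therefore defaults to $w = 5\,\mu m$ (the intrinsic spike
width); `gaussianBump()` keeps $w = 1$ as its default so the printed form
remains available as a special case.

## Pattern classification

`classifyPattern()` maps a steady-state activator field onto the taxonomy
{none, $k$-spike equatorial, polar, tetrahedral, other_spikes, ring,
spike_plus_ring, elongated_tetra_edges, failed}.  All thresholds are
explicit in `classifyControl()`:

* *Contrast gate.*  A field is unpatterned unless its peak exceeds
  `contrastHigh` $\times A^*$ (1.5) **and** its peak-to-valley range
  exceeds `contrastRange` $\times A^*$ (1.0).  A peak-plus-range
  formulation is used because converged four-spike patterns on larger
  domains have valleys near $0.12 A^*$ and peaks near $2A^*$ — gates based
  on fixed valley/peak quantiles alone mislabel genuinely patterned fields
  as none, and a uniformly elevated (stimulus-forced) field must still
  count as unpatterned.
* *Components.*  Nodes above 50% of the field maximum are grouped by mesh
  adjacency.  A component covering $\ge 300^\circ$ of its best-fit great
  circle is a ring; a compact component with tangent-plane extent ratio
  $\ge 3$ is elongated.
* *Geometry.*  One ring alone → `ring`; ring + one spike →
  `spike_plus_ring`; six elongated components → `elongated_tetra_edges`;
  four spikes with all pairwise centre angles within $15^\circ$ of
  $109.47^\circ$ → `tetrahedral`; spikes coplanar with the centre (within
  $15^\circ$) → `equatorial`; two spikes $\ge 150^\circ$ apart (or a
  single spike) → `polar`; anything else → `other_spikes`.  On the ring
  domain the spike count is the number of super-threshold runs with
  periodic wraparound, which merges plateau maxima automatically.

These constants operationalize what was originally a visual classification;
the angular tolerances and extent cutoffs are design choices whose
sensitivity can be probed by passing a modified `classifyControl()`.

## Synthetic labeled fields

`makeLabeledField()` draws a noiseless or noise-perturbed static field of
any taxonomy class: Gaussian bumps/bands/ridges (geodesic distance, widths
in $\mu m$) on an $A^*$ baseline, scaled to a peak of $4A^*$ — comfortably
above the contrast gate — in a uniformly random orientation, with uniform
noise expressed as a fraction of peak height.  Elongated-edge templates are
capsule ridges (half-length half the tetra edge, width $2\,\mu m$) so their
aspect ratio clears the elongation cutoff at both domain sizes without
merging at tetrahedron vertices.  `fixtureSuite()` generates $\ge 20$
fields per class across both domain sizes; the classifier recovers 100% of
the clean suite and of a 10%-noise suite.  These fields validate the
classifier's geometry only — they do not emulate solver dynamics, spike
width variation, or amplitude profiles of real steady states.

## Campaigns and problem sizes

`domainSizeSweep()`, `oatKineticsSweep()` and `stimulusCampaign()` run
seeded replicates over condition grids and return one row per replicate
(long form, with a manifest attribute); `summarizeCampaign()` tabulates
label frequencies per condition.  The package's own validation uses the
full 1D protocol (areas 250–1450 $\mu m^2$ step 50, 25 replicates each;
the 400–700 range for the wild-type statistic) and scaled-down 3D
campaigns: 25 replicates at 550 $\mu m^2$ (level 3), two replicates per
area for the size-range scan, with level 4 above 1100 $\mu m^2$ and level 5
above 1300 $\mu m^2$ — at the largest areas coarser meshes over-count spikes
by one, and the finer mesh is required for resolution-stable counts.  Kinetics monotonicity
checks use four factors within the Turing-stable range and 7 replicates.

## Known limitations

* **Bistable boundaries.**  At sizes where two spike counts compete
  (ring 750 $\mu m^2$: 3 vs 4; sphere 550 $\mu m^2$: 3-equatorial vs
  4-tetrahedral), outcome *fractions* are a delicate property of the
  noise-to-attractor map and differ between discretizations.  This
  implementation yields roughly 60/40 (3 vs 4) on the 750 ring and
  ~35–40% 3-equatorial on the wild-type sphere; the original finite-element
  study reported mostly 4 and 72% respectively.  Individual labels near
  these boundaries also flip under mesh refinement even though the
  distributions are stable, which is why refinement stability is asserted
  per-seed on the ring but distributionally on the sphere.
* **Stimulus threshold.**  With noise $\pm5\times10^{-4}\,\mu M$, transient
  three-spike stimuli reliably lock the three-spike pattern on the larger
  sphere only for amplitudes around $10^{-3}$–$10^{-2}\,\mu M$ in this
  implementation; the reported $10^{-4}\,\mu M$ threshold was not
  reproduced (a stimulus five-fold below the nodewise noise amplitude can
  only win through its spatial coherence, which depends on the effective
  modal noise of the original solver's much finer mesh).
* The microspore is a perfect, static sphere; tetrad contacts, wall
  mechanics and domain growth are out of scope, as are saturation variants
  of the kinetics and stochastic (Langevin) dynamics.
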