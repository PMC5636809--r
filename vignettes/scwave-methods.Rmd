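---
title: "Quantifying and simulating surface contraction waves"
author: "scwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and simulating surface contraction waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scwave)
```

# Scope

Surface contraction waves (SCWs) are bands of cortical flattening that travel
pole to pole across large oocytes at cell-cycle transitions. `scwave`
implements the computational chain used to study them in starfish oocytes:

1. a **synthetic movie generator** with machine-readable ground truth,
2. **Chan--Vese level-set segmentation** of the cell outline,
3. **curvature kymographs** and a wave-strength variance statistic,
4. **wavefront and isoline tracking**,
5. a **3D contractile-shell model** (triangulated membrane, banded tension),
6. an **axisymmetric reaction-diffusion model** of the cdk1-cyclinB/APC
   gradient that guides the wavefront, and
7. **Young--Laplace** cortical tension from micropipette aspiration.

Raw experimental image data for this system is not publicly deposited, so
every claim the package tests is exercised on synthetic data whose generating
parameters are known exactly. This vignette explains the models, the defaults
and their rationale, the numerical choices, and what the tests do and do not
establish about real data.

# Synthetic movies and what they emulate

The generator (`band_movie_params()`, `render_movie()`) draws a roughly
circular cell of radius $R$ (default 85 µm, matching the visual scale of a
starfish oocyte; the true radius is user-configurable because it is not a
published constant) whose outline is flattened by a band travelling from the
vegetal to the animal pole:

$$ r(\theta) = R\,\bigl(1 - d\, g(u)\bigr), \qquad
   u = \frac{\mathrm{arc}(\theta) - v\,(t - t_0)}{w}, $$

where $d$ is the fractional depth, $g$ a half-sine bump that is 1 at the band
centre and 0 outside $|u| > 1/2$, $v$ the band speed (default 42 µm/min, the
regime reported for meiotic SCWs), and $w$ the band width (default 100 µm, the
width used by the mechanical model). The band coordinate is the arc length
from the vegetal pole measured on the undeformed circle, the same convention
the shell model uses for its tension profile, so generator and simulator are
directly comparable. Because the contraction band is a ring perpendicular to
the animal--vegetal axis, the equatorial slice shows **two mirror-image
indentations**; kymographs of such movies carry two symmetric ridges that
converge at the animal pole, and the tracking tools offer a `fold` option
that averages the two sides and reports positions as arc length from the
vegetal pole.

Two channels are rendered: a transmitted-light-like density channel (bright
interior) and a cortical fluorescence channel (thin rim, enriched by
`cortical_gain` inside the band). Both pass through an isotropic Gaussian
point-spread blur (default 1 px; no attempt at a realistic microscope PSF)
and Poisson-then-Gaussian noise. Time resolution defaults to 10 s per frame,
the acquisition rate typical for these recordings. The generator is fully
deterministic given `(params, seed)`.

What the synthetic data does **not** emulate: polar-body protrusion, organelle
texture inside the cell, illumination drift, multiple cells per field, or 3D
sectioning effects. Passing the test suite therefore demonstrates that the
pipeline recovers known waves under controlled noise, not that it is robust to
every artefact of live microscopy.

# Segmentation

`segment_frame()` minimises the Chan--Vese energy

$$ E(\phi) = \mu \oint_{\phi=0} \mathrm{d}s
  + \lambda_\mathrm{in} \int_{\phi>0} (I - c_1)^2
  + \lambda_\mathrm{out} \int_{\phi<0} (I - c_2)^2 $$

over a level-set function $\phi$, with $c_1, c_2$ the mean intensities inside
and outside. The implementation is a dense gradient descent with a normalised
force (so one step moves the interface about one pixel), energy-monotone step
control (a step that would increase the energy is halved and retried, so the
energy trace is non-increasing between re-initialisations), and periodic
re-initialisation of $\phi$ to a signed distance map via Euclidean distance
transforms. A narrow-band (sparse-field) update would compute the same
minimiser faster; the dense update was chosen for clarity since frames of
this size segment in about a second. Convergence is declared when the energy
plateaus (relative improvement below $10^{-9}$ for three consecutive
iterations).

The boundary is read off the converged $\phi$ as the zero contour with linear
interpolation across sign changes, which is what gives sub-pixel accuracy
(a noiseless disk of radius 100 px is recovered to within 0.05 px in the mean
radius; the tests assert 0.25 px). Interior holes surface as separate, much
smaller zero-contours and are ignored by taking the dominant closed contour;
genuinely ambiguous images (several comparable components) raise an error
unless a seed point disambiguates. Defaults $\lambda_\mathrm{in} =
\lambda_\mathrm{out} = 1$ and $\mu = 0.1$ on images normalised to $[0, 1]$
were fixed once against the noiseless-disk oracle. `segment_stack()`
warm-starts each frame from the previous outline.

# Outline metrics

`smooth_outline()` fits a cyclic cubic regression spline (mgcv, `bs = "cc"`)
to $r(\theta)$ — a periodic piecewise polynomial with continuous first and
second derivatives. The basis dimension `k` (default 40) is the smoothing
control; for outlines derived from coarse simulation meshes a smaller `k`
(16) is used to avoid chasing polygonal noise.

`curvature_profile()` resamples the smoothed curve at equal arc length,
computes the planar curvature
$\kappa = (x'y'' - y'x'')/(x'^2+y'^2)^{3/2}$
by central finite differences, and aggregates it into segments of roughly
2 µm. Radii $1/\kappa$ are **signed** (convex positive) and **capped** at
$r_\mathrm{max} = 5 \times$ the effective radius: near inflection points the
radius diverges, and the variance statistic below would otherwise be dominated
by a handful of near-flat segments. The cap is part of the statistic and is
recorded in the kymograph metadata. Only the in-plane curvature of the
equatorial contour is available from a single confocal slice; this is the
"first principal curvature" the readouts use.

`scw_strength()` is the wave-strength statistic: the variance of the capped
radii over all (segment, frame) cells in the wave window minus the variance in
an equal-length, non-overlapping baseline window. It is near zero (within
bootstrap noise) for static movies and grows monotonically with band depth.
`auto_windows()` offers a default window choice: a 7-minute window (the
typical wave duration) centred on the variance peak.

`deviation_kymograph()` complements the curvature kymograph with the radial
deviation from a per-location reference, after removing each frame's
isotropic (mean radius) component. For a half-sine band the deviation keeps
the half-sine shape, so the ridge's full width at half maximum times 3/2
estimates the band width directly — the curvature-radius kymograph cannot do
this because the capped radii spike narrowly where the outline flattens.
Speeds are best read from the curvature kymograph (recovered within 5% in the
tests); widths from the deviation kymograph (within 25%).

# Wavefront tools

`track_band()` detects, per time column, the dominant deviation from a
baseline window (threshold: 3 baseline standard deviations — the data do not
prescribe one) and takes the deviation-weighted centroid of the
above-half-peak neighbourhood as the band position. On curvature-radius
kymographs the capped radii spike narrowly wherever the outline is flattest
and the spike position flickers within the band, so for band tracking the
`smooth_s` option applies a running mean of about half the band width to each
column first, making the tracked peak follow the band centre; a least-squares line of
position versus time gives the speed. Frames whose position lies within half
a band width of either end of the axis are excluded from the fit to avoid
edge truncation bias. `extract_isoline()` contours a kymograph at a level
(marching squares via `grDevices::contourLines`), and
`isoline_wave_overlap()` reports the RMS offset and Pearson correlation
between an isoline and a tracked front. The isoline level that best matches a
wave is not prescribed by the data; the level is an explicit parameter.

# The contractile-shell model

The oocyte surface is a triangulated closed membrane with energy

$$ H = \oint \bigl(2\kappa_b H^2 + \sigma(l)\bigr)\,\mathrm{d}A
   + \oint \bigl(\tfrac{K_\alpha}{2}\alpha^2 + \mu\beta\bigr)\,\mathrm{d}A_0
   + \tfrac{k_V}{2}(V - V_0)^2 $$

— bending, banded surface tension, in-plane elasticity relative to the
undeformed reference mesh, and an osmotic volume-restoring term. The tension
band $\sigma(l)$ is a half-sine period of width 100 µm in the arc length $l$
along the meridional contour of the **reference** surface, measured from the
vegetal pole, so the band position is a purely kinematic control. The elastic
invariants per triangle follow the standard membrane formulation: with
principal stretches $\lambda_1, \lambda_2$ of the deformation relative to the
reference triangle, $\alpha = \lambda_1\lambda_2 - 1$ (area strain) and
$\beta = (\lambda_1 - \lambda_2)^2 / (2\lambda_1\lambda_2)$ (shear strain);
both vanish identically on the undeformed mesh, which the tests assert.

Discretisation: mean curvature by the cotangent-Laplacian formula with
barycentric vertex areas (the discrete bending energy of an icosphere at
subdivision 4 is within 0.2% of the closed form $8\pi\kappa_b$); volume by
signed tetrahedra; tension and elastic terms per face. `relax_shape()`
minimises over all vertex coordinates with L-BFGS-B; the gradient is computed
in compiled code, analytically for the volume and centroid-pin terms and by
locally recomputed central differences (step $10^{-3}$ µm) for the remaining
terms — only the faces incident to a perturbed vertex and the bending terms of
its one-ring change, which keeps the gradient at $O(N)$ cost. A soft centroid
pin removes the rigid-translation null space. After each solve the mesh is
checked with an outward-normal/star-shape test, which detects inversion or
gross self-intersection for the near-axisymmetric shapes this model produces;
it is not a general triangle–triangle intersection test.

Parameter values for the published simulations are not available in the main
text; the defaults here are the package's own calibration, fixed once:
energies are expressed in units of $\kappa_b$, and
$K_\alpha = \mu = 2.5\times10^{-3}\,\kappa_b/\text{µm}^2$,
$k_V = 2\times10^{-8}$, $\sigma_\mathrm{max} = 2\times10^{-3}$ give a
100-µm equatorial band an indentation of about 9% of the radius — the
visually observed regime — with volume held within 0.1%, the deformation
peaked near the equator, and larger deformations when the elastic moduli are
halved (the softening behaviour seen after jelly removal).

**Transient band versus step front.** Replacing the half-sine band by a step
of high tension behind the front distinguishes the two contraction scenarios.
In a quasi-static energy minimisation the distinction is **not** visible in
per-segment curvature alone: behind a step front the covered cap re-rounds
(its curvature returns towards the sphere's) even though it remains strongly
displaced inward, while in the band scenario the volume-conservation bulge
keeps radii perturbed after passage. The package therefore quantifies the
contrast with `deformation_persistence()`: the fraction of post-onset frames
during which a surface location stays indented below 30% of the series'
deepest indentation (isotropic component removed). A travelling band is
transient per location (persistence well below 1); a step front accumulates
(persistence near 1). This statistic is the package's own measure of the
published qualitative contrast.

The uniform-tension stationarity check runs at subdivision 4 (~2.5k
vertices): at coarser subdivision the projected icosphere drifts tangentially
by ~$1.5\times10^{-3}R$ towards the minimum of the *discrete* bending energy,
an artefact of the discretisation rather than a physical motion, and the
$10^{-3}R$ bound is only meaningful once the mesh is fine enough.

# The cdk1-cyclinB / APC gradient model

Starting at nuclear envelope breakdown with cdk1-cyclinB concentrated in the
nuclear region (the germinal vesicle sits against the animal cortex; default
radius 35 µm, nuclear:cytoplasmic ratio 10:1), two fields evolve with
zero-flux boundaries:

$$ \dot c = D_c \Delta c - \Bigl(k_0 + k_1 \frac{a}{J^2 + c^2}\Bigr) c
   + k_2\,\Theta\bigl(R_n^2 - |\vec x - \vec x_n|^2\bigr), \qquad
   \dot a = D_a \Delta a - k_3 a + k_4 \frac{a^2}{K^2 + a^2}\, c. $$

The degradation term is implemented literally as printed; a Michaelis-type
variant is available behind a flag for sensitivity analysis
(`degradation = "michaelis"` is *not* used anywhere by default). APC/C
activation is a slowly igniting positive feedback: the activation term is
zero at $a = 0$, so the uniform seed `APC0` must be positive, and its slow
ignition is what realises the delayed, accelerating collapse of the gradient
(no explicit time delay is used).

Numerics: the domain is an axisymmetric $(z, r)$ finite-volume grid (cell
volumes $2\pi r\,\mathrm{d}r\,\mathrm{d}z$; default 200 × 100 on the default
oocyte), exact for on-axis nuclei; diffusion is integrated implicitly with a
pre-factorised sparse Cholesky solve, which is unconditionally stable and
conserves mass to machine precision by construction; reactions use an
exponential update that is exact for frozen coefficients (a pure $k_0$ decay
matches $e^{-k_0 t}$ to machine precision) and keeps concentrations
non-negative. Halving the grid spacing moves the front arrival time by well
under 2%.

Rate constants are not published; the defaults
($D_c = 3$, $D_a = 15$ µm²/s, $k_0 = 2\times10^{-4}$, $k_1 = 3\times10^{-4}$,
$J = 0.3$, $k_2 = 2\times10^{-3}$, $k_3 = 10^{-3}$, $k_4 = 4.5\times10^{-3}$,
$K = 0.3$, all per second on the a.u. concentration scale) were calibrated
once to give gradient collapse starting about 37 min after nuclear envelope
breakdown with a vegetal-to-animal threshold sweep of ~6 min (~45 µm/min) on
the default 85-µm sphere, and then frozen. APC is taken as effectively
well-mixed ($D_a \gg D_c$; its diffusivity is not constrained by the data):
with localised APC the degradation maximum detaches from the cdk1 minimum and
the front no longer initiates at the pole opposite the nucleus, contradicting
the observed behaviour.

The threshold front (`threshold_front()`, default level 0.4 of the initial
cytoplasmic unit) initiates at the vegetal pole — the point farthest from the
nucleus — and advances monotonically to the animal pole; with two polar
boluses (emulating protein injection into the vegetal half, production off)
it initiates near the equator.

**Known limitation — geometry scaling.** Experimentally, wave speed
correlates positively with the animal--vegetal distance when oocytes are
reshaped. This implementation does not reproduce a strictly increasing
speed-distance relation across A--V scales 0.8/1.0/1.3 under any parameter
regime we probed (production-dominated, bolus-dominated, low-diffusivity
boundary-layer, spatially uniform degradation; fixed equatorial radius and
volume-preserving reshaping). The structural reason: with a fixed polar
source and global degradation, the pole-to-pole amplitude of the gradient
grows at least linearly with cell length (or decays exponentially once a
short cell equilibrates), while the sweep duration is proportional to that
amplitude over the collapse rate, so the speed (length over duration) cannot
increase with length. Reproducing the experimental scaling appears to require
a gradient whose amplitude is roughly geometry-independent while its shape
spans the cell — something this minimal reaction-diffusion system does not
provide at a single diffusivity. The corresponding test states the property
as published and is expected to fail; it is kept failing rather than
weakened, and `speed_vs_distance()` remains available for data that do scale.

# Tension

`laplace_tension()` evaluates $T_c = \Delta P / (2(1/R_p - 1/R_c))$ with
pressures in Pa and radii in µm, reporting Pa·µm and mN/m (1 Pa·µm =
$10^{-3}$ mN/m). A 60-µm pipette ($R_p = 30$ µm) at $\Delta P = 100$ Pa on a
90-µm cell gives 2.25 mN/m. `tension_ratio()` compares condition groups
(e.g. jelly-intact versus jelly-removed) with a seeded percentile bootstrap.

# Problem sizes used by the tests

The acceptance-style tests run the full pipeline on 256 × 256 px, 40-frame
movies (speed recovery), 160 × 160 px, 30-frame movies (strength statistic),
icospheres at subdivisions 2–4 (~160–2,600 vertices), and 200 × 100
finite-volume grids; these sizes keep each check to seconds or a few minutes
while leaving all qualitative behaviour intact, and every size is a plain
function argument.
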