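---
title: "Simulating annular spherical-cap arrays for patterned retinal ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating annular spherical-cap arrays for patterned retinal ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electrical retinal prostheses restore rudimentary vision but require invasive
surgery. Focused ultrasound can stimulate retinal neurons noninvasively, and a
phased array can project a whole spatial pattern of foci onto the retina at
once. A contact-lens shaped transducer is the natural wearable form factor,
but a full cap sends its energy through the crystalline lens, which absorbs
strongly. The device class this package simulates therefore uses an *annular*
("racing") aperture on a spherical cap: a ring of elements whose beams bypass
the lens on their way to the retina.

`racingarray` provides the full simulation chain for such devices:

1. **geometry** — tile a parametric annular (or full-cap) aperture into
   concrete elements on a sphere, and discretize each element into weighted
   surface quadrature points;
2. **propagation** — a discretized Rayleigh–Sommerfeld forward operator
   mapping per-element complex drives to pressures anywhere in the eye;
3. **synthesis** — the inverse problem: minimum-norm (truncated-SVD
   pseudoinverse) excitations that realize a prescribed multi-focus pressure
   pattern, with an iterative amplitude-equalizing refinement;
4. **analysis** — focal-spot metrology (FWHM), multi-focus and depth-scan
   experiments, bitmap ("CAS") patterns, aperture/pitch and safety reports.

## Model and coordinate frame

The eyeball is a sphere of radius $R = 12$ mm centred at the origin. The
array occupies a polar band around the $+z$ apex; the posterior retina sits
at $(0, 0, -12)$ mm, about 24 mm from the aperture — the adult axial eye
length. Interfaces use millimetres and Hz; internal field computation is SI.

The time-harmonic pressure radiated by the source surface $S$ is the
Rayleigh integral

$$p(Q) = \frac{j \rho c k}{2\pi} \int_S u(Q')\,
  \frac{e^{-jk\lvert Q - Q' \rvert}}{\lvert Q - Q' \rvert}\, dS ,$$

with $\rho$ the density, $c$ the sound speed, $k = 2\pi f / c$, and $u$ the
normal surface velocity of the source point (the $e^{j\omega t}$ carrier is
dropped; magnitudes and intensities are unaffected by this convention, and
the sign of the phase is used consistently by the solver). On a sphere the
surface element is $dS = R^2 \sin\phi \, d\phi \, d\theta$. Discretizing the
$N$ elements into quadrature points turns the integral into a complex
$M \times N$ matrix $H$ from element drives $U$ to pressures
$p = H U$ at $M$ observation points. The time-averaged intensity is
$I = p\,p^*/(2 \rho c)$, reported in W/cm².

No obliquity factor beyond the Rayleigh kernel is applied: element
directivity emerges from the surface quadrature itself. Absorption,
nonlinearity and scattering are out of scope — the annular design exists
precisely to avoid the one strongly absorbing structure in the path.

### Pattern synthesis

Given prescribed pressures $p$ at $M \le N$ control points, the exact-fit
solution of smallest Euclidean norm is the right pseudoinverse

$$\hat U = H^{\mathsf H} (H H^{\mathsf H})^{-1} p ,$$

computed via the SVD with relative singular-value truncation (default
$10^{-8}$; control points approaching $\lambda/2$ spacing make
$H H^{\mathsf H}$ ill-conditioned). Target pressures are equal-magnitude and
zero-phase: the literature leaves control-point phases free, and phase
optimization is deliberately out of scope.

The weighted refinement
$\hat U = W H^{\mathsf H} (H W H^{\mathsf H})^{-1} p$, $W$ positive
diagonal and initially the identity, re-distributes drive across elements
without changing the fitted pressures. The update we use scales $W$ by the
reciprocal of the normalized drive amplitudes (floored at $10^{-6}$),
renormalized to unit maximum, so **uniform element amplitudes are the fixed
point**: amplitude-limited drivers then waste no headroom. The iteration
stops when the relative change of the amplitude spread
$\max_n\lvert \hat U_n\rvert / \operatorname{mean}_n\lvert \hat U_n \rvert$
drops below `amplitude_spread_tol` (default $10^{-3}$); on non-convergence
the smallest-spread iterate is returned with a warning flag. This update is
an interpretation: the classic efficiency-improving scheme is cited in the
literature without a reproducible formula. We chose the equalizing direction
because it is the only one under which the amplitude spread is
non-increasing — the property the scheme exists to deliver — and the package
tests assert exactly that, together with exact-fit preservation at every
iterate ($\|H\hat U - p\| / \|p\| \le 10^{-8}$).

A related subtlety: "conjugating the target conjugates the drive" only holds
jointly with the kernel's phase convention. For a fixed complex $H$,
$\operatorname{conj}(\operatorname{solve}(G, p)) \ne
\operatorname{solve}(G, \operatorname{conj}(p))$; the property the tests
assert is $\hat U(\bar H, \bar p) = \overline{\hat U(H, p)}$.

## Element tiling

Published tables give, per configuration, a frequency, an element count, a
nominal element size and the aperture diameters — but not the ring layout or
kerf. The tiling algorithm is therefore the package's own choice:

* split the polar band $[\arcsin(r_{\text{in}}/R), \arcsin(r_{\text{out}}/R)]$
  into rings whose height is as close as possible to the nominal element
  height;
* allocate elements to rings proportionally to ring circumference, with
  largest-remainder rounding so counts sum exactly to $N$;
* centre each element in its ring with exactly the nominal angular extents;
  the remaining area is kerf. This reproduces the sub-unity fill factors the
  published element sizes imply (e.g. $512 \times 0.37 \times 0.50 \approx
  95$ mm² of active area in a 224 mm² band, fill $\approx 0.42$).

The nominal "w × h" element size is interpreted as azimuthal width × polar
height. That orientation makes the 256- and 512-element annular designs
consistent (about 51 elements per ring, with the ring count doubling), which
a height-first reading does not. A request that cannot fit — more elements
than a ring's circumference holds at nominal width — fails with an error
naming the limiting ring.

The full-cap comparator design does not state its curvature radius; we reuse
$R = 12$ mm since it is the same wearable form factor on the same eyeball.

## Numerical choices

* **Quadrature.** Each element is subdivided in $(\phi, \theta)$ so arc
  spacing is at most $\lambda/\texttt{samples\_per\_wavelength}$ (default 4).
  Nodes sit at angular midpoints; weights use the exact zone integral
  $R^2(\cos\phi_a - \cos\phi_b)\,\Delta\theta$ — the same
  $R^2 \sin\tilde\phi\, \Delta\phi\, \Delta\theta$ formula with the
  cell-mean $\sin\tilde\phi$ — so per-element weights sum to the element
  area to machine precision. At the default density the absolute focal
  pressure of the 512-element array still moves by ~0.7% when the sampling
  is doubled; beam *widths* are insensitive to this. Use
  `samples_per_wavelength = 8` when absolute pressures matter.
* **Media.** The sources do not state $c$ or $\rho$; defaults are a
  water-like vitreous, $c = 1500$ m/s, $\rho = 1000$ kg/m³, configurable.
  Plausible $c \in [1480, 1540]$ m/s shifts $\lambda$, and with it every
  beam width, by about ±3%.
* **Kernel guard.** Observation points within $\lambda/10$ of the source
  surface are rejected (the $1/r$ kernel is near-singular there).
* **Grids.** FWHM profiles are sampled at 0.02 mm (interpolation error well
  below other uncertainties); plane maps default to 0.05–0.1 mm spacing.
  Large grids are streamed through the compiled kernel in blocks, so $H$ is
  never materialized for field rendering; streamed evaluation equals the
  explicit $H U$ product to $10^{-12}$.
* **FWHM.** Width between the two half-maximum crossings bracketing the
  global peak, linearly interpolated between samples; a window that does not
  cross half-maximum on both sides raises a classed error rather than
  guessing.
* **Depth-scan direction.** The depth experiment prescribes seven collinear
  foci in the plane $x + y = 0$; "cross-section" width is ambiguous, so the
  profile direction is fixed to the in-plane direction perpendicular to the
  scan line, $(1, -1, 2)/\sqrt{6}$, and recorded in the report so
  alternatives are auditable.
* **Multi-focus windows.** Per-focus profiles are windowed to half the focus
  spacing so neighbouring lobes cannot contaminate a width estimate.
* **Background ratio.** Off-focus background is the peak intensity outside a
  $2\times$FWHM disc around each focus, relative to the focal peak,
  evaluated over the ±6 mm retinal patch — wide enough to contain the
  grating lobes that sparse tilings (pitch > $\lambda$) place several mm
  off-axis.

## What the experiments show — and what they cannot

Within this model the 5 MHz / 512-element annulus produces a single
posterior-retina focus with lateral intensity FWHM ≈ 0.34 mm and a clean
background; dropping to 256 elements keeps the width but roughly doubles the
background ratio; the 2.5 MHz full cap gives ≈ 1.0 mm. Multi-focus grids
(2×2, 3×3, 5×5 at 2 mm spacing) place every requested focus within one grid
cell, at per-focus widths close to the single-focus value. The 512- vs
1024-element fields agree to ~2% along the focal profile, with over 90% of
the difference energy outside the focal zone. A wavelength-pitch tiling of
the annulus at 10 MHz needs ~10⁴ elements — the quantitative form of the
argument for staying at 5 MHz and accepting >λ pitch.

Two caveats are documented rather than hidden. First, published resolution
figures for this device class (0.6 mm / 1.3 mm) are larger than the
diffraction-limited intensity widths this model yields under any profile
convention we tested; they are numerically consistent with −6 dB (amplitude
half-maximum) widths for the planar experiments, a common beamwidth
convention in ultrasound. The package reports intensity-profile FWHM, which
is what its own definitions prescribe, and the acceptance checks record the
discrepancy rather than re-defining the metric per experiment. Second, in
the seven-point depth scan the simulated width is smallest near the central
focus and grows toward both ends of the scan line — shallow points are
measured nearly along their own beam axis, deep points are simply farther
from the aperture. A monotone improvement with depth is not something
diffraction from this aperture produces along a fixed in-plane direction.

The synthetic experiments emulate the study conditions (geometry, frequency,
homogeneous water path, equal-amplitude zero-phase targets). They do not
model real vitreous/scleral attenuation, element electro-acoustic transfer
functions, crosstalk, or fabrication kerf variability — so passing tests
validate the simulation chain, not a physical device.

## Worked example

```{r, eval = FALSE}
library(racingarray)

fit <- synthesize("type_i", make_target(c(0, 0, -12)))
summary(fit)

prof <- beam_profile(fit, c(0, 0, -12), c(1, 0, 0))
fwhm(prof$s, prof$intensity)   # lateral intensity FWHM, mm

plot(fit)                      # focal-plane intensity map
ds <- depth_scan_experiment("type_i")
print(ds)
```

Command-line use mirrors the package functions
(`inst/cli/racingarray.R single-focus --preset type_i`), and
`scripts/acceptance.R` re-runs the headline experiments end-to-end, writing
the resolution figures as JSON.
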