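---
title: "Models and methods behind curvchip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind curvchip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvchip)
```

`curvchip` quantifies curvature organ-chip experiments: a clamped PDMS
membrane inflated into a spherical dome, corneal stromal cells cultured on
it, and readouts spanning geometry, mechanics, fluorescence, alignment,
colony growth and gene expression. This vignette records the models the
package implements, the parameters that matter and why their defaults are
what they are, the numerical choices, and the limitations a user should
know about.

## Dome geometry and keratometry

Side-view imaging of an inflated well yields the chord angle `phi` between
the horizontal baseline and the rim-to-apex chord. For a spherical cap the
inscribed-angle relation fixes the cap half-angle at the sphere center as
`theta = 2 phi` (equivalently `tan phi = h / a`). Everything else follows in
closed form from `(phi, a)`:

- radius of curvature `R = a / sin(theta)`,
- apex height `h = R (1 - cos(theta))`,
- cap volume `V = (pi h / 6)(3 a^2 + h^2)` (1 mm^3 = 1 uL),
- keratometric power `D = 337.5 / R` with `R` in mm.

The constant 337.5 D mm is the standard keratometric convention
`1000 (1.3375 - 1)`: corneal topographers quote the power of a single
refracting surface under the keratometric index 1.3375. The chord-angle
reading `theta = 2 phi` is the only standard interpretation under which the
three nominal chip conditions (11.79, 15 and 20.91 degrees on the 4 mm
well) land on their printed powers (33.75, 42.18 and 56.25 D); the
15-degree case is exact: `R = 4 / sin 30 = 8` mm, `D = 337.5 / 8 =
42.19` D.

```{r geometry}
do.call(rbind, lapply(c(0, 11.79, 15, 20.91), function(phi)
  as.data.frame(angle_to_geometry(phi, 4))))
```

The flat control (`phi = 0`) is a valid degenerate geometry (`R = Inf`,
`D = 0`), not an error, because the experiment uses it as the
zero-curvature reference. Angles at or above 45 degrees would take the cap
past a hemisphere and are rejected. Displayed powers are rounded to two
decimals; internal values keep full precision.

Note that the geometric cap volume of one well is not the injected syringe
volume: the chip shares a hydraulic manifold across 20 wells and has dead
volume, so injected-volume calibration curves are treated as empirical user
data, not predicted.

## Membrane inflation mechanics

The membrane is modelled as a flat incompressible hyperelastic disc of
radius `a = 4` mm and thickness `t0 = 100` um clamped at its rim and loaded
by uniform pressure — the classical axisymmetric inflation problem. In
material coordinates `r0`, with deformed radius `rho`, height `w`, meridian
slope `psi` and stretches `lam1` (meridional), `lam2 = rho / r0` (hoop),
equilibrium on the deformed surface is

- normal (Laplace): `T_m kappa_m + T_h kappa_h = p`, with
  `kappa_m = dpsi/ds`, `kappa_h = sin(psi) / rho`;
- tangential: `d(rho T_m)/dr0 = T_h d(rho)/dr0`.

Tensions come from an incompressible neo-Hookean membrane law
(`mu = E / 3`, `T_i = mu t0 (l_i / l_j - l_i^-3 l_j^-3)`), the appropriate
first choice for PDMS at these strains; a linear-elastic small-strain
option (`poisson` default 0.49, clamped at 0.4999) exists mainly for
comparison against small-deflection theory. The boundary-value problem
(regular apex; zero radial displacement at the clamp, `rho(a) = a`) is
solved by shooting on the apex stretch with `deSolve::lsodar` (relative
tolerance 1e-10, rim residual solved to 1e-13); trial integrations whose
meridian passes vertical are terminated by a root function and rejected.
`solve_for_apex_angle()` then root-finds the pressure whose apex height
matches a dome from `angle_to_geometry()`, to 1e-4 of the well radius, so
mechanical profiles correspond to measured curvature states.

Three properties serve as standing diagnostics and are enforced in the test
suite: apex stress isotropy (`sigma_m(0) = sigma_h(0)` to 1e-6, forced by
axisymmetry), a pointwise Laplace-equilibrium residual below `1e-3 p/t`
recomputed a posteriori from the returned fields (meridional curvature by
spline differentiation of `psi` along arc length), and agreement of the
small-pressure apex deflection with an independently coded small-slope
(Hencky-type) solution to 1%.

Region summaries average `sigma_m` and `sigma_h` with annulus weight
`r * dr` over center (A1), slope (A2) and edge (A3) regions; such region
bounds are typically drawn only pictorially in chip studies, so they are
configurable and default to `a/3` and `2a/3`. For all three chip
curvature levels the meridional-to-hoop ratio rises monotonically from
~100% at the apex to ~145-147% at the clamp, i.e. hoop stress dominates
centrally and meridional stress at the edge.

One point deserves emphasis: published FEA summaries for such chips can
quote a center-region meridional-to-hoop ratio as low as 5%. For an
axisymmetric membrane that is impossible pointwise — at the apex the two
stresses are equal by symmetry — so such values must reflect a different
component convention or averaging scheme, which is not recoverable from the
source. The package reports the membrane-theory result and treats
commercial-FEA figures as non-reproducible at desk scale. Wrinkling (hoop
tension reaching zero near the clamp at extreme pressures) is detected and
flagged (`wrinkled`), not modelled with tension-field theory. Bending
stiffness and viscoelastic relaxation over culture days are out of scope.

## Tiled fluorescence quantification (CTCF)

Stitched quarter-well images are cut into non-overlapping square tiles
(default 1024 px, the field's batch-analysis convention); partial edge
tiles are dropped, and each tile is labelled A1/A2/A3 by the well radius of
its center (center-based labelling is deterministic; majority-area
labelling would differ only for tiles straddling a boundary). The default
well center is the image corner, matching quarter-well acquisitions.

Per tile, the marker channel is Gaussian-smoothed (`sigma = 2` px) and
background-subtracted with a rolling-ball-style filter (radius 15 px, the
middle of the conventional 10-20 px range), implemented as grayscale
morphological opening with a flat disc: the estimated background can
never exceed the image, uniform images map to zero, constant offsets cancel
exactly, and bright features smaller than the element are preserved.
(EBImage's grayscale morphology operates on [0, 1] intensities; the wrapper
rescales affinely, which commutes exactly with min/max filters.) The
foreground mask is Otsu's threshold on the preprocessed tile — the source
protocols say "thresholding" without a rule, so the rule is an explicit,
configurable choice here. Then

`CTCF = IntegratedDensity - Area x MeanBackground`

with the mean background taken over the mask complement. CTCF is normalised
per nucleus and aggregated per region and globally; aggregates are plain
means/s.d.s of the per-tile values and are tested to recompute exactly.

Nucleus counting (no algorithm is standard in the source protocols) uses
Gaussian blur, Otsu threshold, watershed splitting on the distance
transform, and a minimum-area filter (20 px). On generated fields at up to
~0.25 nuclei per 1000 px^2 with 18 px minimum spacing the count is exact to
well under 5% (tested across 10 seeds, 50-500 nuclei); with overlapping
pairs the recall stays above 0.9 but merged doublets are the dominant error
mode at higher densities.

## Orientation analysis

Local orientation comes from the structure tensor: image gradients by
4th-order central differences (a high-order stand-in for cubic-spline
derivative filters), tensor components smoothed with a Gaussian
(`tensor_sigma = 2` px), fiber angle = eigenvector of the smaller
eigenvalue, coherence = eigenvalue contrast, energy = trace. Angles are
axial, in degrees on [-90, 90), measured counter-clockwise from the +x axis
with y up (image rows are flipped internally); the synthetic generators use
the same convention, so truth tables and recovered angles are directly
comparable.

Histograms accumulate pixels above an energy threshold (Otsu on the energy
image by default) and above a coherence floor (0.05) into 1-degree bins and
are normalised by the maximum frequency so the peak equals one — the
convention that makes histograms comparable across conditions. The default
weighting is binary (each selected pixel counts once, mirroring
"frequency of white pixels" in thresholded-image practice); energy
weighting is available. Peaks are local maxima of a circularly 3-bin
smoothed histogram, merged within 10 degrees, and refined to sub-bin
precision by an axial weighted mean over +-5 bins — without the refinement,
peak positions quantise to the bin grid and the crossing angle
`theta_cross` (acute angle between the two dominant modes; the raw signed
difference is retained alongside) carries a +-1 bin bias. Alignment
efficiency is the fraction of histogram weight within +-10 degrees of a
reference axis, computed with fractional bin overlap so a uniform
distribution gives exactly `20/180 = 0.111`.

Per-cell elongation axes use second-moment (inertia-ellipse) orientation on
labelled objects; near-circular objects (aspect ratio < 1.02) get an `NA`
angle since their axis is undefined.

Two method artifacts are worth knowing. First, discrete gradient filters
are anisotropic at the pixel scale: raw white noise produces spurious
+-45-degree modes in any discrete structure tensor; orientation statements
are meaningful only for textures resolved above a few pixels (the test
suite uses band-limited noise for the isotropy property). Second, where
two fiber families cross densely, the smoothed tensor averages their
orientations and a spurious mode appears at the bisector angle; at moderate
densities (the regime the tests generate, ~400 fibers per 512^2 px) the
two family peaks dominate and `theta_cross` is recovered within 2 degrees
for crossings of 60-90 degrees.

## Colony coverage

Coverage is measured on binary colony masks in the projected plane, clipped
to the 4 mm well disc (`area = pixel count x pixel size^2`); the curved
dome surface is not unprojected, matching practice where wells are deflated
flat before imaging. When only nuclei images exist, the colony footprint is
the largest connected component of nuclei detections dilated by 30 um
(about one cell body). Coverage rate between day 3 and day 6 — the
expansion window after curvature application — is the area difference over
three days; fold changes divide by a reference (flat-control) rate, with a
configurable positive floor (`floor_eps = 0.1` mm^2/day) because flat-grown
quiescent keratocytes can have near-zero rates that would otherwise make
fold changes explode. Negative rates are returned but flagged with a
warning.

For a linearly expanding colony (`r(t) = r0 + v t`) the D3-D6 rate equals
`2 pi v r(4.5 d)` exactly, so the generator's programmed speed is
recoverable from rasterised masks to discretisation accuracy; the tests
demand 5% across ten seeds and observe well under 1%.

## Expression analysis (2^-ddCt)

Ct tables carry one row per (sample, cell type, condition, gene). The
package follows the Livak procedure with within-sample pairing:
`dCt = Ct_target - Ct_GAPDH` per sample, `ddCt = mean dCt(condition) -
mean dCt(flat)` per stratum, `fold = 2^-ddCt`, with the reference stratum
exactly 1 by construction. Within-sample pairing (rather than differencing
condition means) is the standard choice because it cancels per-sample
loading differences. Spread is reported as the s.d. of per-sample
`2^-(dCt_i - mean dCt_ref)` values. Validation lists every stratum missing
a housekeeping or reference measurement and warns for Ct outside 10-40
cycles.

Group comparisons use two-sided one-way ANOVA (`stats::oneway.test`, equal
variances) followed by Scheffe's post-hoc test, with the pairwise statistic
`F_s = (m_i - m_j)^2 / (MSE (1/n_i + 1/n_j)(k - 1))` referred to
`F(k-1, N-k)` and stars at 0.05/0.01/0.001. Scheffe is the conservative
all-contrasts procedure: for two groups its p equals the ANOVA p, and its
pairwise p never drops below the unadjusted contrast p — both identities
are tested, along with null calibration of the ANOVA type-I rate at 5%
over 10^4 simulated datasets.

## Synthetic data: what it does and does not emulate

The generators produce, under a mandatory seed with bit-reproducible
output and machine-readable truth tables:

- multichannel images: nuclei as isotropic Gaussian blobs (sigma ~5 px with
  10% jitter), F-actin-like fibers as Gaussian ribbons (length ~80 px,
  width 2.5 px) with uniform, von Mises or two-family orthogonal-mixture
  axial orientation models, condition-dependent marker amplitudes, constant
  + linear-gradient background, Gaussian and optional Poisson noise;
- growth series: linearly expanding colony discs rasterised over the full
  well, clipped at the rim (with analytic `pi min(r, a)^2` truth), plus
  optional nuclei renderings at a programmed density;
- Ct tables: `Ct = baseline - log2(fold) + N(0, sigma)` against a
  housekeeping gene, with the programmed fold table as truth.

Defaults mirror the chip conditions: 4 mm wells, day 0/3/6/9 sampling,
three qPCR replicates with 0.2-cycle noise. What the generators do *not*
emulate — and hence what passing closed-loop tests cannot show about real
data: optical point-spread and stitching seams, intensity vignetting beyond
a linear gradient, cell-shape texture and confluent-layer occlusion,
curvature-projection distortion of the dome (images in the source workflow
are taken after deflation, so fibers are rendered on the projected plane),
biological covariation between markers, and qPCR efficiency differences
between primers (the Pfaffl correction is out of scope). Recovery tests
therefore validate the estimators' correctness and calibration, not their
robustness to every real-world artifact.

## Problem sizes and runtime choices

The shipped tests run each membrane solve on 121-201 radial grid points
(grid-doubling changes the apex height by < 0.1%), nucleus-recovery fields
of 50-500 nuclei at ~0.25 nuclei per 1000 px^2, orientation fields of
512^2-1024^2 px, 10^5-sample efficiency checks, and 10^4-replicate null
simulations for the test calibration — sizes chosen so the full suite
completes in a few minutes on one core while every tolerance above is
exercised at its stated value.
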