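---
title: "Models and methods: quantifying mobile, exchanging protein inclusions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying mobile, exchanging protein inclusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incluflux)
```

`incluflux` implements the image-analysis pipeline used to characterise
large protein inclusions — such as the inclusion bodies (IBs) formed by
polyglutamine-expanded huntingtin fragments in budding yeast — as mobile,
gel-like compartments that continuously exchange material with the
cytoplasm. The pipeline has four analytical arms (single-particle motion,
morphometry, FRAP, photoconversion pulse-chase), all exercised against a
seeded synthetic-microscopy generator that provides ground truth for every
stage. This vignette records the models, the tunable parameters, and the
design decisions that were genuinely open.

## Single-particle motion

### Model

A particle's 2-D position evolves by per-frame Gaussian increments with
per-axis variance $2D\,\Delta t$ (free diffusion with diffusion
coefficient $D$ in µm²/s), optionally plus a drift step of length
$v\,\Delta t$ whose direction re-orients at random with mean waiting time
$\tau$ (the *directed* kind). Motion class is read off the mean squared
displacement,

$$\mathrm{MSD}(\Delta t) \propto \Delta t^{\alpha},$$

estimated per track at lags 1–16 frames using **all overlapping start
frames** ("each possible time interval"), with $\alpha$ the slope of an
ordinary least-squares line through
$(\log_{10}\Delta t, \log_{10}\mathrm{MSD})$. $\alpha = 1$ is free
diffusion, $\alpha > 1$ indicates a directed contribution, $\alpha = 2$ is
ballistic. $D$ comes from the zero-intercept fit
$\mathrm{MSD} = 4D\,\Delta t$ over the same lags — the defining relation
fixes no particular lag, so we use them all rather than lag 1 alone (a
switchable choice).

### Parameters and calibration

- `diffusion_coefficient`: default study value 0.059 µm²/s for small
  cytoplasmic aggregates (of the order of a ribosome's diffusivity).
- Frame rates: 32 fps (GFP-channel imaging) and 10 fps (photoconverted
  channel).
- `max_lag = 16` frames, truncated with a warning on shorter tracks.
- Classification dead-band: $\alpha = 1 \pm 0.05$ counts as diffusive.
  Reported SEMs on $\alpha$ for real ensembles are 0.03–0.06, so a
  knife-edge boundary at exactly 1 would label measurement noise.

Track length matters. The log-log slope estimator is biased low on short
tracks (ensemble mean $\hat\alpha \approx 0.96$ at 60–100 frames, because
the high-lag MSD values of a short track are strongly correlated), and
calibrated at longer ones ($0.99$–$1.00$ from 300 frames). The package's
study condition is therefore **300-frame tracks** (~9.4 s at 32 fps) for
exponent ensembles, and 512 frames where uniformly tight per-track fits
($r^2 \ge 0.98$ on every track) are asserted. At 64 frames the per-track
spread (SD ≈ 0.17, i.e. SEM ≈ 0.035 over 23 tracks) reproduces the
0.04-SEM scale reported for real 1–2 s tracks; we keep that regime out of
the calibration assertions on purpose.

The IB motion model is deliberately minimal: no published drift speed or
persistence exists for these bodies, only the observation
$\alpha \approx 1.2$–$1.4$. We chose $D = 0.005$ µm²/s, $v = 0.2$ µm/s,
$\tau = 1$ s empirically — over 300-frame ensembles this yields mean
$\alpha \approx 1.2$ at 32 fps and $\approx 1.3$ at 10 fps — and we do not
claim these values describe real inclusions; they make the estimator's
monotone response to drift testable.

### Detection and linking

Spots are enhanced with a scale-normalised negative Laplacian-of-Gaussian
filter ($\sigma^2$-normalised so responses are comparable across scales;
exact zero mean, so constant offsets map to zero), with reflective border
padding. The proprietary denoising step used on real movies is replaced by
an optional, documented Gaussian pre-smooth. Candidates are 8-connected
supra-threshold regions of the response with at least `min_size_px` pixels
(2 for small particles, 4 for IBs); the default threshold, mean + 3 SD of
the filtered frame, is a documented convention since the original plugin's
is unpublished.

Linking assumes **one particle per movie** (movies are cropped so that
they contain a single particle) and finds the globally optimal path by
per-frame dynamic programming under the published cost weights: intensity
80%, intensity variation 20%, movement constraint 40%, center constraint
0%, maximum displacement 10 px. The exact functional form combining these
percentages is not published; this package's documented score (responses
min-max-normalised per movie; the center term implemented but inert at its
0% default) *defines* the reference behaviour, and an exhaustive
path-enumeration oracle verifies global optimality on small fixtures.
There is no gap closing: a missed detection breaks the track, because MSD
analysis needs contiguous frames; the longest feasible segment is returned
with a diagnostic.

## Morphometry

Inclusions are segmented on z-stacks by thresholding at
$k \times$ mean cytoplasmic intensity ($k = 1.2$ for morphometry, 1.4 for
FRAP masks, 1.5 for pulse-chase masks, per the respective protocols),
8-connected in-plane, linked across z by centroid overlap, and measured on
the z-slice where the object's peak intensity occurs (exact ties resolved
toward the larger section). Objects are classed by the counting rules: a
supra-threshold object under 0.01 µm² is a *small particle*, as is a
sub-threshold body visible in more than one focal plane; larger
supra-threshold objects are *IBs* unless they meet the cluster-like
inclusion (CLI) rule. CLIs are described only qualitatively in the
literature (asymmetric, multi-lobed, accompanied by many peripheral
aggregates), so a concrete rule was required: ≥ 3 watershed lobes, or
circularity < 0.8 with ≥ 5 accompanying supra-threshold peripheral
objects; both cutoffs are configurable.

**Perimeter estimation.** Circularity $CR = 4\pi A / P^2$ is exquisitely
sensitive to the perimeter estimator: naive pixel-edge counting
overestimates $P$ on digital discs and depresses $CR$ to ~0.79, and we
measured multi-directional (Crofton) and corner-corrected chain-code
estimators at $CR \approx 0.85$–0.91 for discs of radius 4–25 px — all far
from the analytic 1. We therefore extract a **sub-pixel contour**: the
mask is regularised with a small Gaussian (σ = 0.8 px) and the 0.5-level
contour is traced by marching squares with linear interpolation; perimeter
and area are those of the resulting polygon. On digital discs this is
accurate to ~2% in perimeter ($CR$ 0.96–0.99 across radii 4–25 px). The
regularisation rounds true corners, so sharply cornered shapes read high
(a 10-px square gives ~0.89 rather than π/4 ≈ 0.785); analytic shapes are
therefore always evaluated with exact area and perimeter, and the mask
path is intended for the smooth, near-convex objects it measures in
practice. Aspect ratio is the axis ratio of the intensity-weighted
second-moment ellipse.

Apparent volume sums supra-threshold voxels times
$\text{pixel\_size}^2 \times \text{z\_spacing}$; it converges to the
analytic volume as sampling is refined and is reported as *apparent* —
PSF blur inflates it at realistic settings.

The chance-overlap estimate treats an autophagosome as apparently touching
an IB whenever its center falls within a circle of diameter
$d_{IB} + 2 d_{AP}$; the probability is that circle's area over the
available cytoplasmic cross-section. The cytoplasmic area behind the
published ~5–8% figure is not printed; back-solving gives ≈ 15.3–15.7 µm²,
which we use only as a fixture value, never asserting it as measured.

## Rendering and the camera model

Rendered movies place each particle as a 2-D Gaussian (PSF σ = 0.12 µm by
default, matching a high-NA 100× objective at 0.1 µm/px; field 64 × 64 px)
on a constant background. Noise, when enabled, is Poisson on the signal
followed by additive Gaussian read noise — the standard camera model, in
that order. Per-exposure photobleaching is geometric
(`retention^frame`). Trajectories reflect at the field edges so desk-scale
tracks stay in frame. Cell z-stacks render ovoid inclusions as filled
ellipsoids over a circular cytoplasm with a darker vacuole, optionally
PSF-blurred per slice. Geometry tests use unblurred stacks: with blur on,
thresholding at 1.2× cytoplasm genuinely overestimates the section of a
1.6×-intensity sphere (the mask boundary sits where the blurred edge
crosses the threshold, outside the true radius) — a physical effect of the
protocol, not an artifact to calibrate away.

## FRAP

The FRAP simulator realises three recovery regimes on an idealised
confocal section of a spherical compartment: *interior mixing* (incoming
unbleached material equilibrates uniformly; the regime consistent with a
liquid- or gel-like interior), *surface accretion* (material deposits only
in a boundary shell — the competing growth hypothesis), and *no exchange*.
Recovery of the compartment total follows
$dI/dt = k\,(I_{pre} - I)$ against an unlimited unbleached reservoir. The
discriminating statistic is the shell/core mean-intensity ratio (shell =
outer 20% of the radius): uniform mixing keeps it within [0.9, 1.1] while
shell-only deposition drives it far above 2 early in recovery. The
compartment is rendered without PSF blur so the statistic reflects the
regime rather than the optics; with realistic blur the same contrast
survives at larger radii but the package does not rely on that.

Quantification mirrors the experimental protocol: background-corrected
cytoplasm mean from a region away from the IB and vacuole, IB mask at
1.4× cytoplasm on the maximum-intensity projection, integrated intensity =
area × mean, equivalent-circle diameter (chosen over axis lengths because
a single "diameter" time course is reported; the axis-based alternative
exists through the morphometry arm), and the ratio to the pre-bleach
diameter, recording 0 when no supra-threshold object remains.

## Photoconversion pulse-chase

### Two-pool two-colour model

Amounts (A.U.) of green and red protein in cytoplasm ($C$) and inclusion
($B$):

$$\begin{aligned}
\dot C &= -k_{in} C + k_{out} B - k_{deg} C \;[+\, s \text{ for green}],\\
\dot B &= k_{in} C - k_{out} B,
\end{aligned}$$

with rates in 1/min. At $t = 0$ a fraction of the green pool in both
compartments converts irreversibly to red; red is never synthesised again.
At each division time the mother's cytoplasmic pool is divided by
$1 + f_d$ (daughter fraction $f_d$); the inclusion stays with the mother,
as daughters do not usually inherit it. The amount handed to daughters is
retained in a ledger column so that mass balance is auditable: with
degradation and bleach off, each colour's total is conserved exactly
across arbitrary division schedules.

Integration is a fixed-step explicit update with step
$\le 0.1/\max(k)$ and at least 10 steps per sampling interval, aligned
exactly to division and sampling times — the pool model is stiff-free at
these rates, so no implicit solver is warranted; tests check the
trajectory against the closed-form (eigen-decomposition) solution of the
linear system.

### Generator conditions

The minimal kinetic model does not itself fix initial pool sizes, so
the generator adds them (`init_cyto = init_ib = 100` A.U.). Defaults
emulate the published experiment: 4.5-h chase sampled every 10 min;
conversion fraction 0.5; divisions at 100 and 220 min (≈ 2.2 cycles at a
~120-min division time); daughter fraction 0.7; observation bleach
retention 0.94 per cycle for both channels, back-solved from the
rapid-cycle calibration in which cytoplasmic signal falls to 0.54 after
10 back-to-back acquisitions ($0.54^{1/10} \approx 0.94$). The rates
$k_{in} = 0.025$, $k_{out} = 0.010$, $k_{deg} = 0.005$/min were chosen
once so that the corrected red-IB trace shows the observed qualitative
shape — a rise to a maximum near 60 min followed by a ~35% decline over
the remaining 3.5 h; they are generator conditions, not measurements.

### Quantification and correction

Bleach calibration fits $I(c) = I_0\,r^c$ on rapid-cycle series (log-scale
least squares); correction divides each measurement by $r^{\text{cycles}}$.
Whether "cycles" count whole stacks or individual z-planes is not
specified by the protocol, so the `cycles` column is data and either
convention can be supplied. Red traces are normalised to their
post-conversion maximum; green traces to their initial value. Exact green
correction is ill-posed because newly synthesised protein has seen fewer
exposures than old protein, so the green channel is reported as a
bracketing pair — uncorrected (lower bound) and fully corrected assuming
every molecule saw every exposure (upper bound); the true curve lies
between.

The dilution-only prediction is the reciprocal of the dilution factor
(3.7 → 27%). Compounding the division schedule naively,
$(1 + 0.7)^{2.2} \approx 3.2$, does **not** reproduce 3.7, and the
original forward computation is unstated; the package accepts the factor
as input and reports the compounded value flagged as an alternative
derivation rather than asserting either.

`fit_pulse_chase()` inverts the forward model by Nelder-Mead over
log-rates (three fixed generic starts, none at the truth) against the
red-channel cytoplasm and IB traces, with conversion fraction, initial
amounts, division schedule and bleach retention taken as known (each is
measured or calibrated separately in an experiment). At the fixture noise
level (2% multiplicative) all three rates are recovered within 15% —
typically within 8% — per replicate.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the analyses assume:
Brownian and drift-contaminated motion, Gaussian PSF rendering with a
Poisson-Gaussian camera, geometric observation bleach, ovoid inclusions
over a cytoplasmic background, two-pool exchange with division dilution.
It does not emulate cell crowding or out-of-focus motion, 3-D PSF optics,
vesicle traffic, fluorophore blinking or maturation, or mechanistic
aggregation — so passing tests demonstrate that the estimators are
correct and calibrated under their stated assumptions, not that real
inclusions obey those assumptions. The real-cell measurements (the CR of
actual IBs, the 50%-diameter recovery time, the 35% drop, prevalence
percentages) are not reproducible without the original microscopy data;
they are covered by calibration, recovery and discrimination properties
on synthetic ground truth instead.

## Problem sizes

The bundled analyses and tests use 23-track ensembles of 300–512-frame
tracks (the longer length where uniformly tight per-track fits or small
ensembles demand the lowest estimator variance), 64 × 64 px movies of 40–60
frames, 40-cell synthetic populations, 11-plane z-stacks, 28-timepoint
chases, and 10–20 replicate fits — sizes chosen so every stage, including
its oracles, runs comfortably on a laptop-scale machine while leaving the
statistical assertions well-powered.

## Known limitations

- The mask-based perimeter is tuned for smooth near-convex objects;
  cornered or very small (< 3 px radius) masks are better measured
  analytically or at finer rendering.
- The tracker is single-target by design; multi-particle linking
  (cost-matrix assignment across many tracks) is out of scope.
- The FRAP model is compartmental, not spatial: no reaction-diffusion
  PDE inversion, hence no absolute mobility constants from recovery
  curves.
- Green-channel bleach correction is reported as bounds, not a point
  estimate, for the synthesis reason above.
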