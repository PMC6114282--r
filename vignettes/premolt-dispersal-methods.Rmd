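---
title: "Methods: pre-moult dispersal analysis from Argos telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-moult dispersal analysis from Argos telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tawakitrack)
```

This vignette documents the models and procedures implemented in
`tawakitrack`, the assumptions behind them, the parameters that matter,
and what the synthetic-data tests do and do not demonstrate about real
tracks.

## Geodesy and coordinate conventions

All coordinates are WGS84 decimal degrees, longitude in (−180, 180],
and all times UTC — the native Argos conventions. Distances are
great-circle distances by the spherical law of cosines on a sphere of
radius 6,378,137 m (the equatorial radius, the default of the distance
function common in this literature), reported in km. No ellipsoidal
correction is applied: at the few-thousand-km scale of these journeys
the spherical/ellipsoidal difference (< 0.5%) is far below the Argos
noise floor, and sticking to the spherical convention keeps published
table values reproducible.

Planar work (simulation, kernel grids, the environmental grid) uses an
azimuthal-equidistant projection about the colony, implemented with
matched spherical forward/inverse formulas so distance and bearing from
the centre are preserved exactly and the projection round-trips to
floating-point precision. Centring on the colony means colony distances
— the quantity that drives trip segmentation — are undistorted
everywhere.

## The SDA filter

Argos location classes A/B (roughly half of all fixes in this kind of
deployment) carry no accuracy estimate, so class-based filtering would
discard half the data. The speed–distance–angle filter instead removes
fixes that are kinematically implausible:

1. class-Z (invalid) fixes are dropped (configurable; whether the
   original analysis kept them pre-filter is unknowable from the
   publication, so dropping — the cited filter's own behaviour — is the
   default);
2. *speed stage*: iteratively, the non-endpoint fix with the largest
   root-mean-square of segment speeds to its two preceding and two
   succeeding retained neighbours is removed while that RMS exceeds
   `vmax` (2.0 m/s, the mean of reported penguin swimming speeds).
   Fewer neighbours are used near track ends; ties go to the later fix
   so the procedure is deterministic; zero time differences count as
   infinite speed so duplicate-time conflicts are removable;
3. *spike stage*: a fix is an out-and-back transmission spike when its
   internal turning angle is below 15° with both adjacent steps longer
   than 2.5 km, or below 25° with both steps longer than 5 km; spikes
   are removed sharpest-first.

Stages 2–3 are iterated to a fixed point, which makes filtering
idempotent — a property the tests assert by re-filtering the retained
set and by re-scanning for residual RMS violations. The first and last
fixes are never removed, and fixes are only removed, never relocated
(no state-space smoothing; that is a deliberate non-goal).

On realistically noisy synthetic cohorts (below) the filter retains
roughly 80% of fixes, the same order as reported for the real
deployment (82.3%). This is expected, not a defect: with 5–10 km
class-A/B errors at median 3-hour fix intervals, a material fraction of
genuine fixes *are* 2 m/s violations, and the filter is defined by the
kinematic criterion, not by outlier provenance. Filter *discrimination*
— what fraction of injected gross outliers is caught versus collateral
damage to fixes lying exactly on the true path — is therefore measured
on noise-free tracks with 5% of fixes displaced 50–500 km, where
"true-path fix" is well defined; there the filter removes > 95% of
outliers and well under 2% of true-path fixes.

## Daily aggregation

For each bird and UTC calendar day, the representative time is the
arithmetic mean of the fixes' UNIX timestamps and the representative
position the renormalised unit-3-vector mean of their coordinates
(antimeridian-safe; a perfectly antipodal set raises an error rather
than returning an arbitrary point). Daily travel distances and speeds
come from great-circle distances between consecutive mean daily
positions and their mean-time differences. Because days without fixes
occur, a km-per-day rate needs a convention: step distance divided by
the elapsed *calendar days* (so a 160 km step across a 2-day gap is 80
km/day). The source publication leaves this implicit; the choice is
ours and is applied consistently to the daily-distance medians and the
travel-rate model.

## Trip segmentation

* **Final departure** — birds make short coastal foraging sorties
  before leaving for good; these must not contaminate trip statistics.
  The departure is the first day of the *last* maximal run of days with
  colony distance > 20 km spanning at least 3 days. The 20 km
  threshold separates day-trip range from migratory range; 3 days
  ("min away days") is what makes a run "final" rather than a sortie.
* **Trip reversal** — the day of maximum great-circle distance from the
  deployment site, earliest day on ties. If the distance maximum falls
  on the last day and the last three days are still receding on
  average, the bird was still outbound when the transmitter stopped and
  no reversal is assigned.
* **Landfall** — the first post-reversal day within 5 km of the coast
  ("mainland waters").

Duration is the whole-day calendar difference between trip end and
departure — the only convention that reproduces all five published
complete-trip durations (66, 77, 74, 66, 67 days) from their printed
dates. Outward days are reversal − departure and inbound days
landfall − reversal; published per-bird inbound counts do not all equal
landfall − reversal (birds may loiter after the apex and the original
inbound definition is not stated), so those printed values are treated
as not reproducible by convention and are not asserted. Likewise the
published outward-journey median (32 days) is inconsistent with the
median of the printed per-bird outward column (38) and is not used as a
target.

Destination labels use a configurable front boundary latitude (default
−52°): maximum-range positions south of it are "SAF", otherwise "STF".
A latitude rule (rather than clustering) matches how the two
destination regions are described and reproduces the published labels.

## Kernel utilization distributions

Outward-phase points are the daily positions between departure and
reversal (inclusive — the reversal day belongs to the outward phase) of
birds with a reversal; inward-phase points run from reversal to
landfall for birds that reached mainland waters. Points are projected
(azimuthal equidistant about the colony) and smoothed with a bivariate
Gaussian kernel; the original tool and bandwidth are unstated, so the
normal-reference (Silverman) bandwidth per axis is the default with a
fixed-bandwidth override for sensitivity checks. The q% isopleth is the
smallest-area region containing q% of the utilization mass, found by
sorting cell masses in decreasing order and accumulating to q% — the
standard percent-volume contour of home-range analysis. Isopleths are
nested by construction; the evaluation grid (25 km cells, refined to at
least ~4 cells per kernel sd) keeps the contained mass within ±0.02 of
the nominal quantile and the total grid mass within 10⁻³ of 1. Because
the real bandwidth is unknown, quantities that depend on it (e.g. the
300–400 km corridor width) are treated as qualitative only.

## Trip-parameter models

Each trip parameter is modelled as
`parameter ~ destination + sex + (1 | bird)` with reference levels SAF
and female, on the nine birds with a reversal (five complete trips for
duration and trip length). Each bird contributes one observation, so
the fixed effects equal the ordinary least-squares solution — an
identity the package exploits as a correctness oracle
(`ols_trip_solve()`, agreement to 10⁻⁶ relative) — and the
random-intercept variance is not identifiable; the fit reports the
fixed effects and flags the variance decomposition rather than printing
an arbitrary split. Date responses are converted to day offsets from an
arbitrary origin (it cancels in the effects) and the intercept is
back-converted and rounded to the nearest day. Degrees of freedom
follow the small-sample t convention of the published table (n − 3: 6
for the nine-bird models, 2 for the five-bird models). Fitting to the
packaged per-bird table reproduces every published fixed effect to the
printed decimal except the trip-length STF coefficient (−1,823.1
printed vs −1,829.1 computed, with the intercept and sex terms of that
block matching exactly — evidently a typographical issue in the
printed table, so that one coefficient is not asserted).

The travel-rate model is a penalised cubic-spline smooth of km/day
against relative trip time t ∈ [0, 1] (0 = departure, 1 = landfall)
with a bird-level random intercept, smoothness chosen by REML. The
population curve is evaluated with the random effect excluded. With
five birds the mean of the bird offsets is absorbed into the curve
level — a ~2 km/day bias at the offset scales used in testing — which
is inherent to small-cohort GAMMs and well inside the 10%-of-range
recovery tolerance the tests use.

## Environmental stack and K-select

Environmental layers live on a common equal-area grid (57.4 km cells —
the coarsest native resolution among the source products, set by the
mixed-layer-depth climatology) as plain matrices with an explicit grid
object; no raster package is required. Temporal compositing is a
cell-wise mean ignoring masked cells (e.g. seven 5-day sea-level
anomaly fields averaged to match the 32-day windows of the other
products; the mixed-layer depth is a static climatology and is exempt).
Seafloor slope is the Horn 3×3 gradient magnitude in m/km; current
speed is √(u² + v²); resampling to the common grid is bilinear by
default (nearest-neighbour optionally), with masks propagated and
border cells masked.

Habitat selection at the trip destinations uses the daily positions
within 10 days either side of each bird's reversal. The publication
does not define availability; here each bird's availability is every
grid cell within 300 km of its destination-window centroid — a
destination-local disc consistent with describing selection "at the
destination". Each variable is standardized to zero weighted mean and
unit weighted variance over the union of availability sets (each
bird's availability weighted by its relocation share); the bird's
marginality vector is mean(used) − mean(available) in that space, with
used cells counted once per relocation (usage intensity). K-select is
then the eigen-decomposition of Σₖ λₖ mₖ mₖᵀ with λₖ proportional to
relocation counts: a weighted non-centred PCA whose eigenvalue sum
equals the weighted mean squared marginality (asserted to 10⁻⁹), whose
axes are orthonormal, and whose first axis is the common selection
direction when birds select alike. Depth is stored negative-down, so a
preference for shallow water appears as a positive marginality on the
depth variable — the sign convention the loading plots assume. A
permutation test of per-bird marginality (resampling used cells within
availability) is provided but optional; the source analysis reports no
test statistics. The published "81% of marginality on axes 1–2"
depends on the real tracks and rasters and is not reproducible at desk
scale; the two-axis default reproduces the retained-axis count as a
choice, not a result.

## The synthetic cohort: what it emulates, and what it does not

The simulator generates cohorts matching the deployment's structure:
17 birds by default with censoring statuses in the observed 5:4:8
proportions (complete / inbound-incomplete / outward-incomplete), 1–8
fixes per day, a class mix giving ≈ 49% class-A/B fixes, two
destination regimes (1,500 and 2,200 km) around the observed range of
maximum ranges, per-bird mean daily travel drawn from 40–80 km/day, and
10–20 loiter days at the destination. Tracks are three-phase correlated
random walks in the colony-centred plane: an outbound corridor around
heading 230° (SW) with AR(1) heading persistence, small-step loiter,
and an inbound leg homing on the colony. Pre-departure behaviour —
unquantified in the publication and a free parameter here — is modelled
as days ashore punctuated by one-day out-and-back sorties reaching
25–40 km. Argos errors are isotropic bivariate Gaussians with
class-dependent per-axis scales (150 m … 10 km from class 3 to B) and a
5% heavy-tail component at 5× scale; gross outliers (50–500 km
displacements) are injected at a configurable rate. Each bird runs on
its own RNG stream derived from (seed, bird index), so cohorts are
bit-reproducible and parallel-safe.

The synthetic environmental stack mirrors the southern Tasman Sea
qualitatively: SST as a meridional gradient with two front-like steps,
chlorophyll patchiness (optionally elevated along the northern front
when coupling is on), sea-level anomaly as a field of Gaussian eddies
with current speed as its gradient magnitude, a ridge-and-seamount
bathymetry, and a smooth mixed-layer depth built from random plane
waves. Structure scales are chosen so that, with coupling off, the
independently generated source layers are mutually uncorrelated
(|r| < 0.2 over ~10⁴ cells); slope and current speed are deterministic
derivatives of bathymetry and sea-level anomaly and are necessarily
correlated with their parents.

What passing tests on this cohort shows: the filter, segmentation,
kernel, model and K-select implementations recover known ground truth
under realistic noise, sampling irregularity and censoring. What it
does not show: anything about behaviour the simulator lacks — no
behaviourally mechanistic foraging, no tides or wind, no
location-class dependence on transmitter immersion, no
spatially correlated Argos errors, and pre-departure behaviour is
stylised. Claims about real tracks inherit only the filter's kinematic
guarantees, not the recovery rates.

## Numerical choices and test problem sizes

Degenerate inputs are defined, not accidental: coincident points give a
180° turning angle (no spike); an antipodal-symmetric point set is an
error in the geographic mean; all-identical points are an error for the
KDE; a zero-variance variable over availability is an error naming the
variable; empty cohort-statistic subsets are undefined (NA), never
zero. Medians use the even-n mean-of-central-pair convention, with date
medians computed on day offsets and back-converted.

The test suite exercises: 20-bird noise-free cohorts with 5% injected
outliers for filter discrimination; a 40-bird noisy cohort for
departure/reversal recovery (departure within ±1 day for ≥ 95% of
birds, reversal inside the true loiter window for ≥ 90%); ~300-point
kernel checks with mass tolerances of ±0.02; 6–10-animal K-select
designs over 50×50-cell stacks; and 5 birds × 60 days for travel-rate
curve recovery (RMSE < 10% of curve range). These sizes make the whole
suite run in under a minute while keeping the binomial margins of the
stochastic properties meaningful; the shipped analysis scripts use the
full 17-bird study structure.

## Known limitations

* Raster I/O is in-memory only (matrices plus a grid object); there is
  no GeoTIFF/NetCDF reader, and no download clients for the source
  ocean products — composited synthetic stacks stand in.
* The filter only deletes fixes; no state-space position estimates.
* The mixed models assume one observation per bird (the study design);
  repeated-measures extensions are out of scope.
* Availability in K-select is a disc; real availability definitions
  (accessibility, time budgets) are richer.
* The travel-rate smooth treats days as exchangeable given t; no
  autocorrelation structure is fitted.
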