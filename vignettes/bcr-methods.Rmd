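---
title: "Modelling animal movement with a biased and correlated random walk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling animal movement with a biased and correlated random walk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrwalk)
```

## The model

`bcrwalk` analyses GPS relocation data of sedentary animals with a
two-dimensional biased and correlated random walk (BCR) in discrete time and
continuous space. At each step the animal either

* **diffuses** — draws a uniformly random direction (isotropic exploration),
* **repeats** its previous direction exactly (*inertia*, weight $p_I$),
* **stays put** for one step (*immobility*, weight $p_s$), or
* **heads exactly toward a fixed attractor** $X_F$, the "den"
  (*attraction*, weight $p_F$).

Directions are discretised into 8 quadrants, so the branch is selected by a
uniform draw $x \sim U[0, \chi)$ with
$$\chi = 8 + p_I + p_s + p_F,$$
diffusion owning the mass $8$ and each force its weight. Moving steps
displace by a log-normal length $d \sim \ln\mathcal N(\mu, \sigma)$ metres
($\sigma$ is the standard deviation of $\log d$). The attractor is estimated
from data as the isobarycentre of all fixes.

Two *conflicting states* modify the branch table, because the realised step
cannot distinguish the forces there: if the previous displacement was at
most $d_{\min}$ (default 10 m, the magnitude of typical GPS error) the
animal was already immobile and has no defined heading, so the inertia mass
merges into immobility; if it was already heading toward the den (within
$\pi/8$), attraction merges into inertia. A path's origin has no heading and
is treated under the immobile-state table.

## Closed-form estimation

For each interior fix the *state* (previous, current) is classified as
plain `H` or conflicting (`H_Is`, `H_IF`). Over the plain states the
*situations* of the following step are tallied:

* `I` — relative turning angle within $\pi/8$ of straight ahead,
* `s` — outgoing displacement at most $d_{\min}$,
* `F` — outgoing heading within $\pi/8$ of the den direction,

with `I` and `F` evaluated only on mobile outgoing steps. The model implies
$x_1 = (1+p_I)/\chi$, $x_2 = p_s/\chi$, $x_3 = (1+p_F)/\chi$ for the three
situation proportions, which inverts in closed form:
$$\chi = \frac{6}{1 - (x_1 + x_2 + x_3)}, \qquad
  p_I = x_1\chi - 1,\quad p_s = x_2\chi,\quad p_F = x_3\chi - 1.$$
The constant 6 is $8$ minus the two diffusion quadrants absorbed by the `I`
and `F` cones; reduced configurations with fewer active situations adjust it
accordingly (`invert_parameters(active = ...)`). The `I` and `F` cones may
overlap for a given triple; both tallies count it, as each proportion is
estimated independently. Negative inverted weights are flagged and returned
— they mean a direction the animal avoids — but the simulator refuses them.
Step-length parameters are the log-normal maximum-likelihood fit over
mobile steps.

Two properties of this estimator matter in practice:

* With $d_{\min} = 0$ on both the generative and the estimation side it is
  essentially unbiased: the `I` cone receives exactly one diffusion quadrant
  plus the inertia mass, and similarly for `F` (the conflicting-state
  exclusions remove exactly the contaminated cases).
* With the field default $d_{\min} = 10$ m, log-normal steps shorter than
  10 m are classified immobile, so $\hat p_s$ systematically exceeds the
  generative $p_s$ and $\hat\mu$ is shifted up. This is a property of the
  cutoff, not a defect; the package asserts it as a directional test. The
  subsampling study (`scale_invariance_study()`) shows the counterpart:
  $\hat p_I$ and $\hat p_F$ are nearly invariant under decimation while
  $\hat p_s$ decays, because longer sampling intervals make sub-cutoff
  displacements rare.

The den estimate deserves a caveat: the isobarycentre of one finite,
weakly-confined path can sit several hundred metres from the true
attractor, which dilutes $\hat p_F$ (attraction steps point at the true
den, not at the path centroid). `estimate_bcr(X_F = ...)` accepts a known
attractor; the package's parameter-recovery checks use it.

## The five statistics and the error pair

Model fit is judged by comparing statistic profiles between the data and
simulated paths, through $e_1 = \sum_k \sum_j |S_j - \tilde S_{kj}|$ (an
$L^1$ distance, 0 for perfect agreement) and $e_2$, the mean componentwise
ratio $\tilde S/S$ (1 for perfect agreement; zero-reference components are
skipped with a warning).

1. **Turning angles** — relative-frequency histogram over triples whose
   both legs exceed $d_{\min}$ (36 bins over $(-\pi, \pi]$).
2. **Home range** — isopleth areas of a bivariate Gaussian kernel
   utilisation distribution on a $210 \times 210$ grid, at levels
   100–10 %. The diagonal bandwidth uses the Sheather–Jones direct plug-in
   selector per coordinate (`stats::bw.SJ`), the plug-in estimator
   available offline; any positive bandwidth can be supplied. The grid
   window pads the fixes by three bandwidths so the 100 % level is
   meaningful.
3. **Dilation** — area of the Minkowski sum of the path polyline with
   disks of radius 1–100 m, computed on a 1 m raster via an exact
   Euclidean distance transform; the window pads beyond the largest radius
   so the dilated set never collides with a border.
4. **Still transects** — 100 fixed observers with a 200 m line of sight;
   the profile is each observer's number of path *entries* into its sight
   disk (exact segment–circle crossings, not samples), sorted in
   decreasing order to break the spatial dependence. Observer placement is
   not specified by the model; the package uses seeded uniform placement
   in the track's bounding box, and any fixed layout can be passed in.
5. **Mobile transects** — from the first fix and the den, 8 linear
   transects depart in the 8 cardinal directions (16 in all, respawned
   every 10,000 clock ticks), plus one transect orbiting each anchor
   clockwise at 500 m radius; sights {50, 100, 200, 400, 500, 1000} m and
   speeds {s/4, s/2, s, 2s} of the animal's mean speed. The shared clock
   ticks at a tenth of the mean sampling time; at that resolution the
   largest relative displacement per tick (metres) is far below the
   smallest sight radius (50 m), so disk entries cannot tunnel between
   ticks and no continuous-time crossing correction is needed. The
   rotational start phase (due east) and the identification of angular
   speed with linear speed along the 500 m circumference are conventions;
   neither is constrained by the census design.

### Fluctuations

`fluctuation_study()` asks whether a statistic is deterministic enough to
serve as a reference: across replicates of increasing length $n_s$ the
per-component variance should not grow. Census *counts* scale linearly with
recording length, so their raw variance necessarily grows; the study
therefore scales count-valued statistics to sightings per step by default
(`normalize = TRUE`) — that is the scale on which "is this statistic
deterministic?" has an answer. The observer layout is drawn once and held
fixed across all replicates, as a census layout would be. Dilation areas
are reported raw; their variance grows with the window by construction.

## Anomalous spatial voids

Real tracks can contain holes ("voids") caused by terrain the animal cannot
enter — enclosures, water, buildings — rather than by randomness. The
package detects them by comparing the voids of the observed fix set against
a Monte-Carlo null of the fitted BCR:

1. `alpha_shape_voids()` computes the alpha shape of the fix set at a
   60 m alpha radius and extracts interior holes of at least 100 m².
   No triangulation library is available offline, so the shape is realised
   as the morphological closing of the point set with a disk of the alpha
   radius on a raster (exact Euclidean distance transform; dilation by the
   radius, then erosion by the same radius with half-cell tolerance). The
   closing is forced to be extensive — input cells are always retained —
   so a thin strand of fixes splits a void exactly as the triangulated
   alpha shape would. The raster resolution defaults to about 1/1200 of
   the padded window (at least 2 m) and is configurable.
2. A void is *central* when its centroid lies within a core radius of the
   fix isobarycentre (default: the median distance of fixes from that
   centre). Voids outside the densely-sampled core are dominated by
   sampling gaps: a random walk's occupation density decays toward the
   range edge, where arbitrarily large empty patches arise by chance
   alone, so anomaly claims are only meaningful in the core. (An earlier
   design flagged voids merely "away from the outer boundary"; measured on
   simulated tracks, mid-range sampling voids of $10^5$ m² routinely pass
   that rule, drowning any genuine void — the core rule replaces it.)
3. `void_null_distribution()` simulates the fitted BCR many times
   (10,000 in a full analysis; a few hundred suffice for screening) and
   records the largest central void per run; $p_\varnothing(a)$ is the
   fraction of runs with a central void of at least $a$.
4. `flag_anomalous_voids()` marks central observed voids with
   $p_\varnothing(\text{area}) <$ `p_cut` (default 0.05 — a configuration
   value, not a claim about the right threshold).

## Synthetic data

`generate_fixture()` emulates a deer-like GPS campaign: a BCR track at
nominal 10-minute intervals with Gaussian timestamp jitter (sd 3 min,
redrawn where it would break monotonicity), and optionally a planted
exclusion polygon enforced by rejection — the synthetic analogue of a
forest enclosure, leaving a genuine void in the fix set.

The default parameters are `p_I = 0.1, p_s = 1.9, p_F = 1, mu = 3,
sigma = 1`. The immobility weight reproduces a ~17 % exactly-immobile fix
fraction and ~33 m median moving steps, as published red-deer estimates do.
The attraction weight is deliberately *stronger* than published estimates
(which lie at 0.01–0.24): simulated at those weights, a 25,000-step walk
drifts across 7 km and more with no stationary range, whereas real female
red deer hold a home range a few kilometres across. `p_F = 1` delivers a
stationary 2.5–3.5 km range at data-like fix density, which is what a
fixture standing in for the real tracks must reproduce. This gap between
estimated weights and observed confinement is a genuine limitation of the
single-attractor BCR, not of the estimator.

What a green test on synthetic data does establish: the estimator inverts
the generative weights, the statistics discriminate configurations, the
void pipeline detects planted exclusions at the stated sensitivity. What it
does not establish: that real deer movement follows the BCR — real tracks
have temporally correlated rest bouts, habitat structure and memory that
the model deliberately omits.

## Numerical choices and degenerate inputs

* Angles live in $(-\pi, \pi]$; turning angles are counter-clockwise
  positive with 0 = straight ahead. The classification inequalities written
  on geometric vertex angles are converted through the fixed bijection
  $\varphi = \pi - \angle$.
* $d_{\min}$ comparisons are non-strict for immobility ($\le$) and strict
  for mobility ($>$), exactly as the state/situation definitions are
  written.
* Mean sampling time defaults to the mean of the $n-1$ real intervals;
  the literal mean including the leading zero is available via
  `include_first = TRUE`.
* The simulator consumes randomness in a fixed order (branch draw, then
  step length for moving branches, then direction for diffusion only), so
  seeds reproduce trajectories bitwise; the R reference stepper
  (`bcr_step()`) and the compiled loop are tested to agree draw by draw.
* Estimation requires at least 3 fixes, at least one plain state and
  $x_1 + x_2 + x_3 < 1$; constant-position tracks and 2-fix files fail
  with clear errors. Subsampling beyond $n/3$ marks rows degenerate
  rather than erroring the whole study.
* Geographic input is projected on ingest with a local equirectangular
  projection about the track centroid (exact inverse; adequate at
  home-range scale). Full PROJ/EPSG support is out of reach offline.

## Known limitations

* One attractor, one-step memory, no interaction between animals and no
  habitat covariates — by design.
* Negative estimated weights are reported, not re-modelled.
* The raster alpha shape matches the triangulated one up to resolution;
  void areas carry a relative error of order (resolution × perimeter /
  area).
* Immobility is a distance cutoff, not a speed cutoff, so $\hat p_s$ is
  tied to the sampling interval (quantified by the subsampling study).
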