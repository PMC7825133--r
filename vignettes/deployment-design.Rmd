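---
title: "Designing receiver-station deployments for passive animal telemetry"
author: "deploysim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing receiver-station deployments for passive animal telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deploysim)
```

## The problem

Passive tracking systems (VHF/UHF telemetry, acoustic arrays) only recover
the data logged on an animal-borne sensor when the animal comes close to a
receiver station. Deployment design — how many stations, where, with what
reception radius — therefore determines how much of the logged data is ever
recovered. `deploysim` simulates this coupled system and characterises the
*transfer function* $\langle T\rangle$: the mean number of transmitted data
packages per unit time per animal.

## Movement model

Each of $N$ animals moves on the plane in discrete time under a
central-place rule,

$$\vec{x}_i(t+1) = \vec{x}_i(t) + v\,\vec{\nu}(t)
  - a\,\bigl(\vec{x}_i(t) - \vec{x}_{h_i}\bigr),$$

where $\vec{\nu}(t)$ is an independent unit vector with uniformly random
direction per animal per step, $v$ is the step speed and $a \in [0,1]$ the
home attraction. Homes $\vec{x}_{h_i}$ are drawn uniformly on the unit
square and are fixed for a run. The two extremes bracket the behaviour:
$a = 0$ is an isotropic random walk, and $a = 1$ pins every post-step
position onto the circle of radius $v$ about the home. For intermediate
$a$, iterating the update bounds the long-run distance to home by $v/a$
(the distance map is $D(t+1) \le (1-a)D(t) + v$, with fixed point $v/a$);
this $v/a$ bound is what the implementation asserts. The stationary
per-axis spread of the resulting discrete Ornstein–Uhlenbeck process is
$\sigma = v/\sqrt{2(2a - a^2)}$, which for the defaults below is about
0.016 at $a = 0.001$ and 0.005 at $a = 0.01$.

Design choices worth stating explicitly:

* **No boundary conditions.** The update contains no boundary term, so the
  plane is unbounded; only homes and stations are confined to the unit
  square. With the defaults ($v = 0.001$, $a > 0$) trajectories stay near
  their homes and excursions beyond the square are negligible.
* **Initial position = home.** Starting in the attractor basin makes the
  $a = 1$ static limit exact from the first step and avoids a long
  relaxation transient sweeping across the arena.
* **RNG discipline.** One uniform angle per animal per step (then one per
  mobile station), drawn from R's seeded stream; realization $k$ of a
  sweep cell uses an arithmetically derived seed, so every curve is exactly
  reproducible. The compiled loop consumes the stream identically to the
  pure-R `step_population()`, which the tests exploit as a cross-check.

## Transmission rules

Every sensor generates one package per time step. Within a step the order
is: move, then (for mobile deployments) move the stations, then generate,
then detect and flush. An animal within Euclidean distance $\le r$ of *any*
station transmits its entire buffer — including the package generated that
step — as a single event, and the buffer is cleared; being in range of
several stations still yields one event, since a package can only be
deleted once. This ordering makes an animal permanently in range transfer
exactly one package per step, so $\langle T\rangle \in [0,1]$ always, and
package conservation (generated = transmitted + stored) holds per animal
after every step.

## Coverage law and the static limit

For $x$ stations placed independently and uniformly, the expected fraction
of the arena covered by at least one reception disc is

$$f = 1 - (1 - p)^x, \qquad p = \pi r^2 / A,$$

and `covered_fraction()` evaluates it. In the static limit ($a = 1$,
$v \ll r$) this $f$ is the probability that a sensor sits in range at any
given time, hence the analytic prediction for $\langle T\rangle$
(`transfer_static_limit()`).

One subtlety matters when checking this numerically. Because buffers
accumulate, an animal whose $v$-circle *ever* touches a reception disc
eventually flushes its whole history, so over a long horizon the measured
$\langle T\rangle$ converges to the *reach* probability — effectively the
coverage law with radius $r + v$ — which exceeds $f$ by
$O(v/r)$ (about 20% at the default $v/r = 0.1$). The analytic claim is
about the instantaneous in-range probability, so the package's static-limit
checks measure single-step transfer, for which the law holds without the
backlog correction. Over the long horizons used everywhere else the
approximation is still what one sees on a full-scale plot; the bias only
becomes visible at several Monte-Carlo standard errors of resolution.

The "covered area" used as the x-axis of transfer curves is always the
*sum* of disc areas $x \pi r^2$, overlaps not subtracted — e.g. 10 stations
of radius 50 km count as $78{,}539.8\ \mathrm{km}^2$. An expected *union*
coverage would be placement-dependent and is only used via $f$ above.

## Sweeps, R90 and the saturating-exponential law

`sweep_stations()` averages $\langle T\rangle$ over seeded realizations per
station count; `compute_R90()` reports the smallest swept count whose mean
transfer reaches 0.9 (no interpolation — a deployment is an integer number
of stations; granularity is whatever the sweep used). Transfer versus
covered area is fitted by nonlinear least squares
(Levenberg–Marquardt via `minpack.lm`) to the saturating-exponential law

$$\langle T\rangle = c\,\bigl(1 - e^{-d\,A_{\mathrm{cov}}}\bigr),$$

with starting values $c_0 = \max T$, $d_0 = 1/\overline{A}$. The rate $d$
summarises how efficiently added coverage converts into recovered data; it
decreases as the home attraction grows.

Two numerical caveats:

* **The fitted $d$ depends on how the saturation level is handled.** The
  simulated curve is not exactly of the fitted form (animals are
  heterogeneous in their distance to the nearest station), so $c$ and $d$
  trade off strongly whenever the sweep stops short of the plateau: with
  both free, the under-determined $c$ drops below its true level and $d$
  inflates by 15–20%, with an accordingly large standard error. For
  quoting rates the package therefore fixes the saturation level at the
  physical ceiling $c = 1$ (`fix_c = 1`): for weakly attracted movement
  every animal eventually encounters a station, so the recovery fraction
  tends to 1 as coverage grows, and the constrained fit reduces $d$ to the
  well-determined initial-slope content of the curve. The free-$c$ fit
  remains the default of `fit_transfer_vs_area()` for data that do reach
  their plateau.
* **The four-parameter decay** $y = y_0 + A\,e^{-(x - x_0)/t_1}$ used for
  R90 versus radius is over-parameterised ($A$ and $x_0$ only enter through
  $A e^{x_0/t_1}$), so `fit_R90_vs_radius()` fixes $x_0$ at the smallest
  radius by default and estimates $y_0, A, t_1$; the decay scale $t_1$ and
  the fitted curve are unaffected by this normalisation.

Inter-event times — steps between consecutive flushes of one animal,
pooled over animals and realizations — are summarised by
`inter_event_pdf()` as a histogram with bins of equal width in
$\log_{10}\tau$ (30 bins by default, matching the decades-long range the
distribution spans), normalised so the density integrates to 1 over the
binned range.

## Deployment strategies

* **random** — stations i.i.d. uniform on the unit square.
* **at_home** — stations placed exactly at a uniformly sampled subset of
  distinct homes, at most one per home; if more stations than homes are
  requested, the excess is placed uniformly at random (a regime the
  reference analyses never exercise). With one station per home and
  $v < r$, every animal is permanently in range and
  $\langle T\rangle = 1$ exactly.
* **mobile** — stations random-walk with their own speed (the $a = 0$
  movement rule applied to stations), unbounded like the animals. Faster
  stations transfer more at equal count, and mobile deployments plateau
  even at large $a$ where static ones grow only linearly.

## Geographic trajectories

The same transmission rules apply to recorded tracks
(`animal_id,timestamp,lat,lon`): each fix generates one package, and a fix
whose Haversine distance (sphere radius 6371 km) to any station is
*strictly* below the radius flushes the buffer. The strict inequality
mirrors the geographic formulation (the planar engine uses $\le r$); the
boundary set has measure zero, so the choice is immaterial. Irregular
sampling is deliberately ignored — one fix is one time step — matching the
package-per-recorded-position convention. Covered areas in km² use planar
$\pi r^2$ without spherical-cap correction, which at $r \le 50$ km is a
relative error below $10^{-4}$.

Real tracks do not come with a labelled home, so the first recorded fix
stands in for it (central-place foragers are typically released at the
colony or haul-out); station placement regions are the per-track-set
latitude/longitude bounding box.

`generate_synthetic_geotracks()` produces stand-in track sets by running
the central-place update in a local tangent plane (km) around each home and
mapping displacements to degrees (1° latitude = 111.195 km, longitude
scaled by $\cos$ of the home latitude; homes are rejected above |lat| 89°
where the mapping degenerates). Two regimes are provided, emulating the
qualitative contrast between a wide-ranging and a coastal central-place
species: `weak` ($a = 0.005$) and `strong` ($a = 0.1$), both defaulting to
5 km steps, 10 animals, 500 fixes, homes scattered within 0.5° of
(35° S, 135° E). With these values the strong regime stays within a few
tens of km of the colony while the weak regime ranges over hundreds of km —
the intended orders of magnitude for coastal sea lions versus far-ranging
seals. These fixtures reproduce the *mechanism* (central-place movement at
two attraction strengths) but none of the measurement realities of ARGOS
tracks — location error, gappy duty cycles, haul-out clustering — so
passing geographic tests demonstrates the pipeline and the qualitative
strategy ordering, not fidelity to any particular species' data.

## Problem sizes used in the tests

The packaged tests run reduced problem sizes chosen to keep Monte-Carlo
noise well inside the asserted tolerances: sweeps with tens to a few
hundred animals and $10^3$–$10^4$ steps, 10–20 realizations per cell, and
the full reference protocol ($N = 500$, 20,000 steps, 20 realizations) only
for the two headline rate estimates. Tolerances on stochastic checks are
stated as multiples of the measured Monte-Carlo standard error rather than
absolute numbers wherever possible.

## Known limitations

* Transmission always succeeds in range (no collisions, attenuation or
  detection probability below 1); stochastic detection could be folded in
  as an effective radius but is out of scope.
* Movement is two-dimensional and memoryless with a single home per
  animal; diving, migration between multiple homes, correlated or
  heavy-tailed steps are not modelled.
* Station placement is evaluated, not optimised: no coverage-maximising
  arrangement search.
* The fitted rate $d$ is a protocol-level summary: compare values of $d$
  only between fits using the same sweep grid and area range.
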