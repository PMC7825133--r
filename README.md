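# deploysim

Simulation toolkit for designing receiver-station deployments in passive
animal telemetry (VHF/UHF, acoustic arrays). It answers the practical
question a tracking study faces before buying and mooring equipment: *given
how the animals move, how many stations, where, and with what reception
radius are needed to recover the data their tags log?*

## Model

`N` animals move on the plane in discrete time under a central-place rule

    x_i(t+1) = x_i(t) + v ν(t) − a (x_i(t) − x_home_i)

with `ν(t)` an independent random unit vector per animal per step, `v` the
step speed and `a ∈ [0,1]` the home attraction (`a = 0`: pure random walk;
`a = 1`: positions pinned to a circle of radius `v` about the home). Homes
and stations live in a unit square. Every sensor generates one data
package per step and flushes its whole buffer as a single event whenever
the animal comes within the reception radius `r` of any station.

The central observable is the transfer function `⟨T⟩` — mean transmitted
packages per unit time per animal, bounded by 1. The package provides:

* deployment strategies: uniform random, at-home (one station per home),
  and mobile (random-walking) stations;
* the analytic coverage law `f = 1 − (1 − πr²/A)^x`, which predicts `⟨T⟩`
  in the static limit (`a = 1`, `v ≪ r`);
* sweeps of `⟨T⟩` against station count / covered area (`x·πr²`), the
  phase diagram over `(a, x)`, `R90` (smallest count recovering 90% of all
  packages), and inter-event-time distributions;
* saturating-exponential fits `⟨T⟩ = c(1 − e^{−d·area})` and the
  exponential decay of `R90` with `r`;
* the same transmission analysis on geographic tracks
  (`animal_id,timestamp,lat,lon`) with Haversine distances, plus a
  synthetic central-place track generator at weak/strong attraction
  regimes.

## Worked example

```r
library(deploysim)

mp <- movement_params(a = 0.01, v = 0.001, n_animals = 100)
sw <- sweep_stations(mp, counts = c(0, 20, 60, 120, 200), radius = 0.01,
                     n_steps = 4000, n_realizations = 10, base_seed = 1)
sw[, c("n_stations", "covered_area", "T_mean", "T_se")]
#>   n_stations covered_area     T_mean        T_se
#> 1          0  0.000000000 0.00000000 0.000000000
#> 2         20  0.006283185 0.03101225 0.005054313
#> 3         60  0.018849556 0.08881900 0.006555500
#> 4        120  0.037699112 0.16567175 0.012861743
#> 5        200  0.062831853 0.29843925 0.011000737

fit_transfer_vs_area(sw, fix_c = 1)
#> Nonlinear least-squares fit: c*(1 - exp(-d*x))
#>   estimate std.error
#> c    1.000        NA
#> d    5.327    0.1964
#> RSS = 0.0005092 on 5 points
```

With only a short run (4,000 steps) and moderate attraction, 200 stations
at `r = 0.01` recover ~30% of the logged packages; the rate `d ≈ 5.3` per
unit covered area summarises how efficiently extra coverage converts into
recovered data under this movement (longer runs and weaker attraction give
larger rates). `compute_R90(sw)` reports that 90% recovery is not reached
within this sweep.

A command-line wrapper is installed with the package
(`exec/deploysim`), exposing `simulate`, `sweep`, `phase`, `fit`,
`interevent`, `geo` and `synthgeo` subcommands over the same functions,
with YAML config support; see `?cli_main`.

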