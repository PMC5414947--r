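# avrescue

Monte Carlo optimization of avalanche rescue strategies under the
"greatest good for the greatest number" criterion.

When an avalanche buries more than one person, rescue capacity is scarce and
every allocation choice trades one subject's survival chances against
another's. `avrescue` answers two such triage questions by simulation:

1. **Probing depth.** In the first passage of a probe line, how deep should
   each probe stroke go? Deeper strokes find more victims (the burial-depth
   distribution has a long tail) but slow the line down, and survival falls
   steeply with burial time. For a debris field of area *A* searched by
   *n* rescuers in 1.5 m strips, a victim at position *x* with burial depth
   *d* is found iff *d* ≤ probing depth *D*, after a search time
   *t*<sub>search</sub> = *x* / (*v*(*D*) · *n*) and a dig time
   *t*<sub>dig</sub> = *d* / *v*<sub>dig</sub>; survival is
   *S*(*t*<sub>search</sub> + *t*<sub>dig</sub>) for a non-increasing survival
   curve *S*. The package sweeps *D* over a grid (default 0.5–2.5 m in 0.1 m
   steps) and reports the depth maximizing mean survival.

2. **CPR duration.** A lone rescuer has extricated a pulseless, normothermic
   patient (patient 1, buried *t*<sub>b1</sub> minutes) while a second subject
   is still buried. CPR for *t*<sub>CPR</sub> minutes gives patient 1 a
   return-of-spontaneous-circulation probability
   *p*₁ = *a* · (1 − exp(−0.07 · *t*<sub>CPR</sub><sup>1.3</sup>)),
   with ceiling *a* depending on *t*<sub>b1</sub> (0.62 / 0.25 / 0 at
   12 / 20 / 35 min), while patient 2's burial lasts
   *t*<sub>b1</sub> + *t*<sub>CPR</sub> + *t*<sub>search</sub> +
   *d* / *v*<sub>dig</sub> minutes. The package maximizes the expected number
   of survivors *p*₁ + E[*p*₂] over *t*<sub>CPR</sub> = 0…30 min.

Burial depths (and deposit areas) are resampled from an empirical avalanche
table in the Swiss registry CSV layout, or from a calibrated synthetic
stand-in when the registry snapshot is unavailable. The audience is
search-and-rescue researchers and avalanche-safety educators; the output is
survival curves over a decision grid, not clinical recommendations.

## Worked example

```r
library(avrescue)

records <- synthetic_s1_table(seed = 1)   # synthetic registry stand-in
summarize_records(records)
#> Avalanche record summary
#>   rows in source table : 1555
#>   with burial depth    : 1490
#>   with deposit area    : 541
#>   with both            : 477
#>   rejected (no fields) : 1
#>   depth quartiles [m]  : 0.46 / 0.70 / 1.00
#>   area quartiles [m2]  : 3215 / 7200 / 15962

depths <- to_distribution(records, "burial_depth")

# scenario 1: probe line on a 5000 m2 deposit, 20 rescuers
res <- run_probe_grid(probe_config(area_m2 = 5000, n_rescuers = 20,
                                   depth_source = depths, seed = 1))
head(as.data.frame(res)[, 1:4], 3)
#>   depth_m mean_survival se_mean miss_fraction
#> 1     0.5         0.261 0.00405         0.707
#> 2     0.6         0.339 0.00420         0.604
#> 3     0.7         0.403 0.00413         0.505
optimal_probing_depth(res)
#> [1] 1
```

At a shallow 0.5 m probing depth roughly 70 % of victims are missed; by
2.5 m nearly all are found but many die of the slow search. Mean survival
peaks at an interior probing depth (1.0 m here, with the shipped survival
curve and speed model).

```r
# scenario 2: CPR triage, patient 1 buried 12 min (ROSC ceiling a = 0.62)
cres <- run_cpr_grid(cpr_config(t_burial1_min = 12, depth_source = depths,
                                seed = 1))
as.data.frame(cres)[11:14, c("t_cpr_min", "p1", "mean_p2", "expected_survivors")]
#>    t_cpr_min    p1 mean_p2 expected_survivors
#> 11        10 0.467   0.473              0.940
#> 12        11 0.492   0.452              0.944
#> 13        12 0.514   0.431              0.946
#> 14        13 0.533   0.411              0.944
optimal_cpr_duration(cres)
#> [1] 12
```

Each CPR minute raises patient 1's ROSC probability and lowers patient 2's
survival; the expected number of survivors peaks near 12 minutes of CPR —
well short of a 20-minute protocol — and for a 35-minute burial (ceiling
*a* = 0) immediate excavation of patient 2 is optimal.

## Command line

```sh
avrescue synth generate --out table.csv --s1 --seed 1
avrescue data summarize table.csv --out summary
avrescue probe --area 5000 --rescuers 20 --runs 10000 --seed 42 --data table.csv --out probe
avrescue cpr --burial-time 12 --runs 10000 --seed 42 --synthetic --out cpr
```

Every result is written as CSV + JSON alongside a manifest (resolved
configuration, seed, package and survival-curve versions, input fingerprint)
sufficient to reproduce it bit-for-bit.

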