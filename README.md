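# swsshrt

Hydraulic retention time (HRT) modelling for tap water in high-rise
buildings served by secondary water supply systems (SWSS), for water-quality
engineers and drinking-water microbiologists studying premise plumbing.

In an SWSS, mains water is stored in an underground inlet tank, pumped up a
riser to a mechanical floor, gravity-fed down to the storeys below
("SWSS-first"), or stored in a break tank and pumped on to feed the upper
storeys ("SWSS-second"). The age of the water leaving a tap — its HRT —
drives microbial regrowth and metal leaching, and `swsshrt` estimates it per
tap under steady plug flow. Each pipe segment of volume *V* carrying steady
flow *Q* delays water by *V/Q*; with per-storey standpipe volume
*V<sub>s</sub> = (π/4) d<sub>s</sub>² h* and on-floor line volume
*V<sub>h</sub> = (π/4) d<sub>h</sub>² l*, the HRT of a tap on floor *k* is

    HRT(k) = Σ T_tank  +  Σ_legs (Σ traversed V_s) / Q_riser
           + Σ_{j=k..top} V_s,j / Σ_{i≤j} Q_i  +  V_h / Q_k

summing the tank residence times on the supply path, the pumped riser legs
(each carrying the demand of every floor it ultimately feeds), the gravity
down-feed (each storey's volume over the cumulative demand below it) and
the horizontal line. The package provides:

* a validated building-topology data model with YAML/JSON configs
  (`building_topology()`, `read_topology()`, `validate_topology()`);
* the analytic per-tap HRT with component breakdown (`tap_hrt()`,
  `hrt_profile()`) plus an independent plug-flow parcel-tracking oracle
  (`simulate_parcel_oracle()`);
* a seeded synthetic generator of per-tap observations — log10 16S rRNA
  gene copies and Fe linear in HRT with noise calibrated to target
  association strengths, Zn/Cu set by pipe and tap materials
  (`generate_observations()`, `calibrate_noise_sd()`);
* permutation-based correlation analysis (`pearson_r()`, `linfit()`,
  `permutation_p()`, `associate()`, `group_summary()`);
* a config-driven pipeline and CLI (`cmd_full_run()`, `exec/swsshrt`).

## Worked example

Compute the retention-time profile of the packaged 34-storey office layout
(inlet tank two storeys underground, break tank on the mechanical floor 23,
zones 6–23 and 24–34, tank residence 4 h each):

```r
library(swsshrt)
office <- office_topology()
prof <- hrt_profile(office)
prof[prof$floor %in% c(6, 23, 24, 34),
     c("floor","zone","tank_s","riser_s","downfeed_s","horizontal_s","hrt_h")]
#>  floor        zone tank_s riser_s downfeed_s horizontal_s hrt_h
#>      6  office-low  14400 1754.96    7115.17      1696.46  6.94
#>     23  office-low  14400 1754.96     113.10      1696.46  4.99
#>     24 office-high  28800 3790.71    6147.72      1696.46 11.23
#>     34 office-high  28800 3790.71     185.07      1696.46  9.58
```

Water ages are highest just above the mechanical floor (floor 24: 11.2 h —
two tank dwells, two riser legs and the whole upper down-feed) and lowest
just below it (floor 23: 5.0 h), the characteristic saw-tooth of a two-zone
SWSS. Generate 31 synthetic tap observations and test the HRT associations:

```r
obs <- generate_observations(office, generator_params(seed = 1), n_taps = 31)
associate(obs, "hrt_h", "log10_16s", B = 999, seed = 1)
#> log10_16s ~ hrt_h  (n = 31)
#>   r = 0.859, R2 = 0.737, slope = 0.3825, intercept = 2.345
#>   permutation p = 0.0010 (B = 999)
associate(obs, "hrt_h", "fe", B = 999, seed = 1)
#> fe ~ hrt_h  (n = 31)
#>   r = 0.793, R2 = 0.628, slope = 0.003583, intercept = 0.01421
#>   permutation p = 0.0010 (B = 999)
format_group_summary(group_summary(obs, "supply_label", "log10_16s"), digits = 2)
#>    swss-first   swss-second
#> "4.95 ± 0.96" "6.44 ± 0.98"
```

The generator's noise is calibrated so the population R² of the 16S
response is 0.63 and the HRT–Fe correlation 0.79; single 31-tap samples
scatter around those targets (here 0.737 and 0.793), and upper-zone taps
carry roughly 1.5 more log10 units of bacteria than lower-zone taps. The
same analysis runs from a shell:

```sh
swsshrt build-example --which office --out office.yaml
swsshrt compute-hrt --topology office.yaml --out profile.csv
swsshrt full-run --config run.yaml --seed 1
```

## Layout

* `R/` — topology model, HRT engine, synthetic generator, association
  analysis, pipeline/CLI
* `tests/testthat/` — unit, property and end-to-end suites
* `vignettes/hrt-modelling.Rmd` — model, assumptions and design choices
* `inst/exec/swsshrt` — command-line entry point
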