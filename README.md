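# pbsmu — volume-based secondary MU checks for scanned proton beams

`pbsmu` is an R package for **secondary monitor-unit (MU) verification of
single-field-uniform-dose (SFUD) pencil-beam-scanning proton beams**. It is
aimed at medical physicists who need an independent, spot-agnostic sanity
check of the MU a treatment planning system prescribes per beam — before or
after optimization — using nothing but the contoured target, the beam
orientation, and a set of commissioned factor tables.

## The model

The target is approximated by the *equivalent cuboid* with the same volume
`V` and beam's-eye-view projected area `A`, giving an SOBP width
`W = V / A`. The beam range `R` is the mean water-equivalent depth of the
distal target surface (plus the range-shifter water-equivalent thickness,
default 4.1 cm, when a shifter is in the beam). The per-beam MU is then

```
MU = D_rx / ( OF(A, W) · DF(R) · AGF(g) · k_cal )
```

with `D_rx` the prescribed point dose at the SOBP centre (cGy),
`OF` the output factor (cGy/MU) tabulated for cuboids at 20 cm reference
depth and 1 cm reference air gap, `DF` the depth factor (`DF(20 cm) = 1`),
`AGF` the air-gap factor for range-shifted fields (`AGF(1 cm) = 1`; exactly
1 for open fields), and `k_cal` a measured calibration scale. Factor tables
are institution-specific inputs (plain CSV + JSON sidecar); a self-consistent
analytic toy beam model is included to generate realistic tables and
ground-truth test cases so the entire method can be exercised without any
planning system. See `vignettes/secondary-mu-model.Rmd` for the full account,
including known limitations of the cuboid approximation.

## Worked example

```r
library(pbsmu)

cfg  <- toy_model_config()          # analytic stand-in for a TPS beam model
fset <- generate_factor_set(cfg)    # OF / DF / AGF tables + references

# a synthetic pelvis-like beam: ellipsoid target, lateral field, 15 cm deep
case <- generate_case(
  list(shape = "ellipsoid", size = c(3, 2.5, 3.5), center_depth_cm = 15,
       gantry_deg = 90, site_label = "pelvis"),
  cfg, seed = 42)

res <- check_case(case, fset)       # measure -> cuboid -> factors -> MU
```

This prints (via the result fields):

```
volume 110.2 cm^3 | BEV area 27.5 cm^2 | SOBP width 4.01 cm | range 17.00 cm
OF 0.1346  DF 1.0243  AGF 1.0000
MU 1450.3 vs TPS 1408.2 -> +2.99%
```

Reading: the 110 cm³ ellipsoid seen from gantry 90° projects 27.5 cm², so
the equivalent cuboid is 4 cm thick along the beam with its distal face at
17 cm water-equivalent depth. The factor product converts the 200 cGy
prescription into 1450 MU, 3% above the toy planning system's ground truth —
the typical magnitude (and sign) of the cuboid approximation on a curved
target before the final measured-dose calibration is applied.

Batch use, table generation and case generation are also exposed on the
command line (`inst/scripts/mucheck`):

```sh
mucheck gen-factors --out tables/
mucheck gen-cases --n 40 --seed 1 --out cases/
mucheck batch --cases cases/ --factors tables/ --report report.csv
mucheck calc --case cases/case_001.json --factors tables/ --mu-tps 1400 --out result.json
```

Exit codes: 0 success, 2 validation error, 3 when a table lookup was clamped
to its boundary and `--strict` was given.

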