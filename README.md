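# crtscan

Timescale selection for continuous residence times from passive acoustic
telemetry.

## What problem this solves

Fixed acoustic receivers log discrete detections of tagged animals.
Estimating site fidelity means converting those detections into
**continuous residence times (CRTs)**, which requires a **maximum blanking
period (MBP)**: the largest gap between consecutive same-receiver
detections still counted as continuous presence (a detection at another
receiver always ends the residence, whatever the elapsed time). Detection
gaps come both from instrumental noise (transmission collisions, ambient
noise) and from real behavior (excursions out of range), so any fixed,
conventional MBP silently decides which of these gets absorbed into a
"residence".

crtscan treats the MBP as a scanned variable

    MBP_n = n * delta_MBP,  n = 1..N,

builds the CRT set at every grid value, forms the empirical survivor
function of CRT durations S_MBP(t) (fraction of CRTs strictly longer than
t), regrids the curves by gap-limited linear interpolation (step `dt`,
spans wider than `t_max` discarded), and compares consecutive grid values
through the renormalized sum of squared residuals

    rSSR(MBP_n) = (1/T) * sum_i [ S_{MBP_n}(t_i) - S_{MBP_n+delta}(t_i) ]^2,

summed over the T grid points where both curves are defined. The smallest
MBP beyond which the profile sits on its terminal plateau is the
convergence timescale **MBP\*** — the natural processing timescale: below
it, residence times still depend on the processing choice; beyond it they
are insensitive to the gaps caused by noise (or, at coarser grids, by
short behavioral excursions).

The package also includes the discrete-time stochastic simulator used to
validate the scan: independent fish joining/leaving an array of receivers
(constant or sigmoidally time-dependent rejoining probability) with
Bernoulli detection noise. It doubles as a synthetic detection-log
generator. Intended users are movement ecologists working with passive
acoustic telemetry (or any discrete resighting records) who need a
defensible, data-driven MBP.

## Worked example

A small synthetic detection log ships with the package (6 fish, 3
receivers, 4,000 steps, detection probability 0.25 per step of presence —
generated by the package's own simulator):

```r
library(crtscan)

f  <- system.file("extdata", "synthetic_detections.txt", package = "crtscan")
dt <- read_detections(f, format = "supplementary", time_unit = "steps")
dt
#> detection_table: 4610 detections, 6 animals, 3 receivers [time in steps]
#>   time range: 3 .. 3999

res <- run_scan(dt, mbp_grid(10, 15), grid_step = 1, t_max = 100)
head(as.data.frame(res$profile), 8)
#>   mbp mbp_next         rssr n_overlap
#> 1  10       20 7.149510e-02       238
#> 2  20       30 2.206311e-03       498
#> 3  30       40 1.901919e-03       550
#> 4  40       50 1.471901e-04       550
#> 5  50       60 9.275564e-05       550
#> 6  60       70 3.130054e-05       550
#> 7  70       80 3.622054e-05       550
#> 8  80       90 0.000000e+00       550
res$mbp_star
#> [1] 60
```

Read: the pair (10, 20) compares survival curves whose CRTs are still
shredded by detection noise (rSSR ~ 7e-2 over 238 jointly defined grid
points); by MBP = 60 steps the curves have stopped changing (rSSR at the
profile floor, here exactly 0 from MBP = 80 on), so residence times built
with any MBP ≥ 60 steps no longer depend on the blanking choice. CRTs at
the selected timescale:

```r
build_crts(dt, mbp = 60)
#> crt_set: 144 CRTs (mbp = 60 steps), 6 animals
#>   durations: min 0, median 87.5, max 716
```

`plot(res$profile, log = "y")` shows the profile in the usual semi-log
form. For field data in seconds, `scan_presets()` provides the
`fine` (MBP 10–120 min) and `diel` (2–48 h) parameterizations, and
`scenario_presets()` the three validation scenarios of the simulator.

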