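# mrpat: mid-range proton arc therapy planning

Proton arc therapy delivers pencil-beam-scanning spots from many gantry
angles, but stacking every usable energy layer at every angle makes
delivery slow (each within-angle energy switch costs ~0.6 s) and parks
high-LET Bragg peaks near target boundaries, where range errors translate
into biological hot spots in normal tissue. `mrpat` implements a mid-range
planning strategy for this problem: at each control point of the arc it
selects the **single** energy layer whose Bragg peak sits at the
water-equivalent mid-point of the target along that beam direction,

> R(θ) = median over target-intersecting spot rays of R_p + α (R_d − R_p),  α = ½,

where R_p and R_d are the proximal/distal target edges in water-equivalent
path length (WEPL) along each ray. One layer per angle eliminates
within-angle energy switching entirely (ELST = 0 in the delivery-time
model TBD = SST + SSWT + ELST + GRT), and mid-range placement confines
range uncertainty — and the elevated LET_d/RBE at the end of range — to
the target interior. α = 1 reproduces distal-edge tracking for comparison.

The package is a complete planning toolkit for synthetic phantoms:

- voxelized RSP phantoms (elliptical body, C-shaped target around a
  central OAR) plus NRRD I/O for images and structure label maps;
- exact Siddon WEPL tracing and per-ray target range intervals;
- an analytic Bortfeld-type pencil-beam dose engine with a track-LET model
  and dose-averaged LET_d accumulation (a documented substitution for
  Monte Carlo transport — orderings and counting claims are the reliable
  surface, not absolute clinical magnitudes);
- McNamara variable-RBE weighted dose (p0 = 0.99, p1 = 0.36, p2 = 1.101,
  p3 = −0.0039; (α/β)ₓ = 10 Gy target, 3 Gy elsewhere);
- nonnegative spot-weight optimization with quadratic objectives and D95%
  normalization;
- DVH, D_x% and 2-percentile hotspot metrics;
- the eight-scenario robustness evaluation (±3% stopping power, ±3 mm
  shifts) with frozen weights;
- delivery-time accounting and full-range-arc / two-beam-IMPT comparator
  strategies.

See `vignettes/midrange-arc-planning.Rmd` for the models, assumptions,
parameter defaults and limitations.

## Worked example

The default configuration reproduces the study conditions of the shipped
ellipse phantom (20 Gy to 95% of the PTV in 10 fractions, 71-control-point
arc, 3 mm spots, 2 mm voxels):

```r
library(mrpat)

res <- run_pipeline(run_config(strategy = "mrpat"), out_dir = "out")
res$metrics
#>   structure        D98      D50      D2 LETd_2pc DRBE_2pc
#> 1      body  0.7771765  1.91245 21.3324 3.069961 23.07807
#> 2       ptv 19.2820000 21.49444 22.9080 4.162538 25.00187
#> 3       oar  0.0337500  1.25000  4.9450 4.983861  6.24666
#> 4      ring  0.5013333 10.36667 19.8180 4.103129 22.85651
res$timing
#> MU 2.77 | ELs 71 | spots 5379
#> SST 0.07 s + SSWT 10.62 s + ELST 0.00 s + GRT 390.50 s = TBD 401.19 s

body_only <- res$structures$masks$body & !res$structures$masks$ptv
hotspot_percentile(res$dose_let$letd, body_only, 2, valid = res$dose_let$valid)
#> [1] 2.493191
```

Reading the output: the plan uses exactly 71 energy layers (one per
control point; a full-range arc on the same phantom needs 2761), the PTV
receives the prescribed coverage after D95% normalization (D98 ≈ 19.3 Gy,
D2 ≈ 22.9 Gy), the central OAR is spared (median ≈ 1.3 Gy), and the
2-percentile LET_d inside the target (≈ 4.2 keV/µm) exceeds that of the
surrounding body (≈ 2.5 keV/µm excluding the target): the high-LET region
is concentrated in the target. ELST is identically zero — the strategy's
defining delivery property; total beam-on time is dominated by one gantry
rotation. `out/` receives NRRD grids (dose, LET_d, RBE-weighted dose), the
plan JSON, DVH/metric CSVs and a run report with the config hash; rerunning
the same config reproduces all outputs bit-identically.

A thin command-line front end wraps the same pipeline:

```sh
Rscript inst/cli/mrpat.R plan --config cfg.yaml --strategy mrpat --out out/
Rscript inst/cli/mrpat.R compare --config cfg.yaml   # mrpat vs fullarc vs impt
```

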