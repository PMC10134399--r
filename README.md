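# microvasq

Morphometric quantification of tumor microvasculature from contrast-free
ultrasound microvessel imaging.

High-definition microvasculature imaging (HDMI) separates slowly varying
tissue clutter from decorrelating blood signal in high-frame-rate
ultrasound and renders sub-millimeter vessels without contrast agents.
Because malignant lesions grow vascular beds that are denser, more
branched and more tortuous than benign ones, the *shape* of the recovered
vessel network is diagnostic. `microvasq` implements the full
quantification chain for radiology and biomedical-imaging researchers:

- **Clutter filtering and image formation** — SVD filtering of the
  slow-time IQ ensemble on its Casorati matrix (pixels × frames),
  power-Doppler integration, top-hat background equalization, multiscale
  Hessian (Frangi-type) vessel enhancement.
- **Lesion ROI handling** — binary masks with a 10 mm perilesional
  dilation (disk element, clipped at image borders).
- **Vessel segmentation** — thresholding (fixed or Otsu), small-object
  removal and hole filling, topology-preserving thinning, and a
  segment/branch-point graph with distance-transform radii.
- **Nine skeleton biomarkers** — vessel density (VD), segment count (NV),
  branch-point count (NB), mean/max distance-metric tortuosity
  (τ_mean, τ_max = arc length / chord length per segment), mean diameter
  (D_mean), box-counting fractal dimension (FD), mean Murray's-law
  deviation (MD_mean = |d_p³ − d₁³ − d₂³| / d_p³ per bifurcation), and
  mean bifurcation angle (BA_mean, daughter–daughter convention).
- **Group statistics** — mean ± SD summaries and two-sided Wilcoxon
  rank-sum screening at α = 0.05 (exact enumeration for m + n ≤ 20, an
  Edgeworth-corrected normal approximation beyond).
- **Synthetic ground truth** — a vascular-tree generator with exact
  per-segment tortuosity, diameters, bifurcation angles and counts;
  rasterization; a slow-time IQ simulator with rank-limited clutter; and
  two-group cohort emulation at the 10-benign vs 19-malignant study
  design, so every stage is testable with no external data.

## Worked example

```r
library(microvasq)

co  <- generate_cohort(cohort_spec(seed = 42))        # 10 benign + 19 malignant images
res <- run_pipeline(co, pipeline_config(dilation_mm = 0))
res$stats[c("metric", "mean_a", "mean_b", "p", "significant")]
#>        metric      mean_a     mean_b            p significant
#> 1          VD  0.06249186  0.1245688 1.451271e-05        TRUE
#> 4          FD  1.47018650  1.5488742 3.159886e-04        TRUE
#> 5          NB  3.00000000  7.1052632 8.345851e-06        TRUE
#> 6          NV  7.00000000 16.2105263 8.345851e-06        TRUE
#> 8     tau_max  1.01874575  1.1474430 1.451271e-05        TRUE
#> ...
```

`mean_a`/`mean_b` are the benign and malignant group means; `p` is the
two-sided rank-sum p-value. In this simulated cohort the malignant-like
group has more segments (NV 16 vs 7 at the median), more branch points,
higher tortuosity and higher fractal dimension — the malignant effect
directions the biomarkers are designed to detect.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/hdmi.R run --simulate --seed 1 --out hdmi_out
Rscript inst/cli/hdmi.R quantify --image mv.tif --mask mask.png --pixel-size-mm 0.1 --out out
Rscript inst/cli/hdmi.R stats --in out/metrics.csv --contrast benign_vs_malignant
```

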