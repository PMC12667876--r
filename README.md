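# punctaratio

Quantification of fluorescent lipid-biosensor recruitment to organelle
membranes in time-lapse confocal movies, with ground-truth synthetic data
and one-phase kinetics fitting.

## The problem

Low-abundance signalling lipids (PI(3,5)P₂, PI3P, …) are imaged through
biosensors: fluorescently tagged lipid-binding domains that sit on a
membrane while the lipid is present and fall back into the cytosol when
it is not. A typical experiment images a cell every 30 s, treats it after
2 min of baseline (a kinase inhibitor such as apilimod, or
rapamycin-induced FKBP/FRB recruitment of an enzyme), and asks how fast
the biosensor leaves or joins a membrane compartment.

`punctaratio` turns such movies into numbers, for cell biologists who
would otherwise script this in FIJI:

1. **Segmentation** of the compartment from a membrane-marker channel
   (LAMP1, Rab5, dextran, mito-anchor) by a multiscale wavelet product:
   Gaussian blurs at 1–4× the fluorophore's Airy-disc size
   (r = 1.22λ/2NA), successive subtraction into band-pass planes,
   pixel-wise multiplication, a threshold at 3× the SD of the original
   frame, and a 1–2 cycle dilation.
2. **Ratio metric** per frame:
   mean biosensor intensity over (mask ∩ cell ROI) ÷ mean over the whole
   cell ROI, after subtracting a background level of 1.5× the modal
   intensity (clamped at zero). Z-stacks are first averaged over their
   11 central slices.
3. **Aggregation**: grand mean across experiments (cells averaged within
   each experiment first), SEM across experiments.
4. **Kinetics**: constrained least-squares fit of
   `y = plateau + (y0 − plateau)·exp(−K(t − t0))` with K > 0, reporting
   τ = 1/K, its 95% CI (delta method on the asymptotic variance of K, or
   profile likelihood), R², and DF = n − 3.

Because such movies are rarely deposited, the package includes a seeded
synthetic-movie generator (`synthetic_scene()`, `render_movie()`,
`write_fixture_suite()`) producing multi-channel TIFF movies with
ground-truth masks, enrichment curves and kinetic parameters, on which
every stage of the pipeline is validated.

## Worked example

Simulate an inhibitor-style experiment (baseline ratio 2.0 decaying to
1.1 with τ = 9.5 min), segment it, extract the trace and fit the decay:

```r
library(punctaratio)
scene <- preset_scene("decay", seed = 101, n_frames = 64)
movie <- render_movie(scene)
masks <- segment_movie(movie$stack, "marker", scene$optics)
roi   <- auto_cell_roi(movie$stack, "biosensor")
trace <- extract_trace(movie$stack, masks, roi, "biosensor",
                       cell_id = "cell1", experiment_id = "exp1")
head(trace[, c("time_min", "ratio", "mask_area_px")], 5)
#>   time_min    ratio mask_area_px
#> 1      0.0 1.833622         8727
#> 2      0.5 1.833510         8727
#> 3      1.0 1.832413         8734
#> 4      1.5 1.833858         8728
#> 5      2.0 1.837940         8717

fit <- fit_one_phase(trace = trace, model = "decay")
fit
#> One-phase decay fit (K constrained > 0)
#>   y0 = 1.836  plateau = 1.105  K = 0.1006 /min
#>   tau = 9.941 min, 95% CI [9.831, 10.05] (asymptotic)
#>   R2 = 0.9998, DF = 57, n = 60
```

The measured baseline sits at ~1.83 rather than the true 2.0 and τ comes
back at 9.94 rather than 9.50: the wavelet mask is wider than the true
vesicle outlines and modal background subtraction shifts both means, a
faithful rendition of what the real workflow measures. With the
ground-truth masks and noise disabled the extracted trace matches the
analytic enrichment curve to machine precision (see the test suite).

`plot(fit)` draws the data, fitted curve and CI band; `summary(fit)`,
`coef(fit)`, `predict(fit)`, `residuals(fit)` and `simulate(fit)` behave
as for any R model object.

The same pipeline runs from the shell over TIFF movies
(`inst/cli/punctaratio`):

```sh
Rscript inst/cli/punctaratio simulate --out fixtures --seed 1
Rscript inst/cli/punctaratio run --movie fixtures/decay.tif --out results
```

which writes `traces.csv` (tidy per-cell traces), `aggregate.csv`
(grand mean ± SEM), `fits.json` (all fit parameters) and a run manifest,
each stamped with the configuration hash; identical inputs yield
byte-identical outputs.

## Package layout

- `R/optics.R`, `R/wavelet.R` — Airy-scale computation and the
  wavelet-product segmentation chain
- `R/ratio.R` — projection, modal background, frame ratio, traces,
  grand mean
- `R/fit.R` — `fit_one_phase()` and its S3 methods
- `R/scene.R`, `R/kinetics-spec.R` — synthetic scenes with ground truth
- `R/image-stack.R`, `R/io.R`, `R/pipeline.R` — containers, TIFF/CSV/JSON
  I/O, configuration and the `cmd_*` pipeline stages
- `vignettes/biosensor-ratio-kinetics.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical decisions, limitations
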