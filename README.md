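# speckperf

Speed-resolved microcirculatory perfusion, in absolute units, from
multi-exposure laser speckle contrast.

## What it does and for whom

Laser speckle contrast imaging (LSCI) maps skin blood flow from the motion
blur of laser speckle, but a single exposure time yields only a relative
index: static scattering, multiple Doppler shifts and the shape of the red
blood cell (RBC) speed distribution all confound one contrast value.
Multi-exposure LSCI (MELSCI) records contrast at seven exposure times
(1–64 ms), constraining the full decorrelation curve.

`speckperf` is for researchers in biomedical optics and microcirculation
imaging who want to move from relative speckle indices to physiological
quantities. It implements a simulation-trained inverse method:

1. **Forward physics.** Monte Carlo photon transport in a randomized
   three-layer skin model (bloodless epidermis, 0.2 mm upper dermis,
   semi-infinite lower dermis) produces joint per-layer path-length
   distributions. The optical Doppler spectrum is composed from a
   Gegenbauer-kernel single-shift spectrum (anisotropy 0.991 at 780 nm),
   vessel-packaged compound-Poisson shift counts, Beer–Lambert absorption
   with the vessel-packaging correction, and an empirical biological-zero
   component. The Wiener–Khinchine theorem converts the spectrum to the
   field autocorrelation `g¹(τ)`, and

   K²(T) = (2β/T) ∫₀ᵀ |g¹(τ)|² (1 − τ/T) dτ

   gives multi-exposure contrast, to which a correlated measurement-noise
   model is added.

2. **Inverse model.** A 7–25–3 tanh network maps squared contrast `K²(T)`
   to perfusion P[v_min, v_max] = ∫ v·c_RBC(v) dv in the bands 0–1, 1–10
   and >10 mm/s (%RBC × mm/s), trained with a total-perfusion-weighted MSE,
   early stopping and restart selection, and applied per pixel of a
   contrast image stack.

The methods vignette (`vignettes/speed-resolved-perfusion.Rmd`) documents
every model component, parameter distributions, numerical choices and
limitations.

## Worked example

```r
library(speckperf)
cfg <- speckperf_config()
cfg$mc$n_photons <- 5e4            # quick-look scale
tab <- run_mc_grid(cfg, seed = 1)  # ~25 s

m <- sample_tissue_model(cfg)
fw <- forward_contrast(m, tab, cfg)
print(fw$contrast)
print(fw$perfusion)
```

```
Multi-exposure speckle contrast (noise-free)
   1ms    2ms    4ms    8ms   16ms   32ms   64ms
0.9037 0.8561 0.8128 0.7817 0.7627 0.7521 0.7464
Speed-resolved perfusion [%RBC x mm/s]
  0-1 mm/s: 0.0259   1-10 mm/s: 0.0723   >10 mm/s: 0.0000   total: 0.0982
```

This model has a low blood fraction (~0.2%RBC in the upper dermis) moving
at ~1 mm/s: contrast decays from 0.90 at 1 ms toward a static floor of
~0.75 set by the unshifted light, and true perfusion is 0.098 %RBC·mm/s,
mostly in the 1–10 mm/s band.

Training and evaluating a (small, demonstration-scale) network:

```r
pool <- melsci_dataset(4000, tab, cfg, seed = 2, split = "pool")
evds <- melsci_dataset(2000, tab, cfg, seed = 3, split = "eval")
cfg$ann$restarts <- 2
net <- perfann(pool, cfg, seed = 4)
evaluate_perfann(net, evds)
```

```
       component    wmape     mape        r2
p_low      p_low 17.70470       NA 0.3473913
p_mid      p_mid 34.45620       NA 0.6083044
p_high    p_high 22.80763       NA 0.4427237
         p_total       NA 57.65309 0.6026975
```

`wmape` is the per-band absolute error normalized by each sample's *total*
true perfusion (so a small band is not penalized for being small), `mape`
is the plain relative error of total perfusion, and `r2` the explained
variance. Errors shrink at the default study scale (10,000-model pool; see
below) and shrink further with larger corpora.

Per-pixel imaging on a synthetic two-region scene (slow 0.5 mm/s vs fast
10 mm/s region):

```r
labels <- matrix(1L, 24, 24); labels[, 13:24] <- 2L
scene <- list(labels = labels,
              regions = list(list(c_blood = 0.55, mean_speed = 0.5),
                             list(c_blood = 0.55, mean_speed = 10)))
fx <- synth_image_fixture(scene, tab, cfg, seed = 5)
img <- predict_image(net, fx$stack)
roi_stats(img, labels == 2)
```

```
Perfusion image 24 x 24; median total 3.439 %RBC mm/s (1.0 ms/frame)
  component       mean         sd        cv
1     p_low 0.05451009 0.01886891 34.615444
2     p_mid 3.36570358 0.07201698  2.139730
3    p_high 3.62710560 0.10920998  3.010940
4   p_total 7.04731927 0.18093130  2.567378
```

In the fast region the network assigns most perfusion to the >10 mm/s and
1–10 mm/s bands, with the 0–1 mm/s band an order of magnitude smaller —
the speed-resolved separation that single-exposure LSCI cannot provide.

A thin command-line interface (`inst/cli/speckperf`) exposes the pipeline
as subcommands (`simulate-grid`, `gen-dataset`, `train`, `evaluate`,
`sweep`, `synth-image`, `predict-image`, `demo`) with `--config` (YAML),
`--seed` and `--out`.

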