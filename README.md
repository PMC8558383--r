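# thzfb — terahertz spectroscopy and imaging for foreign-body detection

`thzfb` is an R package for detecting low-density organic foreign bodies —
insect fragments — buried in plant-material matrices such as finishing tea,
using terahertz time-domain spectroscopy (THz-TDS) and time-of-flight
reflection imaging. X-ray screening relies on density contrast and misses
organic inclusions; THz pulses, in contrast, are strongly absorbed by the
fat, protein and chitin of insect tissue and pick up a measurable extra
time of flight through denser material, so contaminated samples show a
weaker, delayed pulse.

The package implements the full desk study around that contrast mechanism:

* **Spectra.** A recorded pulse E(t) is converted to its one-sided
  amplitude/phase spectrum Ẽ(ω) = A(ω)·e^(−iφ(ω)) by FFT, replicates are
  averaged, and the analysis is restricted to the discriminative band
  (0.3–1.0 THz by default).
* **Baseline correction.** Scattering at medium boundaries adds a slow
  baseline drift. Three penalized least-squares estimators remove it, all
  built on a shared banded Whittaker solver for
  min_z Σᵢ ωᵢ(yᵢ−zᵢ)² + λ‖Dz‖²:
  * **AsLS** — asymmetric least squares: iterated smoothing with weights
    p above the baseline and 1−p below (`asls()`);
  * **AirPLS** — adaptive iteratively reweighted penalized least squares:
    weights zeroed at peak points and set to exp(t(yᵢ−zᵢ)/|d|) below the
    baseline, stopping when |d| < 0.001·|y| (`airpls()`);
  * **BEADS** — sparsity-assisted joint decomposition y = x + f + w into
    sparse peaks, low-pass baseline and noise via a banded high-pass
    filter H = BA⁻¹ and majorization–minimization (`beads()`).
* **Discrimination.** K-nearest-neighbour (Euclidean, majority vote) and
  two-class PLS-DA (NIPALS latent components on a 0/1 dummy response,
  threshold 0.5) classifiers, fitted on a calibration population of 125
  samples and reported on a held-out prediction population of 51, with
  misclassification counts and half-up two-decimal accuracy percentages.
* **Imaging.** Per-pixel grayscale (peak reflectance) and time-of-flight
  delay maps from an (x, y, t) reflection cube, grayscale windowing to
  reveal low-contrast structure, and shape-gated blob detection
  (8-connected components filtered on area, eccentricity, solidity).
* **Synthetic data.** Measured spectra for this problem are not publicly
  deposited, so a seeded phenomenological generator supplies traces,
  labeled datasets and image cubes with ground-truth baselines, labels
  and masks, emulating the observed class contrast (insect pulses
  attenuated ×0.6 and delayed +0.8 ps).

## Worked example

Run the complete discrimination study on the default synthetic
conditions (88 tea + 88 contaminated tablets, 125/51 stratified
calibration/prediction split, drift ≈ 15 % and noise 1 % of the tea
pulse peak):

```r
library(thzfb)
report <- run_study(thzfb_config(seed = 1))
print(report$table, row.names = FALSE)
#>   model correction n_miscal_cal acc_cal_pct n_miscal_pred acc_pred_pct
#>     KNN         No            0         100             0          100
#>     KNN     AirPLS            0         100             0          100
#>     KNN       AsLS            0         100             0          100
#>     KNN      BEADS            0         100             0          100
#>  PLS-DA         No            0         100             0          100
#>  PLS-DA     AirPLS            0         100             0          100
#>  PLS-DA       AsLS            0         100             0          100
#>  PLS-DA      BEADS            0         100             0          100
```

Each row is one cell of the model × correction grid: misclassified
counts and accuracies for both populations. Under the default synthetic
contrast the two classes are cleanly separable in the 0.3–1.0 THz band,
so every cell reaches 100 % here; the corrections matter when drift is
stronger or the contrast weaker (see the methods vignette).

The imaging arm recovers two implanted worm-shaped foreign bodies from a
96 × 96 × 512 reflection cube (0.2 mm raster step):

```r
im <- run_imaging(thzfb_config(seed = 1))
im$detection
#> <detection_result> 2 component(s), 2 accepted (thr 0.6959)
im$detection$components
#>   label centroid_row centroid_col area_px eccentricity  solidity accepted
#> 1     1     30.40104     30.15104     192    0.9134601 0.9600000     TRUE
#> 2     2     63.98492     61.84925     199    0.8337656 0.9900498     TRUE
round(im$iou, 3)
#> [1] 0.949
```

Both blobs pass the shape gates (elongated but compact), and their
union overlaps the true implant masks with IoU 0.95. The delay map shows
the insect pixels arriving ≈ 0.76 ps later than the tea background —
the programmed 0.8 ps time-of-flight contrast within one sample
interval.

Individual stages are ordinary functions: `generate_trace()`,
`fft_spectrum()`, `asls()`/`airpls()`/`beads()`, `knn_fit()`,
`plsda_fit()`, `evaluate()`, `delay_map()`, `detect_foreign_bodies()`.
A thin command-line wrapper lives in `inst/scripts/thzfb.R`
(`Rscript thzfb.R study --seed 1 --out out/`).

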