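# bbsynth

Vessel-suppressed ("black-blood") brain MRI synthesis from
contrast-enhanced 3D gradient-echo (CE 3D-GRE) volumes, for people who
work on automated detection of brain metastases.

On post-contrast GRE images both metastases and blood vessels are
bright, so small cortical lesions hide among vessels; black-blood (BB)
sequences suppress the blood pool but cost an extra scan and still leave
residual vessel signal. `bbsynth` implements the full pipeline for
learning BB-like contrast directly from GRE:

* **Auto-labelling** — the core algorithm: from a registered GRE/BB
  pair, vessels are extracted from the GRE volume in two passes
  (fuzzy c-means tissue clustering + seeded 3D region growing, then
  difference-image thresholding `(intermediate − BB) > τ`) and replaced
  by the co-located BB values, with a dilated one-voxel ring blended as
  `w·BB + (1−w)·GRE`. The result is a *synthetic BB* label volume:
  vessels dark, metastases and parenchyma untouched.
* **bbnet** — a 3D residual CNN (3×3×3 kernels, batch norm + ReLU,
  single-map final layer, elementwise input addition) trained on
  co-located 31×31×31 patches with Adam, MSE loss, gradient clipping at
  global norm 1 and a step learning-rate schedule; whole-volume
  inference is tiled with receptive-field margins. The conv engine is
  compact single-precision C++ (im2col + BLAS GEMM).
* **Phantoms** — a 3D digital head phantom (three vessel caliber
  classes, blob metastases 1.6–12 mm, two tissue contrasts, noise, BB
  blur, imperfect suppression) with exact voxel ground truth, standing
  in for patient studies.
* **Evaluation** — the vessel suppression ratio
  `R_s = SI_WM / (0.5 (SI_WM + SI_vessel))` over a nine-ROI,
  three-vessel-type scheme (2 = complete suppression, 1 = vessels as
  bright as white matter); per-lesion / per-patient detection
  sensitivity with false-positive counts against phantom truth; and
  weighted kappa for rater agreement.

## Worked example

Generate a phantom pair, auto-label it, and measure suppression:

```r
library(bbsynth)

spec  <- phantom_spec(seed = 7)          # 96^3, 1 mm iso, 8 lesions
truth <- generate_truth(spec)
pair  <- render_pair(truth, spec)

brain <- extract_brain(pair$gre)
res   <- synthesize_bb(study_pair(pair$gre, pair$bb, brain,
                                  registered = TRUE))

rois <- place_phantom_rois(truth)
suppression_report(list(GRE = pair$gre, BB = pair$bb,
                        SYNTH = res$synth), rois)
```

```
  modality vessel_type     si_wm  si_vessel       r_s
1      GRE           1 0.5501353 0.92508713 0.7458337
2      GRE           2 0.5501353 0.92561503 0.7455669
3      GRE           3 0.5501353 0.84134906 0.7907172
4       BB           1 0.4784222 0.09258561 1.6757116
5       BB           2 0.4784222 0.10120891 1.6507817
6       BB           3 0.4784222 0.18889741 1.4338622
7    SYNTH           1 0.5501353 0.09583279 1.7032894
8    SYNTH           2 0.5501353 0.10333996 1.6837219
9    SYNTH           3 0.5501353 0.19294248 1.4806937
```

Reading the table: on GRE every vessel class is brighter than white
matter (`r_s < 1`); on both the acquired BB volume and the auto-labelled
synthetic BB volume the ratios climb toward 2 (vessels pushed to
background) while the white-matter signal is preserved. Type 3 (small
cortical branches) is the hardest class for every modality, exactly as
on the ROI ordering for real vessels. Lesion preservation is checked the
same way:

```r
detect_lesions(res$synth, truth)
#> <detection> TP 7 / FN 1 / FP 0  sensitivity 87.5%  (>=2 mm: 100.0%)
```

The one miss is a 1.99 mm lesion sitting at the single-voxel limit of
the call rule; every lesion at or above 2 mm survives auto-labelling.
Training the desk-scale network on such pairs and running inference on
held-out phantoms is shown in the methods vignette
(`vignettes/blackblood-methods.Rmd`) and exercised end-to-end by the
test suite.

## Command-line use

A thin CLI over the package functions ships in `inst/cli/bbsynth`
(`phantom`, `autolabel` subcommands) for shell pipelines on NIfTI
volumes; training and inference are R-level APIs (`train_bbnet()`,
`infer_bbnet()`).
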