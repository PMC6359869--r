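# microvasq

Quantification of bulbar-conjunctival microvessel density from paired
imaging modalities.

## The problem

The superficial microvessels of the bulbar conjunctiva can be imaged by an
optical-coherence-tomography angiography (OCTA) scanner — a small, coarse,
speckle-dominated en-face angiogram in which flowing blood is *bright* — and
by a functional slit-lamp biomicroscope (FSLB) — a large, fine, vignetted
photograph in which vessels are *dark* against the sclera. `microvasq`
reduces either image to a one-pixel-wide vessel skeleton over a fixed
physical analysis window and summarizes it with two readouts:

* **density percent** — skeleton pixels as a percentage of the window, a
  calibre-independent proxy for vessel length per area;
* **Dbox** — the box-counting fractal dimension of the skeleton
  (slope of log N(s) vs log 1/s over 15 box sizes from 104 px down).

The processing chain is: geometry normalization with physical
field-of-view (FOV) bookkeeping (resample to 1024 px width, crop the central
6.581 × 6.581 mm², resample to a 768 × 768 working grid) → for photographs,
green-channel grayscale, contrast-limited adaptive equalization, and
morphological background removal → shared segmentation (global equalization,
Gaussian blur σ = 4 px, FFT bandpass 3–40 px, Otsu threshold, Zhang–Suen
skeletonization) → quantification. A seedable synthetic generator renders
one ground-truth vascular network through both modality models, and paired
statistics (paired *t* / repeated-measures *F*, Pearson, Bland–Altman limits
of agreement) compare the modalities across a cohort. See the
`microvasq-methods` vignette for the model and every default's rationale.

## Worked example

Simulate a network, render it as an angiogram-like image, and run the full
pipeline:

```r
library(microvasq)

net <- generateNetwork(syntheticConfig(seed = 5, nRoots = 30L))
img <- renderModality(net, modalityParams("octa_like"), seed = 6)
img
#> CalibratedImage [octa_like]: 304 x 304 px, FOV 8.775 x 8.775 mm, 28.87 um/px

res <- runSingle(img, subject = 1, eye = "OD")
res$record
#>   subject eye  modality density_percent     dbox r_squared
#> 1       1  OD octa_like         1.84394 1.126904 0.9888681

res$skeleton
#> SkeletonMask: 768 x 768 px, 10876 foreground (1.84%)
```

A full paired study — 10 subjects, two eyes each, every eye rendered through
both modality models and pushed through the pipeline (about 4 minutes on one
CPU):

```r
report <- runPairedStudy(nSubjects = 10, seed = 42)
```

At the package defaults this gives, per modality (mean ± SD over 20 eyes):

| readout | `octa_like` | `fslb_like` | paired t | p |
|---|---|---|---|---|
| density % | 2.198 ± 0.520 | 2.931 ± 0.337 | −10.24 | 3.6 × 10⁻⁹ |
| Dbox | 1.169 ± 0.063 | 1.249 ± 0.034 | −7.65 | 3.2 × 10⁻⁷ |

The angiogram-like modality reads lower on both metrics despite imaging the
same networks: its coarse grid and flow-detection floor lose the finest
calibres that the photograph retains. Within each device the two readouts
track each other closely (Pearson r = 0.992 and 0.993).

## Command line

A thin CLI over the same functions ships in `inst/exec/microvasq.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "microvasq.R", package = "microvasq"))')
Rscript "$CLI" simulate --seed 5 --modality both --out sim/
Rscript "$CLI" run      --image sim/octa_like.png --csv records.csv
Rscript "$CLI" study    --subjects 10 --seed 42 --out study/
Rscript "$CLI" compare  --csv study/density_records.csv --out report.json
```

Subcommands `prep`, `preprocess`, `segment`, and `quantify` expose the
individual stages; every flag defaults to the package defaults.

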