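# discmorph

Computer-assisted morphometry of the internal composition of lumbar
intervertebral discs (IVD) on transverse T2-weighted images.

Finite-element models of spinal loading need to know not just the outer
disc geometry but how much of the disc's cross-section the nucleus
pulposus (NP) occupies — the **NP-to-CSA ratio**,

```
Ratio = 100 · CSA_NP / CSA_IVD
```

with CSA the cross-sectional area in the transverse plane. Manual tracing
of the NP is unreliable (its boundary with the annulus fibrosus is
blurred), so this package implements two computer-assisted segmentation
routes over a manually traced outer disc contour, plus the statistics
used to assess them. It is aimed at researchers in spine biomechanics and
musculoskeletal image analysis.

**What it provides**

* **Fuzzy C-means (FCM)** clustering of the disc-only image: minimize
  `J = Σ_i Σ_j u_ij^m ‖c_i − x_j‖²` subject to `Σ_i u_ij = 1`, alternating
  the centroid update `c_i = Σ_j u_ij^m x_j / Σ_j u_ij^m` with the
  membership update `u_ij = 1 / Σ_k (d_ij/d_kj)^{2/(m−1)}`; the brightest
  cluster is the T2-hyperintense nucleus.
* **Seeded region growing (RG)**: best-first aggregation of the frontier
  pixel whose gray value is closest to the running region mean
  `mean₂ = (mean₁·size + point)/(size + 1)`, while that difference stays
  within a threshold `maxdis` (default 0.06 on the normalized [0, 1]
  scale), restricted to the traced disc.
* Morphological cleanup, exact pixel-boundary contour extraction, and
  smoothing by a truncated **elliptic-Fourier** parametric curve that
  preserves the oval-to-kidney disc morphology (order 1 = best-fit
  ellipse; default order 4 admits the kidney concavity).
* A **synthetic disc-phantom generator** with exact ground-truth masks,
  so every stage is testable without scan data.
* A **statistics layer**: Pearson correlation with the interpretation
  bands used in this literature (Excellent > 0.810, Good 0.61–0.809,
  Moderate 0.410–0.609, Fair 0.210–0.409, Poor below), paired t tests,
  relative absolute error, ICC(2,1), split-plot factorial ANOVA
  (between-subject gender × within-subject spinal level) and Tukey HSD.
* A command-line front end (`exec/discmorph`) with subcommands
  `phantom`, `segment-fcm`, `segment-rg`, `refine`, `ratio`, `stats`,
  `run`.

## Worked example

```r
library(discmorph)

spec <- phantomSpec(shape = "kidney", npTargetRatio = 0.42, seed = 11)
ph <- generatePhantom(spec)
ph
#> DiscPhantom: 128 x 128 px
#>   CSA_IVD: 2974 px; CSA_NP: 1250 px; true NP-to-CSA ratio: 42.03%

res <- segmentDisc(phantomImage(ph), ivdContour(ph),
                   spacingMm = c(0.69, 0.69), seed = 11,
                   subjectId = "phantom-11", level = "L4/L5")
res$records
#>  subject_id level  gender method   csa_np  csa_ivd ratio_percent
#>  phantom-11 L4/L5 unknown    fcm 596.5533 1415.921      42.13181
#>  phantom-11 L4/L5 unknown     rg 526.0905 1415.921      37.15535
```

The FCM route recovers the true ratio (42.03%) almost exactly
(42.13%, Dice 0.999 against the true NP mask); the RG route reads about
5 points low (37.16%, Dice 0.938) because its acceptance cut sits inside
the blurred NP boundary — see the methods vignette
(`vignettes/disc-morphometry.Rmd`) for the analysis of this bias. Areas
are in mm² because a pixel spacing of 0.69 × 0.69 mm was supplied.

Reliability statistics work on paired ratio series:

```r
p <- pearsonWithBand(c(46, 40, 38, 45, 42, 39, 44, 41),
                     c(44, 39, 40, 43, 41, 38, 45, 40))
sprintf("PCC %.3f (%s)", p$pcc, p$band)
#> "PCC 0.874 (Excellent)"
```

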