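# mcetSeg

Bimodal grayscale image segmentation by **minimum cross-entropy
thresholding (MCET) with interchangeable robust mean estimators**, for
image-analysis work where a bright object (a lesion, a tumor, a cell mass)
must be separated from a darker background and where impulse noise,
outliers and partial-volume "grayness" pixels bias the classical threshold.

## The method

A threshold $t$ splits the gray-level histogram $h(i)$, $i \in [1, L]$
(1-based shifted levels, $L = 256$), into two classes with means
$\mu_1(t)$, $\mu_2(t)$. MCET picks the $t$ minimizing

$$n(t) = -\sum_{i \le t} i\,h(i)\log\mu_1(t) - \sum_{i > t} i\,h(i)\log\mu_2(t),$$

and the mask is $g = \mathbf{1}[I > t-1]$ on the raw scale. Classically the
$\mu_k$ are the arithmetic means of the histogram halves — exactly the
statistic that salt/pepper impulses and transition pixels corrupt. This
package substitutes, for both classes symmetrically, any of five mean
filters adapted to the histogram **mode vectors** (per-pixel multisets of
class levels):

| estimator | formula on a mode $v$ ($n = |v|$) | parameter |
|---|---|---|
| classical | $\sum v_j/n$ | — |
| alpha-trim | mean after dropping $d/2$ smallest and largest entries | $d/2$ |
| harmonic | $n/\sum v_j^{-1}$ | — |
| contraharmonic | $\sum v_j^{Q+1}/\sum v_j^Q$ | $Q$ |
| geometric | $\exp(\tfrac1n\sum\log v_j)$ | — |

with the exact reductions $Q{=}0 \to$ classical, $Q{=}{-1} \to$ harmonic,
$d/2{=}0 \to$ classical. The package also implements the matching
evaluation suite (region uniformity, region contrast, inter-region
disparity; Jaccard / F-score / accuracy against ground truth), a seeded
synthetic bimodal image generator with known truth, and batch sweep tools
over the standard 22-configuration estimator grid.

## Worked example

```r
library(mcetSeg)

# a 128x128 synthetic image: disk (mean 180) on background (mean 60),
# sigma 15, plus 2% salt + 2% pepper impulse noise
fx <- generateFixture(fixtureSpec(saltDensity = 0.02, pepperDensity = 0.02,
                                  seed = 42))

seg <- segmentImage(fx$image, estimatorSpec("alpha_trim", halfTrim = 50))
seg$result
#> ThresholdResult [alpha_trim:50]
#>   threshold: 98 (raw), 99 (shifted)
#>   class means (shifted): mu1 = 58.9256, mu2 = 185.2671
#>   255 feasible candidate level(s)

segmentationMetrics(fx$image, seg, fx$truth)
#>          IU        RC       IRD        JI         F       ACC
#> 1 0.9700519 0.5173843 0.7693981 0.9168019 0.9565954 0.9749756
```

The trimmed estimator recovers class means (≈59, ≈185 on the shifted
scale) close to the generating means (61, 181 shifted) despite the
impulses, places the threshold between the classes, and the mask overlaps
the ground truth at Jaccard 0.92 / accuracy 0.97. A grid comparison on the
same image:

```r
batch <- batchEvaluate(list(fx$image),
                       list("classical", "harmonic", "alpha_trim:50"),
                       truths = list(fx$truth))
sweepSummary(batch)[, c("method", "param", "JI", "ACC", "best")]
#>       method param        JI       ACC             best
#> 1  classical    NA 0.9275303 0.9784546 IU,IRD,JI,F,ACC
#> 2   harmonic    NA 0.2926355 0.3334351              RC
#> 3 alpha_trim    50 0.9168019 0.9749756
```

which also shows the harmonic mean's known failure mode: it suppresses salt
but is dominated by pepper (low) values, collapsing the threshold.

File-based runs (`runSegment()`, `runSweepReport()`, masks as {0, 255}
PNGs, metrics/summary CSVs) and a thin shell wrapper
(`inst/scripts/mcet-cli.R` with `segment`, `sweep`, `evaluate`,
`make-fixtures` subcommands) cover batch use; `writeFixtureSet()`
materializes fixture sets with `<stem>_gt.png` truths and a JSON manifest.

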