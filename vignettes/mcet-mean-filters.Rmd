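---
title: "Minimum cross-entropy thresholding with robust mean-filter estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum cross-entropy thresholding with robust mean-filter estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcetSeg)
```

## The model

Global bimodal thresholding assumes an image contains a bright object on a
darker background and seeks a single gray level $T$ such that the mask
$g(x,y) = \mathbf{1}[I(x,y) > T]$ separates the two. Minimum cross-entropy
thresholding (MCET) selects $T$ by minimizing the cross entropy between the
image and its two-class representation. Working on the histogram $h(i)$ over
*shifted* levels $i \in [1, L]$ (raw intensity $i-1$; $L = 256$ for 8-bit
data), and dropping the term that does not depend on $t$, the objective is

$$
n(t) \;=\; -\sum_{i=1}^{t} i\,h(i)\,\log \mu_1(t)
          \;-\; \sum_{i=t+1}^{L} i\,h(i)\,\log \mu_2(t),
$$

minimized over $t \in [1, L-1]$, where $\mu_1, \mu_2$ are the means of the
two histogram classes. The shift to 1-based levels is not cosmetic: the
objective takes $\log \mu$, and several estimators take $\log i$, $1/i$ or
$i^Q$, all of which degenerate at $i = 0$. Thresholds are reported back on
the raw scale as $T = t - 1$, and the mask uses strict `>` with ties going
to background.

The classical formulation estimates $\mu_k$ as count-weighted arithmetic
means of the histogram halves. That estimator is exactly what impulse noise
(salt at the top of the range, pepper at the bottom), local outliers and
partial-volume "grayness" pixels between the classes bias. The package's
central idea is to keep the MCET machinery fixed and swap the mean
estimator.

## Mode vectors and the five estimators

Each candidate $t$ splits the histogram into two *mode vectors*: the sorted
per-pixel multisets of shifted levels in $[1, t]$ and $[t+1, L]$. The
per-pixel (count-weighted) representation matters: it is what makes the
degenerate parameter settings collapse exactly onto the classical weighted
mean, and it makes zero-count levels a non-issue (they contribute nothing).

On a mode vector $v$ of length $n$ the estimators are:

| method | formula | parameter | excludes |
|---|---|---|---|
| classical | $\sum v_j / n$ | — | nothing |
| alpha-trim | mean of $v$ after dropping the $d/2$ smallest and $d/2$ largest entries; divisor $n - d$ | $d/2 \ge 0$ (pixels per end) | mixed impulse + Gaussian tails, grayness |
| harmonic | $n / \sum 1/v_j$ | — | salt, not pepper |
| contraharmonic | $\sum v_j^{Q+1} / \sum v_j^{Q}$ | finite real $Q$ | pepper for $Q>0$, salt for $Q<0$ |
| geometric | $(\prod v_j)^{1/n}$, computed as $\exp(\text{mean}\log v_j)$ | — | mild smoothing |

The same filter with the same parameter is applied to **both** modes.
Identities used throughout the tests: $Q = 0$ and $d/2 = 0$ reduce to the
classical mean, $Q = -1$ to the harmonic mean; and for any non-constant
positive mode, harmonic < geometric < arithmetic.

Trimming is *positional* on the sorted multiset — exactly $d/2$ entries per
end, duplicates notwithstanding — and $d/2$ is an absolute pixel count, not
a fraction, so appropriate trim values scale with image area. Fractional
trims are rejected rather than interpolated. $Q$ may be any finite real;
power sums are taken on shifted levels (all $\ge 1$), and candidates whose
power sums overflow are treated as infeasible rather than clamped.

## The threshold search

`findThreshold()` evaluates $n(t)$ at every $t \in [1, 255]$, not only at
occupied levels — the argmin is identical either way, but the profile is
kept at full length for inspection. A candidate is infeasible when either
class is empty, when $n_k - d < 1$ for the trim, or when power sums are
non-finite; infeasible candidates are skipped, never given sentinel values.
Ties in $n(t)$ break toward the smallest $t$, deterministically. Natural
logarithms are used throughout (the base cancels in the argmin; fixing it
makes reported objective values reproducible). Contraharmonic means are
reported unclamped, with a diagnostic flag when $\mu_1 \ge \mu_2$ at the
optimum.

Internally the sweep uses count-weighted forms (cumulative counts and
first moments over the histogram), which are algebraically identical to the
per-pixel definitions; the test suite checks both the identity (against the
mode-vector functions) and the argmin (against an independently coded
exhaustive search on pixel multisets).

## Quality metrics

Unsupervised, computed from the image and its segmentation alone:

* **Image uniformity** $1 - (\sigma_1^2 + \sigma_2^2)/Z$ with population
  variances of the two regions and $Z = (I_{\max}-I_{\min})^2/2$, clipped to
  $[0,1]$. The *sum* of variances is used deliberately: a difference of
  variances is sign-indefinite and cannot live in $[0,1]$, which is the
  stated range of all these scores.
* **Region contrast** $|\mu_1-\mu_2|/(\mu_1+\mu_2)$ — again, the sum in the
  denominator is the only normalization that is not identically $\pm 1$.
* **Inter-region disparity** compares interior contrast (max contrast to a
  same-region neighbor, averaged over the region) against exterior contrast
  (max contrast to an out-of-region neighbor, averaged over border pixels),
  with pixel contrast $|I(s)-I(t)|/(L-1)$ over the 8-connected $3\times 3$
  neighborhood, combined per region as $1 - CI/CE$ when $0 < CI < CE$, $CE$
  when $CI = 0$, else $0$, and finally averaged with region-size weights.
  The neighborhood and border definitions are the conventional ones; a pixel
  with no same-region neighbor contributes 0 interior contrast.

Supervised, given a ground-truth mask: Jaccard $tp/(tp+fp+fn)$, F-score
$2PR/(P+R)$, and accuracy. Degenerate cases (empty prediction or empty
truth) raise an "undefined metric" error instead of silently scoring 0, so
batch averages are never quietly polluted. The identity
$J = F/(2-F)$ holds algebraically and is enforced in tests.

## The synthetic generator

`generateFixture()` emulates the nuisance structure the estimators target: a
bright object (disk, rectangle or multi-disk blob) on a dark background with
Gaussian within-class noise, optional salt (255) / pepper (0) impulses at
given per-pixel densities, and an optional linear "grayness" ramp between
the class means across a band around the object boundary (ground truth
unchanged). Defaults — $128\times 128$, class means 60/180, $\sigma = 15$,
a disk of radius $0.3\,\min(h,w)$ — are the package's reference study
condition: the means sit well inside the 8-bit range with a $4\sigma$ gap
(minimal class overlap before noise), and the object occupies about 28% of
the frame, a realistic lesion-scale foreground fraction. Clipping to
$[0,255]$ precedes rounding; one integer seed drives all draws, and the
caller's RNG state is saved and restored.

What the generator does *not* emulate: MRI bias fields and Rician noise,
dermoscopy artifacts (hairs, rulers), textured backgrounds, multi-modal
histograms. Passing tests on fixtures therefore demonstrate correctness of
the machinery and its behavior under the modeled nuisances — not clinical
performance on real medical data.

`sweepGrid()` ships the 22-configuration estimator grid used by the batch
tools (classical, a flagged-unsupported lognormal comparison placeholder,
harmonic, geometric, five contraharmonic orders, thirteen trim values).

## Numerical and design choices

* Candidate range: all of $[1, 255]$; infeasible candidates skipped.
* Tie-break: smallest $t$.
* Population (divisor-$n$) variance in uniformity: regions are complete
  populations of their pixels.
* Batch rows for unsupported or failed configurations are retained with NA
  metrics and a `status` string, so row-counting contracts hold and
  averages never silently change denominator.
* The batch layer is sequential; rows are defined to be order-independent,
  so a parallel map could be substituted without changing any number.
* Problem sizes in the shipped tests (histograms of 900–1500 pixels for
  oracle comparisons, $128\times 128$ fixtures for end-to-end studies, 50
  seeded replicates) were chosen to exercise every code path at full
  statistical strength while keeping the default suite quick to run.

## A finding on noise robustness

Two facts about impulse noise and MCET emerged from the synthetic study and
are worth stating precisely, because they refine the intuitive claim that
"trimming stabilizes the threshold":

1. Under *symmetric* salt + pepper (equal densities), the classical MCET
   threshold is already nearly noise-invariant: pepper biases $\mu_1$
   downward while salt biases $\mu_2$ upward, and the two biases largely
   cancel in the argmin (mean threshold deviation ≈ 0.5 gray levels at 3% +
   3% on the reference fixtures).
2. Trimming changes the estimator itself: on truncated-Gaussian modes the
   trimmed mean differs from the arithmetic mean, and because $n(t)$ is
   flat near its minimum, the alpha-trim threshold sits several levels away
   from the classical one *even on a clean image* (4–15 levels across
   $d/2 \in [10, 110]$ here).

The robust statement that does hold, and that the test suite asserts, is
estimator-consistent: the alpha-trim threshold moves *less* between the
clean and the noisy version of the same image than the classical threshold
does (mean self-deviation ≈ 0.1 vs ≈ 0.5–0.6 levels). Comparisons that
anchor the trimmed threshold to the clean-image *classical* threshold
instead measure the estimator offset, not noise robustness, and fail for
every replicate under symmetric impulse noise.

## Limitations

* Single threshold, bimodal histograms only; no multilevel extension.
* 8-bit, 2-D, single-channel input; color and 16-bit data are rejected
  rather than converted.
* The lognormal-mean MCET variant is a placeholder configuration only.
* Unsupervised metrics reward internally uniform, well-contrasted
  partitions; they are not substitutes for ground truth.
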