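---
title: "Wavelet packet Tsallis entropy and fuzzy SVMs for pathological brain detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet packet Tsallis entropy and fuzzy SVMs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wptefsvm)
```

## The problem and the pipeline

Pathological brain detection (PBD) asks a binary question of a grayscale
brain MR slice: pathological (+1) or healthy (−1). This package implements
a compact texture-based pipeline:

1. **Wavelet packet transform (WPT).** A separable 2D filter bank splits
   the image into approximation and detail channels and — unlike the Mallat
   DWT pyramid, which re-splits only the approximation — re-filters *every*
   channel at every level. At depth $d$ this yields the full tree of $4^d$
   subbands (16 at the default $d = 2$), each downsampled by $2^d$ per
   axis, so the total coefficient count equals the pixel count.
2. **Tsallis entropy features (WPTE).** Each terminal subband is summarised
   by the Tsallis entropy of its coefficient distribution, giving a
   16-element descriptor per image.
3. **Fuzzy SVM (FSVM).** A soft-margin SVM in which every training sample
   carries a membership $s_n \in (0,1]$ scaling its slack penalty;
   samples far from their own class center are down-weighted, which caps
   the influence of outliers and mislabeled images.

Evaluation uses repeated stratified K-fold cross-validation, and the
entropic index $q$ (and penalty $C$) are chosen by grid search in an
offline phase; online prediction reuses the extraction settings frozen in
the model file.

## The wavelet packet transform

The one-level analysis step convolves a signal with a quadrature-mirror
pair — low-pass taps $h$ and high-pass taps $g_j = (-1)^j h_{L-1-j}$ — and
keeps every second output:
$$a_k = \sum_j h_j \, x_{(2k + j) \bmod n}, \qquad
  d_k = \sum_j g_j \, x_{(2k + j) \bmod n}.$$
In 2D the step is applied along columns and then rows, producing four
children per block in the fixed natural (Paley) order LL, LH, HL, HH
(first letter = vertical filter). The recursion over *all* children gives
the packet tree; over the LL child only, the DWT pyramid with $3d + 1$
blocks.

Numerical choices:

* **Boundary handling** defaults to periodic extension. For orthonormal
  taps this makes the transform an orthogonal matrix: energy is conserved
  exactly (Parseval) and `wpt_reconstruct()` inverts `wpt_decompose()` to
  machine precision — both are property-tested at $10^{-8}$. Symmetric
  extension is available for decomposition, but same-length orthogonal
  banks are not invertible under reflection, so reconstruction refuses it.
* **Non-dyadic sizes** are extended to the next multiple of $2^{level}$
  and the padding is recorded; reconstruction crops back.
* **Wavelets**: Haar (default, matching the 2-level Haar configuration the
  pipeline is designed around) and Daubechies-2. Correctness is checked
  against an explicit dense-matrix construction of the same bank.

## Entropy features

Shannon entropy $E = -\sum_k p_k \log_2 p_k$ is additive over independent
subsystems. Tsallis entropy
$$E_q = \frac{\sum_k p_k^q - 1}{1 - q}$$
generalises it with the nonextensivity index $q$ and is instead
*pseudo-additive*: $E_q(X,Y) = E_q(X) + E_q(Y) + (1-q)E_q(X)E_q(Y)$ for
independent $X, Y$ (exported as `pseudo_additivity_check()`). For $q < 1$
the entropy is subextensive ($E_q \ge$ the Shannon value in nats), for
$q > 1$ superextensive; at $q = 1$ the implementation returns the analytic
natural-log limit, so `tsallis_entropy()` is continuous in $q$. Brain
tissue texture shows long-range, self-similar structure across scales,
which is the motivation for a subextensive index; $q = 0.8$ is the
package's default and the grid `seq(0.1, 1, 0.1)` is searched when the
user asks for it.

A subband must first become a probability vector. The text this method
descends from never fixes that estimator, so two are provided:

* `"energy"` (default): $p_k = c_k^2 / \sum_j c_j^2$ — the standard
  wavelet-entropy convention, parameter-free and scale-invariant;
* `"histogram"`: an equal-width binned histogram of coefficient values
  (256 bins by default), closer to a greylevel reading.

An all-zero subband maps to a degenerate distribution (entropy 0): a
constant signal carries no information, and this avoids 0/0. Intensities
are min-max normalised to $[0,1]$ before decomposition so features do not
depend on bit depth; features are *not* z-scored before the classifier by
default, but `model_config(scale = TRUE)` fits a z-scoring on training
folds only.

## The fuzzy SVM

The plain soft-margin dual is
$$\max_\alpha \sum_n \alpha_n - \tfrac12 \sum_{n,m}
  \alpha_n \alpha_m y_n y_m K(x_n, x_m), \quad
  0 \le \alpha_n \le C, \quad \sum_n \alpha_n y_n = 0 .$$
The fuzzy variant changes exactly one thing: the box constraint becomes
$0 \le \alpha_n \le s_n C$. Memberships come from the radius/center rule
$$s_n = 1 - \frac{\lVert x_n - \bar x_{c(n)} \rVert}{r_{c(n)} + \delta},$$
with $\bar x_c$ the class mean, $r_c$ the maximum distance of a member
from it, and $\delta > 0$ a stabiliser (default $10^{-3} \max(r_+, r_-)$,
relative so it is never zero); training memberships are automatically in
$(0,1]$, and unseen points beyond the radius are clamped to a small
positive floor. Memberships and the optional scaling are always fitted on
training folds only — the no-leakage property is tested directly.

The dual is solved by a maximal-violating-pair SMO working-set method
(KKT gap tolerance $10^{-8}$, $10^5$ iteration cap); the per-sample bound
only changes the clipping step. The bias is the mean of
$y_n - \sum_m \alpha_m y_m K(x_m, x_n)$ over free support vectors, or the
midpoint of the KKT-feasible interval when none are free. Decision values
$f(x) = \sum_n \alpha_n y_n K(x_n, x) + b$; the tie $f = 0$ resolves to
+1. Kernels: RBF (default, $\gamma = 1/(p\,\mathrm{var}(X))$ heuristic),
linear, polynomial. On problems small enough to solve exhaustively the
SMO solution is tested against a generic interior-point QP solver to
$10^{-6}$, and unit memberships reproduce the plain SVM exactly.

### When does the membership weighting matter?

With a small penalty $C$ the soft margin itself absorbs label noise: the
offender's $\alpha$ saturates at $C$ and both classifiers coincide, so no
advantage can (or should) appear. The membership cap bites when $C$ is
large — a plain SVM then carves the boundary around a mislabeled point
(with an RBF kernel, a local island), while the FSVM keeps its influence
capped at $s_n C \approx 0$. The robustness demonstrations in this
package therefore run at $C = 100$; the convergence of the fuzzy boundary
to the outlier-free one as $s \to 0$ is a tested property.

## Evaluation protocol

`stratified_kfold()` deals each class round-robin into K folds, so
per-class counts differ by at most one — e.g. an 18/48 split over 6 folds
gives exactly 3 healthy + 8 pathological per fold (15/40 per training
partition), and 20/140 or 35/220 over 5 folds give 4/28 and 7/44. Metrics
use pathological as the positive class; a zero-denominator metric is
reported as `NA`, never 0. Within a run, confusion counts are pooled
across folds before percentages are formed (the least-variance
convention), and the report averages percentages across the R runs.
`grid_search_q()` re-extracts features per candidate (argmax accuracy,
ties to the smaller $q$); `grid_search_C()` nests the selection inside
training partitions by default to avoid optimistic bias, with an
`"outer"` mode that mimics protocols tuning outside the loop.

## The synthetic phantom

Real benchmark image sets of this kind are distributed as downloadable
image archives without an accession mechanism, so the package carries a
generator that emulates their *structure* rather than their appearance:
imbalanced two-class sets of 256×256 grayscale brain-like images. A
healthy phantom is an elliptical brain mask with a smooth radial intensity
gradient, two ventricle-like dark ellipses and Gaussian texture noise
(s.d. 0.02); a pathological phantom adds 1–3 hyper- or hypo-intense
lesions (perturbed-ellipse boundaries, radius 5–10% of the image side,
intensity shift 0.30) whose interior noise s.d. is raised by 0.10 — the
lesion-versus-background texture contrast is the minimal signal the
entropy features consume. Defaults mirror an 18 healthy : 48 pathological
set. It is a stand-in, not an MR simulator: no bias field, no partial
volume, no k-space physics, no disease taxonomy — so passing tests show
the pipeline recovers planted texture contrast, not that it detects real
pathology.

Three presets define the studies used by the tests and the acceptance
script (all at 10 runs of 6-fold stratified CV on 66 images, WPTE at
$q = 0.8$):

* `"easy"` — the defaults above; both SVM and FSVM should exceed 95%
  accuracy.
* `"null"` — lesion intensity and texture cues set to 0, making the class
  generators statistically identical; accuracy can only sit at the
  majority rate (72.7%).
* `"outlier"` — easy conditions plus 10% of *training* labels flipped at
  dataset creation; `run_cv(..., train_labels = )` trains on the corrupted
  labels while scoring against the truth. At $C = 100$ the FSVM is
  expected to match or beat the plain SVM; with only ~7 flips in 66
  samples the margin is small and fluctuates run to run, which is the
  honest size of the effect at this n.

## Known limitations

* The phantom's lesions are the only class signal; conclusions transfer
  to real MR data only insofar as pathology alters subband texture.
* Only Haar and Daubechies-2 filters ship; longer filters would need
  blocks at the deepest level to remain at least as long as the filter.
* The QP solver is dense and targets the few-hundred-sample regime of
  these benchmarks, not large-scale training.
* No probability calibration, multi-class scheme, or best-basis selection
  over the packet tree.
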