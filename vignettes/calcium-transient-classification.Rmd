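---
title: "Classifying drug responses from cardiomyocyte calcium transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying drug responses from cardiomyocyte calcium transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrans)
```

## The problem

Induced pluripotent stem cell-derived cardiomyocytes (iPSC-CMs) carrying
CPVT-causing RyR2 mutations beat spontaneously in culture, and their
intracellular calcium can be followed with the ratiometric Fura-2 dye: each
beat appears as one rise-and-decay "calcium transient" in the 340/380 nm
ratio trace. Adrenaline provokes abnormally shaped transients in these
cells; dantrolene, an inhibitor of sarcoplasmic calcium release, may then
abolish the abnormalities (a *responder* signal), reduce them by more than
half (*semi-responder*) or leave them largely intact (*non-responder*).

`catrans` implements the quantitative side of this assay as a pipeline:

1. recognise beats in each ratio trace with a derivative-phase algorithm,
2. describe every beat by 12 morphological variables,
3. classify whole signals by signal-level leave-one-out (LOO)
   cross-validation with peak-level majority voting over a configurable
   classifier zoo,
4. evaluate with labelled confusion matrices, accuracy, per-class
   sensitivity and class merging.

The original recordings are not publicly deposited, so the package also
ships a synthetic signal generator with ground-truth beat annotations; every
stage of the pipeline is exercised and tested end to end on generated data.

## Peak recognition

Amplitudes are first multiplied by 1000 (`scale_amplitudes()`), moving the
ratio scale into convenient "scaled units". The first derivative s′ is
estimated at every sample as the least-squares slope over a centred segment
of a few samples (default 5 at 50 Hz; truncated at the edges). A beat is the
phase sequence of s′: roughly zero, rapidly positive (onset), back through
zero at the apex, clearly negative on the decaying flank, and back into the
zero band (end). The apex is placed at the signal argmax between onset and
the first non-positive-derivative sample, ties to the earliest sample.

Two thresholds make "roughly zero" and "noise" precise; neither has a
published value, so both are package choices:

* `zero_band` — 5% of a robust derivative amplitude (the 98th percentile of
  |s′|), floored at 3.5 standard deviations of the derivative noise. The
  noise floor matters: the sample noise sd is estimated from the median
  absolute successive difference of the trace and propagated analytically
  through the slope estimator (var = 12σ²/(L(L²−1)Δt²)). Without it, a
  low-amplitude signal's chatter crosses a purely amplitude-scaled band and
  fragments into spurious "beats".
* candidates shorter than `min_peak_duration` (default 0.1 s) are derivative
  chatter and are dropped.

After detection, peaks whose amplitude (max of the left and right
amplitude) is *strictly* below 8% of the reference amplitude of the large
peaks are removed as potential noise; a peak exactly at the boundary is
retained. "The large amplitude peaks" is ambiguous, so the reference
defaults to the median of the upper half of peak amplitudes — close in
spirit to "the large peaks" but robust to a single outlier, unlike the
maximum.

## The 12 peak variables

For a peak with onset, apex and end at times $t_s < t_m < t_e$ on signal
$s$:

| variable | meaning |
|---|---|
| $A_l, A_r$ | amplitudes $s(t_m)-s(t_s)$ and $s(t_m)-s(t_e)$ |
| $D_l, D_r$ | durations $t_m-t_s$ and $t_e-t_m$ |
| $\max(s')$, $|\min(s')|$ | first-derivative extremes on the rising / decaying flank (locations $L_1$, $L_2$) |
| $\max(s'')$, $|\min(s'')|$ | second-derivative extremes, both on the decaying flank ($L_4$, $L_3$) |
| $R$ | trapezoidal area between the curve and the chord joining onset to end |
| $\Delta$ | interval from this apex back to the preceding apex, or to the start of the signal for the first peak |
| $d_l, d_r$ | times from onset to $L_1$ and from apex to $L_2$ |

The second derivative is obtained by re-applying the same segment-slope
operator to s′. Both of its extremes are taken on the decaying flank: the
verbal definition places them there even though sketches put $L_4$ near the
apex, and the text wins. Extremum searches use the half-peak windows
$[t_s, t_m]$ and $[t_m, t_e]$ with ties to the earliest index. $R$ uses the
trapezoid rule on the sampled grid with no sub-sample interpolation.

`build_feature_table()` runs scale → detect → filter → featurize over a
whole dataset and returns one row per retained peak with the signal's label
attached (response class for dantrolene signals, condition otherwise).
Signals whose peaks were all filtered away cannot vote and are dropped with
a warning.

## Classification protocol

All 12 variables are z-score standardized. The default mode computes the
statistics once over the whole dataset, replicating the published protocol;
because that leaks test-set statistics into training, `loo_classify()` also
exposes `standardize = "train_only"`, which recomputes them inside each
fold. The replicated default is the honest re-implementation; the
alternative is there for users who want a leak-free protocol.

Cross-validation is leave-one-out *at the signal level*: all peaks of one
signal form the test set, every other signal's peaks the training set. The
per-peak predictions are aggregated by majority voting; a tie is resolved
by a deterministic cascade — largest summed classifier score among the tied
classes, then the tied class most frequent among training signals, then
lexicographic order — and flagged in the result. The original work defers
its tie strategy to earlier papers, so this cascade is a stated stand-in,
not a reconstruction.

The zoo (`classifier_config()`) covers KNN under eight metrics and three
distance weightings with odd K from 1 to 37, linear/quadratic/Mahalanobis
discriminants, CART, multinomial logistic regression, Gaussian and
kernel-density naive Bayes (normal, box, Epanechnikov, triangle kernels;
Silverman bandwidth per class and variable), random forests with 1–100
trees, and least-squares SVMs. Standard fits go through MASS, rpart, nnet,
e1071 and randomForest; the weighted multi-metric KNN, the kernel naive
Bayes, the log-determinant-free Mahalanobis discriminant and the LS-SVM are
implemented in the package because no installed implementation matches
their required form. Stochastic fits draw from a seed recorded in the
config (default 20200504), so identical inputs give identical results.

### LS-SVM

The binary LS-SVM solves one ridge-regularised linear system
$$\begin{pmatrix} 0 & \mathbf{1}^\top \\ \mathbf{1} & K + I/C \end{pmatrix}
\begin{pmatrix} b \\ \alpha \end{pmatrix} =
\begin{pmatrix} 0 \\ y \end{pmatrix},$$
with kernels linear, $(x^\top y + 1)^2$, $(x^\top y + 1)^3$ and RBF
$\exp(-\lVert x-y\rVert^2 / 2\sigma^2)$ (the polynomial degrees are named
in the source work; the inhomogeneous form and the RBF parameterisation are
package choices). $C$ and $\sigma$ live on the grid $2^{-12}, \dots,
2^{17}$: 30 values for the polynomial kernels and 900 $(C, \sigma)$ pairs
for the RBF kernel. Multiclass problems are decomposed by a hierarchical
tree of binary LS-SVMs; the exact published topology is not printed, so the
default first separates responders + semi-responders from non-responders
and then responders from semi-responders, mirroring the class-merging
analyses. The tree is configurable.

`grid_search()` runs the full LOO procedure for every grid row and selects
the highest LOO accuracy, ties toward the simpler model (smaller K, fewer
trees, smaller C then σ). The selection criterion is the same accuracy
being reported — the published, optimistic protocol — and is flagged as
such here.

## Evaluation

`confusion_matrix()` counts true-by-predicted signals; `accuracy()` is
100·trace/total and `sensitivity()` the per-class diagonal over the row
sum, both reported half-up to one decimal as in the source tables (base R
`round()` rounds half to even, which would flip some printed values).
`merge_scheme("rsr")` unites responders and semi-responders against
non-responders, `"snr"` unites semi- and non-responders against
responders. `summarize_features()` produces the per-class mean ± sd table
of the 12 variables using the sample (n−1) standard deviation.

## The synthetic generator

`generate_signal()` builds a trace as baseline level plus a train of beats
with additive Gaussian noise, emitted on the raw ratio scale (divided by
1000) so generated files look like real recordings to the rest of the
pipeline. Each beat is a raised-cosine (sigmoidal) rise over the rise
duration followed by an exponential decay that reaches 2% of the amplitude
at the decay duration — smooth, differentiable, and qualitatively the shape
seen in published example traces, which is all the morphology available.

Beat parameters are drawn hierarchically: each signal draws its own mean
shape, each beat jitters around it, with the configured dispersion split
evenly between the two levels. Amplitudes are drawn lognormally with
moments matched to the configured mean and sd: the published summary
statistics are strongly right-skewed relative to zero (e.g. baseline
amplitude 277 ± 181 scaled units), and a truncated Gaussian with that sd
piles mass at tiny amplitudes, producing signals whose "beats" sit at the
noise floor — degenerate inputs no real recording session would keep.
Durations and intervals use truncated Gaussians with physiological floors
(rise ≥ 0.08 s, decay ≥ 0.12 s, interval ≥ 0.3 s), and consecutive beats
are never allowed to overlap, so the ground-truth annotation is always
well defined.

Four abnormality kinds, abstracted from published example figures, deform
a configurable fraction of beats: a secondary hump on the decaying flank,
amplitude alternation (a beat fires at 40% of its drawn amplitude), a
plateau holding near the maximum, and a premature beat (the preceding
interval shortened to 30–60%). The class semantics follow the response
definitions: responders contain no abnormal beats, semi-responders a
reduced fraction (default 0.20), non-responders a high fraction (0.55),
adrenaline 0.50, and baseline 0.30 (CPVT cells show abnormalities already
at baseline). The realised per-beat draws are recorded in the annotation,
so tests compare against what was actually generated.

Defaults the data do not pin down were chosen once: 50 Hz sampling and
20 s duration (resolving a 0.2 s rise with ≥ 10 samples), baseline level
100 scaled units, and noise sd 2% of the class mean amplitude (background
noise is subtracted upstream in the real assay; a small residual keeps
detection nontrivial). Condition presets (`ct_presets("study")`) centre
each class on the published per-condition means — e.g. baseline interval
1.038 s vs adrenaline 0.672 s — with the published sds as dispersion, and
emulate the study's composition: 128 baseline, 128 adrenaline and 128
dantrolene signals split 59/28/41 into responders/semi-/non-responders.

### What the generator does and does not show

Passing tests on generated data demonstrate that the pipeline's mechanics
are correct — detection recovers annotated beats exactly on noise-free
trains, features match closed forms on analytic shapes, folds are
hygienic, and well-separated classes are classified almost perfectly. They
do not demonstrate that real CPVT drug responses are separable at the
published accuracies: the generator separates classes mainly through shape
means and abnormal-beat fractions, whereas real signals differ in ways an
expert labels from experience, with overlapping distributions, drifting
baselines and merged beats the generator deliberately omits. The published
headline accuracies are therefore reproduced where they are arithmetic —
from their printed confusion matrices — and not claimed as end-to-end
machine-learning results on synthetic stand-ins.

## Problem sizes and runtime choices

The test-suite and acceptance runs use deliberately modest sizes: the
well-separated three-class demonstration preset (`"demo3"`) generates 20
signals per class of 12 s each (~800 peaks) and classifies them by LOO
random forest in a few seconds; calibration and condition-ordering checks
use 20–30 signals per condition (500+ beats), enough for the stochastic
tolerances stated alongside them. The full `"study"` preset (384 signals)
runs the same code paths and is available for heavier experiments, as are
the full hyperparameter grids (456 KNN configurations, 900 RBF pairs),
which simply multiply the LOO cost per row.

## Known limitations

* Overlapping or merged beats are not deconvolved; the generator never
  produces them, and real traces containing them will yield fewer, longer
  peaks.
* Baseline drift is not corrected; detection is offset-invariant but slow
  drift distorts amplitudes and the chord area R.
* The whole-dataset standardization default replicates a protocol with
  test-set leakage; use `standardize = "train_only"` for unbiased error
  estimates.
* Per-cell-line classification is out of scope (signal counts per line are
  far too small), as are deep-learning classifiers.
```{r example, eval = FALSE}
# end-to-end sketch
dat <- generate_dataset(ct_presets("demo3", seed = 42), seed = 42)
features <- build_feature_table(dat$dataset)
res <- loo_classify(features, classifier_config("random_forest", n_trees = 50))
glance(res)
autoplot(loo_confusion(res))
```
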