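---
title: "Gabor-filtered texture classification with a DBN tuned by an enhanced grasshopper optimizer"
author: "GaborDBN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gabor-filtered texture classification with a DBN tuned by an enhanced grasshopper optimizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

GaborDBN is a self-contained pipeline for two-class classification of
biomedical photographs whose classes differ in oriented texture — the kind
of problem posed by small clinical image collections such as oral-lesion
photograph sets, where a few dozen to a few hundred images per class must
be denoised, summarised, and classified reproducibly. This vignette is the
package's account of its methods: the models, their assumptions, every
tunable that matters, and the choices made where the design was open.

## Gabor preprocessing

The front end is a bank of complex Gabor filters. A Gabor function is an
oriented complex sinusoid damped by a Gaussian envelope; with rotated
coordinates $a' = a\cos\theta + b\sin\theta$, $b' = -a\sin\theta +
b\cos\theta$ the kernel is

$$G(a,b) = \exp\!\left(-\frac{a'^2 + \gamma^2 b'^2}{2\sigma^2}\right)
\exp\!\left(i\left(\frac{2\pi a'}{\delta} + \psi\right)\right),$$

with carrier wavelength $\delta$ (pixels/cycle), orientation $\theta \in
[0, \pi)$ (opposite directions are redundant), phase $\psi$, envelope width
$\sigma$ and aspect ratio $\gamma$ (default 0.5). Instead of $\sigma$ a
spatial-frequency bandwidth $bw$ in octaves may be given, converted by

$$\sigma = \frac{\delta}{\pi}\sqrt{\frac{\ln 2}{2}}
\cdot\frac{2^{bw}+1}{2^{bw}-1},$$

the standard half-response bandwidth relation. `preprocessImage()` converts
colour input to Rec.-601 luminance, computes each filter's **magnitude**
response $\sqrt{\mathrm{Re}^2 + \mathrm{Im}^2}$ by spatial correlation with
reflect padding, takes the per-pixel maximum over the bank, and rescales
into $[0,1]$. Magnitude rather than the real part makes the response
phase-invariant, the standard choice for texture work; the max across the
bank keeps texture at any bank orientation while unoriented noise, which
excites no filter strongly, is attenuated.

Defaults: 8 orientations evenly covering $[0,\pi)$ crossed with
$\delta \in \{4, 8\}$ px, $\psi = 0$, $\gamma = 0.5$, $bw = 1$ octave —
16 filters. Kernel size `"auto"` takes the smallest odd side covering
$\pm 3\sigma$. These are configurable conventions, not claims about any
particular clinical study's (unpublished) filter bank. Filtering is
spatial-domain only, so border policy (symmetric reflection) and
correlation orientation are pinned down exactly, which is what makes runs
bit-reproducible across machines.

## Feature extraction

The default extractor, `pooled_gabor`, is deliberately simple and fully
offline: the image is resized (bilinear) to 224 × 224, each of the 16 bank
filters' raw magnitude responses is summarised by mean, standard deviation
and energy (mean square) over a 4 × 4 spatial grid — 768 raw statistics —
and a random projection matrix with $N(0, 1/768)$ entries, regenerated
identically from the spec's seed on every call, maps them to the output
dimension (default 128). The extractor is a pure function of the image and
the spec, bitwise.

A `cnn_adapter` kind accepts a user-registered pretrained convolutional
backbone (global-average-pooled final feature map, truncated or zero-padded
to the output dimension). No network weights ship with the package and the
adapter never substitutes silently: without a registered backbone it fails
with an explicit error. The pooled extractor is the supported default
because it needs no downloads and keeps the whole pipeline deterministic.

## The DBN classifier

Classification uses a deep belief network: a stack of restricted Boltzmann
machines pretrained greedily with contrastive divergence, then a softmax
output layer, fine-tuned end to end by backpropagation. The RBM is the
standard bipartite energy model

$$E(v,h) = -\sum_{ij}\omega_{ij}v_ih_j - \sum_i a_iv_i - \sum_j b_jh_j,$$

with joint $p(v,h) \propto e^{-E}$ and logistic conditionals
$p(h_j{=}1\mid v) = \sigma(\sum_i \omega_{ij}v_i + b_j)$,
$\sigma(x) = 1/(1+e^{-x})$. For small models the package can enumerate all
$2^{m+n}$ states, which the test suite uses as an exact oracle against the
closed-form conditionals and as an exact log-likelihood tracker for CD.

CD-k follows the common variance-reduction recipe: hidden states are
sampled (Bernoulli), visible reconstructions are mean-field probabilities,
and the final negative-phase statistics use probabilities, not samples.
Features are min-max scaled to $[0,1]$ and used directly as visible
probabilities in the positive phase — no Gaussian visible units. That is
the simplest convention consistent with the binary energy model, and its
cost is real: mid-range feature values carry weak gradients, so CD
pretraining on such data shapes the weights only mildly and most class
information is put in place by fine-tuning. This is a documented
limitation, not an accident.

One learning rate $\alpha$ drives both phases with different batch
conventions: CD updates take the mean-gradient form
$\Delta = (\alpha/\beta)\,(\langle\cdot\rangle_{data} -
\langle\cdot\rangle_{model})$ summed over the batch of size $\beta$, while
fine-tuning takes plain gradient steps of $\alpha$ on each mini-batch's
*summed* cross-entropy. The summed form means the effective fine-tuning
step is $\alpha\beta$; with the defaults $\alpha = 0.1$, $\beta = 16$ this
sits in the regime where a small sigmoid stack initialised at
$N(0, 0.01^2)$ escapes its initial plateau within the default 100
fine-tuning epochs. (With mean-form fine-tuning the same $\alpha$ range
stalls for hundreds of epochs on desk-scale data — the convention is a
deliberate design decision, and it is what makes the tuner's learning-rate
search range $10^{-4}..10^{-1}$ meaningful.)

Defaults: two hidden layers (64, 32), $k = 1$, 15 CD epochs per layer, 100
fine-tune epochs, weights $N(0, 0.01^2)$ from the seed, biases zero.
Everything stochastic — initialisation, Gibbs sampling, batch shuffling —
runs inside one seeded RNG scope, so identical data + config + seed give
bitwise-identical parameters. With `epochsFinetune = 0` the output layer
stays randomly initialised and predictions sit near chance; the RBM stack
alone is a feature model, never a classifier. Prediction is a deterministic
mean-field forward pass; ties in the argmax go to the lexicographically
smaller class label.

## The enhanced grasshopper optimizer

Hyperparameters are tuned by a grasshopper optimization algorithm (GOA)
with opposition-based learning (OBL). Each of $N$ candidates moves under
pairwise "social forces"

$$s(y) = f e^{-y/l} - e^{-y}, \qquad f = 0.5,\; l = 1.5,$$

repulsive at short range, attractive at long range, balanced at a comfort
distance of about 2.08. The position update for candidate $i$ in dimension
$d$ is

$$x_i^d \leftarrow c\left(\sum_{j\ne i}
c\,\frac{u_d - l_d}{2}\, s(|x_j^d - x_i^d|)\,
\frac{x_j - x_i}{d_{ij}}\right) + T_d,$$

with $T_d$ the best solution found so far and the comfort coefficient
shrinking linearly, $c = c_{max} - t(c_{max} - c_{min})/t_{max}$, from 1 to
$10^{-5}$ — wide exploration early, collapse onto the target late. Gravity
and wind-drift terms sometimes written into swarm updates are omitted; the
drift direction is the target itself. Because $s$ saturates to ~0 for
large raw distances (which freezes the swarm), per-dimension distances are
remapped into $[1, 4)$ by $1 + (y \bmod 3)$ before applying $s$ — the
folding analogue of the normalisation used in canonical GOA
implementations. Positions are clamped to the box after every move.

OBL evaluates the bounds-mirrored point $\bar{x}_d = u_d + l_d - x_d$ and
keeps the fitter of the pair (ties keep the original). It is applied in two
places: at initialisation ($N$ uniform candidates plus their $N$ opposites,
best $N$ kept) and, each iteration, to the current global best only. That
placement bounds the extra fitness evaluations at $t_{max}$, giving an
exact, testable budget of $2N + t_{max} + N\,t_{max}$ evaluations.
Non-finite fitness values cause uniform re-sampling (counted and
reported). The whole run is reproducible from the config seed.

`tuneDBN()` searches five dimensions — $\log_{10}\alpha \in (-4,-1)$,
hidden sizes $[16,256]$ and $[8,128]$, CD epochs $[5,50]$, batch size
$[8,64]$; integer dimensions are decoded by rounding half away from zero
while the search itself stays continuous. Fitness is $1 -$ validation
accuracy on a seeded stratified 80/20 split of the *training* portion: the
tuner never touches test data, a deliberate hygiene divergence from
evaluation practices that tune against the reporting split.

## Evaluation conventions

Hold-out reports follow the conventions of published two-class metric
tables: rows per class plus an unweighted "Average" row; precision, recall
and F-score per class in percent; one overall accuracy repeated on each
class row (it is an overall quantity). Macro averages are computed from
**unrounded** per-class values, and rounding — half away from zero, two
decimals — happens only at display time; that is the only order of
operations that reproduces, e.g., an average precision of 96.15 from
92.3077 and 100. Support-weighted recall equals overall accuracy, an
identity the tests assert. ROC and precision-recall curves use a
descending threshold sweep over unique scores with ties grouped; AUROC is
trapezoidal and cross-checked against an independent implementation in the
test suite.

## Synthetic data

The generator emulates a small imbalanced two-class photograph set: 87
"cancer" and 44 "noncancer" images of 128 × 128 pixels, a roughly 2:1
imbalance chosen to stress stratified splitting at the scale of small
public clinical collections. Class A images carry a fine oriented grating
($\delta = 4$ px at $22.5^\circ$) with six dark elliptical blobs; class B a
coarser, differently oriented grating ($\delta = 8$ px at $112.5^\circ$)
with two blobs; both get per-image phase and mild orientation/wavelength
jitter plus Gaussian pixel noise (sd 0.08), clipped to $[0,1]$. The classes
therefore differ exactly in the statistics the pipeline is built to
detect — oriented texture frequency and blob counts — and the
class-conditional filter-bank energies are verifiably different.

What passing tests on this data do **not** show: robustness to
photographic nuisance (lighting, pose, specularity, anatomy), to label
noise, or to class differences subtler than carrier frequency. The
generator makes the pipeline testable end to end with no downloads; it is
not a claim of clinical realism, and accuracy on it does not transfer to
any real lesion dataset.

A second generator, `makeFeatureClusters()`, produces two isotropic
Gaussian clusters at separation $s$ along one axis (min-max scaled), used
to test the classifier in isolation: at $s = 6$ the Bayes error is below
1%, at $s = 0$ the classes are indistinguishable.

## Pipeline, seeds, and problem sizes

`runPipeline()` evaluates hold-out splits at training fractions 0.9, 0.8,
0.7, 0.6 by default. Stratified splits round per-class test counts half
away from zero and adjust by ±1 to hit the global total. The min-max
scaler is fitted on the training portion only; test features outside the
training range are clipped into $[0,1]$ and the clipped count logged. One
master seed derives every stage seed by fixed offsets, so a re-run is
bitwise identical while stages stay independently reproducible.

Desk-scale defaults keep a full synthetic run (131 images, 16-filter bank,
128-dim features, tuner budget $N = 8$, $t_{max} = 10$, i.e. 106 DBN fits,
one split) around three minutes on one core; the optimizer benchmarks in
the test suite use the sphere function in five dimensions with $N = 30$,
$t_{max} = 200$. The tuner budget is configurable; larger budgets buy
little on the synthetic data, whose classes are separable already at the
feature stage.

## Known limitations

* Bernoulli visible units on min-max-scaled real features: pretraining is
  weak on mid-range data (see above); Gaussian visible units are out of
  scope.
* Plain gradient descent everywhere — no momentum, weight decay, or
  persistent CD.
* Two classes only; the metric table and curves are binary by design.
* Spatial-domain filtering only; no FFT path, no learned or steerable
  filters.
* The synthetic generator covers oriented-texture contrasts, not
  photographic variability; results on it bound nothing about clinical
  data.
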