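---
title: "Dual adaptation pathways: model, task and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual adaptation pathways: model, task and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

When an observation contradicts a learned relational expectation — objects of
type B were always larger than objects of type A, and suddenly the opposite is
observed — a learner can resolve the inconsistency in two qualitatively
different ways: *relational adaptation* (update the expected relation) or
*representational adaptation* (re-interpret the objects so that the old
expectation still holds). Behavioural experiments report an inverted-U
pattern: moderate violations change expectations, extreme violations do not.
`dualpath` implements a two-module learning model in which this pattern
emerges from plain gradient descent, with no dedicated gating or immunization
mechanism, together with the full simulation and analysis pipeline around it.

## The order-discrimination task

Stimuli are grayscale images (default $224 \times 224$) of shapes on a
$3\times 3$ grid, characterized by five features: gray level, number, size,
grid arrangement and shape type. One scalar feature (size by default; color
and number are supported) is *predictive*: within a pair it changes from left
to right by the rule parameter $\alpha \in [-1, 1]$, expressed in normalized
feature units so $|\alpha| = 1$ is the maximal possible difference. The left
value is drawn uniformly over the sub-interval for which the partner value
stays in range ($[0, 1-\alpha]$ for $\alpha \ge 0$). All other features are
redrawn per pair but identical within a pair.

Rendering choices that the task statement leaves open, fixed here once:

* normalized size maps to an enclosing-circle diameter of 12–70 px on the
  224 px canvas (cell extent $\approx 74.7$ px), scaled proportionally for
  other canvas sizes;
* normalized color maps to gray levels $[0, 0.78]$ on a white (1.0)
  background, so the faintest shape remains visible;
* the shape catalog is circle, square, triangle, five-pointed star and cross,
  each drawn as a filled figure inscribed in the enclosing circle;
* number (1–9) is normalized as $(n-1)/8$; when predictive, $\alpha$ is
  restricted to multiples of $1/8$, and the two arrangements are nested so
  the shared cells coincide;
* rasterization is hard-edged (a pixel is filled iff its center is inside
  the shape): no anti-aliasing, so rendering is bit-exact reproducible.

## The agent

The *representational module* $Z_\mathbf{w}$ is a small convolutional
encoder: conv(16, $2\times2$) → ReLU → conv(32, $2\times2$) → ReLU → maxpool
(4) → conv(32, $3\times3$) → ReLU → maxpool(6) → linear ($2592 \to 1$), all
conv strides 1, padding 1, producing one scalar per image. The pooling
windows advance by their own extent; this is the only reading of the
architecture that reproduces the stated 2592-dimensional flatten
($224 \to 225 \to 226 \to 56 \to 56 \to 9$, $32 \cdot 9 \cdot 9 = 2592$), and
it matches the framework convention that a pooling layer's stride defaults to
its kernel size. The *relational module* is a single scalar $\theta$, the
expected representation difference.

For a pair $(\mathbf{x}, \mathbf{x}')$ with $\Delta Z =
Z_\mathbf{w}(\mathbf{x}') - Z_\mathbf{w}(\mathbf{x})$, the loss is

$$\tilde{\mathcal{L}}(\mathbf{w}, \theta)
  = (\Delta Z - \theta)^2
  + \lambda\,(\Delta Z^2 + \theta^2 - r^2)^2 .$$

The quadratic term aligns observed and expected differences; the quartic
*ring* term forbids the collapsed solution $\Delta Z = \theta = 0$. The
global minima are exactly $\Delta Z = \theta = \pm r/\sqrt{2}$: two equally
good solutions ("largeness increases" vs "smallness decreases").

Training uses plain SGD, learning rate $0.004$, $\lambda = 4$, $r^2 = 0.1$,
batches of 2 pairs with 20 gradient steps per batch; $\mathbf{w}$ and
$\theta$ share the single optimizer. Weights and biases initialize uniformly
on $\pm 1/\sqrt{N}$ ($N$ = fan-in); $\theta$, a one-input unit, on
$\pm 1$. The batch loss is the *mean* over the batch's pairs (the common
framework default; mean vs sum is not dictated by the model statement — with
2 pairs this only rescales the learning rate by 2). Order decisions compare
the loss of the presented order with the swapped order (which negates
$\Delta Z$); exact ties — a measure-zero event — count as incorrect.

The forward/backward pass is implemented in single-precision C++
(im2col + BLAS GEMM). Because the three input channels carry identical
values, conv1 is computed through the channel-summed kernel; this is
algebraically identical to the 3-channel computation, for gradients too.

## Protocols and pathway classification

A *phase* is 160 training pairs under one rule, probed by 32 held-out pairs
from the same rule. Protocols chain phases: initial learning ($\alpha$),
symmetric reversal ($\alpha \to -\alpha$), general reversal
($\alpha_1 \to -\alpha_2$) and intermediate-step shaping
($\alpha \to \beta \to -\alpha$). Checkpoints record $\theta$, the probe mean
$\Delta Z$ and probe accuracy, by default after every batch.

Classification compares the end of the first phase with the end of the final
phase. Immediately after a reversal the probe $\Delta Z$ flips sign (the
probe pairs now follow the new rule), while $\theta$ is continuous; the sign
reference for $\Delta Z$ is therefore the end-of-phase-1 state probed under
the *final* rule. An agent that flips $\theta$ while the probe $\Delta Z$
keeps its post-switch sign adapted its relational module; the reverse
pattern is representational adaptation; both-kept or both-flipped states
cannot solve the task and are excluded. Numerically signless probes
($|x| < 10^{-6}$) are treated as "sign not kept" and reported. Agents whose
phase-1 accuracy stays below 0.75 are flagged as failed learners and
reported separately rather than silently pooled.

The relational fraction per cell is $\#\theta / (\#Z + \#\theta)$ with
excluded agents removed from both counts. The inflection point
$\bar{\alpha}$ is the parameter $d$ of the logistic
$1/(1 + e^{c(\alpha - d)})$ fitted by least squares, with
$\mathrm{CI}_{95} = 1.96\,\mathrm{SE}(d)$ from the fit covariance. When the
per-cell count $n$ is supplied, the fit uses binomial variance weights
$n/(\hat p(1-\hat p))$ with a continuity-corrected $\hat p$. This is a
deliberate design choice: with *unweighted* least squares the saturated grid
cells (fractions near 0 or 1, tiny variance) deflate the residual-variance
estimate and the nominal 95% interval covers the true inflection in only
about 65–85% of synthetic binomial replicates; with binomial weights,
coverage on an 11-point grid at $n = 100$ is ≈ 92%, which is what a
confidence interval should deliver. Without `n` the fit falls back to the
plain unweighted form. Perfectly separated (step-like) data are handled by a
direct least-squares fall-back with a Gauss–Newton covariance; fraction data
with no transition across $1/2$ raise an explicit error instead of returning
an unidentified $d$.

## The reduced scalar model

Replacing the image pair by a scalar pair differing by $\alpha$ and the
encoder by one weight $w$ (so $\Delta Z = w\alpha$) turns learning into the
gradient flow

$$\frac{1}{\alpha^2}\dot{\Delta Z} = (\theta - \Delta Z)
    - 2\lambda(\Delta Z^2 + \theta^2 - r^2)\,\Delta Z, \qquad
  \dot{\theta} = (\Delta Z - \theta)
    - 2\lambda(\Delta Z^2 + \theta^2 - r^2)\,\theta .$$

The $\alpha^2$ prefactor is the entire story: it sets the relative
adaptation speed of the representational module. The flow always has the
unstable origin and the two stable ring solutions
$\pm(r/\sqrt2, r/\sqrt2)$; for $\lambda > 1/r^2$ an additional unstable
anti-diagonal pair $\Delta Z = -\theta = \pm\sqrt{(r^2 - 1/\lambda)/2}$
appears. Stability is classified from the eigenvalues of the analytic
linearization.

With $\lambda = 0$ the two equations are dependent: $\Delta Z + \alpha^2
\theta$ is conserved and the system relaxes onto the line attractor
$\Delta Z = \theta = (\alpha^2\theta_0 + \Delta Z_0)/(\alpha^2 + 1)$. From
the post-reversal state $(-r/\sqrt2, r/\sqrt2)$ this endpoint is
$(r/\sqrt2)(\alpha^2-1)/(\alpha^2+1)$: $\theta$ flips sign iff $\alpha < 1$.
For a general change $\alpha_1 \to -\alpha_2$ the start is
$(-(r/\sqrt2)\,\alpha_2/\alpha_1,\; r/\sqrt2)$ and the endpoint
$(r/\sqrt2)(\alpha_2^2 - \alpha_2/\alpha_1)/(\alpha_2^2+1)$, positive iff
$\alpha_1\alpha_2 > 1$: the weak-regularization pathway boundary is the
hyperbola $\alpha_1\alpha_2 = 1$.

Numerical choices: integration uses `deSolve::lsodar` with absolute and
relative tolerances $10^{-9}$, a convergence root at flow norm $10^{-8}$,
and horizon $T = 10^4$; horizon exhaustion is reported, never hidden.
Pathway maps label each cell by the attractor reached from the post-switch
state at the reference weak regularization $\lambda = 0.1$, $r^2 = 0.1$; the
product-rule predictor labels $|\alpha_1\alpha_2 - 1| < 0.02$ as "boundary"
because the terminal sign is ill-conditioned on the separatrix. The
boundary-locating routine bisects $\alpha_2$ per $\alpha_1$ (25 log-space
iterations) and summarizes the hyperbola coefficient as the geometric mean
of $\alpha_1\alpha_2^\*$. At $\lambda = 0.1$ this coefficient comes out
$\approx 0.95$ on $[0.25, 4]^2$ rather than exactly 1: the finite-$\lambda$
flow bends the boundary at the extreme corners of the grid (where the
post-switch state starts far off the ring), which is visible in the map and
is the expected departure from the $\lambda \to 0$ prediction.

## Problem sizes used by the tests and the acceptance script

One 160-pair phase of the 224 px convolutional agent costs roughly three
minutes of single-core CPU in this implementation, so the packaged checks
run the published experimental designs at reduced agent counts, chosen once:

* learning-speed and solution-value checks: 1–6 agents at $\alpha = 0.5$,
  full 224 px geometry and stated hyperparameters;
* accuracy-range check: one agent per $\alpha \in \{0.1, 0.5, 1.0\}$;
* reversal checks: one agent each at $\alpha = 0.2$ (small violation) and
  $\alpha = 0.8$ (large violation), which bracket the published inflection
  point ($\bar\alpha \approx 0.34$) from both sides; a full
  fraction-versus-$\alpha$ curve with a logistic fit needs on the order of
  a hundred reversal runs (CPU-days) and is available through
  `reproduce_figure("fig5a")`;
* the intermediate-step (shaping) comparison is likewise a
  multi-hundred-phase experiment at full geometry; the test suite exercises
  it at a 64 px canvas, where the encoder's adaptation is much slower than
  at 224 px and the relational pathway dominates throughout — that check
  documents the machinery and the scale limitation rather than confirming
  the shaping effect, which requires `reproduce_figure("fig6")` at paper
  scale;
* all reduced-model analyses run at full precision in seconds and are not
  scaled down.

Side experiments at reduced canvases (112 px, 64 px) show the transition
point $\bar\alpha$ is *not* invariant to image size: smaller inputs slow the
encoder relative to $\theta$ and shift adaptation toward the relational
pathway. Reduced canvases are therefore never used to check
$\bar\alpha$-dependent claims.

## What the generator does and does not emulate

The stimulus module reproduces the published task generator: procedurally
drawn shape images with one predictive and four irrelevant features, uniform
feasible-interval sampling, and within-pair constancy of irrelevant
features. It does not emulate natural-image statistics, occlusion, noise, or
observer models; passing tests therefore demonstrate properties of the
learning dynamics on this synthetic family, not robustness of the phenomenon
to real visual input.

## Known limitations

* Paper-scale grids (100 agents per cell) are CPU-days on one core here;
  `reproduce_figure(..., scale = "full")` exists but is intended for long
  batch runs.
* The SGD agent is simulated at the stated finite learning rate; the reduced
  model is its continuous-time limit, and no stochastic (finite-step)
  analysis of the reduced flow is attempted.
* Agents are passive: the protocol presents pairs; there is no active
  sampling or intervention by the learner.
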