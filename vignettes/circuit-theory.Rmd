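---
title: "Learning dynamics and activity evolution in categorization circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning dynamics and activity evolution in categorization circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitcat)
```

## The model

`circuitcat` studies how learning reshapes neural activity in a circuit that
bridges a sensory representation and an abstract, binary category. The
circuit is a two-layer feedforward network. An input layer of size $N$
carries a sensory vector $x$; an intermediate layer of the same size
responds with

$$ y = \Psi(u\,x + b), \qquad k \equiv u\,x + b, $$

where $u$ is an $N \times N$ connectivity matrix, $b$ an optional fixed
per-neuron bias (zero in the base model), and $\Psi$ a sigmoidal activation
$\Psi(x) = 1/(1 + e^{-\Theta_1 (x - \Theta_2)})$ whose gain (the slope at
the threshold $\Theta_2$) is $\Theta_1/4$. A single readout neuron reports
the category: $z = \Phi(w \cdot y)$ with its own sigmoid $\Phi$. Weights are
initialized i.i.d. Gaussian with variance $1/N$, which keeps all drives and
activities $O(1)$ in the width.

Learning is full-batch gradient descent on the quadratic readout loss
$E = \frac{1}{2P} \sum_s (\tilde z^s - z^s)^2$, with independent learning
rates $\eta_u$ for $u$ and $\eta_w = \eta_u \cdot \texttt{eta\_ratio}$ for
$w$. Training stops when $E < 10^{-5}$. The default $\eta_u = 0.1$ is small
enough that the discrete updates track the continuous-time gradient flow:
halving it (and letting training run longer) changes converged activity
measures by well under 2% on the problem sizes used here (this is exercised
in the test suite).

## The tasks

All data are generated internally; there are no external inputs.

* **Simple task** (`make_simple_task`): $Q$ stimuli, each an i.i.d. standard
  Gaussian vector $\mu^S$; the first half is category A (target
  $z_A = 0.75$), the second half category B ($z_B = 0.25$). At large $N$
  the inputs are orthonormal and linearly separable.
* **Structured variant** (`make_structured_task`): inputs mix a private
  Gaussian component with a shared two-dimensional continuous component,
  $x^s = \sqrt{1-\Sigma^2}\,\mu^s + \Sigma[\xi_1 \cos\theta_s + \xi_2
  \sin\theta_s]$, $\theta_s = 2\pi s/Q$, producing continuous tuning with
  neighbour correlations $\Sigma^2 \cos(2\pi(s-s')/Q)$. Defaults
  $\Sigma = 1/3$, $Q = 12$, plus per-neuron biases with standard deviation
  0.2 to model heterogeneous baselines.
* **Context-dependent task** (`make_context_task`): $Q$ stimuli and $Q$
  context cues; every combination occurs once ($P = Q^2$), with input
  $(\mu^S + \nu^C)/\sqrt{2}$. Cues $1..Q/2$ signal context 1, the rest
  context 2, and the stimulus-to-category mapping is reversed between
  contexts. Inputs correlate at $1/2$ when two trials share a stimulus or a
  cue. For $Q = 2$ this is an XOR; for every $Q$ the inputs are *not*
  linearly separable.

Stimulus identity maps to category by the fixed "first half is A"
convention, so runs are deterministic given a seed; inputs are re-drawn per
seed and never orthogonalized (the theory relies only on approximate
large-$N$ orthogonality).

## The large-width theory

When $N \gg P$, the weight changes needed to solve the task are small
($\Delta u \sim N^{-3/2}$, $\Delta w \sim N^{-1}$) and activity evolves
linearly in them (the lazy regime): each activity vector moves along fixed
*spanning vectors* $v^{qs} \propto w_0 \odot \Psi'(k_0^q) \odot
\Psi'(k_0^s)$ with *activity coordinates* $c_q$ obtained from a
$P$-dimensional linear system. Dropping the non-self-averaging initial
readout drive, the coordinates take only two values $c_A > c_B$ solving

$$ \Phi^{-1}(z_{A}) = \alpha c_A + \beta (c_A + c_B), \qquad
   \Phi^{-1}(z_{B}) = \alpha c_B + \beta (c_A + c_B), $$

with task-specific $\alpha, \beta$ assembled from Gaussian population
averages of $\Psi$ and $\Psi'$ (`simple_coordinates`,
`context_coordinates`). The averages — $\langle\Psi\rangle$,
$\langle\Psi^2\rangle$, $\langle\Psi'\rangle$, $\langle\Psi'^2\rangle$,
$\langle\Psi'^4\rangle$ and the covariance-$1/2$ pair averages
$\langle\Psi\Psi\rangle$, $\langle\Psi'\Psi'\rangle$ — are computed by
Gauss–Hermite quadrature (`gaussian_averages`).

From the coordinates the package predicts, in closed form for the simple
task (`simple_theory_measures`):

* average category selectivity
  $S \simeq (c_A - c_B)^2 \langle\Psi'^2\rangle^2 / [4N(\langle\Psi^2\rangle -
  \langle\Psi\rangle^2)]$, with the finite-size denominator variant kept as
  the primary prediction;
* category correlation
  $C \propto c_A c_B \langle\Psi'^2\rangle^2$ — its **sign is the sign of
  $c_A c_B$**, controlled by the readout targets and threshold, and it
  decreases monotonically with the learning-rate ratio and the number of
  stimuli;
* per-category response variances $c_{A,B}^2 \langle\Psi'^2\rangle^2/N$
  (response asymmetry).

For the context task, the predicted dot products between trials involve
four-point gain averages whose value depends only on the pattern of shared
stimulus/cue indices among the four trials involved
(`context_dot_products`). Patterns are enumerated programmatically;
disjoint trials factorize analytically and the remaining connected blocks
are integrated by tensor-grid quadrature. The package evaluates the
resulting category/context clustering and correlations numerically
(`context_theory_measures`). Two structural results are reproduced exactly:
drive-level category clustering does not change over learning, and the
drive-level context-selectivity change is proportional to
$(Q/2)(\langle\Psi'\Psi'\rangle - \langle\Psi'\rangle^2) > 0$, which
vanishes only for a linear activation (`a1_minus_a2`).

With a linear intermediate layer, the context-task $\alpha$ vanishes
identically and the coordinates diverge — the analytical signature of the
task's linear non-separability. `context_coordinates` raises a dedicated
`singularity_error` in this case (tolerance $|\alpha| < 10^{-8}$), and the
training loop correspondingly fails to converge.

## Activity measures

All measures act on a trials-by-neurons matrix with trial labels
(`activity_matrix`), for either the activity $y$ or the drive $k$:

* **Selectivity** (`category_selectivity`, `context_selectivity`): per
  neuron, $(D - S)/(D + S)$ from mean squared response differences over
  different- vs same-label trial pairs; same-label averages always exclude
  $s = s'$. The primary context definition also excludes same-cue pairs so
  that an increase cannot reflect mere cue similarity; the secondary
  definition (`exclude_same_cue = FALSE`) keeps them. Zero-denominator
  neurons are flagged and reported as zero rather than dropped, preserving
  array shapes.
* **Clustering** (`clustering`): the population-pooled ratio (numerator and
  denominator averaged over neurons first). It approximates average
  selectivity when both $Q$ and $N$ are large.
* **Signal correlations** (`signal_correlation_matrix`,
  `block_correlation`, `averaged_response_correlation`): Pearson across
  neurons between trial pairs, averaged over different-label pairs, plus
  the label-averaged-profile variant; at leading order the two differ by a
  factor $Q/2$ on the simple task but always share a sign.
* **Gain patterns** (`gain_pattern_stats`): the pre-learning statistics
  $D_i^C$, $D_i^S$ and $G_i = \langle|D_i^C|\rangle_C -
  \langle|D_i^S|\rangle_S$ that separate neurons developing mixed
  category-and-context selectivity from purely category-selective ones.

For structured inputs, a second selectivity definition with
input-structure-tailored pair subsampling exists in the experimental
literature; its subsampling rule is not fully specified, so only the
standard definition is implemented here.

## Design choices and problem sizes

* **Quadrature**: probabilists' Gauss–Hermite at order 201 for one- and
  two-dimensional averages; orders 31/19/13 per dimension for connected
  three-/four-/five-variable blocks of the four-point averages. At these
  orders doubling the order changes results by under $10^{-8}$ for all
  sigmoid parametrizations in the preset registry, and every average agrees
  with a $10^7$-sample Monte-Carlo estimate to three decimals (both are
  asserted in the tests).
* **Presets** (`study_presets`): the registry pins the study's operating
  points — simple task at $N = 200$, $Q = 20$ and context task at
  $N = 600$, $Q = 8$, with the balanced ($\Phi$ threshold 0), shifted
  ($\Phi$ threshold 2 or 4) and plastic-readout variants, plus
  supplementary reference, structured and high-threshold rows. Operating
  points that are swept in the study are pinned at the representative value
  used by the matching fixed row.
* **Theory-versus-simulation harness**: the quantitative comparison runs at
  $N = 800$, $Q = 20$ with a shallow-gain intermediate layer
  ($\Theta_1 = 0.5$, $\Theta_2 = 0$) and frozen readout. The accuracy of
  the linearized prediction improves as $\Psi$ becomes more linear over its
  effective activation range, while the per-neuron $w_{0,i}^2$ signature of
  selectivity strengthens with the coordinate amplitude; the shallow-gain
  point satisfies both at once, which is why it is the default comparison
  condition. Ten seeds are used, matching the scale of the repeated
  realizations used throughout.
* **Training caps**: epoch cap 200,000 (500,000 in `train_config`'s
  default), divergence guard at loss $10^3$; non-converged runs are flagged
  rather than silently included, and only converged runs enter sweep
  averages.
* **Determinism**: a run is fully reproducible from its seed; circuit
  weights are drawn first ($u$, then $w$, then $b$), inputs afterwards from
  a shifted seed. Whether input vectors should be re-drawn per realization
  is not dictated by the model; they are re-drawn here, which makes seeds
  fully independent realizations.

## What the generators do and do not emulate

The synthetic tasks reproduce the statistical structure the theory is built
on: orthonormal (or weakly correlated) Gaussian sensory vectors, balanced
categories, and exact stimulus-cue crossing in the context task. They do
not emulate temporal dynamics within a trial, noise in the responses,
excitatory/inhibitory cell identities, or multi-area interactions — so
passing tests demonstrate the internal consistency of simulation and
theory, not fidelity to any particular recorded dataset. The structured
variant adds continuous tuning and baseline heterogeneity as a first step
toward biological realism; its measures are evaluated by simulation only.

## Known limitations

* Predictions are leading-order in $1/N$; at the widths used in the presets
  ($N = 200$–$800$) the context-task predictions are noticeably less
  accurate than the simple-task ones, as expected from the stronger input
  correlations and larger coordinates.
* The reduced coordinate solvers describe average behaviour; realization-
  to-realization variability (dominated by the frozen component of the
  initial readout drive, see `variability_decomposition`) is substantial
  for correlations in particular. The per-realization solver
  (`activity_coordinates_full`) retains the variable term but is exercised
  only as a consistency check, not as a calibrated predictor.
* Per-neuron selectivity at moderate $Q$ carries $O(1/Q)$ sampling noise:
  rankings of selectivity changes across neurons are reliable only at the
  top of the distribution. Classifications that intersect two noisy
  top-quantile sets (as in `mixed_pure_classification`) inherit that noise.
* The time-resolved coordinate dynamics are not integrated; the solvers
  return the $t \to \infty$ fixed point, which is the object all
  predictions use.
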