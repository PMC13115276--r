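---
title: "Dual dynamic scheduling for differentially private SGD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual dynamic scheduling for differentially private SGD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sddsgd)
```

## The model

DP-SGD privatizes each optimizer step by clipping every per-sample
gradient to an L2 bound $C$ and adding Gaussian noise
$\mathcal{N}(0, \sigma^2 C^2 I)$ to the clipped sum; the clipped sum has
sensitivity $C$, so $\sigma$ is the noise multiplier relative to
sensitivity. This package replaces the static $(\sigma, C)$ pair with a
step-wise dual dynamic schedule. Training is divided into stages
$i = 0, \dots, n-1$ with

$$D_i = D_0 \lambda^i, \qquad \sigma_i = \sigma_0 \beta^{-i}, \qquad
  C_i = C_0 a^i,$$

where $\lambda = 1/\gamma > 1$ is the dynamics factor, $\beta \in (0,1]$
the noise step ratio and $a \in (0,1]$ the clipping decay. The design
targets severely imbalanced data: minority-class gradients are weak and
most informative early, so the first stage is long, low-noise and
high-threshold. Three structural facts drive the parameter choices:

1. **Protection horizon.** Requiring $D_0 \ge \rho T$ under geometric
   growth bounds the usable stage count:
   $n = \lfloor \log_\lambda (1 + (\lambda-1)/\rho) \rfloor$. At
   $\lambda = 1.1$, $\rho = 0.3$ this gives $n = 3$ and a realized
   first-stage fraction of $0.1/0.331 \approx 0.302$.
2. **Uniform privacy expenditure.** The per-stage RDP cost proxy is
   $D_i/\sigma_i^2$; it is constant across stages exactly when
   $\beta = \sqrt{\gamma}$ (at $\gamma = 0.9$, $\beta_{\text{neutral}}
   \approx 0.95$). A smaller $\beta$ (default operating point 0.8) makes
   later stages cheaper — a stability margin at the cost of a slightly
   larger calibrated $\sigma_0$.
3. **Decaying effective noise.** The injected per-coordinate noise
   variance is $V_i = (\sigma_i C_i)^2 = V_0 (a/\beta)^{2i}$. With
   $a < \beta$ (e.g. $a = 0.6 < \beta = 0.8$, ratio $0.5625$ per stage)
   the absolute noise power decays geometrically even though the
   multiplier grows, so the optimizer contracts into an increasingly
   quiet regime late in training.

## Privacy accounting

Each Gaussian step at multiplier $\sigma$ is
$(\alpha, \alpha/(2\sigma^2))$-RDP; costs add over a run, and the total
converts to $(\varepsilon, \delta)$-DP by minimizing
$\mathrm{rdp}(\alpha) + \log(1/\delta)/(\alpha - 1)$ over the order grid
(fractional orders $1.1{-}10.9$, integers to 64, plus 128 and 256 — a
standard grid, configurable). Two modes exist:

- **plain** (default): the per-step cost above, ignoring subsampling
  amplification. This is the cost the schedule design reasons with, and it
  is conservative — it never understates $\varepsilon$.
- **subsampled** (opt-in): the integer-order binomial-expansion bound for
  the Poisson-subsampled Gaussian, for comparability with mainstream
  accountants. At $q = 1$ it coincides with plain mode.

`calibrate_sigma0()` bisects on $\sigma_0 \in [10^{-2}, 10^4]$ — along
which the consumed $\varepsilon$ is strictly decreasing — until the
achieved budget is within $10^{-3}$ of the target or the bracket is below
$10^{-9}$. Both tolerances sit far below any precision at which budgets
are reported.

## Numerical and convention choices

Several points of the scheme admit more than one reading; the package
fixes each explicitly and exposes the alternative where it is defensible.

- **Stage-count convention.** The geometric-series derivation uses stages
  $D_0 \dots D_n$ ($n{+}1$ stages), but combining the floor formula with
  the protection constraint is self-consistent only with $n$ stages:
  under `n_stages` (default) the realized $D_0/T$ meets $\rho$ for every
  $\lambda \in (1, 2]$, $\rho \in [0.05, 0.9]$ (property-tested on a
  grid). `n_plus_1_stages` is available as the literal reading.
- **$n$ formula variant.** `floor` is the default; `floor_minus_1`
  (the stricter derivation endpoint, clamped at 1) is selectable.
- **Noise recurrence direction.** The per-stage update is interpreted as
  $\sigma_{i+1} = \sigma_i/\beta$ — noise *grows* — consistent with the
  closed form $\sigma_i = \sigma_0\beta^{-i}$ and the growth factor
  $1/\beta = 1.25$ at $\beta = 0.8$.
- **$\lambda$ vs $\gamma$.** One dial: if both are supplied they must
  agree ($\lambda = 1/\gamma$ to $10^{-9}$). Note $\lambda = 1.1$ and
  $\gamma = 0.9$ are *different* operating points
  ($1/0.9 \approx 1.111$ yields $n = 2$ at $\rho = 0.3$, not 3); the API
  keeps them distinguishable rather than conflating them.
- **$\beta$ default.** `schedule_config()` defaults $\beta$ to $\gamma$
  (the single-driver coupling); $\sqrt{\gamma}$ (exact uniform
  expenditure) and $0.8$ (conservative margin) are the documented
  alternatives. The choice is left conscious rather than hidden.
- **Integerization.** Real-valued stage durations are integerized by
  rounding cumulative boundaries half-up and differencing — conserving
  $\sum D_i = T$ exactly and deterministically (at $T = 100$,
  $\lambda = 1.1$, $n = 3$: durations 30, 33, 37). Boundary rounding can
  dent monotonicity by one iteration when real stage increments are below
  2; a unit-rebalance pass restores $D_{i+1} \ge D_i$ without breaking
  conservation. Any empty stage raises an error rather than silently
  collapsing the schedule.
- **Iterations, not epochs.** $T$ and $D_i$ count optimizer iterations
  (the unit the accountant charges); `epochs_to_iterations()` converts an
  epoch budget.
- **Noise placement.** The pseudocode-literal reading adds
  $\mathcal{N}(0, \sigma^2C^2)$ to the batch *mean*, which overstates the
  noise the sensitivity argument requires. The default
  (`noise_on_sum`) adds std-$\sigma C$ noise to the clipped *sum* and
  divides by the expected batch size, making the accountant's guarantee
  true of the released quantity; `literal_mean` is kept for fidelity
  experiments. Empty Poisson batches contribute pure noise on the sum.
- **Sampling.** Poisson sampling at rate $q = B/N$ is the default (the
  regime the accountant's $q$ refers to); `fixed_size` uniform subsets
  are available. $\sigma_0 = 0$ is accepted as the no-privacy limit for
  oracle comparisons; such runs carry no ledger.

## The trainer and its oracles

The reference models are softmax regression (convex; zero
initialization) and a one-hidden-layer tanh perceptron (scaled-uniform
initialization from the run seed), both with exact hand-derived,
vectorized per-sample gradients — no autodiff, so clipping is exact. The
test suite pins the trainer to three independent oracles: central finite
differences on over 100 random instances (tolerance $10^{-5}$); exact
agreement (to $10^{-12}$) with a plain mini-batch SGD loop when
$\sigma = 0$ and the threshold is non-binding; and bitwise equality of the
degenerate dual schedule ($\beta = a = 1$) with the static baseline under
a shared seed. One seeded generator per run is split into independent
sampling and noise streams, so batch geometry changes cannot perturb the
noise draws, and results are bit-reproducible from the configuration.

## What the synthetic generator emulates — and what it does not

`ham10000_like_preset()` and `isic2019_like_preset()` mimic the class
*structure* of two dermoscopic benchmarks: 7 (resp. 8) classes, one
dominant class near two thirds of the samples, several classes at or
below 5%, exactly one large-shot class. Per-class proportions are
approximate by design. Features are isotropic Gaussians around mutually
equidistant centroids (a scaled regular simplex, requiring
$d \ge K - 1$), with a single separability dial. Class counts follow
largest-remainder apportionment (exact conservation; every proportion
recovered within one sample).

This emulates the *optimization* difficulty of imbalance — majority
gradients dominating the aggregate, few-shot classes supplying rare,
fragile signal — which is the mechanism the schedule addresses and which
is agnostic to the input domain. It does not emulate image statistics,
intra-class structure, label noise, or pretrained-feature geometry.
Passing the directional test here shows the budget-allocation mechanism
works as designed under controlled imbalance; it does not by itself
predict accuracy on real dermoscopy pipelines.

## Evaluation conventions

Metrics come from the validation confusion matrix: overall accuracy,
multiclass MCC in covariance form (0 by convention when a marginal is
degenerate), macro F1 and macro recall (classes with no true and no
predicted positives contribute 0), and group accuracy defined as the
unweighted mean of per-class recall within the large-shot and few-shot
groups — so a majority-only classifier scores 1 and 0 on the two groups.
The comparison runner reports means and standard deviations over seeds;
no significance test is attached.

## Study conditions of the packaged comparison

The matched-privacy comparison exercised by the test suite uses the
7-class preset with 3500 samples, 10 features, centroid separation 3,
unit within-class spread, data seed 20260924; schedule $\lambda = 1.1$,
$\beta = 0.8$, $a = 0.6$, $\rho = 0.3$ over $T = 2000$ iterations;
Poisson batches of expected size 128; $\delta = 10^{-3}$; budgets matched
at $\varepsilon = 3$ by calibration; softmax regression at learning rate
0.1 (chosen from a non-private sweep — tuning the base learning rate
without spending privacy budget is standard practice); run seeds 1–5.
$C_0 = 5$ scales the high-initial-threshold design to this
model's gradient norms (per-sample norms rarely exceed 5 here, so the
first stage is effectively unclipped, which is the design intent of the
high initial threshold). The static baseline uses the same constant
$C_0$ and a constant $\sigma$ calibrated to the same budget. At this
scale the dual schedule's mean few-shot group accuracy and MCC exceed
the static baseline's; only the ordering is asserted — the stochastic
gap magnitude varies with seeds and is not a stable quantity at desk
scale.

## Known limitations

- The accountant implements the additive RDP composition and the basic
  RDP-to-DP conversion only; privacy-loss-distribution accounting and
  tighter conversions are out of scope, so reported $\varepsilon$ values
  are valid but not minimal.
- The subsampled mode is restricted to integer orders (the standard
  binomial bound); fractional orders fall back to plain mode by design.
- Models are small analytic classifiers; no deep architectures, image
  input, or pretrained weights.
- The literal-mean noise convention and the $n{+}1$-stage convention are
  provided for fidelity but are not the defaults, and mixing them with
  the accountant reflects their (weaker or inconsistent) guarantees.
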