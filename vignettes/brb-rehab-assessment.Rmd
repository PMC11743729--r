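---
title: "Belief-rule-base assessment of upper-limb rehabilitation status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief-rule-base assessment of upper-limb rehabilitation status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brbrehab)
```

## The assessment problem

Robot-assisted rehabilitation of the upper limb produces a small number of
quantitative signals per training session. This package works with three:
the active resistance torque of the upper limb (ARTUL), the rehabilitation
training time (RTT), and the mean amplitude of muscle strength (MAMS).
Clinicians grade the limb's recovery status on a four-level ordinal scale
(grades I-IV, I being the best state). The modelling task is to map the
three continuous measurements onto that ordinal grade in a way that (a)
can be initialised directly from clinical expert knowledge, (b) remains
interpretable rule by rule, and (c) can be sharpened against labelled
records when they are available.

A belief rule base (BRB) fits those constraints. It extends an ordinary
IF-THEN rule system in two ways: each rule's consequent is a *belief
distribution* over the grades rather than a single conclusion, and rules
fire partially, in proportion to how well the input matches their
antecedents. Inference aggregates the activated rules with the evidential
reasoning (ER) rule, an algorithm rooted in Dempster-Shafer theory that
handles unassigned belief mass explicitly.

## The model

Each attribute $i$ carries a short ordered set of referential values
$A_i^1 < \dots < A_i^{J_i}$ with semantic labels (for ARTUL: Small = 4,
Normal = 8, Big = 12; RTT: 5/10/15; MAMS: 5/8/11). Rule $k$ has the form

$$R_k:\ \text{if } x_1 \text{ is } A_1^{k} \wedge \dots \wedge x_M
\text{ is } A_M^{k}\ \text{then } \{(D_j, \beta_{j,k})\}_{j=1}^N,$$

with rule weight $\theta_k \in [0,1]$ and attribute weights
$\delta_i \in [0,1]$. The bundled models have $M = 3$ attributes with
three referential values each, hence $L = 27$ rules over $N = 4$ grades
with utilities $u(D_j) = j$.

Inference proceeds in four steps.

1. **Matching degrees.** An input $x_i \in [A_i^l, A_i^{l+1}]$ is matched
   to the two bracketing referential values by linear interpolation:
   $a_i^l = (A_i^{l+1} - x_i)/(A_i^{l+1} - A_i^l)$, $a_i^{l+1} = 1 -
   a_i^l$, all others 0. Per attribute the degrees sum to 1 and at most
   two adjacent degrees are nonzero.
2. **Activation weights.**
   $\omega_k = \theta_k \prod_i (a_i^k)^{\bar\delta_i} \big/ \sum_l
   \theta_l \prod_i (a_i^l)^{\bar\delta_i}$, with $\bar\delta_i =
   \delta_i / \max_j \delta_j$.
3. **ER aggregation.** With $s_k = \sum_j \beta_{j,k}$ the per-rule
   assigned mass, the analytic ER form gives
   $$\hat\beta_j = \frac{\mu\left[\prod_k\left(\omega_k \beta_{j,k} + 1 -
   \omega_k s_k\right) - \prod_k\left(1 - \omega_k s_k\right)\right]}
   {1 - \mu \prod_k (1 - \omega_k)},$$
   where $1/\mu = \sum_j \prod_k (\omega_k \beta_{j,k} + 1 - \omega_k
   s_k) - (N-1) \prod_k (1 - \omega_k s_k)$.
4. **Utility and grade.** The continuous output is $\hat y = \sum_j
   u(D_j) \hat\beta_j$; the discrete grade is the one whose utility is
   nearest to $\hat y$, ties broken toward the lower (healthier) grade.

```{r}
brb <- brb_expert_initial()
assess(c(6, 7.5, 9), brb)
```

## Training

The trainable parameters are packed into a single vector
$[\theta_1..\theta_L,\ \delta_1..\delta_M,\ \beta_{1,1}..\beta_{N,L}]$ —
138 numbers for the 27-rule model. Given records labelled with true
grades, the target output for a record of grade $g$ is $y^r = u(D_g)$,
and training minimises

$$\mathrm{MSE} = \frac{1}{T} \sum_{i=1}^T (\hat y_i - y_i^r)^2$$

subject to $0 \le \theta_k, \delta_i, \beta_{j,k} \le 1$ and
$\sum_j \beta_{j,k} \le 1$ for every rule. Referential values and grade
utilities are fixed; they are structural, not statistical, choices.

Numerically, `train_brb()` runs a box-constrained quasi-Newton search
(L-BFGS-B) with forward finite-difference gradients (step $10^{-7}$,
switching to a backward step on the upper box face so the search never
evaluates outside the feasible box). The per-rule mass constraints
$\sum_j \beta_{j,k} \le 1$ are enforced during the search by a quadratic
exterior penalty (weight 1000 by default; the data term is of order
$10^{-1}$, so even a $10^{-3}$ violation is heavily dominated) and exactly
afterwards by projection — clipping to the box, then rescaling any rule's
belief vector whose sum still exceeds 1. An accept-if-better guard
re-evaluates the projected candidate with the plain (unpenalised)
objective and keeps the initial rule base if the candidate is not
strictly better, so reported final MSE never exceeds initial MSE, even
when the optimiser fails. The procedure is fully deterministic given the
data, the initialisation and the configuration.

Design choices worth recording:

* **Attribute-weight normalisation.** The activation formula uses
  normalised weights $\bar\delta_i = \delta_i / \max_j \delta_j$, the
  standard BRB convention; it makes $\delta$ scale-free, which is also
  why $\delta$ can be boxed to $[0,1]$ without loss.
* **$0^0$ is not treated as 1** in the activation product: a rule whose
  antecedent has zero matching degree receives zero activation weight no
  matter how small its normalised attribute weight is.
* **ER normaliser.** The $\mu$ regulator uses $N - 1$, the number of
  consequent grades minus one, the standard ER form. (In the bundled
  models $M - 1 = N - 1 = 3$, so the distinction is invisible there; it
  matters for other grade counts and is the form under which the
  analytic expression matches the recursive two-source combination rule,
  which the test suite verifies to $10^{-10}$ on a thousand random
  instances.)
* **Out-of-range inputs** are clamped to the nearest boundary referential
  value, preserving the per-attribute sum-to-1 invariant; the
  interpolation rule is silent outside the grid, and clamping is its
  continuous limit.
* **Incomplete beliefs.** A rule may assign total mass below 1, and then
  the aggregated $\hat\beta$ may too. The expected utility is computed on
  the mass as-is by default (residual mass scores zero); `renormalize =
  TRUE` divides by the total mass first. With positive grade utilities
  the literal reading can fall below $u(D_1)$ — the lower utility bound
  is only guaranteed for complete (or renormalised) beliefs.
* **Degenerate aggregation.** A single fully activated rule passes
  through the analytic formula exactly (the one-hot identity is tested to
  $10^{-12}$); the formula's denominator is guarded and a genuinely
  degenerate combination raises an error rather than returning NaN.
* **Optimiser tolerances.** `tol` (default $10^{-6}$) is mapped onto
  L-BFGS-B's relative-reduction criterion; `max_iter` defaults to 500.
  The studies below use `max_iter = 60`, which on this problem is past
  the point of visible accuracy gain — the objective's remaining descent
  is fitting quantisation noise.

## The synthetic cohort

No patient records ship with the package; `simulate_dataset()` generates
them. The generator mirrors the design of the study the bundled rule
bases come from — 2,000 records, split 1,600/400 into training and test
sets — with the bundled trained reference model as the default
ground-truth labeller:

* features are drawn uniformly over each attribute's referential range
  (or, under the stratified scheme, rejection-sampled until the truth
  model's grade matches a target grade drawn from configurable
  proportions, uniform over the four grades by default — the class
  balance of the original cohort is not published);
* each record is labelled with the truth model's discrete grade
  assessment of its *clean* features;
* optional label noise flips a record's grade to a uniformly drawn other
  grade; the default rate is 0;
* Gaussian observation noise with standard deviation equal to 2% of each
  attribute's referential range is then added to the features and the
  result clamped back into range, emulating sensor error around a
  clinician-graded true state.

Everything is reproducible from a single integer seed.

What the generator deliberately does not emulate: real torque/EMG
dynamics within a session, correlations between the three attributes,
cohort-specific class imbalance, and any drift of a patient across
sessions. Passing the recovery studies below therefore shows that the
estimator can undo parameter perturbations under the model's own data
distribution — it does not certify clinical accuracy on hospital data.

## What the scaled study shows

`scripts/acceptance.R` runs the full pipeline at the study's design size:
simulate 2,000 records from the trained reference model, split 1,600/400,
train from the expert initialisation (`max_iter = 60`), and score the
trained BRB against seeded feed-forward network (`nnet`, one hidden layer
of 8 units, weight decay $10^{-3}$) and radial-kernel SVM (`e1071`)
baselines on the held-out 400. The baselines are deliberately thin
adapters over established implementations; their hyperparameters are
package defaults recorded in `fit_baseline()`, since no reference
settings exist to copy.

Because the expert initialisation is already structurally close to the
reference model, its held-out accuracy starts high (around 0.9 under the
default 2% observation noise) and training reliably lowers the MSE and
nudges accuracy up a few points. The test suite repeats the study over
ten seeds and requires MSE improvement in all ten and held-out accuracy
of at least 0.85 in at least eight.

## Known limitations

* The MSE surface is non-convex; L-BFGS-B finds a local optimum near the
  initialisation, which is the intended use (refining expert knowledge),
  not a global search. `n_starts > 1` adds seeded perturbed restarts.
* Gradients are finite differences over 138 parameters, so each optimiser
  iteration costs 139 objective evaluations; training cost scales
  linearly in records × iterations.
* Matching is piecewise linear between referential values; no other
  membership shapes are provided, and the rule-base structure (grid,
  grades, utilities) is fixed during training.
* The three-attribute, three-level grid yields 27 rules; the full-grid
  construction grows exponentially with attributes, which is acceptable
  here but would need rule reduction for wider inputs.
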