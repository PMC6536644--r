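---
title: "Modelling behavior change: EUT, TPB and the decision-theoretic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling behavior change: EUT, TPB and the decision-theoretic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtmbc)
```

## The modelling problem

Clinicians and public-health researchers who want to change a habitual
behavior — start exercising, stop smoking — need to predict how likely a
person is to *intend* the behavior and, separately, how likely they are to
*do* it. Three model families are implemented here on a common footing:

* **Expected utility theory (EUT).** The agent holds beliefs
  $P(s_n \mid a_j)$ about which outcome state each action produces and
  utilities $U_{\mathrm{self}}(s_n)$ over states. The value of an action is
  $E[U_{\mathrm{self}} \mid a_j] = \sum_n P(s_n \mid a_j)\,U_{\mathrm{self}}(s_n)$,
  and with a binary action set the choice follows the logistic rule
  $P(a_1) = \sigma\!\big(\beta_1\{E[U|a_1]-E[U|a_2]\} + \beta_0\big)$,
  where $\sigma$ is the logistic function, $\beta_1 \ge 0$ the inverse
  temperature and $\beta_0$ a decision bias.

* **Theory of Planned Behavior (TPB).** Behavioral intention is an
  *additive* score
  $BI(i_1) = w_1 E[U_{\mathrm{self}}|a_1] + w_2 U_{\mathrm{others}}(a_1) + w_3 P(a_1|i_1)$
  combining attitude, subjective norm
  ($U_{\mathrm{others}}(a_1)=\sum_k m_k U_k(a_1)$ over referents $k$) and
  perceived self-efficacy $P(a_1|i_1)$. Intention probability is
  $\sigma(\beta_1 BI + \beta_0)$ and behavior probability is the product
  $P(a_1|i_1)\,P(i_1)$ — valid only under the implicit assumption
  $P(a_1|i_2)=0$, i.e. nobody performs the behavior without intending it.

* **Decision-theoretic model (DTM).** Intentions, not actions, are valued.
  An intention set $\{i_1, i_2\}$ feeds an intention→action→state chain:
  $E[U_{\mathrm{total}} \mid i_h] = \sum_j P(a_j|i_h) \sum_n P(s_n|a_j)
  \{U_{\mathrm{self}}(a_j,s_n) + w\,U_{\mathrm{others}}(a_j,s_n)\}$,
  with $w \ge 0$ weighting others' utility. Intention probability is
  logistic in the *difference* $E[U|i_1]-E[U|i_2]$, and behavior
  probability is the mixture
  $P(a_1) = P(a_1|i_1)P(i_1) + P(a_1|i_2)P(i_2)$. Self-efficacy
  *multiplies* value instead of being added to it, utilities may depend on
  the action as well as the state, and the second intention is modelled
  explicitly.

The qualitative divergence between the additive and multiplicative rules
is what `jar_lid_scenario()` demonstrates: an agent who is fully paralyzed
(both self-efficacies zero) cannot open a jar however valuable its
contents. TPB's additive intention score keeps rising with the contents'
value; DTM's intention probability is flat in it and its behavior
probability is exactly zero.

```{r}
jar_lid_scenario(content_values = c(0, 0.5, 1))
```

When the intention→action links are deterministic ($P(a_1|i_1)=1$,
$P(a_1|i_2)=0$), $w=0$ and utilities do not depend on the action, DTM
collapses exactly to EUT; the test suite asserts this reduction
identically, not approximately.

## Conventions and tunable parameters

* **Logistic family.** The sigmoidal selection rule is fixed as the
  standard logistic $1/(1+e^{-x})$; it is the conventional choice for
  binary discrete choice and makes the fitting problem a (generalised)
  logistic regression.
* **Per-model decision parameters.** $\beta_1$ and $\beta_0$ are separate
  parameter instances for the EUT, TPB and DTM rules. They are fitted per
  model anyway, and nothing forces an agent's action noise and intention
  noise to coincide.
* **Probability hygiene.** Conditional-probability columns must sum to 1
  within `1e-6`. Inputs further off are *refused* with an error rather
  than renormalised, so elicited beliefs are never silently altered.
  Binary-state constructors (`belief_set_binary()`) accept the positively
  worded probability alone and fill the complement, because questionnaires
  only elicit the positive-outcome item.
* **Units.** Probabilities live on $[0,1]$; utilities scored from
  questionnaires live on $[-1,1]$; $w$, $\beta_1 \ge 0$ and $\beta_0$ are
  dimensionless. The TPB intention score mixes utility- and
  probability-scaled terms; its weights $w_1,w_2,w_3$ are assumed to
  absorb the scale difference, which is one reason they are not separately
  identifiable from an overall inverse temperature (see fitting below).

## Questionnaire scoring

The TPB instrument measures one item per construct (behavioral belief,
outcome evaluation, one normative referent with motivation to comply,
self-efficacy, intention, and a follow-up behavior report); the DTM
instrument adds the counterfactual belief $P(s_1|a_2)$, the no-intention
self-efficacy $P(a_1|i_2)$, and all four action-by-state cells of both
utility functions. Ratings map to parameters linearly — the instruments
calibrate only the anchors, so linearity is the minimal assumption, and
each item's schema records its scale and which pole is positive:

* probability items: positive anchor $\to 1$, negative anchor $\to 0$;
* utility items: positive anchor $\to +1$, midpoint $\to 0$, negative
  anchor $\to -1$;
* motivation to comply: mapped to $[0,1]$ — it is a weight, and negative
  compliance is not contemplated.

Two scoring conventions are worth flagging. First, the TPB instrument
evaluates only the named outcome, so $U_{\mathrm{self}}(s_2)$ is fixed at
0 (the complementary state is the reference point — consistent with the
worked example's $(1, 0)$ utilities), and $P(s_1|a_2)$, which no TPB
formula uses, is stored as an uninformative 0.5. Second, the DTM
instrument elicits the referent's evaluation of each (action, state) cell
directly; those ratings enter $U_{\mathrm{others}}$ as-is, and the
*strength* of social influence is carried by $w$, which is a decision
parameter, not a questionnaire item. A separate helper,
`tpb_to_dtm_utilities()`, lifts a TPB parameterization into DTM form
($U_{\mathrm{self}}(a_j,s_n) := U_{\mathrm{self}}(s_n)$;
$U_{\mathrm{others}}(a_1,\cdot) := \sum_k m_k U_k(a_1)$,
$U_{\mathrm{others}}(a_2,\cdot) := 0$), preserving the correspondence
between the two intention formulas.

## Estimation

`fit_decision_model()` maximises the Bernoulli likelihood of observed 0/1
intentions (actions, for EUT), treating each respondent's scored beliefs
and utilities as known covariates. Design choices:

* **TPB identifiability.** In $\sigma(\beta_1\{w_1 A + w_2 N + w_3 S\} + \beta_0)$
  only the products $\beta_1 w_j$ enter, so $\beta_1$ is fixed at 1 and
  $(w_1, w_2, w_3, \beta_0)$ are free; the weights keep their standard
  interpretation. This makes the TPB fit an ordinary logistic regression,
  which the tests exploit as an independent cross-check against `glm()`.
* **DTM parameters.** $(\beta_0, \beta_1, w)$ are free with
  $\beta_1 \ge 0$, $w \ge 0$; $w$ is fitted as a population constant. The
  likelihood is nonlinear in $w$ (it multiplies inside the expected
  utility), so a general optimiser is required: multi-start L-BFGS-B
  (default 8 seeded starts: the natural default plus uniform
  perturbations) with the analytic gradient, which a test matches against
  central finite differences.
* **Numerical guards.** Predicted probabilities are clipped to
  $[10^{-12}, 1-10^{-12}]$ inside the likelihood; a constant outcome
  vector (complete separation — no interior optimum) raises a dedicated
  diagnostic error instead of a runaway fit; standard errors come from the
  observed information and are reported as `NA` when the Hessian is not
  positive definite. Fits are bit-reproducible given the seed.
* **Model comparison.** `compare_models()` reports log-likelihoods,
  parameter counts and the AIC difference, and refuses fits computed on
  different outcome vectors. It attaches no verdict language.

## The synthetic cohort generator

`cohort_config()` / `simulate_cohort()` draw heterogeneous agents and push
them through the generative chain: intention
$\sim$ Bernoulli(DTM intention probability), action
$\sim$ Bernoulli(actual self-efficacy of the realised intention), state
$\sim$ Bernoulli(belief of the realised action), in that fixed order on a
single seeded stream. Perceived and actual self-efficacy are distinct
fields — the prediction formulas use the perceived value as a proxy for
the actual one, and the generator lets you break that proxy assumption —
but by default they are equal.

No canonical population distributions exist for these constructs, so the
defaults were chosen once as a plausible mildly-favorable population and
are stated in every config rather than hidden: beliefs that the behavior
helps and with-intention self-efficacy $\sim$ Beta(4, 2) (mean 2/3),
belief that *not* acting helps $\sim$ Beta(2, 4), no-intention
self-efficacy $\sim$ Beta(2, 6) (mean 1/4), and all utility cells
$\sim$ Uniform($-1, 1$). All supports are validated against each field's
range at configuration time, so sampling never rejects (the rejection
count is still recorded for audit). Point-mass distributions reduce the
generator to a single agent replicated $n$ times, which is how the
Monte-Carlo tests compare empirical intention/behavior frequencies with
the closed forms at $3\cdot$SE.

What the generator does *not* emulate: item-level measurement error and
Likert discretisation (agents' parameters are continuous), correlation
between constructs within an agent, per-agent variation in $w$ or the
$\beta$s, and any longitudinal structure. Passing recovery tests
therefore show that the estimator works when the model is true and the
covariates are measured exactly — not that real questionnaire data meet
those conditions.

## Problem sizes and verified tolerances

The test suite runs the algebraic-equivalence properties on 1,000 random
parameter sets (agreement within $10^{-9}$), the Monte-Carlo agreement on
a $10^5$-agent point-mass cohort ($3\cdot$SE), and parameter recovery at
$n = 5000$ with true $(\beta_1, \beta_0, w) = (2, -0.5, 0.5)$. The
recovery tolerance of $\pm 0.15$ per parameter was frozen after a
20-replicate pilot at that design (median absolute errors
$\approx 0.02 / 0.08 / 0.03$ for $\beta_0 / \beta_1 / w$); the consistency
property is checked as a monotone decrease of median error over
$n \in \{500, 2000, 5000\}$.

## Limitations

* Binary action and intention sets only; the state set is general in the
  core model but the questionnaire, generator and fitting layers use the
  two-state case the instruments elicit.
* No temporal structure: single-shot decisions, no discounting, no
  Markov-decision-process dynamics.
* $U_{\mathrm{total}}$ is the weighted sum
  $U_{\mathrm{self}} + w\,U_{\mathrm{others}}$; other social-preference
  functionals (inequality or guilt aversion) are out of scope.
* No psychometrics: single items per construct, no reliability or latent
  structure; scoring is deterministic item arithmetic.
* Estimation is frequentist ML with known covariates; no hierarchical or
  Bayesian treatment, and $w$ is a population constant, not per-agent.
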