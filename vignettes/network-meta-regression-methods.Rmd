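---
title: "Methods: Bayesian network meta-analysis and meta-regression in nmareg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian network meta-analysis and meta-regression in nmareg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nmareg` fits Bayesian network meta-analysis (NMA) models to arm-level
binary outcome data — the setting of anticoagulant trials for stroke
prevention in atrial fibrillation, where a connected network of
randomised comparisons (warfarin-anchored, with placebo, antiplatelets
and novel oral anticoagulants as comparators) must be synthesised into a
single coherent set of relative treatment effects. This vignette states
the model, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data validation does and does not
establish.

## The core model

For arm $k$ of study $i$ with $r_{ik}$ events in $n_{ik}$ patients,

$$r_{ik} \sim \mathrm{Binomial}(n_{ik},\ p_{ik}), \qquad
\mathrm{logit}(p_{ik}) = \mu_i + \delta_{ik}\,\mathbb{1}[k \ne b_i],$$

where $b_i$ is the study's baseline arm (the lowest treatment code
present — a convention, since the data do not order arms), $\mu_i$ is the
trial-specific baseline log-odds, and $\delta_{ik}$ is the trial-specific
log odds ratio of arm $k$'s treatment versus the baseline treatment.

* **Fixed effect (FE):** $\delta_{ik} = d_{t_{ik}} - d_{t_{ib_i}}$, with
  $d_1 = 0$ for the reference treatment (placebo; always code 1).
* **Random effects (RE):** the vector of a study's $\delta_{ik}$ follows
  a multivariate normal with means $d_{t_{ik}} - d_{t_{ib_i}}$, common
  variance $\sigma^2$ and pairwise correlation $1/2$ — the standard
  multi-arm construction that keeps all within-trial contrasts
  exchangeable with common between-study SD $\sigma$. The density is
  evaluated in closed form
  ($\Sigma^{-1} = \tfrac{2}{\sigma^2}(I - \tfrac{1}{m+1}J)$ for $m$
  non-baseline arms), which is equivalent to the usual sequential
  conditional construction.

Zero-event arms enter the likelihood as $n\log(1-p)$ with **no
continuity correction**, and the deviance uses the $0\log 0 = 0$
convention; nothing special is done to zero cells anywhere.

**Priors.** $\mu_i, d_k \sim N(m_0, 100^2)$ and
$\sigma \sim U(0, 2)$. The default prior mean is $m_0 = 0$; a mean of 1
(as sometimes printed for this model family) is supported via
`model_spec(prior_effect_mean = 1)` and is numerically indistinguishable
at SD 100 — the acceptance script measures the shift between the two and
compares it against the sampler's own re-seeding noise floor. The
interaction coefficient (below) has prior $N(0, 100^2)$; the model
family gives no information to choose otherwise.

## Covariate meta-regression

With a study-level covariate $x_i$ (centered at the mean of the retained
studies) the linear predictor becomes

$$\mathrm{logit}(p_{ik}) = \mu_i + \delta_{ik}
  + \beta\, x_i \left(\mathbb{1}[t_{ik} \ne 1] - \mathbb{1}[t_{ib_i} \ne 1]\right).$$

One coefficient $\beta$ modifies every treatment's effect *versus the
reference* identically (a "common interaction"); consequently, in any
trial whose arms are all non-reference the $\beta$ terms cancel in every
within-trial contrast — head-to-head comparisons of active treatments
are covariate-free by construction. This is tested at machine precision.

Studies missing the covariate are dropped (`attach_covariate()`), the
reduced network re-validated, and the matching **unadjusted model is
re-fitted on the same reduced data** before any DIC comparison; DIC is
only meaningful on identical data and `dic_difference()` enforces that.

**Units.** Proportion covariates are regressed in percent (0–100), age
in years; follow-up is stored in months for descriptives but regressed
**per year** (scale $1/12$), since a per-month coefficient would be an
order of magnitude below the other effects. Any scale can be overridden
per call; $\beta$ rescales exactly inversely and nothing else changes.

**Centering algebra.** Shifting $x$ by a constant $c$ leaves $\mu_i$ and
$\beta$ untouched, moves every $d_k$ (defined at $x = 0$) by
$-\beta c$, and cancels in all non-reference contrasts. The test suite
asserts exactly this; note the baseline arms carry no interaction term,
so baselines cannot absorb the shift.

## Baseline risk as a latent covariate

Baseline risk — the underlying risk of the outcome in a study's
population — is operationalised as the trial baseline log-odds. Using
the *observed* baseline-arm logit as a fixed covariate is known to bias
the association: the covariate's sampling error is shared with the
effect estimate (regression dilution and worse). The baseline-risk model
therefore uses the **model's own latent $\mu_i$** as the covariate,
centered at a fixed constant $\bar m$ (the mean of the observed
baseline-arm empirical logits, with a $1/2$ correction only inside this
descriptive constant): uncertainty in every baseline propagates into
$\beta$. Trials without a reference arm use their own baseline $\mu_i$;
their contrasts are invariant to $\beta$ anyway (cancellation above).
$\bar m$ is fixed rather than recomputed per iteration because a moving
center destabilises the chain and changes only the interpretation of the
$d_k$, not of $\beta$.

**Independent versus exchangeable baselines.** With the package's
default vague independent $N(0,100^2)$ priors on $\mu_i$, simulation
shows the latent-covariate model does *not* remove the small-trial bias:
with no distributional model for the latent covariate there is nothing
to correct the errors-in-variables problem with (an incidental-parameters
effect; we verified it persists with 60 studies and 40k iterations, and
vanishes as arm sizes grow). `fit_baseline_risk_model(...,
baseline_prior = "exchangeable")` instead models
$\mu_i \sim N(b_\mu, b_\sigma^2)$ with vague hyperpriors
($b_\mu \sim N(0,100^2)$, $b_\sigma \sim U(0,5)$); this is the full
errors-in-variables treatment, and in paired-seed simulations with a
null interaction it stays near zero where both the naive observed-logit
covariate and the independent-prior latent model drift to $\approx -0.3$.
The default remains `"independent"` to match the model family's stated
vague-prior convention; the dilution demonstration in the test suite
uses `"exchangeable"` deliberately.

## Sampling and convergence

No general-purpose MCMC engine is available to this package at build
time, so the sampler is part of the package: an adaptive
Metropolis-within-Gibbs scheme in C++ (one Gaussian random-walk update
per parameter per sweep, log step sizes adapted toward 44% acceptance
with diminishing adaptation during burn-in, frozen afterwards). Chains
start overdispersed, drawn from the priors truncated to $|v| \le 5$ on
the log-odds scale (the interaction start is truncated to
$5/\mathrm{sd}(x)$ so an extreme start cannot saturate the likelihood).
The production default is 3 chains with 50,000 burn-in and 50,000
retained iterations; `mcmc_config_test()` (3 × 2,000/2,000) is the
scaled-down setting used throughout the tests, and baseline-risk fits
use ≥ 5,000/5,000 because the interaction coefficient mixes more slowly
there. The pure-R `log_joint()` implements the identical density and is
checked against a brute-force pmf-summation oracle; the C++ sampler is
validated against *it* (large-sample posterior checks, parameter
recovery), keeping two independent routes to the same model.

**Convergence.** `convergence_report()` computes a
Brooks-Gelman-Rubin-style potential scale reduction factor per monitored
parameter as the ratio of pooled to mean-within-chain *population*
variances — exactly 1 at zero between-chain variance — on split
half-chains by default, plus lagged autocorrelations. Any value above
the threshold (default 1.05) flags the fit, and fitting functions warn
prominently; nothing fails silently. The statistic agrees with coda's
PSRF at stationarity; on separated chains both diverge but with
different finite-sample corrections.

## Model criticism

Per data point, the residual deviance against the saturated model is
$\mathrm{dev}_{ik} = 2[r\log(r/\hat r) + (n-r)\log\{(n-r)/(n-\hat r)\}]$
with $\hat r = n p_{ik}$, averaged over the posterior
($\bar D = \sum_i \mathrm{dev}_i \approx$ number of data points for an
adequate model). $\hat D$ plugs in the **posterior mean of $p_{ik}$ on
the probability scale** (the plug-in scale is a convention; the linear
predictor scale differs slightly and the choice is recorded here),
$p_D = \bar D - \hat D$, $\mathrm{DIC} = \bar D + p_D$. Leverage plots
place each point at (signed root deviance $w_i$, per-point leverage
$p_{Di}$); points above the parabola $c = x^2 + y$ at $c = 3$ are
flagged. A degenerate plug-in ($\hat r \in \{0, n\}$ against discordant
$r$) propagates an infinite contribution rather than masking it.

## The synthetic world

`simulate_network()` generates from exactly the fitted model: an
anchor-centred network (every study carries the anchor treatment, as in
the motivating warfarin network, so connectivity holds by construction
and loops arise only from multi-arm studies), baselines
$\mu_i \sim N(-2.3, 0.38^2)$ (reference-arm odds centred near 0.10,
spanning roughly 0.05–0.22), uniform covariates over the published
ranges (follow-up 11–42 months, males 46–100%, previous stroke/TIA
0–55%, age 66–75 years), between-study SD 0.26, and per-arm sizes
log-uniform over 150–1,500 with a 15% rate of small (60-patient-arm)
studies whose low event counts produce occasional zero-event arms
naturally — never by post-hoc zeroing. `paper_like_preset()` fixes 19
studies and 15 treatments. When a seed leaves too few free arm slots to
place all treatments, 2-arm studies are upgraded to 3 arms, so the
2-/3-arm mix is approximate. Basic effects are a fixed vector (anchor
−0.9; analogues of the newer anticoagulants near −1; antiplatelet-like
comparators −0.2 to −0.6), chosen once as clinically plausible log odds
ratios.

A green recovery test establishes that the estimation machinery inverts
its own generative model at realistic sizes — nominal-rate CrI coverage
of $d$, $\sigma$, $\beta$ over ≥ 50 seeded replicates. It does **not**
establish agreement with any published posterior: the published
arm-level dataset exists only as a manually transcribed supplementary
table that is not redistributable here, so all validation is against
known synthetic truth, and the preset is labelled a stand-in throughout.

## Known limitations

* Random-walk sampling mixes slowly for weakly-identified corners
  (treatments informed by a single small trial; the baseline-risk
  interaction); the convergence report is the guard, and production runs
  should use the full 50k/50k budget.
* No node-splitting/inconsistency assessment: the anchor-star topology
  has no independent loops to split.
* One covariate at a time; no exchangeable or independent per-treatment
  interactions — the data settings this package targets cannot identify
  them.
* Binary outcomes only; follow-up enters as a covariate, never as an
  exposure-time offset.
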