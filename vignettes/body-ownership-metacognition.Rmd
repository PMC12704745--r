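---
title: "Models and methods: metacognition of body ownership"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: metacognition of body ownership}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models implemented in `metaown`, the
conventions they follow, and the reasoning behind the main design decisions.
It is a methods reference, not a tutorial; see the README for a worked
example.

## The task

The package analyses a two-alternative forced-choice (2AFC) version of the
rubber hand illusion. On every trial two rubber hands are stroked, one
synchronously with the participant's hidden real hand and one with a
visuotactile asynchrony (18–150 ms). The participant reports which hand felt
more like their own (type-1 response) and rates the clarity of that feeling
on the 3-point Perceptual Awareness Scale (PAS; type-2 response). A speeded
variant records decision and post-decision response times for
diffusion-model analyses.

## Type-1 signal detection

With the right hand coded as the signal side, a *hit* is responding "right"
when the right hand was synchronously stroked and a *false alarm* is
responding "right" when the left hand was. `dprime_2afc()` uses the 2AFC
convention

$$d' = \tfrac{1}{\sqrt 2}\left[Z(P_{Hit}) - Z(P_{FA})\right], \qquad
  C = -\tfrac12\left[Z(P_{Hit}) + Z(P_{FA})\right],$$

so that $d'$ is expressed on the single-interval axis of the underlying
evidence. When any raw rate is 0 or 1, the log-linear correction (0.5 added
to each type-1 cell) is applied and flagged in the output. All evidence
distributions are equal-variance Gaussians with $\sigma = 1$; this
$s = 1$ convention is fixed throughout the package.

## Meta-d′ and the M-ratio

`fit_metad()` implements the meta-d′ model: the type-2 (rating) data are fit
with an SDT observer whose stimulus distributions sit at $\pm
\mathrm{meta}\text{-}d'/2$, whose type-1 criterion is pinned at the
empirically observed *relative* criterion $c' = c_1/d'_1$ (so
$c_{1,meta} = c' \cdot \mathrm{meta}\text{-}d'$), and whose two rating
criteria per response side are free parameters. Maximising the
response-conditional multinomial likelihood of the ratings yields meta-d′:
the type-1 sensitivity an SDT-ideal rater would need to reproduce the
observed confidence–accuracy relationship. Zero cells are handled by adding
$1/(2 \times \text{n ratings})$ to every type-2 cell.

Meta-d′ is reported in the same convention as `dprime_2afc()` (divided by
$\sqrt2$ under the default `scale = "2afc"`), so `meta_dprime` and `dprime`
are directly comparable and the efficiency

$$\text{M-ratio} = \mathrm{meta}\text{-}d' / d'$$

is convention-free. Optimisation is bounded quasi-Newton from five
deterministic starts; ties are broken toward the smaller |meta-d′|. The
exported `metad_loglik()` lets the optimum be verified by direct search,
which is exactly what the test suite does.

## The synthetic observer

`simulate_sdt_dataset()` generates data from a two-layer observer:

- **Type 1.** Evidence $x \sim N(\pm D/2, 1)$ with internal separation
  $D = \sqrt2\,d'$, so the fitted 2AFC $d'$ recovers the generative value.
  The response is `right` iff $x > C$.
- **Type 2.** A second evidence sample with separation $m \cdot D$
  (where $m$ is the generative M-ratio) is drawn *conditional on the
  response*: truncated above the proportionally scaled criterion
  $c_{1,meta} = m\,C$ for "right" responses and below it for "left"
  responses, and cut by two outward increments into PAS 1–3.

This response-congruent truncated-Gaussian layer is the exact generative
counterpart of the meta-d′ measurement model, so `fit_metad()` recovers the
generative $m$ for *any* positive value — including $m > 1$
(hyper-efficiency), which an alternative noise-inflation scheme
($\sigma_{meta} > 1$) cannot express. Lapse trials (probability
`lapse_rate`) produce a uniform random response and a rating drawn from
stimulus-independent noise.

## Hierarchical Bayesian group M-ratio

`fit_hmeta_group()` fits one joint model over all subjects and conditions
with JAGS. For condition $c$, subject $s$:

$$\log M_{s,c} \sim N(\mu_c, \sigma_c^2)\ \text{truncated to } [-5, 2.3],
\qquad \mu_c \sim N(0, 1), \qquad \sigma_c \sim N^+(0, 1),$$

with subject meta-d′ $= e^{\log M_{s,c}} \cdot d'_{1,s,c}$ anchored at the
subject's (log-linear corrected) type-1 point estimates, rating-criterion
increments given half-normal priors, and the six rating cells per stimulus
class modelled as a multinomial whose cell probabilities multiply the fixed
type-1 response probability by the meta-level conditional rating
probability. Three chains are run (10,000 kept iterations by default after
1,000 burn-in; the pipeline templates default to a faster 3 × 2,000 / 500
setting). If the split-$\widehat R$ of any group node exceeds 1.05 a warning
is attached and the `credible` flags from `compare_conditions()` are set to
`NA`.

Condition contrasts are summarised by the posterior mean difference in
$\mu$ (log units) and its 95% highest-density interval (`hdi()`, shortest
interval from the sorted draws); a difference is *credible* when the
interval excludes zero.

## Wiener diffusion model

The speeded task is modelled as a Wiener diffusion with diffusion scale
$s = 1$, absorbing boundaries $\{0, a\}$, relative start point $w$, drift
$v$ signed toward the correct boundary, and nondecision time $t_0$.
`wiener_fpt_density()` evaluates the first-passage-time density with the
small-time / large-time series expansions, switching per evaluation to the
representation that needs fewer terms for a truncation error below $10^{-7}$.
The upper-boundary density is obtained from the lower-boundary series by the
reflection $v \to -v$, $w \to 1 - w$.

Simulation (`simulate_ddm_trials()`) uses Euler–Maruyama integration at
`dt = 1` ms; trials not absorbed by the stimulation limit are emitted with
`censored = TRUE` and excluded from fitting by default.

`fit_ddm_mle()` fits one subject by maximum likelihood (per-condition drift,
$\log a$, $\mathrm{logit}\,w$, $\log t_0$). `fit_hddm()` fits the group with
a Metropolis-within-Gibbs sampler: each subject's parameter block is updated
jointly by an adaptive random-walk proposal (target acceptance 0.25,
adaptation during burn-in only), and the group means and variances have
conjugate normal / inverse-gamma updates. Chains start from jittered
subject-level maximum-likelihood fits; convergence is asserted at
split-$\widehat R < 1.02$ on the group parameters.

## v-ratio: postdecisional accumulation

`fit_vratio()` jointly fits the decision-stage diffusion and a
postdecisional accumulator for the PAS report: after the decision, evidence
continues with drift $v_{post}$ (signed by the stimulus) for the trial's
observed post-decision interval $t_{post}$ (capped at the 3 s rating
window). In the frame of the chosen response the terminal state is
$N(\pm v_{post}\,t_{post},\; t_{post})$ on correct/error trials; two fitted
cut-points map it to PAS 1–3. The efficiency measure is

$$\text{v-ratio} = v_{post} / \bar v,$$

the dynamic analogue of the M-ratio: 1 means the rating uses evidence of
the same quality as the decision, 0 means ratings carry no information
about accuracy.

## Group statistics

- `rm_anova_gg()`: one-way repeated-measures ANOVA from sums of squares
  with partial $\eta^2$ and the Greenhouse–Geisser $\epsilon$ computed from
  the double-centred condition covariance matrix (clamped to
  $[1/(k-1), 1]$); degrees of freedom are corrected whenever
  $\epsilon < 1$. `rm_anova_mixed()` adds one between-subject factor.
- `bayes_t_one_sample()`: JZS Bayes factor with a Cauchy(0, 0.707) prior on
  standardised effect size, by direct quadrature of the noncentral-t
  likelihood over the prior; one-sided version over the positive
  half-Cauchy; optional robustness sweep over prior widths.
- `bf_oneway_rm()`: Bayesian repeated-measures ANOVA under Zellner–Siow
  g-priors ($r = 0.5$ fixed, $r = 1$ random effects), marginal likelihoods
  by seeded Monte-Carlo integration over the g parameters; reported as
  BF$_{01}$ (support for the null of no condition effect).
- `nonparametric_tests()`: Kolmogorov–Smirnov normality screening per group
  and the Kruskal–Wallis rank test, the standard treatment for skewed
  response-time data.

## Pipeline and reproducibility

`run_config()` bundles a template (`exp1`, `exp2`, `exp3`, `control1`,
`control2`), design and observer parameters, sampler settings, and a
mandatory seed, and stamps the whole configuration with a hash.
`run_pipeline()` derives a distinct seed for every stage from the
configuration seed, so identical configurations reproduce all non-MCMC
outputs bit-identically and MCMC outputs exactly when the same sampler
settings are used. Every result table carries the configuration hash and
seed as attributes; `write_tables()` writes tab-separated tables, tidy
posterior draws, the stage log, and a manifest.

The five templates encode the study conditions: `exp1` — five asynchronies,
60 trials each, 32 subjects; `exp2` — four asynchronies crossed with three
touch numbers; `exp3` — the speeded design with diffusion and v-ratio
analyses (20 subjects, 96 trials per asynchrony); `control1` — rotated
hands, a chance-level discrimination control analysed for type-1
sensitivity only; `control2` — reduced metacognitive efficiency at intact
type-1 sensitivity.

## Choices and limitations

- Group MCMC defaults in the pipeline templates (3 chains × 2,000 kept
  iterations) are sized for routine use; pass
  `sampler = list(iterations = 10000, burn_in = 1000)` for final inference.
- The hierarchical M-ratio model conditions on subject-level type-1
  estimates (empirical-anchor approach) rather than modelling type-1
  uncertainty; subjects with near-zero $d'$ are anchored at $d' = 0.05$ to
  keep the meta-level scale defined.
- The v-ratio model fixes the postdecisional accumulation interval at the
  observed post-decision response time rather than estimating a latent
  interlude, and fits a single $v_{post}$ across conditions in the default
  pooled mode.
- Censored decision-stage trials are excluded, not integrated over; with
  the default 30 s stimulation limit censoring is negligible at the study's
  drift rates.
- `fit_hddm()` assumes independent group normals on the transformed
  parameters; it does not model parameter correlations across subjects.
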