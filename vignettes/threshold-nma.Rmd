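---
title: "Random-effects NMA and bias-adjustment threshold analysis"
author: "nmarobust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-effects NMA and bias-adjustment threshold analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Public-health interventions for preventing accidents in homes with children
under five are typically bundles of components — education, free or low-cost
safety equipment, fitting of that equipment, home safety inspection — trialled
in heterogeneous designs (individually and cluster-randomised trials, and
non-randomised comparisons). A network meta-analysis (NMA) combines all
head-to-head comparisons into a single coherent analysis and ranks the
interventions, but when the evidence is sparse and heterogeneous the
resulting recommendation can hinge on a handful of estimates. This package
fits the NMA and then asks the robustness question directly: *how much would
any one piece of evidence have to change before a different intervention were
recommended?*

The package ships the two evidence bases it was built around — uptake of safe
storage of household products (15 studies, 7 interventions) and possession of
a fitted stair gate (12 studies, 7 interventions), both binary uptake
outcomes with "usual care" as intervention 1 — plus a generator for synthetic
networks with known truth.

## The NMA model

For arm $k$ of study $i$ with $r_{ik}$ events in $n_{ik}$ households,

$$ r_{ik} \sim \mathrm{Binomial}(p_{ik}, n_{ik}), \qquad
   \mathrm{logit}(p_{ik}) = \mu_i + \delta_{i,k}, $$

with $\delta_{i,b_i} = 0$ for the study's baseline arm (its lowest-coded
intervention). Study effects are exchangeable around the consistency
equations built from the basic parameters $d_{1k}$ (log odds ratio of
intervention $k$ versus the reference, $d_{11}=0$):

$$ \delta_{i,k} \sim \mathrm{Normal}(d_{1,t_{ik}} - d_{1,t_{i1}},\ \tau^2), $$

with the usual conditional construction giving correlation $1/2$ between the
arm effects of multi-arm trials. Priors are deliberately vague:
$\mu_i, d_{1k} \sim \mathrm{N}(0, 100^2)$ and $\tau \sim \mathrm{U}(0, 5)$,
the convention of the technical-support-document family of models this
follows. All three constants are exposed in `nma_config()`; the uniform
upper bound of 5 on a log-odds-ratio scale is effectively unbounded for
uptake outcomes.

Sampling is by MCMC through JAGS, at least two chains, with fixed
per-chain RNG seeds derived from `config$seed` so that every run is exactly
reproducible. A split-chain potential-scale-reduction diagnostic is computed
for every basic parameter and for $\tau$; any value above 1.05 (configurable)
raises a classed warning rather than failing silently.

### Non-integer counts

Cluster-randomised trials enter as design-effect adjusted counts
(`cluster_adjust()`: divide events and denominator by
$1 + (m-1)\,\mathrm{ICC}$), which are not integers — e.g. 46.86/57.96.
The published tables print these adjusted figures and the fixtures carry
them verbatim. JAGS's binomial distribution cannot score non-integer data,
so the likelihood is evaluated directly through its log-gamma
generalisation,

$$ \ell(r, n, p) = \log\Gamma(n{+}1) - \log\Gamma(r{+}1) - \log\Gamma(n{-}r{+}1)
   + r \log p + (n{-}r)\log(1{-}p), $$

attached by the standard Poisson zeros trick. At integer counts this is
exactly the binomial log-likelihood, so one code path serves both.

### Zero cells

A study with an empty 2×2 cell (0 events, or events = size) gets the
Haldane–Anscombe correction in **all** of its arms: events + 0.5,
denominator + 1. The one zero-event study in the poison network is stored
uncorrected in the fixture and corrected on the fly, both for the NMA and
for the delta-method study summaries. (The published footnote describing
the correction is grammatically ambiguous — "adding 0.5 and 1 to
denominator and numerator" — and does not match its own printed counts;
we implement the standard rule and leave the printed counts as they are.)

### Rankings, pairwise analyses, node-splitting

`rank_interventions()` ranks the interventions within every posterior draw
(rank 1 = largest $d_{1k}$; the outcomes here are uptake, so higher is
better) and reports median rank, 95% credible interval (integer quantiles)
and the probability of being best. `fit_pairwise()` runs the same
likelihood and priors restricted to the studies directly comparing one
pair, reproducing the lower triangle of published cross tables, with `NA`
where no head-to-head study exists. `node_split()` separates the direct
evidence on one contrast from the indirect remainder of the network inside
one joint model and reports the two-sided posterior tail probability
$2\min\{\Pr(\Delta>0), \Pr(\Delta<0)\}$ of their difference; the paper the
model family comes from does not state its tail rule, so the symmetric
two-sided version was chosen.

## Threshold analysis

The decision rule is fixed: recommend the intervention with the highest
expected effect (posterior mean of $d_{1k}$). Threshold analysis asks, for
each data point $y_j$, for the smallest additive bias $\varepsilon$ on the
log-OR scale that changes that argmax.

Data points are either the per-study log odds ratios with delta-method
variances $v_j$ (study level), or the fixed-effect inverse-variance pooled
direct estimate per observed contrast (contrast level). The influence of a
bias in $y_j$ on the posterior means $\hat d$ is linearised as

$$ U = \Sigma\, X^\top V^{-1}, $$

where $\Sigma$ is the posterior covariance of $(d_{12},\dots,d_{1K})$
estimated from the MCMC draws, $X$ is the $\pm 1$ design matrix mapping
basic parameters to each data point's contrast, and $V$ is the diagonal
likelihood covariance of the data points under the random-effects marginal:
$v_j + \hat\tau^2$ at study level, pooled variance $+\ \hat\tau^2/m_j$ at
contrast level ($m_j$ = number of direct studies). $\hat\tau$ is a plug-in,
by default the posterior median (the posterior mean is available as an
option). Equating the biased means of the incumbent $k^\*$ and each rival
$a$ gives the candidate thresholds
$(\hat d_{k^\*} - \hat d_a) / (u_{a,j} - u_{k^\*,j})$; the smallest positive
and largest negative candidates are the thresholds $\varepsilon^+_j$,
$\varepsilon^-_j$, the rival achieving them is the new optimum on that
side, and $(y_j + \varepsilon^-_j,\ y_j + \varepsilon^+_j)$ is the
decision-invariant interval. A side with no candidate is unbounded —
exported as the string `NT` ("no threshold"). A data point is *robust*
when its 95% interval lies inside its invariant interval.

This first-order construction is validated in the test suite against a
brute-force oracle (`brute_force_decision_flip()`) that refits the whole
NMA on a grid of biases and reports the first grid point at which the
recommendation actually changes; on 3-treatment synthetic networks the
linear thresholds track the refit flip points to within
max(0.1, 10%) plus one grid step.

### Which interval judges robustness at contrast level?

At study level the 95% interval is the delta-method confidence interval of
the study estimate. At contrast level two candidates exist: the confidence
interval of the pooled direct estimate, and the NMA posterior credible
interval of the contrast. A contrast observed by exactly one study must
agree qualitatively with that study's row in the study-level analysis —
same data point, same variance, hence identical thresholds — and only the
pooled-direct interval preserves that agreement (the posterior credible
interval of a contrast inside a heterogeneous network can be far wider than
the direct evidence and flips such rows to non-robust). The robust flag
therefore uses the pooled-direct interval by default; the posterior
credible intervals are still computed and carried in the report
(`cri_low` / `cri_high`), and `interval = "posterior"` switches the flag to
them.

## The synthetic generator

`simulate_network()` draws networks from exactly the model the NMA assumes:
baselines $\mu_i \sim \mathrm{N}(-0.5, 0.5^2)$ by default (mid-range uptake
proportions comparable to the packaged networks), study effects
$\mathrm{N}(d_k - d_c + \mathrm{bias}_i, \tau^2)$, binomial counts. The
contrast layout always contains a spanning set so the network is connected;
two-arm studies are the default (matching the fixtures) with optional
three-arm studies drawn with the compound-symmetric effect covariance.
Per-study additive biases support consistency and threshold experiments.
`poison_like_scenario()` fixes the topology and arm sizes to the shape of
the poisoning-prevention network.

What the generator deliberately does **not** emulate: raw cluster-level
sampling (only design-effect adjusted summaries), non-randomised-design
confounding, outcome-dependent reporting. Passing recovery tests on this
generator therefore demonstrates correctness of the estimation machinery
under the model's own assumptions, not robustness to violations of them.

## Numerical and design choices

* **Problem sizes.** The replication fits use 3 chains × 20,000 kept
  iterations (burn-in 5,000); the simulation studies in the test suite use
  2 × 2,500 on networks of 3–4 interventions, 50 replicates for coverage
  and 20 for the refit oracle. These sizes give split-Rhat ≈ 1.00 on the
  fixtures and Monte-Carlo error well inside the tolerances checked.
* **Ties.** A tie for the optimal intervention is broken towards the lowest
  code, with a warning (relevant only for degenerate inputs).
* **Near-zero influence denominators.** Candidate thresholds with
  $|u_{a,j} - u_{k^\*,j}| < 10^{-12}$ are skipped; rivals whose influence
  matches the incumbent's cannot be promoted by that data point.
* **Degenerate variances.** A non-positive likelihood variance names the
  offending data point and aborts.
* **Perturbation convention.** The refit oracle shifts a study's
  non-baseline arm log-odds, holding the denominator fixed, after any
  continuity correction — the same data the fit would see.

## Known limitations

* The source analyses the fixtures replicate additionally adjusted for
  non-randomised designs; that down-weighting is out of scope here, and the
  handful of marginal robustness calls involving the non-RCT studies of the
  poisoning network (notably its cluster non-RCT) can land on the other
  side of the robust/non-robust boundary as a result.
* Study-level threshold rows require two-arm studies (all fixture studies
  are two-arm); multi-arm studies are supported in the NMA itself but their
  study-level data points are not defined here.
* The linear threshold approximation degrades for biases far outside the
  range of the data; the refit oracle is the arbiter where it matters.
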