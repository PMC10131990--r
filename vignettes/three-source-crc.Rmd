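---
title: "Three-source capture-recapture population size estimation with crc3s"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-source capture-recapture population size estimation with crc3s}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hidden populations — here, men who have sex with men (MSM) in Rwanda —
have no sampling frame, so their size must be inferred from the overlap
between independent encounters with the population. In a three-source
capture-recapture (3S-CRC) design, each member of the population can be
"captured" on up to three occasions (a tagging-object distribution, a
service-provision round, and a respondent-driven sampling survey). Each
observed individual contributes a capture history: a binary pattern of
length $k = 3$, with the all-zero pattern structurally unobservable. The
$2^k - 1 = 7$ observable counts, together with a model for capture
behaviour, identify the number $n_0$ of never-captured members and hence
the population size $N = n + n_0$.

`crc3s` implements the full workflow: construction and validation of
capture-history tables from published marginal tallies, a Gibbs sampler
for the Bayesian nonparametric latent-class capture-recapture model,
classical comparators, recruitment-homophily and convergence diagnostics,
the study's sample-size calculators, and generative models for synthetic
capture and recruitment data. The `analysis/` scripts in the source
repository run the reproduction end to end.

## From published tallies to tables

Published reports give per-occasion totals $n_1, n_2, n_3$, pairwise
recaptures $n_{12}, n_{13}, n_{23}$ and the triple overlap $n_{123}$, per
stratum. `table_from_marginals()` recovers the seven cells by
inclusion-exclusion, e.g. $|100| = n_1 - n_{12} - n_{13} + n_{123}$.
Published marginals can be mutually inconsistent: the bundled Western
province row implies a *negative* count of $-17$ for the pattern `010`
(captured in round two only). How the original analysis handled this is
not stated anywhere we can check, so both policies are provided:
`policy = "strict"` raises an error naming the offending cell, and
`policy = "clamp"` (the reproduction default) sets the cell to zero,
warns, and records the deficit on the returned table. Clamping yields a
fittable table while keeping the data problem visible in every export.

```{r}
library(crc3s)
m <- rwanda_msm_marginals()
table_from_marginals(m$National)
```

## The latent-class model

Each population member belongs to an unobserved class $z_i = k$ with
probability $\pi_k$; within class $k$, captures are independent across
occasions with occasion-specific probabilities $\lambda_{jk}$:
$$P(x \mid \pi, \lambda) = \sum_k \pi_k \prod_j
  \lambda_{jk}^{x_j} (1-\lambda_{jk})^{1-x_j}.$$
The class weights follow a truncated stick-breaking (Dirichlet-process)
prior, $V_k \sim \mathrm{Beta}(1, \alpha)$ with
$\pi_k = V_k \prod_{l<k}(1-V_l)$ and $V_{K^*} = 1$, with a
$\mathrm{Gamma}(a_\alpha, b_\alpha)$ hyperprior on the concentration
$\alpha$; each $\lambda_{jk}$ has a $\mathrm{Beta}(1,1)$ prior. The
population size receives the scale-invariant prior $p(N) \propto 1/N$,
handled by negative-binomial augmentation: given the current parameters,
the probability of an all-zero history is
$p_0 = \sum_k \pi_k \prod_j (1-\lambda_{jk})$ and
$n_0 \mid \cdot \sim \mathrm{NegBin}(n, 1-p_0)$.

Defaults follow the production configuration of this model family:
$K^* = 5$, $a_\alpha = b_\alpha = 0.25$, 10,000 kept draws after a
burn-in of 10,000 sweeps with thinning 1,000. All of these are exposed in
`lcmcr_config()`; desk-scale analyses use shorter chains (the compiled
sweep makes $10^6$ sweeps a matter of seconds).

One Gibbs sweep: (1) draw $n_0$; (2) allocate the observed pattern counts
and the $n_0$ zero histories to classes from multinomial full
conditionals — collapsed per distinct pattern rather than per individual,
which leaves the stationary distribution unchanged and is far cheaper;
(3) update every $\lambda_{jk}$ from its Beta full conditional, counting
augmented individuals; (4) update the sticks from
$\mathrm{Beta}(1 + m_k,\ \alpha + \sum_{l>k} m_l)$; (5) update $\alpha$
from its Gamma full conditional. $V$ and $\lambda$ are clipped to
$[10^{-12}, 1-10^{-12}]$; a non-finite state aborts with the iteration
index. Runs are bit-reproducible under a fixed `seed`.

### Validation of the sampler

The sampler is checked against independent oracles in the test suite:

* **Exact enumeration at $K^* = 1$.** With one class, $\lambda$
  integrates out analytically and the marginal posterior of $N$ can be
  enumerated; the sampler's median and quantiles match to a fraction of
  a percent.
* **Brute force at $K^* = 2$.** On a tiny table, importance sampling
  from the prior (with $\alpha$ pinned) recovers the exact posterior of
  $N$; the Gibbs quantiles coincide.
* **Closed-form comparators.** On homogeneous simulated data the
  single-class fit agrees with the Chapman estimator (two occasions) and
  the profile-likelihood independence MLE (three occasions) within
  stochastic tolerance.
* **Calibration.** On data simulated from a single-class scenario at
  $N = 18{,}000$, the 95% credible set covers the truth in about 97% of
  replicates (`analysis/05_power_sim.R`).

## Weak identifiability at three occasions — a central finding

With $k = 3$ occasions the seven observable cells carry six free
proportions plus $n$. A latent-class model with $K \ge 2$ classes already
has at least as many parameters, so the likelihood is saturated on the
observable table and the never-captured probability $p_0$ — hence $N$ —
is identified only through the model's low-rank structure (for $K = 2$,
the rank-2 completion of the missing cell of the $2^3$ tensor). The
posterior of $N$ is therefore ridge-like and strongly prior-influenced:
for the bundled national table it is bimodal, with a dominant basin near
$N \approx 6{,}900$ (moderate heterogeneity) and a minor basin near
$N \approx 18{,}000$ (a large, rarely captured class), holding only a few
percent of posterior mass. We verified this with three mutually
independent methods — the Gibbs sampler itself, a random-walk
Metropolis-Hastings sampler on the marginalized conditional likelihood,
and a ten-rung parallel-tempering run — all in agreement.

Two practical consequences:

* **The study's reported medians are not recoverable from its printed
  tallies under this model.** The reported national median (18,100) and
  the provincial medians (except Northern) sit in or beyond the minor
  basin; chains initialized there collapse back to the dominant basin.
  Extensive prior and kernel variants (alternative readings of the
  concentration hyperprior, stick orientation, truncation level,
  U-shaped capture priors, per-class zero imputation) did not produce
  the reported set either. `analysis/02_fit_pse.R` reports what the
  model actually supports: national median near 7,000 with a long upper
  tail whose 95% HDI can extend past 18,000.
* **Frequentist coverage degrades under heterogeneity.** In the
  two-class recovery simulation (`analysis/05_power_sim.R`), the
  equilibrium posterior centres below the true $N$ and the 95% HDI
  covers the truth in well under half of replicates. This is a property
  of the model at $k = 3$, not a sampler defect — the same scenarios
  with a single class are covered at the nominal rate. More capture
  occasions are the structural remedy.

Because of the two basins, chains should be run long (the default
analysis scripts use 50,000 burn-in sweeps and 5,000 kept draws thinned
by 300) and checked with `geweke_z()` and `trace_export()`.

## Credible sets

`credible_set()` implements both the highest-density interval (the
shortest contiguous window over the order statistics; ties broken toward
the smallest lower bound) and the central equal-tail interval. HDI is the
reporting default, matching field practice for skewed population-size
posteriors; for strongly right-skewed draws its upper bound is smaller
than the equal-tail bound.

## RDS diagnostics

The third capture is a respondent-driven sampling survey, so dependence
between recruitment and prior-capture status would violate the
independence assumptions. `recruitment_homophily()` computes
$H = \text{observed}/\text{expected}$, where observed counts
recruiter-recruit pairs sharing the attribute and the random-mixing
expectation accumulates, per edge, the recruit-population share of the
recruit's own attribute value (in aggregate $n_\text{edges}\sum_g s_g^2$
for recruit shares $s_g$). Two conventions circulate for the
expectation — recruiter-share and recruit-share accumulation; they agree
in aggregate expectation under random mixing, and we adopt the
recruit-share form, which reproduces the worked example in our test
suite and keeps $H = 1$ interpretable as "no dependency". Seeds recruit
but are never counted as recruits. `geweke_z()` (first 10% vs last 50%,
AR-spectral long-run variances) and `trace_export()`
(Freedman-Diaconis histogram bins) cover chain convergence.

## Sample-size calculators

Both of the study's calculators are the standard proportion-precision
formula $n = \mathrm{deff}\, z^2 p(1-p)/w^2$ with an inflation
$1/(1-\text{adjust})$, rounded half-up by default (ceiling available,
since field practice often rounds up). With the RDS inputs (design
effect 1.5, precision 0.025, 10% nonresponse) the published provincial
sizes are reproduced exactly for four of five provinces (1027, 141, 308,
121; Western computes to 613.67 → 614 against a printed 613). For the
first two capture rounds (precision 0.005, 15% loss) the published
counts are *not* reproduced by the stated inputs (e.g. the largest
stratum computes to 811 against a printed 803); the convention actually
used is not recoverable, so those values are documented but not asserted.

## Synthetic data

`simulate_captures()` is the generative twin of the fitted model: class
membership from the weights, independent Bernoulli captures, all-zero
histories dropped, truth returned alongside for recovery tests. It
enforces a closed population (no entry/exit between occasions) and does
not model tag misidentification or misreporting — the Western
inconsistency suggests such error exists in real data, but no rate is
published to calibrate it, so passing recovery tests says nothing about
robustness to measurement error. `simulate_chain()` grows a coupon
forest from seeds (default three coupons, 85% return, matching the
15% loss used in the design calculations) with a tunable assortativity
$h$: a recruit copies the recruiter's attribute with probability $h$,
otherwise draws from the population shares, so $h = 0$ calibrates the
homophily statistic's null and $h = 1$ its maximum.

## Numerical choices

* Inclusion-exclusion and pooling are exact integer arithmetic;
  marginal/table round-trips are property-tested.
* The independence MLE profiles out the capture probabilities and
  maximizes the one-dimensional profile likelihood over
  $[n, 100n]$ by `stats::optimize`, falling back to the boundary when
  the profile is monotone (everyone captured everywhere).
* Percentages are rounded half-up to two decimals to match the printed
  style of survey reports (`round_half_up()`), not banker's rounding.
* Per-stratum seeds are derived deterministically from the run seed, so
  multi-stratum runs are reproducible as a whole yet independent across
  strata.

## Known limitations

* $N$ is weakly identified at three occasions (see above); reported
  intervals are prior-sensitive, and comparisons across models with
  different priors are not meaningful.
* No covariate-dependent or behavioural (trap-shy) capture models; no
  open-population dynamics.
* Full RDS estimation (RDS-II weights, successive-sampling estimates,
  bottleneck diagnostics) is out of scope; only the homophily dependency
  check is provided.
* Census denominators for proportion estimates are user inputs; none are
  bundled.
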