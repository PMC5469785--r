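---
title: "A multinomial-mixture removal model for chemical eradication programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multinomial-mixture removal model for chemical eradication programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An invasive-ant eradication program combines two removal processes: monthly
sticky-trap monitoring, which captures (and thereby removes) workers, and
pesticide (toxic bait) applications, which kill them unobserved. When
captures fall to zero the managers must decide whether the population is
gone or merely undetected, and when continued monitoring stops being worth
its cost. `eradmix` implements a removal-protocol multinomial-mixture model
for this situation, its Bayesian fit, the derived eradication-probability
declaration criteria, and a minimum-expected-cost stopping rule, together
with an individual-based simulator of the whole monitoring program.

## The observation model

Each month, every living individual at point $i$ first dies from the bait
with probability $d_{t,i}$ and, if it survives, is captured with probability
$c_{t,i}$. The within-month order — death strictly before capture — is the
model's single canonical ordering: the probability of first capture at the
first survey is $\pi'_{1,i} = (1-d_{1,i})\,c_{1,i}$. Over the monitoring
horizon an individual's fate partitions exhaustively into

* first removal by capture at survey $t$:
  $\pi'_{t,i} = \phi_{t-1,i}(1-d_{t,i})c_{t,i}$,
* first removal by death at survey $t$: $\delta_{t,i} = \phi_{t-1,i}d_{t,i}$,
* neither, through survey $t$:
  $\phi_{t,i} = \prod_{k\le t}(1-d_{k,i})(1-c_{k,i})$,

with $\phi_{0,i}=1$ and, per point,
$\sum_t \pi'_{t,i} + \sum_t \delta_{t,i} + \phi_{T,i} = 1$. The observed
counts follow

$$y_{t,i} \sim \mathrm{Multinomial}\!\left(\pi'_{t,i}/\textstyle\sum_k
\pi'_{k,i},\; n_i\right), \qquad
n_i \sim \mathrm{Binomial}\!\left(\textstyle\sum_k \pi'_{k,i},\; N_i\right),
\qquad N_i \sim \mathrm{NegBin}(\mu, \sigma),$$

where $n_i = \sum_t y_{t,i}$ and the negative binomial has variance
$\mu + \mu^2/\sigma$. Two observation corrections apply:
$c_{t,i} = c'_t \cdot hold_{t,i}$ (a lost trap detects nothing) and
$d_{t,i} = d' \cdot chem_{t,i}$ (no bait, no pesticide death). A lost trap
does **not** protect an ant from the bait — only detection is zeroed.
Detection can optionally follow a complementary log-log temperature
regression $c'_t = 1-\exp(-\exp(\beta_0+\beta_1\,\mathrm{Temp}_t))$; the
default is a constant $c'$, because the temperature coefficient was not
significant in the motivating program and the constant model is the one
whose estimates the package's synthetic worlds are calibrated to.

Setting the chemical term off ($d' \equiv 0$) recovers the original
capture-only removal model, $\pi_{t,i} = \prod_{k<t}(1-c_{k,i})\,c_{t,i}$,
as a special case; the fit, survivor and declaration pathways all accept
this variant.

## Likelihood, priors and sampler

Because the negative binomial is closed under independent binomial thinning,
the latent $N_i$ integrates out in closed form:
$n_i \sim \mathrm{NegBin}(\text{size}=\sigma,\ \text{mean}=p_i\mu)$ with
$p_i = \sum_t \pi'_{t,i}$. `marginalLogLik()` uses this closed form; the
test suite verifies it against brute-force truncated summation over $N$
(tail mass $<10^{-12}$) on randomized instances. Joint products are
accumulated in log space so long horizons cannot underflow; a point with
$p_i = 0$ but $n_i > 0$ returns $-\infty$ (so a sampler rejects the
proposal) rather than raising an error.

`fitEradication()` runs Metropolis-within-Gibbs: random-walk Metropolis on
$(\mathrm{logit}\,c', \mathrm{logit}\,d', \log\mu, \log\sigma)$ against the
marginalized likelihood, with an exact conditional draw of every $N_i$ at
each retained iteration,
$$N_i - n_i \sim \mathrm{NegBin}\!\left(\text{size}=n_i+\sigma,\;
\text{prob}=1-(1-p_i)\frac{\mu}{\mu+\sigma}\right),$$
so $N_i \ge n_i$ holds by construction. Priors are uniform on $(0,1)$ for
the probabilities and gamma for $\mu$ and $\sigma$; the gamma
hyperparameters are not pinned down by the program's published description,
so the package defaults to shape = rate = 0.01 (near-non-informative,
configurable through `priorSpec()`). With the temperature covariate on, the
regression coefficients get Normal(0, 10) priors.

Proposal scales adapt during burn-in toward roughly 30% acceptance (a
Robbins–Monro-style batch update, step size shrinking with iteration) and
are frozen afterwards, keeping the post-burn-in chain a valid Markov chain.
Chains start from independent overdispersed draws: $c'$ uniform on
(0.1, 0.9), $\mathrm{logit}\,d'$ uniform on $(-7, -1)$, $\log\mu$ around the
observed per-point mean count $\pm$ a factor of $e$, $\log\sigma$ on
$(-1, 1.5)$, retried until the posterior density is finite. Pure gamma(0.01,
0.01) prior draws are numerically degenerate as starting points, which is
why the initialization uses these bounded overdispersed ranges instead.
Convergence is monitored with the classic Gelman–Rubin $\hat R$ (`rhat()`,
at least two chains required). The sampler defaults
(22,000 iterations, 2,000 burn-in, thinning 10, three chains) are a
ten-fold desk-scale reduction of the published analysis' settings (220,000 /
20,000 / 100, three chains), chosen so the recovery tests fit a desk-scale
compute budget; the full settings are one `mcmcConfig()` call away.

## Identifiability: why program structure matters

With $c'$, $d'$ constant and bait applied everywhere always, the model is
*exactly* unidentified in one direction: the conditional multinomial cells
reduce to $r^{t-1}/\sum_k r^{k-1}$ with $r=(1-c')(1-d')$, and the $n_i$
marginal depends only on the product $p_i\mu$, so the likelihood is a
function of $(r, p\mu)$ alone — three parameters, two identified functions.
A flat prior on $d'$ then spreads posterior mass along the ridge, dragging
the posterior mean of $c'$ well below the truth and inflating the abundance
estimate. This is not a sampler artifact; it is visible in the profile
likelihood and survives paper-length chains.

What identifies $d'$ in a real program is *variation in bait exposure while
ants are still present*: plots whose applications started late (months of
capture-only removal at full abundance pin down $c'$ directly), and the
six-month stopping rule turning bait off plot-by-plot. The simulator
therefore groups points into plots (default: three consecutive points,
emulating the program's ~1-ha plots) and supports per-point delayed starts;
the larger-site preset (`jonanLike()`) includes one plot whose applications
begin 11 months late, matching the program's schedule. Users fitting data
from a program with uniform, uninterrupted bait application should expect —
and the vignette is explicit about this — a wide, prior-driven posterior for
$d'$ and a correspondingly biased $c'$; the package will not manufacture
information the design does not contain.

For the same reason, per-site abundance is best estimated by fitting all
sites of a program jointly with shared $(c', d')$, which is how the
motivating analysis reports a single detection/death pair for two sites;
`poolSites()` assembles such joint datasets.

## Eradication declaration

`survivorDraws()` redraws, for each retained posterior draw, survivor counts
$s_{t,i} \sim \mathrm{Binomial}(N_i, \phi_{t,i})$ — each month an
independent marginal draw, matching the model's survivor-posterior
construction (no monotone path is enforced within a draw) — and accumulates
site totals $S_t$. The presence probability is
$Ps_t = \Pr(S_t \ge 1)$, the fraction of draws with at least one survivor.
One wording note: the source description writes the quantity as
$\Pr(S_t < 1)$, which is textually the probability of *absence*, but uses it
as the probability that ants are still alive and declares eradication when
it falls below 0.05/0.01; the package implements the internally consistent
reading, presence $= \Pr(S_t \ge 1)$.

`declarationTimes()` applies a *sustained*-crossing rule: the declaration
month for threshold $\alpha$ is the first month from which $Ps_t < \alpha$
holds for every later month. Monte-Carlo noise can push a single month's
$Ps$ below threshold transiently; the sustained rule makes the declared
month invariant to such blips. A threshold never sustainedly crossed yields
an explicit "not reached" result, not an error. $Ps$ is pooled over all
points of a site ($S_t = \sum_i s_{t,i}$); per-point summaries can be
obtained by keeping the per-point survivor array.

## The stopping-cost rule

With $Cs$ the monthly monitoring cost and $Ce$ the cost of declaring
eradication while ants persist, the net expected cost of stopping after $m$
detection-free months is
$$\mathrm{NEC}(m) = (m-1)\,Cs + \Pr(\text{present after } m)\cdot Ce.$$
The persistence series is the calendar $Ps$ re-indexed to months since the
last sighting: $m=1$ is the first monitoring month *after* the last
detection, so `presenceAfterLastDetection()` maps
$\mathrm{presence}(m) = Ps_{\text{last}+m}$. (The source description never
states this alignment explicitly; this is the package's choice and is used
consistently everywhere.) `necCurve()` returns the whole curve and its
minimizer, breaking ties toward the smaller month — stopping earlier is
weakly cheaper under any unmodelled discounting. The program's extra
pesticide applications in the first six months after a sighting
(~JPY 10,000/month) can be added as a per-month surcharge vector; the
default leaves it off. `costSensitivity()` recomputes the optimal month over
a grid of $Ce/Cs$ ratios (the motivating analysis explored 1:25–1:200); for
a non-increasing persistence series the optimal month is non-decreasing in
the ratio, which the test suite checks by exhaustive scan.

## The simulator and what a green test establishes

`simulateSite()` is individual-based: it draws $N_i \sim
\mathrm{NegBin}(\mu,\sigma)$, then walks every individual through monthly
death-then-capture trials, recording captures, deaths and survivors so that
per point and month `captures + deaths + survivors = N_i` exactly. Traps are
lost independently at `trapLossRate` per trap-month (default 0.02 — the
program reported losing most traps once, in a month that is conventionally
excluded, but gave no ongoing rate; 0.02 is a configurable judgment call).
Bait application follows the program's six-month rule at plot level (applied
while the plot had a detection within the previous six months; the program's
start counts as a detection), an always-on policy, or an explicit matrix.
The presets pin the published scale: 59 monthly surveys; 23 points with
expected initial total 1400 (`tokaiLike`), 28 points with 4200
(`jonanLike`, including the delayed-start plot), and the pooled 51-point
program (`programLike`, NegBin mean 110 per point — exactly the pooled
average (1400+4200)/51). $\sigma = 1$ is a default chosen once: the raw
field data that would pin per-point heterogeneity were never released.

The simulator emulates the *model's* world plus the program's decision
rules. It does not emulate spatial spread, colony budding or queen/brood
stage structure, reinvasion, or temperature-driven activity cycles, so a
green recovery test establishes that the fit recovers the parameters of the
stated removal process at the program's scale — not that the model is a
complete description of Argentine-ant biology. Because the six-month rule
makes bait exposure depend on past observed counts, the realized `chem`
matrix is data-dependent; conditioning the likelihood on the realized matrix
remains exact, since the rule is a deterministic function of the observed
history.

## Numerical choices and degenerate inputs

* All joint survival products run in log space; conservation
  $\sum\pi' + \sum\delta + \phi_T = 1$ is verified to $10^{-12}$ after
  exponentiation.
* Impossible data ($n_i > 0$ where capture is impossible) give $-\infty$
  log-likelihood by convention; strict input validation can be disabled for
  sampler internals only.
* All-zero datasets fit without error; $c'$ is then essentially
  prior-driven and the abundance posterior concentrates near zero-consistent
  values.
* Declaration with a never-crossed threshold returns "not reached";
  `nec()` rejects $m < 1$; exact NEC ties resolve to the earlier month.
* Every stochastic routine takes an explicit seed, and identical seeds give
  bit-identical results (tested).

## Known limitations

* $d'$ is only as identifiable as the bait-exposure design makes it
  (see above); with uniform exposure, expect a prior-dominated $d'$
  posterior.
* The NEC rule takes the persistence series as fixed posterior output; it
  does not propagate posterior uncertainty in $Ps$ into the cost curve
  beyond using the posterior probability itself.
* One shared $\mu$ serves all points of a fitted dataset; strong between-
  site abundance differences are absorbed by the negative binomial's
  dispersion rather than modelled hierarchically.
* Costs are plain decimal quantities with no discounting or currency
  handling.
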