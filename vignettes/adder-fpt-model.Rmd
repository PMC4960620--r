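---
title: "A first-passage-time model of bacterial cell-size control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A first-passage-time model of bacterial cell-size control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adderfpt)
```

## The model

Many bacteria grow exponentially and divide by an *adder* rule: the volume
added between birth and division has a fixed distribution, independent of the
size at birth. `adderfpt` implements a mechanistic stochastic explanation of
this rule. A newborn cell of size $V_b$ grows as $V(t) = V_b e^{\alpha t}$.
A *timekeeper* protein (FtsZ- or DnaA-like in its dynamics, though the model
is agnostic about the molecule) starts from zero copies at birth and is
expressed in bursts: burst events arrive as an inhomogeneous Poisson process
with rate $r(t) = k_m V(t)$ — the volume-proportional rate that keeps
concentrations of ordinary proteins constant in a growing cell — and each
event adds $B_i$ molecules, i.i.d. with mean $b$ (geometric by default).
Division fires when the accumulated copy number first reaches a sharp
threshold $X$, after which the protein is degraded or deactivated. The
division time is therefore a first-passage time (FPT), and the added volume
is $\Delta V = V_b(e^{\alpha\,FPT} - 1)$.

Two changes of variable make the model tractable and the simulator exact:

* **Burst count.** $N$, the number of bursts needed to reach $X$, has
  pmf $P(N = n) = P(S_n \ge X) - P(S_{n-1} \ge X)$ with $S_n = B_1 + \dots +
  B_n$. It depends only on $X$ and the burst law.
* **Volume coordinate.** The cumulative arrival rate is $R(t) =
  (k_m V_b/\alpha)(e^{\alpha t} - 1) = (k_m/\alpha)\,\Delta V(t)$: measured
  in *added volume*, arrivals are homogeneous Poisson with rate $\lambda =
  k_m/\alpha$ per size unit. Hence $\Delta V \mid N = n \sim
  \mathrm{Gamma}(n, \lambda)$, and

$$f_{\Delta V}(v) \;=\; \sum_{n \ge 1} P(N = n)\,
  \frac{\lambda^n v^{n-1} e^{-\lambda v}}{(n-1)!},$$

which contains no $V_b$: the adder property is structural, not asymptotic.
The FPT density follows by the time change, $f_{FPT}(t) = r(t)\sum_n P(N=n)
\,\mathrm{Pois}(n-1; R(t))$; it *does* depend on $V_b$, with mean decreasing
and $CV^2$ increasing in $V_b$. Moments of $\Delta V$ come from the
compound-sum identities $E[\Delta V^j] = E[N(N+1)\cdots(N+j-1)]/\lambda^j$;
$CV^2$, skewness, and every mean-scaled moment
$E[\Delta V^j]/E[\Delta V]^j$ involve only moment ratios of $N$, so they are
invariant to $\alpha$ and $k_m$ — the scale-invariance behind the collapse
of mean-rescaled added-size histograms across growth conditions, while
$E[\Delta V] = E[N]/\lambda$ itself is linear in $\alpha$.

## Parameters and defaults

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `k_m` | burst arrival rate, concentration sense | 1/(min · size unit) | 0.13 |
| `alpha` | exponential growth rate | 1/min | 0.03 |
| `b` | mean burst size (geometric) | molecules | 5 |
| `X` | division threshold | molecules | 65 |
| `V_b` | newborn size | size units | 1 |

The defaults are the reference parameterization used throughout the tests
and the acceptance script; they put roughly $E[N] \approx 14$ bursts and
$E[\Delta V] \approx 3.2$ size units per cycle, in the regime of interest
for enteric bacteria growing with ~23 min doubling time. Sizes are abstract
"size units": for rod-shaped cells at fixed width, length and volume are
proportional, so the same model serves either convention.

The geometric burst law defaults to the *shifted* variant on $\{1, 2,
\dots\}$ with mean $b$: every transcription event yields at least one
protein, which guarantees $N \le X$ and avoids degenerate tails from null
bursts. The $\{0, 1, \dots\}$ variant is available
(`burst_geometric(b, "nonnegative")`), and both have mean $b$, so headline
results do not depend on the choice.

## Numerical choices

* $P(S_n \ge X)$ uses negative-binomial survival identities for geometric
  bursts and convolution with absorption at $X$ for tabulated laws; both are
  cross-checked in the tests against an independent brute-force convolution.
* The burst-count series is truncated adaptively so the neglected mass is
  below `tail_bound` (default $10^{-10}$), with a hard cap of 10,000 terms
  that raises an error instead of silently truncating.
* `fpt_pdf` is assembled in log space per mixture term: in the far tail
  $r(t)$ overflows while the Poisson weight underflows, and only their
  product is finite.
* `fpt_moments` integrates by default in the unit-rate coordinate
  $w = \lambda v$, where the integrand keeps $O(1)$ scale for any $\alpha$;
  the direct time-domain quadrature is retained as an independent
  cross-check and the two agree to $10^{-6}$ relative or better. Quadrature
  failures raise errors, never silent `NaN`s.
* $\alpha = 0$ is an explicit homogeneous-Poisson branch (Erlang-mixture
  closed forms), not a division by zero; it exists for limit checks, and the
  $\alpha \to 0$ limit of the general code matches it to $10^{-4}$.

## The simulator

The baseline sampler is exact, with no time discretization: it draws burst
sizes sequentially until the threshold is crossed (giving $N$ and the final
count including overshoot) and then $\Delta V \sim \mathrm{Gamma}(N,
\lambda)$, recovering the division time via the logarithmic time change.
Four deviation mechanisms modify this:

* **Partial degradation** (`retention_kappa`): a fraction of the final count
  survives division. Within lineages daughters inherit
  $\mathrm{Binomial}(\lceil\kappa\,\mathrm{final}\rfloor, 1/2)$ molecules.
  For *isolated* cycles at a prescribed newborn size the inherited count
  must be chosen: because production is volume-proportional, an undegraded
  pool settles over generations to a fixed birth *concentration*, so the
  package draws carryover as $\mathrm{Binomial}(X, \kappa V_b / (2\bar\Delta))$
  with $\bar\Delta$ the baseline mean added volume (the stationary mean
  newborn size at the adder fixed point). Larger newborns start closer to
  threshold and add less volume: a negative correlation.
* **Volume-dependent bursts** (`V_ref`): the geometric mean is re-evaluated
  at the volume at the moment of each burst, $b(V) = b_0 V/V_{ref}$
  (negative correlation).
* **Saturating rate** (`V_sat`): $r(V) = k_m V/(1 + V/V_{sat})$, simulated
  by exact thinning of the unsaturated proposal process (positive
  correlation).
* **Soft threshold** (`H`, `c`): division fires through the finite hazard
  $h(x) = c\,(x/X)^H$ — the simplest monotone family with the sharp
  threshold as $H \to \infty$ — simulated by exact competing exponentials
  between the division hazard (constant between bursts) and the next burst
  arrival (positive correlation).

Lineages follow one daughter with symmetric halving of the division size
(the standard assumption for these organisms; the ratio is exposed for
sensitivity checks only). A single RNG stream drives the whole lineage
table, vectorized across lineages per generation; runs are bit-reproducible
for a fixed seed and configuration (including the lineage count).

### Initiation-triggered division

In the replication-initiation variant the timekeeper accumulates *per origin
of replication*: each burst adds $B/\theta$ to the per-origin level, which
triggers initiation at $X$; the pool then resets and $\theta$ doubles
(origins fire synchronously). Division follows each initiation after the
constant delay $T = C + D$, halving both size and $\theta$; partitioning
noise in the timekeeper at division is neglected, as is any growth-rate
dependence of $T$. The per-origin volume $w = V/\theta$ is then continuous
across divisions and halves exactly at initiations, so the recorded
per-origin added volume $w_{i+1} - w_i/2$ is the initiation-level analogue
of $\Delta V$ and has (approximately) the same mean. The division-to-
division mean is inflated by $e^{\alpha T}$,
$\langle\Delta V^*\rangle = \langle\Delta V\rangle e^{\alpha T}$ — linear in
$\alpha$ for slow growth, exponential for fast growth. Whether an
origin-number prefactor multiplies this mean is left as an explicit argument
(`origin_prefactor`, default 1). Overlapping replication rounds (delay
longer than the doubling time) are handled by a division queue whose depth
is bounded; exceeding it raises an error rather than accumulating silently.

## Analysis protocols

`bin_by_newborn_size` uses half-open bins (last closed) and reports, never
drops, out-of-range records. `cv2_bootstrap` uses the percentile bootstrap;
for this skewed ratio statistic the interval undercovers at small samples
(~92% at n = 500 for a nominal 95%) and reaches the nominal rate by
n ≈ 2000, which the tests verify. Note that the division-time $CV^2$ is a
per-size property: binning cells whose sizes vary widely *within* a bin
confounds it with the variation of the mean division time across the bin,
so per-bin noise comparisons should use narrow bins. `collapse_distance`
takes pairwise two-sample KS tests at the 1% level (conservative, because
several pairs are compared); `adder_trend_test` uses a Spearman statistic
against a permutation null — distribution-free, with the binned means
available alongside for figure-style summaries.

## What the generator does and does not emulate

Simulated tables reproduce the model's own statistical structure:
exponential single-cell growth at a *common, fixed* $\alpha$, burst-driven
timekeeper accumulation, sharp (or specified) division rules, symmetric
division. They do not include measurement noise, cell-to-cell growth-rate
variability, asymmetric or noisy size partitioning, mother-machine ageing
effects, or any coupling between consecutive cycles beyond what a mechanism
specifies. Passing the package's checks therefore demonstrates internal
consistency of the implementation with the model, not that real lineage
data obey the model; with real data, the growth-rate column is taken as
provided (per-cell estimation of $\alpha$ is out of scope).

## Scales used in the bundled checks

The test-suite and acceptance protocols run at desk scale: 10,000-cell
single-cycle experiments (200,000 for moment validation), 10,000 lineages
by 8 generations, 3,000–4,000 initiation cycles per growth rate, and
999-permutation / 400–1,000-resample resampling tests, all seeded. These
sizes put Monte-Carlo standard errors well below the effect sizes being
checked.

## Known limitations

* The added-volume law degenerates as $\alpha \to 0$ (cells stop growing);
  `added_volume_distribution` refuses $\alpha = 0$ rather than guessing.
* The volume-dependent-burst mechanism is defined for geometric bursts only.
* The soft-threshold mechanism has no analytic layer; it is
  simulation-only, as is any mechanism other than the baseline.
* Mechanism parameter defaults ($\kappa = 0.5$, $V_{sat} = 5$, $H = 4$,
  $c = 1$, $V_{ref} = 1$) are choices that reproduce the qualitative
  correlation signs, not fits to any particular dataset.
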